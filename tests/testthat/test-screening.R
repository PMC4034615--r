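make_totals_table <- function(totals) {
  count_table(data.frame(sample = sprintf("s%d", seq_along(totals)),
                         otuA = as.integer(totals)))
}

test_that("low-coverage outlier rule matches hand-computed z-scores", {
  # note a 2.5-SD rule can never fire with very few samples (for n
  # samples the largest attainable |z| is (n-1)/sqrt(n)), so the
  # fixture uses 21 samples with one extreme low-coverage sample
  totals <- c(rep(c(1000, 1100, 900, 1050), 5), 1)
  tbl <- make_totals_table(totals)
  res <- detect_outlier_samples(tbl)
  lt <- log(totals)
  z_hand <- (lt - mean(lt)) / sd(lt)
  expect_equal(res$z_score, z_hand)
  expect_true(z_hand[21] <= -2.5)
  expect_identical(res$sample[res$outlier], "s21")

  # zero variance: nobody is an outlier
  res2 <- detect_outlier_samples(make_totals_table(c(1000, 1000, 1000)))
  expect_false(any(res2$outlier))

  expect_error(detect_outlier_samples(make_totals_table(c(10, 0, 10))),
               "zero total")
  expect_error(detect_outlier_samples(make_totals_table(c(10, 20))),
               "at least 3")
})

test_that("outlier screening is invariant to relabeling and rescaling", {
  set.seed(21)
  totals <- round(exp(rnorm(30, log(1900), 0.6)))
  tbl <- make_totals_table(totals)
  base <- detect_outlier_samples(tbl)

  # common multiplicative factor shifts all logs equally
  scaled <- make_totals_table(totals * 7L)
  expect_equal(detect_outlier_samples(scaled)$outlier, base$outlier)

  # permutation of samples permutes the flags
  perm <- sample(length(totals))
  ptbl <- count_table(data.frame(sample = sprintf("s%d", perm),
                                 otuA = as.integer(totals[perm])))
  pres <- detect_outlier_samples(ptbl)
  expect_equal(pres$outlier[match(base$sample, pres$sample)],
               base$outlier)
})

test_that("a low-coverage sample among lognormal depths is flagged", {
  # depths like a typical run: lognormal around ~1,900, one sample
  # at ~256 stands out and is discarded
  set.seed(8)
  totals <- c(round(exp(rnorm(56, log(1900), 0.45))), 256)
  totals <- pmin(pmax(totals, 864), 5394)
  totals[57] <- 256
  res <- detect_outlier_samples(make_totals_table(totals))
  expect_true(res$outlier[57])
  expect_equal(sum(res$outlier), 1L)
})

test_that("quantifiable-OTU rule is inclusive at the 0.1% boundary", {
  # global total 100,000: 100 counts is exactly 0.1% (kept), 99 dropped
  big <- 100000L - 100L - 99L
  tbl <- count_table(data.frame(sample = c("s1", "s2", "s3"),
                                otuBig = c(big, 0L, 0L),
                                otuAt = c(100L, 0L, 0L),
                                otuBelow = c(99L, 0L, 0L)))
  res <- select_quantifiable_otus(tbl, min_fraction = 0.001)
  expect_true(res$kept[res$otu == "otuAt"])
  expect_false(res$kept[res$otu == "otuBelow"])

  # min_fraction 0 keeps everything; kept/dropped partition the ids
  all_kept <- select_quantifiable_otus(tbl, min_fraction = 0)
  expect_true(all(all_kept$kept))
  expect_setequal(res$otu, otu_ids(tbl))
})

test_that("raising min_fraction never grows the kept set", {
  tbl <- random_count_table(12, 20, seed = 5, lambda = 8)
  fracs <- c(0, 0.0005, 0.001, 0.005, 0.02, 0.1)
  kept <- lapply(fracs, function(f)
    with(select_quantifiable_otus(tbl, f), otu[kept]))
  for (i in seq_along(fracs)[-1])
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
})

test_that("preset screening keeps exactly the 7 quantifiable haplotypes", {
  d <- simulate_counts(orbicella_like_preset(), seed = 301)
  res <- select_quantifiable_otus(d)
  expect_setequal(res$otu[res$kept],
                  c("hapI", "hapII", "hapIII", "hapIV", "hapV",
                    "hapVI", "hapVII"))
})

test_that("chain autocorrelation flags slow random walks, not iid noise", {
  # build a fit-shaped object by hand: iid chains pass, AR(1) with
  # rho = 0.99 is flagged at lag 10
  n <- 600
  draws <- cbind(
    `I[otuA]` = ar1_chain(n, 0, seed = 1),
    `B[otuA:x]` = ar1_chain(n, 0, seed = 2),
    `I[otuB]` = ar1_chain(n, 0.99, seed = 3),
    `B[otuB:x]` = ar1_chain(n, 0, seed = 4))
  fake <- structure(list(draws = draws, otus = c("otuA", "otuB")),
                    class = "pln_fit")
  ac <- stats::acf(draws[, "I[otuB]"], lag.max = 10,
                   plot = FALSE)$acf[11]
  expect_gt(ac, 0.1)
  res <- flag_unreliable_otus(fake)
  expect_false(res$flagged[res$otu == "otuA"])
  expect_true(res$flagged[res$otu == "otuB"])
  expect_error(flag_unreliable_otus(fake, ac_lag = 100), "retained draws")
})

test_that("an OTU found in very few samples yields unreliable chains", {
  # sparse minor OTU: present in 6 of 57 samples only; its chains mix
  # poorly and the reliability screen discards it
  tr <- orbicella_like_preset()
  d <- simulate_counts(tr, seed = 77)
  m <- otu_matrix(d)
  sparse <- integer(nrow(m))
  set.seed(42)
  sparse[sample(nrow(m), 6)] <- rpois(6, 3) + 1L
  df <- dplyr::bind_cols(sample_factors(d),
                         tibble::as_tibble(as.data.frame(m)),
                         tibble::tibble(sparseX = sparse))
  tbl <- count_table(df[, c("sample", "species", "bank",
                            "hapII", "hapI", "sparseX")],
                     factors = c("species", "bank"))
  # the sparse OTU's low effective sample size warning is the very
  # phenomenon under test
  fit <- suppressWarnings(
    pln_fit(tbl, fixed = c("species", "bank"), iterations = 6600,
            burn_in = 600, thin = 10, seed = 5))
  res <- flag_unreliable_otus(fit)
  expect_true(res$flagged[res$otu == "sparseX"])
  expect_false(res$flagged[res$otu == "hapII"])
})
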