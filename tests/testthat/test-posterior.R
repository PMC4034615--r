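# a handmade fit object with known draws, for exercising the
# contrast arithmetic without MCMC noise
fake_fit <- function(drawsB, cells = c("A", "B"), otus = c("o1")) {
  n <- nrow(drawsB)
  X <- diag(length(cells))[, -1, drop = FALSE]
  dimnames(X) <- list(cells, cells[-1])
  units <- c(otus, ".sum")
  cols <- c(paste0("I[", units, "]"),
            paste0("B[", rep(units, each = ncol(X)), ":",
                   rep(colnames(X), length(units)), "]"))
  d <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (nm in colnames(drawsB)) d[, nm] <- drawsB[, nm]
  structure(list(draws = d, otus = units, cells = cells,
                 ref_cell = cells[1], X_cell = X,
                 design = list(sum_otu = TRUE, samples = "s1")),
            class = "pln_fit")
}

test_that("relative effects cancel shared shifts with the sum-OTU", {
  set.seed(1)
  b <- rnorm(200)
  # OTU effect identical to sum-OTU effect in every draw -> 0
  d1 <- cbind(`B[o1:B]` = b, `B[.sum:B]` = b)
  rel <- relative_effects(fake_fit(d1))
  expect_true(all(rel$effect_rel == 0))

  # adding a constant to both leaves the relative effect unchanged
  d2 <- cbind(`B[o1:B]` = b + 5, `B[.sum:B]` = rnorm(200) + 5)
  d3 <- d2; d3[, 1] <- d2[, 1] - 5; d3[, 2] <- d2[, 2] - 5
  expect_equal(relative_effects(fake_fit(d2))$effect_rel,
               relative_effects(fake_fit(d3))$effect_rel + 5 - 5)
})

test_that("contrast cardinality and antisymmetry hold", {
  set.seed(2)
  cells <- c("A", "B", "C", "D")
  otus <- c("o1", "o2", "o3", "o4")
  nmB <- as.vector(outer(cells[-1], c(otus, ".sum"),
                         function(cl, o) paste0("B[", o, ":", cl, "]")))
  d <- matrix(rnorm(300 * length(nmB)), 300,
              dimnames = list(NULL, nmB))
  fit <- fake_fit(d, cells = cells, otus = otus)
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), 4L * 6L)  # 4 OTUs x C(4,2) pairs

  # antisymmetry: recomputing with cells relabelled in reverse order
  # flips every mean difference
  for (k in seq_len(nrow(ct))) {
    a <- ct$condition_a[k]; b <- ct$condition_b[k]; o <- ct$otu[k]
    esum <- d[, paste0("B[.sum:", cells[-1], "]")] %*%
      t(fit$X_cell)
    eo <- d[, paste0("B[", o, ":", cells[-1], "]")] %*% t(fit$X_cell)
    colnames(esum) <- colnames(eo) <- cells
    dd <- (eo[, a] - esum[, a]) - (eo[, b] - esum[, b])
    dd_rev <- (eo[, b] - esum[, b]) - (eo[, a] - esum[, a])
    expect_equal(ct$mean_logdiff[k], mean(dd))
    expect_equal(dd_rev, -dd)
  }
  expect_true(all(ct$ci_low <= ct$mean_logdiff &
                    ct$mean_logdiff <= ct$ci_high))
  expect_true(all(ct$q_fdr >= ct$p_mcmc))
})

test_that("the MCMC p-value follows the add-one tail formula", {
  n <- 1000
  d <- cbind(`B[o1:B]` = rep(1, n), `B[.sum:B]` = rep(0, n))
  ct <- pairwise_contrasts(fake_fit(d))
  # all draws positive: p = 2 * (0 + 1) / (N + 1)
  expect_equal(ct$p_mcmc, 2 / (n + 1))

  set.seed(3)
  x <- rnorm(n, 0.2)
  ct2 <- pairwise_contrasts(fake_fit(cbind(`B[o1:B]` = x)))
  expect_equal(ct2$p_mcmc,
               min(1, 2 * min(sum(x > 0) + 1, sum(x < 0) + 1) / (n + 1)))
})

test_that("BH adjustment equals the step-up reference", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(bh_stepup_reference(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_stepup_reference(p))
  }
})

test_that("q values are monotone in p within a contrast table", {
  set.seed(6)
  nmB <- paste0("B[", rep(c("o1", "o2", "o3"), each = 1), ":B]")
  d <- matrix(rnorm(200 * 3, mean = rep(c(0, 0.3, 1), each = 200)),
              200, 3, dimnames = list(NULL, nmB))
  ct <- pairwise_contrasts(fake_fit(d, otus = c("o1", "o2", "o3")))
  o <- order(ct$p_mcmc)
  expect_true(all(diff(ct$q_fdr[o]) >= -1e-12))
})

test_that("highest-density intervals are shortest at the given mass", {
  set.seed(7)
  x <- c(rnorm(900), rnorm(100, 6))
  h <- hdi(x, 0.9)
  q <- quantile(x, c(0.05, 0.95))
  expect_lte(h[2] - h[1], unname(q[2] - q[1]) + 1e-12)
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.9)
})

test_that("abundance proportions track the planted composition", {
  d <- simulate_counts(orbicella_like_preset(), seed = 55)
  s <- screen_counts(d)
  fit <- pln_fit(s, fixed = c("species", "bank"), iterations = 3000,
                 burn_in = 600, thin = 4, seed = 55)
  props <- abundance_proportions(fit)
  dom <- props[props$otu == "hapII", ]
  expect_true(all(dom$mean_proportion > 0.85 &
                    dom$mean_proportion < 0.95))
  expect_error(abundance_proportions(fit, condition = "nope"),
               "Unknown condition")
})
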