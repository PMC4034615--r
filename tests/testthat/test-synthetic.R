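flat_truth <- function(n_samples = 40, lambda_log = 0, sigma2 = 0,
                       var_c = 0, n_otus = 1) {
  otus <- paste0("o", seq_len(n_otus))
  design <- tibble::tibble(sample = sprintf("s%04d", seq_len(n_samples)),
                           grp = rep_len(c("a", "b"), n_samples))
  eff <- matrix(0, n_otus, 2, dimnames = list(otus, c("a", "b")))
  synthetic_truth(intercepts = setNames(rep(lambda_log, n_otus), otus),
                  effects = eff, design = design, factors = "grp",
                  var_c = var_c, sigma2 = sigma2)
}

test_that("with all effects zero the counts are plain Poisson(1)", {
  tr <- flat_truth(n_samples = 1e5)
  d <- simulate_counts(tr, seed = 1)
  x <- otu_matrix(d)[, 1]
  expect_equal(mean(x), 1, tolerance = 0.02)
  expect_equal(var(x), 1, tolerance = 0.05)
})

test_that("lognormal noise inflates the mean by exp(sigma2/2)", {
  tr <- flat_truth(n_samples = 2e5, lambda_log = 0, sigma2 = 2)
  d <- simulate_counts(tr, seed = 2)
  expect_equal(mean(otu_matrix(d)[, 1]), exp(1), tolerance = 0.05)
})

test_that("identical seeds give identical tables, different seeds differ", {
  tr <- orbicella_like_preset()
  d1 <- simulate_counts(tr, seed = 10)
  d2 <- simulate_counts(tr, seed = 10)
  d3 <- simulate_counts(tr, seed = 11)
  expect_identical(otu_matrix(d1), otu_matrix(d2))
  expect_false(identical(otu_matrix(d1), otu_matrix(d3)))
})

test_that("the community preset matches its calibration targets", {
  tr <- orbicella_like_preset()
  shares <- numeric(0); in_range <- numeric(0); medians <- numeric(0)
  for (sd in 1:5) {
    d <- simulate_counts(tr, seed = sd)
    m <- otu_matrix(d)
    shares <- c(shares, sum(m[, "hapII"]) / sum(m))
    sums <- rowSums(m)
    in_range <- c(in_range, mean(sums >= 250 & sums <= 5400))
    medians <- c(medians, median(sums))
  }
  # dominant haplotype ~90% of all reads
  expect_true(all(shares > 0.85 & shares < 0.95))
  # >=90% of per-sample sums within the emulated coverage range
  expect_true(all(in_range >= 0.9))
  # median total near ~1,900
  expect_true(all(medians > 1000 & medians < 3500))
  # design: 2x2 factorial, 58 samples, three planted bank effects
  expect_equal(nrow(tr$design), 58L)
  expect_equal(nrow(tr$planted), 3L)
  expect_true(all(abs(tr$planted$logdiff) >= 1.0 &
                    abs(tr$planted$logdiff) <= 1.5))
})

test_that("reference sequences keep the requested pairwise divergence", {
  refs <- reference_sequences(4, length = 300, divergence = 0.04,
                              seed = 3)
  for (i in 1:3) for (j in (i + 1):4) {
    id <- seq_identity(refs[i], refs[j])
    expect_equal(id, 1 - 0.04, tolerance = 0.005)
  }
  # 2% divergence pair merges at a 97% threshold
  refs2 <- reference_sequences(2, length = 300, divergence = 0.02,
                               seed = 4)
  cat <- cluster_otus(tibble::tibble(sequence = unname(refs2),
                                     abundance = c(5L, 4L)))
  expect_equal(nrow(cat), 1L)
})

test_that("read simulation is reproducible and writes valid files", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  s1 <- simulate_reads(c(0.7, 0.3), n_samples = 2,
                       reads_per_sample = 50, error_rate = 0.01,
                       dir = dir1, seed = 5)
  s2 <- simulate_reads(c(0.7, 0.3), n_samples = 2,
                       reads_per_sample = 50, error_rate = 0.01,
                       dir = dir2, seed = 5)
  expect_identical(otu_matrix(s1$expected_counts),
                   otu_matrix(s2$expected_counts))
  r1 <- read_amplicon_file(s1$manifest$file[1], "x")
  r2 <- read_amplicon_file(s2$manifest$file[1], "x")
  expect_identical(r1$bases, r2$bases)
  expect_equal(nrow(r1), 50L)
})
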