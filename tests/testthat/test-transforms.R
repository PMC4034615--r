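test_that("size factors equalise sample totals exactly", {
  tbl <- count_table(data.frame(sample = c("s1", "s2"),
                                otuA = c(60L, 180L),
                                otuB = c(40L, 120L)))
  sf <- size_factors(tbl)
  expect_equal(sf$size_factor, c(2, 2 / 3))
  m <- otu_matrix(tbl) * sf$size_factor
  expect_equal(unname(rowSums(m)), c(200, 200))

  # conservation on a random table: normalised totals = grand mean
  tbl2 <- random_count_table(15, 10, seed = 9)
  sf2 <- size_factors(tbl2)
  norm_tot <- rowSums(otu_matrix(tbl2) * sf2$size_factor)
  expect_equal(unname(norm_tot),
               rep(mean(rowSums(otu_matrix(tbl2))), 15))

  # the literal depth-ratio direction is the reciprocal
  lit <- size_factors(tbl, direction = "literal")
  expect_equal(lit$size_factor, 1 / sf$size_factor)
})

test_that("started log maps zeros to log10(0.1) and is monotone", {
  tbl <- count_table(data.frame(sample = c("s1", "s2"),
                                otuA = c(0L, 10L), otuB = c(100L, 90L)))
  v <- started_log(tbl)
  expect_equal(v["s1", "otuA"], -1)  # zero -> log10(0.1)
  sf <- size_factors(tbl)$size_factor
  expect_equal(v["s2", "otuA"], log10(10 * sf[2]))

  # monotone within each sample on random tables
  tbl2 <- random_count_table(8, 15, seed = 13, lambda = 5)
  v2 <- started_log(tbl2)
  m2 <- otu_matrix(tbl2)
  for (k in seq_len(nrow(m2))) {
    o <- order(m2[k, ])
    expect_true(all(diff(v2[k, o]) >= -1e-12))
  }
})

test_that("hybrid transform is continuous at the knot with known values", {
  tbl <- count_table(data.frame(sample = c("s1", "s2"),
                                otuA = c(0L, 10L), otuB = c(10L, 0L)))
  # equal totals: size factors are 1, normalised counts = raw counts
  h <- hybrid_log(tbl, c = 1)
  expect_equal(h["s1", "otuA"], -1 / log(10))  # x = 0, c = 1
  expect_equal(h["s2", "otuA"], 1)             # log10(10)

  # both branches agree at x = c and first derivative matches
  c0 <- 2.5
  f_log <- function(x) log10(x)
  f_lin <- function(x) log10(c0) + (x - c0) / (c0 * log(10))
  expect_equal(f_log(c0), f_lin(c0))
  eps <- 1e-6
  expect_equal((f_log(c0 + eps) - f_log(c0)) / eps,
               (f_lin(c0) - f_lin(c0 - eps)) / eps, tolerance = 1e-4)
})

test_that("hybrid and started-log transforms agree closely in practice", {
  tbl <- random_count_table(20, 25, seed = 17, lambda = 12)
  a <- as.vector(started_log(tbl))
  b <- as.vector(hybrid_log(tbl))
  expect_gt(cor(a, b), 0.99)
})

test_that("PCA retention uses a strict presence threshold", {
  # OTU present in 5/57 samples (8.8%) dropped; 6/57 (10.5%) kept
  n <- 57
  df <- data.frame(sample = sprintf("s%02d", 1:n),
                   base = rpois(n, 50) + 1L,
                   rare5 = c(rep(1L, 5), rep(0L, n - 5)),
                   rare6 = c(rep(1L, 6), rep(0L, n - 6)))
  tbl <- count_table(df)
  prep <- pca_prepare(tbl, min_presence = 0.10)
  expect_true("rare6" %in% prep$retained)
  expect_true("rare5" %in% prep$dropped)
  all_in <- pca_prepare(tbl, min_presence = 0)
  expect_setequal(all_in$retained, c("base", "rare5", "rare6"))
})

test_that("Kaiser component count matches an independent eigendecomposition", {
  tbl <- random_count_table(30, 12, seed = 23, lambda = 20)
  res <- otu_pca(tbl, min_presence = 0)
  x <- started_log(tbl)
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)$values
  expect_equal(res$n_kaiser, sum(sqrt(pmax(ev, 0)) > 1))
  expect_equal(res$variance$prop_var, ev / sum(ev), tolerance = 1e-8)
  expect_equal(sum(res$variance$prop_var), 1)
})

test_that("paralog correlations label copies, substitutes, sparse pairs", {
  set.seed(31)
  n <- 30
  base <- rpois(n, 2000) + 500L
  copy <- as.integer(round(base * 1.5))          # exact paralog
  anti <- as.integer(round(4e5 / base))          # substituting OTU
  sparse_a <- c(3L, 5L, rep(0L, n - 2))
  sparse_b <- c(4L, 0L, 2L, rep(0L, n - 3))      # 1 co-present sample
  df <- data.frame(sample = sprintf("s%02d", 1:n), dom = base,
                   copy = copy, anti = anti, ra = sparse_a,
                   rb = sparse_b)
  res <- paralog_correlations(count_table(df))
  row <- function(a, b) res[res$otu_a == a & res$otu_b == b, ]
  expect_equal(row("dom", "copy")$label, "candidate-paralog")
  expect_gt(row("dom", "copy")$r, 0.99)
  expect_equal(row("dom", "anti")$label, "distinct-genome-support")
  expect_lt(row("dom", "anti")$p_value, 0.001)
  expect_equal(row("ra", "rb")$label, "not-assessable")
  expect_equal(nrow(res), choose(5, 2))
})
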