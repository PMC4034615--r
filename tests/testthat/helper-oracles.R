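# Independent reference implementations used as oracles. These stay
# deliberately naive and separate from the package code paths.

# Benjamini-Hochberg step-up, written from the definition: sort p,
# compute p_(i) * m / i, enforce monotonicity from the largest down.
bh_stepup_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive greedy clustering oracle: same rule as cluster_otus but
# recomputing every pairwise identity with no shortcuts.
greedy_cluster_reference <- function(seqs, abundances, threshold) {
  ord <- order(-abundances, seqs)
  seqs <- seqs[ord]
  centroids <- character(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (j in seq_along(centroids)) {
      if (otupln::seq_identity(seqs[i], centroids[j]) >= threshold) {
        assign[i] <- j; placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids <- c(centroids, seqs[i])
      assign[i] <- length(centroids)
    }
  }
  list(centroids = centroids, assign = assign, order = ord)
}

# AR(1) chain for autocorrelation diagnostics.
ar1_chain <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1, sd = sqrt(1 - rho^2))
  x
}

# Small random count table with two crossed factors.
random_count_table <- function(n_samples = 10, n_otus = 12, seed = 1,
                               lambda = 30) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus)
  df <- data.frame(
    sample = sprintf("s%03d", seq_len(n_samples)),
    species = rep_len(c("faveolata", "franksi"), n_samples),
    bank = rep_len(c("east", "east", "west", "west"), n_samples),
    stringsAsFactors = FALSE)
  for (j in seq_len(n_otus)) df[[paste0("otu", j)]] <- m[, j]
  otupln::count_table(df, factors = c("species", "bank"))
}

# Mutate k distinct interior positions of a nucleotide string.
mutate_positions <- function(s, k, seed = 1) {
  set.seed(seed)
  v <- strsplit(s, "")[[1]]
  pos <- sample(seq(20, length(v) - 20), k)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

random_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Quadrature posterior for the reduced single-OTU model with known
# residual variance and flat intercept prior: p(I | y) on a grid via
# the PLN likelihood evaluated by numerical integration.
quadrature_intercept_posterior <- function(y, sigma2,
                                           grid = seq(-4, 6, length.out = 2001)) {
  loglik <- vapply(grid, function(I)
    sum(log(otupln::pln_pmf(y, I, sigma2))), numeric(1))
  w <- exp(loglik - max(loglik))
  w <- w / sum(w)
  list(mean = sum(grid * w),
       sd = sqrt(sum(grid^2 * w) - sum(grid * w)^2))
}
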