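#' Per-sample size factors
#'
#' Depth-equalising scalars: `factor_k = mean(totals) / total_k`, so
#' multiplying sample k's counts by its factor makes every sample
#' total equal the grand mean exactly. (The inverse, depth-amplifying
#' ratio `total_k / mean(totals)` is available via
#' `direction = "literal"` for comparison, but it is not a
#' normaliser.)
#'
#' @param data A count table.
#' @param direction `"equalise"` (default) or `"literal"`.
#' @return A tibble with `sample`, `total`, `size_factor`.
#' @export
size_factors <- function(data, direction = c("equalise", "literal")) {
  direction <- match.arg(direction)
  data <- as_count_table(data)
  totals <- rowSums(otu_matrix(data))
  if (any(totals == 0))
    abort(paste0("Sample(s) with zero total counts: ",
                 paste(sample_ids(data)[totals == 0], collapse = ", ")))
  f <- if (direction == "equalise") mean(totals) / totals
       else totals / mean(totals)
  tibble(sample = sample_ids(data), total = unname(totals),
         size_factor = unname(f))
}

.normalised_matrix <- function(data) {
  data <- as_count_table(data)
  m <- otu_matrix(data)
  f <- size_factors(data)$size_factor
  m * f
}

.new_transformed <- function(values, policy, size_factors) {
  structure(values, zero_policy = policy, size_factors = size_factors,
            class = c("otu_transformed", class(values)))
}

#' Started-log transform of normalised counts
#'
#' Normalises counts by the per-sample size factor and takes log10.
#' Zero counts are replaced by a small positive value (`zero_sub`,
#' default 0.1) before the log, so zeros map to `log10(zero_sub)`
#' (-1 with the default) and the result has no undefined entries.
#'
#' @param data A count table.
#' @param zero_sub Positive substitute for zero counts; default 0.1.
#' @return A samples-by-OTUs numeric matrix of class
#'   `"otu_transformed"` with attributes `zero_policy` and
#'   `size_factors`.
#' @export
started_log <- function(data, zero_sub = 0.1) {
  stopifnot(zero_sub > 0)
  data <- as_count_table(data)
  norm <- .normalised_matrix(data)
  raw <- otu_matrix(data)
  v <- ifelse(raw > 0, log10(norm), log10(zero_sub))
  .new_transformed(v, list(policy = "started_log", zero_sub = zero_sub),
                   size_factors(data))
}

#' Log-linear hybrid transform of normalised counts
#'
#' Logarithmic above the knot `c`, linear below it, continuous and
#' once-differentiable at the knot:
#' `log10(x)` for `x >= c`; `log10(c) + (x - c) / (c * ln 10)` for
#' `x < c`, where `x` is the size-factor-normalised count. Gives very
#' similar downstream results to [started_log()] while avoiding an
#' arbitrary zero substitute.
#'
#' @param data A count table.
#' @param c Knot on the normalised-count scale; default 1 (the linear
#'   region then covers only sub-single-count values).
#' @return An `"otu_transformed"` matrix.
#' @export
hybrid_log <- function(data, c = 1.0) {
  stopifnot(c > 0)
  data <- as_count_table(data)
  x <- .normalised_matrix(data)
  v <- ifelse(x >= c, log10(x), log10(c) + (x - c) / (c * log(10)))
  .new_transformed(v, list(policy = "hybrid", knot = c),
                   size_factors(data))
}

#' Started-log values with zeros left undefined
#'
#' As [started_log()] but original zero counts become `NA`, for
#' analyses (like paralog correlations) where an imputed zero would
#' manufacture signal.
#'
#' @inheritParams started_log
#' @return An `"otu_transformed"` matrix with `NA` where counts were 0.
#' @export
log_undefined_zeros <- function(data) {
  data <- as_count_table(data)
  norm <- .normalised_matrix(data)
  raw <- otu_matrix(data)
  v <- ifelse(raw > 0, log10(norm), NA_real_)
  .new_transformed(v, list(policy = "undefined"), size_factors(data))
}

#' Prepare a count table for principal component analysis
#'
#' Retains OTUs detected (raw count > 0) in strictly more than
#' `min_presence` of all samples, then applies the started-log
#' transform. Rarely-seen OTUs carry mostly presence/absence noise
#' and would dominate a PCA of log abundances.
#'
#' @param data A count table.
#' @param min_presence Presence fraction that must be exceeded;
#'   default 0.10.
#' @param zero_sub Passed to [started_log()].
#' @return A list: `values` (transformed matrix, retained OTUs only),
#'   `retained`, `dropped` (OTU ids).
#' @export
pca_prepare <- function(data, min_presence = 0.10, zero_sub = 0.1) {
  data <- as_count_table(data)
  m <- otu_matrix(data)
  pres <- colMeans(m > 0)
  keep <- pres > min_presence
  sl <- started_log(data, zero_sub = zero_sub)
  list(values = sl[, keep, drop = FALSE],
       retained = colnames(m)[keep],
       dropped = colnames(m)[!keep])
}

#' PCA of log-transformed normalised OTU abundances
#'
#' Runs [pca_prepare()] then an unscaled, centred principal component
#' analysis. The number of components satisfying Kaiser's criterion
#' (standard deviation greater than one) is reported alongside the
#' variance decomposition.
#'
#' @inheritParams pca_prepare
#' @return A list: `scores` (tibble, samples by components),
#'   `loadings` (tibble, OTUs by components), `variance` (tibble with
#'   `component`, `sdev`, `prop_var`, `cum_var`, `kaiser`),
#'   `n_kaiser`, `retained`, `prcomp` (the underlying fit).
#' @export
otu_pca <- function(data, min_presence = 0.10, zero_sub = 0.1) {
  prep <- pca_prepare(data, min_presence = min_presence,
                      zero_sub = zero_sub)
  pc <- prcomp(prep$values, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  variance <- tibble(component = paste0("PC", seq_along(pc$sdev)),
                     sdev = pc$sdev, prop_var = ve,
                     cum_var = cumsum(ve), kaiser = pc$sdev > 1)
  scores <- dplyr::bind_cols(tibble(sample = rownames(prep$values)),
                             as_tibble(pc$x))
  loadings <- dplyr::bind_cols(tibble(otu = rownames(pc$rotation)),
                               as_tibble(unclass(pc$rotation)))
  list(scores = scores, loadings = loadings, variance = variance,
       n_kaiser = sum(pc$sdev > 1), retained = prep$retained,
       prcomp = pc)
}

#' Pairwise abundance correlations for paralog detection
#'
#' Correlates log abundances between all OTU pairs across samples
#' where both OTUs are present (zero counts are left undefined, not
#' imputed: an imputed zero would correlate absences, not
#' abundances). OTUs from the same genome (paralogous marker copies)
#' co-vary with that genome's abundance and show positive
#' correlation; significant negative correlation supports distinct
#' genomes. Pairs with fewer than `min_shared` co-present samples are
#' reported as not assessable.
#'
#' @param data A count table.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_shared Minimum co-present samples; default 3.
#' @param alpha Significance level for labelling; default 0.05.
#' @return A tibble with one row per unordered OTU pair: `otu_a`,
#'   `otu_b`, `n_shared`, `r`, `p_value`, `label` (one of
#'   `"candidate-paralog"`, `"distinct-genome-support"`,
#'   `"not-significant"`, `"not-assessable"`).
#' @export
paralog_correlations <- function(data, method = c("pearson", "spearman"),
                                 min_shared = 3, alpha = 0.05) {
  method <- match.arg(method)
  data <- as_count_table(data)
  v <- log_undefined_zeros(data)
  otus <- colnames(v)
  if (length(otus) < 2L) abort("Need at least 2 OTUs.")
  pairs <- utils::combn(otus, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    ok <- !is.na(v[, a]) & !is.na(v[, b])
    ns <- sum(ok)
    if (ns < min_shared)
      return(tibble(otu_a = a, otu_b = b, n_shared = ns,
                    r = NA_real_, p_value = NA_real_,
                    label = "not-assessable"))
    xa <- v[ok, a]; xb <- v[ok, b]
    if (sd(xa) == 0 || sd(xb) == 0)
      return(tibble(otu_a = a, otu_b = b, n_shared = ns,
                    r = NA_real_, p_value = NA_real_,
                    label = "not-assessable"))
    r <- cor(xa, xb, method = method)
    if (method == "spearman") {
      p <- stats::cor.test(xa, xb, method = "spearman",
                           exact = FALSE)$p.value
    } else {
      tt <- r * sqrt((ns - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tt), df = ns - 2)
    }
    label <- if (!is.finite(p)) "not-assessable"
             else if (r > 0 && p < alpha) "candidate-paralog"
             else if (r < 0 && p < alpha) "distinct-genome-support"
             else "not-significant"
    tibble(otu_a = a, otu_b = b, n_shared = ns, r = r, p_value = p,
           label = label)
  })
}
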