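#' Flag low-coverage outlier samples
#'
#' Screens sequencing depth before model fitting. A sample is an
#' outlier when its natural-log total count lies at or below
#' `mean - z * sd` of the log totals across all samples (one-sided,
#' low tail): such samples carry too little information and distort
#' the coverage random effect. A two-sided variant is available but
#' off by default, matching typical use where only undersequenced
#' samples are dropped.
#'
#' @param data A count table.
#' @param z Standard-deviation multiple; default 2.5.
#' @param two_sided Also flag the high tail? Default `FALSE`.
#' @return A tibble with one row per sample: `sample`, `total`,
#'   `log_total`, `z_score` and logical `outlier`.
#' @export
detect_outlier_samples <- function(data, z = 2.5, two_sided = FALSE) {
  data <- as_count_table(data)
  if (nrow(data) < 3L)
    abort("Outlier screening needs at least 3 samples.")
  totals <- rowSums(otu_matrix(data))
  if (any(totals == 0))
    abort(paste0("Sample(s) with zero total counts: ",
                 paste(sample_ids(data)[totals == 0], collapse = ", "),
                 ". Remove them before screening."))
  lt <- log(totals)
  s <- sd(lt)
  zs <- if (s == 0) rep(0, length(lt)) else (lt - mean(lt)) / s
  out <- zs <= -z
  if (two_sided) out <- out | zs >= z
  tibble(sample = sample_ids(data), total = unname(totals),
         log_total = unname(lt), z_score = unname(zs),
         outlier = unname(out))
}

#' Select OTUs quantifiable from their global representation
#'
#' An OTU is deemed quantifiable when its summed count across all
#' samples reaches at least `min_fraction` of the global total
#' (inclusive threshold). OTUs below this level are too sparse to
#' estimate abundance changes and typically include sequencing
#' artifacts. OTU order is preserved.
#'
#' @param data A count table.
#' @param min_fraction Minimum share of the global count sum; default
#'   0.001 (0.1%).
#' @return A tibble with one row per OTU: `otu`, `total`, `fraction`
#'   and logical `kept`.
#' @export
select_quantifiable_otus <- function(data, min_fraction = 0.001) {
  data <- as_count_table(data)
  m <- otu_matrix(data)
  tot <- colSums(m)
  grand <- sum(tot)
  frac <- if (grand > 0) tot / grand else rep(0, length(tot))
  tibble(otu = colnames(m), total = unname(tot),
         fraction = unname(frac),
         kept = unname(tot >= min_fraction * grand))
}

#' Drop screened samples/OTUs from a count table
#'
#' Convenience wrapper applying the outputs of
#' [detect_outlier_samples()] and [select_quantifiable_otus()].
#'
#' @param data A count table.
#' @param z,min_fraction Passed to the two screening rules.
#' @return A screened `"otu_counts"` tibble with attributes
#'   `dropped_samples` and `dropped_otus`.
#' @export
screen_counts <- function(data, z = 2.5, min_fraction = 0.001) {
  data <- as_count_table(data)
  outl <- detect_outlier_samples(data, z = z)
  keep_s <- !outl$outlier
  kept <- data[keep_s, , drop = FALSE]
  qual <- select_quantifiable_otus(
    count_table(kept, sample = attr(data, "sample_col"),
                factors = attr(data, "factor_cols")),
    min_fraction = min_fraction)
  keep_o <- qual$otu[qual$kept]
  res <- count_table(
    kept[, c(attr(data, "sample_col"), attr(data, "factor_cols"), keep_o)],
    sample = attr(data, "sample_col"), factors = attr(data, "factor_cols"))
  attr(res, "dropped_samples") <- outl$sample[outl$outlier]
  attr(res, "dropped_otus") <- qual$otu[!qual$kept]
  res
}

#' Flag OTUs with unreliable posterior chains
#'
#' OTUs that are too sparse for the model to pin down show poorly
#' mixing MCMC chains. Each OTU's intercept and fixed-effect chains
#' are checked for autocorrelation at lag `ac_lag` (on the thinned,
#' retained draws); an OTU whose worst chain exceeds `ac_threshold`
#' is flagged and should be excluded from contrast reporting.
#'
#' @param fit A [pln_fit()] result.
#' @param ac_lag Autocorrelation lag on retained draws; default 10.
#' @param ac_threshold Flagging threshold; default 0.1.
#' @return A tibble with one row per modelled OTU (including the
#'   sum-OTU): `otu`, `max_autocorrelation`, logical `flagged`.
#' @export
flag_unreliable_otus <- function(fit, ac_lag = 10, ac_threshold = 0.1) {
  stopifnot(inherits(fit, "pln_fit"))
  draws <- fit$draws
  if (nrow(draws) < 10 * ac_lag)
    abort(paste0("Chains have ", nrow(draws), " retained draws; need at ",
                 "least 10 * ac_lag = ", 10 * ac_lag,
                 " for a reliable lag-", ac_lag, " diagnostic."))
  per_otu <- purrr::map_dbl(fit$otus, function(o) {
    cols <- c(paste0("I[", o, "]"),
              colnames(draws)[startsWith(colnames(draws),
                                         paste0("B[", o, ":"))])
    max(purrr::map_dbl(cols, function(cn) {
      x <- draws[, cn]
      if (sd(x) == 0) return(0)
      acf(x, lag.max = ac_lag, plot = FALSE)$acf[ac_lag + 1L]
    }))
  })
  tibble(otu = fit$otus, max_autocorrelation = per_otu,
         flagged = per_otu > ac_threshold)
}
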