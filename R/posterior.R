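# per-draw cell effects for one unit: draws x cells matrix
.cell_effects <- function(fit, unit) {
  d <- fit$draws
  C <- length(fit$cells); p <- ncol(fit$X_cell)
  if (p == 0L) return(matrix(0, nrow(d), C,
                             dimnames = list(NULL, fit$cells)))
  bcols <- paste0("B[", unit, ":", colnames(fit$X_cell), "]")
  eff <- d[, bcols, drop = FALSE] %*% t(fit$X_cell)
  colnames(eff) <- fit$cells
  eff
}

.real_otus <- function(fit) setdiff(fit$otus, ".sum")

#' Per-draw OTU effects relative to the sum-OTU
#'
#' Expresses each OTU's intercept and condition-cell effects net of
#' the sum-OTU's, draw by draw: `effect' = B_oi - B_i^s`,
#' `intercept' = I_o - I^s`. Because the sum-OTU carries each
#' sample's total, this differencing absorbs systematic coverage
#' biases shared across a condition, leaving genuinely compositional
#' effects.
#'
#' @param fit A [pln_fit()] result fitted with a sum-OTU.
#' @param otus OTU ids to report; default all real OTUs.
#' @return A tibble with columns `draw`, `otu`, `cell`,
#'   `intercept_rel` and `effect_rel` (natural-log scale).
#' @export
relative_effects <- function(fit, otus = NULL) {
  stopifnot(inherits(fit, "pln_fit"))
  if (!fit$design$sum_otu)
    abort("Fit has no sum-OTU; refit with `sum_otu = TRUE`.")
  if (is.null(otus)) otus <- .real_otus(fit)
  if (length(otus) == 0L)
    return(tibble(draw = integer(), otu = character(),
                  cell = character(), intercept_rel = numeric(),
                  effect_rel = numeric()))
  d <- fit$draws
  n <- nrow(d)
  Isum <- d[, "I[.sum]"]
  esum <- .cell_effects(fit, ".sum")
  purrr::map_dfr(otus, function(o) {
    eo <- .cell_effects(fit, o) - esum
    io <- d[, paste0("I[", o, "]")] - Isum
    tibble(draw = rep(seq_len(n), times = length(fit$cells)),
           otu = o,
           cell = rep(fit$cells, each = n),
           intercept_rel = rep(io, times = length(fit$cells)),
           effect_rel = as.vector(eo))
  })
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing a given posterior mass.
#'
#' @param x Numeric draws.
#' @param level Mass; default 0.95.
#' @return `c(lower, upper)`.
#' @export
hdi <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(x[1L], x[n]))
  starts <- seq_len(n - m)
  w <- x[starts + m] - x[starts]
  i <- which.min(w)
  c(x[i], x[i + m])
}

#' Posterior pairwise condition contrasts with FDR correction
#'
#' For every OTU and every unordered pair of condition cells,
#' computes the per-draw difference of sum-OTU-relative effects, its
#' posterior mean and 95% interval, a two-sided MCMC p-value and a
#' Benjamini-Hochberg q-value over the whole table. The MCMC p-value
#' uses the add-one tail estimator
#' `p = 2 * min(#\{d > 0\} + 1, #\{d < 0\} + 1) / (N + 1)` (capped at
#' 1) so that p is never exactly zero at finite chain length.
#'
#' @param fit A [pln_fit()] result (with sum-OTU).
#' @param otus OTU ids to include; default all real OTUs. OTUs
#'   flagged by [flag_unreliable_otus()] should be excluded here.
#' @param level Interval mass; default 0.95.
#' @param interval `"hdi"` (default, highest-density) or `"eti"`
#'   (equal-tail).
#' @return A tibble of class `"pln_contrasts"` with columns `otu`,
#'   `condition_a`, `condition_b`, `mean_logdiff` (natural-log fold
#'   difference, A minus B), `ci_low`, `ci_high`, `p_mcmc`, `q_fdr`.
#' @export
pairwise_contrasts <- function(fit, otus = NULL, level = 0.95,
                               interval = c("hdi", "eti")) {
  stopifnot(inherits(fit, "pln_fit"))
  interval <- match.arg(interval)
  if (length(fit$cells) < 2L)
    abort("Need at least 2 condition cells for contrasts.")
  if (is.null(otus)) otus <- .real_otus(fit)
  if (length(otus) == 0L) {
    res <- tibble(otu = character(), condition_a = character(),
                  condition_b = character(), mean_logdiff = numeric(),
                  ci_low = numeric(), ci_high = numeric(),
                  p_mcmc = numeric(), q_fdr = numeric())
    class(res) <- c("pln_contrasts", class(res))
    return(res)
  }
  esum <- .cell_effects(fit, ".sum")
  pairs <- utils::combn(fit$cells, 2L)
  n <- nrow(fit$draws)
  res <- purrr::map_dfr(otus, function(o) {
    eo <- .cell_effects(fit, o) - esum
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      d <- eo[, a] - eo[, b]
      ci <- if (interval == "hdi") hdi(d, level)
            else unname(quantile(d, c((1 - level) / 2, (1 + level) / 2)))
      tibble(otu = o, condition_a = a, condition_b = b,
             mean_logdiff = mean(d), ci_low = ci[1L], ci_high = ci[2L],
             p_mcmc = min(1, 2 * min(sum(d > 0) + 1, sum(d < 0) + 1) /
                            (n + 1)))
    })
  })
  res$q_fdr <- p.adjust(res$p_mcmc, method = "BH")
  class(res) <- c("pln_contrasts", class(res))
  res
}

#' Posterior OTU abundances as proportions of total
#'
#' The model-scale share of total for OTU `o` in condition cell `i`
#' is `exp(intercept' + effect'_oi)`, the abundance implied relative
#' to the sum-OTU reference. Summaries are the posterior mean and a
#' 95% interval per OTU and condition.
#'
#' @param fit A [pln_fit()] result (with sum-OTU).
#' @param condition Condition cell(s) to report; default all.
#' @param otus OTU ids; default all real OTUs.
#' @param level Interval mass; default 0.95.
#' @return A tibble with `otu`, `condition`, `mean_proportion`,
#'   `ci_low`, `ci_high`.
#' @export
abundance_proportions <- function(fit, condition = NULL, otus = NULL,
                                  level = 0.95) {
  rel <- relative_effects(fit, otus = otus)
  if (!is.null(condition)) {
    bad <- setdiff(condition, fit$cells)
    if (length(bad))
      abort(paste0("Unknown condition cell(s): ",
                   paste(bad, collapse = ", ")))
    rel <- dplyr::filter(rel, .data$cell %in% condition)
  }
  rel |>
    dplyr::mutate(prop = exp(.data$intercept_rel + .data$effect_rel)) |>
    dplyr::group_by(otu = .data$otu, condition = .data$cell) |>
    dplyr::summarise(
      mean_proportion = mean(.data$prop),
      ci_low = hdi(.data$prop, level)[1L],
      ci_high = hdi(.data$prop, level)[2L],
      .groups = "drop")
}

#' @export
#' @rdname pln_fit_tidiers
tidy.pln_fit <- function(x, level = 0.95, ...) {
  d <- x$draws
  purrr::map_dfr(colnames(d), function(cn) {
    v <- d[, cn]
    ci <- hdi(v, level)
    tibble(term = cn, estimate = mean(v), std.error = sd(v),
           conf.low = ci[1L], conf.high = ci[2L])
  })
}

#' Tidiers for Poisson-lognormal model fits
#'
#' `tidy()` summarises every stored chain (posterior mean, sd and
#' highest-density interval); `glance()` gives a one-row fit summary.
#'
#' @param x A [pln_fit()] object.
#' @param level Interval mass for `tidy()`.
#' @param ... Unused.
#' @return A tibble.
#' @name pln_fit_tidiers
NULL

#' @export
#' @rdname pln_fit_tidiers
glance.pln_fit <- function(x, ...) {
  tibble(n_units = length(x$otus),
         n_samples = length(x$design$samples),
         n_cells = length(x$cells),
         n_draws = nrow(x$draws),
         accept_rate = x$accept_rate,
         min_ess = min(x$ess, na.rm = TRUE),
         seed = x$settings$seed)
}
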