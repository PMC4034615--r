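#' Build the model design from a count table
#'
#' Expands a screened count table into the long-format response the
#' sampler consumes, appending one artificial "sum-OTU" per sample
#' whose count is the sample total. The sum-OTU is modelled jointly
#' with the real OTUs; expressing fitted OTU effects relative to its
#' effects later cancels systematic coverage biases across conditions
#' and turns model-scale abundances into shares of total.
#'
#' Condition cells are the combinations of the fixed factors. With
#' `interactions = TRUE` (default) each non-reference cell gets its
#' own coefficient per OTU (reference-cell coding; the reference is
#' the alphabetically first combination). With `interactions = FALSE`
#' only additive main-effect coefficients are used.
#'
#' @param data A count table (screened).
#' @param fixed Character vector of fixed-factor column names, or
#'   `NULL` for an intercept-only model.
#' @param random Character vector of grouping-factor column names for
#'   OTU-specific random effects (may be empty).
#' @param interactions Include all interactions among `fixed`
#'   (cell-means coding)? Default `TRUE`.
#' @param sum_otu Append the sum-OTU? Default `TRUE`.
#' @return A list of class `"pln_design"`: `long` (tibble `otu`,
#'   `sample`, `count`, `cell`), `otus` (modelled units, sum-OTU id
#'   `".sum"` last), `samples`, `cells`, `ref_cell`, `X_cell`
#'   (cells-by-coefficients design), `random` (per-factor level
#'   indices), `sample_cell` (cell of each sample).
#' @export
build_design <- function(data, fixed = NULL, random = NULL,
                         interactions = TRUE, sum_otu = TRUE) {
  data <- as_count_table(data)
  fac <- sample_factors(data)
  names(fac)[1L] <- "sample"
  for (f in c(fixed, random)) {
    if (!f %in% names(fac))
      abort(paste0("Factor '", f, "' is not a column of the count table."))
    if (length(unique(fac[[f]])) < 2L)
      abort(paste0("Factor '", f, "' has a single level; it cannot be ",
                   "used as a model term."))
  }
  m <- otu_matrix(data)
  samples <- rownames(m)
  otus <- colnames(m)
  if (".sum" %in% otus) abort("OTU id '.sum' is reserved for the sum-OTU.")

  if (is.null(fixed) || length(fixed) == 0L) {
    sample_cell <- rep("(all)", length(samples))
  } else {
    sample_cell <- do.call(paste, c(fac[fixed], sep = ":"))
  }
  cells <- sort(unique(sample_cell))
  ref_cell <- cells[[1L]]

  if (length(cells) == 1L) {
    X_cell <- matrix(0, nrow = 1L, ncol = 0L,
                     dimnames = list(cells, NULL))
  } else if (interactions) {
    X_cell <- diag(length(cells))[, -1L, drop = FALSE]
    dimnames(X_cell) <- list(cells, cells[-1L])
  } else {
    cf <- unique(tibble(cell = sample_cell, fac[fixed]))
    cf <- cf[match(cells, cf$cell), , drop = FALSE]
    mm <- stats::model.matrix(
      stats::reformulate(fixed),
      data = as.data.frame(lapply(cf[fixed], factor)))
    X_cell <- mm[, -1L, drop = FALSE]
    rownames(X_cell) <- cells
  }

  units <- if (sum_otu) c(otus, ".sum") else otus
  counts <- if (sum_otu) cbind(m, `.sum` = rowSums(m)) else m
  long <- tibble(
    otu = rep(units, each = length(samples)),
    sample = rep(samples, times = length(units)),
    count = as.integer(counts[, units]),
    cell = rep(sample_cell, times = length(units)))

  random_idx <- NULL
  if (!is.null(random) && length(random)) {
    random_idx <- lapply(setNames(random, random), function(f) {
      lev <- sort(unique(fac[[f]]))
      list(levels = lev, index = match(fac[[f]], lev))
    })
  }

  structure(list(long = long, otus = units, samples = samples,
                 cells = cells, ref_cell = ref_cell, X_cell = X_cell,
                 random = random_idx, sample_cell = sample_cell,
                 fixed = fixed, interactions = interactions,
                 sum_otu = sum_otu, factors = fac),
            class = "pln_design")
}
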