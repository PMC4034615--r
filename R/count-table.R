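#' Build a validated OTU count table
#'
#' A count table is a wide tibble holding one row per sample: a sample
#' identifier column, zero or more categorical design columns (host
#' species, sampling site, treatment, ...) and one nonnegative integer
#' column per OTU. Zero counts are data under the Poisson-lognormal
#' model (absence can reflect undersampling), so they are always kept
#' explicit, never dropped.
#'
#' @param data A data frame with one row per sample.
#' @param sample Name of the sample-identifier column. Default
#'   `"sample"`; if absent, the first non-numeric column is used.
#' @param factors Character vector naming the design (factor) columns.
#'   If `NULL`, every non-numeric column other than the sample column
#'   is treated as a factor.
#'
#' @return A tibble of class `"otu_counts"` with attributes
#'   `sample_col`, `factor_cols` and `otu_cols`.
#'
#' @examples
#' tbl <- count_table(
#'   data.frame(sample = c("s1", "s2"), site = c("east", "west"),
#'              otuA = c(5L, 3L), otuB = c(0L, 7L)),
#'   factors = "site")
#' otu_matrix(tbl)
#' @export
count_table <- function(data, sample = "sample", factors = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  data <- as_tibble(data)
  nms <- names(data)

  if (!sample %in% nms) {
    non_num <- nms[!vapply(data, is.numeric, logical(1))]
    if (length(non_num) == 0L)
      abort("No sample-identifier column found; name one via `sample`.")
    sample <- non_num[[1L]]
  }
  sid <- as.character(data[[sample]])
  if (anyDuplicated(sid))
    abort(paste0("Duplicate sample id(s): ",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")))

  if (is.null(factors)) {
    factors <- setdiff(nms[!vapply(data, is.numeric, logical(1))], sample)
  } else {
    missing_f <- setdiff(factors, nms)
    if (length(missing_f))
      abort(paste0("Factor column(s) not in data: ",
                   paste(missing_f, collapse = ", ")))
  }
  otus <- setdiff(nms, c(sample, factors))
  if (length(otus) == 0L) abort("No OTU count columns found.")

  for (f in factors) {
    lev <- data[[f]]
    if (any(is.na(lev)) || any(!nzchar(as.character(lev))))
      abort(paste0("Factor '", f, "' has a missing level for sample(s): ",
                   paste(sid[is.na(lev) | !nzchar(as.character(lev))],
                         collapse = ", ")))
    data[[f]] <- as.character(lev)
  }
  for (o in otus) {
    x <- data[[o]]
    if (!is.numeric(x))
      abort(paste0("Count column '", o, "' is not numeric."))
    bad <- which(is.na(x) | x < 0 | x != round(x))
    if (length(bad))
      abort(paste0("Invalid count in column '", o, "', row ", bad[[1L]],
                   " (sample '", sid[bad[[1L]]],
                   "'): counts must be nonnegative integers."))
    data[[o]] <- as.integer(round(x))
  }

  data[[sample]] <- sid
  out <- data[, c(sample, factors, otus)]
  structure(out,
            class = c("otu_counts", class(out)),
            sample_col = sample, factor_cols = factors, otu_cols = otus)
}

#' Coerce to a count table
#'
#' Re-derives the sample/factor/OTU column roles if `data` is a plain
#' data frame (e.g. after dplyr verbs stripped attributes).
#'
#' @inheritParams count_table
#' @return A `"otu_counts"` tibble.
#' @export
as_count_table <- function(data, sample = "sample", factors = NULL) {
  if (inherits(data, "otu_counts") &&
      !is.null(attr(data, "otu_cols")) &&
      all(c(attr(data, "sample_col"), attr(data, "factor_cols"),
            attr(data, "otu_cols")) %in% names(data)))
    return(data)
  count_table(data, sample = sample, factors = factors)
}

#' @export
print.otu_counts <- function(x, ...) {
  cat("# OTU count table: ", nrow(x), " samples x ",
      length(attr(x, "otu_cols")), " OTUs",
      if (length(attr(x, "factor_cols")))
        paste0(" | factors: ",
               paste(attr(x, "factor_cols"), collapse = ", ")),
      "\n", sep = "")
  NextMethod()
}

#' Accessors for count tables
#'
#' `otu_matrix()` returns the samples-by-OTUs integer matrix,
#' `sample_factors()` the per-sample design columns, `otu_ids()` and
#' `sample_ids()` the identifiers in table order.
#'
#' @param data A count table (or data frame coercible to one).
#' @return A matrix, tibble or character vector respectively.
#' @export
otu_matrix <- function(data) {
  data <- as_count_table(data)
  m <- as.matrix(data[, attr(data, "otu_cols"), drop = FALSE])
  rownames(m) <- data[[attr(data, "sample_col")]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname otu_matrix
#' @export
sample_factors <- function(data) {
  data <- as_count_table(data)
  data[, c(attr(data, "sample_col"), attr(data, "factor_cols")),
       drop = FALSE]
}

#' @rdname otu_matrix
#' @export
otu_ids <- function(data) attr(as_count_table(data), "otu_cols")

#' @rdname otu_matrix
#' @export
sample_ids <- function(data) {
  data <- as_count_table(data)
  data[[attr(data, "sample_col")]]
}

#' Reshape a count table to long format
#'
#' Produces one row per (OTU, sample) pair. Zero counts are retained as
#' explicit rows: under the model absence is informative, not missing.
#'
#' @param data A count table.
#' @return A tibble with columns `otu`, `sample`, `count` and the
#'   design columns; `nrow = n_samples * n_otus`.
#' @export
to_long <- function(data) {
  data <- as_count_table(data)
  sc <- attr(data, "sample_col")
  long <- tidyr::pivot_longer(as_tibble(data), cols = attr(data, "otu_cols"),
                              names_to = "otu", values_to = "count")
  long <- dplyr::rename(long, sample = dplyr::all_of(sc))
  long$otu <- factor(long$otu, levels = attr(data, "otu_cols"))
  long <- dplyr::arrange(long, .data$otu,
                         match(.data$sample, sample_ids(data)))
  long$otu <- as.character(long$otu)
  dplyr::relocate(long, "otu", "sample", "count")
}

#' Aggregate long-format counts back to a count table
#'
#' Inverse of [to_long()]: `from_long(to_long(x))` reproduces `x`
#' exactly.
#'
#' @param long A tibble with columns `otu`, `sample`, `count` plus
#'   design columns.
#' @param factors Character vector of design columns; default all
#'   columns other than `otu`, `sample`, `count`.
#' @return A `"otu_counts"` tibble.
#' @export
from_long <- function(long, factors = NULL) {
  long <- as_tibble(long)
  need <- c("otu", "sample", "count")
  if (!all(need %in% names(long)))
    abort("Long counts need columns 'otu', 'sample' and 'count'.")
  if (is.null(factors)) factors <- setdiff(names(long), need)
  otu_levels <- unique(long$otu)
  samp_levels <- unique(long$sample)
  wide <- tidyr::pivot_wider(long, names_from = "otu",
                             values_from = "count")
  wide <- wide[match(samp_levels, wide$sample),
               c("sample", factors, otu_levels)]
  if (anyNA(wide[otu_levels]))
    abort("Long counts are incomplete: every (otu, sample) pair needs a row.")
  count_table(wide, sample = "sample", factors = factors)
}

#' Read an OTU count table from tab-separated text
#'
#' Two dialects are supported. `"wide"`: header row; first column the
#' sample id, then the design columns, then one integer column per
#' OTU. `"long"`: columns `otu`, `sample`, `count` plus design
#' columns, one row per (OTU, sample) pair.
#'
#' @param path Path to a TSV file.
#' @param format `"wide"` or `"long"`.
#' @param factors Design column names; if `NULL`, non-numeric columns
#'   are used (wide) or all extra columns (long).
#' @return A `"otu_counts"` tibble.
#' @export
read_counts <- function(path, format = c("wide", "long"), factors = NULL) {
  format <- match.arg(format)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (format == "wide") {
    count_table(raw, sample = names(raw)[[1L]], factors = factors)
  } else {
    if (!is.null(factors)) from_long(raw, factors = factors)
    else from_long(raw)
  }
}

#' Write an OTU count table to tab-separated text
#'
#' `read_counts()` of the written file reproduces the table exactly
#' (counts bit-identical, factor levels lossless).
#'
#' @param data A count table.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(data, path, format = c("wide", "long")) {
  format <- match.arg(format)
  data <- as_count_table(data)
  out <- if (format == "wide") as_tibble(data) else to_long(data)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
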