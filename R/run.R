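#' Run the complete quantitative metabarcoding analysis
#'
#' Orchestrates the full workflow over a configuration list or JSON
#' file: load (or simulate) counts, screen outlier samples and
#' non-quantifiable OTUs, fit the Poisson-lognormal mixed model, drop
#' OTUs with unreliable chains, compute pairwise contrasts with FDR
#' correction, and run the model-free companions (transforms, PCA,
#' paralog correlations). All outputs land in `out_dir` as
#' tab-separated tables plus a JSON manifest recording every
#' parameter and an MD5 of the input; a rerun with identical
#' configuration and seed writes identical tables.
#'
#' Configuration keys: one of `counts` (TSV path), `counts_data` (a
#' data frame) or `preset = "orbicella-like"`; `fixed` (character
#' vector, required); optional `random`, `interactions`, `factors`,
#' `z` (outlier SD multiple, 2.5), `min_fraction` (0.001),
#' `min_presence` (0.10), `ac_lag` (10), `ac_threshold` (0.1),
#' `iterations`, `burn_in`, `thin`, `seed` (required), `alpha`
#' (0.05).
#'
#' @param config A named list or path to a JSON file.
#' @param out_dir Output directory; created if needed.
#' @return A list with the screened counts, fit, reliability table,
#'   contrasts, proportions, PCA, correlations and the manifest,
#'   invisibly writing all of them under `out_dir`.
#' @export
run_full_analysis <- function(config, out_dir = tempfile("otupln")) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(z = 2.5, min_fraction = 0.001, min_presence = 0.10,
                   ac_lag = 10, ac_threshold = 0.1, iterations = 55000,
                   burn_in = 5000, thin = 50, alpha = 0.05,
                   interactions = TRUE, random = NULL, factors = NULL)
  required <- c("seed", "fixed")
  missing_keys <- setdiff(required, names(config))
  has_input <- any(c("counts", "counts_data", "preset") %in% names(config))
  if (!has_input)
    missing_keys <- c(missing_keys, "counts|counts_data|preset")
  if (length(missing_keys))
    abort(paste0("Missing config key(s): ",
                 paste(missing_keys, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)

  input_hash <- NA_character_
  if (!is.null(cfg$counts)) {
    counts <- read_counts(cfg$counts, format = "wide",
                          factors = cfg$factors)
    input_hash <- unname(tools::md5sum(cfg$counts))
  } else if (!is.null(cfg$counts_data)) {
    counts <- as_count_table(cfg$counts_data, factors = cfg$factors)
  } else {
    if (!identical(cfg$preset, "orbicella-like"))
      abort(paste0("Unknown preset: ", cfg$preset))
    counts <- simulate_counts(orbicella_like_preset(), seed = cfg$seed)
  }
  bad_fac <- setdiff(c(cfg$fixed, cfg$random),
                     attr(counts, "factor_cols"))
  if (length(bad_fac))
    abort(paste0("Unknown factor(s) in config: ",
                 paste(bad_fac, collapse = ", ")))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outl <- detect_outlier_samples(counts, z = cfg$z)
  screened <- screen_counts(counts, z = cfg$z,
                            min_fraction = cfg$min_fraction)
  qual <- select_quantifiable_otus(
    counts[!sample_ids(counts) %in% outl$sample[outl$outlier], ],
    min_fraction = cfg$min_fraction)

  fit <- pln_fit(screened, fixed = cfg$fixed, random = cfg$random,
                 interactions = cfg$interactions,
                 iterations = cfg$iterations, burn_in = cfg$burn_in,
                 thin = cfg$thin, seed = cfg$seed)
  rel <- flag_unreliable_otus(fit, ac_lag = cfg$ac_lag,
                              ac_threshold = cfg$ac_threshold)
  keep <- setdiff(rel$otu[!rel$flagged], ".sum")
  contrasts <- pairwise_contrasts(fit, otus = keep)
  props <- abundance_proportions(fit, otus = keep)
  pca <- otu_pca(counts[!sample_ids(counts) %in%
                          outl$sample[outl$outlier], ],
                 min_presence = cfg$min_presence)
  corr <- paralog_correlations(screened)

  readr::write_tsv(outl, file.path(out_dir, "screen_samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(qual, file.path(out_dir, "screen_otus.tsv"),
                   progress = FALSE)
  readr::write_tsv(rel, file.path(out_dir, "chain_reliability.tsv"),
                   progress = FALSE)
  readr::write_tsv(as_tibble(contrasts),
                   file.path(out_dir, "contrasts.tsv"), progress = FALSE)
  readr::write_tsv(props, file.path(out_dir, "proportions.tsv"),
                   progress = FALSE)
  readr::write_tsv(pca$variance, file.path(out_dir, "pca_variance.tsv"),
                   progress = FALSE)
  readr::write_tsv(pca$scores, file.path(out_dir, "pca_scores.tsv"),
                   progress = FALSE)
  readr::write_tsv(corr, file.path(out_dir, "correlations.tsv"),
                   progress = FALSE)
  draws_df <- as_tibble(as.data.frame(fit$draws))
  readr::write_tsv(draws_df, file.path(out_dir, "draws.tsv"),
                   progress = FALSE)
  plot_otu_panels(screened, contrasts,
                  path = file.path(out_dir, "otu_panels.png"),
                  otus = if (length(keep)) keep else otu_ids(screened))

  manifest <- list(
    parameters = cfg[setdiff(names(cfg), "counts_data")],
    input_md5 = input_hash,
    n_samples_in = nrow(counts),
    outlier_samples = outl$sample[outl$outlier],
    kept_otus = keep,
    dropped_otus = c(attr(screened, "dropped_otus"),
                     setdiff(rel$otu[rel$flagged], ".sum")),
    outputs = c("screen_samples.tsv", "screen_otus.tsv",
                "chain_reliability.tsv", "contrasts.tsv",
                "proportions.tsv", "pca_variance.tsv",
                "pca_scores.tsv", "correlations.tsv", "draws.tsv",
                "otu_panels.png"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(counts = counts, screened = screened, fit = fit,
                 reliability = rel, contrasts = contrasts,
                 proportions = props, pca = pca, correlations = corr,
                 manifest = manifest, out_dir = out_dir))
}
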