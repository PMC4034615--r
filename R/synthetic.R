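#' Define ground truth for a synthetic count dataset
#'
#' Bundles every quantity the generative model needs: OTU intercepts
#' (log baseline rates), per-cell fixed effects, the coverage-effect
#' variance, OTU-specific residual log-variances and the factorial
#' design. [simulate_counts()] runs the model forward from it, and
#' recovery tests compare fitted posteriors against it.
#'
#' @param intercepts Named numeric vector: log baseline Poisson rate
#'   per OTU (median rate; the lognormal layer adds `sigma2/2` to the
#'   log mean).
#' @param effects Numeric matrix OTUs x condition cells of log-scale
#'   fixed effects (0 = no effect). Column names are cell labels
#'   `"level1:level2"` matching `design`.
#' @param design A data frame with column `sample` plus one column
#'   per factor, one row per sample.
#' @param factors Character vector naming the factor columns of
#'   `design`.
#' @param var_c Variance of the per-sample coverage effect.
#' @param sigma2 Named per-OTU residual log-variance.
#' @param planted Optional tibble describing which effects are real
#'   (for recovery scoring): columns `otu`, `cell_hi`, `cell_lo`,
#'   `logdiff`.
#' @return A list of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(intercepts, effects, design, factors,
                            var_c = 0, sigma2 = 0, planted = NULL) {
  otus <- names(intercepts)
  stopifnot(!is.null(otus), nrow(effects) == length(otus),
            var_c >= 0, all(sigma2 >= 0))
  sigma2 <- rep_len(sigma2, length(otus))
  names(sigma2) <- otus
  rownames(effects) <- otus
  structure(list(otus = otus, intercepts = intercepts,
                 effects = effects, design = as_tibble(design),
                 factors = factors, var_c = var_c, sigma2 = sigma2,
                 planted = planted),
            class = "synthetic_truth")
}

#' Simulate an OTU count table from the generative model
#'
#' Runs the Poisson-lognormal mixed model forward:
#' `c_k ~ Normal(0, var_c)` per sample,
#' `e ~ Normal(0, sigma2_o)` per observation, and
#' `y ~ Poisson(exp(I_o + B_o,cell(k) + c_k + e))`. Identical seeds
#' give identical tables.
#'
#' @param truth A [synthetic_truth()] object.
#' @param seed Integer RNG seed.
#' @return A `"otu_counts"` tibble with attributes `truth` and
#'   `coverage_effects` (the drawn `c_k`).
#' @export
simulate_counts <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(as.integer(seed))
  des <- truth$design
  K <- nrow(des); otus <- truth$otus; U <- length(otus)
  cell <- do.call(paste, c(des[truth$factors], sep = ":"))
  ci <- match(cell, colnames(truth$effects))
  if (anyNA(ci))
    abort(paste0("Design cell(s) missing from truth effects: ",
                 paste(unique(cell[is.na(ci)]), collapse = ", ")))
  ck <- rnorm(K, 0, sqrt(truth$var_c))
  m <- matrix(0L, K, U, dimnames = list(des$sample, otus))
  for (o in seq_len(U)) {
    psi <- truth$intercepts[o] + truth$effects[o, ci] + ck +
      rnorm(K, 0, sqrt(truth$sigma2[o]))
    m[, o] <- rpois(K, exp(psi))
  }
  tbl <- count_table(
    dplyr::bind_cols(des[c("sample", truth$factors)],
                     as_tibble(as.data.frame(m))),
    sample = "sample", factors = truth$factors)
  attr(tbl, "truth") <- truth
  attr(tbl, "coverage_effects") <- setNames(ck, des$sample)
  tbl
}

#' Coral-symbiont-like synthetic community preset
#'
#' Ground truth emulating a typical quantitative metabarcoding
#' dataset of a quasi-monotypic symbiont community: a 2 species x 2
#' site factorial with 14-15 samples per cell (58 total); one
#' dominant haplotype at ~90% of reads; six minor haplotypes spanning
#' roughly 0.1-10%; eight noise OTUs individually below the 0.1%
#' quantifiability threshold (so screening has real work to do);
#' per-sample coverage varying about tenfold around a median total of
#' ~1,900 (lognormal coverage effects); and bank (site) effects of
#' 1.0-1.5 natural-log units planted on three minor haplotypes, with
#' all other effects null.
#'
#' @return A `"synthetic_truth"` object whose `planted` element lists
#'   the three real bank effects.
#' @export
orbicella_like_preset <- function() {
  shares <- c(hapII = 0.90, hapI = 0.05, hapIII = 0.02, hapIV = 0.012,
              hapV = 0.006, hapVI = 0.004, hapVII = 0.0025,
              noise1 = 5e-4, noise2 = 5e-4, noise3 = 4e-4,
              noise4 = 4e-4, noise5 = 3e-4, noise6 = 3e-4,
              noise7 = 2e-4, noise8 = 2e-4)
  sigma2 <- c(rep(0.3, 7), rep(0.5, 8))
  sigma2[1] <- 0.05
  names(sigma2) <- names(shares)
  baseline_total <- 1900
  intercepts <- log(baseline_total * shares) - sigma2 / 2

  cell_sizes <- c("faveolata:east" = 14, "faveolata:west" = 14,
                  "franksi:east" = 15, "franksi:west" = 15)
  species <- rep(sub(":.*", "", names(cell_sizes)), cell_sizes)
  bank <- rep(sub(".*:", "", names(cell_sizes)), cell_sizes)
  design <- tibble(
    sample = sprintf("s%02d", seq_along(species)),
    species = species, bank = bank)

  cells <- names(cell_sizes)
  effects <- matrix(0, length(shares), length(cells),
                    dimnames = list(names(shares), cells))
  west <- grepl(":west$", cells)
  effects["hapIV", west] <- -1.2
  effects["hapVI", west] <- -1.0
  effects["hapVII", west] <- 1.4

  planted <- tibble(
    otu = c("hapIV", "hapVI", "hapVII"),
    cell_hi = "faveolata:west", cell_lo = "faveolata:east",
    logdiff = c(-1.2, -1.0, 1.4))

  synthetic_truth(intercepts = intercepts, effects = effects,
                  design = design, factors = c("species", "bank"),
                  var_c = 0.33, sigma2 = sigma2, planted = planted)
}

#' Generate divergent reference sequences for a read community
#'
#' Builds `n_otus` sequences of the given length from one random
#' backbone, giving each OTU its own disjoint block of substituted
#' positions so that every pair differs by `divergence` of its
#' length.
#'
#' @param n_otus Number of reference sequences.
#' @param length Sequence length in bases; default 300.
#' @param divergence Pairwise divergence between any two references;
#'   default 0.04 (comfortably above a 3% split threshold).
#' @param seed RNG seed.
#' @return Character vector of sequences named `ref1..refn`.
#' @export
reference_sequences <- function(n_otus, length = 300, divergence = 0.04,
                                seed = 1L) {
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, length, replace = TRUE)
  m <- max(1L, ceiling(divergence * length / 2))
  if (n_otus * m > length - 40L)
    abort("Sequence too short for the requested divergence.")
  # planted substitutions sit in the interior (terminal differences
  # would be clipped by the ends-free alignment) and are spaced two
  # apart (adjacent substitution runs can be re-aligned with a gap,
  # inflating identity)
  if (n_otus * 2L * m > length - 40L)
    abort("Sequence too short for the requested divergence.")
  offset <- (length - n_otus * 2L * m) %/% 2L
  out <- character(n_otus)
  for (i in seq_len(n_otus)) {
    s <- backbone
    pos <- offset + (i - 1L) * 2L * m + seq(1L, 2L * m, by = 2L)
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- paste0("ref", seq_len(n_otus))
  out
}

#' Simulate per-sample amplicon read files from known proportions
#'
#' Draws each sample's reads multinomially from the planted OTU
#' proportions, applies per-base substitution noise, and writes one
#' FASTA (or FASTQ) file per sample. The multinomial draws are
#' recorded as the expected count table: with `error_rate = 0` the
#' reads-to-counts pipeline reproduces it exactly.
#'
#' @param proportions Numeric vector of planted OTU proportions
#'   (summing to 1).
#' @param n_samples Number of samples; default 4.
#' @param reads_per_sample Reads per sample; default 500.
#' @param error_rate Per-base substitution probability; default
#'   0.005.
#' @param ref_seqs Reference sequences; default generated by
#'   [reference_sequences()] at 4% pairwise divergence.
#' @param read_length Length when generating references; default 300.
#' @param format `"fasta"` or `"fastq"` (constant Q35 qualities).
#' @param dir Output directory; created if needed.
#' @param seed RNG seed.
#' @return A list: `manifest` (tibble `sample`, `file`),
#'   `expected_counts` (a `"otu_counts"` tibble of the planted
#'   per-sample draws), `ref_seqs`.
#' @export
simulate_reads <- function(proportions, n_samples = 4,
                           reads_per_sample = 500, error_rate = 0.005,
                           ref_seqs = NULL, read_length = 300,
                           format = c("fasta", "fastq"),
                           dir = tempfile("reads"), seed = 1L) {
  format <- match.arg(format)
  set.seed(as.integer(seed))
  n_otus <- length(proportions)
  if (is.null(ref_seqs))
    ref_seqs <- reference_sequences(n_otus, length = read_length,
                                    seed = sample.int(1e6, 1))
  stopifnot(length(ref_seqs) == n_otus)
  if (is.null(names(ref_seqs)))
    names(ref_seqs) <- paste0("ref", seq_len(n_otus))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bases <- c("A", "C", "G", "T")

  mutate_read <- function(s) {
    v <- strsplit(s, "")[[1L]]
    hit <- which(runif(length(v)) < error_rate)
    for (p in hit) v[p] <- sample(setdiff(bases, v[p]), 1L)
    paste(v, collapse = "")
  }

  samples <- sprintf("sim%02d", seq_len(n_samples))
  counts <- matrix(0L, n_samples, n_otus,
                   dimnames = list(samples, names(ref_seqs)))
  files <- character(n_samples)
  for (k in seq_len(n_samples)) {
    draw <- as.integer(rmultinom(1L, reads_per_sample, proportions))
    counts[k, ] <- draw
    src <- rep(seq_len(n_otus), draw)
    seqs <- vapply(ref_seqs[src], function(s)
      if (error_rate > 0) mutate_read(s) else s, character(1))
    ids <- sprintf("%s_read%04d", samples[k], seq_along(seqs))
    ext <- if (format == "fasta") ".fasta" else ".fastq"
    f <- file.path(dir, paste0(samples[k], ext))
    if (format == "fasta") {
      writeLines(paste0(">", ids, "\n", seqs), f)
    } else {
      q <- strrep(rawToChar(as.raw(35 + 33)), nchar(seqs))
      writeLines(paste0("@", ids, "\n", seqs, "\n+\n", q), f)
    }
    files[k] <- f
  }
  expected <- count_table(
    dplyr::bind_cols(tibble(sample = samples),
                     as_tibble(as.data.frame(counts))),
    sample = "sample", factors = character(0))
  list(manifest = tibble(sample = samples, file = files),
       expected_counts = expected, ref_seqs = ref_seqs)
}
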