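#' Read amplicon reads from FASTA/FASTQ into a tibble
#'
#' One row per read: `id`, `sample`, `bases`, `quals` (phred scores
#' as an integer-list column; `NULL` entries when the input has no
#' qualities). Format is taken from the file extension
#' (`.fastq`/`.fq` vs anything else); gzipped files are accepted.
#'
#' @param file Path to a FASTA or FASTQ file.
#' @param sample Sample id attached to every read; default the file
#'   name without extension.
#' @return A tibble of reads.
#' @export
read_amplicon_file <- function(file, sample = NULL) {
  if (is.null(sample))
    sample <- sub("\\.(fasta|fa|fastq|fq)(\\.gz)?$", "", basename(file))
  is_fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", file)
  if (is_fastq) {
    x <- Biostrings::readDNAStringSet(file, format = "fastq",
                                      with.qualities = TRUE)
    q <- as.character(S4Vectors::mcols(x)$qualities)
    quals <- lapply(q, function(s) utf8ToInt(s) - 33L)
  } else {
    x <- Biostrings::readDNAStringSet(file, format = "fasta")
    quals <- vector("list", length(x))
  }
  tibble(id = names(x), sample = sample,
         bases = as.character(x), quals = quals)
}

#' Quality and length filtering of reads
#'
#' Keeps reads at least `min_len` bases long and, when qualities are
#' present, with at most `max_frac_below` of bases below phred
#' `min_q`. Reads without qualities pass the quality check vacuously.
#'
#' @param reads A reads tibble (see [read_amplicon_file()]).
#' @param min_len Minimum read length; default 290.
#' @param min_q Phred threshold; default 20.
#' @param max_frac_below Tolerated fraction of low-quality bases;
#'   default 0.2.
#' @return The filtered reads tibble.
#' @export
filter_reads <- function(reads, min_len = 290, min_q = 20,
                         max_frac_below = 0.2) {
  reads <- as_tibble(reads)
  len_ok <- nchar(reads$bases) >= min_len
  q_ok <- if (!"quals" %in% names(reads)) rep(TRUE, nrow(reads))
          else vapply(reads$quals, function(q) {
            if (is.null(q) || length(q) == 0L) TRUE
            else mean(q < min_q) <= max_frac_below
          }, logical(1))
  reads[len_ok & q_ok, , drop = FALSE]
}

#' Pairwise sequence identity (ends-free global alignment)
#'
#' Identity is defined as matching columns divided by the alignment
#' length (including internal gaps) of a global alignment with free
#' end gaps. This single fixed definition makes clustering thresholds
#' unambiguous: two 300-mers differing at 8 positions have identity
#' 292/300 = 97.33%. Alignment scoring is match +1 / mismatch -1 with
#' gap opening 10 and extension 4: gaps are deliberately expensive so
#' runs of substitutions are not re-written as indels.
#'
#' @param a,b Nucleotide strings. `a` may be a character vector; the
#'   result is vectorised over it.
#' @return Identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(a), Biostrings::DNAString(b),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 10, gapExtension = 4)
  al_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  unname(ifelse(al_len > 0, Biostrings::nmatch(aln) / al_len, 0))
}

#' Dereplicate reads into unique sequences with abundances
#'
#' @param reads A reads tibble.
#' @return A tibble `sequence`, `abundance`, sorted by abundance
#'   descending with lexicographic tie-break (the deterministic input
#'   order greedy clustering expects).
#' @export
dereplicate <- function(reads) {
  tab <- table(reads$bases)
  out <- tibble(sequence = names(tab), abundance = as.integer(tab))
  dplyr::arrange(out, dplyr::desc(.data$abundance), .data$sequence)
}

#' Greedy centroid clustering of unique sequences
#'
#' Processes sequences in abundance order (descending, lexicographic
#' tie-break). Each sequence joins the first existing centroid (in
#' founding order) with identity at or above the threshold, otherwise
#' founds a new centroid. With the identity definition of
#' [seq_identity()], a 97% threshold merges 300-mers differing at up
#' to 9 positions and splits at 10.
#'
#' @param uniques A tibble `sequence`, `abundance` (see
#'   [dereplicate()]); reads tibbles are dereplicated automatically.
#' @param identity Clustering threshold; default 0.97.
#' @return A tibble catalog: `otu`, `sequence` (the representative),
#'   `abundance` (summed over members), `n_members`.
#' @export
cluster_otus <- function(uniques, identity = 0.97) {
  if (!"abundance" %in% names(uniques)) uniques <- dereplicate(uniques)
  uniques <- dplyr::arrange(as_tibble(uniques),
                            dplyr::desc(.data$abundance), .data$sequence)
  if (nrow(uniques) == 0L)
    return(tibble(otu = character(), sequence = character(),
                  abundance = integer(), n_members = integer()))
  reps <- character(0); ab <- integer(0); nm <- integer(0)
  for (i in seq_len(nrow(uniques))) {
    s <- uniques$sequence[i]
    hit <- 0L
    if (length(reps)) {
      ids <- seq_identity(reps, s)
      ok <- which(ids >= identity)
      if (length(ok)) hit <- ok[[1L]]
    }
    if (hit > 0L) {
      ab[hit] <- ab[hit] + uniques$abundance[i]
      nm[hit] <- nm[hit] + 1L
    } else {
      reps <- c(reps, s)
      ab <- c(ab, uniques$abundance[i])
      nm <- c(nm, 1L)
    }
  }
  tibble(otu = paste0("otu", seq_along(reps)), sequence = reps,
         abundance = ab, n_members = nm)
}

#' Map reads to OTU representatives, counting unambiguous matches
#'
#' Each read is assigned to the unique best-identity representative
#' meeting the threshold. Reads whose top two identities tie, or that
#' reach no representative at the threshold, are left unassigned:
#' only unambiguous matches are counted.
#'
#' @param reads A reads tibble.
#' @param catalog A [cluster_otus()] catalog.
#' @param identity Assignment threshold; default 0.97.
#' @return The reads tibble with added columns `otu` (`NA` when
#'   unassigned) and `identity` (best identity reached).
#' @export
map_reads <- function(reads, catalog, identity = 0.97) {
  if (nrow(catalog) == 0L) abort("Empty OTU catalog.")
  reads <- as_tibble(reads)
  uniq <- unique(reads$bases)
  idm <- vapply(catalog$sequence, function(rep)
    seq_identity(uniq, rep), numeric(length(uniq)))
  idm <- matrix(idm, nrow = length(uniq))
  assign_one <- function(row) {
    best <- max(row)
    if (best < identity) return(NA_character_)
    top <- which(row == best)
    if (length(top) > 1L) return(NA_character_)
    catalog$otu[top]
  }
  uniq_otu <- apply(idm, 1L, assign_one)
  uniq_best <- apply(idm, 1L, max)
  j <- match(reads$bases, uniq)
  reads$otu <- uniq_otu[j]
  reads$identity <- uniq_best[j]
  reads
}

#' Reads-to-counts pipeline
#'
#' Composes the four pipeline stages — quality/length filtering,
#' dereplication, greedy centroid clustering, unambiguous mapping —
#' over per-sample read files described by a manifest, yielding an
#' OTU count table with the manifest's design columns attached.
#'
#' @param manifest A data frame (or TSV path) with columns `sample`,
#'   `file` and any design columns.
#' @param min_len,min_q,max_frac_below Passed to [filter_reads()].
#' @param cluster_identity,map_identity Identity thresholds; default
#'   0.97 each.
#' @return A `"otu_counts"` tibble with attributes `catalog` (the
#'   representative sequences) and `read_stats` (per-sample tibble:
#'   `n_input`, `n_filtered_out`, `n_assigned`, `n_unassigned`;
#'   conservation `n_input = n_filtered_out + n_assigned +
#'   n_unassigned` holds by construction).
#' @export
counts_from_reads <- function(manifest, min_len = 290, min_q = 20,
                              max_frac_below = 0.2,
                              cluster_identity = 0.97,
                              map_identity = 0.97) {
  if (is.character(manifest))
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE,
                                progress = FALSE)
  manifest <- as_tibble(manifest)
  if (!all(c("sample", "file") %in% names(manifest)))
    abort("Manifest needs columns 'sample' and 'file'.")
  factors <- setdiff(names(manifest), c("sample", "file"))

  reads <- purrr::map2_dfr(manifest$file, manifest$sample,
                           function(f, s) read_amplicon_file(f, sample = s))
  n_input <- table(factor(reads$sample, levels = manifest$sample))
  kept <- filter_reads(reads, min_len = min_len, min_q = min_q,
                       max_frac_below = max_frac_below)
  n_kept <- table(factor(kept$sample, levels = manifest$sample))

  catalog <- cluster_otus(dereplicate(kept), identity = cluster_identity)
  mapped <- map_reads(kept, catalog, identity = map_identity)
  n_assigned <- table(factor(mapped$sample[!is.na(mapped$otu)],
                             levels = manifest$sample))

  counts <- matrix(0L, nrow(manifest), nrow(catalog),
                   dimnames = list(manifest$sample, catalog$otu))
  hits <- mapped[!is.na(mapped$otu), ]
  if (nrow(hits)) {
    agg <- dplyr::count(hits, .data$sample, .data$otu)
    counts[cbind(match(agg$sample, manifest$sample),
                 match(agg$otu, catalog$otu))] <- agg$n
  }
  tbl <- count_table(
    dplyr::bind_cols(manifest[, c("sample", factors)],
                     as_tibble(as.data.frame(counts))),
    sample = "sample", factors = factors)
  attr(tbl, "catalog") <- catalog
  attr(tbl, "read_stats") <- tibble(
    sample = manifest$sample,
    n_input = as.integer(n_input),
    n_filtered_out = as.integer(n_input) - as.integer(n_kept),
    n_assigned = as.integer(n_assigned),
    n_unassigned = as.integer(n_kept) - as.integer(n_assigned))
  tbl
}
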