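#' Trellis panels of OTU abundance by condition
#'
#' One panel per OTU showing per-sample observed proportions of total
#' (started-log scale) by condition cell, with panels of OTUs having
#' at least one FDR-significant contrast annotated.
#'
#' @param data A count table.
#' @param contrasts Optional [pairwise_contrasts()] table used for
#'   significance annotation.
#' @param path Optional output file (`.png`, `.svg` or `.pdf`); when
#'   given, the figure is written there.
#' @param otus OTUs to show; default all in `contrasts` (or all in
#'   `data` when no contrasts are given).
#' @param alpha FDR threshold for annotation; default 0.05.
#' @param width,height Device size in inches for `path`.
#' @return The ggplot object, invisibly.
#' @export
plot_otu_panels <- function(data, contrasts = NULL, path = NULL,
                            otus = NULL, alpha = 0.05,
                            width = 8, height = 6) {
  data <- as_count_table(data)
  if (is.null(otus)) {
    otus <- if (!is.null(contrasts) && nrow(contrasts))
      unique(contrasts$otu) else otu_ids(data)
  }
  m <- otu_matrix(data)
  totals <- rowSums(m)
  fac <- sample_factors(data)
  cell <- if (ncol(fac) > 1L) do.call(paste, c(fac[-1L], sep = ":"))
          else rep("(all)", nrow(fac))
  df <- purrr::map_dfr(otus, function(o) {
    tibble(otu = o, sample = rownames(m), cell = cell,
           proportion = pmax(m[, o] / totals, 1e-5))
  })
  sig <- character(0)
  if (!is.null(contrasts) && nrow(contrasts))
    sig <- unique(contrasts$otu[contrasts$q_fdr < alpha])
  df$otu_label <- ifelse(df$otu %in% sig, paste0(df$otu, " *"), df$otu)
  df$otu_label <- factor(df$otu_label,
                         levels = unique(df$otu_label[order(match(df$otu,
                                                                  otus))]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cell,
                                        y = .data$proportion)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, size = 0.6, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~otu_label, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "proportion of sample total",
                  caption = if (length(sig))
                    paste0("* at least one contrast with FDR < ", alpha)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(path))
    ggplot2::ggsave(path, p, width = width, height = height)
  invisible(p)
}

#' @export
autoplot.pln_contrasts <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  df$pair <- paste(df$condition_a, "-", df$condition_b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_logdiff,
                                   y = .data$pair,
                                   colour = .data$q_fdr < alpha)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~otu) +
    ggplot2::labs(x = "posterior log fold difference", y = NULL,
                  colour = paste0("FDR < ", alpha)) +
    ggplot2::theme_bw()
}

#' @export
autoplot.pln_fit <- function(object, level = 0.95, ...) {
  props <- abundance_proportions(object, level = level)
  ggplot2::ggplot(props, ggplot2::aes(x = .data$condition,
                                      y = .data$mean_proportion)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~otu) +
    ggplot2::labs(x = NULL, y = "posterior proportion of total") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
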