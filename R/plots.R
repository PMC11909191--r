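#' Plot target and decoy score distributions with the FDR threshold
#'
#' @param object An `fdr_filter` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fdr_filter <- function(object, ...) {
  d <- bind_rows(
    object$all_targets %>% mutate(class = "target"),
    tibble(score = numeric(0), class = character(0))
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6, position = "identity") +
    ggplot2::labs(
      x = "best peptide score", y = "peptides",
      title = sprintf(
        "Peptide-level target-decoy filter (q <= %g, threshold %.2f)",
        object$alpha, object$threshold
      )
    ) +
    ggplot2::theme_minimal()
  if (is.finite(object$threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = object$threshold, linetype = 2)
  }
  p
}

#' Body versus upstream phenotype-score plot
#'
#' The classic screen scatter: each point is one ORF, body score against
#' upstream (host-RNA control) score, coloured by hit class, with the
#' classification cutoffs drawn.
#'
#' @param object A `screen_phenotypes` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screen_phenotypes <- function(object, ...) {
  bc <- attr(object, "body_cutoff")
  uc <- attr(object, "upstream_cutoff")
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$body_score, y = .data$upstream_score, colour = .data$hit_class)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-bc, bc), linetype = 2) +
    ggplot2::geom_hline(yintercept = c(-uc, uc), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(
      pro_proliferative = "#c0392b", anti_proliferative = "#27ae60",
      host_rna_effect = "#f39c12", non_hit = "grey60"
    )) +
    ggplot2::labs(
      x = "ORF body score (mean guide log2 fold change)",
      y = "upstream control score", colour = "class"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of start-codon usage
#'
#' @param catalogue ORF or peptide catalogue with a `start_codon` column.
#' @return A ggplot.
#' @export
plot_start_codon_usage <- function(catalogue) {
  ggplot2::ggplot(
    start_codon_usage(catalogue),
    ggplot2::aes(x = .data$start_codon, y = .data$fraction)
  ) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "start codon", y = "fraction of ORFs") +
    ggplot2::theme_minimal()
}

#' Peptide length distributions by host transcript type
#'
#' @param catalogue Catalogue with `peptide` and `category` columns.
#' @return A ggplot.
#' @export
plot_length_distribution <- function(catalogue) {
  d <- catalogue %>% mutate(
    aa_len = nchar(.data$peptide),
    host = ifelse(.data$category == "novel_nc", "ncRNA", "mRNA")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$aa_len, fill = .data$host)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "peptide length (aa)", y = "density", fill = "host") +
    ggplot2::theme_minimal()
}

#' Absolute guide fold change by control class
#'
#' @param lfc Tibble from [guide_lfc()].
#' @param manifest sgRNA manifest.
#' @return A ggplot.
#' @export
plot_control_separation <- function(lfc, manifest) {
  d <- manifest %>% left_join(lfc, by = "sgrna_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = abs(.data$lfc))) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::labs(x = "sgRNA class", y = "|log2 fold change|") +
    ggplot2::theme_minimal()
}
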