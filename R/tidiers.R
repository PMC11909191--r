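#' Tidy a peptide-level FDR filter
#'
#' Returns one row per target peptide with its best score, PSM count and
#' q-value, plus a logical `retained` column.
#'
#' @param x An `fdr_filter` object from [peptide_level_fdr()].
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.fdr_filter <- function(x, ...) {
  x$all_targets %>%
    mutate(retained = .data$q_value <= x$alpha) %>%
    arrange(dplyr::desc(.data$score))
}

#' One-row summary of a peptide-level FDR filter
#'
#' @inheritParams tidy.fdr_filter
#' @return One-row tibble: `alpha`, `n_target_peptides`,
#'   `n_decoy_peptides`, `n_retained`, `threshold`.
#' @export
glance.fdr_filter <- function(x, ...) {
  tibble(
    alpha = x$alpha,
    n_target_peptides = x$n_target_peptides,
    n_decoy_peptides = x$n_decoy_peptides,
    n_retained = x$n_retained,
    threshold = x$threshold
  )
}

#' Tidy screen phenotype calls
#'
#' @param x A `screen_phenotypes` tibble from [phenotype_scores()].
#' @param ... Unused.
#' @return Plain tibble of per-ORF scores and classes.
#' @export
tidy.screen_phenotypes <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "screen_phenotypes")
  as_tibble(out)
}

#' One-row summary of screen phenotype calls
#'
#' @inheritParams tidy.screen_phenotypes
#' @return One-row tibble with cutoffs and per-class ORF counts.
#' @export
glance.screen_phenotypes <- function(x, ...) {
  tb <- table(factor(
    x$hit_class,
    levels = c("pro_proliferative", "anti_proliferative", "host_rna_effect", "non_hit")
  ))
  tibble(
    n_orfs = nrow(x),
    n_pro_proliferative = as.integer(tb[["pro_proliferative"]]),
    n_anti_proliferative = as.integer(tb[["anti_proliferative"]]),
    n_host_rna_effect = as.integer(tb[["host_rna_effect"]]),
    n_non_hit = as.integer(tb[["non_hit"]]),
    body_cutoff = attr(x, "body_cutoff"),
    upstream_cutoff = attr(x, "upstream_cutoff")
  )
}
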