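#' Start-codon usage of a catalogue
#'
#' @param catalogue Tibble with a `start_codon` column.
#' @param codons Codons to tabulate (zero counts are kept).
#' @return Tibble `start_codon`, `n`, `fraction`; fractions sum to 1.
#' @export
start_codon_usage <- function(catalogue, codons = c("ATG", "CTG", "GTG", "TTG")) {
  if (nrow(catalogue) == 0L) abort("empty catalogue")
  counts <- table(factor(catalogue$start_codon, levels = codons))
  tibble(
    start_codon = codons,
    n = as.integer(counts),
    fraction = as.integer(counts) / nrow(catalogue)
  )
}

#' Length and host-origin summaries of a catalogue
#'
#' Stratifies peptide lengths by host type -- `nc` for ORFs on noncoding
#' transcripts versus `mRNA` for mRNA-hosted classes (u/alt/d) -- and
#' tabulates per-gene peptide counts and ORF-type fractions.
#'
#' @param catalogue Tibble with `category`, `peptide` and gene columns
#'   (`gene_name`, falling back to `gene_id`).
#' @return List of tibbles: `length_by_host` (host, n, median/mean length),
#'   `per_gene` (gene, n_peptides), `by_category` (category, n, fraction).
#' @export
length_origin_summary <- function(catalogue) {
  if (nrow(catalogue) == 0L) abort("empty catalogue")
  d <- catalogue %>%
    mutate(
      aa_len = nchar(.data$peptide),
      host = ifelse(.data$category == "novel_nc", "nc", "mRNA"),
      gene = ifelse(is.na(.data$gene_name) | .data$gene_name == "",
        .data$gene_id, .data$gene_name
      )
    )
  list(
    length_by_host = d %>%
      group_by(.data$host) %>%
      summarise(
        n = n(), median_aa = median(.data$aa_len),
        mean_aa = mean(.data$aa_len), .groups = "drop"
      ),
    per_gene = d %>%
      group_by(.data$gene) %>%
      summarise(n_peptides = n(), .groups = "drop") %>%
      arrange(dplyr::desc(.data$n_peptides), .data$gene),
    by_category = d %>%
      group_by(.data$category) %>%
      summarise(n = n(), .groups = "drop") %>%
      mutate(fraction = .data$n / sum(.data$n))
  )
}

#' Associate phenotype scores with external per-ORF covariates
#'
#' For each numeric covariate (e.g. a coding-potential or conservation
#' score supplied by an external tool), reports the Spearman correlation
#' between the covariate and the absolute phenotype score, and a two-sided
#' Wilcoxon rank-sum contrast of the covariate between hit and non-hit
#' ORFs. Raw p-values are Benjamini-Hochberg adjusted across the whole
#' battery; both raw and adjusted values are emitted.
#'
#' @param phenotypes `screen_phenotypes` tibble (needs `orf_id`,
#'   `body_score`, `hit_class`).
#' @param covariates Tibble with `orf_id` plus numeric covariate columns.
#' @return Tibble: `covariate`, `test` (`spearman` or `wilcoxon_hit`),
#'   `estimate`, `n`, `p_value`, `p_adj`.
#' @export
covariate_association <- function(phenotypes, covariates) {
  joined <- dplyr::inner_join(
    as_tibble(phenotypes), covariates,
    by = "orf_id"
  )
  if (nrow(joined) < 3L) abort("fewer than 3 ORFs shared between phenotypes and covariates")
  covs <- setdiff(names(covariates), "orf_id")
  joined$abs_score <- abs(joined$body_score)
  joined$is_hit <- joined$hit_class %in% c("pro_proliferative", "anti_proliferative")
  rows <- purrr::map(covs, function(cv) {
    x <- joined[[cv]]
    ok <- is.finite(x) & is.finite(joined$abs_score)
    ct <- suppressWarnings(
      cor.test(joined$abs_score[ok], x[ok], method = "spearman", exact = FALSE)
    )
    out <- tibble(
      covariate = cv, test = "spearman",
      estimate = unname(ct$estimate), n = sum(ok), p_value = ct$p.value
    )
    hit <- x[joined$is_hit & is.finite(x)]
    non <- x[!joined$is_hit & is.finite(x)]
    if (length(hit) >= 2L && length(non) >= 2L) {
      wt <- suppressWarnings(wilcox.test(hit, non, exact = FALSE))
      out <- bind_rows(out, tibble(
        covariate = cv, test = "wilcoxon_hit",
        estimate = median(hit) - median(non),
        n = length(hit) + length(non), p_value = wt$p.value
      ))
    }
    out
  })
  out <- bind_rows(rows)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}
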