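#' Read a peptide-spectrum-match table
#'
#' Expects a TSV with columns `spectrum_id`, `sample_id`, `peptide`,
#' `orf_ids` (semicolon-separated library entries sharing the matched
#' sequence), `score` (higher is better) and `is_decoy`. Duplicate
#' `(spectrum_id, peptide)` rows are collapsed keeping the best score.
#'
#' @param path Path to a TSV file.
#' @return Tibble of typed PSM records; `orf_ids` is a list-column of
#'   character vectors.
#' @export
read_psm_table <- function(path) {
  req <- c("spectrum_id", "sample_id", "peptide", "orf_ids", "score", "is_decoy")
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L) {
    abort(paste0("PSM table missing column(s): ", paste(missing, collapse = ", ")))
  }
  score_num <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score_num) & !is.na(df$score))
  if (length(bad) > 0L) {
    abort(paste0("non-numeric score at row ", bad[[1]], ": '", df$score[[bad[[1]]]], "'"))
  }
  if (anyNA(score_num)) abort("missing score value(s) in PSM table")
  df$score <- score_num
  df$is_decoy <- df$is_decoy %in% c("TRUE", "True", "true", "1")
  df %>%
    group_by(.data$spectrum_id, .data$peptide) %>%
    slice(which.max(.data$score)) %>%
    ungroup() %>%
    mutate(orf_ids = strsplit(.data$orf_ids, ";", fixed = TRUE)) %>%
    arrange(.data$spectrum_id, .data$peptide)
}

#' Discard spectra matched to multiple distinct peptide sequences
#'
#' A spectrum assigned two or more distinct peptide sequences is removed
#' entirely (every record it produced). A spectrum whose single sequence is
#' shared by several library ORFs is retained: distinctness is judged at
#' the sequence level, not the ORF level.
#'
#' @param psms PSM tibble from [read_psm_table()].
#' @return Filtered PSM tibble.
#' @export
discard_ambiguous_spectra <- function(psms) {
  psms %>%
    group_by(.data$spectrum_id) %>%
    filter(n_distinct(.data$peptide) == 1L) %>%
    ungroup()
}

#' Peptide-level target-decoy FDR filtering
#'
#' Aggregates PSMs to the best score per peptide sequence (targets and
#' decoys separately), sweeps every observed score as a threshold, and
#' estimates `FDR(t) = #decoy peptides >= t / #target peptides >= t`. The
#' estimates are converted to monotone q-values (the minimum FDR over all
#' less stringent thresholds) and target peptides with `q <= alpha` are
#' retained; peptides tied exactly at the threshold score are kept.
#'
#' @param psms PSM tibble containing both target and decoy records.
#' @param alpha Nominal peptide-level FDR, in (0, 1); default 0.01.
#' @return An object of class `fdr_filter`: a list with `peptides` (the
#'   retained target peptides with `peptide`, `score`, `psm_count`,
#'   `samples` list-column, `orf_ids` list-column and `q_value`),
#'   `all_targets` (every target peptide with its q-value), `threshold`
#'   (lowest retained score, `Inf` if nothing retained), `alpha`, and
#'   counts. Use [tidy()] / [glance()] to extract tibbles.
#' @export
peptide_level_fdr <- function(psms, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  if (!any(psms$is_decoy)) {
    abort("no decoy records present; run the search with a decoy database")
  }
  agg <- psms %>%
    group_by(.data$peptide, .data$is_decoy) %>%
    summarise(
      score = max(.data$score),
      psm_count = n(),
      samples = list(sort(unique(.data$sample_id))),
      orf_ids = list(sort(unique(unlist(.data$orf_ids)))),
      .groups = "drop"
    )
  targets <- agg %>% filter(!.data$is_decoy)
  decoys <- agg %>% filter(.data$is_decoy)
  thr <- sort(unique(agg$score), decreasing = TRUE)
  n_t <- vapply(thr, function(t) sum(targets$score >= t), integer(1))
  n_d <- vapply(thr, function(t) sum(decoys$score >= t), integer(1))
  fdr <- ifelse(n_t == 0L, 0, n_d / n_t)
  qv <- rev(cummin(rev(fdr)))
  targets$q_value <- vapply(targets$score, function(s) qv[[findInterval(-s, -thr)]], numeric(1))
  retained <- targets %>% filter(.data$q_value <= alpha) %>% select(-"is_decoy")
  structure(
    list(
      peptides = retained,
      all_targets = targets %>% select(-"is_decoy"),
      threshold = if (nrow(retained) > 0L) min(retained$score) else Inf,
      alpha = alpha,
      n_target_peptides = nrow(targets),
      n_decoy_peptides = nrow(decoys),
      n_retained = nrow(retained)
    ),
    class = "fdr_filter"
  )
}

#' @export
print.fdr_filter <- function(x, ...) {
  cat(
    "Peptide-level target-decoy FDR filter\n",
    "  targets: ", x$n_target_peptides,
    "  decoys: ", x$n_decoy_peptides, "\n",
    "  retained at q <= ", x$alpha, ": ", x$n_retained,
    " (score threshold ", format(x$threshold, digits = 4), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Remove annotated and canonically embedded peptides
#'
#' Drops identified peptides whose supporting ORFs are all of category
#' `annotated` (already catalogued proteins), then drops peptides whose
#' supporting ORFs are all internal ORFs (`intORF`) and whose sequence is
#' an exact substring of any canonical protein. The embedding test applies
#' to internal ORFs only: an ncRNA-hosted peptide that happens to match a
#' canonical substring is retained. Matching is exact (no I/L equivalence)
#' unless `collapse_il = TRUE`, which treats I and L as identical on both
#' sides.
#'
#' @param pepids Peptide tibble with `peptide` and `orf_ids` list-column.
#' @param catalogue ORF catalogue providing `orf_id` and `category`.
#' @param canonical Named character vector of canonical protein sequences,
#'   or a path to a canonical proteome FASTA.
#' @param collapse_il Treat isoleucine and leucine as equivalent in the
#'   embedding test. Default `FALSE`.
#' @return Filtered peptide tibble with a `category` column (the unique
#'   supporting-ORF categories, collapsed with `;`).
#' @export
remove_annotated_and_embedded <- function(pepids, catalogue, canonical,
                                          collapse_il = FALSE) {
  if (is.character(canonical) && length(canonical) == 1L && file.exists(canonical)) {
    aa <- Biostrings::readAAStringSet(canonical)
    canonical <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  }
  if (!is.character(canonical)) abort("canonical proteome unreadable")
  cat_of <- setNames(catalogue$category, catalogue$orf_id)
  cats <- purrr::map(pepids$orf_ids, function(ids) {
    cc <- cat_of[ids]
    if (anyNA(cc)) abort(paste0("orf_id not in catalogue: ", ids[is.na(cc)][[1]]))
    sort(unique(unname(cc)))
  })
  pepids$category <- vapply(cats, paste, character(1), collapse = ";")
  keep1 <- !vapply(cats, function(cc) all(cc == "annotated"), logical(1))
  pepids <- pepids[keep1, ]
  cats <- cats[keep1]
  haystack <- paste(canonical, collapse = "|")
  pep <- pepids$peptide
  if (collapse_il) {
    haystack <- chartr("I", "L", haystack)
    pep <- chartr("I", "L", pep)
  }
  int_only <- vapply(cats, function(cc) all(cc == "intORF"), logical(1))
  embedded <- int_only & stringr::str_detect(haystack, stringr::fixed(pep))
  pepids[!embedded, ]
}

#' Resolve redundant overlapping ORFs
#'
#' Identified ORFs are grouped by genomic overlap on the same strand
#' (connected components of the overlap graph over their normalised
#' genomic spans). Within each group, ORFs are processed in descending
#' length: when a longer ORF carries at least one supporting identified
#' peptide that maps outside the shorter overlapping ORF (its sequence is
#' not a substring of the shorter ORF's peptide), the shorter ORF is
#' discarded. Groups where no such evidence exists keep all members,
#' flagged `unresolved_redundant`. Peptides losing every supporting ORF
#' are removed; surviving peptides have discarded ORFs pruned from their
#' `orf_ids`.
#'
#' @param pepids Peptide tibble with `peptide` and `orf_ids` list-column.
#' @param catalogue ORF catalogue with `orf_id`, `chrom`, `strand`,
#'   `g_min`, `g_max`, `length_nt`, `peptide`.
#' @return Peptide tibble with pruned `orf_ids` and a logical
#'   `unresolved_redundant` flag.
#' @export
resolve_redundant_orfs <- function(pepids, catalogue) {
  support_ids <- sort(unique(unlist(pepids$orf_ids)))
  orfs <- catalogue %>% filter(.data$orf_id %in% support_ids)
  if (nrow(orfs) == 0L) {
    pepids$unresolved_redundant <- logical(nrow(pepids))
    return(pepids)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$chrom,
    ranges = IRanges::IRanges(start = orfs$g_min, end = orfs$g_max),
    strand = orfs$strand
  )
  red <- GenomicRanges::reduce(gr)
  grp <- GenomicRanges::findOverlaps(gr, red, select = "first")
  # peptides supporting each ORF
  peps_of <- split(
    rep(pepids$peptide, lengths(pepids$orf_ids)),
    unlist(pepids$orf_ids)
  )
  removed <- character(0)
  unresolved <- character(0)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    sub <- orfs[idx, ] %>% arrange(dplyr::desc(.data$length_nt), .data$orf_id)
    gone <- rep(FALSE, nrow(sub))
    for (i in seq_len(nrow(sub) - 1L)) {
      if (gone[[i]]) next
      for (j in (i + 1L):nrow(sub)) {
        if (gone[[j]]) next
        same_strand <- sub$strand[[i]] == sub$strand[[j]]
        overlaps <- sub$g_min[[i]] <= sub$g_max[[j]] && sub$g_min[[j]] <= sub$g_max[[i]]
        if (!same_strand || !overlaps) next
        long_peps <- peps_of[[sub$orf_id[[i]]]]
        if (is.null(long_peps)) next
        unique_support <- any(!stringr::str_detect(
          sub$peptide[[j]], stringr::fixed(long_peps)
        ))
        if (unique_support) gone[[j]] <- TRUE
      }
    }
    if (any(gone)) {
      removed <- c(removed, sub$orf_id[gone])
    } else {
      unresolved <- c(unresolved, sub$orf_id)
    }
  }
  pepids$orf_ids <- purrr::map(pepids$orf_ids, ~ setdiff(.x, removed))
  pepids$unresolved_redundant <- purrr::map_lgl(
    pepids$orf_ids, ~ any(.x %in% unresolved)
  )
  pepids[lengths(pepids$orf_ids) > 0L, ]
}

#' Summarise PSM and cross-sample support for the final catalogue
#'
#' @param pepids Peptide tibble with `psm_count` and `samples` list-column.
#' @return One-row tibble: `n_peptides`, `n_single_psm`, `frac_single_psm`,
#'   `n_multi_psm`, `frac_multi_psm`, `n_multi_sample`, `frac_multi_sample`.
#' @export
summarize_support <- function(pepids) {
  n <- nrow(pepids)
  single <- sum(pepids$psm_count == 1L)
  multi_sample <- sum(lengths(pepids$samples) >= 2L)
  tibble(
    n_peptides = n,
    n_single_psm = single,
    frac_single_psm = if (n > 0) single / n else NA_real_,
    n_multi_psm = n - single,
    frac_multi_psm = if (n > 0) (n - single) / n else NA_real_,
    n_multi_sample = multi_sample,
    frac_multi_sample = if (n > 0) multi_sample / n else NA_real_
  )
}

#' Run the full PSM filter cascade
#'
#' Applies, in fixed order: ambiguous-spectrum removal, peptide-level
#' target-decoy FDR control, annotated/canonically-embedded removal, and
#' redundant-ORF resolution. A stage-by-stage audit ledger records record
#' counts in and out of every stage (PSM records for the first stage,
#' peptide identifications thereafter); counts never increase through the
#' cascade.
#'
#' @param psms PSM tibble from [read_psm_table()].
#' @param catalogue ORF catalogue from [build_orf_library()].
#' @param canonical Canonical proteome (named character vector or FASTA
#'   path).
#' @param alpha Nominal peptide-level FDR. Default 0.01.
#' @param collapse_il Passed to [remove_annotated_and_embedded()].
#' @return List with `peptides` (final catalogue tibble), `report` (tibble
#'   `stage`, `unit`, `n_in`, `n_out`), `fdr` (the `fdr_filter` object) and
#'   `threshold`.
#' @export
filter_psms <- function(psms, catalogue, canonical, alpha = 0.01,
                        collapse_il = FALSE) {
  n0 <- nrow(psms)
  unamb <- discard_ambiguous_spectra(psms)
  fdr <- peptide_level_fdr(unamb, alpha = alpha)
  pep1 <- fdr$peptides
  pep2 <- remove_annotated_and_embedded(pep1, catalogue, canonical,
    collapse_il = collapse_il
  )
  pep3 <- resolve_redundant_orfs(pep2, catalogue)
  report <- tibble(
    stage = c(
      "ambiguous_spectra", "peptide_fdr", "annotated_embedded",
      "redundant_orfs"
    ),
    unit = c("psm", "peptide", "peptide", "peptide"),
    n_in = c(n0, fdr$n_target_peptides, nrow(pep1), nrow(pep2)),
    n_out = c(nrow(unamb), nrow(pep1), nrow(pep2), nrow(pep3))
  )
  list(peptides = pep3, report = report, fdr = fdr, threshold = fdr$threshold)
}
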