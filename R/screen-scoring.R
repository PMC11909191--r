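#' Reads-per-million log2 normalisation of sgRNA counts
#'
#' Each count column is scaled to reads per million (count / column sum x
#' 1e6) and transformed as `log2(rpm + 1)`; the pseudocount keeps
#' zero-count guides finite (a zero count maps exactly to 0).
#'
#' @param counts Tibble with an `sgrna_id` column and one non-negative
#'   integer column per sequencing sample.
#' @return Tibble of the same shape with normalised values.
#' @export
normalize_rpm_log2 <- function(counts) {
  stopifnot("sgrna_id" %in% names(counts))
  num_cols <- setdiff(names(counts), "sgrna_id")
  for (cl in num_cols) {
    v <- counts[[cl]]
    if (any(v < 0)) abort(paste0("negative count in column ", cl))
    tot <- sum(v)
    if (tot == 0) abort(paste0("zero column sum in ", cl))
    counts[[cl]] <- log2(v / tot * 1e6 + 1)
  }
  counts
}

#' Per-sgRNA log2 fold change between screen start and end
#'
#' Replicates are averaged on the normalised log2 scale before
#' differencing: `lfc = mean(final) - mean(initial)` per guide.
#'
#' @param norm Normalised tibble from [normalize_rpm_log2()].
#' @param initial,final Character vectors naming the initial- and
#'   final-timepoint replicate columns.
#' @return Tibble with `sgrna_id` and `lfc`.
#' @export
guide_lfc <- function(norm, initial, final) {
  stopifnot(length(initial) >= 1L, length(final) >= 1L)
  missing <- setdiff(c(initial, final), names(norm))
  if (length(missing) > 0L) {
    abort(paste0("column(s) not in count table: ", paste(missing, collapse = ", ")))
  }
  tibble(
    sgrna_id = norm$sgrna_id,
    lfc = rowMeans(as.matrix(norm[final])) - rowMeans(as.matrix(norm[initial]))
  )
}

#' Per-ORF phenotype scores and proliferation hit calls
#'
#' The phenotype (body) score of an ORF is the mean log2 fold change of the
#' sgRNAs targeting its coding region; the upstream score averages the
#' guides targeting the 1-kb region upstream, a host-RNA knockout control.
#' Classification uses the dual criterion: `|body| > body_cutoff` and
#' `|upstream| < upstream_cutoff` calls a hit, with the sign of the body
#' score separating pro-proliferative (body <= -cutoff, guides depleted)
#' from anti-proliferative (body >= cutoff, guides enriched);
#' `|body| > body_cutoff` with `|upstream| >= upstream_cutoff` is a
#' `host_rna_effect`; everything else is a `non_hit`. ORFs without
#' upstream guides get an `NA` upstream score, class `non_hit` and the
#' `no_upstream_guides` flag; ORFs with zero body guides are excluded with
#' a warning.
#'
#' @param lfc Tibble from [guide_lfc()].
#' @param manifest Tibble with `sgrna_id`, `target_id` and
#'   `region` in `body`/`upstream`/`scramble`/`essential`.
#' @param body_cutoff,upstream_cutoff Magnitude thresholds, default 1.
#' @return A tibble of class `screen_phenotypes`: `orf_id`, `body_score`,
#'   `upstream_score`, `n_body`, `n_upstream`, `hit_class`, `flag`.
#' @export
phenotype_scores <- function(lfc, manifest, body_cutoff = 1, upstream_cutoff = 1) {
  m <- manifest %>%
    filter(.data$region %in% c("body", "upstream")) %>%
    left_join(lfc, by = "sgrna_id")
  if (anyNA(m$lfc)) abort("manifest sgRNA(s) missing from the count table")
  per <- m %>%
    group_by(.data$target_id, .data$region) %>%
    summarise(score = mean(.data$lfc), n = n(), .groups = "drop") %>%
    tidyr::pivot_wider(
      names_from = "region", values_from = c("score", "n"),
      values_fill = list(n = 0L)
    )
  if (!"score_upstream" %in% names(per)) per$score_upstream <- NA_real_
  if (!"n_upstream" %in% names(per)) per$n_upstream <- 0L
  if (!"score_body" %in% names(per)) per$score_body <- NA_real_
  if (!"n_body" %in% names(per)) per$n_body <- 0L
  no_body <- per$n_body == 0L
  if (any(no_body)) {
    warn(paste0(
      sum(no_body), " ORF(s) with zero body guides excluded: ",
      paste(head(per$target_id[no_body], 5L), collapse = ", ")
    ))
    per <- per[!no_body, ]
  }
  out <- per %>%
    mutate(
      hit_class = case_when(
        .data$n_upstream == 0L ~ "non_hit",
        abs(.data$score_body) > body_cutoff &
          abs(.data$score_upstream) < upstream_cutoff &
          .data$score_body < 0 ~ "pro_proliferative",
        abs(.data$score_body) > body_cutoff &
          abs(.data$score_upstream) < upstream_cutoff ~ "anti_proliferative",
        abs(.data$score_body) > body_cutoff ~ "host_rna_effect",
        TRUE ~ "non_hit"
      ),
      flag = ifelse(.data$n_upstream == 0L, "no_upstream_guides", "")
    ) %>%
    rename(
      orf_id = "target_id", body_score = "score_body",
      upstream_score = "score_upstream"
    ) %>%
    select(
      "orf_id", "body_score", "upstream_score", "n_body", "n_upstream",
      "hit_class", "flag"
    ) %>%
    arrange(.data$orf_id)
  structure(out,
    class = c("screen_phenotypes", class(out)),
    body_cutoff = body_cutoff, upstream_cutoff = upstream_cutoff
  )
}

#' Control-class separation QC for a pooled screen
#'
#' Compares the absolute log2 fold-change distributions of essential-gene
#' and scramble control guides with a one-sided Wilcoxon rank-sum test
#' (essential expected to shift away from zero); per-region summaries are
#' always reported. If either control class is absent the QC test is
#' skipped with a warning.
#'
#' @param lfc Tibble from [guide_lfc()].
#' @param manifest sgRNA manifest (see [phenotype_scores()]).
#' @return List with `summary` (per-region n, median and mean of `|lfc|`),
#'   `p_value` (essential vs scramble, `NA` if skipped) and `qc_pass`.
#' @export
control_separation <- function(lfc, manifest) {
  d <- manifest %>% left_join(lfc, by = "sgrna_id")
  summ <- d %>%
    group_by(.data$region) %>%
    summarise(
      n = n(),
      median_abs_lfc = median(abs(.data$lfc)),
      mean_abs_lfc = mean(abs(.data$lfc)),
      .groups = "drop"
    )
  ess <- abs(d$lfc[d$region == "essential"])
  scr <- abs(d$lfc[d$region == "scramble"])
  if (length(ess) == 0L || length(scr) == 0L) {
    warn("scramble and/or essential controls missing; QC test skipped")
    return(list(summary = summ, p_value = NA_real_, qc_pass = NA))
  }
  p <- wilcox.test(ess, scr, alternative = "greater", exact = FALSE)$p.value
  list(
    summary = summ,
    p_value = p,
    qc_pass = p < 0.05 && median(ess) > median(scr)
  )
}

#' Read an sgRNA manifest TSV
#'
#' @param path TSV with columns `sgrna_id`, `target_id`, `region`.
#' @return Typed tibble.
#' @export
read_sgrna_manifest <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  req <- c("sgrna_id", "target_id", "region")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L) {
    abort(paste0("manifest missing column(s): ", paste(missing, collapse = ", ")))
  }
  ok <- df$region %in% c("body", "upstream", "scramble", "essential")
  if (!all(ok)) abort(paste0("unknown region value: ", df$region[!ok][[1]]))
  df
}

#' Read a wide sgRNA count TSV
#'
#' @param path TSV with `sgrna_id` plus one integer column per sample.
#' @return Tibble with integer count columns.
#' @export
read_count_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sgrna_id = readr::col_character(), .default = readr::col_double()
  ))
  if (!"sgrna_id" %in% names(df)) abort("count table missing sgrna_id column")
  df
}
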