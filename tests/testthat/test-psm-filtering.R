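make_psms <- function(peptide, score, is_decoy = FALSE, spectrum_id = NULL,
                      sample_id = "s1", orf_ids = NULL) {
  n <- length(peptide)
  tibble::tibble(
    spectrum_id = spectrum_id %||% sprintf("sp%03d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    peptide = peptide,
    orf_ids = orf_ids %||% as.list(paste0("o_", peptide)),
    score = score,
    is_decoy = rep_len(is_decoy, n)
  )
}

test_that("PSM tables load typed, collapse duplicates, and validate columns", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "spectrum_id\tsample_id\tpeptide\torf_ids\tscore\tis_decoy",
    "s1\ta\tPEPK\to1;o2\t10\tFALSE",
    "s1\ta\tPEPK\to1;o2\t12\tFALSE",
    "s2\tb\tACDK\to3\t5\tTRUE"
  ), tsv)
  got <- read_psm_table(tsv)
  expect_equal(nrow(got), 2L)
  pep <- got[got$peptide == "PEPK", ]
  expect_equal(pep$score, 12)  # duplicate spectrum/peptide keeps best score
  expect_identical(pep$orf_ids[[1]], c("o1", "o2"))
  expect_true(got$is_decoy[got$peptide == "ACDK"])

  writeLines(c("spectrum_id\tsample_id\tpeptide\tscore\tis_decoy", "s\ta\tP\t1\tF"), tsv)
  expect_error(read_psm_table(tsv), "orf_ids")
  writeLines(c(
    "spectrum_id\tsample_id\tpeptide\torf_ids\tscore\tis_decoy",
    "s1\ta\tPEPK\to1\tbad\tFALSE"
  ), tsv)
  expect_error(read_psm_table(tsv), "row 1")
})

test_that("simulated PSM tables round-trip losslessly through write/read", {
  sim <- simulate_genome_annotation(seed = 7, n_mrna = 3, n_ncrna = 3)
  lib <- build_orf_library(sim$transcripts, sim$genome)
  ps <- simulate_psm_table(lib, seed = 7, n_true = 50, n_false = 30, n_decoy = 30)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(ps$psms, tsv)
  back <- read_psm_table(tsv)
  orig <- dplyr::arrange(ps$psms, spectrum_id, peptide)
  expect_equal(nrow(back), nrow(orig))
  expect_identical(back$peptide, orig$peptide)
  expect_equal(back$score, orig$score)
  expect_identical(back$orf_ids, orig$orf_ids)
})

test_that("spectra matching multiple distinct sequences are discarded; shared-ORF spectra retained", {
  psms <- dplyr::bind_rows(
    make_psms(c("ACDK", "ACEK"), c(10, 9), spectrum_id = c("S1", "S1")),
    make_psms("ACDK", 8, spectrum_id = "S2", orf_ids = list(c("o1", "o2")))
  )
  out <- discard_ambiguous_spectra(psms)
  expect_identical(out$spectrum_id, "S2")

  # property: every surviving spectrum maps to exactly one sequence
  set.seed(31)
  for (i in 1:20) {
    n <- 50
    psms <- make_psms(
      sample(c("AAAK", "CCCK", "GGGK", "TTTK"), n, replace = TRUE),
      runif(n, 5, 30),
      spectrum_id = sprintf("S%02d", sample.int(30, n, replace = TRUE))
    ) %>% dplyr::distinct(spectrum_id, peptide, .keep_all = TRUE)
    out <- discard_ambiguous_spectra(psms)
    per <- tapply(out$peptide, out$spectrum_id, function(x) length(unique(x)))
    expect_true(all(per == 1L))
    # idempotent
    expect_identical(discard_ambiguous_spectra(out), out)
  }
})

test_that("target-decoy q-value filtering matches the hand-enumerated sweep", {
  psms <- dplyr::bind_rows(
    make_psms(paste0("T", 1:6, "K"), c(10, 9, 8, 7, 3, 2)),
    make_psms(paste0("D", 1:2, "K"), c(6, 1), is_decoy = TRUE)
  )
  fit <- peptide_level_fdr(psms, alpha = 0.01)
  expect_equal(fit$n_retained, 4L)
  expect_equal(fit$threshold, 7)
  expect_setequal(fit$peptides$peptide, paste0("T", 1:4, "K"))
  # adding the score-6 region would admit 1 decoy over 5 targets (FDR 0.20)
  td <- tidy(fit)
  expect_equal(td$q_value[td$peptide == "T5K"], 1 / 6)
  g <- glance(fit)
  expect_equal(g$n_target_peptides, 6L)
  expect_equal(g$n_decoy_peptides, 2L)

  # degenerate case: no decoys anywhere above any target keeps all targets
  psms2 <- dplyr::bind_rows(
    make_psms(paste0("T", 1:3, "K"), c(10, 9, 8)),
    make_psms("D1K", 1, is_decoy = TRUE)
  )
  fit2 <- peptide_level_fdr(psms2, alpha = 0.01)
  expect_equal(fit2$n_retained, 3L)
  expect_true(all(fit2$peptides$q_value == 0))

  expect_error(peptide_level_fdr(make_psms("T1K", 10)), "decoy")
})

test_that("annotated-only peptides and canonically embedded internal ORFs are removed", {
  catalogue <- tibble::tibble(
    orf_id = c("oa", "oi", "on", "ox"),
    category = c("annotated", "intORF", "novel_nc", "intORF")
  )
  canonical <- c(P1 = "MAAACDEFGHIKLLL", P2 = "MTTTRRR")
  pep <- tibble::tibble(
    peptide = c("ACDEFGHIK", "ACDEFGHIK", "WWWWKTTTK", "AAACDEFGH"),
    orf_ids = list("oa", "on", "ox", "oi")
  )
  out <- remove_annotated_and_embedded(pep, catalogue, canonical)
  # row 1: only annotated support -> gone; row 2: same sequence but nc host -> kept
  # row 3: intORF but not a canonical substring -> kept
  # row 4: intORF-only and exact canonical substring -> gone
  expect_identical(out$peptide, c("ACDEFGHIK", "WWWWKTTTK"))
  expect_identical(out$orf_ids, list("on", "ox"))
  # idempotent
  expect_identical(remove_annotated_and_embedded(out, catalogue, canonical), out)

  # I/L collapsing is available behind the flag
  pep_il <- tibble::tibble(peptide = "ACDEFGHLK", orf_ids = list("oi"))
  expect_equal(nrow(remove_annotated_and_embedded(pep_il, catalogue, canonical)), 1L)
  expect_equal(
    nrow(remove_annotated_and_embedded(pep_il, catalogue, canonical, collapse_il = TRUE)),
    0L
  )
})

test_that("redundant overlapping ORFs resolve by unique-region support", {
  catalogue <- tibble::tibble(
    orf_id = c("A", "B"),
    chrom = "c1", strand = "+",
    g_min = c(100L, 190L), g_max = c(280L, 280L),
    length_nt = c(181L, 91L),
    peptide = c("MAAAAKEEEEKCCCCK", "EEEEKCCCCK")
  )
  pep <- tibble::tibble(
    peptide = c("MAAAAKEEEEKCCCCK", "EEEEKCCCCK"),
    orf_ids = list("A", c("A", "B"))
  )
  out <- resolve_redundant_orfs(pep, catalogue)
  # A carries support outside B -> B discarded, shared peptide keeps A
  expect_identical(out$orf_ids, list("A", "A"))
  expect_false(any(out$unresolved_redundant))

  # all of A's support lies inside B -> both retained, flagged
  pep2 <- tibble::tibble(peptide = "EEEEKCCCCK", orf_ids = list(c("A", "B")))
  out2 <- resolve_redundant_orfs(pep2, catalogue)
  expect_identical(out2$orf_ids, list(c("A", "B")))
  expect_true(all(out2$unresolved_redundant))

  # idempotence on the resolved output
  out_again <- resolve_redundant_orfs(dplyr::select(out, -unresolved_redundant), catalogue)
  expect_identical(out_again$orf_ids, out$orf_ids)
})

test_that("redundancy removals equal an exhaustive pairwise oracle on random nested fixtures", {
  redundancy_oracle <- function(orfs, pep) {
    # direct restatement over all ordered pairs, longest first
    support <- lapply(orfs$orf_id, function(o) {
      pep$peptide[vapply(pep$orf_ids, function(x) o %in% x, logical(1))]
    })
    names(support) <- orfs$orf_id
    ord <- order(-orfs$length_nt, orfs$orf_id)
    removed <- character(0)
    for (i in ord) {
      if (orfs$orf_id[[i]] %in% removed) next
      for (j in ord) {
        if (i == j || orfs$length_nt[[j]] > orfs$length_nt[[i]]) next
        if (orfs$orf_id[[j]] %in% removed) next
        if (orfs$strand[[i]] != orfs$strand[[j]]) next
        if (orfs$g_min[[i]] > orfs$g_max[[j]] || orfs$g_min[[j]] > orfs$g_max[[i]]) next
        if (orfs$orf_id[[j]] == orfs$orf_id[[i]]) next
        if (orfs$length_nt[[j]] == orfs$length_nt[[i]] &&
              orfs$orf_id[[j]] < orfs$orf_id[[i]]) next
        longsup <- support[[orfs$orf_id[[i]]]]
        if (length(longsup) > 0 &&
              any(!vapply(longsup, grepl, logical(1), x = orfs$peptide[[j]], fixed = TRUE))) {
          removed <- c(removed, orfs$orf_id[[j]])
        }
      }
    }
    removed
  }
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    base <- paste(sample(c("A", "C", "D", "E", "G", "K"), 60, replace = TRUE), collapse = "")
    # nested suffix peptides anchored at a shared stop
    lens <- sort(sample(10:50, n), decreasing = TRUE)
    orfs <- tibble::tibble(
      orf_id = sprintf("O%02d", seq_len(n)),
      chrom = "c1", strand = "+",
      g_min = 300L - lens * 3L, g_max = 300L,
      length_nt = lens * 3L + 3L,
      peptide = vapply(lens, function(l) substr(base, 60 - l + 1L, 60), character(1))
    )
    # random supporting peptides: substrings of the ORFs' peptides
    pep_rows <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.3) return(NULL)
      p <- orfs$peptide[[i]]
      a <- sample.int(nchar(p) - 4L, 1)
      frag <- substr(p, a, a + 4L)
      hosts <- orfs$orf_id[vapply(orfs$peptide, grepl, logical(1),
        pattern = frag, fixed = TRUE
      )]
      tibble::tibble(peptide = frag, orf_ids = list(hosts))
    })
    pep <- dplyr::bind_rows(pep_rows)
    if (is.null(pep) || nrow(pep) == 0L) next
    pep <- dplyr::distinct(pep, peptide, .keep_all = TRUE)
    out <- resolve_redundant_orfs(pep, orfs)
    kept <- sort(unique(unlist(out$orf_ids)))
    supported <- sort(unique(unlist(pep$orf_ids)))
    expect_identical(kept, sort(setdiff(supported, redundancy_oracle(orfs, pep))))
  }
})

test_that("support summary reports single-PSM and cross-sample fractions", {
  pep <- tibble::tibble(
    peptide = c("A", "B", "C"),
    psm_count = c(1L, 2L, 5L),
    samples = list("s1", c("s1", "s2"), "s2")
  )
  s <- summarize_support(pep)
  expect_equal(s$frac_single_psm, 1 / 3)
  expect_equal(s$frac_multi_psm, 2 / 3)
  expect_equal(s$n_multi_sample, 1L)
  expect_equal(s$frac_single_psm + s$frac_multi_psm, 1)
})

test_that("the filter cascade keeps a monotone audit ledger on simulated data", {
  sim <- simulate_genome_annotation(seed = 8, n_mrna = 6, n_ncrna = 6)
  lib <- build_orf_library(sim$transcripts, sim$genome)
  ps <- simulate_psm_table(lib, seed = 8, ambiguity_rate = 0.05)
  canonical <- setNames(
    lib$peptide[lib$category == "annotated"],
    lib$orf_id[lib$category == "annotated"]
  )
  res <- filter_psms(ps$psms, lib, canonical)
  expect_identical(
    res$report$stage,
    c("ambiguous_spectra", "peptide_fdr", "annotated_embedded", "redundant_orfs")
  )
  expect_true(all(res$report$n_out <= res$report$n_in))
  expect_true(all(diff(res$report$n_out) <= 0 | res$report$unit[-1] == "psm"))
  expect_true(all(res$peptides$q_value <= 0.01))
  expect_false(any(res$peptides$category == "annotated"))
})
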