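#' Enumerate candidate ORFs on a transcript sequence
#'
#' Scans all three frames of a spliced transcript sequence for every
#' occurrence of an allowed start codon and extends each to the first
#' in-frame stop codon (TAA/TAG/TGA). Starts with no downstream in-frame
#' stop are discarded; nested ORFs sharing a stop are all kept. The ORF
#' length in nucleotides includes the stop codon, so the encoded peptide has
#' `length_nt/3 - 1` residues; the peptide-length filter
#' `min_aa <= len <= max_aa` is applied on that value. Codons containing `N`
#' never match a start codon and never terminate an ORF.
#'
#' @param tseq Transcript nucleotide string over `ACGTN`.
#' @param starts Character vector of allowed start codons; default the four
#'   initiators ATG/CTG/GTG/TTG.
#' @param min_aa Minimum peptide length in residues (default 6, the
#'   practical lower bound of tryptic MS detectability).
#' @param max_aa Maximum peptide length in residues (default 249: sequences
#'   of 250 aa or more are excluded).
#' @return Tibble with columns `t_start`, `t_stop` (1-based inclusive,
#'   `t_stop` is the last base of the stop codon), `start_codon` and
#'   `length_nt`, sorted by `t_start` then `t_stop`.
#' @export
enumerate_orfs <- function(tseq, starts = c("ATG", "CTG", "GTG", "TTG"),
                           min_aa = 6L, max_aa = 249L) {
  stopifnot(max_aa >= min_aa, min_aa >= 1L)
  empty <- tibble(
    t_start = integer(), t_stop = integer(),
    start_codon = character(), length_nt = integer()
  )
  n <- nchar(tseq)
  if (n < 6L || length(starts) == 0L) return(empty)
  cod <- substring(tseq, 1:(n - 2L), 3:n)
  res <- vector("list", 3L)
  for (f in 0:2) {
    idx <- seq.int(1L + f, n - 2L, by = 3L)
    cf <- cod[idx]
    start_pos <- idx[cf %in% starts]
    stop_pos <- idx[cf %in% STOP_CODONS]
    if (length(start_pos) == 0L || length(stop_pos) == 0L) next
    j <- findInterval(start_pos, stop_pos) + 1L
    ok <- j <= length(stop_pos)
    if (!any(ok)) next
    t_start <- start_pos[ok]
    t_stop <- stop_pos[j[ok]] + 2L
    res[[f + 1L]] <- tibble(
      t_start = t_start, t_stop = t_stop,
      start_codon = cod[t_start],
      length_nt = t_stop - t_start + 1L
    )
  }
  out <- bind_rows(res)
  if (nrow(out) == 0L) return(empty)
  aa_len <- out$length_nt %/% 3L - 1L
  out <- out[aa_len >= min_aa & aa_len <= max_aa, ]
  arrange(out, .data$t_start, .data$t_stop)
}

#' Classify an ORF relative to a transcript's annotated CDS
#'
#' Vectorised over ORF intervals. Categories follow the position of the ORF
#' relative to the stop-inclusive CDS span in transcript coordinates:
#' no CDS gives `novel_nc`; coordinates identical to the CDS give
#' `annotated`; entirely 5' gives `uORF`; straddling the CDS start gives
#' `overlap_uORF`; entirely 3' gives `dORF`; straddling the CDS stop gives
#' `overlap_dORF`; contained within the CDS span in a different frame gives
#' `intORF`; any other CDS overlap (including same-frame truncations) gives
#' `altORF`.
#'
#' @param t_start,t_stop Integer vectors of ORF transcript intervals.
#' @param cds_t_start,cds_t_end Stop-inclusive CDS span in transcript
#'   coordinates (scalars or vectors; `NA` means no annotated CDS).
#' @return Character vector of categories.
#' @export
classify_orf <- function(t_start, t_stop, cds_t_start, cds_t_end) {
  case_when(
    is.na(cds_t_start) ~ "novel_nc",
    t_start == cds_t_start & t_stop == cds_t_end ~ "annotated",
    t_stop < cds_t_start ~ "uORF",
    t_start < cds_t_start ~ "overlap_uORF",
    t_start > cds_t_end ~ "dORF",
    t_stop > cds_t_end ~ "overlap_dORF",
    (t_start - cds_t_start) %% 3L != 0L ~ "intORF",
    TRUE ~ "altORF"
  )
}

#' Compose an ORF identifier
#'
#' The identifier joins the transcript ID, the genomic coordinate of the
#' first base of the start codon, the genomic coordinate of the last base of
#' the stop codon, and the spliced ORF length in nucleotides (stop codon
#' included) with underscores, e.g.
#' `"ENST00000242109_26533546_26533680_135"`. On the minus strand the start
#' coordinate is the transcript-orientation first base and is numerically
#' the larger of the two.
#'
#' @param transcript_id,g_start,g_stop,length_nt Identifier components
#'   (vectorised).
#' @return Character vector of ORF IDs.
#' @export
make_orf_id <- function(transcript_id, g_start, g_stop, length_nt) {
  paste(transcript_id, g_start, g_stop, length_nt, sep = "_")
}

#' Build the candidate sORF library across a transcriptome
#'
#' Runs [enumerate_orfs()] on every spliced transcript, classifies each ORF
#' against the transcript's annotated CDS, projects ORF endpoints onto the
#' genome, translates the peptide (stop excluded) and assigns ORF IDs.
#' Output ordering is deterministic: chromosome, normalised genomic start,
#' transcript ID, length.
#'
#' @param transcripts Transcript tibble from [read_gtf()].
#' @param genome Named character vector from [read_genome()].
#' @param starts,min_aa,max_aa Passed to [enumerate_orfs()].
#' @return Tibble with one row per candidate ORF: identifiers, host gene
#'   info, `chrom`, `strand`, transcript and genomic coordinates (both the
#'   orientation-aware `g_start`/`g_stop` and normalised `g_min`/`g_max`),
#'   `length_nt`, `start_codon`, `category` and `peptide`.
#' @export
build_orf_library <- function(transcripts, genome,
                              starts = c("ATG", "CTG", "GTG", "TTG"),
                              min_aa = 6L, max_aa = 249L) {
  if (nrow(transcripts) == 0L) abort("empty annotation: no transcripts")
  transcripts <- spliced_sequence(transcripts, genome)
  rows <- purrr::pmap(
    transcripts[c(
      "transcript_id", "gene_id", "gene_name", "biotype", "chrom", "strand",
      "exons", "cds_t_start", "cds_t_end", "tx_seq"
    )],
    function(transcript_id, gene_id, gene_name, biotype, chrom, strand,
             exons, cds_t_start, cds_t_end, tx_seq) {
      orfs <- enumerate_orfs(tx_seq, starts = starts, min_aa = min_aa, max_aa = max_aa)
      if (nrow(orfs) == 0L) return(NULL)
      g5 <- tx_to_genomic(exons, strand, orfs$t_start)
      g3 <- tx_to_genomic(exons, strand, orfs$t_stop)
      orfs %>%
        mutate(
          transcript_id = transcript_id,
          gene_id = gene_id,
          gene_name = gene_name,
          biotype = biotype,
          chrom = chrom,
          strand = strand,
          g_start = g5,
          g_stop = g3,
          g_min = pmin(g5, g3),
          g_max = pmax(g5, g3),
          category = classify_orf(.data$t_start, .data$t_stop, cds_t_start, cds_t_end),
          peptide = purrr::map2_chr(
            .data$t_start, .data$t_stop,
            ~ translate_nt(substr(tx_seq, .x, .y - 3L))
          ),
          orf_id = make_orf_id(transcript_id, g5, g3, .data$length_nt)
        )
    }
  )
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(
      orf_id = character(), transcript_id = character(), gene_id = character(),
      gene_name = character(), biotype = character(), chrom = character(),
      strand = character(), t_start = integer(), t_stop = integer(),
      g_start = integer(), g_stop = integer(), g_min = integer(),
      g_max = integer(), length_nt = integer(), start_codon = character(),
      category = character(), peptide = character()
    ))
  }
  out %>%
    select(
      "orf_id", "transcript_id", "gene_id", "gene_name", "biotype", "chrom",
      "strand", "t_start", "t_stop", "g_start", "g_stop", "g_min", "g_max",
      "length_nt", "start_codon", "category", "peptide"
    ) %>%
    arrange(.data$chrom, .data$g_min, .data$transcript_id, .data$length_nt)
}

#' Write target and reversed-decoy peptide FASTA files
#'
#' One target entry per ORF (`>orf_id gene=... type=... start_codon=...
#' len_nt=...`) and one decoy entry holding the reversed peptide with the
#' header prefixed `DECOY_`. Decoys whose reversed sequence collides with
#' any target peptide sequence are reported and tagged `collision=target`
#' in the header; they are retained so the decoy length multiset always
#' matches the targets.
#'
#' @param library ORF catalogue from [build_orf_library()].
#' @param target_path,decoy_path Output FASTA paths.
#' @return Invisibly, a list with the two paths and the number of decoy
#'   collisions.
#' @export
write_orf_fasta <- function(library, target_path, decoy_path) {
  gene <- ifelse(is.na(library$gene_name) | library$gene_name == "",
    library$gene_id, library$gene_name
  )
  hdr <- paste0(
    library$orf_id, " gene=", gene, " type=", library$category,
    " start_codon=", library$start_codon, " len_nt=", library$length_nt
  )
  tgt <- setNames(library$peptide, hdr)
  rev_pep <- vapply(
    strsplit(library$peptide, ""),
    function(x) paste(rev(x), collapse = ""), character(1)
  )
  collide <- rev_pep %in% library$peptide
  if (any(collide)) {
    inform(paste0(sum(collide), " decoy sequence(s) collide with a target peptide"))
  }
  dhdr <- paste0(
    "DECOY_", library$orf_id, " gene=", gene, " type=decoy",
    ifelse(collide, " collision=target", "")
  )
  dec <- setNames(rev_pep, dhdr)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(tgt), target_path, width = 60L)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(dec), decoy_path, width = 60L)
  invisible(list(target = target_path, decoy = decoy_path, n_collisions = sum(collide)))
}

#' Name identified peptides by ORF class and host gene
#'
#' Applies the `pepNo.-Type-Gene` scheme: the type code is `u` for
#' (overlap) upstream ORFs, `d` for (overlap) downstream ORFs, `alt` for
#' internal/alternative ORFs and `nc` for ORFs on noncoding transcripts.
#' Within a gene, peptides are numbered in ascending order of the
#' normalised genomic start of their parent ORF; a gene contributing a
#' single identified peptide is labelled plainly `pep-Type-Gene`. Genes
#' without a `gene_name` fall back to `gene_id`. Input order never affects
#' the assignment. ORFs of category `annotated` must have been removed
#' upstream and raise an error here.
#'
#' @param identified Tibble with at least `orf_id`, `gene_id`, `gene_name`,
#'   `category`, `g_min` (and optionally `g_max` used as a tie-break).
#' @return The input, with columns `type_code`, `host_gene` and `name`
#'   added, sorted by gene then coordinate.
#' @export
assign_peptide_names <- function(identified) {
  if (any(identified$category == "annotated")) {
    abort("annotated-category ORFs must be filtered out before naming")
  }
  type_map <- c(
    uORF = "u", overlap_uORF = "u", dORF = "d", overlap_dORF = "d",
    intORF = "alt", altORF = "alt", novel_nc = "nc"
  )
  unknown <- setdiff(unique(identified$category), names(type_map))
  if (length(unknown) > 0L) {
    abort(paste0("unknown ORF category: ", paste(unknown, collapse = ", ")))
  }
  g_max <- identified[["g_max"]] %||% identified$g_min
  identified %>%
    mutate(
      type_code = unname(type_map[.data$category]),
      host_gene = ifelse(is.na(.data$gene_name) | .data$gene_name == "",
        .data$gene_id, .data$gene_name
      ),
      .g_max = g_max
    ) %>%
    arrange(.data$host_gene, .data$g_min, .data$.g_max, .data$orf_id) %>%
    group_by(.data$host_gene) %>%
    mutate(
      name = if (n() == 1L) {
        paste0("pep-", .data$type_code, "-", .data$host_gene)
      } else {
        paste0("pep", row_number(), "-", .data$type_code, "-", .data$host_gene)
      }
    ) %>%
    ungroup() %>%
    select(-".g_max")
}
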