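# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of (parameters, seed). The ORF truth set is produced by a
# deliberately independent codon-walk enumerator (orf_scan_oracle) and an
# independent per-base coordinate map (tx_pos_map_oracle), never by the
# library-construction code, so the generators can serve as oracles for it.

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"), c("A", "C", "G", "T")),
    1, paste, collapse = ""
  ),
  c("TAA", "TAG", "TGA")
)

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

random_cds <- function(n_codons, start = "ATG") {
  paste0(
    start,
    paste(sample(NON_STOP_CODONS, n_codons, replace = TRUE), collapse = ""),
    sample(STOP_CODONS, 1)
  )
}

#' Independent brute-force ORF enumerator
#'
#' Walks the sequence base by base: every allowed start codon is extended
#' codon by codon to its first in-frame stop. Quadratic and simple on
#' purpose -- this is the reference against which the production
#' enumerator is checked, so it shares no code with it.
#'
#' @inheritParams enumerate_orfs
#' @return Tibble `t_start`, `t_stop`, `start_codon`, `length_nt`, sorted.
#' @export
orf_scan_oracle <- function(tseq, starts = c("ATG", "CTG", "GTG", "TTG"),
                            min_aa = 6L, max_aa = 249L) {
  n <- nchar(tseq)
  rows <- list()
  i <- 1L
  while (i + 5L <= n) {
    cod <- substr(tseq, i, i + 2L)
    if (cod %in% starts) {
      j <- i + 3L
      while (j + 2L <= n) {
        cj <- substr(tseq, j, j + 2L)
        if (cj %in% STOP_CODONS) {
          len <- j + 2L - i + 1L
          aa <- len %/% 3L - 1L
          if (aa >= min_aa && aa <= max_aa) {
            rows[[length(rows) + 1L]] <- tibble(
              t_start = i, t_stop = j + 2L, start_codon = cod, length_nt = len
            )
          }
          break
        }
        j <- j + 3L
      }
    }
    i <- i + 1L
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(
      t_start = integer(), t_stop = integer(),
      start_codon = character(), length_nt = integer()
    ))
  }
  arrange(out, .data$t_start, .data$t_stop)
}

#' Independent transcript-to-genome position map
#'
#' Expands a transcript's exons into the full vector of genomic positions,
#' index `t` giving the genomic base occupied by transcript position `t`
#' (descending on the minus strand). The brute-force counterpart of
#' [tx_to_genomic()].
#'
#' @inheritParams tx_to_genomic
#' @return Integer vector of length `sum(exon widths)`.
#' @export
tx_pos_map_oracle <- function(exons, strand) {
  g <- unlist(Map(seq.int, exons$start, exons$end), use.names = FALSE)
  if (strand == "-") rev(g) else g
}

# independent interval-logic classifier used only for simulator truth
classify_oracle <- function(ts, te, cs, ce) {
  if (is.na(cs)) return("novel_nc")
  if (ts == cs && te == ce) return("annotated")
  if (te < cs) return("uORF")
  if (ts < cs && te >= cs) return("overlap_uORF")
  if (ts > ce) return("dORF")
  if (ts >= cs && te > ce) return("overlap_dORF")
  # contained in the CDS span
  if ((ts - cs) %% 3L == 0L) return("altORF")
  "intORF"
}

#' Simulate a genome, annotation, and exhaustive ORF truth set
#'
#' Generates a small random genome carrying multi-exon stranded
#' transcripts: protein-coding transcripts with an in-frame CDS plus
#' planted upstream and downstream sORFs in the UTRs, and noncoding
#' transcripts with planted sORFs. The returned truth contains every ORF
#' satisfying the enumeration rules, computed with the independent
#' brute-force oracles, together with the planted transcript models. With
#' `dir` set, a FASTA and an Ensembl-dialect GTF (CDS records excluding
#' the stop codon) are written.
#'
#' @param seed Integer seed; identical (parameters, seed) give identical
#'   output.
#' @param n_chrom,n_mrna,n_ncrna Numbers of chromosomes and transcripts.
#' @param exon_count_range,intron_len_range Exon count and intron length
#'   ranges per transcript.
#' @param utr_len_range UTR length range (5' and 3') for mRNAs.
#' @param cds_codon_range Number of CDS codons (excluding start and stop).
#' @param nc_len_range Length range of noncoding transcripts.
#' @param starts,min_aa,max_aa Enumeration rules used for the truth set.
#' @param dir Optional output directory for `genome.fa` and `annotation.gtf`.
#' @return List with `genome` (named character), `transcripts` (tibble in
#'   the [read_gtf()] layout), `orfs` (truth catalogue in the
#'   [build_orf_library()] layout), `files` (paths or `NULL`) and `params`.
#' @export
simulate_genome_annotation <- function(seed, n_chrom = 2L, n_mrna = 5L,
                                       n_ncrna = 5L,
                                       exon_count_range = c(1L, 3L),
                                       intron_len_range = c(80L, 250L),
                                       utr_len_range = c(90L, 240L),
                                       cds_codon_range = c(60L, 180L),
                                       nc_len_range = c(360L, 720L),
                                       starts = c("ATG", "CTG", "GTG", "TTG"),
                                       min_aa = 6L, max_aa = 249L,
                                       dir = NULL) {
  stopifnot(n_chrom >= 1L, n_mrna + n_ncrna >= 1L)
  set.seed(seed)
  n_tx <- n_mrna + n_ncrna
  specs <- vector("list", n_tx)
  for (i in seq_len(n_tx)) {
    coding <- i <= n_mrna
    if (coding) {
      u5 <- sample(utr_len_range[1]:utr_len_range[2], 1)
      u3 <- sample(utr_len_range[1]:utr_len_range[2], 1)
      m <- sample(cds_codon_range[1]:cds_codon_range[2], 1)
      cds_seq <- random_cds(m)
      tseq <- paste0(random_seq(u5), cds_seq, random_seq(u3))
      # plant a uORF and a dORF inside the UTRs where room allows
      k <- sample(8:15, 1)
      if (u5 >= 3 * k + 9) {
        off <- sample.int(u5 - (3 * k + 6), 1)
        substr(tseq, off + 1L, off + 3 * k + 6L) <- random_cds(k)
      }
      k2 <- sample(8:15, 1)
      if (u3 >= 3 * k2 + 9) {
        off <- u5 + nchar(cds_seq) + sample.int(u3 - (3 * k2 + 6), 1)
        substr(tseq, off + 1L, off + 3 * k2 + 6L) <- random_cds(k2)
      }
      cds_t <- c(u5 + 1L, u5 + nchar(cds_seq))  # stop-inclusive
    } else {
      L <- sample(nc_len_range[1]:nc_len_range[2], 1)
      tseq <- random_seq(L)
      for (p in seq_len(sample(1:2, 1))) {
        k <- sample(10:30, 1)
        if (L >= 3 * k + 9) {
          off <- sample.int(L - (3 * k + 6), 1)
          substr(tseq, off + 1L, off + 3 * k + 6L) <- random_cds(k)
        }
      }
      cds_t <- c(NA_integer_, NA_integer_)
    }
    specs[[i]] <- list(
      transcript_id = sprintf("TX%04d", i),
      gene_id = sprintf("G%04d", i),
      gene_name = sprintf("GENE%d", i),
      biotype = if (coding) "protein_coding" else "lncRNA",
      tseq = tseq, cds_t = cds_t
    )
  }

  # exon structure + sequential genomic placement
  chrom_names <- sprintf("chr%d", seq_len(n_chrom))
  cursor <- setNames(rep(1L, n_chrom), chrom_names)
  chrom_of <- chrom_names[(seq_len(n_tx) - 1L) %% n_chrom + 1L]
  tx_rows <- vector("list", n_tx)
  for (i in seq_len(n_tx)) {
    sp <- specs[[i]]
    L <- nchar(sp$tseq)
    n_ex <- sample(exon_count_range[1]:exon_count_range[2], 1)
    n_ex <- min(n_ex, L %/% 60L)
    n_ex <- max(n_ex, 1L)
    if (n_ex > 1L) {
      cuts <- sort(sample(seq(40L, L - 40L), n_ex - 1L))
      while (any(diff(c(0L, cuts, L)) < 30L)) {
        cuts <- sort(sample(seq(40L, L - 40L), n_ex - 1L))
      }
      widths <- diff(c(0L, cuts, L))
    } else {
      widths <- L
    }
    introns <- if (n_ex > 1L) {
      sample(intron_len_range[1]:intron_len_range[2], n_ex - 1L, replace = TRUE)
    } else {
      integer(0)
    }
    chrom <- chrom_of[[i]]
    strand <- sample(c("+", "-"), 1)
    g0 <- cursor[[chrom]] + 200L
    ex_start <- integer(n_ex)
    ex_end <- integer(n_ex)
    pos <- g0
    for (k in seq_len(n_ex)) {
      ex_start[[k]] <- pos
      ex_end[[k]] <- pos + widths[[k]] - 1L
      pos <- ex_end[[k]] + if (k < n_ex) introns[[k]] + 1L else 1L
    }
    cursor[[chrom]] <- ex_end[[n_ex]]
    tx_rows[[i]] <- tibble(
      transcript_id = sp$transcript_id, gene_id = sp$gene_id,
      gene_name = sp$gene_name, biotype = sp$biotype,
      chrom = chrom, strand = strand, tx_len = L,
      exons = list(tibble(start = ex_start, end = ex_end)),
      cds_t_start = sp$cds_t[[1]], cds_t_end = sp$cds_t[[2]],
      tseq = sp$tseq
    )
  }
  tx <- bind_rows(tx_rows)

  # genome: random background overwritten with the designed transcripts
  genome <- lapply(chrom_names, function(cn) {
    len <- cursor[[cn]] + 200L
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    for (i in which(tx$chrom == cn)) {
      gpos <- tx_pos_map_oracle(tx$exons[[i]], tx$strand[[i]])
      bases <- strsplit(tx$tseq[[i]], "")[[1]]
      if (tx$strand[[i]] == "-") {
        bases <- chartr("ACGT", "TGCA", bases)
      }
      chars[gpos] <- bases
    }
    paste(chars, collapse = "")
  })
  genome <- setNames(unlist(genome), chrom_names)

  # CDS genomic blocks (Ensembl convention: stop codon excluded from CDS)
  cds_blocks <- purrr::pmap(
    tx[c("exons", "strand", "cds_t_start", "cds_t_end")],
    function(exons, strand, cds_t_start, cds_t_end) {
      if (is.na(cds_t_start)) return(NULL)
      gpos <- tx_pos_map_oracle(exons, strand)
      p <- sort(gpos[cds_t_start:(cds_t_end - 3L)])
      brk <- which(diff(p) != 1L)
      tibble(start = p[c(1L, brk + 1L)], end = p[c(brk, length(p))])
    }
  )
  tx$cds <- cds_blocks

  # exhaustive truth ORF set via the independent oracles
  truth_rows <- purrr::pmap(
    tx[c("transcript_id", "gene_id", "gene_name", "biotype", "chrom", "strand",
         "exons", "cds_t_start", "cds_t_end", "tseq")],
    function(transcript_id, gene_id, gene_name, biotype, chrom, strand,
             exons, cds_t_start, cds_t_end, tseq) {
      orfs <- orf_scan_oracle(tseq, starts = starts, min_aa = min_aa, max_aa = max_aa)
      if (nrow(orfs) == 0L) return(NULL)
      gpos <- tx_pos_map_oracle(exons, strand)
      g5 <- gpos[orfs$t_start]
      g3 <- gpos[orfs$t_stop]
      orfs %>% mutate(
        transcript_id = transcript_id, gene_id = gene_id,
        gene_name = gene_name, biotype = biotype, chrom = chrom,
        strand = strand, g_start = g5, g_stop = g3,
        g_min = pmin(g5, g3), g_max = pmax(g5, g3),
        category = purrr::map2_chr(
          .data$t_start, .data$t_stop,
          ~ classify_oracle(.x, .y, cds_t_start, cds_t_end)
        ),
        peptide = purrr::map2_chr(
          .data$t_start, .data$t_stop,
          ~ translate_nt(substr(tseq, .x, .y - 3L))
        ),
        orf_id = paste(transcript_id, g5, g3, .data$length_nt, sep = "_")
      )
    }
  )
  truth <- bind_rows(truth_rows) %>%
    select(
      "orf_id", "transcript_id", "gene_id", "gene_name", "biotype", "chrom",
      "strand", "t_start", "t_stop", "g_start", "g_stop", "g_min", "g_max",
      "length_nt", "start_codon", "category", "peptide"
    ) %>%
    arrange(.data$chrom, .data$g_min, .data$transcript_id, .data$length_nt)

  transcripts <- tx %>% select(-"tseq") %>%
    select(
      "transcript_id", "gene_id", "gene_name", "biotype", "chrom", "strand",
      "tx_len", "exons", "cds", "cds_t_start", "cds_t_end"
    )

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    gtf <- file.path(dir, "annotation.gtf")
    write_genome_fasta(genome, fa)
    write_gtf(transcripts, gtf)
    files <- list(fasta = fa, gtf = gtf)
  }
  list(
    genome = genome, transcripts = transcripts, orfs = truth, files = files,
    params = list(
      seed = seed, n_chrom = n_chrom, n_mrna = n_mrna, n_ncrna = n_ncrna,
      starts = starts, min_aa = min_aa, max_aa = max_aa
    )
  )
}

#' Write a transcript table to an Ensembl-dialect GTF
#'
#' Emits one `exon` record per exon and one `CDS` record per CDS block
#' (stop codon excluded, Ensembl style).
#'
#' @param transcripts Transcript tibble (layout of [read_gtf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    r <- transcripts[i, ]
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";',
      r$gene_id, r$transcript_id, r$gene_name, r$biotype
    )
    ex <- r$exons[[1]]
    lines <- c(lines, sprintf(
      "%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
      r$chrom, ex$start, ex$end, r$strand, attrs
    ))
    cds <- r$cds[[1]]
    if (!is.null(cds)) {
      lines <- c(lines, sprintf(
        "%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\t%s",
        r$chrom, cds$start, cds$end, r$strand, attrs
      ))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Simulate a peptide-spectrum-match table with known truth
#'
#' Samples a set of truly present target peptides and, per sample, draws
#' their detection and PSM scores from the true-score component
#' `Normal(mu1, sd1)`; absent target peptides and reversed decoys draw
#' from the null component `Normal(mu0, sd0)`. A stated fraction of
#' spectra is deliberately assigned a second, distinct peptide to exercise
#' the ambiguity filter.
#'
#' @param library ORF catalogue from [build_orf_library()] (or the
#'   simulator truth); identical peptide sequences collapse to one
#'   searchable peptide listing all its ORF IDs.
#' @param seed Integer seed.
#' @param n_samples Number of MS samples.
#' @param n_true Number of truly present peptides.
#' @param n_false Number of null target PSMs.
#' @param n_decoy Number of decoy PSMs.
#' @param detect_prob Per-sample detection probability of a present
#'   peptide.
#' @param mu1,sd1 True-score component.
#' @param mu0,sd0 Null/decoy score component; `mu1 > mu0` expected.
#' @param ambiguity_rate Fraction of spectra given a second distinct
#'   peptide.
#' @return List with `psms` (tibble in [read_psm_table()] layout) and
#'   `truth` (tibble `peptide`, `present`).
#' @export
simulate_psm_table <- function(library, seed, n_samples = 3L, n_true = 300L,
                               n_false = 200L, n_decoy = 200L,
                               detect_prob = 0.8, mu1 = 25, sd1 = 3,
                               mu0 = 10, sd0 = 3, ambiguity_rate = 0) {
  if (nrow(library) == 0L) abort("empty library")
  set.seed(seed)
  peps <- library %>%
    group_by(.data$peptide) %>%
    summarise(orf_ids = list(sort(unique(.data$orf_id))), .groups = "drop")
  n_true <- min(n_true, nrow(peps))
  present_idx <- sample.int(nrow(peps), n_true)
  present <- peps$peptide[present_idx]
  absent <- setdiff(peps$peptide, present)
  samples <- sprintf("sample%02d", seq_len(n_samples))
  spec_counter <- 0L
  next_spec <- function(k) {
    ids <- sprintf("spec%06d", spec_counter + seq_len(k))
    spec_counter <<- spec_counter + k
    ids
  }
  rows <- list()
  for (s in samples) {
    det <- present[runif(length(present)) < detect_prob]
    if (length(det) > 0L) {
      n_psm <- 1L + rpois(length(det), 0.6)
      pep_rep <- rep(det, n_psm)
      rows[[length(rows) + 1L]] <- tibble(
        spectrum_id = next_spec(length(pep_rep)),
        sample_id = s, peptide = pep_rep,
        score = rnorm(length(pep_rep), mu1, sd1),
        is_decoy = FALSE
      )
    }
  }
  if (n_false > 0L && length(absent) > 0L) {
    fp <- sample(absent, n_false, replace = TRUE)
    rows[[length(rows) + 1L]] <- tibble(
      spectrum_id = next_spec(n_false),
      sample_id = sample(samples, n_false, replace = TRUE),
      peptide = fp,
      score = rnorm(n_false, mu0, sd0),
      is_decoy = FALSE
    )
  }
  if (n_decoy > 0L) {
    src <- sample.int(nrow(peps), n_decoy, replace = TRUE)
    dpep <- vapply(
      strsplit(peps$peptide[src], ""),
      function(x) paste(rev(x), collapse = ""), character(1)
    )
    keep <- !dpep %in% peps$peptide  # drop palindromic collisions
    rows[[length(rows) + 1L]] <- tibble(
      spectrum_id = next_spec(sum(keep)),
      sample_id = sample(samples, sum(keep), replace = TRUE),
      peptide = dpep[keep],
      score = rnorm(sum(keep), mu0, sd0),
      is_decoy = TRUE
    )
  }
  psms <- bind_rows(rows)
  # deliberate ambiguity: give some spectra a second distinct peptide
  n_amb <- floor(ambiguity_rate * nrow(psms))
  if (n_amb > 0L) {
    pick <- sample.int(nrow(psms), n_amb)
    second <- sample(peps$peptide, n_amb, replace = TRUE)
    ok <- second != psms$peptide[pick]
    if (any(ok)) {
      amb <- psms[pick[ok], ]
      amb$peptide <- second[ok]
      amb$score <- rnorm(sum(ok), mu0, sd0)
      psms <- bind_rows(psms, amb)
    }
  }
  orf_of <- setNames(peps$orf_ids, peps$peptide)
  ids <- unname(orf_of[psms$peptide])
  ids[psms$is_decoy] <- list("DECOY")
  psms$orf_ids <- ids
  psms <- psms %>%
    select("spectrum_id", "sample_id", "peptide", "orf_ids", "score", "is_decoy") %>%
    arrange(.data$spectrum_id, .data$peptide)
  list(
    psms = psms,
    truth = tibble(peptide = peps$peptide, present = peps$peptide %in% present)
  )
}

#' Write a PSM table to TSV
#'
#' Serialises the list-column `orf_ids` with semicolons; inverse of
#' [read_psm_table()].
#'
#' @param psms PSM tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  out <- psms %>% mutate(orf_ids = purrr::map_chr(.data$orf_ids, paste, collapse = ";"))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Simulate a pooled CRISPR screen with planted proliferation effects
#'
#' Draws initial sgRNA counts from a negative binomial with the given mean
#' coverage and dispersion (variance = mean + dispersion x mean^2) and
#' final counts from the same model with the mean multiplied by
#' `2^lfc` for each guide's planted log2 fold change. Body guides carry
#' their ORF's planted effect; upstream guides are null; scramble controls
#' are null and essential-gene controls deplete at `essential_lfc`.
#'
#' @param orf_ids Character vector of screened ORF identifiers.
#' @param effects Tibble `orf_id`, `lfc` of planted effects (ORFs not
#'   listed are null).
#' @param seed Integer seed.
#' @param n_body,n_upstream Guides per ORF.
#' @param coverage Mean initial count per guide.
#' @param dispersion NB dispersion; 0 gives Poisson counts.
#' @param replicates Replicates per timepoint.
#' @param n_scramble,n_essential Numbers of control guides.
#' @param essential_lfc Planted LFC of essential controls.
#' @return List with `manifest`, `counts` (wide tibble, columns
#'   `T0_r*`/`Tf_r*`), and `truth` (per-ORF planted LFC including nulls).
#' @export
simulate_screen_counts <- function(orf_ids, effects = NULL, seed,
                                   n_body = 4L, n_upstream = 2L,
                                   coverage = 500, dispersion = 0.05,
                                   replicates = 2L, n_scramble = 100L,
                                   n_essential = 50L, essential_lfc = -3) {
  stopifnot(coverage > 0, dispersion >= 0)
  set.seed(seed)
  eff <- setNames(rep(0, length(orf_ids)), orf_ids)
  if (!is.null(effects) && nrow(effects) > 0L) {
    eff[effects$orf_id] <- effects$lfc
  }
  manifest <- bind_rows(
    tibble(
      sgrna_id = paste0(rep(orf_ids, each = n_body), "_body_", seq_len(n_body)),
      target_id = rep(orf_ids, each = n_body), region = "body",
      lfc_planted = rep(unname(eff), each = n_body)
    ),
    if (n_upstream > 0L) tibble(
      sgrna_id = paste0(rep(orf_ids, each = n_upstream), "_up_", seq_len(n_upstream)),
      target_id = rep(orf_ids, each = n_upstream), region = "upstream",
      lfc_planted = 0
    ),
    tibble(
      sgrna_id = sprintf("scramble_%03d", seq_len(n_scramble)),
      target_id = "scramble", region = "scramble", lfc_planted = 0
    ),
    tibble(
      sgrna_id = sprintf("essential_%03d", seq_len(n_essential)),
      target_id = "essential", region = "essential",
      lfc_planted = essential_lfc
    )
  )
  n_g <- nrow(manifest)
  draw <- function(mu) {
    if (dispersion == 0) rpois(length(mu), mu) else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  counts <- tibble(sgrna_id = manifest$sgrna_id)
  for (r in seq_len(replicates)) {
    counts[[paste0("T0_r", r)]] <- draw(rep(coverage, n_g))
  }
  mu_final <- coverage * 2^manifest$lfc_planted
  for (r in seq_len(replicates)) {
    counts[[paste0("Tf_r", r)]] <- draw(mu_final)
  }
  list(
    manifest = manifest %>% select("sgrna_id", "target_id", "region"),
    counts = counts,
    truth = tibble(orf_id = orf_ids, lfc = unname(eff))
  )
}
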