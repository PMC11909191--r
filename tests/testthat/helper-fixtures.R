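# Shared helpers: tiny builders and brute-force oracles used across tests.
# Oracles are written independently of the code paths they check.

`%||%` <- function(x, y) if (is.null(x)) y else x

# named genome from a list of sequences
toy_genome <- function(...) {
  unlist(list(...))
}

# one-row transcript tibble in the read_gtf() layout
toy_transcript <- function(transcript_id = "tx1", chrom = "chr1", strand = "+",
                           exons = tibble::tibble(start = 1L, end = 9L),
                           cds_t_start = NA_integer_, cds_t_end = NA_integer_,
                           gene_id = "g1", gene_name = "GENE1",
                           biotype = "lncRNA") {
  tibble::tibble(
    transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
    biotype = biotype, chrom = chrom, strand = strand,
    tx_len = sum(exons$end - exons$start + 1L),
    exons = list(exons), cds = list(NULL),
    cds_t_start = cds_t_start, cds_t_end = cds_t_end
  )
}

# random exon structure within a chromosome of length chrom_len
random_exons <- function(chrom_len, max_exons = 4L) {
  n_ex <- sample.int(max_exons, 1L)
  repeat {
    pos <- sort(sample.int(chrom_len, 2L * n_ex))
    starts <- pos[seq(1L, by = 2L, length.out = n_ex)]
    ends <- pos[seq(2L, by = 2L, length.out = n_ex)]
    if (n_ex == 1L || all(starts[-1L] > ends[-n_ex] + 1L)) {
      return(tibble::tibble(start = starts, end = ends))
    }
  }
}

# brute-force per-base spliced-sequence extractor (oracle for spliced_sequence)
spliced_oracle <- function(exons, strand, chrom_seq) {
  bases <- character(0)
  for (i in seq_len(nrow(exons))) {
    for (p in exons$start[[i]]:exons$end[[i]]) {
      bases <- c(bases, substr(chrom_seq, p, p))
    }
  }
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    bases <- rev(unname(comp[bases]))
  }
  paste(bases, collapse = "")
}

# regex-frame brute-force ORF enumerator (second independent oracle,
# distinct from both enumerate_orfs and orf_scan_oracle)
orf_regex_oracle <- function(tseq, starts = c("ATG", "CTG", "GTG", "TTG"),
                             min_aa = 6L, max_aa = 249L) {
  rows <- list()
  n <- nchar(tseq)
  for (f in 0:2) {
    if (n - f < 6L) next
    frame_seq <- substr(tseq, f + 1L, n)
    n_cod <- nchar(frame_seq) %/% 3L
    codons <- substring(
      frame_seq,
      seq(1L, by = 3L, length.out = n_cod),
      seq(3L, by = 3L, length.out = n_cod)
    )
    stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))
    for (ci in which(codons %in% starts)) {
      nxt <- stop_idx[stop_idx > ci]
      if (length(nxt) == 0L) next
      so <- nxt[[1]]
      aa <- (so - ci + 1L) - 1L
      if (aa < min_aa || aa > max_aa) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        t_start = f + (ci - 1L) * 3L + 1L,
        t_stop = f + so * 3L,
        start_codon = codons[[ci]],
        length_nt = (so - ci + 1L) * 3L
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      t_start = integer(), t_stop = integer(),
      start_codon = character(), length_nt = integer()
    ))
  }
  dplyr::arrange(out, t_start, t_stop)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "sorfscreen", mustWork = TRUE)
}

load_fixture_psms <- function() read_psm_table(fixture_path("psm_fixture.tsv"))

load_fixture_catalogue <- function() {
  readr::read_tsv(fixture_path("orf_fixture_catalogue.tsv"),
    show_col_types = FALSE
  )
}
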