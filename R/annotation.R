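#' Read an Ensembl-dialect GTF into a transcript table
#'
#' Parses `exon` and `CDS` features into one row per transcript. Exons are
#' stored sorted by genomic start regardless of file order. CDS intervals are
#' attached when present, mapped to transcript coordinates, and checked for
#' frame consistency: a CDS whose total length is not divisible by 3 is
#' dropped (with a warning) rather than propagated. Ensembl CDS features
#' exclude the stop codon; when the three bases immediately following the
#' annotated CDS form an in-frame stop, the stored transcript-coordinate CDS
#' span is extended to include it so that CDS spans and ORF spans (which are
#' stop-inclusive) are directly comparable.
#'
#' @param path Path to a GTF file with `gene_id`, `transcript_id` and strand
#'   on every exon record; `gene_name` and `gene_biotype`/`transcript_biotype`
#'   are used when present.
#' @param genome Named character vector from [read_genome()], used for bounds
#'   checking and stop-codon absorption.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `gene_name`, `biotype`, `chrom`, `strand`, `tx_len`, list-columns
#'   `exons` and `cds` (tibbles of `start`,`end`, 1-based inclusive), and
#'   `cds_t_start`/`cds_t_end` (stop-inclusive transcript coordinates, `NA`
#'   for noncoding transcripts).
#' @export
read_gtf <- function(path, genome) {
  if (!file.exists(path)) abort(paste0("GTF file not found: ", path))
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!"type" %in% names(df)) abort("GTF has no feature type column")
  df <- df %>% filter(.data$type %in% c("exon", "CDS"))
  if (nrow(df) == 0L) abort("GTF contains no exon features")
  if (!"transcript_id" %in% names(df)) df$transcript_id <- NA_character_
  missing_tx <- is.na(df$transcript_id) | df$transcript_id == ""
  if (any(missing_tx)) {
    warn(paste0("skipping ", sum(missing_tx), " GTF record(s) without transcript_id"))
    df <- df[!missing_tx, ]
  }
  if (!"gene_name" %in% names(df)) df$gene_name <- NA_character_
  bt <- df[["transcript_biotype"]] %||% df[["gene_biotype"]] %||% rep(NA_character_, nrow(df))
  df$biotype <- bt
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)

  out <- df %>%
    group_by(.data$transcript_id) %>%
    dplyr::group_map(function(d, key) {
      tid <- key$transcript_id[[1]]
      if (n_distinct(d$seqnames) > 1L) {
        abort(paste0("transcript ", tid, " spans multiple chromosomes"))
      }
      chrom <- d$seqnames[[1]]
      if (!chrom %in% names(genome)) {
        abort(paste0("transcript ", tid, " is on unknown chromosome ", chrom))
      }
      strand <- d$strand[[1]]
      if (!strand %in% c("+", "-")) {
        abort(paste0("transcript ", tid, " has no usable strand"))
      }
      ex <- d %>% filter(.data$type == "exon") %>% arrange(.data$start)
      if (nrow(ex) == 0L) abort(paste0("transcript ", tid, " has CDS but no exons"))
      if (any(ex$start < 1L) || any(ex$end > nchar(genome[[chrom]]))) {
        abort(paste0("transcript ", tid, " has exon(s) outside chromosome bounds"))
      }
      if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
        abort(paste0("transcript ", tid, " has overlapping exons"))
      }
      exons <- tibble(start = as.integer(ex$start), end = as.integer(ex$end))
      cd <- d %>% filter(.data$type == "CDS") %>% arrange(.data$start)
      cds <- NULL
      if (nrow(cd) > 0L) {
        cds <- tibble(start = as.integer(cd$start), end = as.integer(cd$end))
        if (sum(cds$end - cds$start + 1L) %% 3L != 0L) {
          warn(paste0("transcript ", tid, ": CDS length not divisible by 3, dropping CDS"))
          cds <- NULL
        }
      }
      tibble(
        transcript_id = tid,
        gene_id = d$gene_id[[1]] %||% NA_character_,
        gene_name = d$gene_name[[1]],
        biotype = d$biotype[[1]],
        chrom = chrom,
        strand = strand,
        tx_len = sum(exons$end - exons$start + 1L),
        exons = list(exons),
        cds = list(cds)
      )
    }) %>%
    bind_rows() %>%
    arrange(.data$chrom, purrr::map_int(.data$exons, ~ .x$start[[1]]), .data$transcript_id)

  # map CDS to transcript coordinates, absorb a trailing stop codon
  span <- purrr::pmap(
    list(out$exons, out$cds, out$strand, out$chrom, out$transcript_id),
    function(exons, cds, strand, chrom, tid) {
      if (is.null(cds)) return(c(NA_integer_, NA_integer_))
      if (!all(cds_within_exons(cds, exons))) {
        warn(paste0("transcript ", tid, ": CDS outside exons, dropping CDS"))
        return(c(NA_integer_, NA_integer_))
      }
      g <- if (strand == "+") c(min(cds$start), max(cds$end)) else c(max(cds$end), min(cds$start))
      t5 <- genomic_to_tx(exons, strand, g[[1]])
      t3 <- genomic_to_tx(exons, strand, g[[2]])
      txlen <- sum(exons$end - exons$start + 1L)
      tseq <- spliced_seq_one(exons, strand, genome[[chrom]])
      if (t3 + 3L <= txlen && substr(tseq, t3 + 1L, t3 + 3L) %in% STOP_CODONS) {
        t3 <- t3 + 3L
      }
      c(t5, t3)
    }
  )
  out$cds_t_start <- purrr::map_int(span, 1L)
  out$cds_t_end <- purrr::map_int(span, 2L)
  out$cds[is.na(out$cds_t_start)] <- list(NULL)
  out
}

cds_within_exons <- function(cds, exons) {
  vapply(seq_len(nrow(cds)), function(i) {
    any(exons$start <= cds$start[[i]] & cds$end[[i]] <= exons$end)
  }, logical(1))
}

# spliced sequence for one exon table (used internally; see spliced_sequence)
spliced_seq_one <- function(exons, strand, chrom_seq) {
  parts <- substring(chrom_seq, exons$start, exons$end)
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Assemble spliced transcript sequences
#'
#' Concatenates each transcript's exon sequences in transcription order; for
#' minus-strand transcripts the result is reverse-complemented so the
#' returned string reads 5' to 3' of the transcript.
#'
#' @param transcripts Transcript tibble from [read_gtf()].
#' @param genome Named character vector from [read_genome()].
#' @return `transcripts` with an added character column `tx_seq`.
#' @export
spliced_sequence <- function(transcripts, genome) {
  transcripts$tx_seq <- purrr::pmap_chr(
    list(transcripts$exons, transcripts$strand, transcripts$chrom),
    function(exons, strand, chrom) {
      if (max(exons$end) > nchar(genome[[chrom]])) {
        abort(paste0("exon beyond end of chromosome ", chrom))
      }
      spliced_seq_one(exons, strand, genome[[chrom]])
    }
  )
  transcripts
}

#' Map transcript positions to genomic coordinates
#'
#' Positions are 1-based inclusive on the spliced transcript. The returned
#' coordinate of a position is the genomic base it occupies; on the minus
#' strand transcript position 1 is the numerically largest genomic
#' coordinate of the last exon.
#'
#' @param exons Tibble of exon `start`,`end` sorted by genomic start.
#' @param strand `"+"` or `"-"`.
#' @param pos Integer vector of transcript positions.
#' @return Integer vector of genomic positions.
#' @export
tx_to_genomic <- function(exons, strand, pos) {
  widths <- exons$end - exons$start + 1L
  txlen <- sum(widths)
  if (any(pos < 1L | pos > txlen)) {
    abort("transcript position out of range")
  }
  if (strand == "+") {
    cum <- cumsum(widths)
    k <- findInterval(pos - 1L, cum) + 1L
    off <- pos - c(0L, cum)[k] - 1L
    exons$start[k] + off
  } else {
    widths_r <- rev(widths)
    cum <- cumsum(widths_r)
    k <- findInterval(pos - 1L, cum) + 1L
    off <- pos - c(0L, cum)[k] - 1L
    rev(exons$end)[k] - off
  }
}

#' Map genomic coordinates back to transcript positions
#'
#' Inverse of [tx_to_genomic()]; errors if a coordinate falls outside every
#' exon.
#'
#' @inheritParams tx_to_genomic
#' @param gpos Integer vector of genomic positions.
#' @return Integer vector of transcript positions.
#' @export
genomic_to_tx <- function(exons, strand, gpos) {
  widths <- exons$end - exons$start + 1L
  n <- nrow(exons)
  out <- integer(length(gpos))
  for (i in seq_along(gpos)) {
    g <- gpos[[i]]
    k <- which(exons$start <= g & g <= exons$end)
    if (length(k) != 1L) abort(paste0("genomic position ", g, " not in any exon"))
    if (strand == "+") {
      out[[i]] <- sum(widths[seq_len(k - 1L)]) + (g - exons$start[[k]]) + 1L
    } else {
      upstream <- if (k < n) sum(widths[(k + 1L):n]) else 0L
      out[[i]] <- upstream + (exons$end[[k]] - g) + 1L
    }
  }
  out
}

#' Project a transcript interval onto the genome
#'
#' Returns both orientation-aware endpoints (the genomic base of the
#' interval's first and last transcript position, so on the minus strand
#' `g_start > g_stop`) and the normalised genomic blocks covered, suitable
#' for BED-style export.
#'
#' @inheritParams tx_to_genomic
#' @param t_start,t_end Transcript interval, 1-based inclusive,
#'   `t_start <= t_end`.
#' @return List with `g_start`, `g_stop` (orientation-aware), `g_min`,
#'   `g_max` (normalised span) and `blocks` (tibble of `start`,`end` sorted
#'   by genomic start).
#' @export
tx_interval_to_genomic <- function(exons, strand, t_start, t_end) {
  stopifnot(length(t_start) == 1L, length(t_end) == 1L, t_start <= t_end)
  g <- tx_to_genomic(exons, strand, c(t_start, t_end))
  pos_all <- tx_to_genomic(exons, strand, t_start:t_end)
  pos_all <- sort(pos_all)
  brk <- which(diff(pos_all) != 1L)
  starts <- pos_all[c(1L, brk + 1L)]
  ends <- pos_all[c(brk, length(pos_all))]
  list(
    g_start = g[[1]], g_stop = g[[2]],
    g_min = pos_all[[1]], g_max = pos_all[[length(pos_all)]],
    blocks = tibble(start = starts, end = ends)
  )
}
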