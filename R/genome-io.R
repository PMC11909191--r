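#' Read a genome FASTA into a named sequence set
#'
#' Loads every record of a (multi-)FASTA file into a named character vector,
#' one uppercase nucleotide string per chromosome. Lowercase (soft-masked)
#' bases are uppercased and any character outside `A`/`C`/`G`/`T`/`N` is
#' mapped to `N`, so downstream codon matching only ever sees the five-letter
#' alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping chromosome name (the first
#'   whitespace-delimited token of each header) to its sequence.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt", ">chr2", "NNNN"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  dss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(dss) == 0L) abort(paste0("FASTA '", path, "' contains no records"))
  seqs <- toupper(as.character(dss))
  # header up to first whitespace is the chromosome name
  names(seqs) <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    abort(paste0("duplicate chromosome name(s) in FASTA: ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(seqs))) {
    abort("FASTA contains empty sequence record(s)")
  }
  seqs <- gsub("[^ACGTN]", "N", seqs)
  seqs
}

#' Write a genome to FASTA
#'
#' Inverse of [read_genome()]; sequences are wrapped at 60 columns.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' `N` stays `N`. Vectorised over `x`.
#'
#' @param x Character vector of sequences over `ACGTN`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(
    x,
    function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1),
    USE.NAMES = FALSE
  )
}

# Codon -> amino acid lookup; codons containing N (or any ambiguity) give X.
codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  gc[gc == "*"] <- "*"
  gc
})

#' Translate an in-frame nucleotide string
#'
#' Translates codon by codon with the standard genetic code. Stop codons
#' become `*`; any codon containing a base other than A/C/G/T (e.g. `N`)
#' becomes `X`. Trailing bases short of a full codon are dropped.
#'
#' @param nt Single nucleotide string, length a multiple of 3 (extra 1-2
#'   bases tolerated and ignored).
#' @return Single amino-acid string.
#' @export
translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, by = 3L, length.out = n), seq(3L, by = 3L, length.out = n))
  aa <- unname(codon_table[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
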