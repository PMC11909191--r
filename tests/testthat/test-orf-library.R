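test_that("enumeration finds minimal and noncanonical-start ORFs", {
  one <- enumerate_orfs("ATGTAA", starts = "ATG", min_aa = 1L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$t_start, 1L)
  expect_equal(one$t_stop, 6L)
  expect_equal(one$start_codon, "ATG")
  expect_equal(one$length_nt, 6L)

  ctg <- enumerate_orfs("CTGAAATGA", min_aa = 1L)
  expect_equal(nrow(ctg), 1L)
  expect_equal(unlist(ctg[1, c("t_start", "t_stop")], use.names = FALSE), c(1L, 9L))
  expect_equal(ctg$start_codon, "CTG")
  expect_identical(translate_nt("CTGAAA"), "LK")

  # start with no downstream in-frame stop is discarded
  expect_equal(nrow(enumerate_orfs("ATGAAAAAA", min_aa = 1L)), 0L)
  # empty start set yields nothing
  expect_equal(nrow(enumerate_orfs("ATGTAA", starts = character(0), min_aa = 1L)), 0L)
})

test_that("nested ORFs sharing a stop are all kept and N never starts or stops", {
  # two in-frame starts, one stop
  s <- "ATGATGAAATAA"
  got <- enumerate_orfs(s, starts = "ATG", min_aa = 1L)
  expect_equal(got$t_start, c(1L, 4L))
  expect_equal(got$t_stop, c(12L, 12L))
  # ATN is not a start; TAN/TNA never a stop, translation gives X
  expect_equal(nrow(enumerate_orfs("ATNAAATAA", min_aa = 1L)), 0L)
  withN <- enumerate_orfs("ATGTANAAATAA", starts = "ATG", min_aa = 1L)
  expect_equal(withN$t_stop, 12L)  # TAN is not a stop; the ORF runs to TAA
  expect_identical(translate_nt("ATGTANAAA"), "MXK")
})

test_that("enumeration agrees with a frame-regex brute-force oracle on random sequence", {
  set.seed(21)
  for (i in 1:60) {
    s <- random_dna(sample(200:1000, 1))
    min_aa <- sample(1:8, 1)
    expect_equal(
      as.data.frame(enumerate_orfs(s, min_aa = min_aa)),
      as.data.frame(orf_regex_oracle(s, min_aa = min_aa))
    )
  }
})

test_that("ORF classification follows position and frame relative to the CDS", {
  # transcript with CDS occupying positions 100-400
  expect_equal(classify_orf(10L, 60L, 100L, 400L), "uORF")
  expect_equal(classify_orf(90L, 120L, 100L, 400L), "overlap_uORF")
  expect_equal(classify_orf(100L, 400L, 100L, 400L), "annotated")
  expect_equal(classify_orf(150L, 250L, 100L, 400L), "intORF") # 150-100 = 50, frame-shifted
  expect_equal(classify_orf(151L, 250L, 100L, 400L), "altORF") # same frame, contained
  expect_equal(classify_orf(390L, 450L, 100L, 400L), "overlap_dORF")
  expect_equal(classify_orf(410L, 500L, 100L, 400L), "dORF")
  expect_equal(classify_orf(10L, 60L, NA_integer_, NA_integer_), "novel_nc")
})

test_that("classification matches an exhaustive interval-logic oracle", {
  oracle <- function(ts, te, cs, ce) {
    if (is.na(cs)) return("novel_nc")
    if (ts == cs && te == ce) return("annotated")
    if (te < cs) return("uORF")
    if (ts < cs) return("overlap_uORF")
    if (ts > ce) return("dORF")
    if (te > ce) return("overlap_dORF")
    if ((ts - cs) %% 3L == 0L) return("altORF")
    "intORF"
  }
  set.seed(22)
  for (i in 1:500) {
    cs <- sample(20:60, 1)
    ce <- cs + 3L * sample(5:20, 1) - 1L
    ts <- sample(1:100, 1)
    te <- ts + 3L * sample(2:30, 1) - 1L
    expect_equal(classify_orf(ts, te, cs, ce), oracle(ts, te, cs, ce))
  }
})

test_that("the documented single-exon worked example produces the expected ORF ID", {
  exons <- tibble::tibble(start = 26533001L, end = 26534000L)
  t_start <- genomic_to_tx(exons, "+", 26533546L)
  t_stop <- genomic_to_tx(exons, "+", 26533680L)
  len <- t_stop - t_start + 1L
  expect_equal(len, 135L)
  r <- tx_interval_to_genomic(exons, "+", t_start, t_stop)
  id <- make_orf_id("ENST00000242109", r$g_start, r$g_stop, len)
  expect_identical(id, "ENST00000242109_26533546_26533680_135")
  expect_identical(make_orf_id("tx1", 1L, 6L, 6L), "tx1_1_6_6")
})

test_that("spliced ORF length field is the spliced length, not the genomic span", {
  # ORF crosses an intron: exons (1,9) and (101,109), ORF covers all 18 nt
  genome <- toy_genome(chr1 = paste0(
    "ATGAAACCC", strrep("G", 91), "AAATTTTAA", strrep("G", 91)
  ))
  tx <- toy_transcript(exons = tibble::tibble(start = c(1L, 101L), end = c(9L, 109L)))
  lib <- build_orf_library(tx, genome, min_aa = 1L)
  orf <- lib[lib$t_start == 1L & lib$start_codon == "ATG", ]
  expect_equal(nrow(orf), 1L)
  expect_equal(orf$length_nt, 18L)
  expect_equal(orf$length_nt, sum(9L - 1L + 1L, 109L - 101L + 1L))
  expect_gt(orf$g_max - orf$g_min + 1L, orf$length_nt)
  expect_identical(orf$orf_id, paste0("tx1_", orf$g_start, "_", orf$g_stop, "_18"))
})

test_that("candidate library equals the simulator's independently computed truth", {
  for (seed in c(1, 9)) {
    sim <- simulate_genome_annotation(seed = seed)
    lib <- build_orf_library(sim$transcripts, sim$genome)
    truth <- sim$orfs
    expect_identical(lib$orf_id, truth$orf_id)
    expect_identical(lib$peptide, truth$peptide)
    expect_identical(lib$category, truth$category)
    expect_identical(lib$t_start, truth$t_start)
    expect_identical(lib$g_start, truth$g_start)
    expect_identical(lib$start_codon, truth$start_codon)
  }
})

test_that("library construction is deterministic and respects peptide invariants", {
  sim <- simulate_genome_annotation(seed = 2)
  lib <- build_orf_library(sim$transcripts, sim$genome)
  expect_identical(lib, build_orf_library(sim$transcripts, sim$genome))
  # every peptide: allowed start residue mapping, no internal stop, <= 249 aa
  expect_false(any(grepl("*", lib$peptide, fixed = TRUE)))
  expect_true(all(nchar(lib$peptide) <= 249L))
  expect_true(all(nchar(lib$peptide) == lib$length_nt / 3 - 1L))
  expect_true(all(lib$length_nt == lib$t_stop - lib$t_start + 1L))
  expect_true(all(lib$length_nt %% 3L == 0L))
  expect_true(all(lib$start_codon %in% c("ATG", "CTG", "GTG", "TTG")))

  d <- withr::local_tempdir()
  f1 <- file.path(d, "t1.fa"); f2 <- file.path(d, "d1.fa")
  f3 <- file.path(d, "t2.fa"); f4 <- file.path(d, "d2.fa")
  write_orf_fasta(lib, f1, f2)
  write_orf_fasta(lib, f3, f4)
  expect_identical(readLines(f1), readLines(f3))
  expect_identical(readLines(f2), readLines(f4))
  # decoys carry the same length multiset as targets
  tgt <- Biostrings::readAAStringSet(f1)
  dec <- Biostrings::readAAStringSet(f2)
  expect_identical(sort(Biostrings::width(dec)), sort(Biostrings::width(tgt)))
  expect_true(all(startsWith(names(dec), "DECOY_")))

  expect_error(build_orf_library(sim$transcripts[0, ], sim$genome), "empty annotation")
  none <- build_orf_library(sim$transcripts, sim$genome, starts = character(0))
  expect_equal(nrow(none), 0L)
})

test_that("library is peptide-identical under genome reverse complement with flipped annotation", {
  sim <- simulate_genome_annotation(seed = 5, n_mrna = 3, n_ncrna = 3)
  lib <- build_orf_library(sim$transcripts, sim$genome)
  lens <- vapply(sim$genome, nchar, integer(1))
  genome_rc <- setNames(revcomp(sim$genome), names(sim$genome))
  tx_rc <- sim$transcripts
  for (i in seq_len(nrow(tx_rc))) {
    L <- lens[[tx_rc$chrom[[i]]]]
    ex <- tx_rc$exons[[i]]
    tx_rc$exons[[i]] <- tibble::tibble(
      start = rev(L - ex$end + 1L), end = rev(L - ex$start + 1L)
    )
    tx_rc$strand[[i]] <- if (tx_rc$strand[[i]] == "+") "-" else "+"
  }
  lib_rc <- build_orf_library(tx_rc, genome_rc)
  expect_identical(sort(lib_rc$peptide), sort(lib$peptide))
})

test_that("peptide naming follows the per-gene coordinate-ordered scheme", {
  identified <- tibble::tibble(
    orf_id = c("a", "b", "c"),
    gene_id = c("g1", "g1", "g2"),
    gene_name = c("KIAA0087", "KIAA0087", "ZNF436-AS1"),
    category = c("novel_nc", "novel_nc", "novel_nc"),
    g_min = c(26533546L, 26600000L, 1000L),
    g_max = c(26533680L, 26600100L, 1100L)
  )
  named <- assign_peptide_names(identified)
  expect_identical(named$name[named$orf_id == "a"], "pep1-nc-KIAA0087")
  expect_identical(named$name[named$orf_id == "b"], "pep2-nc-KIAA0087")
  # single-peptide genes carry no number
  expect_identical(named$name[named$orf_id == "c"], "pep-nc-ZNF436-AS1")
  expect_false(anyDuplicated(named$name) > 0)

  # shuffling the input order never changes the assignment
  shuffled <- assign_peptide_names(identified[c(3, 1, 2), ])
  expect_identical(
    named[order(named$orf_id), c("orf_id", "name")],
    shuffled[order(shuffled$orf_id), c("orf_id", "name")]
  )

  # type codes map from categories; annotated input is an error
  mixed <- tibble::tibble(
    orf_id = c("u", "d", "i", "n"),
    gene_id = paste0("g", 1:4), gene_name = paste0("G", 1:4),
    category = c("overlap_uORF", "dORF", "intORF", "novel_nc"),
    g_min = 1:4 * 100L, g_max = 1:4 * 100L + 50L
  )
  nm <- assign_peptide_names(mixed)
  expect_identical(nm$type_code[match(c("u", "d", "i", "n"), nm$orf_id)],
                   c("u", "d", "alt", "nc"))
  expect_error(
    assign_peptide_names(dplyr::mutate(mixed, category = "annotated")),
    "annotated"
  )

  # missing gene_name falls back to gene_id
  anon <- dplyr::mutate(mixed, gene_name = NA_character_)
  expect_identical(assign_peptide_names(anon)$name[[1]], "pep-u-g1")
})
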