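Package: sorfscreen
Title: Short ORF Discovery, Proteogenomic Peptide Filtering, and CRISPR
    Screen Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cataloguing the noncanonical peptidome encoded by
    short open reading frames (sORFs). Enumerates candidate ORFs starting
    at ATG/CTG/GTG/TTG across spliced transcripts, classifies them relative
    to annotated coding sequences (uORF, dORF, internal, alternative,
    ncRNA-hosted), and emits a searchable target plus reversed-decoy
    peptide library. Filters peptide-spectrum-match tables by ambiguity
    removal, peptide-level target-decoy false-discovery-rate control,
    canonical-proteome exclusion, and redundant-ORF resolution, and names
    the surviving peptides with a coordinate-ordered per-gene scheme.
    Scores peptide-targeting pooled CRISPR proliferation screens with
    reads-per-million log2 fold changes and dual ORF-body versus upstream
    hit criteria, and ships negative-binomial and score-mixture simulators
    with planted ground truth for closed-loop validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
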