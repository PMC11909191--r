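---
title: "Models and methods behind sorfscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sorfscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorfscreen)
library(tibble)
```

sorfscreen implements three connected analyses for the noncanonical
peptidome — candidate short-ORF library construction, peptide-spectrum-match
(PSM) filtering, and CRISPR proliferation-screen scoring — together with
synthetic-data generators that plant a known truth for each stage. This
vignette explains the models, the conventions that had to be fixed where a
convention was genuinely open, the tunable parameters, and what the
synthetic benchmarks do and do not establish.

## Coordinates and sequence conventions

All coordinates are 1-based and inclusive, the GTF (Ensembl) dialect.
Transcript positions count along the spliced transcript 5'→3'; for a
minus-strand transcript, position 1 sits at the numerically largest genomic
coordinate of the last exon. Consequently an ORF's reported genomic *start*
is the transcript-orientation first base, which on the minus strand is
numerically larger than its *stop*; a normalised `(g_min, g_max)` span is
carried alongside for BED-style interval work. Both are emitted because
printed identifiers of the form `transcript_start_stop_length` are
orientation-ambiguous for minus-strand ORFs; the package fixes the
transcript-orientation convention and keeps the normalised span in the
catalogue columns.

Soft-masked (lowercase) bases are uppercased at parse time and any
character outside `ACGTN` becomes `N`. A codon containing `N` never
matches a start codon, never terminates an ORF (only a literal TAA/TAG/TGA
does), and translates to `X`. This is conservative and deterministic: an
ambiguous base can suppress an ORF call but never invent a stop.

Ensembl GTF `CDS` features exclude the stop codon, whereas the ORF
convention here is stop-inclusive (an ORF runs from the first base of its
start codon to the last base of its stop codon; `length_nt` includes the
stop, the peptide excludes it — so the worked 135-nt example encodes a
44-residue peptide). To make the two comparable, `read_gtf()` absorbs an
in-frame stop codon immediately following the annotated CDS into the
stored transcript-coordinate CDS span. Annotations that already include
the stop pass through unchanged (the following codon will not be a stop).

## ORF enumeration and classification

`enumerate_orfs()` scans all three frames for the four initiator codons
ATG/CTG/GTG/TTG (the set is configurable) and extends each occurrence to
the *first* in-frame stop. Starts with no downstream in-frame stop are
discarded; nested starts sharing a stop are all kept, because initiation
at internal near-cognate starts is exactly the biology of interest.
Peptide length is bounded to 6–249 residues by default: 250 aa and above
is the conventional boundary between microproteins and annotated small
proteins, and 6 aa is the practical lower bound of tryptic MS
detectability. No minimum is dictated by the enumeration itself; 6 was
fixed once as the field-standard default and is a parameter.

Classification is positional, relative to the stop-inclusive CDS span in
transcript coordinates, with this precedence: no CDS → `novel_nc`;
identical span → `annotated`; entirely 5' → `uORF`; straddling the CDS
start → `overlap_uORF`; entirely 3' → `dORF`; straddling the CDS stop →
`overlap_dORF`; contained in a shifted frame → `intORF`; any remaining
overlap → `altORF`. Two cases the category vocabulary leaves open were
fixed here: an ORF containing the entire CDS classifies by the first
straddle it meets (`overlap_uORF`), and a same-frame contained ORF (an
N-terminal truncation sharing the CDS stop) is assigned `altORF`, the
only remaining alternative-translation bucket. For downstream naming,
categories map to type codes u (upstream classes), d (downstream
classes), alt (internal/alternative), nc (noncoding host); `annotated`
ORFs must be filtered out before naming and raise an error otherwise.

Decoys are whole-entry sequence reversals — the simplest reproducible
choice among the standard decoy constructions. Reversal preserves the
length multiset and amino-acid composition; palindromic peptides can
collide with a target sequence, in which case the decoy entry is tagged
in the FASTA header and counted, never silently dropped.

## Peptide-level target-decoy FDR

PSMs are aggregated to the best score per peptide sequence, targets and
decoys separately. For each observed score threshold $t$,

$$\widehat{\mathrm{FDR}}(t) = \frac{\#\{\text{decoy peptides} \ge t\}}
{\#\{\text{target peptides} \ge t\}},$$

converted to monotone q-values ($q(t) = \min_{t' \le t}
\widehat{\mathrm{FDR}}(t')$), and targets with $q \le \alpha$ (default
0.01) are retained. Peptides tied exactly at the threshold score are
retained — a stated, deterministic tie-break. The estimator is the plain
ratio without the +1 numerator correction and without $\pi_0$
estimation. This is deliberately the simplest defensible form of the
target-decoy method; its known cost is mild anti-conservativeness,
because the threshold is chosen adaptively where the decoy count dips.
In the package's calibration study (200 synthetic tables, true scores
$\mathcal{N}(25,3)$, null and decoy scores $\mathcal{N}(10,3)$) the mean
realised FDR at nominal 1% comes out near 1.3% — within the documented
Monte-Carlo tolerance of 1.5× nominal that the calibration test asserts.
Users who need strict sub-nominal control should lower `alpha`
accordingly. FDR is estimated globally across samples; per-sample
filtering can be had by subsetting the PSM table first.

The downstream filters run in a fixed order: ambiguity removal (spectra
matching two or more *distinct sequences* are discarded entirely; a
spectrum whose one sequence is shared by several ORFs is kept), FDR,
annotated-peptide removal, canonical-embedding removal (internal-ORF
peptides that are exact substrings of a canonical protein; I/L
equivalence is off by default and available as a flag, since exact
matching is the reproducible default), then redundancy resolution. Each
stage logs counts in and out, and each stage is idempotent on its own
output.

Redundancy resolution groups identified ORFs by genomic overlap on the
same strand (connected components over normalised spans) and processes
each group longest-first: a longer ORF carrying at least one supporting
peptide that is not a substring of a shorter overlapping ORF's peptide
discards the shorter. The "maps outside" condition is evaluated at
sequence level rather than by projecting each PSM to genome coordinates;
for exact-substring geometries the two are equivalent and the sequence
test is simpler to audit. Groups in which the longer ORF has no such
unique support keep all members and are flagged `unresolved_redundant` —
the conservative reading of a rule that only specifies the removal case.

## Screen scoring

Counts are normalised per column to reads per million and transformed as
$\log_2(\mathrm{rpm} + 1)$; the pseudocount keeps zero-count guides
finite and maps a zero count exactly to zero. Replicates are averaged on
the normalised log scale before differencing; with equal replicate
counts this equals averaging per-replicate fold changes. The per-ORF
phenotype (body) score is the mean guide LFC over ORF-body guides;
the upstream score averages guides placed in the 1-kb region upstream,
which knock out the host RNA without touching the ORF. Hit calling is the
dual criterion: $|\text{body}| > 1$ *and* $|\text{upstream}| < 1$, with
the body-score sign separating pro-proliferative (depleted, $\le -1$)
from anti-proliferative (enriched); $|\text{body}| > 1$ with a moving
upstream score is reported as `host_rna_effect`, everything else
`non_hit`. Strict inequalities follow the stated cutoff criterion;
boundary values are non-hits. The average-LFC statistic is the score
definition implemented here; moderated (shrinkage) effect estimates in
the style of count-model packages are intentionally out of scope — the
statistic is the defined quantity, and the thresholds are calibrated to
it. Classification is invariant to per-column depth scaling up to the
pseudocount's vanishing effect at very low counts, and to any
permutation of guide rows.

## Synthetic generators and what they establish

`simulate_genome_annotation()` designs each transcript's spliced sequence
first — mRNAs as 5'UTR + ATG·(60–180 codons)·stop + 3'UTR with a uORF and
dORF planted where the UTRs have room, noncoding transcripts as random
sequence with 1–2 planted sORFs — then scatters it across 1–3 exons on
either strand of a random genome. Exhaustive ORF truth is computed by an
independent codon-walk enumerator over the designed sequence and an
independent per-base coordinate map, never by the library-construction
code, so the generator is a genuine oracle for it (anti-circularity).
`simulate_psm_table()` draws present-peptide scores from
$\mathcal{N}(\mu_1, \sigma_1)$ and null/decoy scores from
$\mathcal{N}(\mu_0, \sigma_0)$ (defaults 25/3 and 10/3), with per-sample
detection probability 0.8 over 3 samples, 300 present peptides, 200 null
target PSMs and 200 decoy PSMs per table — sizes chosen to resemble a
small enrichment-MS study while keeping a 200-replicate calibration fast.
`simulate_screen_counts()` draws negative-binomial counts with
variance $= \mu + \phi\mu^2$ (defaults: coverage 500, $\phi = 0.05$, two
replicates per timepoint, 4 body + 2 upstream guides, scramble nulls and
essential controls planted at LFC −3).

What passing the closed-loop tests shows: the enumeration, coordinate,
classification, naming, filtering, and scoring code implement their
stated rules exactly, and the FDR/hit-calling procedures are calibrated
under the generating models. What it does not show: robustness to real
MS score distributions (which are neither Gaussian nor two-component),
to tryptic-fragment peptides (simulated "peptides" are whole ORF
translations), to chimeric spectra beyond the simple two-sequence
ambiguity model, to guide-efficiency heterogeneity, or to annotation
pathologies (trans-splicing, selenoproteins, chromosome aliasing) that
the parsers deliberately reject rather than repair.

## Problem sizes and numerical choices in the test suite

The suite exercises: 500 random kilobase sequences plus 100 random
spliced models for enumerator-oracle equivalence; 1000 random coordinate
round-trips; 200 PSM tables for FDR calibration (mean realised FDR
asserted ≤ 1.5% at nominal 1%); a 1000-ORF screen with 50 planted
pro-proliferative and 10 anti-proliferative effects at $|LFC| = 2$
(≥ 95% sign-correct recovery, ≤ 1% null calls asserted); and a packaged
40-row PSM fixture whose four-stage filter ledger is enumerated by hand.
These sizes make the defaults of the generators concrete and keep the
whole suite in the low minutes on one CPU.

Remaining fixed choices worth knowing: FASTA headers are split at the
first whitespace; duplicate chromosome names are an error, not a merge;
transcripts spanning chromosomes or with out-of-bounds exons are errors,
while records lacking a `transcript_id` are skipped with a warning; a
CDS whose length is not divisible by 3 is dropped (with a warning)
rather than trusted; library output ordering is fixed (chromosome,
normalised start, transcript, length) so identical inputs give
byte-identical FASTA/TSV outputs; and genes lacking a `gene_name` fall
back to `gene_id` in peptide names.

## Limitations

The package does not run or emulate an MS search engine — PSM tables are
its boundary — and does not compute coding-potential or conservation
scores, which enter only as external covariates via
`covariate_association()`. Matching a full-scale human library size or
published catalogue counts requires the full genome, annotation and raw
spectra, which are outside the scope of the packaged benchmarks; the
synthetic studies validate the procedures, not the published totals.
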