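#' Build a validated pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with the study's
#' default values: the four initiator codons, the 6-249 aa peptide-length
#' window, 1% peptide-level FDR, and the dual |body| > 1 / |upstream| < 1
#' screen thresholds. Validation happens here, before any stage runs.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving every stochastic stage.
#' @param starts Allowed start codons.
#' @param min_aa,max_aa Peptide-length window (residues).
#' @param fdr Nominal peptide-level FDR.
#' @param body_cutoff,upstream_cutoff Screen hit thresholds.
#' @param simulate Named list of overrides for the simulators
#'   (`genome`, `psms`, `screen`), each passed on as extra arguments.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       starts = c("ATG", "CTG", "GTG", "TTG"),
                       min_aa = 6L, max_aa = 249L, fdr = 0.01,
                       body_cutoff = 1, upstream_cutoff = 1,
                       simulate = list()) {
  if (!is.numeric(seed) || length(seed) != 1L) abort("seed must be a single integer")
  if (max_aa < 1L || min_aa < 1L || max_aa < min_aa) {
    abort("invalid peptide-length window: need 1 <= min_aa <= max_aa")
  }
  if (fdr <= 0 || fdr >= 1) abort("fdr must be in (0, 1)")
  if (body_cutoff <= 0 || upstream_cutoff <= 0) abort("screen cutoffs must be positive")
  bad <- setdiff(starts, c("ATG", "CTG", "GTG", "TTG"))
  if (length(bad) > 0L) abort(paste0("unsupported start codon(s): ", paste(bad, collapse = ",")))
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), starts = starts,
      min_aa = as.integer(min_aa), max_aa = as.integer(max_aa), fdr = fdr,
      body_cutoff = body_cutoff, upstream_cutoff = upstream_cutoff,
      simulate = simulate
    ),
    class = "run_config"
  )
}

#' Run the full pipeline on simulated fixtures
#'
#' Executes simulate -> build-library -> filter-psms -> score-screen ->
#' characterize with one validated config, writing every stage output plus
#' a provenance manifest (package version, config, MD5 checksums of every
#' written file) into `config$out_dir`. Identical config gives
#' byte-identical outputs.
#'
#' @param config A `run_config` object.
#' @return Invisibly, a list with the final `peptides`, `report`,
#'   `phenotypes`, `support`, `paths` of all written files and the
#'   provenance list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("config must come from run_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  sim <- stage("simulate-genome", do.call(simulate_genome_annotation, c(
    list(seed = config$seed, starts = config$starts, min_aa = config$min_aa,
         max_aa = config$max_aa, dir = config$out_dir),
    config$simulate$genome
  )))

  genome <- read_genome(sim$files$fasta)
  transcripts <- read_gtf(sim$files$gtf, genome)
  lib <- stage("build-library", build_orf_library(
    transcripts, genome,
    starts = config$starts, min_aa = config$min_aa, max_aa = config$max_aa
  ))
  readr::write_tsv(lib, out("orf_catalogue.tsv"))
  write_orf_fasta(lib, out("targets.fasta"), out("decoys.fasta"))

  # canonical stand-in proteome: the annotated CDS translations
  canonical <- lib %>% filter(.data$category == "annotated")
  canonical_seqs <- setNames(canonical$peptide, canonical$orf_id)

  psim <- stage("simulate-psms", do.call(simulate_psm_table, c(
    list(library = lib, seed = config$seed + 1L),
    config$simulate$psms
  )))
  write_psm_table(psim$psms, out("psms.tsv"))

  filt <- stage("filter-psms", filter_psms(
    psim$psms, lib, canonical_seqs, alpha = config$fdr
  ))
  named <- stage("name-peptides", {
    idx <- match(
      purrr::map_chr(filt$peptides$orf_ids, 1L),
      lib$orf_id
    )
    info <- lib[idx, c("gene_id", "gene_name", "category", "g_min", "g_max")]
    keep <- info$category != "annotated"
    assign_peptide_names(bind_rows(list(
      filt$peptides[keep, c("peptide", "psm_count", "q_value")] %>%
        mutate(
          orf_id = purrr::map_chr(filt$peptides$orf_ids[keep], 1L),
          gene_id = info$gene_id[keep], gene_name = info$gene_name[keep],
          category = info$category[keep], g_min = info$g_min[keep],
          g_max = info$g_max[keep]
        )
    )))
  })
  readr::write_tsv(named, out("peptide_catalogue.tsv"))
  readr::write_tsv(filt$report, out("filter_report.tsv"))
  support <- summarize_support(filt$peptides)
  readr::write_tsv(support, out("support_summary.tsv"))

  screened_ids <- head(lib$orf_id[lib$category != "annotated"], 1000L)
  ssim <- stage("simulate-screen", do.call(simulate_screen_counts, c(
    list(orf_ids = screened_ids, seed = config$seed + 2L),
    config$simulate$screen
  )))
  readr::write_tsv(ssim$manifest, out("sgrna_manifest.tsv"))
  readr::write_tsv(ssim$counts, out("sgrna_counts.tsv"))
  norm <- normalize_rpm_log2(ssim$counts)
  reps <- setdiff(names(ssim$counts), "sgrna_id")
  lfc <- guide_lfc(norm, grep("^T0_", reps, value = TRUE), grep("^Tf_", reps, value = TRUE))
  phen <- stage("score-screen", phenotype_scores(
    lfc, ssim$manifest,
    body_cutoff = config$body_cutoff, upstream_cutoff = config$upstream_cutoff
  ))
  readr::write_tsv(as_tibble(phen), out("phenotypes.tsv"))
  qc <- control_separation(lfc, ssim$manifest)
  readr::write_tsv(qc$summary, out("screen_qc.tsv"))

  usage <- start_codon_usage(lib)
  readr::write_tsv(usage, out("start_codon_usage.tsv"))

  paths <- list.files(config$out_dir, full.names = TRUE)
  paths <- setdiff(paths, out("provenance.json"))
  provenance <- list(
    package = "sorfscreen",
    version = as.character(utils::packageVersion("sorfscreen")),
    config = config[setdiff(names(config), "out_dir")],
    checksums = as.list(tools::md5sum(sort(paths)))
  )
  jsonlite::write_json(provenance, out("provenance.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(list(
    peptides = filt$peptides, report = filt$report, named = named,
    phenotypes = phen, support = support, qc = qc,
    paths = c(paths, out("provenance.json")), provenance = provenance
  ))
}
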