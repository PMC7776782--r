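#' Build and validate a pipeline configuration
#'
#' Accepts a nested list or a YAML file path and fills in documented
#' defaults. A `seed` is mandatory — every stochastic stage derives its seed
#' from it, so a config fully determines the run. Threshold bounds are
#' checked here, before any compute.
#'
#' Config schema (all sections optional except `seed`):
#' \describe{
#'   \item{seed}{integer master seed (required)}
#'   \item{panel}{`n_targets`, `length`, `gc` — or `fasta`, `bed`,
#'     `annotations` paths for an external panel}
#'   \item{scenario}{`control_mf`, `treated_mf`, `strand_bias_factor`,
#'     `tissues`, `treatments` (first = control), `n_replicates`,
#'     `signature` (per-treatment list: `sub`, `p5`, `p3`, `weight`),
#'     `clones` (list of `target`, `pos`, `alt`, `fraction`, ...)}
#'   \item{sequencing}{`n_genomes`, `reads_per_strand`, `reads_dist`,
#'     `strand_dropout`, `error_rate`, `damage_rate`, `shear_jitter`,
#'     `barcode_error_rate`}
#'   \item{consensus}{`min_reads_per_strand`, `min_family_agreement`,
#'     `trim_quality`, `mask_quality`, `end_trim`}
#'   \item{calling}{`min_alt_count`, `germline_vaf`, `clonality_cutoff_sd`}
#'   \item{clustering}{`linkage`}
#' }
#'
#' @param x List or YAML path.
#' @return Validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  if (is.null(x$seed)) abort("config error: `seed` is mandatory")
  seed <- as.integer(x$seed)

  def <- function(section, field, default) {
    v <- x[[section]][[field]]
    if (is.null(v)) default else v
  }
  cfg <- list(
    seed = seed,
    panel = list(
      n_targets = def("panel", "n_targets", 4L),
      length = def("panel", "length", 400L),
      gc = def("panel", "gc", 0.5),
      fasta = x$panel$fasta, bed = x$panel$bed,
      annotations = x$panel$annotations
    ),
    scenario = list(
      control_mf = def("scenario", "control_mf", 1.5e-7),
      treated_mf = def("scenario", "treated_mf", 1.2e-6),
      strand_bias_factor = def("scenario", "strand_bias_factor", 1),
      tissues = def("scenario", "tissues", c("liver", "marrow")),
      treatments = def("scenario", "treatments", c("VC", "mutagen")),
      n_replicates = def("scenario", "n_replicates", 3L),
      signature = x$scenario$signature,
      clones = x$scenario$clones
    ),
    sequencing = list(
      n_genomes = def("sequencing", "n_genomes", 500L),
      reads_per_strand = def("sequencing", "reads_per_strand", 2),
      reads_dist = def("sequencing", "reads_dist", "ztpois"),
      strand_dropout = def("sequencing", "strand_dropout", 0.2),
      error_rate = def("sequencing", "error_rate", 1e-3),
      damage_rate = def("sequencing", "damage_rate", 1e-3),
      shear_jitter = def("sequencing", "shear_jitter", 5L),
      barcode_error_rate = def("sequencing", "barcode_error_rate", 0.02)
    ),
    consensus = list(
      min_reads_per_strand = def("consensus", "min_reads_per_strand", 1L),
      min_family_agreement = def("consensus", "min_family_agreement", 0.7),
      trim_quality = def("consensus", "trim_quality", 20),
      mask_quality = def("consensus", "mask_quality", 20),
      end_trim = def("consensus", "end_trim", 5L)
    ),
    calling = list(
      min_alt_count = def("calling", "min_alt_count", 1L),
      germline_vaf = def("calling", "germline_vaf", 0.3),
      clonality_cutoff_sd = def("calling", "clonality_cutoff_sd", 3)
    ),
    clustering = list(
      linkage = def("clustering", "linkage", "wpgma")
    )
  )
  with(cfg$consensus, {
    if (min_family_agreement <= 0.5 || min_family_agreement > 1) {
      abort("config error: min_family_agreement must lie in (0.5, 1]")
    }
    if (min_reads_per_strand < 1) {
      abort("config error: min_reads_per_strand must be >= 1")
    }
  })
  with(cfg$sequencing, {
    if (error_rate < 0 || error_rate >= 0.5 ||
        damage_rate < 0 || damage_rate >= 0.5) {
      abort("config error: error rates must lie in [0, 0.5)")
    }
  })
  with(cfg$calling, {
    if (germline_vaf <= 0 || germline_vaf > 1) {
      abort("config error: germline_vaf must lie in (0, 1]")
    }
  })
  if (!cfg$clustering$linkage %in% c("wpgma", "ward")) {
    abort("config error: linkage must be wpgma or ward")
  }
  structure(cfg, class = "pipeline_config")
}

#' A small bundled demonstration configuration
#'
#' Desk-scale cohort (2 tissues x 2 treatments x 2 replicates, 3 short
#' targets) that runs the full pipeline in seconds. Mutant frequencies are
#' inflated relative to a real study so that the tiny territory still
#' yields calls.
#'
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 20201214) {
  pipeline_config(list(
    seed = seed,
    panel = list(n_targets = 3L, length = 240L),
    scenario = list(control_mf = 2e-5, treated_mf = 2e-4,
                    n_replicates = 2L,
                    signature = list(
                      mutagen = list(sub = "T>A", p3 = "G", weight = 0.8))),
    sequencing = list(n_genomes = 400L, reads_per_strand = 2,
                      damage_rate = 1e-3)
  ))
}

#' @noRd
config_signature <- function(cfg) {
  spec <- cfg$scenario$signature
  treatments <- cfg$scenario$treatments
  if (is.null(spec)) return(signature_flat())
  sigs <- lapply(treatments, function(tr) {
    s <- spec[[tr]]
    if (is.null(s)) return(signature_flat())
    signature_concentrated(s$sub, p5 = s$p5, p3 = s$p3,
                           weight = s$weight %||% 0.9)
  })
  setNames(sigs, treatments)
}

#' Run the full duplex sequencing analysis pipeline
#'
#' Executes simulate -> consensus -> call -> metrics -> spectra -> cluster
#' for every sample of the configured cohort and writes all outputs (FASTA,
#' BED, truth tables, read dumps, consensus TSV, per-sample VCF + TSV calls,
#' metrics TSVs, spectra TSVs, Newick dendrogram, JSON run manifest) under
#' `out_dir`. Re-running with the same config reproduces the deterministic
#' outputs byte for byte.
#'
#' @param config A [pipeline_config()] (or list / YAML path coerced by it).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a result bundle: `panel`, `samples`, `calls`,
#'   `sample_metrics`, `cohort_metrics`, `fold_induction`, `spectra`,
#'   `dendrogram`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config

  # --- panel -----------------------------------------------------------
  if (!is.null(cfg$panel$fasta)) {
    panel <- read_targets(cfg$panel$bed, cfg$panel$fasta,
                          cfg$panel$annotations)
  } else {
    panel <- generate_reference_panel(cfg$panel$n_targets, cfg$panel$length,
                                      seed = cfg$seed, gc = cfg$panel$gc)
  }
  write_panel(panel,
              file.path(out_dir, "panel.fasta"),
              file.path(out_dir, "targets.bed"),
              file.path(out_dir, "annotations.tsv"))

  clones <- cfg$scenario$clones
  if (!is.null(clones)) clones <- dplyr::bind_rows(clones)
  scenario <- mutagenesis_scenario(
    mf = tidyr::expand_grid(tissue = cfg$scenario$tissues,
                            treatment = cfg$scenario$treatments) |>
      dplyr::mutate(mf = ifelse(treatment == cfg$scenario$treatments[1],
                                cfg$scenario$control_mf,
                                cfg$scenario$treated_mf)),
    signature = config_signature(cfg),
    strand_bias_factor = cfg$scenario$strand_bias_factor,
    clones = clones,
    tissues = cfg$scenario$tissues,
    treatments = cfg$scenario$treatments,
    n_replicates = cfg$scenario$n_replicates,
    seed = cfg$seed)

  samples <- tidyr::expand_grid(
    tissue = scenario$tissues, treatment = scenario$treatments,
    replicate = seq_len(scenario$n_replicates)) |>
    dplyr::mutate(sample_id = sprintf("%s_%s_r%d", tissue, treatment,
                                      replicate))

  whitelist <- generate_barcode_whitelist(256, 10,
                                          seed = (cfg$seed %% 2^20) + 1L)
  n_warn <- c(rejected_reads = 0, tied_families = 0, boundary_calls = 0)

  all_calls <- vector("list", nrow(samples))
  all_truth <- vector("list", nrow(samples))
  depth_tab <- vector("list", nrow(samples))
  sample_spectra <- list()

  for (s in seq_len(nrow(samples))) {
    srow <- samples[s, ]
    sseed <- (cfg$seed + 7919L * s) %% .Machine$integer.max
    truth <- simulate_true_mutations(
      panel, scenario, n_genomes = cfg$sequencing$n_genomes,
      tissue = srow$tissue, treatment = srow$treatment,
      replicate = srow$replicate, seed = sseed)
    reads <- simulate_read_families(
      panel, truth,
      reads_per_strand = cfg$sequencing$reads_per_strand,
      reads_dist = cfg$sequencing$reads_dist,
      strand_dropout = cfg$sequencing$strand_dropout,
      error_rate = cfg$sequencing$error_rate,
      damage_rate = cfg$sequencing$damage_rate,
      shear_jitter = cfg$sequencing$shear_jitter,
      whitelist = whitelist,
      barcode_error_rate = cfg$sequencing$barcode_error_rate,
      seed = sseed + 1L)
    trimmed <- quality_trim(reads$bases, reads$quals,
                            trim_quality = cfg$consensus$trim_quality,
                            mask_quality = cfg$consensus$mask_quality)
    reads$bases <- trimmed$bases
    reads$quals <- trimmed$quals
    reads <- reads[nchar(reads$bases) > 0, , drop = FALSE]
    attr(reads, "whitelist") <- whitelist
    fams <- suppressMessages(group_families(reads))
    n_warn["rejected_reads"] <- n_warn["rejected_reads"] +
      attr(fams, "n_rejected") + attr(fams, "n_unoriented")
    fams <- suppressMessages(filter_cigar_groups(fams))
    n_warn["tied_families"] <- n_warn["tied_families"] +
      attr(fams, "n_families_rejected")
    cons <- call_duplex_consensus(
      fams,
      min_reads_per_strand = cfg$consensus$min_reads_per_strand,
      min_family_agreement = cfg$consensus$min_family_agreement,
      end_trim = cfg$consensus$end_trim)
    cols <- pileup(cons, panel)
    bp <- duplex_base_pairs(cols)
    calls <- call_variants(cols, min_alt_count = cfg$calling$min_alt_count) |>
      flag_germline(vaf_threshold = cfg$calling$germline_vaf) |>
      classify_clonality(cutoff_sd = cfg$calling$clonality_cutoff_sd) |>
      suppressWarnings() |>
      dplyr::mutate(sample_id = srow$sample_id, tissue = srow$tissue,
                    treatment = srow$treatment)
    if (s == 1) {
      write_read_dump(reads, file.path(out_dir, "reads_sample1.fastq.gz"),
                      file.path(out_dir, "families_sample1.tsv"))
      readr::write_tsv(cons, file.path(out_dir, "consensus_sample1.tsv"))
    }
    write_variants(calls, file.path(out_dir,
                                    paste0("calls_", srow$sample_id, ".vcf")),
                   file.path(out_dir,
                             paste0("calls_", srow$sample_id, ".tsv")),
                   sample_id = srow$sample_id)
    all_calls[[s]] <- calls
    all_truth[[s]] <- dplyr::mutate(truth, sample_id = srow$sample_id)
    depth_tab[[s]] <- tibble(sample_id = srow$sample_id,
                             tissue = srow$tissue,
                             treatment = srow$treatment, duplex_bp = bp)
    sp <- simple_spectrum(calls[!calls$germline, , drop = FALSE], panel)
    if (attr(sp, "normalized")) {
      sample_spectra[[srow$sample_id]] <- sp
    }
  }

  calls <- dplyr::bind_rows(all_calls)
  truth <- dplyr::bind_rows(all_truth)
  depths <- dplyr::bind_rows(depth_tab)
  readr::write_tsv(truth, file.path(out_dir, "truth_mutations.tsv"))

  sample_metrics <- mutant_frequency(
    calls, depths[, c("sample_id", "duplex_bp")], by = "sample_id") |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::relocate(sample_id, tissue, treatment)
  cohort_depths <- depths |>
    dplyr::group_by(tissue, treatment) |>
    dplyr::summarise(duplex_bp = sum(duplex_bp), .groups = "drop")
  cohort_metrics <- mutant_frequency(calls, cohort_depths,
                                     by = c("tissue", "treatment"))
  control <- scenario$treatments[1]
  fi <- cohort_metrics |>
    dplyr::group_by(tissue) |>
    dplyr::mutate(fold_induction = fold_induction(
      mf, mf[treatment == control])) |>
    dplyr::ungroup() |>
    dplyr::filter(treatment != control) |>
    dplyr::select(tissue, treatment, fold_induction)
  readr::write_tsv(sample_metrics, file.path(out_dir, "sample_metrics.tsv"))
  readr::write_tsv(dplyr::left_join(cohort_metrics, fi,
                                    by = c("tissue", "treatment")),
                   file.path(out_dir, "cohort_metrics.tsv"))

  # --- spectra by treatment -------------------------------------------
  spectra <- lapply(setNames(nm = scenario$treatments), function(tr) {
    tc <- calls[calls$treatment == tr & !calls$germline, , drop = FALSE]
    suppressMessages(trinucleotide_spectrum(tc, panel))
  })
  for (tr in names(spectra)) {
    readr::write_tsv(spectra[[tr]],
                     file.path(out_dir, paste0("spectrum96_", tr, ".tsv")))
  }

  dend <- NULL
  if (length(sample_spectra) >= 2) {
    dend <- hierarchical_cluster(bind_spectra(sample_spectra),
                                 linkage = cfg$clustering$linkage)
    writeLines(as_newick(dend), file.path(out_dir, "dendrogram.nwk"))
    readr::write_tsv(tidy(dend), file.path(out_dir, "dendrogram_merges.tsv"))
  }

  manifest <- list(
    package = "dupseq",
    version = as.character(utils::packageVersion("dupseq")),
    seed = cfg$seed,
    config = unclass(cfg),
    outputs = sort(unique(c(list.files(out_dir), "manifest.json"))),
    warning_counts = as.list(n_warn)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(panel = panel, samples = samples, calls = calls,
                 truth = truth, depths = depths,
                 sample_metrics = sample_metrics,
                 cohort_metrics = cohort_metrics,
                 fold_induction = fi, spectra = spectra,
                 dendrogram = dend, manifest = manifest))
}
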