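manifest_path <- function(out_dir) file.path(out_dir, "run_manifest.jsonl")

append_manifest <- function(out_dir, stage, inputs, outputs, cfg, seed,
                            counts) {
  counts <- lapply(counts, function(x) {
    if (inherits(x, "table")) as.list(setNames(as.integer(x), names(x))) else x
  })
  entry <- list(
    stage = stage,
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    inputs = as.list(inputs), outputs = as.list(outputs),
    config_hash = rlang::hash(unclass(cfg)),
    seed = seed, counts = as.list(counts)
  )
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = manifest_path(out_dir), append = TRUE, sep = "")
  invisible(entry)
}

require_inputs <- function(stage, paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("stage '", stage, "': missing input file(s): ",
                 paste(missing, collapse = ", ")))
  }
}

#' Pipeline stages
#'
#' File-based stage runners chaining the package's in-memory functions:
#' `run_simulate()` writes every input the pipeline consumes;
#' `run_detect_polymorphisms()`, `run_liftover()`, `run_design_panel()`,
#' `run_genotype()` and `run_linkage_qc()` each read their stage inputs
#' from `out_dir`, write their outputs there and append an entry to
#' `run_manifest.jsonl`; `run_all()` chains the five analysis stages.
#'
#' @param out_dir Working directory holding all stage files.
#' @param cfg A [pipeline_config()] (analysis stages).
#' @param sim_cfg A [sim_config()] (`run_simulate()`).
#' @param seed Integer seed.
#' @param quotas Per-chromosome marker quotas for [select_panel()], or a
#'   total count.
#' @return Each runner invisibly returns its main output tibble(s).
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
run_simulate <- function(out_dir, sim_cfg = sim_config(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(sim_cfg, seed)
  cross <- simulate_lines_and_cross(ref, sim_cfg, seed)
  write_fasta(ref$genome, file.path(out_dir, "genome.fa"))
  write_fasta(ref$unigenes, file.path(out_dir, "unigenes.fa"))
  write_alignments(ref$alignments, file.path(out_dir, "alignments.tsv"))
  write_anchor_table(ref$anchors, file.path(out_dir, "anchors.tsv"))
  write_variant_table(cross$variants, file.path(out_dir, "variants.tsv"))
  saveRDS_loci <- ref$truth$loci
  readr::write_tsv(saveRDS_loci, file.path(out_dir, "truth_loci.tsv"),
                   progress = FALSE)
  append_manifest(out_dir, "simulate", character(),
                  c("genome.fa", "unigenes.fa", "alignments.tsv",
                    "anchors.tsv", "variants.tsv", "truth_loci.tsv"),
                  sim_cfg, seed,
                  list(n_genes = nrow(ref$truth$genes),
                       n_variant_rows = nrow(cross$variants)))
  invisible(list(ref = ref, cross = cross))
}

#' @rdname pipeline-stages
#' @export
run_detect_polymorphisms <- function(out_dir, cfg = pipeline_config(),
                                     seed = 1) {
  cfg <- as_config(cfg)
  vp <- file.path(out_dir, "variants.tsv")
  require_inputs("detect-polymorphisms", vp)
  variants <- read_variant_table(vp)
  sites <- detect_polymorphic_sites(variants, cfg)
  ap <- file.path(out_dir, "anchors.tsv")
  anchors <- if (file.exists(ap)) read_anchor_table(ap) else {
    warn("anchor table missing: all sites categorized as no_information")
    NULL
  }
  sites <- categorize_sites(sites, anchors)
  readr::write_tsv(sites, file.path(out_dir, "polymorphic_sites.tsv"),
                   progress = FALSE)
  summ <- summarize_site_classification(sites)
  readr::write_tsv(summ, file.path(out_dir, "site_classification.tsv"),
                   progress = FALSE)
  append_manifest(out_dir, "detect-polymorphisms", "variants.tsv",
                  c("polymorphic_sites.tsv", "site_classification.tsv"),
                  cfg, seed, list(n_sites = nrow(sites)))
  invisible(sites)
}

#' @rdname pipeline-stages
#' @export
run_liftover <- function(out_dir, cfg = pipeline_config(), seed = 1) {
  cfg <- as_config(cfg)
  req <- file.path(out_dir, c("polymorphic_sites.tsv", "alignments.tsv"))
  require_inputs("liftover", req)
  sites <- readr::read_tsv(req[1], show_col_types = FALSE, progress = FALSE)
  aln <- read_alignments(req[2])
  lifted <- lift_sites(sites, aln, flank = cfg$flank)
  readr::write_tsv(lifted, file.path(out_dir, "lifted_sites.tsv"),
                   progress = FALSE)
  append_manifest(out_dir, "liftover", basename(req), "lifted_sites.tsv",
                  cfg, seed,
                  list(n_in = nrow(sites),
                       n_kept = sum(is.na(lifted$drop_reason)),
                       drop_reasons = table(lifted$drop_reason)))
  invisible(lifted)
}

#' @rdname pipeline-stages
#' @export
run_design_panel <- function(out_dir, cfg = pipeline_config(), seed = 1,
                             quotas = 48) {
  cfg <- as_config(cfg)
  req <- file.path(out_dir, c("lifted_sites.tsv", "genome.fa"))
  require_inputs("design-panel", req)
  lifted <- readr::read_tsv(req[1], show_col_types = FALSE, progress = FALSE)
  genome <- read_fasta(req[2])
  bl <- build_kmer_blacklist(genome, cfg$kmer_k, cfg$blacklist_cutoff)
  designs <- design_markers(lifted, genome, bl, cfg)
  panel <- select_panel(designs, quotas)
  panel <- append_common_tags(panel)
  panel <- pool_primers(panel, cfg$pool_size)
  readr::write_tsv(designs, file.path(out_dir, "marker_designs.tsv"),
                   progress = FALSE)
  readr::write_tsv(panel, file.path(out_dir, "panel.tsv"), progress = FALSE)
  write_amplicon_bed(panel, file.path(out_dir, "amplicons.bed"))
  append_manifest(out_dir, "design-panel", basename(req),
                  c("marker_designs.tsv", "panel.tsv", "amplicons.bed"),
                  cfg, seed,
                  list(n_candidates = nrow(designs),
                       n_designable = sum(designs$design_status == "ok"),
                       n_panel = nrow(panel)))
  invisible(panel)
}

#' @rdname pipeline-stages
#' @param sim_cross Optional in-memory cross (from [run_simulate()]); when
#'   absent, a depth table named `amplicon_depths.tsv` must exist in
#'   `out_dir`.
#' @export
run_genotype <- function(out_dir, cfg = pipeline_config(), seed = 1,
                         sim_cross = NULL) {
  cfg <- as_config(cfg)
  pp <- file.path(out_dir, "panel.tsv")
  require_inputs("genotype", pp)
  panel <- readr::read_tsv(pp, show_col_types = FALSE, progress = FALSE)
  dp <- file.path(out_dir, "amplicon_depths.tsv")
  require_inputs("genotype", dp)
  depths <- read_depth_table(dp)
  calls <- call_genotypes(depths, cfg)
  parent_ids <- grep("^P[12]_amp", unique(calls$sample_id), value = TRUE)
  f1_ids <- grep("^F1", unique(calls$sample_id), value = TRUE)
  f2_ids <- setdiff(unique(calls$sample_id), c(parent_ids, f1_ids))
  pcalls <- calls |>
    filter(.data$sample_id %in% parent_ids) |>
    mutate(line_id = sub("_amp.*$", "", .data$sample_id))
  consensus <- parental_consensus(pcalls)
  variant_seen <- calls |>
    group_by(.data$marker_id) |>
    summarise(had_any_variant = any(.data$alt_count > 0 &
                                      .data$call != "no_call"),
              .groups = "drop")
  classes <- classify_markers(consensus, variant_seen)
  f2_calls <- calls |> filter(.data$sample_id %in% f2_ids)
  mat <- build_genotype_matrix(f2_calls, classes)
  filt <- filter_matrix(mat, cfg)
  readr::write_tsv(classes, file.path(out_dir, "marker_classes.tsv"),
                   progress = FALSE)
  write_genotype_matrix(filt$matrix, file.path(out_dir, "genotype_matrix.tsv"))
  readr::write_tsv(filt$report, file.path(out_dir, "filter_report.tsv"),
                   progress = FALSE)
  append_manifest(out_dir, "genotype",
                  c("panel.tsv", "amplicon_depths.tsv"),
                  c("marker_classes.tsv", "genotype_matrix.tsv",
                    "filter_report.tsv"),
                  cfg, seed,
                  list(n_markers = nrow(mat),
                       n_kept = nrow(filt$matrix),
                       class_counts = table(classes$class)))
  invisible(list(classes = classes, matrix = filt$matrix,
                 report = filt$report))
}

#' @rdname pipeline-stages
#' @export
run_linkage_qc <- function(out_dir, cfg = pipeline_config(), seed = 1) {
  cfg <- as_config(cfg)
  mp <- file.path(out_dir, "genotype_matrix.tsv")
  require_inputs("linkage-qc", mp)
  mat <- read_genotype_matrix(mp)
  scan <- pairwise_linkage(mat)
  groups <- group_markers(scan, cfg$lod_threshold, cfg$max_rf)
  readr::write_tsv(scan$pairs, file.path(out_dir, "linkage_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(groups, file.path(out_dir, "linkage_groups.tsv"),
                   progress = FALSE)
  append_manifest(out_dir, "linkage-qc", "genotype_matrix.tsv",
                  c("linkage_pairs.tsv", "linkage_groups.tsv"),
                  cfg, seed,
                  list(n_markers = length(scan$markers),
                       n_groups = max(groups$group)))
  invisible(list(scan = scan, groups = groups))
}

#' @rdname pipeline-stages
#' @export
run_simulate_depths <- function(out_dir, sim_cfg = sim_config(), seed = 1) {
  pp <- file.path(out_dir, "panel.tsv")
  require_inputs("simulate-depths", pp)
  panel <- readr::read_tsv(pp, show_col_types = FALSE, progress = FALSE)
  ref <- simulate_reference(sim_cfg, seed)
  cross <- simulate_lines_and_cross(ref, sim_cfg, seed)
  amp <- simulate_amplicon_depths(panel, cross, ref, sim_cfg, seed)
  write_depth_table(amp$depths, file.path(out_dir, "amplicon_depths.tsv"))
  readr::write_tsv(amp$truth_class, file.path(out_dir, "truth_classes.tsv"),
                   progress = FALSE)
  append_manifest(out_dir, "simulate-depths", "panel.tsv",
                  c("amplicon_depths.tsv", "truth_classes.tsv"),
                  sim_cfg, seed, list(n_rows = nrow(amp$depths)))
  invisible(amp)
}

#' @rdname pipeline-stages
#' @export
run_all <- function(out_dir, cfg = pipeline_config(), seed = 1, quotas = 48,
                    sim_cfg = NULL) {
  run_detect_polymorphisms(out_dir, cfg, seed)
  run_liftover(out_dir, cfg, seed)
  run_design_panel(out_dir, cfg, seed, quotas)
  if (!file.exists(file.path(out_dir, "amplicon_depths.tsv"))) {
    if (is.null(sim_cfg)) {
      abort("stage 'genotype': missing input file(s): amplicon_depths.tsv")
    }
    run_simulate_depths(out_dir, sim_cfg, seed)
  }
  run_genotype(out_dir, cfg, seed)
  run_linkage_qc(out_dir, cfg, seed)
  invisible(out_dir)
}
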