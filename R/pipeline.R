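## End-to-end orchestration: simulate (or load) a cohort, map the deletion
## from genotypes, characterize it from sequencing evidence, run the
## transmission statistics, and emit one reproducible report.

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file holding one) with a
#' required integer `seed` and optional sections `simulation` (overrides
#' passed to [simulation_config()]), `mendel_scan`, `breakpoint` and `stats`
#' (parameter overrides for the respective stages) plus `out_dir`.
#'
#' @param x a named list or the path to a YAML file.
#' @return validated list of class `run_config`.
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x))
      stop_hemidel(paste("config file not found:", x), "hemidel_config_error")
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x))
    stop_hemidel("config must be a named list or YAML file", "hemidel_config_error")
  if (is.null(x$seed))
    stop_hemidel("missing required config key: seed", "hemidel_config_error")
  x$seed <- as.integer(x$seed)
  known <- c("seed", "simulation", "mendel_scan", "breakpoint", "stats",
             "out_dir")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop_hemidel(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
                 "hemidel_config_error")
  sim_args <- c(list(seed = x$seed), x$simulation)
  ## validates ranges (rates in [0,1], flank order, ...) and freezes defaults
  x$simulation_config <- do.call(simulation_config, sim_args)
  structure(x, class = "run_config")
}

run_stage <- function(name, expr, verbose) {
  if (verbose) message(sprintf("[%s] running", name))
  tryCatch(expr, error = function(e) {
    stop_hemidel(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 "hemidel_stage_error")
  })
}

#' Run the full mapping / characterization / transmission pipeline
#'
#' Stages, in order: cohort simulation, Mendelian-error region calling,
#' depth segmentation plus junction assembly, transmission statistics, and
#' truth-vs-called comparison.  The whole run is a deterministic function
#' of the configuration (same config, same report).
#'
#' @param config a `run_config` from [validate_config()], a plain list, or a
#'   YAML path.
#' @param dry_run if TRUE, list the planned stages without computing.
#' @param verbose emit per-stage progress messages.
#' @return list of class `run_report` with elements `candidate_regions`,
#'   `deletion_call`, `stats`, `truth_recovery` and `provenance`.  When
#'   `out_dir` is configured, writes `report.json`, `regions.bed`,
#'   `profile.tsv` and `segments.tsv` there.
#' @export
run_pipeline <- function(config, dry_run = FALSE, verbose = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  stages <- c("simulate", "mendel_scan", "depth_breakpoint", "stats",
              "compare_truth")
  if (dry_run) return(stages)
  cfg <- config$simulation_config

  bundle <- run_stage("simulate", simulate_cohort(cfg), verbose)

  ms_args <- config$mendel_scan
  regions <- run_stage("mendel_scan", {
    prof <- build_error_profile(bundle$genotypes, bundle$pedigree, "SIRE")
    do.call(call_candidate_regions,
            c(list(profile = prof, map = bundle$marker_map), ms_args))
  }, verbose)

  bp_args <- config$breakpoint
  call <- run_stage("depth_breakpoint", {
    segs <- segment_depth(normalize_depth(bundle$depth_carrier))
    bracket <- locate_breakpoints_from_pairs(bundle$pairs, cfg$insert_mean,
                                             cfg$insert_sd,
                                             read_len = cfg$read_len)
    junction <- if (is.null(bracket)) NULL else tryCatch(
      do.call(assemble_junction,
              c(list(pairs = bundle$pairs,
                     reference_fetch = bundle$reference_fetch,
                     bracket = bracket, read_len = cfg$read_len), bp_args)),
      hemidel_error = function(e) NULL)
    merge_evidence(segs, junction)
  }, verbose)

  stats_cfg <- do.call(lethality_config, as.list(config$stats))
  report_stats <- run_stage("stats", inheritance_report(
    birth = bundle$counts$birth, sperm = bundle$counts$sperm,
    blastocyst = bundle$counts$blastocyst, ai = bundle$ai_records,
    cfg = stats_cfg), verbose)

  truth <- bundle$truth
  recovery <- run_stage("compare_truth", {
    top <- if (nrow(regions) > 0) regions[1, ] else NULL
    overlap <- !is.null(top) && top$chrom == truth$chrom &&
      top$start <= truth$deleted_interval[2] &&
      top$end >= truth$deleted_interval[1]
    junction_exact <- !is.null(call$junction) &&
      call$junction$left_flank == truth$left_flank &&
      call$junction$right_flank == truth$right_flank &&
      identical(call$junction$inserted_seq, truth$inserted_seq)
    concordant <- identical(call$evidence, "concordant")
    list(region_overlaps_truth = overlap, junction_exact = junction_exact,
         evidence_concordant = concordant,
         mosaicism_truth = truth$mosaicism,
         mosaicism_hat = if (is.null(report_stats$mosaicism)) NA_real_
           else report_stats$mosaicism$mosaicism,
         lethality_truth = truth$male_lethality,
         lambda_hat = report_stats$lambda_hat)
  }, verbose)

  report <- structure(list(
    candidate_regions = regions,
    deletion_call = call,
    stats = report_stats,
    truth_recovery = recovery,
    provenance = list(seed = config$seed,
                      package_version = as.character(utils::packageVersion("hemidel")),
                      simulation = cfg[setdiff(names(cfg), "")])),
    class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_files(report, bundle, config$out_dir)
  }
  report
}

write_report_files <- function(report, bundle, dir) {
  if (nrow(report$candidate_regions) > 0) {
    regions <- report$candidate_regions
    regions$label <- sprintf("region_%d_score_%g", seq_len(nrow(regions)),
                             regions$score)
    write_bed(regions, file.path(dir, "regions.bed"))
  }
  prof <- build_error_profile(bundle$genotypes, bundle$pedigree, "SIRE")
  utils::write.table(prof, file.path(dir, "profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  segs <- segment_depth(normalize_depth(bundle$depth_carrier))
  utils::write.table(segs, file.path(dir, "segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(serialize_report(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

## flatten S3 pieces into plain lists for stable JSON output
serialize_report <- function(report) {
  strip <- function(x) {
    if (inherits(x, "test_result") || inherits(x, "mosaicism_estimate"))
      return(unclass(x))
    if (is.function(x)) return(NULL)
    if (is.data.frame(x)) return(as.data.frame(x))
    if (is.table(x)) return(as.list(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(report)
}
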