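#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis into one
#' serializable object. The resolved configuration (including the seed) is
#' written beside the outputs of every [run_pipeline()] run.
#'
#' @param mode Input mode: `"simulate"` (generate data via [simulate_dataset()]),
#'   `"dataset"` (load a directory written by [write_dataset()]), or
#'   `"supplementary"` (deposited electrode-level MAT matrices; the BGA and
#'   latency stages are unavailable because raw traces are not deposited).
#' @param sim A [sim_config()] (simulate mode).
#' @param input Input path (dataset directory), or for supplementary mode a
#'   named list/vector with entries `vtc_left`, `vtc_right`, `loc`.
#' @param out_dir Output directory for tables and the manifest.
#' @param stages Character subset of `c("selectivity", "latency", "topology")`.
#' @param n_perm,q Permutations and FDR level for the selectivity stage.
#' @param alpha,persistence_s,latency_window Latency-stage parameters.
#' @param band,baseline_window,analysis_window BGA parameters.
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "dataset", "supplementary"),
                            sim = sim_config(), input = NULL, out_dir = NULL,
                            stages = c("selectivity", "latency", "topology"),
                            n_perm = 10000, q = 0.01, alpha = 0.05,
                            persistence_s = 0.1, latency_window = c(0, 0.7),
                            band = c(60, 120),
                            baseline_window = c(-0.7, -0.2),
                            analysis_window = c(0.1, 0.4), seed = 1) {
  mode <- match.arg(mode)
  stages <- match.arg(stages, several.ok = TRUE)
  if (mode != "simulate" && is.null(input)) {
    abort(sprintf("mode '%s' requires `input`.", mode))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order: simulate/load, BGA extraction +
#' selectivity table, onset latencies, topology models. All tables, the
#' resolved configuration and a content-hash manifest are staged in a
#' temporary directory and moved into `out_dir` in one step, so a partial run
#' never leaves a half-written output directory. Reruns with the same
#' configuration and seed reproduce the manifest hashes.
#'
#' In supplementary mode the latency stage is skipped (raw voltage traces are
#' not part of the deposited matrices) and selectivity p-values are recomputed
#' from the stored shuffled d-prime indices.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the computed tables (`selectivity`,
#'   `counts`, `latency`, `latency_summary`, `topology`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a <pipeline_config>.")
  }
  out <- list()
  stage_dir <- tempfile("gammasel_stage_")
  dir.create(stage_dir)
  emit <- function(df, name) {
    write_tsv17(df, file.path(stage_dir, paste0(name, ".tsv")))
  }
  log_stage <- function(...) message(sprintf(...))

  if (config$mode == "supplementary") {
    paths <- as.list(config$input)
    need <- c("vtc_left", "vtc_right", "loc")
    if (!all(need %in% names(paths))) {
      abort("Supplementary mode `input` needs entries vtc_left, vtc_right, loc.")
    }
    log_stage("stage load: supplementary matrices (%s)",
              paste(basename(unlist(paths[need])), collapse = ", "))
    rep <- reproduce_supplementary(paths$vtc_left, paths$vtc_right, paths$loc,
                                   q = config$q)
    out$selectivity <- rep$selectivity
    out$counts <- rep$counts
    if ("topology" %in% config$stages) out$topology <- rep$topology
    log_stage("stage selectivity: %d electrode-categories, %d selective electrodes",
              nrow(rep$selectivity), rep$counts$n_selective)
  } else {
    dataset <- if (config$mode == "simulate") {
      cfg <- config$sim
      cfg$seed <- config$seed
      log_stage("stage simulate: %d subjects, seed %d", cfg$n_subjects, cfg$seed)
      simulate_dataset(cfg)
    } else {
      log_stage("stage load: dataset '%s'", config$input)
      read_dataset(config$input)
    }
    emit(dataset$geometry, "geometry")
    if ("selectivity" %in% config$stages) {
      out$selectivity <- selectivity_table(
        dataset, n_perm = config$n_perm, q = config$q,
        window = config$analysis_window, seed = config$seed,
        band = config$band, baseline_window = config$baseline_window
      )
      out$counts <- selectivity_counts(out$selectivity)
      log_stage("stage selectivity: %d rows, %d/%d electrodes selective",
                nrow(out$selectivity), out$counts$n_selective, out$counts$n_total)
    }
    if ("latency" %in% config$stages) {
      if (is.null(out$selectivity)) {
        abort("Stage 'latency' needs the selectivity stage (missing upstream artifact: selectivity table).")
      }
      out$latency <- latency_table(
        dataset, selectivity = out$selectivity, alpha = config$alpha,
        window = config$latency_window, persistence_s = config$persistence_s,
        band = config$band, baseline_window = config$baseline_window
      )
      out$latency_summary <- latency_summary(out$latency)
      log_stage("stage latency: %d scans, %d onsets detected",
                nrow(out$latency), sum(!is.na(out$latency$onset_ms)))
    }
    if ("topology" %in% config$stages) {
      if (is.null(out$selectivity)) {
        abort("Stage 'topology' needs the selectivity stage (missing upstream artifact: selectivity table).")
      }
      out$topology <- topology_report(out$selectivity, dataset$geometry)
      log_stage("stage topology: %d mixed-effects fits", length(out$topology$fits))
    }
  }

  if (!is.null(out$selectivity)) emit(out$selectivity, "selectivity")
  if (!is.null(out$counts)) {
    emit(out$counts$by_region, "counts_by_region")
    emit(out$counts$by_category, "counts_by_category")
  }
  if (!is.null(out$latency)) emit(out$latency, "latency")
  if (!is.null(out$latency_summary)) {
    emit(out$latency_summary$cells, "latency_cells")
    emit(out$latency_summary$pairwise, "latency_pairwise")
  }
  if (!is.null(out$topology)) {
    emit(out$topology$coefficients, "lme_coefficients")
    emit(out$topology$screen, "collinearity")
  }
  jsonlite::write_json(
    resolved_config_json(config), file.path(stage_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  files <- sort(list.files(stage_dir))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(stage_dir, files))),
    bytes = file.size(file.path(stage_dir, files))
  )
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest

  if (!is.null(config$out_dir)) {
    if (dir.exists(config$out_dir)) unlink(config$out_dir, recursive = TRUE)
    dir.create(dirname(config$out_dir), recursive = TRUE, showWarnings = FALSE)
    ok <- file.rename(stage_dir, config$out_dir)
    if (!ok) { # cross-device fallback: copy then remove staging
      dir.create(config$out_dir, recursive = TRUE)
      file.copy(file.path(stage_dir, list.files(stage_dir)), config$out_dir)
      unlink(stage_dir, recursive = TRUE)
    }
    log_stage("outputs written to %s", config$out_dir)
  } else {
    unlink(stage_dir, recursive = TRUE)
  }
  invisible(out)
}

resolved_config_json <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg$out_dir <- NULL # machine-specific; keep the record location-independent
  cfg
}
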