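#' Assemble a pipeline run configuration
#'
#' @param out_dir output directory.
#' @param synth a `synth_config` for data synthesis, or NULL to analyze an
#'   existing dataset.
#' @param image_dir,cohort_csv existing data (used when `synth` is NULL):
#'   directory holding `<scan_id>.nii.gz` / `<scan_id>_mask.nii.gz` pairs
#'   and the cohort CSV.
#' @param n_levels,direction_mode,log_base texture settings.
#' @param rim_fraction,resample_isotropic shape settings.
#' @param alpha significance level; `knot_dates` spline knots;
#'   `corstr` working correlation.
#' @param seed integer seed for the whole run.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, synth = NULL, image_dir = NULL,
                       cohort_csv = NULL, n_levels = 32L,
                       direction_mode = "3d", log_base = 2,
                       rim_fraction = 0.1, resample_isotropic = FALSE,
                       alpha = 0.05, knot_dates = as.Date("2020-03-11"),
                       corstr = "unstructured", seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("run_config: alpha must be in (0, 1)")
  if (is.null(synth) && (is.null(image_dir) || is.null(cohort_csv)))
    stop("run_config: provide either 'synth' or image_dir + cohort_csv")
  structure(list(out_dir = out_dir, synth = synth, image_dir = image_dir,
                 cohort_csv = cohort_csv, n_levels = as.integer(n_levels),
                 direction_mode = direction_mode, log_base = log_base,
                 rim_fraction = rim_fraction,
                 resample_isotropic = resample_isotropic, alpha = alpha,
                 knot_dates = as.Date(knot_dates), corstr = corstr,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [run_config()] arguments; a `synth:` block holds
#' [synth_config()] arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) {
    for (fld in c("ga_range_weeks", "voxel_spacing_mm", "effect_table"))
      if (!is.null(y$synth[[fld]]))
        y$synth[[fld]] <- unlist(y$synth[[fld]])
    y$synth <- do.call(synth_config, y$synth)
  }
  do.call(run_config, y)
}

# digest of the scientific configuration (paths excluded, so the digest
# identifies the analysis, not where it ran)
config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg <- cfg[setdiff(names(cfg), c("out_dir", "image_dir", "cohort_csv"))]
  ser <- rapply(cfg, function(x)
    if (inherits(x, "Date")) as.character(x) else x, how = "replace")
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) synthesize or load the dataset; (2) extract the 23 features
#' per scan; (3) validate distress scores and derive the high-distress
#' indicator; (4) fit the cohort-comparison, mediation, birth-weight and
#' time-trend models. Every intermediate is a file under `out_dir`, so
#' stages can be inspected and re-run; no stage mutates its inputs. A
#' manifest (JSON) records the config digest, seed, package version,
#' output checksums and collected warnings — it contains no timestamps, so
#' a rerun of the same config is byte-identical. Timings go to
#' `pipeline.log`.
#'
#' @param config a `run_config`.
#' @return `out_dir`, invisibly; side effects: features.csv,
#'   cohort_with_features.csv, comparison.csv, birthweight.csv,
#'   timetrend_cohort.csv, timetrend_spline.csv, mediation.json,
#'   distress_report.json, manifest.json, pipeline.log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "pipeline.log")
  cat("placentex pipeline\n", file = logf)
  warnings_seen <- character(0)
  note <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = logf, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", stage, "' failed: ",
             conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    note(stage, sprintf("done in %.1f s", proc.time()[["elapsed"]] - t0))
    res
  }

  set.seed(config$seed)
  ds <- run_stage("synthesize", {
    if (!is.null(config$synth)) {
      synthesize_dataset(config$synth, out)
    } else {
      cohort <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
      man <- data.frame(
        scan_id = cohort$scan_id,
        image_path = file.path(config$image_dir,
                               paste0(cohort$scan_id, ".nii.gz")),
        mask_path = file.path(config$image_dir,
                              paste0(cohort$scan_id, "_mask.nii.gz")),
        stringsAsFactors = FALSE)
      list(cohort = cohort, manifest = man)
    }
  })

  feats <- run_stage("extract_features", {
    extract_features_batch(ds$manifest,
                           out_csv = file.path(out, "features.csv"),
                           n_levels = config$n_levels,
                           direction_mode = config$direction_mode,
                           log_base = config$log_base,
                           rim_fraction = config$rim_fraction,
                           resample_isotropic = config$resample_isotropic)
  })

  tab <- run_stage("distress", {
    cohort <- ds$cohort
    measured <- merge(cohort[, setdiff(names(cohort), feature_names())],
                      feats, by = "scan_id", sort = FALSE)
    rep <- validate_scores(measured)
    jsonlite::write_json(rep, file.path(out, "distress_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    measured <- derive_high_distress(measured)
    measured <- measured[order(measured$scan_id), ]
    utils::write.csv(measured,
                     file.path(out, "cohort_with_features.csv"),
                     row.names = FALSE)
    measured
  })

  run_stage("stats", {
    cmp <- cohort_comparison(tab, corstr = config$corstr)
    utils::write.csv(cmp, file.path(out, "comparison.csv"),
                     row.names = FALSE)
    med <- mediation(tab, alpha = config$alpha, corstr = config$corstr)
    write_mediation_json(med, file.path(out, "mediation.json"))
    bw <- birthweight_models(tab, corstr = config$corstr)
    utils::write.csv(bw, file.path(out, "birthweight.csv"),
                     row.names = FALSE)
    tt <- time_trend(tab, knot_dates = config$knot_dates,
                     corstr = config$corstr)
    utils::write.csv(tt$per_cohort, file.path(out, "timetrend_cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(tt$spline, file.path(out, "timetrend_spline.csv"),
                     row.names = FALSE)
    NULL
  })

  outputs <- c("features.csv", "cohort_with_features.csv", "comparison.csv",
               "birthweight.csv", "timetrend_cohort.csv",
               "timetrend_spline.csv", "mediation.json",
               "distress_report.json")
  sums <- vapply(outputs, function(f)
    unname(tools::md5sum(file.path(out, f))), character(1))
  manifest <- list(
    package = "placentex",
    version = as.character(utils::packageVersion("placentex")),
    seed = config$seed,
    config_md5 = config_digest(config),
    n_scans = nrow(ds$cohort),
    outputs = as.list(sums),
    warnings = sort(unique(warnings_seen)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
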