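#' Evaluation configuration
#'
#' Bundles the settings of an end-to-end run. The scenario presets fix the
#' distance threshold: 0.005 m for indoor scenes, 0.01 m for larger, more
#' complex outdoor scenes; `"custom"` requires an explicit `threshold_d`.
#'
#' @param scenario `"indoor"`, `"outdoor"` or `"custom"`.
#' @param threshold_d evaluation distance threshold (meters); `NULL` resolves
#'   from the scenario preset.
#' @param icp an [icp_config()].
#' @param plateau a [plateau_config()].
#' @param seed integer seed echoed into the run manifest.
#' @param output_dir directory receiving the report bundle.
#' @return object of class `eval_config`.
#' @export
eval_config <- function(scenario = c("indoor", "outdoor", "custom"),
                        threshold_d = NULL, icp = NULL, plateau = plateau_config(),
                        seed = 1L, output_dir = ".") {
  scenario <- match.arg(scenario)
  if (is.null(threshold_d))
    threshold_d <- switch(scenario, indoor = 0.005, outdoor = 0.01,
                          custom = abort_input("scenario 'custom' needs an explicit threshold_d"))
  if (!is.finite(threshold_d) || threshold_d <= 0)
    abort_input("threshold_d must be > 0")
  if (is.null(icp))
    icp <- icp_config(voxel_size = 2 * threshold_d, distance_threshold = 4 * threshold_d)
  stopifnot(inherits(icp, "icp_config"), inherits(plateau, "plateau_config"))
  structure(list(scenario = scenario, threshold_d = threshold_d, icp = icp,
                 plateau = plateau, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "eval_config")
}

#' Run the full reconstruction evaluation workflow
#'
#' Mirrors the registration-and-evaluation pipeline: (1) initial similarity
#' alignment from manually picked correspondences (skipped when none are
#' given), (2) ICP refinement, (3) optional crop of both clouds to the
#' evaluation bounding volume, (4) metric evaluation at the configured
#' threshold plus a precision-recall sweep, and (5) dual-direction point
#' labeling — the precision pass labels the reconstruction against the ground
#' truth, the recall pass labels the ground truth against the reconstruction.
#'
#' Writes into `config$output_dir`: `report.json`, `pr_curve.csv`,
#' `labeled_precision.ply`, `labeled_recall.ply`, `transform.json`,
#' `manifest.json` and `run.log`. Any stage failure aborts with the stage
#' name, and partial outputs are removed.
#'
#' @param recon_path,gt_path point-cloud files ([load_cloud()] formats).
#' @param correspondences_path optional correspondence JSON
#'   ([read_correspondences_json()]).
#' @param bounds_path optional bounding-volume JSON ([read_bounds_json()]).
#' @param config an [eval_config()].
#' @return (invisibly) list with `report`, `curve`, `transform`,
#'   `registration`, `labels_precision`, `labels_recall`, `files`.
#' @export
run_evaluation <- function(recon_path, gt_path, correspondences_path = NULL,
                           bounds_path = NULL, config = eval_config()) {
  stopifnot(inherits(config, "eval_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(config$output_dir,
                     c("report.json", "pr_curve.csv", "labeled_precision.ply",
                       "labeled_recall.ply", "transform.json", "manifest.json",
                       "run.log"))
  names(files) <- c("report", "curve", "labeled_precision", "labeled_recall",
                    "transform", "manifest", "log")
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("%s %s", format(Sys.time(), "%H:%M:%S"),
                                       sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(files)
      abort_stage("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  recon <- stage("load", load_cloud(recon_path))
  gt <- stage("load", load_cloud(gt_path))
  note("loaded reconstruction (%d points) and ground truth (%d points)",
       n_points(recon), n_points(gt))

  initial <- similarity_transform()
  if (!is.null(correspondences_path)) {
    corr <- stage("initial-alignment", read_correspondences_json(correspondences_path))
    initial <- stage("initial-alignment",
                     estimate_initial_transform(corr$source, corr$target))
    note("initial alignment from %d correspondences (scale %.6g)",
         nrow(corr$source), initial$scale)
  }

  reg <- stage("icp", icp_refine(recon, gt, initial, config$icp))
  recon_aligned <- apply_transform(recon, reg$transform)
  note("ICP: fitness %.4f, inlier RMSE %.6g m, %d iterations",
       reg$fitness, reg$inlier_rmse, reg$iterations_run)

  if (!is.null(bounds_path)) {
    bounds <- stage("crop", read_bounds_json(bounds_path))
    recon_aligned <- stage("crop", crop_to_bounds(recon_aligned, bounds))
    gt <- stage("crop", crop_to_bounds(gt, bounds))
    note("cropped to bounds: %d reconstruction / %d ground-truth points",
         n_points(recon_aligned), n_points(gt))
  }

  d <- config$threshold_d
  report <- stage("evaluate", evaluate_reconstruction(recon_aligned, gt, d))
  curve <- stage("evaluate", pr_curve(recon_aligned, gt, d / 5, d * 4, 20L))
  note("metrics at d = %g m: P %.2f  R %.2f  F1 %.2f",
       d, report$precision, report$recall, report$f1)

  lab_p <- stage("label", label_points(recon_aligned, gt, d))
  lab_r <- stage("label", label_points(gt, recon_aligned, d))
  note("labels (precision pass): %s", paste(sprintf("%s=%d",
       levels(lab_p$labels), tabulate(lab_p$labels, 3)), collapse = " "))

  stage("write", {
    write_report_json(report, files[["report"]])
    write_pr_curve_csv(curve, files[["curve"]])
    write_cloud(labeled_cloud(recon_aligned, lab_p), files[["labeled_precision"]])
    write_cloud(labeled_cloud(gt, lab_r), files[["labeled_recall"]])
    write_transform_json(reg$transform, files[["transform"]])
    write_manifest(files[["manifest"]], config,
                   inputs = c(recon = recon_path, gt = gt_path,
                              correspondences = correspondences_path,
                              bounds = bounds_path))
    writeLines(log_lines, files[["log"]])
  })

  invisible(list(report = report, curve = curve, transform = reg$transform,
                 registration = reg, labels_precision = lab_p,
                 labels_recall = lab_r, files = files))
}

#' Run the early-stopping monitor workflow
#'
#' Reads a checkpoint metric series (CSV with columns `iteration,value`),
#' interpolates it, detects the plateau, and writes `decision.json` plus a
#' plot-ready `monitor_curve.csv` holding the interpolated series with the
#' recommended iteration marked.
#'
#' @param series_path metric-series CSV path.
#' @param config an [eval_config()] (its `plateau` and `output_dir` are used).
#' @return (invisibly) list with `decision` (the [recommend_stop()] output)
#'   and `files`.
#' @export
run_monitor <- function(series_path, config = eval_config()) {
  stopifnot(inherits(config, "eval_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  series <- read_metric_series(series_path)
  dec <- recommend_stop(series, config$plateau)
  files <- file.path(config$output_dir, c("decision.json", "monitor_curve.csv"))
  names(files) <- c("decision", "curve")
  jsonlite::write_json(
    list(found = dec$result$found,
         plateau_index = if (dec$result$found) dec$result$plateau_index else NULL,
         recommended_iteration = dec$iteration,
         config = list(theta = config$plateau$theta,
                       consistency = config$plateau$consistency,
                       granularity = config$plateau$granularity,
                       total_iterations = config$plateau$total_iterations)),
    files[["decision"]], auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(
    data.frame(iteration = dec$interpolated$iterations,
               value = dec$interpolated$values,
               recommended = dec$interpolated$iterations == dec$iteration),
    files[["curve"]], row.names = FALSE)
  invisible(list(decision = dec, files = files))
}

write_manifest <- function(path, config, inputs) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  hashes <- vapply(unlist(inputs), function(p)
    unname(tools::md5sum(p)), character(1))
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("plantrecon")),
         r_version = as.character(getRversion()),
         seed = config$seed,
         scenario = config$scenario,
         threshold_d = config$threshold_d,
         icp = unclass(config$icp),
         plateau = unclass(config$plateau),
         inputs = as.list(hashes)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
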