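#' Pipeline configuration
#'
#' Nested configuration for the end-to-end registration pipeline, loadable
#' from YAML. Unknown keys are rejected.
#'
#' @param preprocessing list: `tile_rows`, `tile_cols`, `clip_limit`.
#' @param calibration list: `window_half`, `snap_radius`.
#' @param registration list: `keypoint_radius`, `n_aux`, `ratio`,
#'   `reproj_thresh`, `max_iter`, `confidence`.
#' @param segmentation list: `threshold`.
#' @param evaluation list: `step`, `max_threshold`, `statistic`.
#' @param seed global RNG seed.
#' @param verbose logical.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocessing = list(), calibration = list(),
                            registration = list(), segmentation = list(),
                            evaluation = list(), seed = 1L, verbose = FALSE) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown ", where, " config key(s): ", paste(bad, collapse = ", "))
    x
  }
  preprocessing <- check_keys(preprocessing,
                              c("tile_rows", "tile_cols", "clip_limit"),
                              "preprocessing")
  calibration <- check_keys(calibration, c("window_half", "snap_radius"),
                            "calibration")
  registration <- check_keys(registration,
                             c("keypoint_radius", "n_aux", "ratio",
                               "reproj_thresh", "max_iter", "confidence"),
                             "registration")
  segmentation <- check_keys(segmentation, c("threshold"), "segmentation")
  evaluation <- check_keys(evaluation, c("step", "max_threshold", "statistic"),
                           "evaluation")
  structure(list(preprocessing = preprocessing, calibration = calibration,
                 registration = registration, segmentation = segmentation,
                 evaluation = evaluation, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the sections of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

config_to_register <- function(cfg) {
  pp <- cfg$preprocessing; cb <- cfg$calibration; rg <- cfg$registration
  args <- list(clahe = do.call(clahe_params, pp),
               calibration = do.call(calibration_params, cb),
               seed = cfg$seed)
  if (!is.null(cfg$segmentation$threshold))
    args$segment_threshold <- cfg$segmentation$threshold
  do.call(register_config, c(args, rg))
}

#' Run the full registration pipeline on an image pair
#'
#' Reads both images (and optional masks), registers the sensed image onto
#' the reference, and writes `H.txt` (3 x 3 row-major), `warped.png`,
#' `matches.csv` and a `log.json` of per-stage counts to the output
#' directory. When a ground-truth correspondence file is supplied, a
#' `metrics.json` with the control-point error is written as well.
#'
#' @param config a [pipeline_config()].
#' @param ref_path,sensed_path image files.
#' @param out_dir output directory (created).
#' @param ref_mask_path,sensed_mask_path optional binary mask PNGs.
#' @param gt_path optional 4-column correspondence file.
#' @return integer exit status: 0 ok, 2 insufficient matches or degenerate,
#'   1 I/O error (with no partial outputs).
#' @export
run_pipeline <- function(config, ref_path, sensed_path, out_dir,
                         ref_mask_path = NULL, sensed_mask_path = NULL,
                         gt_path = NULL) {
  ok <- tryCatch({
    ref <- read_image(ref_path)
    sensed <- read_image(sensed_path)
    ref_mask <- if (!is.null(ref_mask_path)) read_mask(ref_mask_path)
    sensed_mask <- if (!is.null(sensed_mask_path)) read_mask(sensed_mask_path)
    gt <- if (!is.null(gt_path)) read_correspondences(gt_path)
    TRUE
  }, error = function(e) {
    message("input error: ", conditionMessage(e))
    FALSE
  })
  if (!ok) return(1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- register_pair(ref, sensed, ref_mask = ref_mask,
                       sensed_mask = sensed_mask,
                       config = config_to_register(config))
  jsonlite::write_json(c(list(status = res$status), res$counts),
                       file.path(out_dir, "log.json"), auto_unbox = TRUE)
  if (res$status != "ok") {
    if (config$verbose) message("registration failed: ", res$status)
    return(2L)
  }
  write_homography(res$homography, file.path(out_dir, "H.txt"))
  write_image(res$warped, file.path(out_dir, "warped.png"))
  write.csv(as.data.frame(res$matches), file.path(out_dir, "matches.csv"),
            row.names = FALSE)
  if (!is.null(gt_path)) {
    err <- registration_error(res$homography, gt)
    jsonlite::write_json(list(control_point_error = err,
                              n_correspondences = nrow(gt$ref)),
                         file.path(out_dir, "metrics.json"), auto_unbox = TRUE)
  }
  0L
}
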