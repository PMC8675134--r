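#' Run configuration for the calibration pipeline
#'
#' @param radius descriptor sphere radius, bohr (> 0); default 0.06.
#' @param n_radial radial quadrature points (>= 2); default 30.
#' @param n_angular Lebedev angular points; default 110.
#' @param descriptor_name descriptor column for fixture-only runs.
#' @param seed integer seed for any synthetic generation.
#' @param log_level `"quiet"` or `"info"`.
#' @return A validated list of class `moss_config`.
#' @export
run_config <- function(radius = 0.06, n_radial = 30, n_angular = 110,
                       descriptor_name = "rho_sphere_006", seed = 1L,
                       log_level = c("info", "quiet")) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    stop("config validation error: radius must be a single positive number")
  }
  if (n_radial < 2) stop("config validation error: n_radial must be >= 2")
  structure(list(radius = radius, n_radial = n_radial, n_angular = n_angular,
                 descriptor_name = descriptor_name, seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "moss_config")
}

#' End-to-end isomer-shift calibration pipeline
#'
#' Wires the modules together: computes the sphere-integrated density
#' descriptor for any supplied wavefunctions, joins descriptors with
#' experimental shifts, fits the calibration line, cross-validates it, and
#' predicts shifts for query descriptors. With no wavefunctions and no
#' external shifts, the packaged dataset is used and the result reproduces
#' the published calibration.
#'
#' @param config a [run_config()].
#' @param wavefunctions optional named list of [wavefunction()] objects; the
#'   descriptor is integrated around the first atom of each.
#' @param delta_exp optional named numeric vector of experimental shifts
#'   (mm/s) keyed like `wavefunctions`; required when wavefunctions are
#'   given. Unmatched names on either side are an error.
#' @param predict_x optional numeric vector of descriptor values to predict
#'   shifts for with the fitted line.
#' @return List of class `moss_report`: `fit`, `loocv`, `descriptors`
#'   (data.frame key/x/delta), `predictions`, `config`.
#' @export
run_pipeline <- function(config = run_config(), wavefunctions = NULL,
                         delta_exp = NULL, predict_x = NULL) {
  stopifnot(inherits(config, "moss_config"))
  set.seed(config$seed)
  info <- function(...) {
    if (config$log_level == "info") message(...)
  }
  if (is.null(wavefunctions)) {
    ds <- load_calibration_dataset()
    info("using packaged calibration dataset (", nrow(ds), " rows)")
    x <- ds[[config$descriptor_name]]
    y <- ds$delta_exp
    key <- paste0(ds$complex_id, ".", ds$site_index)
  } else {
    if (is.null(delta_exp)) {
      stop("experimental shifts are required to calibrate wavefunctions")
    }
    miss_wf <- setdiff(names(wavefunctions), names(delta_exp))
    miss_d <- setdiff(names(delta_exp), names(wavefunctions))
    if (length(miss_wf) || length(miss_d)) {
      stop("descriptor/shift join mismatch; unmatched: ",
           paste(c(miss_wf, miss_d), collapse = ", "))
    }
    key <- names(wavefunctions)
    x <- vapply(wavefunctions, function(wf) {
      ctr <- as.numeric(wf$atoms[1, c("x", "y", "z")])
      g <- sphere_grid(ctr, config$radius, config$n_radial, config$n_angular)
      integrate_sphere(wf, g)$value
    }, numeric(1))
    y <- as.numeric(delta_exp[key])
    info("integrated descriptor for ", length(key), " wavefunction(s)")
  }
  fit <- fit_calibration(x, y, descriptor_name = config$descriptor_name)
  cv <- loocv_calibration(x, y)
  preds <- if (!is.null(predict_x)) {
    data.frame(x = predict_x, delta_pred = stats::predict(fit, predict_x))
  }
  structure(list(fit = fit, loocv = cv,
                 descriptors = data.frame(key = key, x = x, delta_exp = y),
                 predictions = preds, config = config),
            class = "moss_report")
}

#' @export
print.moss_report <- function(x, ...) {
  print(x$fit)
  print(x$loocv)
  if (!is.null(x$predictions)) {
    cat("predictions:\n")
    print(x$predictions, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Floating-point formatting is pinned (all significant digits) so that
#' identical configurations yield bit-identical files.
#'
#' @param report a `moss_report`.
#' @param file output path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, file = NULL) {
  stopifnot(inherits(report, "moss_report"))
  obj <- list(
    fit = report$fit[c("slope", "intercept", "r_squared", "rmsd", "n",
                       "center", "descriptor_name")],
    loocv = list(q_squared = report$loocv$q_squared, mae = report$loocv$mae),
    predictions = report$predictions,
    config = unclass(report$config))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
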