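#' Load the packaged 57Fe isomer-shift calibration dataset
#'
#' Returns the curated experimental/computed dataset of iron complexes used
#' to calibrate the isomer shift against the sphere-integrated density
#' descriptor: 69 base complexes, one row per Fe site and spin assignment,
#' with the 4.2 K experimental isomer shift, the contact density rho(0), the
#' descriptor value at R = 0.06 bohr, the published predicted shift, and the
#' crystal-structure code. Four complexes carry an additional alternate-spin
#' recomputation (flagged `is_alternate_spin`); the default signal set
#' excludes them, leaving 103 signals.
#'
#' Values are stored exactly as tabulated: shifts to 2 decimals (mm/s),
#' rho(0) to 3 and the sphere descriptor to 6 decimals (atomic units).
#'
#' @param file path to the fixture CSV; defaults to the packaged copy.
#' @return Object of class `moss_dataset` (a data.frame) with attributes
#'   `descriptor_name` (`"rho_sphere_006"`) and `provenance`.
#' @export
load_calibration_dataset <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "fe57_isomer_shift_signals.csv",
                        package = "mosscalib")
  }
  if (!nzchar(file) || !file.exists(file)) {
    stop("calibration fixture not found: dataset file is missing or corrupt")
  }
  d <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = c(complex_id = "character",
                                      formal_os = "character",
                                      structure_code = "character"))
  required <- c("complex_id", "site_index", "ligand_formula", "s_total",
                "formal_os", "delta_exp", "rho0", "rho_sphere_006",
                "delta_calc_paper", "structure_code", "is_alternate_spin")
  if (!all(required %in% names(d))) {
    stop("calibration fixture is corrupt: missing columns ",
         paste(setdiff(required, names(d)), collapse = ", "))
  }
  validate_dataset(d)
  structure(d, class = c("moss_dataset", "data.frame"),
            descriptor_name = "rho_sphere_006",
            provenance = "packaged 57Fe calibration tables, B3LYP/def2-TZVP")
}

validate_dataset <- function(d) {
  alt_ids <- c("1a", "27a", "28a", "29a")
  if (!setequal(unique(d$complex_id[d$is_alternate_spin]), alt_ids)) {
    stop("calibration fixture is corrupt: alternate-spin flags do not match ",
         "complexes 1a/27a/28a/29a")
  }
  main <- d[!d$is_alternate_spin, ]
  if (nrow(main) != 103L) {
    stop("dataset integrity error: expected 103 default signals, found ",
         nrow(main))
  }
  if (length(unique(main$complex_id)) != 69L) {
    stop("dataset integrity error: expected 69 base complexes, found ",
         length(unique(main$complex_id)))
  }
  if (min(main$delta_exp) != -0.90 || max(main$delta_exp) != 1.48) {
    stop("dataset integrity error: experimental shift range is not ",
         "[-0.90, +1.48] mm/s")
  }
  if (any(main$rho0 < 11579 | main$rho0 > 11588) ||
      any(main$rho_sphere_006 < 1.3467 | main$rho_sphere_006 > 1.3477)) {
    stop("dataset integrity error: density descriptor out of expected range")
  }
  invisible(d)
}

#' Default 103-signal calibration set
#'
#' Removes the alternate-spin rows (complexes 1a, 27a, 28a, 29a), leaving
#' exactly the 103 distinct experimental signals over 69 complexes. The
#' operation is idempotent and preserves row order.
#'
#' @param ds a `moss_dataset` from [load_calibration_dataset()].
#' @return A `moss_dataset` with 103 rows.
#' @export
default_signals <- function(ds) {
  stopifnot(inherits(ds, "moss_dataset"))
  if (nrow(ds) == 0L) stop("dataset integrity error: empty dataset")
  out <- ds[!ds$is_alternate_spin, , drop = FALSE]
  if (nrow(out) != 103L) {
    stop("dataset integrity error: filtered set has ", nrow(out),
         " records, expected 103")
  }
  rownames(out) <- NULL
  attr(out, "descriptor_name") <- attr(ds, "descriptor_name")
  attr(out, "provenance") <- attr(ds, "provenance")
  class(out) <- class(ds)
  out
}

#' Summarize a calibration dataset
#'
#' @param object a `moss_dataset`.
#' @param ... unused.
#' @return Invisibly, a list of summary statistics (also printed).
#' @export
summary.moss_dataset <- function(object, ...) {
  main <- object[!object$is_alternate_spin, ]
  s <- list(n_records = nrow(object),
            n_default = nrow(main),
            n_complexes = length(unique(main$complex_id)),
            n_alternate = sum(object$is_alternate_spin),
            delta_range = range(main$delta_exp),
            rho0_range = range(main$rho0),
            descriptor_range = range(main$rho_sphere_006),
            os_levels = sort(unique(object$formal_os)))
  cat("57Fe isomer-shift calibration dataset\n")
  cat("  records:", s$n_records, "(default signals:", s$n_default,
      "over", s$n_complexes, "complexes;", s$n_alternate,
      "alternate-spin rows)\n")
  cat("  delta_exp range: [", s$delta_range[1], ",", s$delta_range[2], "] mm/s\n")
  cat("  rho(0) range: [", s$rho0_range[1], ",", s$rho0_range[2], "] a.u.\n")
  cat("  <rho>_0.06 range: [", sprintf("%.6f", s$descriptor_range[1]), ",",
      sprintf("%.6f", s$descriptor_range[2]), "] a.u.\n")
  cat("  oxidation states:", paste(s$os_levels, collapse = ", "), "\n")
  invisible(s)
}
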