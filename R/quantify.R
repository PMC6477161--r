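#' Two-point phantom calibration curve
#'
#' Linear calibration from the corrected signal means of the two in-FoV agar
#' tubes to concentration. With exactly two tubes the line is fully
#' determined: `slope = (c80 - c20) / (s80 - s20)` and the curve passes
#' through both points exactly. Supplying more than two tubes fits an
#' ordinary least-squares line through all of them.
#'
#' @param tube_means Numeric vector of tube ROI signal means (increasing
#'   concentration order).
#' @param concs Known tube concentrations in mM (default `c(20, 80)`).
#' @return A list of class `"CalibrationCurve"` with `slope` (mM per signal
#'   unit), `intercept` (mM), `source_signals`, `source_concs`.
#' @export
#' @examples
#' fitCalibration(c(100, 400))  # slope 0.2, intercept 0
fitCalibration <- function(tube_means, concs = c(20, 80)) {
  stopifnot(length(tube_means) == length(concs), length(concs) >= 2)
  if (any(!is.finite(tube_means)) || any(tube_means <= 0))
    stop("fitCalibration: tube signals must be finite and positive")
  if (length(concs) == 2L) {
    if (tube_means[2] <= tube_means[1])
      stop("fitCalibration: inverted or degenerate calibration (s80 <= s20)")
    slope <- diff(concs) / diff(tube_means)
    intercept <- concs[1] - slope * tube_means[1]
  } else {
    fit <- stats::lm(concs ~ tube_means)
    slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
    if (slope <= 0) stop("fitCalibration: non-positive calibration slope")
  }
  structure(list(slope = slope, intercept = intercept,
                 source_signals = tube_means, source_concs = concs),
            class = "CalibrationCurve")
}

#' @export
print.CalibrationCurve <- function(x, ...) {
  cat(sprintf("CalibrationCurve: conc = %.4g * S + %.4g mM (tubes %s mM)\n",
              x$slope, x$intercept, paste(x$source_concs, collapse = "/")))
  invisible(x)
}

#' Apply a calibration curve to a corrected image
#'
#' Voxelwise affine map `slope * S + intercept`; negative concentrations are
#' floored at 0 (and counted), `NA` voxels (B1-invalid) propagate.
#'
#' @param image Corrected 3D signal array.
#' @param curve A `"CalibrationCurve"` from [fitCalibration()].
#' @param kind `"TSC"` or `"IWS"`.
#' @param provenance Character vector of upstream processing steps.
#' @return A [ConcentrationMap-class].
#' @export
applyCalibration <- function(image, curve, kind = c("TSC", "IWS"),
                             provenance = character()) {
  kind <- match.arg(kind)
  conc <- curve$slope * image + curve$intercept
  n_floored <- sum(conc < 0, na.rm = TRUE)
  conc[conc < 0] <- 0
  new("ConcentrationMap", data = conc, kind = kind,
      provenance = c(provenance, "calibrate"), n_floored = as.integer(n_floored))
}

#' Combine multiple tumour deposits into one ROI
#'
#' Patients with multiple peritoneal deposits are analysed as a single
#' tumour volume: the union of the per-deposit masks.
#'
#' @param deposits A list of logical arrays on a common grid.
#' @return Logical array, the union mask.
#' @export
combineDeposits <- function(deposits) {
  if (length(deposits) == 0L) stop("combineDeposits: at least one deposit required")
  out <- deposits[[1]]
  for (d in deposits[-1]) {
    stopifnot(identical(dim(d), dim(out)))
    out <- out | d
  }
  out
}

#' Missing-aware ROI summary statistics
#'
#' Mean, standard deviation, observed voxel count and missing (B1-excluded)
#' voxel count of a concentration map over each named ROI. A fully missing
#' ROI is flagged (`all_missing = TRUE`) rather than silently zeroed.
#'
#' @param map A [ConcentrationMap-class] or a plain 3D array.
#' @param rois Named list of logical arrays on the map grid.
#' @return A data frame with one row per ROI: `roi`, `mean`, `sd`,
#'   `n_voxels`, `n_missing`, `all_missing`.
#' @export
roiSummary <- function(map, rois) {
  dat <- if (is(map, "ConcentrationMap")) map@data else map
  stopifnot(is.list(rois), length(rois) > 0, !is.null(names(rois)))
  do.call(rbind, lapply(names(rois), function(nm) {
    m <- rois[[nm]]
    stopifnot(identical(dim(m), dim(dat)))
    if (!any(m)) stop(sprintf("roiSummary: empty ROI '%s'", nm))
    v <- dat[m]
    miss <- sum(is.na(v))
    obs <- v[!is.na(v)]
    data.frame(roi = nm,
               mean = if (length(obs)) mean(obs) else NA_real_,
               sd = if (length(obs) > 1) stats::sd(obs) else NA_real_,
               n_voxels = length(obs), n_missing = miss,
               all_missing = length(obs) == 0L)
  }))
}

#' Assemble the cohort table
#'
#' Joins per-subject ROI summaries with cellularity into the table feeding
#' the cohort statistics, with a stable column order.
#'
#' @param subject_results A data frame with columns `subject_id`,
#'   `tsc_tumour`, `tsc_muscle`, `iws_tumour`, `iws_muscle` (mM, ROI means).
#' @param cellularity A data frame with `subject_id` and `cellularity`.
#' @return A data frame with one row per subject, columns `subject_id`,
#'   `tsc_tumour`, `tsc_muscle`, `iws_tumour`, `iws_muscle`, `cellularity`.
#' @export
buildCohortTable <- function(subject_results, cellularity) {
  need <- c("subject_id", "tsc_tumour", "tsc_muscle", "iws_tumour", "iws_muscle")
  stopifnot(all(need %in% names(subject_results)),
            all(c("subject_id", "cellularity") %in% names(cellularity)))
  bad <- setdiff(union(subject_results$subject_id, cellularity$subject_id),
                 intersect(subject_results$subject_id, cellularity$subject_id))
  if (length(bad))
    stop("buildCohortTable: subject id mismatch: ", paste(bad, collapse = ", "))
  out <- merge(subject_results[need], cellularity[c("subject_id", "cellularity")],
               by = "subject_id", sort = TRUE)
  if (anyNA(out)) stop("buildCohortTable: missing headline fields")
  out[c(need, "cellularity")]
}
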