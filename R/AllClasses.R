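#' @import methods
NULL

#' Surface-coil field model
#'
#' Smooth monotone model of the relative transmit/receive field of a
#' single-channel surface coil. The relative field is 1 at the coil surface
#' point and decays with Euclidean distance `d` from it as
#' `floor ^ ((d / penetration_depth) ^ falloff_exponent)`, reaching the
#' configured floor (default 0.1) at the penetration depth (default 120 mm,
#' matching per-patient power adjustment for up to 12 cm penetration).
#' Transmit and receive are assumed reciprocal: receive sensitivity is
#' proportional to the transmit field.
#'
#' @slot surface_position numeric(3), coil surface point in mm.
#' @slot penetration_depth depth in mm at which the field equals `floor`.
#' @slot falloff_exponent shape parameter of the decay (> 0).
#' @slot floor relative field at `penetration_depth`, in (0, 1).
#' @export
setClass("CoilFieldModel", representation(
  surface_position = "numeric",
  penetration_depth = "numeric",
  falloff_exponent = "numeric",
  floor = "numeric"
), validity = function(object) {
  msg <- character()
  if (length(object@surface_position) != 3L)
    msg <- c(msg, "surface_position must have length 3")
  if (object@penetration_depth <= 0) msg <- c(msg, "penetration_depth must be > 0")
  if (object@falloff_exponent <= 0) msg <- c(msg, "falloff_exponent must be > 0")
  if (object@floor <= 0 || object@floor >= 1) msg <- c(msg, "floor must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Digital subject
#'
#' One synthetic patient: a labelled 3D volume (0 background, 1 tumour,
#' 2 muscle, 3 tube20, 4 tube80) with isotropic voxel size, voxelwise
#' ground-truth TSC and IWS concentration maps, the intracellular volume
#' fraction map, the relative coil field sampled at every voxel, and the
#' subject's true cellularity.
#'
#' @slot labels integer 3D array of compartment labels.
#' @slot tsc_true,iws_true,f_ic_map,coil_field numeric 3D arrays on the same
#'   grid (mM, mM, dimensionless, dimensionless).
#' @slot voxel_mm isotropic voxel size in mm.
#' @slot cellularity_true cells per 1000 square micrometres.
#' @slot f_ic named numeric, the subject's compartment-mean intracellular
#'   fractions actually drawn (tumour, muscle).
#' @slot seed integer seed the subject was generated from.
#' @export
setClass("DigitalSubject", representation(
  labels = "array",
  tsc_true = "array",
  iws_true = "array",
  f_ic_map = "array",
  coil_field = "array",
  voxel_mm = "numeric",
  cellularity_true = "numeric",
  f_ic = "numeric",
  seed = "integer"
), validity = function(object) {
  msg <- character()
  d <- dim(object@labels)
  for (s in c("tsc_true", "iws_true", "f_ic_map", "coil_field"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, sprintf("%s grid does not match labels", s))
  if (any(object@tsc_true[object@labels == 3L] != 20))
    msg <- c(msg, "tube20 ground truth must be exactly 20 mM")
  if (any(object@tsc_true[object@labels == 4L] != 80))
    msg <- c(msg, "tube80 ground truth must be exactly 80 mM")
  if (any(object@tsc_true < object@iws_true - 1e-9))
    msg <- c(msg, "tsc_true must be >= iws_true voxelwise")
  if (any(object@tsc_true[object@labels != 0L] <= 0))
    msg <- c(msg, "non-background voxels must have positive tsc_true")
  if (object@cellularity_true <= 0) msg <- c(msg, "cellularity must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DigitalSubject", function(object) {
  d <- dim(object@labels)
  cat(sprintf("DigitalSubject %dx%dx%d @ %.1f mm (seed %d)\n",
              d[1], d[2], d[3], object@voxel_mm, object@seed))
  cat(sprintf("  tumour f_ic %.3f (true TSC %.1f mM), muscle f_ic %.3f (true TSC %.1f mM)\n",
              object@f_ic[["tumour"]],
              mean(object@tsc_true[object@labels == 1L]),
              object@f_ic[["muscle"]],
              mean(object@tsc_true[object@labels == 2L])))
  cat(sprintf("  cellularity %.2f cells / 1000 um^2\n", object@cellularity_true))
})

#' 3D-cones k-space trajectory
#'
#' Sample coordinates of a simplified 3D-cones readout: each excitation
#' spirals outward on the surface of a cone from the k-space centre to
#' `kmax`, with cone half-angles tiling the sphere area-uniformly.
#'
#' @slot k numeric matrix (n_samples x 3), k-space coordinates in cycles/mm.
#' @slot readout integer vector, readout id per sample.
#' @slot dcf numeric vector, density-compensation weight per sample.
#' @slot kmax maximum sampled spatial frequency (cycles/mm).
#' @slot fov field of view in mm.
#' @export
setClass("ConesTrajectory", representation(
  k = "matrix",
  readout = "integer",
  dcf = "numeric",
  kmax = "numeric",
  fov = "numeric"
), validity = function(object) {
  msg <- character()
  n <- nrow(object@k)
  if (ncol(object@k) != 3L) msg <- c(msg, "k must have 3 columns")
  if (length(object@readout) != n) msg <- c(msg, "readout length mismatch")
  if (length(object@dcf) != n) msg <- c(msg, "dcf length mismatch")
  if (any(object@dcf <= 0)) msg <- c(msg, "dcf must be positive")
  if (any(sqrt(rowSums(object@k^2)) > object@kmax + 1e-9))
    msg <- c(msg, "samples must satisfy |k| <= kmax")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConesTrajectory", function(object) {
  cat(sprintf("ConesTrajectory: %d readouts, %d samples, kmax %.5f cycles/mm (FoV %g mm)\n",
              length(unique(object@readout)), nrow(object@k), object@kmax, object@fov))
})

#' B1 (true flip angle) map
#'
#' Voxelwise achieved flip angle from dual-flip-angle mapping, expressed at
#' the low nominal angle, together with the dimensionless scale
#' `alpha_true / alpha_nom` and a validity mask. Invalid voxels (excluded
#' flip-angle range or sub-threshold signal) are excluded from all
#' downstream analysis.
#'
#' @slot alpha_true numeric 3D array, achieved flip at the low nominal flip
#'   (degrees).
#' @slot scale numeric 3D array, `alpha_true / alpha_nom`.
#' @slot valid logical 3D array.
#' @slot nominal_low low nominal flip angle in degrees (default 30).
#' @export
setClass("B1Map", representation(
  alpha_true = "array",
  scale = "array",
  valid = "array",
  nominal_low = "numeric"
), validity = function(object) {
  msg <- character()
  if (!identical(dim(object@alpha_true), dim(object@scale)) ||
      !identical(dim(object@alpha_true), dim(object@valid)))
    msg <- c(msg, "alpha_true, scale and valid must share a grid")
  a <- object@alpha_true[object@valid]
  if (length(a) && (min(a) < 0 || max(a) > 180))
    msg <- c(msg, "valid alpha_true must lie in [0, 180] degrees")
  if (length(msg)) msg else TRUE
})

setMethod("show", "B1Map", function(object) {
  cat(sprintf("B1Map (%s): %.1f%% voxels valid, median scale %.3f\n",
              paste(dim(object@scale), collapse = "x"),
              100 * mean(object@valid),
              stats::median(object@scale[object@valid])))
})

#' Calibrated sodium concentration map
#'
#' A 3D map in mM (TSC or IWS) with missing-value support and a record of
#' the corrections applied upstream.
#'
#' @slot data numeric 3D array in mM; `NA` where excluded.
#' @slot kind `"TSC"` or `"IWS"`.
#' @slot provenance character vector of applied processing steps.
#' @slot n_floored number of negative voxels floored to zero at calibration.
#' @export
setClass("ConcentrationMap", representation(
  data = "array",
  kind = "character",
  provenance = "character",
  n_floored = "integer"
), validity = function(object) {
  if (!object@kind %in% c("TSC", "IWS")) "kind must be TSC or IWS" else TRUE
})

setMethod("show", "ConcentrationMap", function(object) {
  cat(sprintf("ConcentrationMap [%s] %s: range %.1f-%.1f mM, %d NA, steps: %s\n",
              object@kind, paste(dim(object@data), collapse = "x"),
              min(object@data, na.rm = TRUE), max(object@data, na.rm = TRUE),
              sum(is.na(object@data)), paste(object@provenance, collapse = " -> ")))
})

#' @describeIn ConcentrationMap-class numeric array of concentrations (mM).
#' @param object A `ConcentrationMap`.
#' @export
concValues <- function(object) object@data
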