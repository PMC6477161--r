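#' Signal-to-noise ratio of a magnitude image
#'
#' SNR as the mean signal over a region of interest divided by the standard
#' deviation of the background signal. By convention SNR is measured on the
#' raw magnitude image, before noise-bias correction; the pipeline enforces
#' that order.
#'
#' @param image 3D numeric array.
#' @param signal_roi Logical array (same grid), the signal ROI.
#' @param background Logical array (same grid), outside-subject background.
#' @return Scalar SNR.
#' @export
snr <- function(image, signal_roi, background) {
  stopifnot(identical(dim(image), dim(signal_roi)),
            identical(dim(image), dim(background)))
  if (!any(signal_roi) || !any(background)) stop("snr: empty ROI")
  s <- stats::sd(image[background])
  if (s == 0) stop("snr: zero background standard deviation")
  mean(image[signal_roi]) / s
}

#' Per-slice squared noise floor
#'
#' Mean squared background pixel value for each axial slice, the quantity
#' subtracted (in the squared domain) by the squared-subtraction noise-bias
#' correction. For Rayleigh-distributed background with parameter `sigma`
#' the floor converges to `2 * sigma^2`.
#'
#' @param image 3D numeric array (nx x ny x nslices).
#' @param background Logical array flagging outside-subject voxels.
#' @return Numeric vector of per-slice floors (length `dim(image)[3]`).
#' @export
noiseFloor <- function(image, background) {
  stopifnot(identical(dim(image), dim(background)))
  nz <- dim(image)[3]
  vapply(seq_len(nz), function(z) {
    b <- background[, , z]
    if (!any(b)) stop(sprintf("noiseFloor: no background voxels on slice %d", z))
    mean(image[, , z][b]^2)
  }, numeric(1))
}

#' Squared-subtraction noise-bias correction
#'
#' Magnitude images carry a Rician noise floor that biases low-SNR regions
#' upward. The correction squares the image, subtracts the per-slice mean
#' squared background value, and takes the square root:
#' `sqrt(max(S^2 - floor, 0))`. Negative radicands are clamped to zero; the
#' number of clamped voxels is recorded in the `"n_clamped"` attribute.
#'
#' @param image 3D numeric array.
#' @param floor Per-slice squared floor from [noiseFloor()], or a scalar.
#' @return Corrected array with attribute `n_clamped`.
#' @export
correctNoiseBias <- function(image, floor) {
  if (any(floor < 0)) stop("correctNoiseBias: floor must be >= 0")
  nz <- dim(image)[3]
  if (length(floor) == 1L) floor <- rep(floor, nz)
  stopifnot(length(floor) == nz)
  fl <- aperm(array(floor, dim = c(nz, dim(image)[1], dim(image)[2])), c(2, 3, 1))
  r <- image^2 - fl
  n_clamped <- sum(r < 0)
  out <- sqrt(pmax(r, 0))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Dual-flip-angle B1 map
#'
#' Estimates the achieved flip angle from two spoiled gradient-echo images
#' at nominal flips `alpha` and `2 * alpha` (here 30 and 60 degrees). In the
#' `TR >> T1` regime the signal is proportional to `sin(flip)`, so
#' `s_high / s_low = 2 * cos(alpha_true)` and
#' `alpha_true = acos(clamp(s_high / (2 * s_low), -1, 1))` at the low
#' nominal angle. Voxels whose low-flip signal falls below
#' `low_signal_threshold` are marked invalid (the arccos of a noisy ratio
#' near +/-1 is unstable).
#'
#' @param s_low 3D magnitude image at the low nominal flip.
#' @param s_high 3D magnitude image at twice that flip, same grid.
#' @param nominal_low Low nominal flip angle in degrees (default 30).
#' @param low_signal_threshold Absolute signal threshold for validity
#'   (default 0: all voxels valid).
#' @param ratio_smooth_sd_vox Optional regularisation: Gaussian sd (voxels)
#'   of a normalized smoothing of the signal-ratio map over valid voxels
#'   before the arccos. The underlying coil field varies over centimetres,
#'   so this suppresses the strong noise amplification of the arccos at low
#'   flip angles without biasing the field; 0 disables it.
#' @param noise_sd Effective per-voxel noise sd of the magnitude images
#'   (e.g. the background sd). When positive, the first-order convexity bias
#'   of the signal ratio, `E[s_high/s_low] ~ (S_high/S_low) (1 + CV_low^2)`,
#'   is removed before the arccos.
#' @return A [B1Map-class] with `alpha_true` (degrees at the low flip),
#'   `scale = alpha_true / nominal_low`, and the validity mask.
#' @export
#' @examples
#' # homogeneous field: s60 / s30 = 2 * cos(30 deg)
#' lo <- array(sin(pi / 6), c(2, 2, 2)); hi <- array(sin(pi / 3), c(2, 2, 2))
#' estimateB1(lo, hi)@scale[1]  # 1
estimateB1 <- function(s_low, s_high, nominal_low = 30,
                       low_signal_threshold = 0, ratio_smooth_sd_vox = 0,
                       noise_sd = 0) {
  if (!identical(dim(s_low), dim(s_high)))
    stop("estimateB1: images must share a grid")
  ratio <- s_high / (2 * s_low)
  if (noise_sd > 0) {
    cv2 <- (noise_sd / pmax(s_low, noise_sd))^2
    ratio <- ratio / (1 + cv2)
  }
  ratio[!is.finite(ratio)] <- 1
  ratio <- pmin(pmax(ratio, -1), 1)
  valid <- s_low > low_signal_threshold
  if (ratio_smooth_sd_vox > 0) {
    w <- array(as.numeric(valid), dim(valid))
    num <- gaussianBlur3D(ratio * w, ratio_smooth_sd_vox)
    den <- gaussianBlur3D(w, ratio_smooth_sd_vox)
    ok <- valid & den > 1e-6
    ratio[ok] <- pmin(pmax(num[ok] / den[ok], -1), 1)
  }
  alpha <- acos(ratio) * 180 / pi
  new("B1Map", alpha_true = alpha, scale = alpha / nominal_low,
      valid = valid, nominal_low = nominal_low)
}

#' Mask unreliable flip-angle regions
#'
#' Dual-angle mapping is inaccurate at very low and very high effective flip
#' angles; voxels whose effective flip at the imaging excitation
#' (`scale * imaging_flip`) falls below `lo` (default 10 degrees) or above
#' `hi` (default 140 degrees) are marked invalid and excluded from all
#' subsequent analysis.
#'
#' @param b1 A [B1Map-class].
#' @param lo,hi Exclusion thresholds in degrees at the imaging flip.
#' @param imaging_flip Nominal imaging flip in degrees (default 90).
#' @return The masked [B1Map-class].
#' @export
maskB1 <- function(b1, lo = 10, hi = 140, imaging_flip = 90) {
  if (lo >= hi) stop("maskB1: lo must be < hi")
  eff <- b1@scale * imaging_flip
  b1@valid <- b1@valid & eff >= lo & eff <= hi
  b1
}

#' Smooth the flip-angle scale map
#'
#' Optional Gaussian smoothing of the B1 scale map (the underlying coil
#' field varies on the scale of centimetres, far above the voxel size, so
#' smoothing suppresses voxel noise without biasing the field). Smoothing is
#' restricted to valid voxels (normalised convolution).
#'
#' @param b1 A [B1Map-class].
#' @param sd_vox Gaussian sd in voxels; 0 returns the map unchanged.
#' @return The smoothed [B1Map-class].
#' @export
smoothB1 <- function(b1, sd_vox = 2) {
  if (sd_vox <= 0) return(b1)
  w <- array(as.numeric(b1@valid), dim(b1@valid))
  num <- gaussianBlur3D(b1@scale * w, sd_vox)
  den <- gaussianBlur3D(w, sd_vox)
  sm <- b1@scale
  ok <- b1@valid & den > 1e-6
  sm[ok] <- num[ok] / den[ok]
  b1@scale <- sm
  b1@alpha_true <- sm * b1@nominal_low
  b1
}

#' Transmit/receive inhomogeneity correction
#'
#' With a transmit/receive surface coil both excitation and reception scale
#' with the local relative field; for `TR >> T1` the combined dependence of
#' the gradient-echo signal reduces to
#' `S proportional to [Na] * alpha_true * sin(alpha_true)`, so the corrected
#' signal is `S / (alpha_true * sin(alpha_true))` with `alpha_true` in
#' radians at the imaging flip. Invalid voxels become `NA`.
#'
#' @param image 3D magnitude image.
#' @param b1 A (masked) [B1Map-class] on the same grid.
#' @param nominal_flip Nominal imaging flip in degrees (default 90).
#' @return Corrected array with `NA` at invalid voxels.
#' @export
correctInhomogeneity <- function(image, b1, nominal_flip = 90) {
  stopifnot(identical(dim(image), dim(b1@scale)))
  a <- b1@scale * nominal_flip * pi / 180
  if (any(b1@valid & a == 0))
    stop("correctInhomogeneity: zero effective flip on a valid voxel")
  out <- image / (a * sin(a))
  out[!b1@valid] <- NA_real_
  out
}
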