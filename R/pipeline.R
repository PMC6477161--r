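## Forward signal model, scan simulation and the full processing chain.

# Signed (real) steady-state signal image of a subject under a protocol.
# Transmit and receive both scale with the relative coil field (reciprocity):
# noiseless signal = B1rel * sum_pools conc_pool * seq_weight(B1rel * alpha).
.signalImage <- function(subject, proto, config = defaultConfig(),
                         uniform_b1 = FALSE) {
  lab <- subject@labels
  r <- if (uniform_b1) array(1, dim(lab)) else subject@coil_field
  alpha <- r * proto$nominal_flip * pi / 180
  sig <- array(0, dim(lab))
  cmp <- config$compartments
  acq <- config$acquisition
  pool <- function(m, conc, t1) {
    if (!any(m)) return()
    s <- if (proto$name == "IWS") {
      irSignal(conc, ti = proto$ti, t1 = t1, tr = proto$tr, alpha = alpha[m],
               efficiency = acq$inversion_efficiency,
               exact_steady_state = acq$exact_ir_steady_state)
    } else {
      geSignal(conc, alpha[m], tr = proto$tr, t1 = t1)
    }
    sig[m] <<- sig[m] + s
  }
  for (nm in c("tumour", "muscle")) {
    ci <- if (nm == "tumour") 1L else 2L
    m <- lab == ci
    f <- subject@f_ic_map[m]
    sp <- cmp[[nm]]
    pool(m, f * sp$na_ic, sp$t1_bound)
    pool(m, (1 - f) * sp$na_ec, sp$t1_fluid)
  }
  for (tb in c(tube20 = 3L, tube80 = 4L)) {
    tg <- cmp[[names(which(c(tube20 = 3L, tube80 = 4L) == tb))]]
    pool(lab == tb, tg$conc * tg$f_bound, tg$t1_bound)
    pool(lab == tb, tg$conc * (1 - tg$f_bound), tg$t1_fluid)
  }
  sig * r
}

#' Simulate one sodium acquisition
#'
#' Generates the magnitude image of a [DigitalSubject-class] under one of
#' the four protocols. In `"fast"` mode the acquisition is simulated in the
#' image domain: the signed steady-state signal per voxel plus complex
#' Gaussian noise (coherently averaged over NEX), followed by the magnitude
#' -- yielding exactly the Rician statistics the correction chain expects.
#' In `"full"` mode the signal image is sampled along a 3D-cones trajectory,
#' k-space noise is added and the volume is reconstructed by gridding.
#'
#' @param subject A [DigitalSubject-class].
#' @param proto A [protocol()] object or protocol name.
#' @param noise_sd Per-excitation complex-channel noise sd (image-domain
#'   units in fast mode, k-space units in full mode); 0 = noiseless.
#' @param seed Integer noise seed.
#' @param mode `"fast"` (image-domain) or `"full"` (cones + gridding).
#' @param config Configuration list.
#' @param recon_matrix Full mode only: cubic reconstruction matrix size
#'   (default 120, the protocol value).
#' @param uniform_b1 Replace the coil field by 1 everywhere (homogeneity
#'   checks).
#' @param traj Full mode only: a precomputed [ConesTrajectory-class].
#' @return 3D magnitude array (subject grid in fast mode, recon grid in
#'   full mode).
#' @export
simulateScan <- function(subject, proto, noise_sd = NULL, seed = 1L,
                         mode = c("fast", "full"), config = defaultConfig(),
                         recon_matrix = NULL, uniform_b1 = FALSE,
                         traj = NULL) {
  mode <- match.arg(mode)
  if (is.character(proto)) proto <- protocol(proto)
  if (!inherits(proto, "Protocol")) stop("simulateScan: unknown protocol")
  if (is.null(noise_sd)) noise_sd <- config$acquisition$noise_sd
  nex <- proto$nex
  sig <- .signalImage(subject, proto, config, uniform_b1)
  if (mode == "fast") {
    if (noise_sd == 0) return(abs(sig))
    set.seed(as.integer(seed))
    n <- length(sig)
    eff <- noise_sd / sqrt(nex)
    re <- sig + stats::rnorm(n, 0, eff)
    im <- stats::rnorm(n, 0, eff)
    return(array(sqrt(re^2 + im^2), dim(sig)))
  }
  fov <- dim(sig)[1] * subject@voxel_mm
  if (is.null(recon_matrix)) recon_matrix <- proto$recon_matrix
  if (is.null(traj)) traj <- designCones(fov, fov / recon_matrix)
  kd <- sampleKspace(sig, traj)
  kd <- addNoise(kd, noise_sd, seed = seed, nex = nex)
  gridReconstruct(kd, traj, recon_matrix)
}

# fixed outside-subject background ROI: a corner box spanning all slices
.backgroundMask <- function(labels) {
  d <- dim(labels)
  m <- array(FALSE, d)
  m[(d[1] - 14):d[1], (d[2] - 14):d[2], ] <- TRUE
  if (any(labels[m] != 0L))
    stop("background ROI overlaps the subject; adjust geometry")
  m
}

# nearest-neighbour resampling of a label/mask array onto an n^3 grid
# covering the same field of view
.resampleNN <- function(vol, n_out) {
  n_in <- dim(vol)[1]
  # voxel centres: (i - (n+1)/2) scaled; map output centre to input index
  idx <- round((seq_len(n_out) - (n_out + 1) / 2) * n_in / n_out + (n_in + 1) / 2)
  idx <- pmin(pmax(idx, 1L), n_in)
  vol[idx, idx, idx]
}

#' Run the correction and calibration chain on acquired volumes
#'
#' The post-processing chain applied to the four magnitude volumes of one
#' subject: SNR measurement (before any correction), per-slice
#' squared-subtraction noise-bias correction, dual-flip-angle B1 mapping
#' (from the noise-corrected 30/60 images) with flip-range masking and
#' optional smoothing, transmit/receive inhomogeneity correction of the TSC
#' and IWS images, two-point tube calibration of each, and missing-aware ROI
#' summaries.
#'
#' @param vols Named list of magnitude arrays on one grid: `tsc`, `b1low`,
#'   `b1high`, `iws`.
#' @param labels Integer label array on the same grid (0 background,
#'   1 tumour, 2 muscle, 3 tube20, 4 tube80).
#' @param config Configuration list.
#' @param noiseless If `TRUE`, skip noise-dependent steps (zero floors, no
#'   low-signal threshold); used for calibration readback checks.
#' @return A list: `summary` (one-row data frame with tumour/muscle TSC and
#'   IWS ROI means), `roi_tables` (full [roiSummary()] tables), `tsc_map`,
#'   `iws_map` ([ConcentrationMap-class]), `b1` ([B1Map-class]),
#'   `snr` (named: tsc, iws), `floors`, `curves`.
#' @export
processVolumes <- function(vols, labels, config = defaultConfig(),
                           noiseless = FALSE) {
  stopifnot(all(c("tsc", "b1low", "b1high", "iws") %in% names(vols)))
  pr <- config$processing
  bg <- .backgroundMask(labels)
  rois <- list(tumour = labels == 1L, muscle = labels == 2L,
               tube20 = labels == 3L, tube80 = labels == 4L)

  # SNR by convention on the raw images, before noise correction
  snr_tsc <- if (noiseless) NA_real_ else snr(vols$tsc, rois$tumour, bg)
  snr_iws <- if (noiseless) NA_real_ else snr(vols$iws, rois$tumour, bg)

  if (noiseless) {
    den <- vols
    floors <- lapply(vols, function(v) rep(0, dim(v)[3]))
    thr <- 0
    sigma_bg <- 0
  } else {
    floors <- lapply(vols, noiseFloor, background = bg)
    den <- mapply(correctNoiseBias, vols, floors, SIMPLIFY = FALSE)
    sigma_bg <- stats::sd(vols$b1low[bg])
    thr <- pr$low_signal_k * sigma_bg
  }

  b1 <- estimateB1(den$b1low, den$b1high, nominal_low = 30,
                   low_signal_threshold = thr,
                   ratio_smooth_sd_vox = pr$b1_ratio_smooth_sd_vox,
                   noise_sd = if (pr$b1_ratio_debias) sigma_bg else 0)
  b1 <- maskB1(b1, pr$b1_mask_lo, pr$b1_mask_hi, imaging_flip = 90)
  b1 <- smoothB1(b1, pr$b1_smooth_sd_vox)

  tsc_c <- correctInhomogeneity(den$tsc, b1, 90)
  iws_c <- correctInhomogeneity(den$iws, b1, 90)

  tubeMean <- function(img, m) mean(img[m], na.rm = TRUE)
  curve_tsc <- fitCalibration(c(tubeMean(tsc_c, rois$tube20),
                                tubeMean(tsc_c, rois$tube80)))
  curve_iws <- fitCalibration(c(tubeMean(iws_c, rois$tube20),
                                tubeMean(iws_c, rois$tube80)))
  prov <- c("noise_bias", "b1_inhomogeneity")
  tsc_map <- applyCalibration(tsc_c, curve_tsc, "TSC", prov)
  iws_map <- applyCalibration(iws_c, curve_iws, "IWS", prov)

  st <- roiSummary(tsc_map, rois)
  si <- roiSummary(iws_map, rois)
  summary <- data.frame(
    tsc_tumour = st$mean[st$roi == "tumour"],
    tsc_muscle = st$mean[st$roi == "muscle"],
    iws_tumour = si$mean[si$roi == "tumour"],
    iws_muscle = si$mean[si$roi == "muscle"]
  )
  list(summary = summary, roi_tables = list(tsc = st, iws = si),
       tsc_map = tsc_map, iws_map = iws_map, b1 = b1,
       snr = c(tsc = snr_tsc, iws = snr_iws), floors = floors,
       curves = list(tsc = curve_tsc, iws = curve_iws))
}

#' Simulate and process one subject end to end
#'
#' Convenience wrapper: four acquisitions via [simulateScan()] followed by
#' [processVolumes()]. In full mode the label map is resampled to the
#' reconstruction grid by nearest neighbour.
#'
#' @inheritParams simulateScan
#' @param recon_matrix Full mode reconstruction matrix (default 32 for
#'   desk-scale runs).
#' @return As [processVolumes()].
#' @export
processSubject <- function(subject, config = defaultConfig(), seed = 1L,
                           mode = c("fast", "full"), noise_sd = NULL,
                           uniform_b1 = FALSE, recon_matrix = 32L) {
  mode <- match.arg(mode)
  if (is.null(noise_sd)) noise_sd <- config$acquisition$noise_sd
  protos <- list(tsc = "TSC", b1low = "B1_LOW", b1high = "B1_HIGH", iws = "IWS")
  if (mode == "full") {
    fov <- dim(subject@labels)[1] * subject@voxel_mm
    traj <- designCones(fov, fov / recon_matrix)
    labels <- .resampleNN(subject@labels, recon_matrix)
  } else {
    traj <- NULL
    labels <- subject@labels
  }
  vols <- lapply(seq_along(protos), function(i) {
    simulateScan(subject, protos[[i]], noise_sd = noise_sd,
                 seed = seed + i, mode = mode, config = config,
                 recon_matrix = recon_matrix, uniform_b1 = uniform_b1,
                 traj = traj)
  })
  names(vols) <- names(protos)
  processVolumes(vols, labels, config, noiseless = (noise_sd == 0))
}
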