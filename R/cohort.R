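## Cohort-level pipeline: an optimized fast-mode engine (identical chain to
## processVolumes, restricted to a bounding box around the compartments plus
## the background ROI) and the cohort statistics stage.

#' Precompute the cohort processing plan
#'
#' The phantom geometry, coil field and protocol weighting factors are
#' identical across subjects; only the subject-level intracellular fractions
#' and the noise differ. This precomputes everything subject-independent:
#' the label volume, a processing bounding box around the compartments (with
#' margin for B1 smoothing), the background ROI, and per-voxel per-pool
#' signal weights for each protocol.
#'
#' @param config Configuration list.
#' @return An opaque plan object for [runCohortPipeline()].
#' @export
cohortPlan <- function(config = defaultConfig()) {
  lab <- buildLabels(config$geometry, config$coil)
  d <- dim(lab)
  coil <- coilFieldModel(config$coil$surface_position,
                         config$coil$penetration_depth,
                         config$coil$falloff_exponent, config$coil$floor)
  co <- .coordArrays(config$geometry$n, config$geometry$voxel_mm)
  field <- array(coilSensitivity(coil, cbind(as.vector(co$x), as.vector(co$y),
                                             as.vector(co$z))), d)
  pad <- ceiling(3 * max(config$processing$b1_smooth_sd_vox,
                         config$processing$b1_ratio_smooth_sd_vox, 1)) + 2L
  fg <- which(lab != 0L, arr.ind = TRUE)
  box <- lapply(1:3, function(a)
    max(1L, min(fg[, a]) - pad):min(d[a], max(fg[, a]) + pad))
  crop <- function(v) v[box[[1]], box[[2]], box[[3]]]
  labc <- crop(lab)
  rc <- crop(field)
  bg <- .backgroundMask(lab)
  if (any(bg[box[[1]], box[[2]], box[[3]]]))
    bg[box[[1]], box[[2]], box[[3]]] <- bg[box[[1]], box[[2]], box[[3]]] & FALSE
  nbg_slice <- apply(bg, 3, sum)

  protos <- list(tsc = protocol("TSC"), b1low = protocol("B1_LOW"),
                 b1high = protocol("B1_HIGH"), iws = protocol("IWS"))
  cmp <- config$compartments
  acq <- config$acquisition
  weights <- lapply(protos, function(p) {
    a <- rc * p$nominal_flip * pi / 180
    wOf <- function(t1) {
      if (p$name == "IWS")
        irSignal(1, ti = p$ti, t1 = t1, tr = p$tr, alpha = a,
                 efficiency = acq$inversion_efficiency,
                 exact_steady_state = acq$exact_ir_steady_state)
      else geSignal(1, a, tr = p$tr, t1 = t1)
    }
    tubeW <- function(tb)
      tb$f_bound * wOf(tb$t1_bound) + (1 - tb$f_bound) * wOf(tb$t1_fluid)
    list(tumour_b = wOf(cmp$tumour$t1_bound), tumour_f = wOf(cmp$tumour$t1_fluid),
         muscle_b = wOf(cmp$muscle$t1_bound), muscle_f = wOf(cmp$muscle$t1_fluid),
         tube20 = tubeW(cmp$tube20), tube80 = tubeW(cmp$tube80))
  })
  list(config = config, labels = lab, labc = labc, rc = rc, box = box,
       dims = d, bg = bg, nbg_slice = nbg_slice, weights = weights,
       masks = list(tumour = labc == 1L, muscle = labc == 2L,
                    tube20 = labc == 3L, tube80 = labc == 4L),
       zs = box[[3]])
}

# signed signal on the cropped grid for one subject and protocol
.cropSignal <- function(plan, which_proto, f_t, f_m) {
  w <- plan$weights[[which_proto]]
  cmp <- plan$config$compartments
  m <- plan$masks
  sig <- array(0, dim(plan$labc))
  sig[m$tumour] <- f_t * cmp$tumour$na_ic * w$tumour_b[m$tumour] +
    (1 - f_t) * cmp$tumour$na_ec * w$tumour_f[m$tumour]
  sig[m$muscle] <- f_m * cmp$muscle$na_ic * w$muscle_b[m$muscle] +
    (1 - f_m) * cmp$muscle$na_ec * w$muscle_f[m$muscle]
  sig[m$tube20] <- cmp$tube20$conc * w$tube20[m$tube20]
  sig[m$tube80] <- cmp$tube80$conc * w$tube80[m$tube80]
  sig * plan$rc
}

# process one subject on the plan; returns the summary row
.processSubjectPlan <- function(plan, subject_seed) {
  cfg <- plan$config
  pr <- cfg$processing
  sc <- .drawSubjectScalars(cfg, subject_seed)
  sd0 <- cfg$acquisition$noise_sd
  eff <- sd0 / sqrt(cfg$acquisition$nex)
  nc <- prod(dim(plan$labc))
  nbg <- sum(plan$nbg_slice)
  noisy <- function(sig) {
    if (sd0 == 0) return(abs(sig))
    array(sqrt((sig + stats::rnorm(nc, 0, eff))^2 + stats::rnorm(nc, 0, eff)^2),
          dim(sig))
  }
  bgMag <- function() {
    if (sd0 == 0) return(rep(0, nbg))
    sqrt(stats::rnorm(nbg, 0, eff)^2 + stats::rnorm(nbg, 0, eff)^2)
  }
  # same draw order per image: crop noise then background noise
  imgs <- list(); bgs <- list()
  for (nm in c("tsc", "b1low", "b1high", "iws")) {
    imgs[[nm]] <- noisy(.cropSignal(plan, nm, sc$f_tumour, sc$f_muscle))
    bgs[[nm]] <- bgMag()
  }
  slice_of <- rep(seq_along(plan$nbg_slice), plan$nbg_slice)

  snr_tsc <- if (sd0 == 0) NA_real_ else
    mean(imgs$tsc[plan$masks$tumour]) / stats::sd(bgs$tsc)
  snr_iws <- if (sd0 == 0) NA_real_ else
    mean(imgs$iws[plan$masks$tumour]) / stats::sd(bgs$iws)

  den <- list()
  for (nm in names(imgs)) {
    if (sd0 == 0) { den[[nm]] <- imgs[[nm]]; next }
    fl <- vapply(split(bgs[[nm]]^2, slice_of), mean, numeric(1))   # per-slice floor
    flc <- fl[plan$zs]                                             # crop z window
    den[[nm]] <- correctNoiseBias(imgs[[nm]], flc)
  }
  sigma_bg <- if (sd0 == 0) 0 else stats::sd(bgs$b1low)
  thr <- pr$low_signal_k * sigma_bg

  b1 <- estimateB1(den$b1low, den$b1high, nominal_low = 30,
                   low_signal_threshold = thr,
                   ratio_smooth_sd_vox = pr$b1_ratio_smooth_sd_vox,
                   noise_sd = if (pr$b1_ratio_debias) sigma_bg else 0)
  b1 <- maskB1(b1, pr$b1_mask_lo, pr$b1_mask_hi, imaging_flip = 90)
  b1 <- smoothB1(b1, pr$b1_smooth_sd_vox)

  tsc_c <- correctInhomogeneity(den$tsc, b1, 90)
  iws_c <- correctInhomogeneity(den$iws, b1, 90)
  mn <- function(img, m) mean(img[m], na.rm = TRUE)
  curve_t <- fitCalibration(c(mn(tsc_c, plan$masks$tube20),
                              mn(tsc_c, plan$masks$tube80)))
  curve_i <- fitCalibration(c(mn(iws_c, plan$masks$tube20),
                              mn(iws_c, plan$masks$tube80)))
  cal <- function(x, cv) pmax(cv$slope * x + cv$intercept, 0)
  cmp <- cfg$compartments
  wts_t <- iwsWeights(cmp$tumour, cmp$tube20)
  wts_m <- iwsWeights(cmp$muscle, cmp$tube20)
  data.frame(
    f_ic_tumour = sc$f_tumour, f_ic_muscle = sc$f_muscle,
    cellularity = sc$cellularity,
    tsc_tumour_true = tscFromFractions(sc$f_tumour, cmp$tumour$na_ic, cmp$tumour$na_ec),
    tsc_muscle_true = tscFromFractions(sc$f_muscle, cmp$muscle$na_ic, cmp$muscle$na_ec),
    iws_tumour_true = iwsFromFractions(sc$f_tumour, min(max(wts_t[["fluid"]], 0), 0.999),
                                       cmp$tumour$na_ic, cmp$tumour$na_ec,
                                       max(wts_t[["bound"]], 0)),
    iws_muscle_true = iwsFromFractions(sc$f_muscle, min(max(wts_m[["fluid"]], 0), 0.999),
                                       cmp$muscle$na_ic, cmp$muscle$na_ec,
                                       max(wts_m[["bound"]], 0)),
    tsc_tumour = cal(mn(tsc_c, plan$masks$tumour), curve_t),
    tsc_muscle = cal(mn(tsc_c, plan$masks$muscle), curve_t),
    iws_tumour = cal(mn(iws_c, plan$masks$tumour), curve_i),
    iws_muscle = cal(mn(iws_c, plan$masks$muscle), curve_i),
    snr_tsc = snr_tsc, snr_iws = snr_iws
  )
}

#' Run the cohort pipeline
#'
#' Generates a seeded synthetic cohort, runs the full acquisition +
#' correction + calibration chain per subject (fast, image-domain mode by
#' default), assembles the cohort table and computes the cohort statistics:
#' normality-gated paired tumour-vs-muscle comparisons for TSC and IWS, the
#' exact Wilcoxon signed-rank p-values, and Spearman correlations of
#' estimated TSC/IWS against cellularity.
#'
#' @param n Cohort size (default 12).
#' @param seed Integer master seed.
#' @param config Configuration list.
#' @param plan Optional precomputed [cohortPlan()] (reused across cohorts).
#' @param out_dir Optional directory: writes `cohort_table.csv` and
#'   `report.json`.
#' @return A list: `table` (per-subject estimates + truth + cellularity),
#'   `comparisons` (TSC and IWS tumour-vs-muscle), `correlations` (TSC and
#'   IWS vs cellularity), `snr` (cohort mean SNRs), `seed`.
#' @export
#' @examples
#' \donttest{
#' rep <- runCohortPipeline(n = 12, seed = 1)
#' rep$correlations$tsc$spearman_rho
#' }
runCohortPipeline <- function(n = 12L, seed = 1L, config = defaultConfig(),
                              plan = NULL, out_dir = NULL) {
  if (n < 2) stop("runCohortPipeline: cohort size must be at least 2")
  if (is.null(plan)) plan <- cohortPlan(config)
  set.seed(as.integer(seed))
  subseeds <- sample.int(2^30, n)
  rows <- lapply(subseeds, function(s) .processSubjectPlan(plan, s))
  tab <- cbind(subject_id = seq_len(n), do.call(rbind, rows))

  gate_t <- normalityGate(tab$tsc_tumour - tab$tsc_muscle)
  gate_i <- normalityGate(tab$iws_tumour - tab$iws_muscle)
  comparisons <- list(
    tsc = list(wilcoxon = wilcoxonSignedRank(tab$tsc_tumour, tab$tsc_muscle),
               t = pairedTTest(tab$tsc_tumour, tab$tsc_muscle),
               gate = gate_t),
    iws = list(wilcoxon = wilcoxonSignedRank(tab$iws_tumour, tab$iws_muscle),
               t = pairedTTest(tab$iws_tumour, tab$iws_muscle),
               gate = gate_i)
  )
  correlations <- list(
    tsc = spearmanCorrelation(tab$tsc_tumour, tab$cellularity),
    iws = spearmanCorrelation(tab$iws_tumour, tab$cellularity)
  )
  rep <- list(table = tab, comparisons = comparisons,
              correlations = correlations,
              snr = c(tsc = mean(tab$snr_tsc), iws = mean(tab$snr_iws)),
              seed = as.integer(seed))
  if (!is.null(out_dir)) writeCohortReport(rep, out_dir)
  rep
}

#' Write a cohort report
#'
#' `cohort_table.csv` (per-subject estimates and truth) and `report.json`
#' (cohort means, test results, correlations, seed).
#'
#' @param report As returned by [runCohortPipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
writeCohortReport <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(out_dir, "cohort_table.csv"),
                   row.names = FALSE)
  tab <- report$table
  js <- list(
    seed = report$seed,
    n = nrow(tab),
    means = list(tsc_tumour = mean(tab$tsc_tumour),
                 tsc_muscle = mean(tab$tsc_muscle),
                 iws_tumour = mean(tab$iws_tumour),
                 iws_muscle = mean(tab$iws_muscle)),
    snr = as.list(report$snr),
    comparisons = lapply(report$comparisons, function(cm) list(
      test_chosen = cm$gate$test, normality_p = cm$gate$normality_p,
      wilcoxon_p = cm$wilcoxon$p_two_sided, t_p = cm$t$p_two_sided)),
    correlations = lapply(report$correlations, function(cr) list(
      spearman_rho = cr$spearman_rho, p_two_sided = cr$p_two_sided))
  )
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
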