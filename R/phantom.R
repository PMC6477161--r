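#' Two-compartment tissue sodium concentration
#'
#' Tissue sodium concentration as the volume-weighted average of the
#' intracellular and extracellular sodium concentrations:
#' `TSC = f_ic * na_ic + (1 - f_ic) * na_ec`. Because `na_ic < na_ec`,
#' higher cellularity (larger intracellular fraction) lowers TSC.
#'
#' @param f_ic Intracellular volume fraction in `[0, 1]`. Vectorised.
#' @param na_ic Intracellular sodium concentration (mM, default 12).
#' @param na_ec Extracellular sodium concentration (mM, default 145).
#' @return TSC in mM.
#' @export
#' @examples
#' tscFromFractions(0.663158)  # ~56.8 mM, a cellular tumour
tscFromFractions <- function(f_ic, na_ic = 12, na_ec = 145) {
  if (any(f_ic < 0 | f_ic > 1)) stop("tscFromFractions: f_ic must be in [0, 1]")
  if (any(na_ic <= 0) || any(na_ec <= 0)) stop("concentrations must be positive")
  f_ic * na_ic + (1 - f_ic) * na_ec
}

#' Intracellular-weighted sodium ground truth
#'
#' IWS is intracellular-weighted, not purely intracellular: inversion
#' recovery nulls the extracellular/fluid pool only incompletely, so a
#' leakage fraction of the extracellular term survives, and the bound
#' (intracellular-weighted) pool itself carries a calibration weight
#' relative to the agar tubes:
#' `IWS = bound_weight * f_ic * na_ic + leakage * (1 - f_ic) * na_ec`,
#' capped voxelwise at the TSC of the same voxel (a suppressed signal cannot
#' exceed the total). With `bound_weight = 1` this is the pure incomplete-
#' nulling leakage model.
#'
#' @param f_ic Intracellular volume fraction.
#' @param leakage Fraction of the extracellular term surviving inversion
#'   recovery, in `[0, 1)`.
#' @param bound_weight Calibration weight of the intracellular term
#'   (default 1).
#' @inheritParams tscFromFractions
#' @return IWS in mM.
#' @seealso [iwsWeights()] for the weights implied by the relaxation times
#'   and the inversion-recovery protocol.
#' @export
iwsFromFractions <- function(f_ic, leakage, na_ic = 12, na_ec = 145,
                             bound_weight = 1) {
  if (any(f_ic < 0 | f_ic > 1)) stop("iwsFromFractions: f_ic must be in [0, 1]")
  if (any(leakage < 0 | leakage >= 1)) stop("leakage must be in [0, 1)")
  pmin(bound_weight * f_ic * na_ic + leakage * (1 - f_ic) * na_ec,
       tscFromFractions(f_ic, na_ic, na_ec))
}

#' IWS pool weights implied by the inversion-recovery protocol
#'
#' The calibrated IWS map divides the tissue inversion-recovery signal by
#' the agar-tube signal, so each tissue pool enters the map with weight
#' equal to the ratio of its IR weighting to the tube's. This returns those
#' two ratios for one compartment: `fluid` is the extracellular leakage
#' fraction, `bound` the intracellular-term weight.
#'
#' @param compartment A compartment spec (list with `t1_fluid`, `t1_bound`).
#' @param tube Tube spec (list with `f_bound`, `t1_bound`, `t1_fluid`).
#' @param proto The IWS protocol, see [protocol()].
#' @param efficiency Inversion efficiency.
#' @return Named numeric: `bound`, `fluid`.
#' @export
iwsWeights <- function(compartment, tube = defaultConfig()$compartments$tube20,
                       proto = protocol("IWS"), efficiency = 1) {
  a <- pi / 180 * proto$nominal_flip
  w <- function(t1) irSignal(1, ti = proto$ti, t1 = t1, tr = proto$tr,
                             alpha = a, efficiency = efficiency)
  wt <- tube$f_bound * w(tube$t1_bound) + (1 - tube$f_bound) * w(tube$t1_fluid)
  c(bound = w(compartment$t1_bound) / wt,
    fluid = w(compartment$t1_fluid) / wt)
}

#' Cellularity linked to intracellular volume fraction
#'
#' Higher cellularity means a greater intracellular volume fraction, hence a
#' lower TSC; only the monotone direction is physiologically fixed, so the
#' link is modelled linearly with Gaussian jitter:
#' `max(rho_per_unit_f * f_ic + N(0, jitter_sd), floor)`.
#'
#' @param f_ic Intracellular volume fraction in `[0, 1]`.
#' @param rho_per_unit_f Cells per 1000 um^2 at `f_ic = 1` (default 10).
#' @param jitter_sd Gaussian jitter sd in cells per 1000 um^2; the committed
#'   default (see [defaultConfig()]) is Monte-Carlo calibrated so 12-subject
#'   cohorts reproduce the emulated TSC-cellularity Spearman correlation.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param floor Small positive floor (cells per 1000 um^2).
#' @return Cellularity in cells per 1000 um^2.
#' @export
#' @examples
#' linkCellularity(0.5, 10, jitter_sd = 0)  # exactly 5
linkCellularity <- function(f_ic, rho_per_unit_f = 10, jitter_sd = 0.45,
                            seed = NULL, floor = 0.05) {
  if (any(f_ic < 0 | f_ic > 1)) stop("linkCellularity: f_ic must be in [0, 1]")
  if (jitter_sd < 0) stop("linkCellularity: jitter_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  pmax(rho_per_unit_f * f_ic + stats::rnorm(length(f_ic), 0, jitter_sd), floor)
}

#' Construct a coil field model
#'
#' @param surface_position Coil surface point in mm.
#' @param penetration_depth Depth (mm) at which the field reaches `floor`.
#' @param falloff_exponent Shape of the decay.
#' @param floor Relative field at the penetration depth.
#' @return A [CoilFieldModel-class] object.
#' @export
coilFieldModel <- function(surface_position = c(0, -179.2, 0),
                           penetration_depth = 120,
                           falloff_exponent = 2, floor = 0.1) {
  new("CoilFieldModel", surface_position = as.numeric(surface_position),
      penetration_depth = penetration_depth,
      falloff_exponent = falloff_exponent, floor = floor)
}

#' Relative coil field at a position
#'
#' Relative transmit/receive field of the surface coil:
#' `floor ^ ((d / penetration_depth) ^ falloff_exponent)` where `d` is the
#' Euclidean distance from the coil surface point. Equal to 1 at the coil
#' surface, strictly decreasing in depth, positive everywhere.
#'
#' @param model A [CoilFieldModel-class].
#' @param position Numeric vector of length 3 (mm) or an `n x 3` matrix.
#' @return Relative field in `(0, 1]`.
#' @export
#' @examples
#' coilSensitivity(coilFieldModel(), c(0, -179.2, 0))  # 1 at the surface
coilSensitivity <- function(model, position) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3)
  d <- sqrt(colSums((t(position) - model@surface_position)^2))
  model@floor ^ ((d / model@penetration_depth) ^ model@falloff_exponent)
}

## ---- geometry helpers ------------------------------------------------------

#' Voxel-centre world coordinates of the phantom grid
#'
#' 0-based voxel indices; world coordinates in mm with the volume centre at
#' the origin, so index `i` maps to `(i - (n - 1) / 2) * voxel_mm`.
#' @keywords internal
gridCoords <- function(n, voxel_mm) {
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * voxel_mm
  list(x = ax, y = ax, z = ax)
}

# world coordinate arrays (n^3 each) for vectorised mask construction
.coordArrays <- function(n, voxel_mm) {
  g <- gridCoords(n, voxel_mm)
  list(
    x = array(rep(g$x, times = n * n), dim = c(n, n, n)),
    y = array(rep(rep(g$y, each = n), times = n), dim = c(n, n, n)),
    z = array(rep(g$z, each = n * n), dim = c(n, n, n))
  )
}

#' Compartment label volume from the geometry configuration
#'
#' Labels: 0 background, 1 tumour (sphere), 2 muscle (ellipsoid), 3/4 the
#' 20/80 mM calibration tubes (cylinders along z). All compartments must lie
#' inside the field of view and the tumour centroid must be shallower
#' (closer to the coil) than the muscle centroid.
#' @keywords internal
buildLabels <- function(geometry, coil) {
  n <- geometry$n; v <- geometry$voxel_mm
  co <- .coordArrays(n, v)
  lab <- array(0L, dim = c(n, n, n))
  half <- n * v / 2
  inFov <- function(centre, extent) {  # extent per axis
    if (any(abs(centre) + extent > half))
      stop("phantom geometry places a compartment outside the field of view")
  }
  tum <- geometry$tumour
  inFov(tum$centre, rep(tum$radius, 3))
  r2 <- (co$x - tum$centre[1])^2 + (co$y - tum$centre[2])^2 + (co$z - tum$centre[3])^2
  lab[r2 <= tum$radius^2] <- 1L
  mus <- geometry$muscle
  inFov(mus$centre, max(mus$semiaxes))
  q <- ((co$x - mus$centre[1]) / mus$semiaxes[1])^2 +
       ((co$y - mus$centre[2]) / mus$semiaxes[2])^2 +
       ((co$z - mus$centre[3]) / mus$semiaxes[3])^2
  lab[q <= 1 & lab == 0L] <- 2L
  for (tb in c("tube20", "tube80")) {
    # tubes lie with their long axis along y (against the anterior surface)
    tg <- geometry[[tb]]
    inFov(tg$centre, c(tg$radius, tg$height / 2, tg$radius))
    inCyl <- ((co$x - tg$centre[1])^2 + (co$z - tg$centre[3])^2 <= tg$radius^2) &
      (abs(co$y - tg$centre[2]) <= tg$height / 2)
    if (any(inCyl & lab != 0L))
      stop("phantom geometry: calibration tube overlaps a tissue compartment")
    lab[inCyl] <- if (tb == "tube20") 3L else 4L
  }
  dTum <- sqrt(sum((tum$centre - coil$surface_position)^2))
  dMus <- sqrt(sum((mus$centre - coil$surface_position)^2))
  if (dTum >= dMus)
    stop("tumour must be superficial: shallower than the muscle centroid")
  if (max(dTum, dMus) > coil$penetration_depth)
    stop("tissue compartments must lie within the coil penetration depth")
  lab
}

# subject-level random scalars: intracellular fractions (correlated via a
# shared latent factor, Gaussian, clipped to [0.02, 0.98]) and cellularity.
# Called under set.seed(subject seed); consumed draws are identical between
# makeSubject and the fast cohort engine.
.drawSubjectScalars <- function(config, seed) {
  set.seed(as.integer(seed))
  cmp <- config$compartments
  rho <- config$cohort$pair_correlation
  z <- stats::rnorm(1)
  e <- stats::rnorm(2)
  clip <- function(x) pmin(pmax(x, 0.02), 0.98)
  f_t <- clip(cmp$tumour$f_ic_mean +
                cmp$tumour$f_ic_sd * (rho * z + sqrt(1 - rho^2) * e[1]))
  f_m <- clip(cmp$muscle$f_ic_mean +
                cmp$muscle$f_ic_sd * (rho * z + sqrt(1 - rho^2) * e[2]))
  cell <- linkCellularity(f_t, config$cellularity$rho_per_unit_f,
                          config$cellularity$jitter_sd, seed = NULL,
                          floor = config$cellularity$floor)
  list(f_tumour = f_t, f_muscle = f_m, cellularity = cell)
}

#' Generate one digital subject
#'
#' Draws subject-level intracellular volume fractions for tumour and muscle
#' (Gaussian, clipped to `[0.02, 0.98]`, with a shared latent factor giving
#' the configured tumour-muscle correlation), builds the label volume, fills
#' voxelwise ground-truth TSC and IWS maps from the two-compartment model,
#' samples the coil field at every voxel and links cellularity to the tumour
#' intracellular fraction. Calibration tubes are noiseless ground truth at
#' exactly 20 and 80 mM.
#'
#' @param config Configuration list, see [defaultConfig()].
#' @param seed Integer seed; the subject is fully reproducible from it.
#' @return A [DigitalSubject-class].
#' @export
#' @examples
#' s <- makeSubject(seed = 1)
#' sort(unique(as.vector(s@labels)))  # 0..4
makeSubject <- function(config = defaultConfig(), seed = 1L) {
  seed <- as.integer(seed)
  sc <- .drawSubjectScalars(config, seed)
  f_t <- sc$f_tumour; f_m <- sc$f_muscle; cell <- sc$cellularity
  cmp <- config$compartments

  lab <- buildLabels(config$geometry, config$coil)
  n <- config$geometry$n; v <- config$geometry$voxel_mm
  tsc <- array(0, dim(lab)); iws <- array(0, dim(lab)); fic <- array(0, dim(lab))
  for (ci in c(tumour = 1L, muscle = 2L)) {
    nm <- names(which(c(tumour = 1L, muscle = 2L) == ci))
    f <- if (nm == "tumour") f_t else f_m
    sp <- cmp[[nm]]
    wts <- iwsWeights(sp, cmp$tube20, protocol("IWS"))
    m <- lab == ci
    fic[m] <- f
    tsc[m] <- tscFromFractions(f, sp$na_ic, sp$na_ec)
    iws[m] <- iwsFromFractions(f, min(max(wts[["fluid"]], 0), 0.999),
                               sp$na_ic, sp$na_ec,
                               bound_weight = max(wts[["bound"]], 0))
  }
  tsc[lab == 3L] <- 20; tsc[lab == 4L] <- 80
  iws[lab == 3L] <- 20; iws[lab == 4L] <- 80  # tubes are single-pool: no suppression

  coil <- coilFieldModel(config$coil$surface_position, config$coil$penetration_depth,
                         config$coil$falloff_exponent, config$coil$floor)
  co <- .coordArrays(n, v)
  field <- array(coilSensitivity(coil, cbind(as.vector(co$x), as.vector(co$y),
                                             as.vector(co$z))), dim(lab))

  new("DigitalSubject", labels = lab, tsc_true = tsc, iws_true = iws,
      f_ic_map = fic, coil_field = field, voxel_mm = v,
      cellularity_true = cell, f_ic = c(tumour = f_t, muscle = f_m),
      seed = seed)
}

#' Generate a synthetic cohort
#'
#' @param n Cohort size (default 12 subjects).
#' @param seed Integer master seed; subject seeds are derived from it.
#' @param config Configuration list.
#' @return A list with `subjects` (list of [DigitalSubject-class]) and
#'   `truth`, a data frame with one row per subject: `subject_id`,
#'   `f_ic_tumour`, `f_ic_muscle`, `tsc_tumour_true`, `tsc_muscle_true`,
#'   `iws_tumour_true`, `iws_muscle_true`, `cellularity`.
#' @export
#' @examples
#' ch <- makeCohort(n = 3, seed = 7)
#' ch$truth
makeCohort <- function(n = 12L, seed = 1L, config = defaultConfig()) {
  if (n < 2) stop("makeCohort: cohort size must be at least 2")
  set.seed(as.integer(seed))
  subseeds <- sample.int(2^30, n)
  subjects <- lapply(subseeds, function(s) makeSubject(config, seed = s))
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- subjects[[i]]
    data.frame(
      subject_id = i,
      f_ic_tumour = s@f_ic[["tumour"]],
      f_ic_muscle = s@f_ic[["muscle"]],
      tsc_tumour_true = mean(s@tsc_true[s@labels == 1L]),
      tsc_muscle_true = mean(s@tsc_true[s@labels == 2L]),
      iws_tumour_true = mean(s@iws_true[s@labels == 1L]),
      iws_muscle_true = mean(s@iws_true[s@labels == 2L]),
      cellularity = s@cellularity_true
    )
  }))
  list(subjects = subjects, truth = truth)
}

#' Write a digital subject to NIfTI + CSV
#'
#' Writes `labels`, `tsc_true`, `iws_true` and `coil_field` as NIfTI-1
#' volumes (`.nii.gz`) with the voxel size in the header.
#'
#' @param subject A [DigitalSubject-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
writeSubject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- list(labels = subject@labels, tsc_true = subject@tsc_true,
               iws_true = subject@iws_true, coil_field = subject@coil_field)
  paths <- vapply(names(vols), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    img <- RNifti::asNifti(vols[[nm]])
    RNifti::pixdim(img) <- rep(subject@voxel_mm, 3)
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  invisible(paths)
}
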