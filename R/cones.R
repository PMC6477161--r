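#' Design a simplified 3D-cones trajectory
#'
#' Each excitation samples a spiral on the surface of a cone, spiralling
#' outward from the k-space centre to `kmax = 1 / (2 * resolution)`; cone
#' half-angles tile the full sphere with area-uniform density
#' (`cos(theta)` equally spaced). The number of azimuthal revolutions per
#' readout grows with `sin(theta)` so the spiral pitch stays at the Nyquist
#' spacing `1 / fov`. This is a deliberately simple cones family: acceptance
#' of the pipeline depends on faithful sampling and reconstruction, not on
#' trajectory optimality.
#'
#' @param fov Field of view in mm.
#' @param resolution Nominal isotropic resolution in mm (> 0).
#' @param n_cones Number of cones (>= 4); default `ceiling(pi * N / 2)` with
#'   `N = fov / resolution`.
#' @param samples_per_readout Samples per readout; the default resolves the
#'   equatorial spiral at the Nyquist arc spacing.
#' @return A [ConesTrajectory-class] with density-compensation weights.
#' @export
#' @examples
#' tr <- designCones(300, 5.6, n_cones = 16, samples_per_readout = 200)
#' tr@kmax  # 1 / 11.2
designCones <- function(fov, resolution, n_cones = NULL,
                        samples_per_readout = NULL) {
  if (resolution <= 0) stop("designCones: resolution must be positive")
  kmax <- 1 / (2 * resolution)
  N <- fov / resolution
  if (is.null(n_cones)) n_cones <- ceiling(pi * N / 2)
  if (n_cones < 4) stop("designCones: need at least 4 cones")
  theta <- acos(1 - (2 * seq_len(n_cones) - 1) / n_cones)  # area-uniform
  nrev <- pmax(1, ceiling(N / 2 * sin(theta)))
  if (is.null(samples_per_readout))
    samples_per_readout <- ceiling(pi * N / 2 * max(nrev))
  # a readout must at least resolve kmax radially
  if (samples_per_readout < N / 2)
    stop("designCones: too few samples per readout to reach kmax at Nyquist")
  S <- samples_per_readout
  t <- (seq_len(S) - 0.5) / S
  kl <- vector("list", n_cones)
  for (c in seq_len(n_cones)) {
    r <- kmax * t
    phi <- 2 * pi * (nrev[c] * t + (c - 1) / n_cones)  # golden-ish offset
    kl[[c]] <- cbind(r * sin(theta[c]) * cos(phi),
                     r * sin(theta[c]) * sin(phi),
                     r * cos(theta[c]))
  }
  k <- do.call(rbind, kl)
  traj <- new("ConesTrajectory", k = k,
              readout = rep(seq_len(n_cones), each = S),
              dcf = rep(1, nrow(k)), kmax = kmax, fov = fov)
  traj@dcf <- densityCompensation(traj)
  traj
}

#' Radial-shell density compensation
#'
#' Density-compensation weights estimated from the radial sample density:
#' k-space is divided into spherical shells of width `1 / fov` and each
#' sample is weighted by the shell volume divided by the number of samples
#' in its shell. For radially-uniform sampling the weights grow as `|k|^2`
#' away from the centre, with a finite-width correction in the innermost
#' shell and at the `kmax` boundary. Weights are normalised to mean 1.
#'
#' @param traj A [ConesTrajectory-class].
#' @return Positive numeric vector of per-sample weights.
#' @export
densityCompensation <- function(traj) {
  r <- sqrt(rowSums(traj@k^2))
  n <- length(r)
  if (n == 1L) return(1)
  if (max(r) - min(r) < 1e-12 && n > 1)
    stop("densityCompensation: degenerate trajectory (all samples identical)")
  dk <- 1 / traj@fov
  shell <- pmin(floor(r / dk), ceiling(traj@kmax / dk)) + 1L
  counts <- tabulate(shell, nbins = max(shell))
  vol <- diff((dk * (0:max(shell)))^3)  # proportional to shell volume
  w <- vol[shell] / counts[shell]
  w / mean(w)
}

#' Export a trajectory to CSV
#'
#' Columns: `readout_id`, `sample_id`, `kx`, `ky`, `kz`, `dcf`
#' (k in cycles/mm).
#'
#' @param traj A [ConesTrajectory-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  sid <- stats::ave(seq_along(traj@readout), traj@readout, FUN = seq_along)
  utils::write.csv(data.frame(readout_id = traj@readout, sample_id = sid,
                              kx = traj@k[, 1], ky = traj@k[, 2],
                              kz = traj@k[, 3], dcf = traj@dcf),
                   path, row.names = FALSE)
  invisible(path)
}
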