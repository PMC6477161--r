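#' @useDynLib sodiumq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Non-Cartesian k-space data
#'
#' Complex Fourier samples of an image along a [ConesTrajectory-class].
#'
#' @slot samples complex vector, one value per trajectory sample.
#' @slot noise_sd per-channel Gaussian k-space noise sd (0 = noiseless).
#' @slot nex number of averaged excitations.
#' @slot seed integer noise seed (NA if noiseless).
#' @export
setClass("KSpaceData", representation(
  samples = "complex", noise_sd = "numeric", nex = "integer", seed = "integer"
), validity = function(object) {
  if (any(!is.finite(Re(object@samples))) || any(!is.finite(Im(object@samples))))
    "samples must be finite" else TRUE
})

setMethod("show", "KSpaceData", function(object) {
  cat(sprintf("KSpaceData: %d samples, noise sd %g, NEX %d\n",
              length(object@samples), object@noise_sd, object@nex))
})

# Kaiser-Bessel shape parameter (Beatty et al. choice) for oversampling os
.kbBeta <- function(width, os = 2) pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)

# 1D apodization at image positions n (voxels from centre) for oversampled
# grid size G: the discrete Fourier transform of the integer-sampled kernel,
# which matches the spreading/interpolation operation in scale exactly
.kbApod1D <- function(n, G, width, beta) {
  halfw <- width / 2
  j <- -ceiling(halfw):ceiling(halfw)
  u <- pmin(abs(j) / halfw, 1)
  phi <- besselI(beta * sqrt(1 - u^2), 0)
  vapply(n, function(nn) sum(phi * cos(2 * pi * nn * j / G)), numeric(1))
}

.fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) c(((n %/% 2) + 1):n, 1:(n %/% 2)))
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
.ifftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) c((n - (n %/% 2) + 1):n, 1:(n - (n %/% 2))))
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Sample k-space along a trajectory (forward model)
#'
#' Type-2 non-uniform Fourier transform of a real image: apodization
#' pre-compensation, 2x-oversampled FFT and Kaiser-Bessel interpolation onto
#' the trajectory coordinates. Agrees with direct discrete-Fourier summation
#' to high accuracy (increasing with `width`). The phase convention places
#' the spatial origin at voxel `N/2` (0-based).
#'
#' @param image 3D numeric (or complex) array, cubic grid.
#' @param traj A [ConesTrajectory-class]; voxel size is `fov / N` with `N`
#'   the image matrix size.
#' @param width Kaiser-Bessel kernel full width in (oversampled) grid
#'   samples; 4 is fast, 8 is accurate to ~1e-7.
#' @param os Grid oversampling factor (default 2).
#' @return A [KSpaceData-class].
#' @export
sampleKspace <- function(image, traj, width = 8, os = 2) {
  N <- dim(image)[1]
  stopifnot(all(dim(image) == N))
  if (any(!is.finite(image))) stop("sampleKspace: image must be finite")
  G <- os * N
  beta <- .kbBeta(width, os)
  apod <- .kbApod1D(seq_len(N) - 1 - N / 2, G, width, beta)
  xa <- image / (outer(outer(apod, apod), apod))
  xp <- array(0 + 0i, c(G, G, G))
  off <- (G - N) / 2
  xp[off + seq_len(N), off + seq_len(N), off + seq_len(N)] <- xa
  X <- .fftshift3(stats::fft(.ifftshift3(xp)))
  voxel <- traj@fov / N
  u <- traj@k * (voxel * G) + G / 2     # k * voxel * os * N + G/2
  if (any(u < -0.5 | u > G + 0.5))
    stop("sampleKspace: trajectory exceeds the sampled bandwidth (FoV/units mismatch)")
  s <- .kbInterp(as.vector(X), as.integer(G), u, width, beta)
  new("KSpaceData", samples = as.complex(s), noise_sd = 0, nex = 1L,
      seed = NA_integer_)
}

#' Add complex Gaussian noise to k-space data
#'
#' Independent Gaussian perturbations of the real and imaginary channels.
#' `nex` excitations are averaged coherently, so the effective noise sd is
#' `noise_sd / sqrt(nex)`; magnitude reconstruction then yields
#' Rician-distributed voxel noise (Rayleigh in the background).
#'
#' @param k A [KSpaceData-class].
#' @param noise_sd Per-excitation, per-channel noise sd (>= 0).
#' @param seed Integer seed.
#' @param nex Number of averaged excitations (default 1).
#' @return A [KSpaceData-class] with noise added.
#' @export
addNoise <- function(k, noise_sd, seed = 1L, nex = 1L) {
  if (noise_sd < 0) stop("addNoise: noise_sd must be >= 0")
  if (noise_sd == 0) return(k)
  set.seed(as.integer(seed))
  n <- length(k@samples)
  eff <- noise_sd / sqrt(nex)
  k@samples <- k@samples + complex(real = stats::rnorm(n, 0, eff),
                                   imaginary = stats::rnorm(n, 0, eff))
  k@noise_sd <- noise_sd
  k@nex <- as.integer(nex)
  k@seed <- as.integer(seed)
  k
}

#' Gridding reconstruction
#'
#' Density-compensated adjoint non-uniform Fourier transform with
#' apodization correction: spread `dcf`-weighted samples onto the
#' 2x-oversampled grid with the Kaiser-Bessel kernel, inverse FFT, crop,
#' deapodize, and take the magnitude. The result is normalised by the
#' point-spread-function peak of the operator so that a unit point source
#' reconstructs to a unit peak.
#'
#' @param k A [KSpaceData-class].
#' @param traj The matching [ConesTrajectory-class].
#' @param recon_matrix Output cubic matrix size.
#' @param width,os Kernel width and oversampling, as in [sampleKspace()].
#' @return 3D magnitude array (`recon_matrix`^3).
#' @export
gridReconstruct <- function(k, traj, recon_matrix, width = 8, os = 2) {
  if (length(k@samples) != nrow(traj@k))
    stop("gridReconstruct: sample count does not match trajectory")
  N <- as.integer(recon_matrix)
  img <- nufftAdjoint(k@samples * traj@dcf, traj, N, width, os)
  psf <- nufftAdjoint(as.complex(traj@dcf), traj, N, width, os)
  ctr <- N / 2 + 1
  scale <- Re(psf[ctr, ctr, ctr])
  Mod(img) / scale
}

#' Adjoint non-uniform Fourier transform
#'
#' The exact adjoint of the linear operator applied by [sampleKspace()]:
#' Kaiser-Bessel spreading of the (already weighted) samples onto the
#' oversampled grid, adjoint FFT, crop and deapodization. Satisfies
#' `<A x, y> = <x, A^H y>` to machine precision for matching parameters.
#'
#' @param samples Complex vector of per-sample values.
#' @param traj The [ConesTrajectory-class].
#' @param recon_matrix Output cubic matrix size.
#' @param width,os Kernel width and oversampling, as in [sampleKspace()].
#' @return Complex 3D array.
#' @export
nufftAdjoint <- function(samples, traj, recon_matrix, width = 8, os = 2) {
  N <- as.integer(recon_matrix)
  G <- os * N
  beta <- .kbBeta(width, os)
  voxel <- traj@fov / N
  u <- traj@k * (voxel * G) + G / 2
  grid <- array(.kbSpread(as.complex(samples), as.integer(G), u, width, beta),
                c(G, G, G))
  xs <- .fftshift3(stats::fft(.ifftshift3(grid), inverse = TRUE))
  off <- (G - N) / 2
  xc <- xs[off + seq_len(N), off + seq_len(N), off + seq_len(N)]
  apod <- .kbApod1D(seq_len(N) - 1 - N / 2, G, width, beta)
  xc / outer(outer(apod, apod), apod)
}

#' Gaussian blur of a 3D array
#'
#' Separable Gaussian convolution with edge renormalisation.
#'
#' @param vol 3D numeric array.
#' @param sd_vox Gaussian sd in voxels.
#' @return Blurred array of the same dimensions.
#' @export
gaussianBlur3D <- function(vol, sd_vox) {
  if (sd_vox <= 0) return(vol)
  array(.gaussBlur3D(as.numeric(vol), as.integer(dim(vol)), sd_vox), dim(vol))
}
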