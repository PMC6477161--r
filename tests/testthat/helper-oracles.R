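# Independent oracles and small fixtures used across the suite.

# brute-force non-uniform DFT of a cubic image at k-space coordinates (the
# reference for the gridding forward model); origin at voxel N/2, 0-based
bruteDft <- function(image, kmat, voxel_mm) {
  N <- dim(image)[1]
  co <- ((0:(N - 1)) - N / 2) * voxel_mm
  ii <- as.matrix(expand.grid(x = co, y = co, z = co))
  v <- as.vector(image)
  apply(kmat, 1, function(k) sum(v * exp(-2i * pi * (ii %*% k))))
}

# brute-force adjoint (direct summation) with the same phase convention
bruteAdjoint <- function(samples, kmat, N, voxel_mm) {
  co <- ((0:(N - 1)) - N / 2) * voxel_mm
  ii <- as.matrix(expand.grid(x = co, y = co, z = co))
  array(as.vector((exp(2i * pi * (ii %*% t(kmat))) %*% samples)), c(N, N, N))
}

# Rician magnitude draws with true signal s and per-channel sd sigma
riceDraws <- function(n, s, sigma) {
  sqrt((s + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

# exact two-sided signed-rank p by explicit enumeration of all 2^n sign
# patterns (the independent oracle for the generating-function path)
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# a small reduced-size configuration for fast full-array tests
testConfig <- function(...) {
  defaultConfig(...)
}
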