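test_that("spoiled GE signal matches the closed form and its limits", {
  expect_equal(geSignal(1, 0, tr = 100, t1 = 40), 0)
  # TR >> T1: signal -> m0 sin(alpha)
  a <- seq(0.1, pi / 2, length.out = 7)
  expect_equal(geSignal(2, a, tr = 1e6, t1 = 40), 2 * sin(a), tolerance = 1e-9)
  expect_equal(geSignal(1, pi / 2, tr = 100, t1 = 40), 1 - exp(-2.5))
  expect_equal(geSignal(1, pi / 2, tr = 100, t1 = 40), 0.9179, tolerance = 1e-4)
  expect_error(geSignal(1, 1, tr = -1, t1 = 40), "positive")
})

test_that("IR signal nulls at t1 = ti/log(2) and recovers fully for ti >> t1", {
  expect_equal(irSignal(1, ti = 30, t1 = 30 / log(2), tr = Inf), 0,
               tolerance = 1e-12)
  expect_equal(irSignal(1, ti = 30, t1 = 43.28, tr = Inf), 0, tolerance = 1e-4)
  expect_equal(irSignal(3, ti = 5000, t1 = 15, tr = Inf, alpha = pi / 3),
               3 * sin(pi / 3), tolerance = 1e-9)
  expect_equal(irSignal(1, ti = 30, t1 = 15, tr = 1e7, alpha = pi / 2),
               1 - 2 * exp(-2), tolerance = 1e-6)
  expect_equal(abs(irSignal(1, ti = 30, t1 = 15, tr = 1e7)), 0.7293,
               tolerance = 1e-4)
  expect_error(irSignal(1, ti = -1, t1 = 10), "positive")
})

test_that("cones trajectories respect kmax and Nyquist bookkeeping", {
  tr <- designCones(300, 5.6, n_cones = 16, samples_per_readout = 200)
  expect_equal(tr@kmax, 1 / (2 * 5.6))
  expect_equal(tr@kmax, 0.08929, tolerance = 1e-4)
  expect_true(all(sqrt(rowSums(tr@k^2)) <= tr@kmax + 1e-9))
  tr2 <- designCones(300, 5.6, n_cones = 32, samples_per_readout = 200)
  expect_equal(tr2@kmax, tr@kmax)  # kmax depends only on resolution
  expect_error(designCones(300, 5.6, n_cones = 3), "4 cones")
  expect_error(designCones(300, 5.6, n_cones = 8, samples_per_readout = 5),
               "too few samples")
})

test_that("density compensation is positive and grows ~ |k|^2", {
  tr <- designCones(300, 9.375, n_cones = 24, samples_per_readout = 300)
  w <- densityCompensation(tr)
  expect_true(all(w > 0))
  r <- sqrt(rowSums(tr@k^2))
  mid <- r > 0.3 * tr@kmax & r < 0.9 * tr@kmax
  fit <- lm(log(w[mid]) ~ log(r[mid]))
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 0.2)
  # single sample normalises to weight 1
  tr1 <- tr
  tr1@k <- tr@k[1, , drop = FALSE]
  tr1@readout <- 1L
  tr1@dcf <- 1
  expect_equal(densityCompensation(tr1), 1)
})

test_that("k-space sampling agrees with direct Fourier summation", {
  set.seed(5)
  N <- 8
  fov <- N * 5.6
  tr <- designCones(fov, fov / N, n_cones = 8, samples_per_readout = 30)
  img <- array(rnorm(N^3), c(N, N, N))
  kd <- sampleKspace(img, tr, width = 8)
  idx <- c(1L, 77L, 155L, nrow(tr@k))
  ref <- bruteDft(img, tr@k[idx, , drop = FALSE], 5.6)
  expect_lt(max(Mod(kd@samples[idx] - ref) / Mod(ref)), 1e-6)
  # zero image -> zero samples; DC sample equals the image sum
  expect_true(all(Mod(sampleKspace(array(0, c(N, N, N)), tr)@samples) == 0))
  trDC <- tr
  trDC@k <- matrix(0, 1, 3); trDC@readout <- 1L; trDC@dcf <- 1
  expect_equal(Re(sampleKspace(img, trDC)@samples), sum(img), tolerance = 1e-6)
  # shifted point source: phase ramp exp(-2 pi i k . x0)
  ps <- array(0, c(N, N, N)); ps[N / 2 + 2, N / 2 + 1, N / 2 + 1] <- 1
  kd_ps <- sampleKspace(ps, tr, width = 8)
  expected <- exp(-2i * pi * tr@k[idx, , drop = FALSE] %*% c(5.6, 0, 0))
  expect_lt(max(Mod(kd_ps@samples[idx] - expected)), 1e-6)
})

test_that("k-space noise is seed-reproducible and Rayleigh in the background", {
  N <- 12
  fov <- N * 5.6
  tr <- designCones(fov, fov / N, n_cones = 12, samples_per_readout = 60)
  img <- array(0, c(N, N, N)); img[N / 2, N / 2, N / 2] <- 1
  kd <- sampleKspace(img, tr)
  expect_identical(addNoise(kd, 0)@samples, kd@samples)
  n1 <- addNoise(kd, 0.5, seed = 9)
  n2 <- addNoise(kd, 0.5, seed = 9)
  expect_identical(n1@samples, n2@samples)
  # background magnitude voxels: mean/sd = sqrt(pi/2) / sqrt(2 - pi/2) ~ 1.91
  set.seed(2)
  mags <- riceDraws(2e5, 0, 1)
  expect_equal(mean(mags) / sd(mags), sqrt(pi / 2) / sqrt(2 - pi / 2),
               tolerance = 0.02)
  # NEX-fold averaging shrinks the effective sd by sqrt(NEX)
  a1 <- addNoise(kd, 1, seed = 1, nex = 1)@samples - kd@samples
  a6 <- addNoise(kd, 1, seed = 1, nex = 6)@samples - kd@samples
  expect_equal(sd(Re(a1)) / sd(Re(a6)), sqrt(6), tolerance = 0.05)
})

test_that("gridding reconstruction is the exact adjoint and centres the PSF", {
  set.seed(8)
  N <- 16
  fov <- N * 5.6
  tr <- designCones(fov, fov / N)
  img <- array(rnorm(N^3), c(N, N, N))
  y <- complex(real = rnorm(nrow(tr@k)), imaginary = rnorm(nrow(tr@k)))
  Ax <- sampleKspace(img, tr, width = 8)@samples
  Aty <- nufftAdjoint(y, tr, N, width = 8)
  lhs <- sum(Ax * Conj(y))
  rhs <- sum(img * Conj(Aty))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
  ps <- array(0, c(N, N, N)); ps[N / 2 + 1, N / 2 + 1, N / 2 + 1] <- 2
  rec <- gridReconstruct(sampleKspace(ps, tr), tr, N)
  expect_equal(which.max(rec),
               (N / 2) * N * N + (N / 2) * N + N / 2 + 1)
  expect_equal(max(rec), 2, tolerance = 0.01)
})

test_that("density compensation improves reconstruction of a uniform sphere", {
  N <- 16
  fov <- N * 5.6
  tr <- designCones(fov, fov / N)
  co <- ((0:(N - 1)) - N / 2)
  r2 <- outer(outer(co^2, co^2, `+`), co^2, `+`)
  img <- array(0, c(N, N, N)); img[r2 <= 16] <- 1
  kd <- sampleKspace(img, tr)
  ref <- Mod(bruteAdjoint(kd@samples * tr@dcf, tr@k, N, 5.6))
  ref <- ref / max(ref) * max(img)
  rec <- gridReconstruct(kd, tr, N, width = 8)
  trU <- tr; trU@dcf <- rep(1, nrow(tr@k))
  recU <- gridReconstruct(kd, trU, N, width = 8)
  nrmse <- function(x) {
    x <- x / mean(x[r2 <= 9]) * mean(img[r2 <= 9])   # common interior scale
    sqrt(mean((x - img)^2)) / sqrt(mean(img^2))
  }
  expect_lt(nrmse(rec), nrmse(recU))
  # gridding agrees with the direct-summation reference reconstruction
  expect_lt(max(abs(rec / max(rec) - ref / max(ref))), 1e-3)
})

test_that("simulated scans are linear in concentration and reproducible", {
  cfg <- defaultConfig()
  s <- makeSubject(cfg, seed = 2)
  img <- simulateScan(s, "TSC", noise_sd = 0, mode = "fast", config = cfg,
                      uniform_b1 = TRUE)
  ratio <- mean(img[s@labels == 4L]) / mean(img[s@labels == 3L])
  expect_equal(ratio, 4, tolerance = 0.02)
  # IWS with tubes at the fluid null: tube signal collapses
  cfgN <- cfg
  cfgN$compartments$tube20$f_bound <- 0
  cfgN$compartments$tube80$f_bound <- 0
  cfgN$compartments$tube20$t1_fluid <- 43.28
  cfgN$compartments$tube80$t1_fluid <- 43.28
  sN <- makeSubject(cfgN, seed = 2)
  tscN <- simulateScan(sN, "TSC", noise_sd = 0, mode = "fast", config = cfgN)
  iwsN <- simulateScan(sN, "IWS", noise_sd = 0, mode = "fast", config = cfgN)
  expect_lt(mean(iwsN[sN@labels == 4L]) / mean(tscN[sN@labels == 4L]), 0.05)
  n1 <- simulateScan(s, "TSC", noise_sd = 1, seed = 5, config = cfg)
  n2 <- simulateScan(s, "TSC", noise_sd = 1, seed = 5, config = cfg)
  expect_identical(n1, n2)
  expect_error(simulateScan(s, "XX"), "")
})

test_that("image-domain noise sd scales as 1/sqrt(NEX)", {
  cfg <- defaultConfig()
  s <- makeSubject(cfg, seed = 2)
  bg <- sodiumq:::.backgroundMask(s@labels)
  p1 <- protocol("TSC"); p1$nex <- 1L
  p6 <- protocol("TSC"); p6$nex <- 6L
  i1 <- simulateScan(s, p1, noise_sd = 2, seed = 3, config = cfg)
  i6 <- simulateScan(s, p6, noise_sd = 2, seed = 3, config = cfg)
  expect_equal(sd(i1[bg]) / sd(i6[bg]), sqrt(6), tolerance = 0.05)
})

test_that("trajectories export to CSV with one row per sample", {
  tr <- designCones(300, 30, n_cones = 6, samples_per_readout = 20)
  p <- tempfile(fileext = ".csv")
  writeTrajectory(tr, p)
  d <- utils::read.csv(p)
  expect_equal(nrow(d), nrow(tr@k))
  expect_identical(names(d), c("readout_id", "sample_id", "kx", "ky", "kz", "dcf"))
  unlink(p)
})
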