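test_that("SNR is mean signal over background sd and scale invariant", {
  img <- array(0, c(6, 6, 4))
  roi <- array(FALSE, dim(img)); roi[2:3, 2:3, 2] <- TRUE
  bg <- array(FALSE, dim(img)); bg[5:6, 5:6, ] <- TRUE
  img[roi] <- 10
  set.seed(1)
  img[bg] <- rnorm(sum(bg), 0, 2)
  s <- sd(img[bg])
  expect_equal(snr(img, roi, bg), 10 / s)
  expect_equal(snr(3 * img, roi, bg), snr(img, roi, bg))
  img0 <- img; img0[bg] <- 1
  expect_error(snr(img0, roi, bg), "zero background")
})

test_that("noise floor is the per-slice mean squared background value", {
  img <- array(0, c(2, 2, 2))
  img[, , 1] <- c(1, 2, 2, 3)
  bg <- array(TRUE, dim(img))
  expect_equal(noiseFloor(img, bg), c(4.5, 0))
  # Rayleigh background floor converges to 2 sigma^2
  set.seed(4)
  big <- array(riceDraws(2 * 50^2, 0, 1.5), c(50, 50, 2))
  fl <- noiseFloor(big, array(TRUE, dim(big)))
  expect_equal(fl, rep(2 * 1.5^2, 2), tolerance = 0.05)
  bg2 <- bg; bg2[, , 2] <- FALSE
  expect_error(noiseFloor(img, bg2), "slice 2")
})

test_that("squared-subtraction debias matches hand values and clamps", {
  img <- array(c(5, 2), c(2, 1, 1))
  out <- correctNoiseBias(img, 9)
  expect_equal(as.vector(out), c(4, 0))
  expect_equal(attr(out, "n_clamped"), 1L)
  # idempotent once floored with zero floor
  expect_equal(correctNoiseBias(out, 0), out, ignore_attr = TRUE)
  expect_error(correctNoiseBias(img, -1), "floor")
})

test_that("debiasing recovers the true signal from Rician magnitudes at SNR 5", {
  set.seed(11)
  sigma <- 2; strue <- 10
  draws <- riceDraws(1e5, strue, sigma)
  floor_hat <- mean(riceDraws(1e5, 0, sigma)^2)    # background-measured floor
  img <- array(draws, c(100, 100, 10))
  corrected <- correctNoiseBias(img, rep(floor_hat, 10))
  expect_gt(mean(draws), strue)                    # uncorrected is biased high
  # ROI estimate in the squared (subtraction) domain is unbiased
  expect_equal(sqrt(mean(corrected^2)), strue, tolerance = 0.02)
  # the voxelwise mean keeps a small concavity bias; exact value by
  # quadrature of the Rice density: E[sqrt(max(M^2 - 2 s^2, 0))] = 9.7825
  expect_equal(mean(corrected), 9.7825, tolerance = 0.005)
})

test_that("dual-angle mapping inverts the sine model voxelwise", {
  lo <- array(sin(pi / 6), c(3, 3, 3))
  hi <- array(sin(pi / 3), c(3, 3, 3))
  b1 <- estimateB1(lo, hi)
  expect_equal(b1@alpha_true[1], 30, tolerance = 1e-9)
  expect_equal(b1@scale[1], 1)
  # s_high / s_low = 1 -> 60 degrees at the low nominal, scale 2
  b2 <- estimateB1(array(0.5, c(2, 2, 2)), array(0.5, c(2, 2, 2)))
  expect_equal(b2@alpha_true[1], 60)
  expect_equal(b2@scale[1], 2)
  expect_error(estimateB1(lo, array(1, c(2, 2, 2))), "grid")
})

test_that("B1 recovery on a simulated subject tracks the coil field within 3%", {
  cfg <- defaultConfig()
  s <- makeSubject(cfg, seed = 4)
  lo <- simulateScan(s, "B1_LOW", noise_sd = 0, mode = "fast", config = cfg)
  hi <- simulateScan(s, "B1_HIGH", noise_sd = 0, mode = "fast", config = cfg)
  b1 <- estimateB1(lo, hi)
  for (lab in c(1L, 2L)) {
    m <- s@labels == lab
    expect_equal(median(b1@scale[m]), median(s@coil_field[m]),
                 tolerance = 0.03)
  }
})

test_that("flip-angle masking excludes <10 and >140 degrees at the imaging flip", {
  b1 <- estimateB1(array(0.5, c(3, 1, 1)), array(0.5, c(3, 1, 1)))
  b1@scale <- array(c(1.0, 1.6, 0.1), c(3, 1, 1))
  m <- maskB1(b1, 10, 140)
  expect_identical(as.vector(m@valid), c(TRUE, FALSE, FALSE))
  expect_error(maskB1(b1, 140, 10), "lo must be")
})

test_that("the inhomogeneity correction divides by alpha sin(alpha)", {
  b1 <- estimateB1(array(0.5, c(1, 1, 1)), array(0.5 * 2 * cos(pi / 6), c(1, 1, 1)))
  img <- array(3.1416, c(1, 1, 1))
  out <- correctInhomogeneity(img, b1, 90)
  expect_equal(out[1], 3.1416 / ((pi / 2) * sin(pi / 2)))
  expect_equal((pi / 2) * sin(pi / 2), 1.5708, tolerance = 1e-4)
})

test_that("the correction equalizes equal-sodium voxels across 20-140 degrees", {
  # TR >> T1 forward model with reciprocity: S = r sin(r * 90deg), r = scale
  scales <- seq(20, 140, by = 5) / 90
  a_eff <- scales * pi / 2
  s_img <- array(scales * sin(a_eff), c(length(scales), 1, 1))
  s30 <- array(scales * sin(scales * pi / 6), dim(s_img))
  s60 <- array(scales * sin(scales * pi / 3), dim(s_img))
  b1 <- maskB1(estimateB1(s30, s60))
  out <- correctInhomogeneity(s_img, b1, 90)
  v <- out[b1@valid]
  expect_lt(diff(range(v)) / mean(v), 0.005)
})

test_that("a uniform B1 map leaves ROI ratios untouched", {
  cfg <- defaultConfig()
  s <- makeSubject(cfg, seed = 5)
  img <- simulateScan(s, "TSC", noise_sd = 0, mode = "fast", config = cfg,
                      uniform_b1 = TRUE)
  b1 <- estimateB1(array(sin(pi / 6), dim(img)), array(sin(pi / 3), dim(img)))
  out <- correctInhomogeneity(img, b1, 90)
  r0 <- mean(img[s@labels == 4L]) / mean(img[s@labels == 3L])
  r1 <- mean(out[s@labels == 4L]) / mean(out[s@labels == 3L])
  expect_equal(r1, r0, tolerance = 1e-3)
})

test_that("ratio smoothing regularises without biasing a smooth field", {
  # smoothly varying true scale; noiseless ratio map is reproduced
  n <- 12
  sc <- array(0.8 + 0.1 * outer(outer(sin((1:n) / n), rep(1, n)), rep(1, n)),
              c(n, n, n))
  lo <- sin(sc * pi / 6); hi <- sin(sc * pi / 3)
  b1 <- estimateB1(lo, hi, ratio_smooth_sd_vox = 1)
  expect_equal(b1@scale, sc, tolerance = 0.01)
})

test_that("SNR is measured before noise correction in the processing chain", {
  cfg <- defaultConfig()
  s <- makeSubject(cfg, seed = 6)
  vols <- lapply(list(tsc = "TSC", b1low = "B1_LOW", b1high = "B1_HIGH",
                      iws = "IWS"),
                 function(p) simulateScan(s, p, seed = 20, config = cfg))
  res <- processVolumes(vols, s@labels, cfg)
  bg <- sodiumq:::.backgroundMask(s@labels)
  expect_equal(res$snr[["tsc"]],
               snr(vols$tsc, s@labels == 1L, bg))   # raw image, by definition
})
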