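test_that("two-point calibration is exact through both tube points", {
  cv <- fitCalibration(c(100, 400))
  expect_equal(cv$slope, 0.2)
  expect_equal(cv$intercept, 0)
  cv2 <- fitCalibration(c(150, 450))
  expect_equal(cv2$slope, 0.2)
  expect_equal(cv2$intercept, -10)
  # self-consistency: the curve maps the tube signals back to 20 / 80
  expect_equal(cv2$slope * c(150, 450) + cv2$intercept, c(20, 80))
  expect_error(fitCalibration(c(400, 100)), "inverted")
  expect_error(fitCalibration(c(100, 100)), "inverted")
  # >= 3 tubes: least squares through all points
  cv3 <- fitCalibration(c(100, 250, 400), concs = c(20, 50, 80))
  expect_equal(cv3$slope, 0.2)
})

test_that("calibration application is affine, floored and missing-aware", {
  cv <- fitCalibration(c(100, 400))
  img <- array(c(100, 250, 400, -50, NA), c(5, 1, 1))
  m <- applyCalibration(img, cv, "TSC")
  expect_equal(concValues(m)[1:3], c(20, 50, 80))
  expect_equal(concValues(m)[4], 0)       # floored
  expect_equal(m@n_floored, 1L)
  expect_true(is.na(concValues(m)[5]))    # missing propagates
})

test_that("multiple deposits combine into one tumour volume", {
  d1 <- array(FALSE, c(4, 4, 4)); d1[1:2, 1, 1] <- TRUE
  d2 <- array(FALSE, c(4, 4, 4)); d2[3:4, 4, 4] <- TRUE
  u <- combineDeposits(list(d1, d2))
  expect_equal(sum(u), sum(d1) + sum(d2))
  expect_identical(combineDeposits(list(d1)), d1)
  expect_error(combineDeposits(list()), "at least one")
  # union ROI mean equals the count-weighted mean of per-deposit means
  set.seed(2)
  vals <- array(rnorm(64), c(4, 4, 4))
  wmean <- (sum(d1) * mean(vals[d1]) + sum(d2) * mean(vals[d2])) /
    (sum(d1) + sum(d2))
  expect_equal(mean(vals[u]), wmean)
})

test_that("ROI summaries are missing-aware and match direct recomputation", {
  set.seed(3)
  vals <- array(rnorm(27, 50, 5), c(3, 3, 3))
  vals[1:5] <- NA
  roi <- array(TRUE, c(3, 3, 3))
  out <- roiSummary(vals, list(all = roi))
  obs <- vals[!is.na(vals)]
  expect_equal(out$mean, mean(obs))
  expect_equal(out$sd, sd(obs))
  expect_equal(out$n_voxels, length(obs))
  expect_equal(out$n_missing, 5L)
  expect_false(out$all_missing)
  const <- array(56.8, c(2, 2, 2))
  out2 <- roiSummary(const, list(c = array(TRUE, c(2, 2, 2))))
  expect_equal(out2$mean, 56.8)
  expect_equal(out2$sd, 0)
  allna <- array(NA_real_, c(2, 2, 2))
  out3 <- roiSummary(allna, list(c = array(TRUE, c(2, 2, 2))))
  expect_true(out3$all_missing)
  expect_error(roiSummary(const, list(e = array(FALSE, c(2, 2, 2)))), "empty")
})

test_that("the noiseless uniform-B1 chain recovers true TSC within 2%", {
  cfg <- defaultConfig()
  cfg$compartments$tumour$f_ic_sd <- 0
  cfg$compartments$muscle$f_ic_sd <- 0
  s <- makeSubject(cfg, seed = 1)
  res <- processSubject(s, cfg, noise_sd = 0, mode = "fast", uniform_b1 = TRUE)
  expect_equal(res$summary$tsc_tumour, mean(s@tsc_true[s@labels == 1L]),
               tolerance = 0.02)
  # calibrated maps are increasing affine functions of the corrected signal
  expect_gt(res$curves$tsc$slope, 0)
  expect_gt(res$curves$iws$slope, 0)
})

test_that("cohort tables join on subject id with stable column order", {
  sr <- data.frame(subject_id = 1:3, tsc_tumour = c(55, 60, 58),
                   tsc_muscle = c(33, 30, 35), iws_tumour = c(31, 29, 32),
                   iws_muscle = c(20, 21, 19))
  cl <- data.frame(subject_id = 3:1, cellularity = c(6, 7, 5))
  tab <- buildCohortTable(sr, cl)
  expect_equal(nrow(tab), 3)
  expect_identical(names(tab), c("subject_id", "tsc_tumour", "tsc_muscle",
                                 "iws_tumour", "iws_muscle", "cellularity"))
  expect_equal(tab$cellularity, c(5, 7, 6))  # joined by id, not order
  expect_error(buildCohortTable(sr, cl[1:2, ]), "mismatch")
  # CSV round trip preserves values
  p <- tempfile(fileext = ".csv")
  utils::write.csv(tab, p, row.names = FALSE)
  back <- utils::read.csv(p)
  expect_equal(back, tab, tolerance = 1e-6)
  unlink(p)
})
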