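test_that("two-compartment TSC weighting matches its closed form and limits", {
  expect_equal(tscFromFractions(0, 12, 145), 145)
  expect_equal(tscFromFractions(1, 12, 145), 12)
  # fraction solved by hand from f = (145 - 56.8) / (145 - 12)
  expect_equal(tscFromFractions(0.6632, 12, 145), 56.8, tolerance = 0.05 / 56.8)
  expect_error(tscFromFractions(1.2), "f_ic")
  f <- runif(50)
  expect_equal(tscFromFractions(f), f * 12 + (1 - f) * 145)
})

test_that("IWS ground truth never exceeds TSC and respects the leakage form", {
  f <- seq(0, 1, by = 0.05)
  iws <- iwsFromFractions(f, leakage = 0.45, bound_weight = 1.4)
  expect_true(all(iws <= tscFromFractions(f) + 1e-12))
  # away from the cap the affine form holds exactly
  expect_equal(iwsFromFractions(0.5, 0.4), 0.5 * 12 + 0.4 * 0.5 * 145)
  expect_error(iwsFromFractions(0.5, 1.2), "leakage")
})

test_that("cellularity link is linear with a positive floor and reproducible", {
  expect_equal(linkCellularity(0.5, 10, jitter_sd = 0), 5)
  expect_gt(linkCellularity(0, 10, jitter_sd = 0), 0)
  expect_identical(linkCellularity(0.7, seed = 42), linkCellularity(0.7, seed = 42))
  expect_error(linkCellularity(0.5, jitter_sd = -1), "jitter_sd")
})

test_that("coil sensitivity is 1 at the surface, monotone, and hits the floor", {
  m <- coilFieldModel(c(0, -179.2, 0), penetration_depth = 120,
                      falloff_exponent = 6, floor = 0.1)
  expect_equal(coilSensitivity(m, c(0, -179.2, 0)), 1)
  depths <- seq(5, 119, by = 2)
  f <- coilSensitivity(m, cbind(0, -179.2 + depths, 0))
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1))
  expect_equal(coilSensitivity(m, c(0, -179.2 + 120, 0)), 0.1)
})

test_that("digital subjects satisfy the phantom invariants", {
  s <- makeSubject(seed = 7)
  expect_identical(sort(unique(as.vector(s@labels))), 0:4)
  expect_true(all(s@tsc_true[s@labels == 3L] == 20))
  expect_true(all(s@tsc_true[s@labels == 4L] == 80))
  expect_true(all(s@tsc_true >= s@iws_true - 1e-9))
  expect_true(all(s@tsc_true[s@labels != 0L] > 0))
  # voxelwise conservation of the weighting model in tissue
  tis <- s@labels %in% c(1L, 2L)
  expect_equal(s@tsc_true[tis],
               s@f_ic_map[tis] * 12 + (1 - s@f_ic_map[tis]) * 145)
  # determinism
  s2 <- makeSubject(seed = 7)
  expect_identical(s@tsc_true, s2@tsc_true)
  expect_identical(s@cellularity_true, s2@cellularity_true)
})

test_that("the default tumour fraction gives ground-truth mean TSC near 56.8 mM", {
  cfg <- defaultConfig()
  cfg$compartments$tumour$f_ic_sd <- 0
  cfg$compartments$muscle$f_ic_sd <- 0
  s <- makeSubject(cfg, seed = 1)
  expect_equal(mean(s@tsc_true[s@labels == 1L]), 56.8, tolerance = 1 / 56.8)
  expect_equal(mean(s@tsc_true[s@labels == 2L]), 33.2, tolerance = 1 / 33.2)
})

test_that("cohorts have one truth row per subject and are reproducible", {
  ch <- makeCohort(n = 3, seed = 11)
  expect_length(ch$subjects, 3)
  expect_equal(nrow(ch$truth), 3)
  expect_identical(names(ch$truth),
                   c("subject_id", "f_ic_tumour", "f_ic_muscle",
                     "tsc_tumour_true", "tsc_muscle_true",
                     "iws_tumour_true", "iws_muscle_true", "cellularity"))
  expect_true(all(ch$truth$cellularity > 0))
  ch2 <- makeCohort(n = 3, seed = 11)
  expect_identical(ch$truth, ch2$truth)
  expect_error(makeCohort(n = 1), "at least 2")
})

test_that("true tumour TSC and cellularity are negatively associated at scale", {
  cfg <- defaultConfig()
  f <- vapply(1:500, function(i) {
    sc <- sodiumq:::.drawSubjectScalars(cfg, i)
    c(sc$f_tumour, sc$cellularity)
  }, numeric(2))
  tsc <- tscFromFractions(f[1, ])
  expect_lt(cor(rank(tsc), rank(f[2, ])), 0)
  # tumour exceeds muscle in most subjects (paired latent factor)
  both <- vapply(1:200, function(i) {
    sc <- sodiumq:::.drawSubjectScalars(cfg, i)
    tscFromFractions(sc$f_tumour) > tscFromFractions(sc$f_muscle)
  }, logical(1))
  expect_gte(mean(both), 11 / 12)
})

test_that("subjects round-trip through NIfTI with voxel size preserved", {
  s <- makeSubject(seed = 3)
  d <- tempfile()
  paths <- writeSubject(s, d)
  expect_true(all(file.exists(paths)))
  img <- RNifti::readNifti(file.path(d, "tsc_true.nii.gz"))
  expect_equal(RNifti::pixdim(img), rep(5.6, 3), tolerance = 1e-6)
  expect_equal(as.array(img), s@tsc_true, ignore_attr = TRUE)
  unlink(d, recursive = TRUE)
})

test_that("misplaced geometry is rejected", {
  cfg <- defaultConfig()
  cfg$geometry$tumour$centre <- c(170, -150, 0)
  expect_error(makeSubject(cfg, seed = 1), "field of view|overlaps")
  cfg <- defaultConfig()
  cfg$geometry$muscle$centre <- c(0, -170, -40)  # shallower than the tumour
  expect_error(makeSubject(cfg, seed = 1), "superficial|overlaps|field of view")
})
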