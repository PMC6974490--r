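test_that("a voxel with the reference kinetics has DVR exactly 1", {
  sch <- defaultScheme()
  ref <- simulateReferenceTAC(0.25, 0.25, sch)
  dvr <- loganDVR(tacImage(matrix(ref, 1), sch), ref, 30)
  expect_equal(dvr@values[1, 1, 1], 1, tolerance = 1e-6)
})

test_that("DVR is invariant to a common rescaling of target and reference", {
  sch <- defaultScheme()
  ref <- simulateReferenceTAC(0.25, 0.25, sch)
  tac <- simulateTargetTAC(referenceCurve(0.25, 0.25), 0.85, 0.2125, 0.3, sch)
  d1 <- loganDVR(tacImage(matrix(tac, 1), sch), ref, 30)@values[1, 1, 1]
  d2 <- loganDVR(tacImage(matrix(tac * 7, 1), sch), ref * 7, 30)@values[1, 1, 1]
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("noiseless recovery is within 0.02 across the binding range", {
  sch <- defaultScheme()
  ref <- simulateReferenceTAC(0.25, 0.25, sch)
  refFun <- referenceCurve(0.25, 0.25)
  bps <- c(0, 0.1, 0.28, 0.44, 1.0)
  tacs <- t(vapply(bps, function(bp)
    simulateTargetTAC(refFun, 0.85, 0.2125, bp, sch), numeric(nFrames(sch))))
  est <- loganDVR(tacImage(tacs, sch), ref, 30)@values[, 1, 1]
  expect_lt(max(abs(est - (1 + bps))), 0.02)
})

test_that("estimates at t* = 30 and 40 min agree on noiseless data", {
  sch <- defaultScheme()
  ref <- simulateReferenceTAC(0.25, 0.25, sch)
  tac <- simulateTargetTAC(referenceCurve(0.25, 0.25), 0.85, 0.2125, 0.44, sch)
  img <- tacImage(matrix(tac, 1), sch)
  expect_equal(loganDVR(img, ref, 30)@values[1, 1, 1],
               loganDVR(img, ref, 40)@values[1, 1, 1], tolerance = 0.005)
})

test_that("the optional k2' term leaves noiseless estimates near truth", {
  sch <- defaultScheme()
  ref <- simulateReferenceTAC(0.25, 0.25, sch)
  tac <- simulateTargetTAC(referenceCurve(0.25, 0.25), 0.85, 0.2125, 0.44, sch)
  img <- tacImage(matrix(tac, 1), sch)
  est <- loganDVR(img, ref, 30, k2prime = 0.25)@values[1, 1, 1]
  expect_equal(est, 1.44, tolerance = 0.02)
  expect_equal(loganDVR(img, ref, 30, k2prime = 0.25)@provenance$k2prime, 0.25)
})

test_that("multiplicative frame noise biases the median DVR downwards", {
  sch <- defaultScheme()
  ref <- simulateReferenceTAC(0.25, 0.25, sch)
  tac <- simulateTargetTAC(referenceCurve(0.25, 0.25), 0.85, 0.2125, 0.44, sch)
  noiseless <- loganDVR(tacImage(matrix(tac, 1), sch), ref, 30)@values[1, 1, 1]
  set.seed(2)
  V <- 500L
  noisy <- matrix(rep(tac, each = V), V) * (1 + matrix(rnorm(V * nFrames(sch), 0, 0.2), V))
  est <- loganDVR(tacImage(noisy, sch), ref, 30)@values[, 1, 1]
  expect_lte(median(est, na.rm = TRUE), noiseless)
})

test_that("voxels with non-positive late activity are flagged, not fitted", {
  sch <- defaultScheme()
  ref <- simulateReferenceTAC(0.25, 0.25, sch)
  good <- simulateTargetTAC(referenceCurve(0.25, 0.25), 0.85, 0.2125, 0.3, sch)
  bad <- good; bad[25] <- -0.1
  expect_message(dvr <- loganDVR(tacImage(rbind(good, bad), sch), ref, 30),
                 "1 voxel")
  expect_false(is.na(dvr@values[1, 1, 1]))
  expect_true(is.na(dvr@values[2, 1, 1]))
  expect_equal(dvr@provenance$n_invalid, 1L)
})

test_that("ROI summaries average valid voxels and reject empty ROIs", {
  vals <- array(NA_real_, c(2, 2, 1))
  vals[1, 1, 1] <- 1.2; vals[2, 1, 1] <- 1.4
  map <- new("ParametricMap", values = vals, quantity = "DVR",
             units = "unitless", provenance = list())
  roi <- array(TRUE, c(2, 2, 1))
  s <- roiMean(map, roi)
  expect_equal(s$mean, 1.3)
  expect_equal(s$n, 2L)
  const <- array(2.5, c(2, 2, 1))
  expect_equal(roiMean(const, roi), list(mean = 2.5, sd = 0, n = 4L))
  expect_error(roiMean(map, array(c(FALSE, FALSE, TRUE, TRUE), c(2, 2, 1))),
               "empty")
})
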