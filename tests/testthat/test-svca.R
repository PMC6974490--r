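test_that("frame normalization z-scores every frame over the brain", {
  sch <- parseFrameScheme("2x60")
  arr <- array(0, c(3, 1, 1, 2))
  arr[, 1, 1, 1] <- c(1, 2, 3)
  arr[, 1, 1, 2] <- c(5, 5, 8)
  img <- dynamicImage(arr, sch, 2)
  brain <- array(TRUE, c(3, 1, 1))
  z <- normalizeFrames(img, brain)
  expect_equal(z[, 1, 1, 1], (c(1, 2, 3) - 2) / sd(c(1, 2, 3)))
  expect_equal(mean(z[, 1, 1, 2]), 0)
  expect_equal(sd(z[, 1, 1, 2]), 1)
})

test_that("a zero-variance frame aborts with the frame named", {
  sch <- parseFrameScheme("2x60")
  arr <- array(1, c(4, 1, 1, 2)); arr[, 1, 1, 1] <- c(1, 2, 3, 4)
  img <- dynamicImage(arr, sch, 2)
  expect_error(normalizeFrames(img, array(TRUE, c(4, 1, 1))),
               "frame 2 has zero variance")
})

test_that("normalized phantom frames have brain mean 0 and SD 1", {
  ph <- buildPhantom(smallPhantomSpec(noiseScale = 0.15, seed = 3L))
  z <- normalizeFrames(ph$dynamic, ph$masks$brain)
  idx <- which(ph$masks$brain)
  nv <- prod(dim(z)[1:3])
  for (f in c(1L, 13L, 26L)) {
    v <- z[idx + (f - 1L) * nv]
    expect_lt(abs(mean(v)), 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
  }
})

test_that("blood-voxel selection finds the planted vessels and breaks ties by index", {
  ph <- buildPhantom(smallPhantomSpec(noiseScale = 0.1, seed = 2L))
  sel <- selectBloodVoxels(ph$dynamic, ph$masks$brain)
  expect_identical(which(sel), which(ph$truth@labelMap == 3L))
  # all-constant early frames: full tie -> lowest voxel indices win, stably
  sch <- defaultScheme()
  arr <- array(1, c(5, 2, 1, nFrames(sch)))
  img <- dynamicImage(arr, sch, 2)
  brain <- array(TRUE, c(5, 2, 1))
  s1 <- selectBloodVoxels(img, brain, n = 4L)
  expect_identical(which(s1), 1:4)
  expect_identical(s1, selectBloodVoxels(img, brain, n = 4L))
  expect_error(selectBloodVoxels(img, brain, n = 30L), "30 required")
})

test_that("class curves reproduce a uniform tissue's normalized kinetics", {
  ph <- buildPhantom(smallPhantomSpec())   # noiseless: GM voxels share one TAC
  dyn <- decayCorrect(ph$dynamic)
  cls <- buildKineticClasses(dyn, ph$masks$gm, ph$masks$wm, ph$masks$brain)
  z <- normalizeFrames(dyn, ph$masks$brain)
  gmIdx <- which(ph$masks$gm)
  nv <- prod(dim(z)[1:3])
  zGm <- vapply(seq_len(nFrames(dyn@scheme)),
                function(f) z[gmIdx[1] + (f - 1L) * nv], numeric(1))
  expect_equal(unname(cls@classes[, "gm"]), zGm)
  expect_equal(cls@nControls, 1L)
})

test_that("the NNLS solver agrees with an established reference implementation", {
  skip_if_not_installed("pracma")
  set.seed(42)
  for (rep in 1:20) {
    X <- matrix(rnorm(26 * 3), 26, 3)
    Z <- matrix(rnorm(26 * 5), 26, 5)
    W <- MyelinPET:::.nnls3(X, Z)
    for (j in 1:5) {
      ora <- pracma::lsqnonneg(X, Z[, j])$x
      expect_equal(unname(W[, j]), unname(ora), tolerance = 1e-8)
    }
  }
})

test_that("reference extraction recovers exactly the grey-matter ground truth", {
  ph <- buildPhantom(smallPhantomSpec())
  dyn <- decayCorrect(ph$dynamic)
  cls <- buildKineticClasses(dyn, ph$masks$gm, ph$masks$wm, ph$masks$brain)
  rr <- extractReference(dyn, cls, ph$masks$gm, ph$masks$brain)
  expect_identical(which(rr@mask), which(ph$truth@labelMap == 1L))
  expect_equal(rr@refTac, ph$truth@referenceTac, tolerance = 1e-12)
  # pure class-2 kinetics are excluded: weight ratio far below threshold
  expect_true(all(rr@weightMap[which(rr@mask)] > 0.9))
})

test_that("the extraction is invariant to global rescaling of the scan", {
  ph <- buildPhantom(smallPhantomSpec(noiseScale = 0.1, seed = 6L))
  dyn <- decayCorrect(ph$dynamic)
  cls <- buildKineticClasses(dyn, ph$masks$gm, ph$masks$wm, ph$masks$brain)
  rr1 <- extractReference(dyn, cls, ph$masks$gm, ph$masks$brain)
  scaled <- dyn; scaled@data <- scaled@data * 3.7
  rr2 <- extractReference(scaled, cls, ph$masks$gm, ph$masks$brain)
  expect_identical(rr1@mask, rr2@mask)
  expect_equal(rr2@refTac, 3.7 * rr1@refTac)
})

test_that("raising the threshold never grows the reference mask", {
  ph <- buildPhantom(smallPhantomSpec(noiseScale = 0.3, seed = 7L))
  dyn <- decayCorrect(ph$dynamic)
  cls <- buildKineticClasses(dyn, ph$masks$gm, ph$masks$wm, ph$masks$brain)
  masks <- lapply(c(0.5, 0.7, 0.9), function(th)
    extractReference(dyn, cls, ph$masks$gm, ph$masks$brain, threshold = th)@mask)
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
  expect_error(extractReference(dyn, cls, ph$masks$gm, ph$masks$brain,
                                threshold = 1.0), "empty reference")
})
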