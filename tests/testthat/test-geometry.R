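test_that("NAWM is white matter minus the lesion union", {
  dm <- c(10, 10, 6)
  wm <- array(FALSE, dm); wm[3:8, 3:8, 2:5] <- TRUE
  none <- array(FALSE, dm)
  expect_equal(nawmMask(wm, none, none), wm)
  expect_false(any(nawmMask(wm, none, wm)))
  t2 <- array(FALSE, dm); t2[4:5, 4:5, 3] <- TRUE
  expect_equal(sum(nawmMask(wm, none, t2)), sum(wm) - 4L)
  outside <- array(FALSE, dm); outside[1, 1, 1] <- TRUE
  expect_warning(nawmMask(wm, none, outside), "1 lesion voxel")
})

test_that("NAWM voxel counting matches sphere voxelization on a phantom", {
  ph <- buildPhantom(smallPhantomSpec())
  nawm <- nawmMask(ph$masks$wm, ph$masks$t1, ph$masks$t2)
  expect_equal(sum(nawm), sum(ph$masks$wm) - sum(ph$masks$t2))
})

test_that("the distance transform equals the brute-force all-pairs oracle", {
  set.seed(31)
  dm <- c(14, 12, 9)
  vs <- c(1.5, 1.5, 3)            # square in-plane, thick slices
  feat <- array(runif(prod(dm)) < 0.06, dm)
  feat[5, 5, 4] <- TRUE
  for (mode in c("3d", "2d")) {
    got <- distanceToMask(feat, vs, mode)
    want <- bruteDistance(feat, vs, mode)
    fin <- is.finite(want)
    expect_equal(got[fin], want[fin], tolerance = 1e-10)
    expect_true(all(is.infinite(got[!fin])))
  }
  expect_error(distanceToMask(feat, c(1, 2, 2), "2d"), "square in-plane")
})

test_that("rings around a single-voxel lesion form the in-plane disk", {
  dm <- c(15, 15, 5)
  les <- array(0L, dm); les[8, 8, 3] <- 1L
  ls <- perilesionalRings(les, list(c(0, 4), c(4, 8)), mode = "2d",
                          voxelSize = 1)
  inner <- ls@maskList[["lesion1.perilesional_inner"]]
  # oracle: all voxels in the same slice within 4 mm, lesion excluded
  want <- array(FALSE, dm)
  for (i in 1:15) for (j in 1:15) {
    d <- sqrt((i - 8)^2 + (j - 8)^2)
    if (d > 0 && d <= 4) want[i, j, 3] <- TRUE
  }
  expect_identical(inner, want)
  # empty band gives an empty ring
  ls0 <- perilesionalRings(les, list(c(0, 0)), mode = "2d", voxelSize = 1)
  expect_false(any(ls0@maskList[[1]]))
})

test_that("ring and layer masks match the brute-force oracle on a 3D grid", {
  set.seed(5)
  dm <- c(20, 18, 16); vs <- c(2, 2, 2)
  les <- array(0L, dm)
  les[5:8, 5:8, 5:8] <- 1L
  les[13:15, 9:11, 9:11] <- 2L
  for (mode in c("3d", "2d")) {
    ls <- perilesionalRings(les, list(c(0, 4), c(4, 8)), mode = mode,
                            voxelSize = vs, excludeOverlap = TRUE)
    d1 <- bruteDistance(les == 1L, vs, mode)
    d2 <- bruteDistance(les == 2L, vs, mode)
    shared <- (d1 > 0 & d1 <= 8) & (d2 > 0 & d2 <= 8)
    for (k in 1:2) {
      d <- if (k == 1) d1 else d2
      expect_identical(ls@maskList[[sprintf("lesion%d.perilesional_inner", k)]],
                       d > 0 & d <= 4 & les == 0L & !shared)
      expect_identical(ls@maskList[[sprintf("lesion%d.perilesional_outer", k)]],
                       d > 4 & d <= 8 & les == 0L & !shared)
    }
    # no ring voxel may fall inside any lesion
    allRings <- Reduce(`|`, ls@maskList)
    expect_false(any(allRings & les > 0L))
  }
})

test_that("intralesional layers partition a sphere into shell and core", {
  dm <- c(17, 17, 17)
  co <- (1:17) - 9
  d <- sqrt(outer(outer(co^2, co^2, `+`), co^2, `+`))
  les <- array(0L, dm); les[d <= 4] <- 1L    # 4 mm sphere, 1 mm voxels
  ls <- intralesionalLayers(les, 2L, 1)
  outer_ <- ls@maskList[["lesion1.intralesional_outer"]]
  inner_ <- ls@maskList[["lesion1.intralesional_inner"]]
  # exact partition
  expect_false(any(outer_ & inner_))
  expect_identical(outer_ | inner_, les == 1L)
  # against the brute-force depth oracle with equal-depth binning
  depth <- bruteDistance(les == 0L, 1, "3d")
  dmax <- max(depth[les == 1L])
  expect_identical(inner_, les == 1L & depth > dmax / 2)
  # one layer is the lesion itself
  ls1 <- intralesionalLayers(les, 1L, 1)
  expect_identical(ls1@maskList[["lesion1.core"]], les == 1L)
})

test_that("a plane-slab lesion splits into parallel half-slabs", {
  dm <- c(9, 9, 8)
  les <- array(0L, dm); les[, , 3:6] <- 1L   # slab spanning 4 slices
  ls <- intralesionalLayers(les, 2L, 1)
  inner <- ls@maskList[["lesion1.intralesional_inner"]]
  outer_ <- ls@maskList[["lesion1.intralesional_outer"]]
  # depth only depends on the slice index: inner = middle slices
  expect_true(all(inner[, , 4:5]))
  expect_false(any(inner[, , c(3, 6)]))
  expect_true(all(outer_[, , c(3, 6)]))
})

test_that("a single-voxel lesion degenerates to the outer layer with a warning", {
  dm <- c(7, 7, 7)
  les <- array(0L, dm); les[4, 4, 4] <- 1L
  expect_warning(ls <- intralesionalLayers(les, 2L, 2), "uniform depth")
  expect_identical(ls@maskList[["lesion1.intralesional_outer"]], les == 1L)
  expect_false(any(ls@maskList[["lesion1.intralesional_inner"]]))
})

test_that("lesions below the scanner resolution are dropped, idempotently", {
  dm <- c(20, 20, 20)
  les <- array(0L, dm)
  les[2:3, 2, 2] <- 1L                       # 2 voxels @1mm: ~1.6 mm equiv
  co <- (1:20) - 10
  d <- sqrt(outer(outer(co^2, co^2, `+`), co^2, `+`))
  les[d <= 3 & les == 0L] <- 2L              # 6 mm diameter sphere
  suppressMessages({
    f1 <- filterSmallLesions(les, 4.3, 1)
    f2 <- filterSmallLesions(f1, 4.3, 1)
  })
  expect_equal(attr(f1, "dropped"), 1L)
  expect_equal(attr(f1, "retained"), 2L)
  expect_false(any(f1 == 1L))
  expect_true(any(f1 == 2L))
  expect_equal(as.integer(f2), as.integer(f1))
})

test_that("lesion filtering on a phantom keeps exactly the large lesions", {
  lesions <- list(
    list(center = c(7, 8, 8), radius_mm = 5, bp = 0.28, t1 = FALSE, profile = NULL),
    list(center = c(12, 9, 8), radius_mm = 1.9, bp = 0.23, t1 = FALSE, profile = NULL))
  ph <- buildPhantom(smallPhantomSpec(lesions = lesions))
  suppressMessages(f <- filterSmallLesions(ph$masks$lesionLabels, 4.3, 2))
  expect_equal(attr(f, "retained"), 1L)
  expect_equal(attr(f, "dropped"), 2L)
})

test_that("the impaired-WM cutoff is mean minus 1.96 SD of reference DVR", {
  vals <- array(1.44, c(4, 4, 1))
  vals[1, 1, 1] <- 1.20                    # below cutoff -> impaired
  vals[2, 1, 1] <- 1.23                    # above cutoff -> unaffected
  wm <- array(TRUE, c(4, 4, 1))
  res <- impairedWMMask(vals, wm, refMean = 1.44, refSd = 0.11)
  expect_equal(res$cutoff, 1.44 - 1.96 * 0.11)
  expect_true(res$impaired[1, 1, 1])
  expect_false(res$impaired[2, 1, 1])
  # partition of white matter
  expect_false(any(res$impaired & res$unaffected))
  expect_identical(res$impaired | res$unaffected, wm)
  # constant map at the reference mean: nothing impaired
  resC <- impairedWMMask(array(1.44, c(4, 4, 1)), wm, 1.44, 0.11)
  expect_false(any(resC$impaired))
  expect_error(impairedWMMask(vals, wm, 1.44, 0), "refSd")
})
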