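test_that("perfectly separated and fully overlapping scores bracket the AUC", {
  r <- rocAuc(c(5, 6, 7, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
              direction = "high")
  expect_equal(r@auc, 1)
  expect_equal(r@curve$fpr[1], 0); expect_equal(r@curve$tpr[1], 0)
  expect_equal(utils::tail(r@curve$fpr, 1), 1)
  expect_equal(utils::tail(r@curve$tpr, 1), 1)
  # identical score sets in both classes: all ties, AUC exactly 1/2
  r2 <- rocAuc(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0), direction = "high")
  expect_equal(r2@auc, 0.5)
  expect_error(rocAuc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("trapezoid AUC equals exhaustive concordant-pair counting", {
  pos <- c(1.2, 1.9, 2.3, 2.3, 3.1, 0.8)
  neg <- c(1.0, 1.2, 2.0, 2.6, 0.5, 1.7)
  r <- rocAuc(c(pos, neg), rep(c(TRUE, FALSE), each = 6), direction = "high")
  expect_equal(r@auc, pairCountAuc(pos, neg))   # 6 x 6 = 36 pairs, with ties
  # property: identity holds over random draws with heavy ties
  set.seed(9)
  for (i in 1:25) {
    m <- sample(3:40, 1); n <- sample(3:40, 1)
    sc <- sample(round(rnorm(m + n), 1))        # rounding forces ties
    lb <- c(rep(TRUE, m), rep(FALSE, n))
    r <- rocAuc(sc, lb, direction = "high")
    expect_equal(r@auc, pairCountAuc(sc[lb], sc[!lb]))
    # Mann-Whitney identity through wilcox.test's U statistic
    U <- suppressWarnings(stats::wilcox.test(sc[lb], sc[!lb])$statistic)
    expect_equal(r@auc, unname(U) / (m * n))
  }
})

test_that("lower-is-lesion orientation flips the score sign coherently", {
  sc <- c(1.1, 1.2, 1.15, 1.4, 1.45, 1.38)
  lb <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)   # lesions have LOW DVR
  rLow <- rocAuc(sc, lb, direction = "low")
  expect_equal(rLow@auc, 1)
  rAuto <- rocAuc(sc, lb)
  expect_equal(rAuto@direction, "low")
  expect_equal(rAuto@auc, rLow@auc)
})

test_that("AUC and DeLong variance agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:10) {
    m <- sample(10:60, 1); n <- sample(10:60, 1)
    sc <- c(rnorm(m, 1), rnorm(n))
    lb <- c(rep(1, m), rep(0, n))
    r <- rocAuc(sc, lb, direction = "high")
    pr <- pROC::roc(lb, sc, direction = "<", quiet = TRUE)
    expect_equal(r@auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r@variance, as.numeric(pROC::var(pr, method = "delong")),
                 tolerance = 1e-12)
  }
})

test_that("the paired DeLong test matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (i in 1:10) {
    m <- 40; n <- 50
    lb <- c(rep(1, m), rep(0, n))
    base <- c(rnorm(m, 0.8), rnorm(n))
    s1 <- base + rnorm(m + n, 0, 0.4)
    s2 <- 0.7 * base + rnorm(m + n, 0, 0.6)
    got <- compareAuc(s1, s2, lb, direction = "high")
    ref <- pROC::roc.test(pROC::roc(lb, s1, direction = "<", quiet = TRUE),
                          pROC::roc(lb, s2, direction = "<", quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(got$z, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("comparing a score with itself yields zero difference and p = 1", {
  set.seed(16)
  sc <- rnorm(40); lb <- rep(c(1, 0), 20)
  got <- compareAuc(sc, sc, lb, direction = "high")
  expect_equal(got$delta, 0)
  expect_equal(got$z, 0)
  expect_equal(got$p, 1)
  expect_error(compareAuc(sc, sc[-1], lb), "paired")
})

test_that("the DeLong p-value is consistent with a bootstrap oracle", {
  set.seed(17)
  m <- 60; n <- 60
  lb <- c(rep(TRUE, m), rep(FALSE, n))
  base <- c(rnorm(m, 0.9), rnorm(n))
  s1 <- base + rnorm(m + n, 0, 0.5)
  s2 <- 0.8 * base + rnorm(m + n, 0, 0.8)
  got <- compareAuc(s1, s2, lb, direction = "high")
  B <- 10000L
  auc <- function(s, l) {
    r <- rank(s); (sum(r[l]) - sum(l) * (sum(l) + 1) / 2) / (sum(l) * sum(!l))
  }
  deltaHat <- auc(s1, lb) - auc(s2, lb)
  deltas <- numeric(B)
  for (b in seq_len(B)) {
    ip <- sample(which(lb), m, replace = TRUE)
    im <- sample(which(!lb), n, replace = TRUE)
    i <- c(ip, im); l <- lb[i]
    deltas[b] <- auc(s1[i], l) - auc(s2[i], l)
  }
  # bootstrap z-test of delta = 0 using the resampling SD
  zBoot <- deltaHat / sd(deltas)
  pBoot <- 2 * pnorm(-abs(zBoot))
  expect_equal(got$p, pBoot, tolerance = 0.06)
})

test_that("ROI export produces one row per map and non-empty ROI", {
  vals <- array(1.3, c(4, 4, 2))
  map <- new("ParametricMap", values = vals, quantity = "DVR",
             units = "unitless", provenance = list())
  roiA <- array(FALSE, c(4, 4, 2)); roiA[1:2, 1, 1] <- TRUE
  roiEmpty <- array(FALSE, c(4, 4, 2))
  expect_warning(
    tab <- exportRoiTable(list(dvr = map), list(a = roiA, none = roiEmpty),
                          subject = "s1", voxelSize = 2),
    "omitted")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$mean, roiMean(map, roiA)$mean)
  expect_equal(tab$volume_mm3, 2 * 8)
  # full grid: maps x ROIs rows
  tab2 <- exportRoiTable(list(dvr = map, suv = map),
                         list(a = roiA, b = !roiA), voxelSize = 2)
  expect_equal(nrow(tab2), 4L)
})
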