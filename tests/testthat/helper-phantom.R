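# Shared fixtures and independent oracles, built in code at test time.

defaultScheme <- function() parseFrameScheme("8x15,3x60,5x120,5x300,5x600")

# one-voxel-per-TAC dynamic image (voxels x 1 x 1 x frames)
tacImage <- function(tacs, scheme, voxelSize = 2, decayCorrected = TRUE) {
  if (is.null(dim(tacs))) tacs <- matrix(tacs, nrow = 1)  # voxels x frames
  arr <- array(0, c(nrow(tacs), 1, 1, ncol(tacs)))
  for (f in seq_len(ncol(tacs))) arr[, 1, 1, f] <- tacs[, f]
  dynamicImage(arr, scheme, voxelSize, decayCorrected)
}

# small noiseless phantom reused across modules (16^3, two lesions)
smallPhantomSpec <- function(noiseScale = 0, seed = 1L, lesions = NULL, ...) {
  if (is.null(lesions))
    lesions <- list(list(center = c(7, 8, 8), radius_mm = 4, bp = 0.28,
                         t1 = FALSE, profile = NULL),
                    list(center = c(12, 9, 8), radius_mm = 3, bp = 0.23,
                         t1 = TRUE, profile = NULL))
  phantomSpec(gridShape = c(16, 16, 16), voxelSizeMm = 2,
              brainRadiusMm = 15, wmRadiusMm = 10, lesions = lesions,
              noiseScale = noiseScale, seed = seed, ...)
}

# brute-force all-pairs distance oracle (mm): distance from every voxel to
# the nearest TRUE voxel of `feature`; per-axial-slice when mode = "2d"
bruteDistance <- function(feature, voxelSize, mode = "3d") {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  dm <- dim(feature)
  idx <- which(feature, arr.ind = TRUE)
  out <- array(Inf, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    f <- if (mode == "2d") idx[idx[, 3] == k, , drop = FALSE] else idx
    if (!nrow(f)) next
    d2 <- ((f[, 1] - i) * voxelSize[1])^2 + ((f[, 2] - j) * voxelSize[2])^2 +
      ((f[, 3] - k) * voxelSize[3])^2
    out[i, j, k] <- sqrt(min(d2))
  }
  out
}

# exhaustive concordant-pair AUC oracle with half-credit ties
pairCountAuc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}
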