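# Digital dynamic-PET/MR phantom: a spherical brain with a grey-matter
# shell, a white-matter core, spherical demyelinating lesions with known
# DVR, planted blood-pool voxels, an ASL triplet encoding known CBF, and
# DTI-like scalar maps linearly coupled to true DVR. Everything downstream
# is validated against the ground truth this module emits.

#' Phantom specification
#'
#' All tunable parameters of the digital phantom. Defaults emulate the study
#' conditions: a 90-min multi-frame acquisition, white matter at DVR 1.44
#' (healthy-control value), T2-type lesions near DVR 1.28, 30 planted
#' blood-pool voxels, approximately 300 MBq injected dose and 75 kg body
#' weight, and white-matter CBF of 33.73 ml/100g/min.
#'
#' @slot gridShape integer length 3, voxels per axis.
#' @slot voxelSizeMm isotropic voxel edge length (mm).
#' @slot brainRadiusMm,wmRadiusMm radii of the brain sphere and the
#'   white-matter core (mm); grey matter is the shell between them.
#' @slot frameSchemeSpec compact frame-scheme text (see [parseFrameScheme()]).
#' @slot tissueParams list with \code{gm = list(k1, k2)} (reference kinetics,
#'   1/min) and \code{wm = list(r1, k2, bp)} (reference-tissue-model
#'   parameters; ground-truth DVR = 1 + bp).
#' @slot lesions list of lesions, each \code{list(center, radius_mm, bp, t1,
#'   profile)}: center in (1-based) voxel coordinates, \code{t1} flags
#'   membership of the T1 (black-hole) mask, and \code{profile} is an
#'   optional data.frame \code{(r_mm, bp)} of concentric shells for graded
#'   demyelination (shells with r_mm beyond radius_mm form a perilesional
#'   rim that keeps the WM label but carries the shell's true DVR).
#' @slot bloodVoxels number of pure blood-pool voxels planted in grey matter.
#' @slot noiseScale unitless noise multiplier (0 = noiseless).
#' @slot seed integer RNG seed (required whenever noise is drawn).
#' @slot injectedDoseMBq,bodyWeightKg subject metadata for SUV.
#' @slot cbfParams per-tissue perfusion, ml/100g/min: \code{gm, wm, lesion}.
#' @slot aslParams pCASL generation constants: \code{lambda, t1BloodS, alpha,
#'   tauS, pldS, m0, base, nPairs, noiseSd}.
#' @slot dtiParams per-map \code{c(intercept, slope, sd)} of the linear
#'   DVR-coupling model for \code{fa, md, ad, rd}.
#'
#' @seealso [phantomSpec()], [buildPhantom()]
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSizeMm = "numeric",
                 brainRadiusMm = "numeric", wmRadiusMm = "numeric",
                 frameSchemeSpec = "character", tissueParams = "list",
                 lesions = "list", bloodVoxels = "integer",
                 noiseScale = "numeric", seed = "integer",
                 injectedDoseMBq = "numeric", bodyWeightKg = "numeric",
                 cbfParams = "list", aslParams = "list", dtiParams = "list"),
  validity = function(object) {
    if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
      return("gridShape must be 3 axis lengths >= 4")
    if (object@voxelSizeMm <= 0) return("voxelSizeMm must be > 0")
    if (object@wmRadiusMm >= object@brainRadiusMm)
      return("wmRadiusMm must be smaller than brainRadiusMm")
    sch <- tryCatch(parseFrameScheme(object@frameSchemeSpec),
                    error = function(e) e)
    if (inherits(sch, "error"))
      return(paste("frameSchemeSpec does not parse:", conditionMessage(sch)))
    for (les in object@lesions) {
      if (les$radius_mm <= 0) return("all lesion radii must be > 0")
      if (les$bp < 0) return("lesion bp must be >= 0 (DVR >= 1)")
      if (!is.null(les$profile)) {
        pr <- les$profile
        if (any(diff(pr$r_mm) <= 0)) return("lesion profile r_mm must increase")
        if (any(pr$bp < 0)) return("lesion profile bp must be >= 0")
      }
    }
    if (object@tissueParams$wm$bp < 0) return("wm bp must be >= 0")
    if (object@bloodVoxels < 0L) return("bloodVoxels must be >= 0")
    if (object@noiseScale < 0) return("noiseScale must be >= 0")
    if (object@injectedDoseMBq <= 0 || object@bodyWeightKg <= 0)
      return("injected dose and body weight must be > 0")
    TRUE
  }
)

#' Ground truth of a built phantom
#'
#' @slot dvrMap 3D array of true DVR (NA outside the brain and in pure
#'   blood-pool voxels, which carry no tissue binding).
#' @slot labelMap 3D integer array: 0 background, 1 grey matter, 2 white
#'   matter, 3 blood pool, 10 + k for lesion k. The labels partition the grid.
#' @slot referenceTac noiseless decay-corrected grey-matter TAC (kBq/ml per
#'   frame) - the curve SVCA should recover.
#' @slot cbfMapTrue 3D array of true CBF (ml/100g/min, NA outside brain).
#'
#' @export
setClass("GroundTruth",
  representation(dvrMap = "array", labelMap = "array",
                 referenceTac = "numeric", cbfMapTrue = "array"))

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels @ %g mm, %d lesion(s), noise %g, seed %d\n",
              paste(object@gridShape, collapse = "x"), object@voxelSizeMm,
              length(object@lesions), object@noiseScale, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  tb <- table(object@labelMap)
  cat("GroundTruth labels:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
})

#' Create a phantom specification
#'
#' All arguments have study-condition defaults; see [PhantomSpec-class] for
#' their meaning.
#'
#' @param gridShape,voxelSizeMm,brainRadiusMm,wmRadiusMm grid geometry.
#' @param frameSchemeSpec frame-scheme text.
#' @param tissueParams kinetic parameters per tissue class.
#' @param lesions list of lesion descriptors.
#' @param bloodVoxels,noiseScale,seed simulation controls.
#' @param injectedDoseMBq,bodyWeightKg subject metadata.
#' @param cbfParams,aslParams,dtiParams perfusion/diffusion generation models.
#' @return A validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(noiseScale = 0)
#' ph <- buildPhantom(spec)
#' ph$dynamic
#' @export
phantomSpec <- function(gridShape = c(24L, 24L, 24L), voxelSizeMm = 2,
                        brainRadiusMm = 22, wmRadiusMm = 14,
                        frameSchemeSpec = "8x15,3x60,5x120,5x300,5x600",
                        tissueParams = list(
                          gm = list(k1 = 0.25, k2 = 0.25),
                          wm = list(r1 = 0.85, k2 = 0.2125, bp = 0.44)),
                        lesions = list(
                          list(center = c(10, 12, 12), radius_mm = 5,
                               bp = 0.28, t1 = FALSE, profile = NULL),
                          list(center = c(16, 13, 12), radius_mm = 3,
                               bp = 0.23, t1 = TRUE, profile = NULL)),
                        bloodVoxels = 30L, noiseScale = 0.1, seed = 1L,
                        injectedDoseMBq = 300, bodyWeightKg = 75,
                        cbfParams = list(gm = 60, wm = 33.73, lesion = 30.05),
                        aslParams = list(lambda = 0.9, t1BloodS = 1.65,
                                         alpha = 0.85, tauS = 1.5, pldS = 1.8,
                                         m0 = 1000, base = 500, nPairs = 30L,
                                         noiseSd = 1),
                        dtiParams = list(fa = c(0.10, 0.25, 0.02),
                                         md = c(1.40e-3, -0.40e-3, 5e-5),
                                         ad = c(1.70e-3, -0.30e-3, 5e-5),
                                         rd = c(1.25e-3, -0.45e-3, 5e-5))) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSizeMm = voxelSizeMm, brainRadiusMm = brainRadiusMm,
      wmRadiusMm = wmRadiusMm, frameSchemeSpec = frameSchemeSpec,
      tissueParams = tissueParams, lesions = lesions,
      bloodVoxels = as.integer(bloodVoxels), noiseScale = noiseScale,
      seed = as.integer(seed), injectedDoseMBq = injectedDoseMBq,
      bodyWeightKg = bodyWeightKg, cbfParams = cbfParams,
      aslParams = aslParams, dtiParams = dtiParams)
}

# voxel-center coordinates (mm) relative to the grid center, per axis
.axisCoords <- function(n, vs) (seq_len(n) - (n + 1) / 2) * vs

# 3 arrays of per-voxel center coordinates
.coordArrays <- function(shape, vs) {
  cx <- .axisCoords(shape[1L], vs)
  cy <- .axisCoords(shape[2L], vs)
  cz <- .axisCoords(shape[3L], vs)
  list(x = array(cx, shape),
       y = array(rep(cy, each = shape[1L]), shape),
       z = array(rep(cz, each = shape[1L] * shape[2L]), shape))
}

#' Build the digital phantom
#'
#' Voxelizes the geometry (center-inside sphere tests, so ground truth stays
#' piecewise constant), simulates the per-class TACs, plants exactly
#' \code{bloodVoxels} early-peaking blood-pool voxels in grey matter, removes
#' decay correction (the emitted dynamic image is "as measured"), and adds
#' zero-mean Gaussian frame noise with SD proportional to
#' \code{sqrt(activity / frame_duration)} scaled by \code{noiseScale}.
#' Also emits T2/T1 lesion masks (T1 a subset of T2), tissue masks, a pCASL
#' control/label/M0 triplet whose pairwise difference encodes the true CBF
#' through the inverse of the consensus equation, and FA/MD/AD/RD-like maps
#' linear in true DVR.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements \code{dynamic} ([DynamicImage-class], decay
#'   correction NOT applied), \code{truth} ([GroundTruth-class]),
#'   \code{masks} (brain, gm, wm, t2, t1, lesionLabels), \code{asl}
#'   (control, label, m0), \code{scalarMaps} (fa, md, ad, rd), \code{scheme}
#'   and \code{spec}.
#' @export
buildPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  if (spec@noiseScale > 0 && is.na(spec@seed))
    stop("a seed is required when noiseScale > 0")
  set.seed(spec@seed)

  shape <- spec@gridShape
  vs <- spec@voxelSizeMm
  scheme <- parseFrameScheme(spec@frameSchemeSpec)
  nf <- nFrames(scheme)
  co <- .coordArrays(shape, vs)
  rBrain <- sqrt(co$x^2 + co$y^2 + co$z^2)

  label <- array(0L, shape)
  label[rBrain <= spec@brainRadiusMm] <- 1L    # GM shell
  label[rBrain <= spec@wmRadiusMm] <- 2L       # WM core

  # bp per voxel: NA outside tissue; GM bp 0 (reference), WM bp from spec
  wmBp <- spec@tissueParams$wm$bp
  bpMap <- array(NA_real_, shape)
  bpMap[label == 1L] <- 0
  bpMap[label == 2L] <- wmBp

  # lesion cores (and optional graded shells / perilesional rims)
  for (k in seq_along(spec@lesions)) {
    les <- spec@lesions[[k]]
    ctr <- (les$center - (shape + 1) / 2) * vs
    d <- sqrt((co$x - ctr[1L])^2 + (co$y - ctr[2L])^2 + (co$z - ctr[3L])^2)
    core <- d <= les$radius_mm
    if (any(label[core] != 2L))
      stop(sprintf("lesion %d extends outside the white-matter compartment", k))
    label[core] <- 10L + k
    bpMap[core] <- les$bp
    if (!is.null(les$profile)) {
      pr <- les$profile
      lower <- c(0, pr$r_mm[-nrow(pr)])
      for (s in seq_len(nrow(pr))) {
        shell <- d > lower[s] & d <= pr$r_mm[s]
        if (pr$r_mm[s] <= les$radius_mm) {           # graded core shell
          bpMap[shell] <- pr$bp[s]
        } else {                                      # perilesional rim
          shell <- shell & label == 2L
          if (any(rBrain[shell] > spec@wmRadiusMm))
            stop(sprintf("rim of lesion %d extends outside white matter", k))
          bpMap[shell] <- pr$bp[s]
        }
      }
    }
  }

  # plant blood-pool voxels in grey matter
  gmIdx <- which(label == 1L)
  if (spec@bloodVoxels > 0L) {
    if (length(gmIdx) < spec@bloodVoxels)
      stop("not enough grey-matter voxels to plant blood pool")
    bloodIdx <- sort(sample(gmIdx, spec@bloodVoxels))
    label[bloodIdx] <- 3L
    bpMap[bloodIdx] <- NA_real_
  }

  # --- kinetics: one TAC per distinct (tissue-kind, bp) ---
  gmPar <- spec@tissueParams$gm
  wmPar <- spec@tissueParams$wm
  refFun <- referenceCurve(gmPar$k1, gmPar$k2)
  refTac <- simulateReferenceTAC(gmPar$k1, gmPar$k2, scheme)
  bloodTac <- .frameAverage(fengInput()(.fineGrid(scheme) / 60), scheme)

  key <- array("", shape)
  key[label == 1L] <- "gm"
  key[label == 3L] <- "blood"
  tis <- label == 2L | label >= 10L
  key[tis] <- sprintf("bp%.8f", bpMap[tis])

  tacs <- list(gm = refTac, blood = bloodTac)
  for (kk in setdiff(unique(key[key != ""]), c("gm", "blood"))) {
    bp <- as.numeric(sub("bp", "", kk))
    tacs[[kk]] <- if (bp == 0) refTac else
      simulateTargetTAC(refFun, wmPar$r1, wmPar$k2, bp, scheme)
  }

  data <- array(0, c(shape, nf))
  nvox <- prod(shape)
  for (kk in names(tacs)) {
    idx <- which(key == kk)
    if (!length(idx)) next
    for (f in seq_len(nf)) data[idx + (f - 1L) * nvox] <- tacs[[kk]][f]
  }

  # remove decay correction: emitted image is what the scanner measures
  dfac <- decayFactors(scheme)
  data <- data / rep(dfac, each = nvox)

  if (spec@noiseScale > 0) {
    durMin <- rep(frameDuration(scheme) / 60, each = nvox)
    sd <- spec@noiseScale * sqrt(pmax(data, 0) / durMin)
    data <- data + array(stats::rnorm(length(data), 0, sd), dim(data))
  }

  dyn <- dynamicImage(data, scheme, vs, decayCorrected = FALSE)

  # --- masks ---
  lesionLabels <- array(0L, shape)
  for (k in seq_along(spec@lesions)) lesionLabels[label == 10L + k] <- k
  t2 <- lesionLabels > 0L
  t1 <- array(FALSE, shape)
  for (k in seq_along(spec@lesions))
    if (isTRUE(spec@lesions[[k]]$t1)) t1[lesionLabels == k] <- TRUE
  masks <- list(brain = label > 0L, gm = label == 1L,
                wm = label == 2L | t2, t2 = t2, t1 = t1,
                lesionLabels = lesionLabels)

  # --- ground-truth maps ---
  dvr <- array(NA_real_, shape)
  dvr[!is.na(bpMap)] <- 1 + bpMap[!is.na(bpMap)]
  cbfTrue <- array(NA_real_, shape)
  cbfTrue[label == 1L | label == 3L] <- spec@cbfParams$gm
  cbfTrue[label == 2L] <- spec@cbfParams$wm
  cbfTrue[label >= 10L] <- spec@cbfParams$lesion
  truth <- new("GroundTruth", dvrMap = dvr, labelMap = label,
               referenceTac = refTac, cbfMapTrue = cbfTrue)

  # --- ASL triplet encoding cbfTrue through the inverse consensus model ---
  ap <- spec@aslParams
  m0 <- array(0, shape)
  m0[label > 0L] <- ap$m0
  cbf0 <- ifelse(is.na(cbfTrue), 0, cbfTrue)
  dM <- cbfToDeltaM(cbf0, m0, lambda = ap$lambda, t1BloodS = ap$t1BloodS,
                    alpha = ap$alpha, tauS = ap$tauS, pldS = ap$pldS)
  nP <- ap$nPairs
  control <- array(ap$base, c(shape, nP)) + array(dM, c(shape, nP))
  lab4d <- array(ap$base, c(shape, nP))
  if (spec@noiseScale > 0 && ap$noiseSd > 0) {
    s <- spec@noiseScale * ap$noiseSd
    control <- control + array(stats::rnorm(length(control), 0, s), dim(control))
    lab4d <- lab4d + array(stats::rnorm(length(lab4d), 0, s), dim(lab4d))
  }

  # --- DTI-like maps linear in true DVR ---
  scalarMaps <- lapply(spec@dtiParams, function(p) {
    m <- p[1L] + p[2L] * dvr
    if (spec@noiseScale > 0 && p[3L] > 0)
      m <- m + array(stats::rnorm(length(m), 0, spec@noiseScale * p[3L]), shape)
    m
  })

  list(dynamic = dyn, truth = truth, masks = masks,
       asl = list(control = control, label = lab4d, m0 = m0),
       scalarMaps = scalarMaps, scheme = scheme, spec = spec)
}
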