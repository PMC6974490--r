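# Frame-scheme arithmetic, F-18 decay correction and window averaging.
# All disk/time metadata is in seconds from injection; kinetic math uses
# frame midpoints in minutes.

#' Half-life of Fluorine-18 in minutes
#' @export
F18_HALF_LIFE_MIN <- 109.77

#' Construct a frame scheme
#'
#' @param start_s per-frame start times (s from injection); first must be 0.
#' @param duration_s per-frame durations (s).
#' @return A [FrameScheme-class].
#' @export
frameScheme <- function(start_s, duration_s) {
  new("FrameScheme", start_s = as.numeric(start_s),
      duration_s = as.numeric(duration_s))
}

#' Parse a compact frame-scheme specification
#'
#' Expands a text like \code{"8x15,3x60,5x120,5x300,5x600"} (count x
#' duration-in-seconds groups) into contiguous frames starting at injection.
#' The default study scheme \code{"8x15,3x60,5x120,5x300,5x600"} expands to
#' 26 frames covering 90 min.
#'
#' @param text scheme text, comma-separated \code{countxseconds} groups.
#' @return A [FrameScheme-class].
#' @examples
#' sch <- parseFrameScheme("8x15,3x60,5x120,5x300,5x600")
#' nFrames(sch)        # 26
#' totalDuration(sch)  # 5400 s = 90 min
#' @export
parseFrameScheme <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  groups <- strsplit(trimws(text), ",", fixed = TRUE)[[1L]]
  if (!length(groups)) stop("empty frame-scheme specification")
  durs <- unlist(lapply(groups, function(g) {
    m <- regmatches(g, regexec("^\\s*([0-9]+)\\s*[xX]\\s*([0-9.]+)\\s*$", g))[[1L]]
    if (length(m) != 3L) stop("malformed frame group: '", g,
                              "' (expected countxseconds, e.g. 8x15)")
    n <- as.integer(m[2L]); d <- as.numeric(m[3L])
    if (n < 1L || !is.finite(d) || d <= 0)
      stop("frame group '", g, "' must have count >= 1 and duration > 0")
    rep(d, n)
  }))
  frameScheme(cumsum(c(0, durs[-length(durs)])), durs)
}

#' Format a frame scheme back to its compact text form
#'
#' Inverse of [parseFrameScheme()] on valid schemes: runs of equal-duration
#' frames are compressed to \code{countxseconds} groups.
#'
#' @param scheme a [FrameScheme-class].
#' @return A single string.
#' @export
formatFrameScheme <- function(scheme) {
  d <- scheme@duration_s
  r <- rle(d)
  paste(sprintf("%dx%s", r$lengths, format(r$values, trim = TRUE)),
        collapse = ",")
}

#' @describeIn frameScheme Number of frames.
#' @param scheme a [FrameScheme-class].
#' @export
nFrames <- function(scheme) length(scheme@start_s)

#' @describeIn frameScheme Total scan duration in seconds.
#' @export
totalDuration <- function(scheme) {
  n <- nFrames(scheme)
  scheme@start_s[n] + scheme@duration_s[n]
}

#' @describeIn frameScheme Frame midpoints in minutes from injection.
#' @export
frameMid <- function(scheme) (scheme@start_s + scheme@duration_s / 2) / 60

#' @describeIn frameScheme Frame start times in seconds.
#' @export
frameStart <- function(scheme) scheme@start_s

#' @describeIn frameScheme Frame durations in seconds.
#' @export
frameDuration <- function(scheme) scheme@duration_s

#' Construct a dynamic image
#'
#' @param data 4D array (x, y, z, frame), activity concentration in kBq/ml.
#' @param scheme the [FrameScheme-class].
#' @param voxelSize voxel edge lengths in mm (length 1 or 3).
#' @param decayCorrected has decay correction been applied already?
#' @return A [DynamicImage-class].
#' @export
dynamicImage <- function(data, scheme, voxelSize, decayCorrected = FALSE) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("DynamicImage", data = data, scheme = scheme,
      voxelSize = as.numeric(voxelSize),
      decayCorrected = as.logical(decayCorrected))
}

#' Per-frame decay-correction factors
#'
#' \code{exp(lambda * t_mid)} with \code{lambda = ln(2) / half-life},
#' referenced to injection time (t = 0), evaluated at frame midpoints.
#'
#' @param scheme a [FrameScheme-class].
#' @param halfLifeMin isotope half-life in minutes (default F-18).
#' @return Numeric vector, one factor per frame.
#' @export
decayFactors <- function(scheme, halfLifeMin = F18_HALF_LIFE_MIN) {
  stopifnot(halfLifeMin > 0)
  exp(log(2) / halfLifeMin * frameMid(scheme))
}

#' Apply radioactive-decay correction to a dynamic image
#'
#' Multiplies every frame by \code{exp(lambda * t_mid)} referenced to the
#' injection time. The operation is guarded by the image's
#' \code{decayCorrected} flag and refuses to run twice.
#'
#' @param img a [DynamicImage-class] with \code{decayCorrected = FALSE}.
#' @param halfLifeMin isotope half-life in minutes (default F-18, 109.77).
#' @return The corrected [DynamicImage-class] (flag set).
#' @export
decayCorrect <- function(img, halfLifeMin = F18_HALF_LIFE_MIN) {
  stopifnot(is(img, "DynamicImage"))
  if (img@decayCorrected)
    stop("image is already decay-corrected; refusing to correct twice")
  f <- decayFactors(img@scheme, halfLifeMin)
  img@data <- img@data * rep(f, each = prod(dim(img@data)[1:3]))
  img@decayCorrected <- TRUE
  img
}

#' Duration-weighted average over a time window
#'
#' Averages all frames whose midpoints fall in the half-open window
#' \code{[t0, t1)} minutes, weighting by frame duration. This is how the
#' late static image (e.g. 70-90 min) for SUV mapping is formed.
#'
#' @param img a [DynamicImage-class].
#' @param t0Min,t1Min window bounds in minutes from injection.
#' @return 3D numeric array, same units as the input (kBq/ml).
#' @export
windowAverage <- function(img, t0Min, t1Min) {
  stopifnot(is(img, "DynamicImage"), t1Min > t0Min)
  mid <- frameMid(img@scheme)
  sel <- which(mid >= t0Min & mid < t1Min)
  if (!length(sel))
    stop(sprintf("no frame midpoint falls in [%g, %g) min", t0Min, t1Min))
  w <- frameDuration(img@scheme)[sel]
  w <- w / sum(w)
  dm <- dim(img@data)
  out <- array(0, dm[1:3])
  for (i in seq_along(sel)) out <- out + w[i] * img@data[, , , sel[i]]
  out
}
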