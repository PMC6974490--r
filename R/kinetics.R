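# Compartmental kinetics for the digital phantom: analytic plasma input,
# one-tissue reference curve (closed form), and reference-tissue target
# curves via convolution on a fine time grid.

#' Tri-exponential analytic plasma input
#'
#' A Feng-style arterial input function
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3) e^{-l_1 t} + A_2 e^{-l_2 t} + A_3 e^{-l_3 t}}
#' with t in minutes. The default coefficients give a realistic bolus shape
#' (sharp peak around 15 s, slow tail), scaled so that tissue curves land in
#' the few-kBq/ml range typical of brain PET. The absolute scale is
#' irrelevant to DVR/SUVR-type ratios.
#'
#' @param A amplitudes (A1 in kBq/ml/min, A2, A3 in kBq/ml).
#' @param lambda decay rates in 1/min, decreasing.
#' @return A function of time in minutes returning kBq/ml (vectorised).
#' @export
fengInput <- function(A = c(851.1, 21.88, 20.81) * 0.05,
                      lambda = c(4.1339, 0.1191, 0.01043)) {
  stopifnot(length(A) == 3L, length(lambda) == 3L, all(lambda > 0))
  force(A); force(lambda)
  function(tMin) {
    tMin <- pmax(tMin, 0)
    (A[1L] * tMin - A[2L] - A[3L]) * exp(-lambda[1L] * tMin) +
      A[2L] * exp(-lambda[2L] * tMin) +
      A[3L] * exp(-lambda[3L] * tMin)
  }
}

# exact response of dC/dt = k1*Cp - k2*C to one input term c*exp(-l*t):
# E(l, t) = (exp(-l t) - exp(-k2 t)) / (k2 - l), degenerate limit t*exp(-l t)
.expResponse <- function(l, k2, tMin) {
  a <- k2 - l
  if (abs(a) < 1e-9) tMin * exp(-l * tMin)
  else (exp(-l * tMin) - exp(-k2 * tMin)) / a
}

# response to the ramp term A1 * t * exp(-l t)
.rampResponse <- function(l, k2, tMin) {
  a <- k2 - l
  if (abs(a) < 1e-9) tMin^2 / 2 * exp(-l * tMin)
  else exp(-l * tMin) * (tMin / a - 1 / a^2) + exp(-k2 * tMin) / a^2
}

#' Instantaneous one-tissue curve driven by the analytic input
#'
#' Closed-form solution of \code{dC/dt = k1 Cp(t) - k2 C(t)}, C(0) = 0, for a
#' tri-exponential input; used as the noiseless reference-tissue kinetic.
#'
#' @param k1 influx rate (1/min), >= 0.
#' @param k2 efflux rate (1/min), > 0.
#' @param A,lambda input coefficients as in [fengInput()].
#' @return A function of time in minutes returning kBq/ml (vectorised).
#' @export
referenceCurve <- function(k1, k2, A = c(851.1, 21.88, 20.81) * 0.05,
                           lambda = c(4.1339, 0.1191, 0.01043)) {
  if (k1 < 0) stop("k1 must be >= 0")
  if (k2 <= 0) stop("k2 must be > 0")
  force(k1); force(k2); force(A); force(lambda)
  function(tMin) {
    tMin <- pmax(tMin, 0)
    k1 * (A[1L] * .rampResponse(lambda[1L], k2, tMin) -
            (A[2L] + A[3L]) * .expResponse(lambda[1L], k2, tMin) +
            A[2L] * .expResponse(lambda[2L], k2, tMin) +
            A[3L] * .expResponse(lambda[3L], k2, tMin))
  }
}

# fine time grid (seconds) covering a scheme, step dtS
.fineGrid <- function(scheme, dtS = 1) seq(0, totalDuration(scheme), by = dtS)

# trapezoidal frame averages of a curve sampled on the fine grid
.frameAverage <- function(values, scheme, dtS = 1) {
  s0 <- frameStart(scheme)
  s1 <- s0 + frameDuration(scheme)
  vapply(seq_len(nFrames(scheme)), function(f) {
    i0 <- round(s0[f] / dtS) + 1L
    i1 <- round(s1[f] / dtS) + 1L
    v <- values[i0:i1]
    (sum(v) - (v[1L] + v[length(v)]) / 2) / (i1 - i0)
  }, numeric(1L))
}

#' Simulate the frame-averaged reference-tissue TAC
#'
#' Evaluates the closed-form one-tissue curve of [referenceCurve()] on a fine
#' internal grid (default 1 s) and averages it over each frame interval by
#' the trapezoidal rule, mimicking what the scanner measures.
#'
#' @param k1 influx rate (1/min), >= 0 (0 gives an all-zero TAC).
#' @param k2 efflux rate (1/min), > 0.
#' @param scheme a [FrameScheme-class].
#' @param input optional plasma-input function of minutes; when supplied the
#'   curve is obtained by fine-grid convolution instead of the closed form
#'   (an identically-zero input gives an all-zero TAC).
#' @param fineDtS internal grid step in seconds.
#' @return Numeric TAC, one kBq/ml value per frame.
#' @export
simulateReferenceTAC <- function(k1, k2, scheme, input = NULL, fineDtS = 1) {
  stopifnot(is(scheme, "FrameScheme"))
  if (k1 < 0) stop("k1 must be >= 0")
  if (k2 <= 0) stop("k2 must be > 0")
  tS <- .fineGrid(scheme, fineDtS)
  if (is.null(input)) {
    fine <- referenceCurve(k1, k2)(tS / 60)
  } else {
    cp <- input(tS / 60)
    fine <- k1 * .expConvolve(cp, k2, fineDtS / 60)
  }
  .frameAverage(fine, scheme, fineDtS)
}

# causal convolution of a sampled curve with exp(-k*t) by exact recursive
# update assuming the curve is piecewise linear on the grid (dtMin in min)
.expConvolve <- function(values, k, dtMin) {
  n <- length(values)
  out <- numeric(n)
  e <- exp(-k * dtMin)
  h <- dtMin / 2
  for (i in 2:n) out[i] <- out[i - 1L] * e + h * (values[i - 1L] * e + values[i])
  out
}

#' Simulate a target-tissue TAC under the simplified reference-tissue model
#'
#' \deqn{C_t(t) = R_1 C_{ref}(t) + (k_2 - R_1 k_{2a}) \int_0^t C_{ref}(s)
#'   e^{-k_{2a}(t-s)} ds, \quad k_{2a} = k_2 / (1 + BP_{nd})}
#' so the ground-truth distribution volume ratio is \code{1 + bpNd}.
#' The convolution is computed on a fine internal grid (default 1 s) and the
#' instantaneous curve is then frame-averaged.
#'
#' @param ref the reference kinetic: either a function of minutes
#'   (instantaneous curve) or a numeric per-frame TAC on \code{scheme}
#'   (linearly interpolated at frame midpoints, anchored at C(0) = 0).
#' @param r1 relative delivery R1 (unitless, > 0).
#' @param k2 target efflux rate (1/min, > 0).
#' @param bpNd non-displaceable binding potential (>= 0).
#' @param scheme a [FrameScheme-class].
#' @param fineDtS internal grid step in seconds.
#' @return Numeric TAC, one kBq/ml value per frame.
#' @export
simulateTargetTAC <- function(ref, r1, k2, bpNd, scheme, fineDtS = 1) {
  stopifnot(is(scheme, "FrameScheme"))
  if (bpNd < 0) stop("bpNd must be >= 0")
  if (r1 <= 0 || k2 <= 0) stop("r1 and k2 must be > 0")
  tS <- .fineGrid(scheme, fineDtS)
  if (is.function(ref)) {
    refFine <- ref(tS / 60)
  } else {
    if (length(ref) != nFrames(scheme))
      stop("per-frame ref TAC length does not match the scheme")
    refFine <- stats::approx(c(0, frameMid(scheme) * 60), c(0, ref),
                             xout = tS, rule = 2)$y
  }
  k2a <- k2 / (1 + bpNd)
  conv <- .expConvolve(refFine, k2a, fineDtS / 60)
  fine <- r1 * refFine + (k2 - r1 * k2a) * conv
  .frameAverage(fine, scheme, fineDtS)
}
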