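#' Well-mixed loop dilution model
#'
#' In the flow phantom, a loop of tubing initially filled with a
#' microbubble suspension is pumped continuously while bubble-free liquid
#' is drawn in through an input valve, so the circulating concentration
#' decays approximately exponentially: \eqn{C(t) = C_1 e^{-Dt}}.
#'
#' The decay constant \eqn{D} is the primary parameter, matching how
#' experimental runs are reported (e.g. \eqn{D = 0.056\,\mathrm{s}^{-1}} at
#' a pump rate of 80 ml/min). As a documented convenience, \eqn{D} may
#' instead be computed from the loop parameters with the well-mixed
#' single-compartment assumption \eqn{D = R\,Q/(V_p + V_l)} -- see
#' [decay_constant()] -- where \eqn{Q} is the pump flow rate,
#' \eqn{V_p}/\eqn{V_l} the loop volumes either side of the junctions and
#' \eqn{R} the output-to-pump flow-rate ratio set by the pinch valve.
#'
#' @param C1 initial volume concentration (gas volume fraction).
#' @param D decay constant, 1/s; if \code{NULL}, computed from
#'   \code{Q, V_p, V_l, R}.
#' @param Q pump flow rate, ml/s.
#' @param V_p,V_l loop tubing volumes, ml (defaults 2.3 and 2.8).
#' @param R output-to-pump flow-rate ratio, in [0, 1].
#' @return object of class \code{dilution_model} with fields \code{C1},
#'   \code{D} and \code{mode} (\code{"direct"} or \code{"well_mixed"}).
#' @examples
#' dilution_model(C1 = 0.01, D = 0.056)
#' dilution_model(C1 = 0.01, Q = 250 / 60, R = 0.2)
#' @export
dilution_model <- function(C1 = 0.01, D = NULL, Q = NULL, V_p = 2.3,
                           V_l = 2.8, R = NULL) {
  stopifnot(C1 >= 0)
  if (!is.null(D)) {
    stopifnot(D >= 0)
    mode <- "direct"
  } else {
    if (is.null(Q) || is.null(R)) {
      stop("supply either D directly or all of Q and R ",
           "(with V_p, V_l) for the well-mixed formula")
    }
    D <- decay_constant(Q, V_p, V_l, R)
    mode <- "well_mixed"
  }
  structure(
    list(C1 = C1, D = D, Q = Q, V_p = V_p, V_l = V_l, R = R, mode = mode),
    class = "dilution_model"
  )
}

#' @export
print.dilution_model <- function(x, ...) {
  cat(sprintf("<dilution: C1 = %.4g, D = %.4g 1/s (%s)>\n",
              x$C1, x$D, x$mode))
  invisible(x)
}

#' Decay constant from loop parameters (well-mixed assumption)
#'
#' \eqn{D = R\,Q/(V_p + V_l)}: the loop (total volume \eqn{V_p + V_l}) is
#' treated as a single well-stirred compartment flushed at the rate
#' \eqn{R\,Q} at which fresh bubble-free liquid enters. This
#' single-compartment form is an explicit modelling assumption of this
#' package, not a published result; supply \code{D} directly to
#' [dilution_model()] to bypass it.
#'
#' @param Q pump flow rate, ml/s.
#' @param V_p,V_l loop volumes, ml.
#' @param R output-to-pump flow-rate ratio, dimensionless in [0, 1].
#' @return decay constant, 1/s.
#' @examples
#' decay_constant(Q = 250 / 60, V_p = 2.3, V_l = 2.8, R = 0.2)  # ~0.163
#' @export
decay_constant <- function(Q, V_p = 2.3, V_l = 2.8, R) {
  stopifnot(Q >= 0, V_p >= 0, V_l >= 0, R >= 0, R <= 1)
  if (V_p + V_l <= 0) stop("V_p + V_l must be positive")
  R * Q / (V_p + V_l)
}

#' Concentration at time t
#'
#' @param model a [dilution_model()].
#' @param t time(s) since valve opening, s (vectorized, nonnegative).
#' @return \eqn{C_1 e^{-Dt}}.
#' @export
concentration_at <- function(model, t) {
  stopifnot(inherits(model, "dilution_model"))
  if (any(t < 0)) stop("t must be nonnegative")
  model$C1 * exp(-model$D * t)
}

#' Acquisition timing
#'
#' @param exposure_s exposure time per frame (default 0.5 s).
#' @param readout_s detector readout time (default 0.27 s); together these
#'   give the 0.77 s frame period of the binned CCD.
#' @return object of class \code{acquisition_timing}.
#' @export
acquisition_timing <- function(exposure_s = 0.5, readout_s = 0.27) {
  if (exposure_s < 0 || readout_s < 0) {
    stop("exposure_s and readout_s must be nonnegative")
  }
  structure(list(exposure_s = exposure_s, readout_s = readout_s),
            class = "acquisition_timing")
}

#' Frame period (exposure + readout)
#'
#' @param timing an [acquisition_timing()].
#' @return frame period in s.
#' @export
frame_period <- function(timing) {
  stopifnot(inherits(timing, "acquisition_timing"))
  timing$exposure_s + timing$readout_s
}

#' Mid-exposure frame times
#'
#' Frame k (k = 0, 1, ...) is stamped at its mid-exposure time
#' \code{t0 + k * frame_period + exposure/2}, which pairs each intensity
#' with the concentration at the middle of its integration window and
#' minimizes bias from decay within a frame.
#'
#' @param timing an [acquisition_timing()].
#' @param n_frames number of frames (>= 1).
#' @param t0 acquisition start time, s.
#' @return numeric vector of length \code{n_frames}.
#' @export
frame_times <- function(timing, n_frames, t0 = 0) {
  stopifnot(inherits(timing, "acquisition_timing"))
  if (n_frames < 1) stop("n_frames must be >= 1")
  t0 + (seq_len(n_frames) - 1) * frame_period(timing) + timing$exposure_s / 2
}
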