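#' Ground-truth kinetic parameters for the hyperpolarized pyruvate system
#'
#' Describes the unidirectional first-order label-flux model used by the
#' simulator: pyruvate magnetization is driven by a parametric injection
#' input, decays with an effective rate \code{rho_p} (longitudinal relaxation
#' plus outflow), and feeds each downstream pool x (lactate, alanine,
#' bicarbonate, ...) with rate \code{k_px}; each product pool decays with its
#' own effective rate \code{rho_x} which lumps relaxation and any back-flux.
#' PDH-derived label is split between bicarbonate and CO2 by
#' \code{co2_bicarbonate_ratio}.
#'
#' Default rates are representative of in-vivo rodent heart hyperpolarized
#' pyruvate experiments (rates of order 0.005--0.02 s^-1, effective decay
#' times of order 20--30 s).
#'
#' @param k_px Named numeric vector of label-flux rate constants (s^-1), one
#'   per downstream metabolite, e.g. \code{c(lactate = 0.015, ...)}. The
#'   special name \code{"pdh"} is expanded into bicarbonate and CO2 pools
#'   according to \code{co2_bicarbonate_ratio}.
#' @param rho_x Effective decay rate(s) of the product pools (s^-1); a single
#'   value is recycled.
#' @param rho_p Effective decay rate of pyruvate excluding conversion (s^-1).
#' @param input_start,input_duration,input_amplitude Trapezoidal injection
#'   input: label arrives between \code{input_start} and
#'   \code{input_start + input_duration} (seconds) with linear ramps over
#'   \code{ramp_fraction} of the duration at each end and peak rate
#'   \code{input_amplitude} (arbitrary units / s).
#' @param ramp_fraction Fraction of the injection spent ramping up (and down).
#' @param co2_bicarbonate_ratio Fraction of PDH-derived label observed as CO2
#'   rather than bicarbonate, in [0, 1].
#' @return An object of class \code{"kinetic_truth"}.
#' @examples
#' kinetic_truth()
#' @export
kinetic_truth <- function(k_px = c(lactate = 0.015, alanine = 0.008,
                                   pdh = 0.008),
                          rho_x = 1 / 25,
                          rho_p = 0.05,
                          input_start = 0,
                          input_duration = 10,
                          input_amplitude = 1,
                          ramp_fraction = 0.2,
                          co2_bicarbonate_ratio = 0.1) {
  stop_if_not_finite(c(k_px, rho_x, rho_p, input_start, input_duration,
                       input_amplitude, co2_bicarbonate_ratio),
                     "kinetic parameters")
  stopifnot(all(k_px >= 0), all(rho_x >= 0), rho_p >= 0,
            input_duration > 0, input_amplitude >= 0,
            co2_bicarbonate_ratio >= 0, co2_bicarbonate_ratio <= 1,
            ramp_fraction >= 0, ramp_fraction <= 0.5)
  if (is.null(names(k_px)) || any(!nzchar(names(k_px))))
    stop("k_px must be a named vector", call. = FALSE)
  if ("pdh" %in% names(k_px)) {
    k_pdh <- k_px[["pdh"]]
    k_px <- k_px[names(k_px) != "pdh"]
    k_px <- c(k_px,
              bicarbonate = unname(k_pdh * (1 - co2_bicarbonate_ratio)),
              co2 = unname(k_pdh * co2_bicarbonate_ratio))
  }
  rho_x <- rep_len(rho_x, length(k_px))
  names(rho_x) <- names(k_px)
  structure(list(
    k_px = k_px, rho_x = rho_x, rho_p = rho_p,
    input_start = input_start, input_duration = input_duration,
    input_amplitude = input_amplitude, ramp_fraction = ramp_fraction,
    co2_bicarbonate_ratio = co2_bicarbonate_ratio
  ), class = "kinetic_truth")
}

# Trapezoidal injection rate u(t) (arbitrary units per second).
injection_input <- function(truth) {
  t0 <- truth$input_start
  dur <- truth$input_duration
  a <- truth$input_amplitude
  r <- truth$ramp_fraction * dur
  function(t) {
    s <- t - t0
    out <- numeric(length(t))
    if (r > 0) {
      up <- s >= 0 & s < r
      out[up] <- a * s[up] / r
      down <- s > dur - r & s <= dur
      out[down] <- a * (dur - s[down]) / r
      flat <- s >= r & s <= dur - r
      out[flat] <- a
    } else {
      out[s >= 0 & s <= dur] <- a
    }
    out
  }
}

#' Simulate longitudinal magnetization of the pyruvate system
#'
#' Integrates the first-order label-flux model between excitations with a
#' fixed-step 4th-order Runge-Kutta scheme and applies the instantaneous
#' cos(flip) polarization loss of each excitation pulse to every pool.
#' The model is
#' \deqn{dM_p/dt = u(t) - (\rho_p + \sum_x k_{px}) M_p,\qquad
#'       dM_x/dt = k_{px} M_p - \rho_x M_x,}
#' so that with all decay rates and the flip angle at zero the total
#' magnetization is conserved once the injection has finished.
#'
#' @param truth A \code{\link{kinetic_truth}} object.
#' @param acq An \code{\link{acquisition_params}} object.
#' @param n_substeps Runge-Kutta sub-steps per repetition interval.
#' @param initial Optional named initial magnetizations (default: all zero at
#'   the earlier of time 0 and the injection start).
#' @return A matrix [n_repetitions x n_pools] of pre-excitation longitudinal
#'   magnetizations with column names \code{pyruvate} then the product pools,
#'   and attribute \code{time} (seconds, first excitation at 0).
#' @examples
#' m <- simulate_kinetics(kinetic_truth(), acquisition_params())
#' dim(m)
#' @export
simulate_kinetics <- function(truth, acq, n_substeps = 10, initial = NULL) {
  stopifnot(inherits(truth, "kinetic_truth"),
            inherits(acq, "acquisition_params"), n_substeps >= 1)
  pools <- c("pyruvate", names(truth$k_px))
  np <- length(pools)
  k <- truth$k_px
  rho <- c(truth$rho_p + sum(k), truth$rho_x)  # total removal rate per pool
  u <- injection_input(truth)
  cosf <- cos(acq$flip_angle * pi / 180)

  deriv <- function(t, M) {
    dp <- u(t) - rho[1] * M[1]
    dx <- k * M[1] - truth$rho_x * M[-1]
    c(dp, dx)
  }
  rk4_step <- function(t, M, h) {
    k1 <- deriv(t, M)
    k2 <- deriv(t + h / 2, M + h / 2 * k1)
    k3 <- deriv(t + h / 2, M + h / 2 * k2)
    k4 <- deriv(t + h, M + h * k3)
    M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  M <- numeric(np)
  names(M) <- pools
  if (!is.null(initial)) M[names(initial)] <- initial

  # burn-in from injection start to the first excitation, if it precedes it
  t <- min(0, truth$input_start)
  if (t < 0) {
    h <- acq$repetition_time / n_substeps
    while (t < -1e-12) {
      step <- min(h, -t)
      M <- rk4_step(t, M, step)
      t <- t + step
    }
    t <- 0
  }

  out <- matrix(NA_real_, acq$n_repetitions, np,
                dimnames = list(NULL, pools))
  h <- acq$repetition_time / n_substeps
  for (rep in seq_len(acq$n_repetitions)) {
    out[rep, ] <- M            # pre-excitation magnetization
    M <- M * cosf              # RF depletion of every pool
    if (rep < acq$n_repetitions) {
      for (s in seq_len(n_substeps)) {
        M <- rk4_step(t, M, h)
        t <- t + h
      }
    }
  }
  attr(out, "time") <- (seq_len(acq$n_repetitions) - 1) * acq$repetition_time
  out
}
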