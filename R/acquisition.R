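#' Acquisition parameters for a dynamic pulse-acquire 13C experiment
#'
#' Bundles the acquisition settings of an ECG-gated dynamic hyperpolarized
#' 13C pulse-acquire series. Defaults correspond to a typical 7 T cardiac
#' protocol: 60 repetitions at TR 1 s, 5 degree excitation, sweep width
#' 13593 Hz, 2048 complex points.
#'
#' @param repetition_time Repetition time in seconds (> 0).
#' @param flip_angle Excitation flip angle in degrees, in (0, 90).
#'   A value of 0 is accepted for simulation-only "no readout" experiments.
#' @param sweep_width Spectral sweep width in Hz (> 0). The dwell time of the
#'   sampled free induction decay is \code{1 / sweep_width}.
#' @param n_points Number of complex points per free induction decay (>= 2).
#' @param n_repetitions Number of repetitions (>= 1).
#' @param reference_frequency 13C reference frequency in MHz (7 T default).
#'
#' @return An object of class \code{"acquisition_params"}: a list with the
#'   above fields plus \code{dwell_time}.
#' @examples
#' acq <- acquisition_params()
#' acq$dwell_time * acq$sweep_width  # == 1
#' @export
acquisition_params <- function(repetition_time = 1,
                               flip_angle = 5,
                               sweep_width = 13593,
                               n_points = 2048,
                               n_repetitions = 60,
                               reference_frequency = 75.46) {
  stopifnot(
    is.numeric(repetition_time), repetition_time > 0,
    is.numeric(flip_angle), flip_angle >= 0, flip_angle < 90,
    is.numeric(sweep_width), sweep_width > 0,
    n_points >= 2, n_repetitions >= 1
  )
  structure(list(
    repetition_time = repetition_time,
    flip_angle = flip_angle,
    sweep_width = sweep_width,
    n_points = as.integer(n_points),
    n_repetitions = as.integer(n_repetitions),
    reference_frequency = reference_frequency,
    dwell_time = 1 / sweep_width
  ), class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "Acquisition: %d repetitions, TR %g s, flip %g deg, SW %g Hz, %d points\n",
    x$n_repetitions, x$repetition_time, x$flip_angle, x$sweep_width, x$n_points
  ))
  invisible(x)
}

#' Default chemical-shift tables
#'
#' Frequency offsets (Hz, relative to the pyruvate resonance), linewidths and
#' phases of the metabolite resonances observed after injection of
#' hyperpolarized \code{[1-13C]}- or \code{[2-13C]}pyruvate at 7 T. Offsets
#' are editable placeholders: the simulator and the fitter only require that
#' they agree with each other, and any study-specific table can be passed
#' instead.
#'
#' @param linewidth Default Lorentzian linewidth in Hz applied to every peak.
#' @param phase Common zero-order phase in radians.
#' @return A data frame with columns \code{name}, \code{frequency_offset}
#'   (Hz), \code{linewidth} (Hz) and \code{phase} (radians), usable both as a
#'   peak specification for \code{\link{render_fids}} and as the basis of
#'   fitting priors (\code{\link{peak_priors}}).
#' @examples
#' c1_shift_table()
#' @export
c1_shift_table <- function(linewidth = 30, phase = 0) {
  peaks <- data.frame(
    name = c("pyruvate", "lactate", "pyruvate_hydrate", "alanine",
             "bicarbonate", "co2"),
    frequency_offset = c(0, 1000, 630, 570, -1320, -6130),
    stringsAsFactors = FALSE
  )
  peaks$linewidth <- linewidth
  peaks$phase <- phase
  peaks
}

#' @rdname c1_shift_table
#' @export
c2_shift_table <- function(linewidth = 30, phase = 0) {
  peaks <- data.frame(
    name = c("pyruvate", "acetylcarnitine", "citrate", "glutamate"),
    frequency_offset = c(0, 2400, 800, 400),
    stringsAsFactors = FALSE
  )
  peaks$linewidth <- linewidth
  peaks$phase <- phase
  peaks
}

check_peak_table <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("name", "frequency_offset", "linewidth", "phase")
                %in% names(peaks)))
  if (anyDuplicated(peaks$name))
    stop("peak names must be unique", call. = FALSE)
  if (any(peaks$linewidth <= 0))
    stop("linewidths must be positive", call. = FALSE)
  stop_if_not_finite(peaks$frequency_offset, "frequency offsets")
  invisible(peaks)
}
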