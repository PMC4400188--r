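#' Render magnetization time courses into a noisy FID series
#'
#' Converts per-repetition longitudinal magnetizations into the complex
#' free induction decays a pulse-acquire experiment would record. Each
#' repetition's FID is
#' \deqn{y(t) = \sum_k A_k \sin\theta\, e^{i\phi_k}
#'   e^{(-\pi w_k + i 2\pi f_k) t} + c + \epsilon(t),}
#' sampled at the dwell time, where \eqn{A_k} is the pool magnetization,
#' \eqn{w_k} the Lorentzian linewidth (Hz), \eqn{f_k} the frequency offset
#' (Hz), \eqn{c} an optional DC offset and \eqn{\epsilon} i.i.d. circular
#' complex Gaussian noise with standard deviation \code{noise_sd} per channel.
#'
#' @param magnetizations Matrix [n_repetitions x n_metabolites] as returned
#'   by \code{\link{simulate_kinetics}}; column names must match peak names.
#' @param peaks Peak table (\code{\link{c1_shift_table}} format); one row per
#'   magnetization column.
#' @param acq \code{\link{acquisition_params}}.
#' @param noise_sd Noise standard deviation per real/imaginary channel (>= 0).
#' @param seed Integer seed for reproducible noise, or NULL.
#' @param dc_offset Complex DC offset added to every sample.
#' @return A \code{"fid_series"} object: complex matrix \code{fids}
#'   [n_repetitions x n_points] plus acquisition metadata, peak table, seed
#'   and an ISO-8601 creation stamp.
#' @examples
#' acq <- acquisition_params(n_repetitions = 4, n_points = 256)
#' m <- simulate_kinetics(kinetic_truth(), acq)
#' fs <- render_fids(m, c1_shift_table(), acq, noise_sd = 0.01, seed = 1)
#' @export
render_fids <- function(magnetizations, peaks, acq, noise_sd = 0,
                        seed = NULL, dc_offset = 0 + 0i) {
  stopifnot(inherits(acq, "acquisition_params"), noise_sd >= 0)
  check_peak_table(peaks)
  magnetizations <- as.matrix(magnetizations)
  if (!is.null(colnames(magnetizations))) {
    # match peaks to columns by name; extra peak rows are ignored
    peaks <- peaks[match(colnames(magnetizations), peaks$name), ]
    if (anyNA(peaks$frequency_offset))
      stop("peak table lacks entries for some magnetization columns",
           call. = FALSE)
  } else if (ncol(magnetizations) != nrow(peaks)) {
    stop("need one peak spec per metabolite column (",
         ncol(magnetizations), " columns, ", nrow(peaks), " peaks)",
         call. = FALSE)
  }

  t <- (seq_len(acq$n_points) - 1) * acq$dwell_time
  sinf <- sin(acq$flip_angle * pi / 180)
  # basis[(point, peak)]: unit-amplitude damped complex exponentials
  basis <- exp(outer(t, -pi * peaks$linewidth +
                        2i * pi * peaks$frequency_offset))
  basis <- basis * matrix(exp(1i * peaks$phase), nrow(basis), nrow(peaks),
                          byrow = TRUE)
  fids <- (magnetizations * sinf) %*% t(basis) + dc_offset
  if (noise_sd > 0) {
    fids <- fids + with_seed(seed, {
      n <- length(fids)
      matrix(complex(real = stats::rnorm(n, 0, noise_sd),
                     imaginary = stats::rnorm(n, 0, noise_sd)),
             nrow(fids), ncol(fids))
    })
  }
  structure(list(
    fids = fids,
    acq = acq,
    peaks = peaks,
    noise_sd = noise_sd,
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "fid_series")
}

#' @export
print.fid_series <- function(x, ...) {
  cat(sprintf("FID series: %d repetitions x %d complex points (%s)\n",
              nrow(x$fids), ncol(x$fids),
              paste(x$peaks$name, collapse = ", ")))
  invisible(x)
}

#' Read and write FID series containers
#'
#' A \code{fid_series} is stored as a single self-describing serialized
#' container carrying the complex sample matrix, all acquisition parameters,
#' the peak table, the generating seed and a creation timestamp.
#'
#' @param x A \code{fid_series}.
#' @param path File path (conventionally \code{.fids.rds}).
#' @return \code{read_fid_series} returns the \code{fid_series};
#'   \code{write_fid_series} returns \code{path} invisibly.
#' @export
write_fid_series <- function(x, path) {
  stopifnot(inherits(x, "fid_series"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_fid_series
#' @export
read_fid_series <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "fid_series")) stop("not a FID series container")
  x
}
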