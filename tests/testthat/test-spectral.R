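test_that("DC-offset correction removes a pure offset", {
  expect_true(all(dc_offset_correct(rep(3 + 4i, 100)) == 0))
})

test_that("DC-offset correction leaves offset-free signals alone", {
  fid <- c(complex(real = rnorm(50), imaginary = rnorm(50)), rep(0i, 50))
  expect_equal(dc_offset_correct(fid), fid)
})

test_that("DC-offset correction recovers a known complex offset", {
  n <- 1024
  t <- seq_len(n) - 1
  sig <- exp(-t / 20) * exp(2i * pi * 0.1 * t)  # decayed to ~0 by n/2
  fid <- sig + (3 + 4i)
  corrected <- dc_offset_correct(fid)
  tail_mean <- mean(corrected[(n / 2 + 1):n])
  expect_lt(Mod(tail_mean), 1e-9)
  expect_lt(max(Mod(corrected - sig)), 1e-7)
})

test_that("DC-offset correction is idempotent once the tail mean is zero", {
  fid <- complex(real = rnorm(64), imaginary = rnorm(64)) + (1 - 2i)
  once <- dc_offset_correct(fid)
  expect_equal(dc_offset_correct(once), once, tolerance = 1e-12)
})

test_that("noiseless two-peak amplitudes are recovered at oracle precision", {
  acq <- small_acq(n_repetitions = 1, n_points = 2048)
  pk <- oracle_peaks(2)  # pyruvate + lactate
  amps <- c(1, 0.25)
  fs <- render_fids(matrix(amps, 1, dimnames = list(NULL, pk$name)),
                    pk, acq, noise_sd = 0)
  rendered <- amps * sin(acq$flip_angle * pi / 180)  # readout scaling
  fit <- fit_spectrum(fs$fids[1, ], peak_priors(pk), acq)
  expect_true(attr(fit, "converged"))
  expect_lt(max(abs(fit$amplitude - rendered) / rendered), 1e-6)
  expect_lt(max(abs(fit$frequency - pk$frequency_offset)), 1e-3)
  expect_lt(max(abs(fit$linewidth - pk$linewidth) / pk$linewidth), 1e-5)
})

test_that("a zero FID fits to zero amplitudes", {
  acq <- small_acq(n_repetitions = 1, n_points = 256)
  fit <- fit_spectrum(rep(0i, 256), peak_priors(oracle_peaks()), acq)
  expect_true(all(fit$amplitude == 0))
})

test_that("time-domain amplitude agrees with frequency-domain integration", {
  # sum of all DFT bins times the bin width, normalized by the sweep width,
  # equals the t = 0 signal value, i.e. the amplitude
  acq <- small_acq(n_repetitions = 1, n_points = 2048)
  pk <- data.frame(name = "pyruvate", frequency_offset = 0,
                   linewidth = 50, phase = 0)
  fs <- render_fids(matrix(0.8, 1, dimnames = list(NULL, "pyruvate")),
                    pk, acq, noise_sd = 0)
  fit <- fit_spectrum(fs$fids[1, ], peak_priors(pk, freq_tol = 0), acq)
  spectral_integral <- Re(sum(fft(fs$fids[1, ]))) *
    (acq$sweep_width / acq$n_points) / acq$sweep_width
  expect_lt(abs(fit$amplitude - spectral_integral) / spectral_integral,
            1e-4)
})

test_that("amplitudes are invariant to a global phase rotation", {
  acq <- small_acq(n_repetitions = 1, n_points = 1024)
  pk <- oracle_peaks(2)
  fs <- render_fids(matrix(c(1, 0.3), 1, dimnames = list(NULL, pk$name)),
                    pk, acq, noise_sd = 0)
  pri <- peak_priors(pk)
  base <- fit_spectrum(fs$fids[1, ], pri, acq)
  rotated <- fit_spectrum(fs$fids[1, ] * exp(0.7i), pri, acq)
  expect_lt(max(abs(rotated$amplitude - base$amplitude) /
                  base$amplitude), 1e-6)
})

test_that("the fitted residual never exceeds the input norm", {
  acq <- small_acq(n_repetitions = 1, n_points = 512)
  set.seed(21)
  fid <- complex(real = rnorm(512), imaginary = rnorm(512))
  fit <- fit_spectrum(fid, peak_priors(oracle_peaks()), acq)
  expect_lte(attr(fit, "rss"), sum(Re(fid)^2 + Im(fid)^2) + 1e-9)
})

test_that("quantify_series reproduces generator amplitudes when noiseless", {
  acq <- acquisition_params(n_repetitions = 30, n_points = 2048)
  truth <- kinetic_truth()
  m <- simulate_kinetics(truth, acq)
  # priors cover exactly the rendered resonances so the model is identified
  pk <- oracle_peaks()[match(colnames(m), oracle_peaks()$name), ]
  fs <- render_fids(m, pk, acq, noise_sd = 0)
  ps <- quantify_series(fs, peak_priors(pk))
  expected <- m * sin(acq$flip_angle * pi / 180)
  scale <- max(expected)
  rel <- abs(ps$amplitudes[, colnames(expected)] - expected) /
    pmax(abs(expected), scale * 1e-3)
  expect_lt(max(rel), 1e-5)
})

test_that("an all-zero series quantifies to zero everywhere", {
  acq <- small_acq(n_repetitions = 3, n_points = 256)
  pk <- oracle_peaks(2)
  fs <- render_fids(matrix(0, 3, 2, dimnames = list(NULL, pk$name)),
                    pk, acq, noise_sd = 0)
  ps <- quantify_series(fs, peak_priors(pk))
  expect_true(all(ps$amplitudes == 0))
})

test_that("the series time axis spans 0 to 59 s for 60 reps at TR 1 s", {
  acq <- acquisition_params()  # 60 repetitions, TR 1 s
  pk <- oracle_peaks(1)
  fs <- render_fids(matrix(1, 60, 1, dimnames = list(NULL, "pyruvate")),
                    pk, acq, noise_sd = 0)
  ps <- quantify_series(fs, peak_priors(pk, freq_tol = 0))
  expect_equal(range(ps$time), c(0, 59))
  expect_equal(unique(diff(ps$time)), acq$repetition_time)
})

test_that("noisy amplitude series track the ground truth", {
  acq <- acquisition_params(n_repetitions = 40)
  truth <- kinetic_truth()
  m <- simulate_kinetics(truth, acq)
  pk <- c1_shift_table()
  nsd <- peak_snr_noise_sd(truth, acq, 50)
  fs <- render_fids(m, pk, acq, noise_sd = nsd, seed = 31)
  ps <- suppressWarnings(quantify_series(
    fs, peak_priors(pk),
    control = minpack.lm::nls.lm.control(maxiter = 150, ftol = 1e-6,
                                         ptol = 1e-5, gtol = 0)))
  expected <- m * sin(acq$flip_angle * pi / 180)
  for (met in c("pyruvate", "lactate", "bicarbonate"))
    expect_gt(cor(ps$amplitudes[, met], expected[, met]), 0.99)
})

test_that("summed-window ratios recover a fixed metabolite fraction", {
  acq <- acquisition_params()
  pk <- c2_shift_table(linewidth = 60)
  arrival <- c(rep(0, 4), seq(0.2, 1, length.out = 6), exp(-(0:49) / 20))
  m <- outer(arrival, c(pyruvate = 1, acetylcarnitine = 0.1,
                        citrate = 0.1, glutamate = 0.1))
  fs <- render_fids(m, pk, acq, noise_sd = 0)
  r <- sum_window_ratios(fs, peak_priors(pk))
  expect_lt(max(abs(r$ratios - 0.1)), 1e-6)
  expect_equal(unname(diff(r$window)), 30)
})

test_that("the summation window covers 30 repetitions from appearance", {
  acq <- acquisition_params()
  pk <- c2_shift_table(linewidth = 60)
  sig <- c(rep(0, 4), rep(1, 56))  # appears at repetition 5
  m <- outer(sig, c(pyruvate = 1, acetylcarnitine = 0, citrate = 0,
                    glutamate = 0))
  fs <- render_fids(m, pk, acq, noise_sd = 0)
  r <- sum_window_ratios(fs, peak_priors(pk))
  expect_equal(r$appearance_rep, 5)
  expect_equal(r$n_summed, 30)        # repetitions 5..34 inclusive
  expect_equal(unname(r$window["start"]), 4)
  expect_true(all(r$ratios < 1e-8))   # zero metabolite signal
})

test_that("a series with no pyruvate raises a no-signal error", {
  acq <- small_acq(n_repetitions = 12, n_points = 256)
  pk <- c2_shift_table(linewidth = 60)
  m <- matrix(0, 12, 4, dimnames = list(NULL, pk$name))
  fs <- render_fids(m, pk, acq, noise_sd = 0.01, seed = 5)
  expect_error(sum_window_ratios(fs, peak_priors(pk)), "never appears")
})

test_that("a degenerate warm start cannot pin amplitudes at zero", {
  # a previous all-zero fit carries an arbitrary phase; starting the next
  # repetition from it must not trap non-negative amplitudes at the bound
  acq <- small_acq(n_repetitions = 1, n_points = 1024)
  pk <- oracle_peaks(2)
  fs <- render_fids(matrix(c(1, 0.3), 1, dimnames = list(NULL, pk$name)),
                    pk, acq, noise_sd = 0)
  pri <- peak_priors(pk)
  poisoned <- structure(
    data.frame(name = pri$names, amplitude = 0,
               frequency = pri$freq + 15, linewidth = 150,
               phase = pi * 0.9, amplitude_se = NA_real_,
               stringsAsFactors = FALSE),
    class = c("peak_fit", "data.frame"))
  fit <- fit_spectrum(fs$fids[1, ], pri, acq, start = poisoned)
  rendered <- c(1, 0.3) * sin(acq$flip_angle * pi / 180)
  expect_lt(max(abs(fit$amplitude - rendered) / rendered), 1e-5)
})
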