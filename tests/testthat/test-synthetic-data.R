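test_that("downstream pools stay empty without flux", {
  acq <- small_acq()
  truth <- kinetic_truth(k_px = c(lactate = 0, alanine = 0, pdh = 0))
  m <- simulate_kinetics(truth, acq)
  expect_true(all(m[, colnames(m) != "pyruvate"] == 0))
  expect_gt(max(m[, "pyruvate"]), 0)
})

test_that("label is conserved in a closed system", {
  # no relaxation, no RF depletion, injection finished before acquisition
  acq <- acquisition_params(flip_angle = 0, n_repetitions = 30,
                            n_points = 64)
  truth <- kinetic_truth(rho_x = 0, rho_p = 0,
                         input_start = -15, input_duration = 10)
  m <- simulate_kinetics(truth, acq)
  total <- rowSums(m)
  expect_lt(diff(range(total)) / total[1], 1e-9)
})

test_that("integrator matches the constant-input closed form", {
  # pyruvate held at P0 by a balancing input; product follows
  # (k P0 / rho) (1 - exp(-rho t)), the analytic solution of the linear ODE
  k <- 0.02; rho <- 0.1; P0 <- 2
  acq <- acquisition_params(flip_angle = 0, n_repetitions = 60,
                            n_points = 64)
  truth <- kinetic_truth(k_px = c(lactate = k), rho_x = rho, rho_p = 0,
                         input_start = 0, input_duration = 60,
                         input_amplitude = k * P0, ramp_fraction = 0)
  m <- simulate_kinetics(truth, acq, initial = c(pyruvate = P0))
  tt <- attr(m, "time")
  closed <- k * P0 / rho * (1 - exp(-rho * tt))
  expect_equal(max(abs(m[, "pyruvate"] - P0)), 0)
  expect_lt(max(abs(m[-1, "lactate"] - closed[-1]) / closed[-1]), 1e-6)
})

test_that("closed form holds on step sizes down to TR/10", {
  k <- 0.05; rho <- 0.3; P0 <- 1
  acq <- acquisition_params(flip_angle = 0, n_repetitions = 20,
                            n_points = 64)
  truth <- kinetic_truth(k_px = c(x = k), rho_x = rho, rho_p = 0,
                         input_start = 0, input_duration = 30,
                         input_amplitude = k * P0, ramp_fraction = 0)
  for (sub in c(10, 20)) {
    m <- simulate_kinetics(truth, acq, n_substeps = sub,
                           initial = c(pyruvate = P0))
    tt <- attr(m, "time")
    closed <- k * P0 / rho * (1 - exp(-rho * tt))
    expect_lt(max(abs(m[-1, "x"] - closed[-1]) / closed[-1]), 1e-6)
  }
})

test_that("larger flip angles never leave more magnetization", {
  truth <- kinetic_truth()
  finals <- sapply(c(0, 2, 5, 10, 30), function(fa) {
    acq <- acquisition_params(flip_angle = fa, n_repetitions = 30,
                              n_points = 64)
    sum(simulate_kinetics(truth, acq)[30, ])
  })
  expect_true(all(diff(finals) <= 1e-12))
})

test_that("non-finite kinetic parameters are rejected", {
  expect_error(kinetic_truth(k_px = c(lactate = NaN)), "non-finite")
  expect_error(kinetic_truth(k_px = c(lactate = -1)))
  expect_error(kinetic_truth(co2_bicarbonate_ratio = 1.5))
})

test_that("rendering zero magnetization gives zero FIDs", {
  acq <- small_acq(n_repetitions = 3, n_points = 128)
  pk <- oracle_peaks(2)
  m <- matrix(0, 3, 2, dimnames = list(NULL, pk$name))
  fs <- render_fids(m, pk, acq, noise_sd = 0)
  expect_true(all(fs$fids == 0))
})

test_that("a single on-resonance peak renders as a real decaying exponential", {
  acq <- small_acq(n_repetitions = 1, n_points = 256)
  pk <- data.frame(name = "pyruvate", frequency_offset = 0,
                   linewidth = 40, phase = 0)
  m <- matrix(1, 1, 1, dimnames = list(NULL, "pyruvate"))
  fs <- render_fids(m, pk, acq, noise_sd = 0)
  y <- fs$fids[1, ]
  expect_equal(max(abs(Im(y))), 0)
  expect_true(all(Re(y) > 0))
  expect_true(all(diff(Re(y)) < 0))
})

test_that("rendered peaks appear at their offsets in the spectrum", {
  acq <- small_acq(n_repetitions = 1, n_points = 2048)
  pk <- data.frame(name = c("a", "b"),
                   frequency_offset = c(-1320, 1000),
                   linewidth = c(30, 30), phase = 0)
  m <- matrix(c(1, 0.5), 1, dimnames = list(NULL, pk$name))
  fs <- render_fids(m, pk, acq, noise_sd = 0)
  spec <- Mod(fft(fs$fids[1, ]))
  n <- acq$n_points
  freqs <- ((seq_len(n) - 1)) / n * acq$sweep_width
  freqs[freqs >= acq$sweep_width / 2] <-
    freqs[freqs >= acq$sweep_width / 2] - acq$sweep_width
  # two local maxima, each within one spectral bin of its specified offset
  top2 <- order(spec, decreasing = TRUE)
  found <- freqs[top2[1:50]]
  bin <- acq$sweep_width / n
  expect_true(any(abs(found - 1000) <= bin))
  expect_true(any(abs(found + 1320) <= bin))
})

test_that("rendering with a mismatched peak table is a shape error", {
  acq <- small_acq(n_repetitions = 2, n_points = 64)
  m <- matrix(1, 2, 3)  # no column names, 3 columns vs 2 peaks
  expect_error(render_fids(m, oracle_peaks(2), acq), "one peak spec")
})

test_that("identical seeds give bit-identical FID series", {
  acq <- small_acq(n_repetitions = 4, n_points = 128)
  truth <- kinetic_truth()
  m <- simulate_kinetics(truth, acq)
  pk <- oracle_peaks()
  a <- render_fids(m, pk, acq, noise_sd = 0.1, seed = 11)
  b <- render_fids(m, pk, acq, noise_sd = 0.1, seed = 11)
  d <- render_fids(m, pk, acq, noise_sd = 0.1, seed = 12)
  expect_identical(a$fids, b$fids)
  expect_false(identical(a$fids, d$fids))
})

test_that("cine generator reports its own analytic ground truth", {
  # single slice: areas follow the stated ellipse contraction exactly
  sim <- simulate_cine(base_radius_mm = 3, axis_ratio = 0.8,
                       wall_thickness_mm = 1, contraction_fraction = 0.5,
                       n_slices = 1, n_frames = 8,
                       slice_thickness_mm = 2)
  tab <- sim$table
  a_ed <- tab$endo_area_mm2[tab$frame == 1]
  expect_equal(sim$truth$edv_ul, a_ed * 2)
  es <- sim$truth$es_frame
  a_es <- tab$endo_area_mm2[tab$frame == es]
  expect_equal(sim$truth$esv_ul, a_es * 2)
  expect_equal(a_es, a_ed * (1 - 0.5), tolerance = 1e-12)
  expect_equal(sim$truth$ef, 0.5, tolerance = 1e-12)
})

test_that("zero wall thickness makes epi and endo areas equal", {
  sim <- simulate_cine(wall_thickness_mm = 0, n_slices = 3, n_frames = 6)
  expect_equal(sim$table$epi_area_mm2, sim$table$endo_area_mm2)
})

test_that("cine tables are reproducible under a fixed seed", {
  a <- simulate_cine(area_noise_sd = 0.05, seed = 9)
  b <- simulate_cine(area_noise_sd = 0.05, seed = 9)
  expect_identical(a, b)
})

test_that("cohort draws respect their group specification", {
  spec <- reference_cohort_spec()
  # zero-SD spec: every animal equals its group mean
  s0 <- spec; s0$sd <- 0
  tab0 <- simulate_cohort(cohort_spec(s0), seed = 1)
  one <- subset(tab0, week == 4 & measure == "edv_ul" &
                  surgery == "sham" & diet == "chow")
  expect_true(all(one$value == 550))
  # law-of-large-numbers check on an inflated-n spec
  big <- subset(spec, week == 4 & measure == "sv_ul")
  big$n <- 10000
  tabb <- simulate_cohort(cohort_spec(big), seed = 2)
  for (i in seq_len(nrow(big))) {
    g <- subset(tabb, surgery == big$surgery[i] & diet == big$diet[i])
    expect_lt(abs(mean(g$value) - big$mean[i]),
              3 * big$sd[i] / sqrt(10000))
  }
})

test_that("reference cohort spec reproduces the 4-week group sizes", {
  tab <- simulate_cohort(reference_cohort_spec(), seed = 3)
  n4 <- with(subset(tab, week == 4 & measure == "edv_ul"),
             table(surgery, diet))
  expect_equal(n4["sham", "chow"][[1]], 11)
  expect_equal(n4["sham", "WD"][[1]], 8)
  expect_equal(n4["AAB", "chow"][[1]], 10)
  expect_equal(n4["AAB", "WD"][[1]], 8)
})

test_that("cohort simulation is seed-deterministic", {
  spec <- reference_cohort_spec()
  expect_identical(simulate_cohort(spec, seed = 4),
                   simulate_cohort(spec, seed = 4))
})
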