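# shared fixtures: small, fast acquisition settings for unit tests

small_acq <- function(n_repetitions = 20, n_points = 512, ...) {
  acquisition_params(n_repetitions = n_repetitions, n_points = n_points, ...)
}

# linewidth 50 Hz: fully decayed within the acquisition window so the
# DC-offset rule does not bias on-resonance amplitudes at oracle precision
oracle_peaks <- function(n = NULL, linewidth = 50) {
  pk <- c1_shift_table(linewidth = linewidth)
  if (!is.null(n)) pk <- pk[seq_len(n), ]
  pk
}

# brute-force two-way ANOVA oracle for a balanced a x b x n layout:
# textbook cell-means sums of squares, independent of the package's
# lm/Type-II route
balanced_anova_oracle <- function(values, A, B) {
  A <- factor(A); B <- factor(B)
  n <- length(values) / (nlevels(A) * nlevels(B))
  stopifnot(n == round(n))
  g <- mean(values)
  mA <- tapply(values, A, mean)
  mB <- tapply(values, B, mean)
  mAB <- tapply(values, list(A, B), mean)
  ss_a <- n * nlevels(B) * sum((mA - g)^2)
  ss_b <- n * nlevels(A) * sum((mB - g)^2)
  ss_ab <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + g)^2)
  ss_e <- sum((values - mAB[cbind(A, B)])^2)
  df_e <- length(values) - nlevels(A) * nlevels(B)
  ms_e <- ss_e / df_e
  list(
    ss = c(surgery = ss_a, diet = ss_b, interaction = ss_ab,
           residuals = ss_e),
    F = c(surgery = ss_a / ms_e, diet = ss_b / ms_e,
          interaction = ss_ab / ms_e),
    p = stats::pf(c(ss_a, ss_b, ss_ab) / ms_e, 1, df_e, lower.tail = FALSE)
  )
}

# cohort table laid out as one (week, measure) slice
make_cells <- function(values, surgery, diet, week = 4,
                       measure = "m") {
  data.frame(
    animal_id = sprintf("a%02d", seq_along(values)),
    surgery = surgery, diet = diet, week = week, measure = measure,
    value = values, stringsAsFactors = FALSE
  )
}
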