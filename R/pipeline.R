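#' Configuration of a full synthetic study run
#'
#' Collects every tunable of the end-to-end synthetic study: acquisition
#' settings, kinetic ground truth and group effect multipliers, noise level,
#' CINE geometry, cohort layout and output directory. The resolved
#' configuration is written beside the outputs of every run in R's native
#' text representation (\code{dput}), which round-trips losslessly via
#' \code{\link{read_run_config}}.
#'
#' @param seed Root seed; all stage randomness is derived from it.
#' @param n_per_group Animals per surgery-by-diet group.
#' @param weeks Timepoints (weeks post surgery).
#' @param acq \code{\link{acquisition_params}}.
#' @param truth Baseline \code{\link{kinetic_truth}} shared by all groups.
#' @param aab_k_multipliers Named list mapping week (as character) to a named
#'   multiplier vector applied to the AAB groups' rate constants, e.g.
#'   \code{list(`9` = c(lactate = 1.3))}.
#' @param wd_k_multipliers Same, applied to Western-diet groups.
#' @param bio_cv Between-animal coefficient of variation (lognormal) of the
#'   rate constants.
#' @param peak_snr Peak-pyruvate time-domain signal-to-noise ratio of the
#'   rendered FIDs.
#' @param peaks Shift table used for rendering and fitting.
#' @param cine Named list of \code{\link{simulate_cine}} arguments common to
#'   all animals (per-animal segmentation noise uses
#'   \code{area_noise_sd}).
#' @param hr_mean,hr_sd Heart rate distribution (bpm).
#' @param bw_mean,bw_sd Body weight distribution (g).
#' @param outdir Output directory.
#' @return A \code{"run_config"} list.
#' @export
run_config <- function(seed = 1,
                       n_per_group = 8,
                       weeks = c(4, 9, 14),
                       acq = acquisition_params(),
                       truth = kinetic_truth(),
                       aab_k_multipliers = list(`9` = c(lactate = 1.3),
                                                `14` = c(lactate = 1.3)),
                       wd_k_multipliers = list(),
                       bio_cv = 0.1,
                       peak_snr = 50,
                       peaks = c1_shift_table(),
                       cine = list(area_noise_sd = 0.02),
                       hr_mean = 355, hr_sd = 25,
                       bw_mean = 400, bw_sd = 30,
                       outdir = tempfile("cardioflux_run_")) {
  stopifnot(n_per_group >= 2, bio_cv >= 0, peak_snr > 0)
  structure(list(
    seed = seed, n_per_group = n_per_group, weeks = weeks, acq = acq,
    truth = truth, aab_k_multipliers = aab_k_multipliers,
    wd_k_multipliers = wd_k_multipliers, bio_cv = bio_cv,
    peak_snr = peak_snr, peaks = peaks, cine = cine,
    hr_mean = hr_mean, hr_sd = hr_sd, bw_mean = bw_mean, bw_sd = bw_sd,
    outdir = outdir
  ), class = "run_config")
}

#' @rdname run_config
#' @param path File written by \code{write_run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- dget(path)
  if (!inherits(cfg, "run_config")) stop("not a run_config file")
  cfg
}

#' @rdname run_config
#' @param config A \code{"run_config"}.
#' @export
write_run_config <- function(config, path) {
  dput(config, file = path, control = c("all", "digits17"))
  invisible(path)
}

#' Run the full synthetic study end to end
#'
#' Generates a four-group (sham/AAB x chow/WD) cohort followed at the
#' configured weeks. Per animal and week it simulates kinetic ground truth
#' (with between-animal variability and group effect multipliers), renders
#' and quantifies a dynamic FID series, fits the kinetic model, simulates a
#' CINE segmentation table and computes the cardiac function indices. It
#' then runs the per-timepoint two-way ANOVA (with conditional post-hoc
#' tests) on every derived measure and writes all results, the resolved
#' configuration and a log to \code{config$outdir}.
#'
#' @param config A \code{\link{run_config}}.
#' @param measures_stats Measures passed to the statistics stage.
#' @return Invisibly, a list: \code{manifest} (character vector of files
#'   written, all existing), \code{cohort} (the derived cohort table),
#'   \code{stats} (per-measure \code{\link{analyze_measure}} output),
#'   \code{outdir}.
#' @examples
#' \donttest{
#' cfg <- run_config(n_per_group = 2, weeks = 4,
#'                   acq = acquisition_params(n_repetitions = 20,
#'                                            n_points = 256))
#' res <- run_study(cfg)
#' }
#' @export
run_study <- function(config,
                      measures_stats = c("k_lactate", "k_bicarbonate",
                                         "ef_pct", "edv_ul")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  log_lines <- c(
    sprintf("cardioflux %s", as.character(utils::packageVersion("cardioflux"))),
    sprintf("seed: %s", config$seed),
    sprintf("started: %s", format(t_start, "%Y-%m-%dT%H:%M:%S%z")))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf(
      "stage %s: %.2f s", name, as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  groups <- expand.grid(surgery = c("sham", "AAB"), diet = c("chow", "WD"),
                        stringsAsFactors = FALSE)
  noise_sd <- peak_snr_noise_sd(config$truth, config$acq, config$peak_snr)
  pri <- peak_priors(config$peaks)

  cohort <- stage("simulate+quantify+fit", {
    rows <- list()
    idx <- 0L
    for (wk in config$weeks) for (g in seq_len(nrow(groups))) {
      surgery <- groups$surgery[g]; diet <- groups$diet[g]
      mult <- rep(1, length(config$truth$k_px))
      names(mult) <- names(config$truth$k_px)
      for (ml in list(if (surgery == "AAB")
                        config$aab_k_multipliers[[as.character(wk)]],
                      if (diet == "WD")
                        config$wd_k_multipliers[[as.character(wk)]])) {
        if (!is.null(ml)) mult[names(ml)] <- mult[names(ml)] * ml
      }
      for (animal in seq_len(config$n_per_group)) {
        idx <- idx + 1L
        s_animal <- sub_seed(config$seed, "animal", idx)
        tr <- config$truth
        tr$k_px <- with_seed(s_animal, tr$k_px * mult *
                               exp(stats::rnorm(length(tr$k_px), 0,
                                                config$bio_cv)))
        m <- simulate_kinetics(tr, config$acq)
        fs <- render_fids(m, config$peaks, config$acq, noise_sd = noise_sd,
                          seed = sub_seed(config$seed, "fid", idx))
        ps <- suppressWarnings(quantify_series(
          fs, pri, control = minpack.lm::nls.lm.control(
            maxiter = 150, ftol = 1e-6, ptol = 1e-5, gtol = 0)))
        kf <- fit_kinetics(ps, config$acq,
                           products = c("lactate", "bicarbonate"))
        k <- setNames(kf$estimates$k, kf$estimates$product)

        cine_args <- config$cine
        cine_args$seed <- sub_seed(config$seed, "cine", idx)
        bio <- with_seed(sub_seed(config$seed, "bio", idx),
                         stats::rnorm(4))
        cine_args$base_radius_mm <- (cine_args$base_radius_mm %||% 4.3) *
          exp(0.04 * bio[1])
        cine_args$contraction_fraction <-
          min(0.95, max(0.3, (cine_args$contraction_fraction %||% 0.78) +
                          0.03 * bio[2]))
        sim <- do.call(simulate_cine, cine_args)
        hr <- config$hr_mean + config$hr_sd * bio[3]
        bw <- config$bw_mean + config$bw_sd * bio[4]
        cf <- cardiac_function(sim$table, hr_bpm = hr, body_weight_g = bw)

        vals <- c(k_lactate = unname(k["lactate"]),
                  k_bicarbonate = unname(k["bicarbonate"]),
                  edv_ul = cf$edv_ul, esv_ul = cf$esv_ul,
                  sv_ul = cf$sv_ul, ef_pct = 100 * cf$ef,
                  co_ml_min = cf$co_ml_min, lvm_mg = cf$lvm_mg,
                  hr_bpm = hr, body_weight_g = bw)
        rows[[idx]] <- data.frame(
          animal_id = sprintf("%s_%s_%02d", surgery, diet, animal),
          surgery = surgery, diet = diet, week = wk,
          measure = names(vals), value = unname(vals),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("cohort_table", "data.frame")
    out
  })

  stats_out <- stage("statistics", {
    res <- lapply(measures_stats, function(ms)
      analyze_measure(cohort, ms, weeks = config$weeks))
    names(res) <- measures_stats
    res
  })

  manifest <- stage("write", {
    paths <- character()
    p <- file.path(config$outdir, "cohort.csv")
    write_cohort_table(cohort, p); paths <- c(paths, p)

    anova_rows <- do.call(rbind, lapply(measures_stats, function(ms)
      do.call(rbind, lapply(names(stats_out[[ms]]), function(wk) {
        a <- stats_out[[ms]][[wk]]$anova
        data.frame(measure = ms, week = attr(a, "week"),
                   as.data.frame(a), stringsAsFactors = FALSE)
      }))))
    p <- file.path(config$outdir, "anova.csv")
    utils::write.csv(anova_rows, p, row.names = FALSE)
    paths <- c(paths, p)

    summary_rows <- do.call(rbind, lapply(measures_stats, function(ms)
      do.call(rbind, lapply(names(stats_out[[ms]]), function(wk) {
        s <- stats_out[[ms]][[wk]]$summary
        data.frame(measure = ms, week = sub("week", "", wk), s,
                   stringsAsFactors = FALSE)
      }))))
    summary_rows$report <- sprintf("%g ± %g",
                                   signif(summary_rows$mean, 3),
                                   signif(summary_rows$sd, 2))
    p <- file.path(config$outdir, "group_summary.csv")
    utils::write.csv(summary_rows, p, row.names = FALSE)
    paths <- c(paths, p)

    p <- file.path(config$outdir, "config.R")
    write_run_config(config, p); paths <- c(paths, p)
    paths
  })

  log_lines <- c(log_lines, sprintf(
    "total: %.2f s", as.numeric(Sys.time() - t_start, units = "secs")))
  log_path <- file.path(config$outdir, "run.log")
  writeLines(log_lines, log_path)
  manifest <- c(manifest, log_path)
  stopifnot(all(file.exists(manifest)))
  invisible(list(manifest = manifest, cohort = cohort, stats = stats_out,
                 outdir = config$outdir))
}
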