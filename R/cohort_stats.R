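select_cells <- function(table, week, measure) {
  d <- table[table$week == week & table$measure == measure, , drop = FALSE]
  if (nrow(d) == 0)
    stop("no rows for week ", week, ", measure '", measure, "'",
         call. = FALSE)
  d$surgery <- factor(d$surgery, levels = c("sham", "AAB"))
  d$diet <- factor(d$diet, levels = c("chow", "WD"))
  if (anyNA(d$surgery) || anyNA(d$diet))
    stop("surgery must be sham/AAB and diet chow/WD", call. = FALSE)
  d
}

#' Two-way ANOVA of one measure at one timepoint
#'
#' Fits the two-factor surgery-by-diet model with interaction on the
#' selected (week, measure) slice of a cohort table and returns the F test
#' of each effect. Unbalanced cells are handled with Type II sums of
#' squares, which coincide with the classical (Type I) decomposition when
#' the design is balanced.
#'
#' @param table A cohort table (\code{\link{simulate_cohort}} /
#'   \code{\link{read_cohort_table}} format).
#' @param week Timepoint to analyse.
#' @param measure Measure label to analyse.
#' @return An \code{"anova_result"}: data frame with rows \code{surgery},
#'   \code{diet}, \code{surgery:diet}, \code{Residuals} and columns
#'   \code{ss}, \code{df}, \code{F}, \code{p}; attributes \code{cell_n}
#'   (2x2 table of group sizes), \code{week}, \code{measure}.
#' @examples
#' tab <- simulate_cohort(reference_cohort_spec(), seed = 1)
#' two_way_anova(tab, week = 4, measure = "esv_ul")
#' @export
two_way_anova <- function(table, week, measure) {
  d <- select_cells(table, week, measure)
  cell_n <- table(d$surgery, d$diet)
  if (any(cell_n < 2)) {
    bad <- which(cell_n < 2, arr.ind = TRUE)
    stop("cell ", rownames(cell_n)[bad[1, 1]], "/",
         colnames(cell_n)[bad[1, 2]], " has fewer than 2 animals",
         call. = FALSE)
  }
  fit <- stats::lm(value ~ surgery * diet, data = d)
  a2 <- car::Anova(fit, type = 2)
  out <- data.frame(
    effect = rownames(a2),
    ss = a2[["Sum Sq"]],
    df = a2[["Df"]],
    F = a2[["F value"]],
    p = a2[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  structure(out, class = c("anova_result", "data.frame"),
            cell_n = cell_n, week = week, measure = measure)
}

#' Conditional Bonferroni post-hoc t tests
#'
#' Run only when the ANOVA interaction term is significant (p <= alpha),
#' mirroring the conditional testing scheme of the study design: four
#' pooled-variance, two-sided, unpaired t tests (sham vs AAB within each
#' diet; chow vs WD within each surgery), Bonferroni-adjusted for m = 4
#' comparisons (adjusted p = min(1, 4p)).
#'
#' @param table Cohort table.
#' @param week,measure Selection, matching the ANOVA.
#' @param anova The \code{\link{two_way_anova}} result for that selection.
#' @param alpha Interaction significance gate.
#' @return Data frame with one row per comparison: \code{comparison},
#'   \code{t}, \code{df}, \code{p_raw}, \code{p_adj}, \code{m},
#'   \code{significant}. When the interaction is not significant an empty
#'   data frame is returned with a message.
#' @export
bonferroni_posthoc <- function(table, week, measure, anova, alpha = 0.05) {
  stopifnot(inherits(anova, "anova_result"))
  empty <- data.frame(comparison = character(), t = numeric(),
                      df = numeric(), p_raw = numeric(),
                      p_adj = numeric(), m = integer(),
                      significant = logical())
  p_int <- anova$p[anova$effect == "surgery:diet"]
  if (length(p_int) != 1 || !(p_int <= alpha)) {
    message("interaction not significant (p = ",
            signif(p_int, 3), "); no post-hoc tests run")
    return(empty)
  }
  d <- select_cells(table, week, measure)
  comps <- list(
    "sham vs AAB | chow" = list(d$value[d$surgery == "sham" & d$diet == "chow"],
                                d$value[d$surgery == "AAB" & d$diet == "chow"]),
    "sham vs AAB | WD"   = list(d$value[d$surgery == "sham" & d$diet == "WD"],
                                d$value[d$surgery == "AAB" & d$diet == "WD"]),
    "chow vs WD | sham"  = list(d$value[d$surgery == "sham" & d$diet == "chow"],
                                d$value[d$surgery == "sham" & d$diet == "WD"]),
    "chow vs WD | AAB"   = list(d$value[d$surgery == "AAB" & d$diet == "chow"],
                                d$value[d$surgery == "AAB" & d$diet == "WD"])
  )
  m <- length(comps)
  rows <- lapply(names(comps), function(nm) {
    g <- comps[[nm]]
    tt <- stats::t.test(g[[1]], g[[2]], var.equal = TRUE)
    data.frame(comparison = nm, t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               p_adj = min(1, m * tt$p.value), m = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj <= alpha
  out
}

#' Per-group mean, SD and n summaries
#'
#' Sample mean and sample standard deviation (n - 1 denominator) for each
#' surgery-by-diet cell of the selected (week, measure); cells with a single
#' animal report a missing SD.
#'
#' @param table Cohort table.
#' @param week,measure Selection.
#' @return Data frame: \code{surgery}, \code{diet}, \code{mean}, \code{sd},
#'   \code{n}.
#' @examples
#' tab <- simulate_cohort(reference_cohort_spec(), seed = 1)
#' summarize_cohort(tab, 4, "sv_ul")
#' @export
summarize_cohort <- function(table, week, measure) {
  d <- select_cells(table, week, measure)
  out <- do.call(rbind, lapply(split(d, list(d$surgery, d$diet), drop = TRUE),
    function(g) {
      data.frame(surgery = as.character(g$surgery[1]),
                 diet = as.character(g$diet[1]),
                 mean = mean(g$value),
                 sd = if (nrow(g) > 1) stats::sd(g$value) else NA_real_,
                 n = nrow(g), stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Study-style cohort analysis of one measure across all timepoints
#'
#' For each week present: the two-way ANOVA, the conditional post-hoc
#' tests, and the mean +/- SD summary.
#'
#' @param table Cohort table.
#' @param measure Measure label.
#' @param weeks Weeks to analyse (default: all present).
#' @return Named list (one element per week) of lists with \code{anova},
#'   \code{posthoc}, \code{summary}.
#' @export
analyze_measure <- function(table, measure, weeks = NULL) {
  weeks <- weeks %||% sort(unique(table$week[table$measure == measure]))
  out <- lapply(weeks, function(wk) {
    a <- two_way_anova(table, wk, measure)
    ph <- suppressMessages(bonferroni_posthoc(table, wk, measure, a))
    list(anova = a, posthoc = ph,
         summary = summarize_cohort(table, wk, measure))
  })
  names(out) <- paste0("week", weeks)
  out
}
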