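#' Group-level specification of a factorial cohort
#'
#' A cohort specification lists, for every cell of the surgery-by-diet
#' design at every timepoint, the mean, standard deviation and group size of
#' each measurement of interest. \code{simulate_cohort} draws per-animal
#' values from these cells.
#'
#' @param means Data frame with columns \code{surgery} (\code{"sham"} or
#'   \code{"AAB"}), \code{diet} (\code{"chow"} or \code{"WD"}), \code{week},
#'   \code{measure}, \code{mean}, \code{sd}, \code{n}.
#' @return The validated data frame with class \code{"cohort_spec"}.
#' @seealso \code{\link{reference_cohort_spec}} for a ready-made specification.
#' @export
cohort_spec <- function(means) {
  req <- c("surgery", "diet", "week", "measure", "mean", "sd", "n")
  stopifnot(is.data.frame(means), all(req %in% names(means)))
  if (any(means$sd < 0)) stop("SD must be >= 0", call. = FALSE)
  if (any(means$n < 2)) stop("each cell needs n >= 2", call. = FALSE)
  structure(means, class = c("cohort_spec", "data.frame"))
}

#' Reference cohort specification: in-vivo cardiac structure and function
#'
#' Mean, SD and group size of body weight, ventricular volumes, ejection
#' fraction, stroke volume, heart rate and cardiac output in a four-group
#' (sham/AAB surgery crossed with chow/Western diet) rat cohort followed at
#' 4, 9 and 14 weeks: group sizes 11/8/10/8 at 4 weeks, 11/9/10/8 at
#' 9 weeks and 9/6/8/6 at 14 weeks.
#'
#' @return A \code{\link{cohort_spec}} covering measures
#'   \code{body_weight_g}, \code{edv_ul}, \code{esv_ul}, \code{ef_pct},
#'   \code{sv_ul}, \code{hr_bpm}, \code{co_ml_min} at weeks 4, 9, 14.
#' @examples
#' spec <- reference_cohort_spec()
#' subset(spec, week == 4 & measure == "esv_ul")
#' @export
reference_cohort_spec <- function() {
  groups <- data.frame(
    surgery = c("sham", "sham", "AAB", "AAB"),
    diet    = c("chow", "WD", "chow", "WD"),
    stringsAsFactors = FALSE
  )
  ns <- list(`4` = c(11, 8, 10, 8), `9` = c(11, 9, 10, 8),
             `14` = c(9, 6, 8, 6))
  # per week: measure -> rbind(mean, sd) for (sham-chow, sham-WD, AAB-chow, AAB-WD)
  cells <- list(
    `4` = list(
      body_weight_g = rbind(c(340, 350, 340, 340), c(20, 20, 20, 20)),
      edv_ul   = rbind(c(550, 570, 620, 610), c(50, 80, 70, 50)),
      esv_ul   = rbind(c(120, 100, 160, 140), c(20, 30, 40, 20)),
      ef_pct   = rbind(c(78, 83, 74, 77), c(4, 5, 5, 3)),
      sv_ul    = rbind(c(430, 470, 450, 470), c(50, 50, 60, 50)),
      hr_bpm   = rbind(c(350, 360, 360, 360), c(20, 40, 30, 30)),
      co_ml_min = rbind(c(150, 170, 160, 170), c(20, 20, 20, 20))
    ),
    `9` = list(
      body_weight_g = rbind(c(400, 420, 420, 400), c(30, 30, 20, 40)),
      edv_ul   = rbind(c(640, 660, 660, 710), c(50, 60, 80, 60)),
      esv_ul   = rbind(c(150, 130, 160, 170), c(20, 30, 30, 30)),
      ef_pct   = rbind(c(76, 81, 75, 77), c(4, 3, 5, 4)),
      sv_ul    = rbind(c(490, 530, 500, 550), c(60, 40, 80, 60)),
      hr_bpm   = rbind(c(350, 380, 360, 350), c(40, 30, 30, 40)),
      co_ml_min = rbind(c(170, 190, 180, 190), c(30, 30, 30, 30))
    ),
    `14` = list(
      body_weight_g = rbind(c(440, 490, 450, 480), c(30, 40, 30, 40)),
      edv_ul   = rbind(c(640, 760, 740, 730), c(100, 90, 120, 70)),
      esv_ul   = rbind(c(140, 160, 180, 170), c(30, 40, 50, 20)),
      ef_pct   = rbind(c(78, 79, 75, 77), c(2, 4, 5, 4)),
      sv_ul    = rbind(c(500, 600, 560, 560), c(70, 70, 110, 70)),
      hr_bpm   = rbind(c(350, 350, 360, 380), c(30, 30, 40, 30)),
      co_ml_min = rbind(c(180, 210, 200, 210), c(20, 20, 30, 30))
    )
  )
  rows <- do.call(rbind, lapply(names(cells), function(wk) {
    do.call(rbind, lapply(names(cells[[wk]]), function(ms) {
      m <- cells[[wk]][[ms]]
      data.frame(groups, week = as.integer(wk), measure = ms,
                 mean = m[1, ], sd = m[2, ], n = ns[[wk]],
                 stringsAsFactors = FALSE)
    }))
  }))
  cohort_spec(rows)
}

#' Simulate a per-animal cohort table from a group-level specification
#'
#' Draws independent Normal(mean, SD) values per animal within each
#' (surgery, diet, week, measure) cell. Animal identifiers are stable within
#' a (surgery, diet) group across weeks and measures so that repeated
#' measurements of the same synthetic animal share an id.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A \code{"cohort_table"} data frame with columns
#'   \code{animal_id}, \code{surgery}, \code{diet}, \code{week},
#'   \code{measure}, \code{value}.
#' @examples
#' tab <- simulate_cohort(reference_cohort_spec(), seed = 1)
#' head(tab)
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      r <- spec[i, ]
      data.frame(
        animal_id = sprintf("%s_%s_%02d", r$surgery, r$diet, seq_len(r$n)),
        surgery = r$surgery, diet = r$diet, week = r$week,
        measure = r$measure,
        value = stats::rnorm(r$n, r$mean, r$sd),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Read and write cohort tables
#'
#' Plain CSV with header \code{animal_id,surgery,diet,week,measure,value}.
#' @param x A cohort table data frame.
#' @param path CSV file path.
#' @export
write_cohort_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "surgery", "diet", "week", "measure", "value")
  if (!all(req %in% names(out)))
    stop("cohort CSV must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
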