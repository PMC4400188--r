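#' Read and validate a CINE segmentation area table
#'
#' @param path CSV with columns \code{slice}, \code{frame},
#'   \code{endo_area_mm2}, \code{epi_area_mm2}, \code{thickness_mm}.
#' @return Validated data frame.
#' @export
read_cine_table <- function(path) {
  validate_cine_table(utils::read.csv(path))
}

validate_cine_table <- function(table) {
  req <- c("slice", "frame", "endo_area_mm2", "epi_area_mm2",
           "thickness_mm")
  stopifnot(is.data.frame(table))
  if (!all(req %in% names(table)))
    stop("CINE table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(table$endo_area_mm2 < 0))
    stop("negative endocardial area", call. = FALSE)
  if (any(table$epi_area_mm2 < table$endo_area_mm2 - 1e-9))
    stop("epicardial area smaller than endocardial area", call. = FALSE)
  if (any(table$thickness_mm <= 0) ||
      length(unique(table$thickness_mm)) != 1)
    stop("slice thickness must be positive and uniform", call. = FALSE)
  key <- paste(table$slice, table$frame)
  if (anyDuplicated(key))
    stop("duplicate (slice, frame) cells: ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  full <- expand.grid(slice = unique(table$slice),
                      frame = unique(table$frame))
  missing <- setdiff(paste(full$slice, full$frame), key)
  if (length(missing))
    stop("missing (slice, frame) cells: ",
         paste(missing, collapse = "; "), call. = FALSE)
  table
}

#' Cavity volume per CINE frame
#'
#' Simpson-style slice summation: per frame, volume = sum over slices of
#' endocardial area (mm^2) times slice thickness (mm); 1 mm^3 = 1 uL.
#'
#' @param table CINE area table (see \code{\link{read_cine_table}}).
#' @return Named numeric vector of cavity volumes (uL), names = frame index.
#' @examples
#' sim <- simulate_cine(n_slices = 8, n_frames = 10)
#' cavity_volume_per_frame(sim$table)
#' @export
cavity_volume_per_frame <- function(table) {
  table <- validate_cine_table(table)
  v <- tapply(table$endo_area_mm2 * table$thickness_mm, table$frame, sum)
  v <- setNames(as.numeric(v), names(v))
  v[order(as.numeric(names(v)))]
}

#' Select end-diastolic and end-systolic frames
#'
#' ED is the frame with the largest cavity volume and ES the frame with the
#' smallest; ties are broken by the earliest frame.
#'
#' @param volumes Named vector of per-frame cavity volumes
#'   (\code{\link{cavity_volume_per_frame}}).
#' @return List with \code{ed_frame}, \code{es_frame} (frame labels) and the
#'   corresponding \code{edv_ul}, \code{esv_ul}.
#' @export
select_ed_es <- function(volumes) {
  if (length(volumes) < 2) stop("need at least 2 frames", call. = FALSE)
  frames <- if (is.null(names(volumes))) seq_along(volumes)
            else as.numeric(names(volumes))
  if (diff(range(volumes)) == 0)
    warning("degenerate cycle: all frame volumes equal", call. = FALSE)
  ed <- which.max(volumes)  # which.max/min already take the earliest tie
  es <- which.min(volumes)
  list(ed_frame = frames[ed], es_frame = frames[es],
       edv_ul = unname(volumes[ed]), esv_ul = unname(volumes[es]))
}

#' Cardiac functional indices from volumes, heart rate and body weight
#'
#' \code{SV = EDV - ESV} (uL), \code{EF = SV / EDV} (fraction),
#' \code{CO = SV x HR / 1000} (mL/min), \code{CI = CO / body weight}
#' (mL/min/g).
#'
#' @param edv_ul,esv_ul End-diastolic and end-systolic volumes (uL), with
#'   \code{edv_ul >= esv_ul >= 0}.
#' @param hr_bpm Heart rate (beats/min, > 0).
#' @param body_weight_g Body weight (g); NULL omits the cardiac index.
#' @return List with \code{sv_ul}, \code{ef}, \code{co_ml_min} and (when the
#'   body weight is given) \code{ci_ml_min_g}. Stored at full precision;
#'   see \code{\link{format_function_report}} for study-style rounding.
#' @examples
#' functional_indices(550, 120, 350)  # SV 430 uL, EF 0.7818, CO 150.5
#' @export
functional_indices <- function(edv_ul, esv_ul, hr_bpm,
                               body_weight_g = NULL) {
  stopifnot(esv_ul >= 0, hr_bpm > 0)
  if (esv_ul > edv_ul) stop("ESV exceeds EDV", call. = FALSE)
  if (edv_ul == 0) stop("EDV is zero: EF undefined", call. = FALSE)
  sv <- edv_ul - esv_ul
  out <- list(sv_ul = sv, ef = sv / edv_ul, co_ml_min = sv * hr_bpm / 1000)
  if (!is.null(body_weight_g)) {
    stopifnot(body_weight_g > 0)
    out$ci_ml_min_g <- out$co_ml_min / body_weight_g
  }
  out
}

#' Left ventricular mass from a segmentation table
#'
#' LV mass = sum over slices of (epicardial - endocardial area, mm^2) x
#' slice thickness (mm) x myocardial specific gravity 1.05 (mg/mm^3),
#' evaluated at one frame (conventionally end diastole).
#'
#' @param table CINE area table.
#' @param frame Frame at which to evaluate the mass.
#' @param specific_gravity Myocardial specific gravity (mg/mm^3).
#' @return Mass in mg.
#' @examples
#' tab <- data.frame(slice = 1, frame = 1, endo_area_mm2 = 40,
#'                   epi_area_mm2 = 120, thickness_mm = 1.6)
#' lv_mass(tab, 1)  # 134.4 mg
#' @export
lv_mass <- function(table, frame, specific_gravity = 1.05) {
  table <- validate_cine_table(table)
  rows <- table[table$frame == frame, ]
  if (nrow(rows) == 0) stop("frame ", frame, " not present", call. = FALSE)
  myo <- rows$epi_area_mm2 - rows$endo_area_mm2
  if (any(myo < 0)) stop("negative myocardial area", call. = FALSE)
  sum(myo * rows$thickness_mm) * specific_gravity
}

#' Full cardiac function assessment from a segmentation table
#'
#' Convenience wrapper: computes per-frame cavity volumes, selects ED/ES,
#' derives the functional indices and the LV mass at the ED frame.
#'
#' @param table CINE area table.
#' @param hr_bpm Heart rate (beats/min).
#' @param body_weight_g Body weight (g), optional.
#' @return A \code{"cardiac_function"} list: \code{edv_ul}, \code{esv_ul},
#'   \code{sv_ul}, \code{ef}, \code{hr_bpm}, \code{co_ml_min},
#'   \code{ci_ml_min_g} (or NA), \code{lvm_mg}, \code{ed_frame},
#'   \code{es_frame}.
#' @examples
#' sim <- simulate_cine()
#' cardiac_function(sim$table, hr_bpm = 350)
#' @export
cardiac_function <- function(table, hr_bpm, body_weight_g = NULL) {
  v <- cavity_volume_per_frame(table)
  sel <- select_ed_es(v)
  fi <- functional_indices(sel$edv_ul, sel$esv_ul, hr_bpm, body_weight_g)
  structure(c(sel[c("edv_ul", "esv_ul")], fi,
              list(hr_bpm = hr_bpm,
                   ci_ml_min_g = fi$ci_ml_min_g %||% NA_real_,
                   lvm_mg = lv_mass(table, sel$ed_frame),
                   ed_frame = sel$ed_frame, es_frame = sel$es_frame)),
            class = "cardiac_function")
}

#' @export
print.cardiac_function <- function(x, ...) {
  cat(format_function_report(x), sep = "\n")
  invisible(x)
}

#' Format cardiac function indices at study reporting precision
#'
#' Volumes to the nearest 10 uL, ejection fraction to integer percent,
#' cardiac output to the nearest 10 mL/min, LV mass to the nearest mg.
#' Rounding is applied only here, never to stored values.
#'
#' @param x A \code{"cardiac_function"}.
#' @return Character vector of report lines.
#' @export
format_function_report <- function(x) {
  c(sprintf("EDV %g uL, ESV %g uL (frames %s/%s)",
            round(x$edv_ul / 10) * 10, round(x$esv_ul / 10) * 10,
            x$ed_frame, x$es_frame),
    sprintf("SV %g uL, EF %d%%, CO %g mL/min",
            round(x$sv_ul / 10) * 10, as.integer(round(100 * x$ef)),
            round(x$co_ml_min / 10) * 10),
    if (is.finite(x$ci_ml_min_g))
      sprintf("CI %.2f mL/min/g", x$ci_ml_min_g),
    sprintf("LVM %g mg", round(x$lvm_mg)))
}
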