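#' Simulate a short-axis CINE segmentation area table
#'
#' Emulates the per-slice, per-frame endocardial and epicardial areas a
#' reader would obtain by outlining short-axis CINE images of a rodent left
#' ventricle: an ellipsoidal cavity sliced into contiguous short-axis
#' sections, contracting smoothly over the cardiac cycle, wrapped in an
#' incompressible myocardial wall (constant wall cross-sectional area per
#' slice over the cycle).
#'
#' Cavity areas scale as \eqn{A(s, f) = A_{ED}(s) (1 - c\, g(f))} with a
#' smooth cyclic \eqn{g} rising from 0 (end diastole, frame 1) to 1 (end
#' systole) and back, so the ground-truth ejection fraction equals the
#' contraction fraction \code{c} exactly.
#'
#' @param base_radius_mm End-diastolic mid-ventricular cavity radius (mm) of
#'   the elliptical cross section's major semi-axis.
#' @param axis_ratio Minor/major semi-axis ratio of the elliptical cavity.
#' @param wall_thickness_mm End-diastolic wall thickness (mm) at the
#'   mid-ventricle; wall cross-sectional area per slice is held constant over
#'   the cycle (incompressible myocardium). Zero gives epi == endo areas.
#' @param contraction_fraction Fraction of end-diastolic cavity volume
#'   ejected at end systole, in (0, 1); equals the ground-truth EF.
#' @param n_slices Number of contiguous slices covering the ventricle.
#' @param n_frames Frames per heart cycle (>= 2).
#' @param slice_thickness_mm Slice thickness (mm).
#' @param area_noise_sd Multiplicative segmentation noise SD (0 = exact).
#' @param seed Seed for the segmentation noise.
#' @return A list: \code{table} (data frame with columns \code{slice},
#'   \code{frame}, \code{endo_area_mm2}, \code{epi_area_mm2},
#'   \code{thickness_mm}) and \code{truth} (list with \code{edv_ul},
#'   \code{esv_ul}, \code{ef}, \code{ed_frame}, \code{es_frame},
#'   \code{lvm_mg}). Ground truth refers to the noise-free areas.
#' @examples
#' sim <- simulate_cine(n_slices = 8, n_frames = 30)
#' sim$truth$ef
#' @export
simulate_cine <- function(base_radius_mm = 4.3,
                          axis_ratio = 0.95,
                          wall_thickness_mm = 1.8,
                          contraction_fraction = 0.78,
                          n_slices = 8,
                          n_frames = 30,
                          slice_thickness_mm = 1.6,
                          area_noise_sd = 0,
                          seed = NULL) {
  stopifnot(contraction_fraction > 0, contraction_fraction < 1,
            n_slices >= 1, n_frames >= 2, slice_thickness_mm > 0,
            base_radius_mm > 0, wall_thickness_mm >= 0,
            axis_ratio > 0, axis_ratio <= 1, area_noise_sd >= 0)
  n_slices <- as.integer(n_slices); n_frames <- as.integer(n_frames)

  # ellipsoidal long-axis profile: slice centres at relative height z
  z <- (seq_len(n_slices) - 0.5) / n_slices        # 0 apexward .. 1 base
  profile <- sqrt(pmax(0, 1 - (2 * z - 1)^2 * 0.64))  # truncated ellipsoid
  a_ed <- pi * (base_radius_mm * profile) *
    (base_radius_mm * axis_ratio * profile)        # endo area at ED, mm^2
  wall_area <- pi * ((base_radius_mm * profile + wall_thickness_mm) *
                       (base_radius_mm * axis_ratio * profile +
                          wall_thickness_mm)) - a_ed

  g <- (1 - cos(2 * pi * (seq_len(n_frames) - 1) / n_frames)) / 2
  endo <- outer(a_ed, 1 - contraction_fraction * g)  # [slice x frame]
  epi <- endo + wall_area

  tab <- data.frame(
    slice = rep(seq_len(n_slices), times = n_frames),
    frame = rep(seq_len(n_frames), each = n_slices),
    endo_area_mm2 = as.vector(endo),
    epi_area_mm2 = as.vector(epi),
    thickness_mm = slice_thickness_mm
  )
  if (area_noise_sd > 0) {
    tab[, c("endo_area_mm2", "epi_area_mm2")] <- with_seed(seed, {
      f <- matrix(exp(stats::rnorm(2 * nrow(tab), 0, area_noise_sd)),
                  ncol = 2)
      cbind(tab$endo_area_mm2 * f[, 1],
            pmax(tab$epi_area_mm2 * f[, 2], tab$endo_area_mm2 * f[, 1]))
    })
  }

  ed_frame <- 1L
  es_frame <- which.max(g)
  edv <- sum(endo[, ed_frame]) * slice_thickness_mm   # mm^3 == uL
  esv <- sum(endo[, es_frame]) * slice_thickness_mm
  list(
    table = tab,
    truth = list(
      edv_ul = edv, esv_ul = esv, ef = (edv - esv) / edv,
      ed_frame = ed_frame, es_frame = es_frame,
      lvm_mg = sum(wall_area) * slice_thickness_mm * 1.05
    )
  )
}
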