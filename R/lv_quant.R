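## Planimetric left-ventricular quantification: summation of discs,
## mass, ejection fraction, heart rate and phase-contrast stroke volume.

#' Area of a binary mask in cm^2
#'
#' @param mask binary (0/1 or logical) matrix.
#' @param pixel_spacing (row, col) spacing in mm.
#' @return Area in cm^2.
#' @export
area_from_mask <- function(mask, pixel_spacing) {
  v <- as.numeric(mask)
  if (!all(v %in% c(0, 1))) stop("invalid mask: values must be binary")
  if (any(pixel_spacing <= 0)) stop("invalid mask: pixel spacing must be > 0")
  sum(v) * prod(rep_len(pixel_spacing, 2)) / 100
}

#' Volume by summation of discs
#'
#' `sum(area_i) x (thickness + gap) / 10` so that cm^2 x mm gives ml.
#'
#' @param areas_cm2 per-slice areas in cm^2.
#' @param slice_thickness slice thickness in mm.
#' @param slice_gap inter-slice gap in mm.
#' @return Volume in ml.
#' @export
volume_summation_of_discs <- function(areas_cm2, slice_thickness,
                                      slice_gap = 0) {
  if (any(areas_cm2 < 0)) stop("invalid area: negative slice area")
  if (slice_thickness <= 0) stop("invalid area: thickness must be > 0")
  sum(areas_cm2) * (slice_thickness + slice_gap) / 10
}

#' Left-ventricular mass from myocardial volume
#'
#' Myocardial volume (epicardial minus endocardial) times the specific
#' density of myocardium, 1.05 g/cm^3.
#'
#' @param epi_volume_ml,endo_volume_ml epicardial and endocardial volumes.
#' @return Mass in g.
#' @export
lv_mass <- function(epi_volume_ml, endo_volume_ml) {
  if (endo_volume_ml < 0) stop("inverted delineation: negative endo volume")
  if (endo_volume_ml > epi_volume_ml)
    stop("inverted delineation: endo volume exceeds epi volume")
  (epi_volume_ml - endo_volume_ml) * 1.05
}

#' Stroke volume and ejection fraction
#'
#' `SV = EDV - ESV`; `EF = SV / EDV`.
#'
#' @param edv_ml,esv_ml end-diastolic and end-systolic volumes in ml.
#' @return List with `sv_ml` and `ef` (fraction).
#' @export
sv_ef <- function(edv_ml, esv_ml) {
  if (esv_ml < 0) stop("negative stroke volume: ESV must be >= 0")
  if (esv_ml > edv_ml) stop("negative stroke volume: ESV exceeds EDV")
  if (edv_ml <= 0) stop("EF undefined: EDV must be > 0")
  sv <- edv_ml - esv_ml
  list(sv_ml = sv, ef = sv / edv_ml)
}

#' Left-ventricular mass index
#'
#' @param lvm_g LV mass in g.
#' @param bsa_m2 body surface area in m^2.
#' @return LVMI in g/m^2.
#' @export
lv_mass_index <- function(lvm_g, bsa_m2) {
  if (bsa_m2 <= 0) stop("invalid BSA: must be > 0")
  lvm_g / bsa_m2
}

#' Body surface area by the Mosteller formula (convenience only)
#'
#' `sqrt(height_cm x weight_kg / 3600)`. Never applied implicitly:
#' quantification takes BSA as an input.
#'
#' @param height_cm,weight_kg height and weight.
#' @return BSA in m^2.
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  if (height_cm <= 0 || weight_kg <= 0) stop("invalid BSA inputs")
  sqrt(height_cm * weight_kg / 3600)
}

#' Heart rate averaged over three slices
#'
#' Per slice the mean ED-to-ED interval gives a rate; the result is the
#' arithmetic mean over slices chosen near the beginning, middle and end
#' of the acquisition (heart rate can drift, especially under exercise).
#'
#' @param ed_frames_per_slice list of per-slice ED frame index vectors
#'   (each with at least 2 events).
#' @param frame_interval frame interval in ms.
#' @return Heart rate in beats/min.
#' @export
heart_rate_from_ed_frames <- function(ed_frames_per_slice, frame_interval) {
  if (!is.list(ed_frames_per_slice)) ed_frames_per_slice <-
      list(ed_frames_per_slice)
  rates <- vapply(ed_frames_per_slice, function(ed) {
    if (length(ed) < 2) stop("insufficient beats: need >= 2 ED events per slice")
    60000 / (mean(diff(sort(ed))) * frame_interval)
  }, numeric(1))
  mean(rates)
}

#' Phase-contrast flow curve
#'
#' @param time_ms strictly increasing sample times in ms.
#' @param flow_ml_s flow rate in ml/s per sample.
#' @param diastole_markers strictly increasing sample indices of
#'   consecutive diastoles (>= 2).
#' @return An object of class `flow_curve`.
#' @export
flow_curve <- function(time_ms, flow_ml_s, diastole_markers) {
  if (length(time_ms) != length(flow_ml_s)) stop("time and flow lengths differ")
  if (is.unsorted(time_ms, strictly = TRUE)) stop("time must be strictly increasing")
  if (length(diastole_markers) < 2)
    stop("insufficient beats: need >= 2 diastole markers")
  if (is.unsorted(diastole_markers, strictly = TRUE))
    stop("diastole markers must be strictly increasing")
  if (min(diastole_markers) < 1 || max(diastole_markers) > length(time_ms))
    stop("diastole markers outside the curve")
  structure(list(time_ms = time_ms, flow_ml_s = flow_ml_s,
                 diastole_markers = as.integer(diastole_markers)),
            class = "flow_curve")
}

#' Average stroke volume from a phase-contrast flow curve
#'
#' Net flow (trapezoidal integral on the native sample grid) from the
#' first to the last diastole, divided by the number of beats (markers
#' minus one).
#'
#' @param curve a [flow_curve()].
#' @return Stroke volume in ml.
#' @export
flow_stroke_volume <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  m <- curve$diastole_markers
  idx <- m[1]:m[length(m)]
  t_s <- curve$time_ms[idx] / 1000
  f <- curve$flow_ml_s[idx]
  net <- sum(diff(t_s) * (head(f, -1) + tail(f, -1)) / 2)
  net / (length(m) - 1)
}

#' Quantify LV volumes and mass from a sorted stack and masks
#'
#' Per respiratory state, endo/epicardial areas at ED and ES are summed
#' into volumes by [volume_summation_of_discs()]; LVM is taken from the
#' ED delineation (the ES value is also reported). Papillary and
#' trabecular exclusion is a property of the input masks.
#'
#' @param sorted a [assemble_stack()] result.
#' @param masks nested list `masks[[state]][[slice_index]]` with elements
#'   `ed` and `es`, each a list of binary `endo` and `epi` matrices
#'   aligned to the selected frames. Slices flagged incomplete (or with
#'   missing masks) are skipped.
#' @param state respiratory state to quantify.
#' @param bsa_m2 optional body surface area for LVMI.
#' @return An object of class `lv_result` with fields `edv_ml`, `esv_ml`,
#'   `sv_ml`, `ef`, `lvm_g`, `lvm_es_g`, `lvmi_g_m2`, the per-slice area
#'   table, and the state label.
#' @export
quantify_stack <- function(sorted, masks, state = "exp", bsa_m2 = NULL) {
  stopifnot(inherits(sorted, "sorted_stack"))
  sl <- sorted$states[[state]]
  if (is.null(sl)) stop("state not present in sorted stack: ", state)
  mk <- masks[[state]]
  sp <- sorted$pixel_spacing
  rows <- list()
  for (i in seq_along(sl)) {
    s <- sl[[i]]
    m <- if (i <= length(mk)) mk[[i]] else NULL
    if (s$incomplete || is.null(m) || is.null(m$ed) || is.null(m$es)) next
    rows[[length(rows) + 1L]] <- data.frame(
      slice = s$slice, label = s$label,
      ed_frame = s$ed_frame, es_frame = s$es_frame,
      endo_ed_cm2 = area_from_mask(m$ed$endo, sp),
      epi_ed_cm2 = area_from_mask(m$ed$epi, sp),
      endo_es_cm2 = area_from_mask(m$es$endo, sp),
      epi_es_cm2 = area_from_mask(m$es$epi, sp),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("empty stack: no delineated slices to quantify")
  tab <- do.call(rbind, rows)
  dz_args <- list(slice_thickness = sorted$slice_thickness,
                  slice_gap = sorted$slice_gap)
  vol <- function(a) do.call(volume_summation_of_discs, c(list(a), dz_args))
  edv <- vol(tab$endo_ed_cm2); esv <- vol(tab$endo_es_cm2)
  epi_ed <- vol(tab$epi_ed_cm2); epi_es <- vol(tab$epi_es_cm2)
  sv <- sv_ef(edv, esv)
  res <- list(edv_ml = edv, esv_ml = esv, sv_ml = sv$sv_ml, ef = sv$ef,
              lvm_g = lv_mass(epi_ed, edv), lvm_es_g = lv_mass(epi_es, esv),
              lvmi_g_m2 = if (!is.null(bsa_m2))
                lv_mass_index(lv_mass(epi_ed, edv), bsa_m2) else NA_real_,
              state = state, per_slice = tab)
  class(res) <- "lv_result"
  res
}

#' @export
print.lv_result <- function(x, ...) {
  cat(sprintf("LV quantification [%s], %d slices:\n", x$state,
              nrow(x$per_slice)))
  cat(sprintf("  EDV %.1f ml  ESV %.1f ml  SV %.1f ml  EF %.1f%%\n",
              x$edv_ml, x$esv_ml, x$sv_ml, 100 * x$ef))
  cat(sprintf("  LVM %.1f g (ED)  %.1f g (ES)", x$lvm_g, x$lvm_es_g))
  if (is.finite(x$lvmi_g_m2)) cat(sprintf("  LVMI %.1f g/m2", x$lvmi_g_m2))
  cat("\n")
  invisible(x)
}

#' @export
summary.lv_result <- function(object, ...) {
  print(object)
  cat("per-slice areas (cm^2):\n")
  print(object$per_slice, row.names = FALSE)
  invisible(object)
}
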