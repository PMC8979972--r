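## Synthetic real-time cine phantom with exact per-frame ground truth.
##
## The image model: a bright-lung / dark-abdomen intensity step (the
## "diaphragm") translated vertically by a respiratory waveform with a
## configurable end-expiratory plateau, and a bright LV blood disc inside
## a mid-grey myocardial annulus whose endocardial radius follows cardiac
## phase. The LV translates with a fraction of the respiratory
## displacement and its blood intensity is mildly modulated with
## respiration to emulate through-plane content change. Additive Gaussian
## noise; truth (displacement, state, phase, radii, areas) is noise-free
## and analytic. Radii are expressed in pixel units on the index grid.

PHANTOM_INT <- list(lung = 0.80, abdomen = 0.15, myo = 0.35, blood = 0.90)

#' Respiratory waveform parameters
#'
#' The waveform is a raised cosine over the respiratory cycle with a flat
#' plateau of fractional width `plateau_asymmetry` around the expiratory
#' extreme, reproducing the longer end-expiratory interval of quiet
#' breathing (end inspiration is comparatively brief).
#'
#' @param period_frames respiratory period in frames (>= 4).
#' @param amplitude_px half peak-to-peak diaphragm excursion in pixels.
#' @param plateau_asymmetry fraction of the cycle flattened at the
#'   expiratory extreme, in `[0, 1)`.
#' @param period_jitter_frac multiplicative SD of per-cycle period jitter.
#' @param phase_offset starting phase in `[0, 1)` (0 = end expiration).
#' @return An object of class `resp_waveform_params`.
#' @export
resp_waveform_params <- function(period_frames = 90, amplitude_px = 6,
                                 plateau_asymmetry = 0.3,
                                 period_jitter_frac = 0,
                                 phase_offset = 0) {
  if (period_frames < 4) stop("period_frames must be >= 4")
  if (amplitude_px < 0) stop("amplitude_px must be >= 0")
  if (plateau_asymmetry < 0 || plateau_asymmetry >= 1)
    stop("plateau_asymmetry must be in [0, 1)")
  if (period_jitter_frac < 0) stop("period_jitter_frac must be >= 0")
  if (phase_offset < 0 || phase_offset >= 1)
    stop("phase_offset must be in [0, 1)")
  structure(list(period_frames = period_frames, amplitude_px = amplitude_px,
                 plateau_asymmetry = plateau_asymmetry,
                 period_jitter_frac = period_jitter_frac,
                 phase_offset = phase_offset),
            class = "resp_waveform_params")
}

#' Cardiac geometry parameters for the phantom
#'
#' The endocardial radius interpolates smoothly between its ED and ES
#' values with a systolic fraction of 1/3 of the cardiac cycle. With
#' `conserve_myocardium = TRUE` (default) the epicardial radius varies
#' with phase so the myocardial annulus keeps constant area
#' (incompressible myocardium); `epi_radius_px` is then the ED epicardial
#' radius. With `FALSE` the epicardial radius is fixed.
#'
#' @param period_frames cardiac period in frames.
#' @param endo_radius_ed_px,endo_radius_es_px endocardial radii (px) at ED
#'   and ES; must satisfy `es < ed < epi`.
#' @param epi_radius_px epicardial radius (px) at ED.
#' @param phase_offset starting cardiac phase in `[0, 1)` (0 = ED).
#' @param conserve_myocardium logical; keep annulus area constant.
#' @return An object of class `cardiac_params`.
#' @export
cardiac_params <- function(period_frames = 28, endo_radius_ed_px = 15,
                           endo_radius_es_px = 10, epi_radius_px = 19,
                           phase_offset = 0, conserve_myocardium = TRUE) {
  if (period_frames < 2) stop("period_frames must be >= 2")
  ## equality of ED and ES radii gives a non-beating phantom (useful as a
  ## static control); ES larger than ED is always an error
  if (endo_radius_es_px > endo_radius_ed_px ||
      endo_radius_ed_px >= epi_radius_px)
    stop("radii must satisfy endo ES <= endo ED < epi")
  if (phase_offset < 0 || phase_offset >= 1)
    stop("phase_offset must be in [0, 1)")
  structure(list(period_frames = period_frames,
                 endo_radius_ed_px = endo_radius_ed_px,
                 endo_radius_es_px = endo_radius_es_px,
                 epi_radius_px = epi_radius_px,
                 phase_offset = phase_offset,
                 conserve_myocardium = conserve_myocardium),
            class = "cardiac_params")
}

#' Default phantom geometry
#'
#' @param nrow,ncol image size in pixels.
#' @param pixel_spacing (row, col) spacing in mm.
#' @param frame_interval frame interval in ms.
#' @param slice_thickness,slice_gap slice geometry in mm.
#' @return A geometry list for [generate_cine_slice()].
#' @export
phantom_geometry <- function(nrow = 128, ncol = 128,
                             pixel_spacing = c(2, 2), frame_interval = 33,
                             slice_thickness = 10, slice_gap = 0) {
  list(nrow = nrow, ncol = ncol, pixel_spacing = pixel_spacing,
       frame_interval = frame_interval, slice_thickness = slice_thickness,
       slice_gap = slice_gap)
}

#' Noise SD for a target signal-to-noise ratio
#'
#' SNR is defined relative to the lung/abdomen intensity step of the
#' phantom (amplitude 0.65): `sd = 0.65 / 10^(snr_db / 20)`.
#'
#' @param snr_db target SNR in dB.
#' @return Gaussian noise standard deviation.
#' @export
noise_sd_from_snr <- function(snr_db) {
  (PHANTOM_INT$lung - PHANTOM_INT$abdomen) / 10^(snr_db / 20)
}

## waveform value at phase u: +1 on the expiratory plateau, -1 at end
## inspiration; C1-continuous
resp_wave <- function(u, plateau) {
  u <- u %% 1
  w <- cos(2 * pi * (u - plateau / 2) / (1 - plateau))
  w[u < plateau / 2 | u > 1 - plateau / 2] <- 1
  w
}

## accumulate respiratory phase with optional per-cycle period jitter;
## draws from the current RNG stream
resp_phase_series <- function(n, params) {
  per_cycle <- function(i) {
    if (params$period_jitter_frac <= 0) return(params$period_frames)
    params$period_frames * max(0.25, 1 + params$period_jitter_frac * rnorm(1))
  }
  total <- numeric(n)
  acc <- params$phase_offset
  p_cur <- per_cycle(1)
  cyc <- floor(acc)
  for (t in seq_len(n)) {
    total[t] <- acc
    acc <- acc + 1 / p_cur
    if (floor(acc) != cyc) { cyc <- floor(acc); p_cur <- per_cycle(cyc + 1) }
  }
  total
}

## fractional systolic contraction g(c): 0 at ED (c = 0), 1 at ES (c = 1/3)
cardiac_contraction <- function(phase) {
  c1 <- phase %% 1
  ifelse(c1 < 1 / 3,
         (1 - cos(pi * c1 / (1 / 3))) / 2,
         (1 + cos(pi * (c1 - 1 / 3) / (2 / 3))) / 2)
}

endo_radius_at <- function(phase, cardiac) {
  g <- cardiac_contraction(phase)
  cardiac$endo_radius_ed_px - (cardiac$endo_radius_ed_px -
                               cardiac$endo_radius_es_px) * g
}

epi_radius_at <- function(endo_r, cardiac) {
  if (cardiac$conserve_myocardium) {
    sqrt(cardiac$epi_radius_px^2 - cardiac$endo_radius_ed_px^2 + endo_r^2)
  } else {
    rep_len(cardiac$epi_radius_px, length(endo_r))
  }
}

clamp01 <- function(x) pmin(1, pmax(0, x))

render_phantom_frame <- function(nr, nc, edge_row, lv_row, lv_col,
                                 r_endo, r_epi, blood_int) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img <- PHANTOM_INT$abdomen +
    (PHANTOM_INT$lung - PHANTOM_INT$abdomen) *
    clamp01(edge_row - rows + 0.5)
  d <- sqrt((rows - lv_row)^2 + (cols - lv_col)^2)
  cov_myo <- clamp01(r_epi + 0.5 - d)
  img <- img * (1 - cov_myo) + PHANTOM_INT$myo * cov_myo
  cov_blood <- clamp01(r_endo + 0.5 - d)
  img * (1 - cov_blood) + blood_int * cov_blood
}

## true cardiac event frames: phase crosses `target` (0 = ED, 1/3 = ES)
cardiac_event_frames <- function(n, cardiac, target) {
  ## total phase at frame t is offset + (t - 1) / period
  j <- seq(floor(cardiac$phase_offset) - 1,
           ceiling(cardiac$phase_offset + n / cardiac$period_frames) + 1)
  t_star <- round((j + target - cardiac$phase_offset) *
                  cardiac$period_frames) + 1
  sort(t_star[t_star >= 1 & t_star <= n])
}

## Per-cycle respiratory extrema from the noise-free waveform. Expiration
## (phase 0) sits at the cycle boundary, so expiratory grouping is shifted
## by half a cycle to keep each plateau whole; extrema truncated by the
## sequence ends are dropped.
resp_truth_extrema <- function(total_phase, w) {
  n <- length(w)
  exp_frames <- integer(0); plateaus <- list()
  for (g in unique(floor(total_phase + 0.5))) {
    idx <- which(floor(total_phase + 0.5) == g)
    plateau <- idx[w[idx] >= 1 - 1e-9]
    if (length(plateau)) {
      if (min(plateau) == 1 || max(plateau) == n) next
      exp_frames <- c(exp_frames, plateau[ceiling(length(plateau) / 2)])
      plateaus[[length(plateaus) + 1L]] <- plateau
    } else {
      i <- idx[which.max(w[idx])]
      if (i > min(idx) && i < max(idx) && i > 1 && i < n) {
        exp_frames <- c(exp_frames, i)
        plateaus[[length(plateaus) + 1L]] <- i
      }
    }
  }
  insp_frames <- integer(0)
  for (g in unique(floor(total_phase))) {
    idx <- which(floor(total_phase) == g)
    j <- idx[which.min(w[idx])]
    if (j > min(idx) && j < max(idx) && j > 1 && j < n)
      insp_frames <- c(insp_frames, j)
  }
  list(expiration = sort(unique(exp_frames)),
       inspiration = sort(unique(insp_frames)),
       expiration_plateaus = plateaus)
}

#' Generate one synthetic real-time cine slice with ground truth
#'
#' @param resp a [resp_waveform_params()].
#' @param cardiac a [cardiac_params()].
#' @param geometry a [phantom_geometry()] list.
#' @param n_frames number of frames; at least two respiratory cycles.
#' @param noise_sd additive Gaussian noise SD (image intensities are on a
#'   0-1 scale; see [noise_sd_from_snr()]).
#' @param seed integer RNG seed (mandatory, for reproducibility).
#' @param lv_resp_fraction fraction of the diaphragm displacement applied
#'   to the LV centre (cardiac translation is smaller than diaphragmatic).
#' @param through_plane fractional modulation of blood intensity with the
#'   respiratory waveform (through-plane content change).
#' @param label series label.
#' @return A list with elements `series` (a [cine_series()]) and `truth`
#'   (per-frame data frame plus respiratory extrema, true ED/ES frames and
#'   the generating parameters).
#' @export
generate_cine_slice <- function(resp = resp_waveform_params(),
                                cardiac = cardiac_params(),
                                geometry = phantom_geometry(),
                                n_frames = 500, noise_sd = 0.065,
                                seed, lv_resp_fraction = 0.4,
                                through_plane = 0.05, label = "phantom") {
  stopifnot(inherits(resp, "resp_waveform_params"),
            inherits(cardiac, "cardiac_params"))
  if (missing(seed)) stop("seed is required")
  if (n_frames < 2 * resp$period_frames)
    stop("insufficient respiratory coverage: need n_frames >= 2 x respiratory period")
  nr <- geometry$nrow; nc <- geometry$ncol
  diaphragm_row0 <- round(0.32 * nr)
  lv_row0 <- round(0.66 * nr); lv_col0 <- round(0.50 * nc)
  A <- resp$amplitude_px
  max_epi <- cardiac$epi_radius_px
  if (diaphragm_row0 - A < 2 || diaphragm_row0 + A > nr - 1 ||
      lv_row0 - lv_resp_fraction * A - max_epi < 2 ||
      lv_row0 + lv_resp_fraction * A + max_epi > nr - 1 ||
      lv_col0 - max_epi < 2 || lv_col0 + max_epi > nc - 1)
    stop("phantom exceeds field of view")

  set.seed(as.integer(seed))
  total_phase <- resp_phase_series(n_frames, resp)
  w <- resp_wave(total_phase, resp$plateau_asymmetry)
  c_phase <- (cardiac$phase_offset +
              (seq_len(n_frames) - 1) / cardiac$period_frames) %% 1
  r_endo <- endo_radius_at(c_phase, cardiac)
  r_epi <- epi_radius_at(r_endo, cardiac)
  edge_row <- diaphragm_row0 - A * w          # cranial (small row) at exp
  lv_row <- lv_row0 - lv_resp_fraction * A * w
  ## content change is driven by the respiratory displacement itself, so a
  ## motionless phantom (A = 0) has none
  blood <- PHANTOM_INT$blood * (1 + through_plane * w * (A / max(1, A)))

  frames <- array(0, dim = c(nr, nc, n_frames))
  for (t in seq_len(n_frames))
    frames[, , t] <- render_phantom_frame(nr, nc, edge_row[t], lv_row[t],
                                          lv_col0, r_endo[t], r_epi[t],
                                          blood[t])
  if (noise_sd > 0)
    frames <- frames + array(rnorm(length(frames), sd = noise_sd),
                             dim = dim(frames))

  px_cm2 <- prod(geometry$pixel_spacing) / 100
  state <- ifelse(w > 0.9, "end-exp", ifelse(w < -0.9, "end-insp", "transit"))
  per_frame <- data.frame(
    frame = seq_len(n_frames),
    displacement_px = A * w,
    resp_state = state,
    cardiac_phase = c_phase,
    endo_radius_px = r_endo,
    epi_radius_px = r_epi,
    endo_area_cm2 = pi * r_endo^2 * px_cm2,
    epi_area_cm2 = pi * r_epi^2 * px_cm2,
    lv_row = lv_row, lv_col = lv_col0,
    edge_row = edge_row,
    stringsAsFactors = FALSE)

  series <- cine_series(frames, pixel_spacing = geometry$pixel_spacing,
                        frame_interval = geometry$frame_interval,
                        slice_thickness = geometry$slice_thickness,
                        slice_gap = geometry$slice_gap,
                        slice_location = 0, label = label)
  truth <- c(list(per_frame = per_frame,
                  ed_frames = cardiac_event_frames(n_frames, cardiac, 0),
                  es_frames = cardiac_event_frames(n_frames, cardiac, 1 / 3),
                  resp = resp, cardiac = cardiac, geometry = geometry,
                  noise_sd = noise_sd, seed = seed,
                  lv_resp_fraction = lv_resp_fraction,
                  through_plane = through_plane),
             resp_truth_extrema(total_phase, w))
  list(series = series, truth = truth)
}

#' Generate a multi-slice phantom stack with analytic true volumes
#'
#' Slices are independent acquisitions: respiratory and cardiac phase
#' offsets are randomized per slice (non-gated free breathing), while the
#' slice geometry tapers base to apex through `slice_scales`. True EDV,
#' ESV, epicardial volumes and LV mass follow in closed form as sums of
#' discs.
#'
#' @param resp,cardiac,geometry as in [generate_cine_slice()]; `cardiac`
#'   gives the basal (scale 1) radii.
#' @param n_slices number of slices (>= 3), base to apex.
#' @param n_frames frames per slice.
#' @param noise_sd additive noise SD.
#' @param seed integer RNG seed.
#' @param slice_scales non-increasing per-slice radius scale factors;
#'   default an ellipsoid-like taper to ~0.5 at the apex.
#' @param randomize_phases logical; draw per-slice respiratory/cardiac
#'   phase offsets (default) or keep the supplied offsets for all slices.
#' @param ... passed to [generate_cine_slice()].
#' @return A list: `stack` (a [cine_stack()]), `truth` (per-slice truth
#'   lists), `slice_scales`, and `volumes` with analytic `edv_ml`,
#'   `esv_ml`, `epi_edv_ml`, `epi_esv_ml`, `lvm_g`.
#' @export
generate_cine_stack <- function(resp = resp_waveform_params(),
                                cardiac = cardiac_params(),
                                geometry = phantom_geometry(),
                                n_slices = 8, n_frames = 500,
                                noise_sd = 0.065, seed,
                                slice_scales = NULL,
                                randomize_phases = TRUE, ...) {
  if (missing(seed)) stop("seed is required")
  if (n_slices < 3) stop("stack too short: need at least 3 slices")
  if (is.null(slice_scales)) {
    z <- 0.85 * (seq_len(n_slices) - 1) / (n_slices - 1)
    slice_scales <- sqrt(1 - z^2)
  }
  if (length(slice_scales) != n_slices || is.unsorted(rev(slice_scales)))
    stop("slice_scales must be non-increasing, one per slice")

  set.seed(as.integer(seed))
  resp_off <- if (randomize_phases) runif(n_slices) else
    rep(resp$phase_offset, n_slices)
  card_off <- if (randomize_phases) runif(n_slices) else
    rep(cardiac$phase_offset, n_slices)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_slices)

  slices <- vector("list", n_slices)
  truths <- vector("list", n_slices)
  dz <- geometry$slice_thickness + geometry$slice_gap
  for (i in seq_len(n_slices)) {
    s <- slice_scales[i]
    ci <- cardiac_params(period_frames = cardiac$period_frames,
                         endo_radius_ed_px = s * cardiac$endo_radius_ed_px,
                         endo_radius_es_px = s * cardiac$endo_radius_es_px,
                         epi_radius_px = s * cardiac$epi_radius_px,
                         phase_offset = card_off[i],
                         conserve_myocardium = cardiac$conserve_myocardium)
    ri <- resp_waveform_params(period_frames = resp$period_frames,
                               amplitude_px = resp$amplitude_px,
                               plateau_asymmetry = resp$plateau_asymmetry,
                               period_jitter_frac = resp$period_jitter_frac,
                               phase_offset = resp_off[i])
    out <- generate_cine_slice(ri, ci, geometry, n_frames = n_frames,
                               noise_sd = noise_sd, seed = sub_seeds[i],
                               label = sprintf("slice_%02d", i), ...)
    out$series$slice_location <- (i - 1) * dz
    slices[[i]] <- out$series
    truths[[i]] <- out$truth
  }

  px_cm2 <- prod(geometry$pixel_spacing) / 100
  disc <- function(r_px) pi * r_px^2 * px_cm2 * dz / 10  # ml per slice
  r_ed <- slice_scales * cardiac$endo_radius_ed_px
  r_es <- slice_scales * cardiac$endo_radius_es_px
  R_ed <- slice_scales * cardiac$epi_radius_px
  R_es <- if (cardiac$conserve_myocardium)
    sqrt(R_ed^2 - r_ed^2 + r_es^2) else R_ed
  volumes <- list(edv_ml = sum(disc(r_ed)), esv_ml = sum(disc(r_es)),
                  epi_edv_ml = sum(disc(R_ed)), epi_esv_ml = sum(disc(R_es)),
                  lvm_g = (sum(disc(R_ed)) - sum(disc(r_ed))) * 1.05)
  list(stack = cine_stack(slices), truth = truths,
       slice_scales = slice_scales, volumes = volumes)
}

#' Default ROI placements for the phantom
#'
#' In practice the respiratory and LV ROIs are placed by the user; for the
#' phantom their correct positions follow from the generating parameters.
#' `phantom_resp_roi()` covers the diaphragm edge over its full excursion,
#' `phantom_lv_roi()` covers the LV at its largest extent.
#'
#' @param geometry a [phantom_geometry()] list.
#' @param resp a [resp_waveform_params()].
#' @param cardiac a [cardiac_params()].
#' @param width ROI width in pixels (respiratory ROI).
#' @return A [resp_roi()].
#' @export
phantom_resp_roi <- function(geometry = phantom_geometry(),
                             resp = resp_waveform_params(), width = 40) {
  r0 <- round(0.32 * geometry$nrow)
  half <- ceiling(resp$amplitude_px) + 8
  c0 <- round(0.50 * geometry$ncol)
  resp_roi(max(1, r0 - half), min(geometry$nrow, r0 + half),
           max(1, c0 - width %/% 2), min(geometry$ncol, c0 + width %/% 2 - 1))
}

#' @rdname phantom_resp_roi
#' @export
phantom_lv_roi <- function(geometry = phantom_geometry(),
                           cardiac = cardiac_params(),
                           resp = resp_waveform_params()) {
  r0 <- round(0.66 * geometry$nrow)
  c0 <- round(0.50 * geometry$ncol)
  half <- ceiling(cardiac$epi_radius_px + 0.4 * resp$amplitude_px) + 3
  resp_roi(max(1, r0 - half), min(geometry$nrow, r0 + half),
           max(1, c0 - half), min(geometry$ncol, c0 + half))
}

#' Rasterized true endo/epicardial masks for a phantom frame
#'
#' Binary discs (pixel centre within the true radius) at the true LV
#' position of the requested frame; the reference delineation for testing
#' quantification against the phantom.
#'
#' @param truth a slice truth list from [generate_cine_slice()].
#' @param frame frame index.
#' @return A list with binary matrices `endo` and `epi`.
#' @export
phantom_masks <- function(truth, frame) {
  pf <- truth$per_frame
  stopifnot(frame >= 1, frame <= nrow(pf))
  nr <- truth$geometry$nrow; nc <- truth$geometry$ncol
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((rows - pf$lv_row[frame])^2 + (cols - pf$lv_col[frame])^2)
  list(endo = (d <= pf$endo_radius_px[frame]) * 1,
       epi = (d <= pf$epi_radius_px[frame]) * 1)
}
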