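# Small phantom configurations shared across test files. The full-size
# stack used by the end-to-end checks is generated once per session and
# cached, since several tests measure different properties of the same
# seeded acquisition.

small_geometry <- function() phantom_geometry(nrow = 96, ncol = 96)

small_resp <- function(...) {
  args <- list(period_frames = 40, amplitude_px = 5, plateau_asymmetry = 0.3)
  args[names(list(...))] <- list(...)
  do.call(resp_waveform_params, args)
}

small_cardiac <- function(...) {
  args <- list(period_frames = 16, endo_radius_ed_px = 12,
               endo_radius_es_px = 8, epi_radius_px = 15)
  args[names(list(...))] <- list(...)
  do.call(cardiac_params, args)
}

small_slice <- function(seed = 11, n_frames = 160, noise_sd = 0.02, ...) {
  generate_cine_slice(small_resp(), small_cardiac(), small_geometry(),
                      n_frames = n_frames, noise_sd = noise_sd,
                      seed = seed, ...)
}

.phantom_cache <- new.env(parent = emptyenv())

# seeded 8-slice, 500-frame acquisition at SNR 20 dB: the study conditions
# of the end-to-end checks
study_stack <- function() {
  if (is.null(.phantom_cache$stack))
    .phantom_cache$stack <- generate_cine_stack(
      resp = resp_waveform_params(period_frames = 90, amplitude_px = 6,
                                  plateau_asymmetry = 0.3,
                                  period_jitter_frac = 0.05),
      cardiac = cardiac_params(), geometry = phantom_geometry(),
      n_slices = 8, n_frames = 500, noise_sd = noise_sd_from_snr(20),
      seed = 20220404)
  .phantom_cache$stack
}

study_sorted <- function() {
  if (is.null(.phantom_cache$sorted)) {
    ph <- study_stack()
    .phantom_cache$sorted <- respiratory_sort(
      ph$stack, phantom_resp_roi(), phantom_lv_roi(),
      mode = "rest", states = "exp")
  }
  .phantom_cache$sorted
}

# truth-rasterized masks at the selected frames of a sorted run
truth_masks_for <- function(ph, selections, state = "exp") {
  out <- list()
  out[[state]] <- lapply(seq_along(ph$truth), function(i) {
    sel <- selections[selections$slice == i & selections$state == state, ]
    if (!nrow(sel) || is.na(sel$ed_frame) || is.na(sel$es_frame)) return(NULL)
    list(ed = phantom_masks(ph$truth[[i]], sel$ed_frame),
         es = phantom_masks(ph$truth[[i]], sel$es_frame))
  })
  out
}

contiguous_groups <- function(frames) {
  if (!length(frames)) return(list())
  frames <- sort(frames)
  split(frames, cumsum(c(1, diff(frames) > 1)))
}

# Bidirectional extrema match against truth, restricted to the interior
# (a centered smoothing window cannot establish an extreme at the ends).
# A true extreme is a per-cycle frame set: the whole plateau for
# expiration, the labelled end-state neighbourhood for inspiration.
match_extrema <- function(detected, cycle_sets, n, period, tol = 2) {
  margin <- ceiling(period / 4)
  interior <- vapply(cycle_sets, function(s)
    min(s) > margin && max(s) < n - margin, logical(1))
  fwd <- vapply(cycle_sets[interior], function(s)
    min(outer(detected, s, function(a, b) abs(a - b))), numeric(1))
  all_truth <- unlist(cycle_sets)
  de <- detected[detected > margin & detected < n - margin]
  bwd <- if (length(de))
    vapply(de, function(f) min(abs(all_truth - f)), numeric(1)) else numeric(0)
  list(truth_matched = all(fwd <= tol),
       detected_matched = all(bwd <= tol),
       counts_equal = sum(interior) == length(de),
       max_offset = if (length(fwd)) max(fwd) else 0)
}
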