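## Respiratory extrema detection, state windows, ED/ES frame selection and
## assembly of respiratory-matched short-axis stacks with QC checks.

## centered moving average with partial windows at the boundaries
moving_average <- function(y, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(y)
  n <- length(y)
  h <- width %/% 2
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

## dominant nonzero-frequency period of a (mean-removed) signal, frames
estimate_period <- function(y) {
  n <- length(y)
  sp <- Mod(stats::fft(y - mean(y)))[2:floor(n / 2)]
  if (!length(sp) || all(sp == 0)) return(NA_real_)
  n / which.max(sp)
}

## local maxima indices with plateaus collapsed to their midpoints
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  ## run-length encode to handle flat tops
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_up <- i > 1 && r$values[i - 1] < r$values[i]
    right_dn <- i < k && r$values[i + 1] < r$values[i]
    if (left_up && right_dn)
      out <- c(out, starts[i] + (r$lengths[i] - 1) %/% 2)
  }
  out
}

## topographic prominence of peaks at indices `pk` of signal y
peak_prominence <- function(y, pk) {
  vapply(pk, function(i) {
    h <- y[i]
    lmin <- h; j <- i
    while (j > 1) { j <- j - 1; if (y[j] > h) break; lmin <- min(lmin, y[j]) }
    base_l <- if (j >= 1 && y[j] > h) lmin else min(y[1:i])
    rmin <- h; j <- i; n <- length(y)
    while (j < n) { j <- j + 1; if (y[j] > h) break; rmin <- min(rmin, y[j]) }
    base_r <- if (j <= n && y[j] > h) rmin else min(y[i:n])
    h - max(base_l, base_r)
  }, numeric(1))
}

## greedy minimum-separation filter keeping higher peaks first
enforce_separation <- function(pk, height, min_sep) {
  keep <- logical(length(pk))
  for (i in order(height, decreasing = TRUE)) {
    if (!any(keep & abs(pk - pk[i]) < min_sep)) keep[i] <- TRUE
  }
  sort(pk[keep])
}

#' Detect respiratory extrema on an oriented curve
#'
#' The curve is smoothed by a centered moving average (default width a
#' quarter of the respiratory period, estimated from the dominant FFT
#' frequency), then local maxima/minima are kept if their topographic
#' prominence reaches `min_prominence_frac` of the smoothed curve range
#' and they are separated by at least half a period. Maxima are
#' end expiration under the `"expiration-up"` orientation. Extrema of the
#' same type are finally forced to interleave (the more extreme of an
#' adjacent same-type pair is kept).
#'
#' @param curve an oriented `resp_curve`, or a numeric vector together
#'   with `orientation = "expiration-up"`.
#' @param smoothing_width moving-average width in frames; default
#'   `round(0.25 * period)`.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   smoothed curve range (default 0.2).
#' @param orientation required when `curve` is a bare vector or the curve
#'   orientation is `"undetermined"`.
#' @return An object of class `resp_extrema`: `expiration_frames`,
#'   `inspiration_frames`, `estimated_period_frames`, `smoothing_width`,
#'   `confidence`.
#' @export
detect_extrema <- function(curve, smoothing_width = NULL,
                           min_prominence_frac = 0.2, orientation = NULL) {
  if (inherits(curve, "resp_curve")) {
    y <- curve$values
    if (is.null(orientation)) orientation <- curve$orientation
  } else {
    y <- as.numeric(curve)
    if (is.null(orientation)) stop("orientation must be supplied for a bare vector")
  }
  if (identical(orientation, "undetermined"))
    stop("curve orientation is undetermined; supply orientation or manual extrema")
  n <- length(y)
  rng <- diff(range(y))
  if (rng <= 1e-12 * max(abs(y), 1)) stop("no respiratory signal: curve is constant")
  period0 <- estimate_period(y)
  if (!is.finite(period0)) stop("no respiratory signal: flat spectrum")
  if (is.null(smoothing_width)) smoothing_width <- max(1, round(0.25 * period0))
  ys <- moving_average(y, smoothing_width)
  period <- estimate_period(ys)
  if (!is.finite(period)) period <- period0
  if (n < 2 * period) stop("insufficient cycles: need at least two periods")

  srng <- diff(range(ys))
  find <- function(sig) {
    pk <- local_maxima(sig)
    if (!length(pk)) return(integer(0))
    prom <- peak_prominence(sig, pk)
    pk <- pk[prom >= min_prominence_frac * srng]
    if (!length(pk)) return(integer(0))
    enforce_separation(pk, sig[pk], 0.5 * period)
  }
  maxima <- find(ys)
  minima <- find(-ys)
  if (length(maxima) < 2 || length(minima) < 2)
    stop("insufficient cycles: fewer than 2 extrema of each type detected")

  ## enforce interleaving: in runs of same-type extrema keep the most extreme
  ext <- data.frame(frame = c(maxima, minima),
                    type = rep(c("max", "min"), c(length(maxima), length(minima))))
  ext <- ext[order(ext$frame), ]
  val <- ifelse(ext$type == "max", ys[ext$frame], -ys[ext$frame])
  keep <- rep(TRUE, nrow(ext))
  i <- 1
  while (i < nrow(ext)) {
    j <- i
    while (j < nrow(ext) && ext$type[j + 1] == ext$type[i]) j <- j + 1
    if (j > i) {
      run <- i:j
      keep[run] <- FALSE
      keep[run[which.max(val[run])]] <- TRUE
    }
    i <- j + 1
  }
  ext <- ext[keep, ]
  maxima <- ext$frame[ext$type == "max"]
  minima <- ext$frame[ext$type == "min"]

  intervals <- diff(sort(c(maxima)))
  confidence <- if (length(intervals) >= 2)
    max(0, min(1, 1 - stats::sd(intervals) / mean(intervals))) else 0.5
  structure(list(expiration_frames = maxima, inspiration_frames = minima,
                 estimated_period_frames = period,
                 smoothing_width = smoothing_width,
                 min_prominence_frac = min_prominence_frac,
                 confidence = confidence, n = n),
            class = "resp_extrema")
}

#' @export
print.resp_extrema <- function(x, ...) {
  cat(sprintf("resp_extrema: %d end-expiration, %d end-inspiration extrema\n",
              length(x$expiration_frames), length(x$inspiration_frames)))
  cat(sprintf("  period ~ %.1f frames, smoothing %d, confidence %.2f\n",
              x$estimated_period_frames, x$smoothing_width, x$confidence))
  invisible(x)
}

#' Respiratory-state search windows around each extreme
#'
#' Default half-widths reflect the relative durations of the respiratory
#' states: at rest +/-15 frames around end expiration and +/-10 around
#' end inspiration; during exercise (shorter cycles) +/-8 and +/-5.
#' Windows are clipped to the acquisition and truncated at the midpoint
#' between adjacent opposite-state extrema so they never overlap (the
#' midpoint frame is assigned to the earlier window).
#'
#' @param extrema a [detect_extrema()] result.
#' @param mode `"rest"` or `"exercise"`.
#' @param n_frames total frame count (defaults to the curve length).
#' @param halfwidth_exp,halfwidth_insp half-width overrides in frames.
#' @return Data frame: `extreme_frame`, `state`, `lo`, `hi`.
#' @export
state_windows <- function(extrema, mode = c("rest", "exercise"),
                          n_frames = extrema$n,
                          halfwidth_exp = NULL, halfwidth_insp = NULL) {
  stopifnot(inherits(extrema, "resp_extrema"))
  mode <- match.arg(mode)
  hw <- switch(mode, rest = c(exp = 15, insp = 10),
               exercise = c(exp = 8, insp = 5))
  if (!is.null(halfwidth_exp)) hw["exp"] <- halfwidth_exp
  if (!is.null(halfwidth_insp)) hw["insp"] <- halfwidth_insp
  ext <- rbind(
    data.frame(extreme_frame = extrema$expiration_frames, state = "exp"),
    data.frame(extreme_frame = extrema$inspiration_frames, state = "insp"))
  if (!nrow(ext)) stop("no extrema")
  ext <- ext[order(ext$extreme_frame), ]
  h <- hw[ext$state]
  ext$lo <- pmax(1, ext$extreme_frame - h)
  ext$hi <- pmin(n_frames, ext$extreme_frame + h)
  ## non-overlap: truncate adjacent windows at the midpoint
  if (nrow(ext) > 1) {
    for (i in seq_len(nrow(ext) - 1)) {
      if (ext$hi[i] >= ext$lo[i + 1]) {
        mid <- (ext$extreme_frame[i] + ext$extreme_frame[i + 1]) %/% 2
        ext$hi[i] <- min(ext$hi[i], mid)
        ext$lo[i + 1] <- max(ext$lo[i + 1], mid + 1)
      }
    }
  }
  rownames(ext) <- NULL
  ext
}

## Otsu threshold on a 256-bin histogram (maximum between-class variance)
otsu_threshold <- function(x, nbins = 256) {
  rng <- range(x)
  if (diff(rng) <= 0) stop("lumen proxy unavailable: degenerate ROI histogram")
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  if (all(sb2 == 0)) stop("lumen proxy unavailable: degenerate ROI histogram")
  kstar <- mean(which(sb2 == max(sb2)))  # tie -> midpoint, as usual
  rng[1] + kstar / nbins * diff(rng)
}

#' Per-frame lumen blood-pool proxy
#'
#' Bright-blood convention: the count of pixels within the LV ROI above an
#' Otsu threshold computed over the whole cropped sub-sequence, times the
#' pixel area. Tracks cavity area well enough to rank frames by lumen
#' blood volume (maximum = ED, minimum = ES).
#'
#' @param series a [cine_series()].
#' @param lv_roi a [resp_roi()] containing the LV.
#' @return Numeric vector, one area (cm^2) per frame, with attribute
#'   `threshold`.
#' @export
lumen_signal <- function(series, lv_roi) {
  x <- crop_roi(series, lv_roi)
  thr <- otsu_threshold(as.numeric(x))
  out <- rowSums(x > thr) * pixel_area_cm2(series)
  attr(out, "threshold") <- thr
  out
}

#' Suggest ED and ES frames within a respiratory window
#'
#' ED is the in-window argmax of the lumen proxy and ES the argmin, with
#' ties broken toward the window centre (the respiratory extreme), then
#' toward the later frame.
#'
#' @param proxy per-frame lumen proxy ([lumen_signal()]).
#' @param window integer frame window (>= 3 frames), e.g. `lo:hi` from
#'   [state_windows()].
#' @param centre the anchoring extreme frame (default window midpoint).
#' @return List with `ed_frame`, `es_frame`.
#' @export
suggest_ed_es <- function(proxy, window, centre = NULL) {
  window <- as.integer(window)
  if (length(window) < 3) stop("window too narrow: need at least 3 frames")
  if (is.null(centre)) centre <- window[(length(window) + 1) %/% 2]
  v <- proxy[window]
  if (diff(range(v)) == 0) stop("no cardiac variation in window")
  pick <- function(vals) {
    o <- order(-vals, abs(window - centre), -window)
    window[o[1]]
  }
  ed <- pick(v)
  es <- pick(-v)
  if (ed == es) stop("no cardiac variation in window")
  list(ed_frame = ed, es_frame = es)
}

#' Assemble a respiratory-matched short-axis stack
#'
#' Copies the selected ED/ES frames of each slice and requested
#' respiratory state into a `sorted_stack` with provenance. Slices missing
#' a phase are included but flagged incomplete (mirroring exclusion of a
#' basal slice whose ED/ES never coincides with the state); slices with an
#' explicit `skip` are dropped.
#'
#' @param stack a [cine_stack()].
#' @param selections data frame with columns `slice`, `state`
#'   (`"exp"`/`"insp"`), `ed_frame`, `es_frame` (NA allowed), and
#'   optionally `source`, `anchor`, `skip`.
#' @param states respiratory states to assemble.
#' @return An object of class `sorted_stack`.
#' @export
assemble_stack <- function(stack, selections, states = c("exp", "insp")) {
  stopifnot(inherits(stack, "cine_stack"))
  states <- match.arg(states, c("exp", "insp"), several.ok = TRUE)
  if (!nrow(selections)) stop("empty stack: no slice selected")
  if (is.null(selections$source)) selections$source <- "auto"
  if (is.null(selections$skip)) selections$skip <- FALSE
  out <- list()
  for (st in states) {
    sel <- selections[selections$state == st & !selections$skip, , drop = FALSE]
    if (!nrow(sel)) stop("empty stack: no slice selected for state ", st)
    slices <- list()
    for (r in seq_len(nrow(sel))) {
      i <- sel$slice[r]
      s <- stack$slices[[i]]
      ed <- sel$ed_frame[r]; es <- sel$es_frame[r]
      slices[[length(slices) + 1L]] <- list(
        slice = i, label = s$label, slice_location = s$slice_location,
        ed = if (!is.na(ed)) s$frames[, , ed] else NULL,
        es = if (!is.na(es)) s$frames[, , es] else NULL,
        ed_frame = ed, es_frame = es,
        source = sel$source[r],
        anchor = if (!is.null(sel$anchor)) sel$anchor[r] else NA,
        incomplete = is.na(ed) || is.na(es))
    }
    slices <- slices[order(vapply(slices, `[[`, numeric(1), "slice_location"))]
    out[[st]] <- slices
  }
  geom <- stack$slices[[1]]
  structure(list(states = out,
                 pixel_spacing = geom$pixel_spacing,
                 frame_interval = geom$frame_interval,
                 slice_thickness = geom$slice_thickness,
                 slice_gap = geom$slice_gap,
                 flags = list(duplicates = list(), lv_length = NULL)),
            class = "sorted_stack")
}

#' @export
print.sorted_stack <- function(x, ...) {
  for (st in names(x$states)) {
    sl <- x$states[[st]]
    inc <- sum(vapply(sl, `[[`, logical(1), "incomplete"))
    cat(sprintf("sorted_stack [%s]: %d slices (%d incomplete)\n",
                st, length(sl), inc))
    for (s in sl)
      cat(sprintf("  %-12s ED frame %4s  ES frame %4s%s\n", s$label,
                  ifelse(is.na(s$ed_frame), "-", s$ed_frame),
                  ifelse(is.na(s$es_frame), "-", s$es_frame),
                  if (s$incomplete) "  [incomplete]" else ""))
  }
  if (length(x$flags$duplicates))
    cat(sprintf("  duplicate-slice flags: %d pair(s)\n",
                length(x$flags$duplicates)))
  invisible(x)
}

## zero-normalized cross-correlation of two images
zncc <- function(a, b) {
  av <- as.numeric(a) - mean(a); bv <- as.numeric(b) - mean(b)
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(NA_real_)
  sum(av * bv) / den
}

#' Flag potential duplicate slices
#'
#' Cardiac translation during free breathing can acquire the same
#' anatomical slice twice. For each adjacent slice pair and state, the
#' zero-normalized cross-correlation of the ED images is computed; pairs
#' with NCC at or above the threshold are flagged for review. Flag-only:
#' removal is the user's decision.
#'
#' @param sorted a [assemble_stack()] result.
#' @param ncc_threshold flag threshold (default 0.98).
#' @return The `sorted_stack` with `flags$duplicates` populated
#'   (list of `state`, `pair`, `ncc`).
#' @export
flag_duplicate_slices <- function(sorted, ncc_threshold = 0.98) {
  stopifnot(inherits(sorted, "sorted_stack"))
  flags <- list()
  for (st in names(sorted$states)) {
    sl <- sorted$states[[st]]
    if (length(sl) < 2) next
    for (i in seq_len(length(sl) - 1)) {
      a <- sl[[i]]$ed; b <- sl[[i + 1]]$ed
      if (is.null(a) || is.null(b)) next
      r <- zncc(a, b)
      if (!is.na(r) && r >= ncc_threshold)
        flags[[length(flags) + 1L]] <-
          list(state = st, pair = c(sl[[i]]$slice, sl[[i + 1]]$slice), ncc = r)
    }
  }
  sorted$flags$duplicates <- flags
  sorted
}

#' Check LV length against the 4-chamber view
#'
#' The short-axis LV length implied by the delineated slices,
#' `count x (thickness + gap)`, is compared with the length measured in
#' the 4-chamber view; a discrepancy of more than one slice spacing raises
#' the mismatch flag (too few or too many slices included).
#'
#' @param slice_thickness,slice_gap slice geometry in mm.
#' @param lv_length_4ch_mm LV length measured in the 4-chamber view (mm).
#' @param delineated_slice_count number of delineated short-axis slices.
#' @return List with `computed_length_mm`, `measured_length_mm`,
#'   `mismatch` (logical).
#' @export
check_lv_length <- function(slice_thickness, slice_gap = 0,
                            lv_length_4ch_mm, delineated_slice_count) {
  if (slice_thickness <= 0 || lv_length_4ch_mm <= 0 ||
      delineated_slice_count <= 0 || slice_gap < 0)
    stop("invalid length: inputs must be positive")
  dz <- slice_thickness + slice_gap
  computed <- delineated_slice_count * dz
  list(computed_length_mm = computed,
       measured_length_mm = lv_length_4ch_mm,
       mismatch = abs(computed - lv_length_4ch_mm) > dz)
}

#' Run the respiratory sorting pipeline over a stack
#'
#' For every slice: embed the diaphragm ROI, detect extrema, build state
#' windows, rank the windows of each requested state by in-window lumen
#' variation, and suggest ED/ES in the best window. Slices where no
#' window yields both phases are flagged incomplete.
#'
#' @param stack a [cine_stack()].
#' @param resp_roi a [resp_roi()] over the diaphragm (shared by slices, or
#'   a list of one per slice).
#' @param lv_roi a [resp_roi()] over the LV (shared or per-slice list).
#' @param mode `"rest"` or `"exercise"`.
#' @param states respiratory states to assemble.
#' @param k,sigma2 embedding parameters.
#' @param smoothing_width,min_prominence_frac extrema parameters.
#' @param curves optional list of precomputed oriented `resp_curve`s (one
#'   per slice), e.g. manual fallback when the diaphragm leaves the ROI.
#' @return A list: `sorted` (the [assemble_stack()] result, with duplicate
#'   flags), `selections`, `curves`, `extrema`.
#' @export
respiratory_sort <- function(stack, resp_roi, lv_roi,
                             mode = c("rest", "exercise"),
                             states = c("exp", "insp"), k = 10,
                             sigma2 = NULL, smoothing_width = NULL,
                             min_prominence_frac = 0.2, curves = NULL) {
  stopifnot(inherits(stack, "cine_stack"))
  mode <- match.arg(mode)
  states <- match.arg(states, c("exp", "insp"), several.ok = TRUE)
  ns <- length(stack$slices)
  get_roi <- function(r, i) if (inherits(r, "resp_roi")) r else r[[i]]
  sel <- list(); all_curves <- list(); all_ext <- list()
  for (i in seq_len(ns)) {
    s <- stack$slices[[i]]
    curve <- if (!is.null(curves)) curves[[i]] else
      resp_embed(s, get_roi(resp_roi, i), k = k, sigma2 = sigma2)
    ext <- detect_extrema(curve, smoothing_width = smoothing_width,
                          min_prominence_frac = min_prominence_frac)
    win <- state_windows(ext, mode = mode, n_frames = n_frames(s))
    proxy <- lumen_signal(s, get_roi(lv_roi, i))
    for (st in states) {
      w_st <- win[win$state == st, , drop = FALSE]
      best <- NULL; best_range <- -Inf
      for (r in seq_len(nrow(w_st))) {
        idx <- w_st$lo[r]:w_st$hi[r]
        if (length(idx) < 3) next
        rng <- diff(range(proxy[idx]))
        if (rng > best_range) { best_range <- rng; best <- r }
      }
      ed <- es <- NA_integer_; anchor <- NA_integer_
      if (!is.null(best) && best_range > 0) {
        idx <- w_st$lo[best]:w_st$hi[best]
        anchor <- w_st$extreme_frame[best]
        sugg <- tryCatch(suggest_ed_es(proxy, idx, centre = anchor),
                         error = function(e) NULL)
        if (!is.null(sugg)) { ed <- sugg$ed_frame; es <- sugg$es_frame }
      }
      sel[[length(sel) + 1L]] <- data.frame(
        slice = i, state = st, ed_frame = ed, es_frame = es,
        source = "auto", anchor = anchor, skip = FALSE,
        stringsAsFactors = FALSE)
    }
    all_curves[[i]] <- curve
    all_ext[[i]] <- ext
  }
  selections <- do.call(rbind, sel)
  sorted <- flag_duplicate_slices(assemble_stack(stack, selections, states))
  list(sorted = sorted, selections = selections,
       curves = all_curves, extrema = all_ext)
}
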