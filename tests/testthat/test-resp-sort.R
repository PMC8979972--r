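test_that("analytic cosine extrema are recovered within one frame", {
  p <- 50; n <- 200
  y <- cos(2 * pi * (seq_len(n) - 13) / p)
  ex <- detect_extrema(y, orientation = "expiration-up")
  expect_true(all(abs(ex$expiration_frames - c(13, 63, 113, 163)) <= 1))
  expect_true(all(abs(ex$inspiration_frames - c(38, 88, 138, 188)) <= 1))
  expect_equal(ex$estimated_period_frames, p, tolerance = 0.05)
})

test_that("degenerate curves are rejected", {
  expect_error(detect_extrema(rep(1, 100), orientation = "expiration-up"),
               "no respiratory signal")
  ## a single cycle is not enough
  expect_error(detect_extrema(cos(2 * pi * seq_len(80) / 100),
                              orientation = "expiration-up"),
               "insufficient cycles")
})

test_that("undetermined orientation requires explicit input", {
  fake <- structure(list(values = cos(seq_len(100) / 5), n = 100,
                         orientation = "undetermined"),
                    class = "resp_curve")
  expect_error(detect_extrema(fake), "undetermined")
  expect_silent(detect_extrema(fake, orientation = "expiration-up"))
})

test_that("detected extrema interleave between states", {
  for (seed in c(1, 13, 31)) {
    p <- small_slice(seed = seed, n_frames = 240, noise_sd = 0.04)
    ex <- detect_extrema(resp_embed(p$series,
      phantom_resp_roi(small_geometry(), small_resp())))
    all_e <- sort(c(ex$expiration_frames, ex$inspiration_frames))
    types <- ifelse(all_e %in% ex$expiration_frames, "e", "i")
    expect_true(all(types[-1] != types[-length(types)]))
  }
})

test_that("phantom extrema land on the truth state sets with correct labels", {
  p <- small_slice(seed = 8, n_frames = 240, noise_sd = 0.02)
  curve <- resp_embed(p$series,
                      phantom_resp_roi(small_geometry(), small_resp()))
  ex <- detect_extrema(curve)
  per <- small_resp()$period_frames
  m_exp <- match_extrema(ex$expiration_frames, p$truth$expiration_plateaus,
                         240, per)
  expect_true(m_exp$truth_matched)
  expect_true(m_exp$detected_matched)
  insp_sets <- contiguous_groups(
    which(p$truth$per_frame$resp_state == "end-insp"))
  m_insp <- match_extrema(ex$inspiration_frames, insp_sets, 240, per)
  expect_true(m_insp$truth_matched)
  expect_true(m_insp$detected_matched)
})

test_that("state windows use the rest and exercise half-widths", {
  ex <- structure(list(expiration_frames = 101, inspiration_frames = 161,
                       estimated_period_frames = 120, n = 500),
                  class = "resp_extrema")
  w <- state_windows(ex, "rest", n_frames = 500)
  expect_equal(unlist(w[w$state == "exp", c("lo", "hi")]),
               c(lo = 86, hi = 116), ignore_attr = TRUE)
  expect_equal(unlist(w[w$state == "insp", c("lo", "hi")]),
               c(lo = 151, hi = 171), ignore_attr = TRUE)
  we <- state_windows(ex, "exercise", n_frames = 500)
  expect_equal(we$hi - we$extreme_frame, c(8, 5))
})

test_that("windows are clipped at the acquisition boundaries", {
  ex <- structure(list(expiration_frames = 450, inspiration_frames = 5,
                       estimated_period_frames = 100, n = 455),
                  class = "resp_extrema")
  w <- state_windows(ex, "exercise", n_frames = 455)
  expect_equal(w$lo[w$state == "insp"], 1)
  expect_equal(w$hi[w$state == "insp"], 10)
  expect_equal(w$hi[w$state == "exp"], 455)
})

test_that("adjacent opposite-state windows truncate at the midpoint", {
  ex <- structure(list(expiration_frames = 100, inspiration_frames = 110,
                       estimated_period_frames = 30, n = 500),
                  class = "resp_extrema")
  w <- state_windows(ex, "rest", n_frames = 500)
  expect_equal(w$hi[w$state == "exp"], 105)
  expect_equal(w$lo[w$state == "insp"], 106)
  expect_lt(w$hi[1], w$lo[2])
})

test_that("lumen proxy tracks the blood pool and rejects flat ROIs", {
  p <- small_slice(seed = 4, n_frames = 160, noise_sd = 0.02)
  lv <- phantom_lv_roi(small_geometry(), small_cardiac(), small_resp())
  proxy <- lumen_signal(p$series, lv)
  ed <- p$truth$ed_frames[2]
  expect_equal(proxy[ed], p$truth$per_frame$endo_area_cm2[ed],
               tolerance = 0.1)
  ## within one cardiac cycle the proxy peaks at ED and bottoms at ES
  cyc <- p$truth$ed_frames[2]:(p$truth$ed_frames[3] - 1)
  expect_lte(min(abs(cyc[which.max(proxy[cyc])] - p$truth$ed_frames)), 1)
  expect_lte(min(abs(cyc[which.min(proxy[cyc])] - p$truth$es_frames)), 1)
  flat <- cine_series(array(1, c(16, 16, 4)), c(2, 2), 33, 10)
  expect_error(lumen_signal(flat, resp_roi(1, 16, 1, 16)),
               "lumen proxy unavailable")
})

test_that("ED/ES suggestion takes argmax/argmin with centre-then-later ties", {
  proxy <- numeric(20)
  proxy[10:14] <- c(5, 9, 3, 7, 4)
  s <- suggest_ed_es(proxy, 10:14, centre = 12)
  expect_equal(s$ed_frame, 11)
  expect_equal(s$es_frame, 12)
  proxy[10:14] <- c(5, 9, 3, 9, 3)
  s2 <- suggest_ed_es(proxy, 10:14, centre = 12)
  expect_equal(s2$ed_frame, 13)  # tie at 9: equidistant, later frame wins
  expect_equal(s2$es_frame, 12)  # tie at 3: 12 is closer to the centre
  expect_error(suggest_ed_es(proxy, 10:11), "window too narrow")
  expect_error(suggest_ed_es(rep(1, 20), 10:14), "no cardiac variation")
})

test_that("stack assembly flags incomplete slices and keeps both states", {
  ph <- generate_cine_stack(small_resp(), small_cardiac(), small_geometry(),
                            n_slices = 4, n_frames = 160, noise_sd = 0.02,
                            seed = 6)
  sel <- expand.grid(slice = 1:4, state = c("exp", "insp"),
                     stringsAsFactors = FALSE)
  sel$ed_frame <- 10L; sel$es_frame <- 18L
  sorted <- assemble_stack(ph$stack, sel)
  expect_equal(length(sorted$states$exp), 4)
  expect_equal(length(sorted$states$insp), 4)
  expect_false(any(vapply(sorted$states$exp, `[[`, logical(1), "incomplete")))
  ## drop one basal ES -> that slice flagged, others intact
  sel$es_frame[sel$slice == 1 & sel$state == "exp"] <- NA
  sorted2 <- assemble_stack(ph$stack, sel)
  inc <- vapply(sorted2$states$exp, `[[`, logical(1), "incomplete")
  expect_equal(sum(inc), 1)
  expect_true(inc[[1]])
  expect_error(assemble_stack(ph$stack, sel[0, ]), "empty stack")
})

test_that("duplicate-slice flags fire on copies and not on distinct slices", {
  ph <- generate_cine_stack(small_resp(), small_cardiac(), small_geometry(),
                            n_slices = 4, n_frames = 160, noise_sd = 0.02,
                            seed = 9)
  sel <- data.frame(slice = 1:4, state = "exp", ed_frame = 12L,
                    es_frame = 20L)
  sorted <- flag_duplicate_slices(assemble_stack(ph$stack, sel, "exp"))
  expect_equal(length(sorted$flags$duplicates), 0)
  ## make slice 3's ED a copy of slice 2's
  sorted$states$exp[[3]]$ed <- sorted$states$exp[[2]]$ed
  sorted <- flag_duplicate_slices(sorted)
  expect_equal(length(sorted$flags$duplicates), 1)
  expect_equal(sorted$flags$duplicates[[1]]$pair, c(2, 3))
  expect_equal(sorted$flags$duplicates[[1]]$ncc, 1)
  ## uncorrelated noise is never flagged
  set.seed(1)
  noise <- cine_stack(lapply(1:2, function(i) {
    cine_series(array(rnorm(16 * 16 * 4), c(16, 16, 4)), c(2, 2), 33, 10,
                slice_location = 10 * i)
  }))
  seln <- data.frame(slice = 1:2, state = "exp", ed_frame = 1L, es_frame = 2L)
  flagged <- flag_duplicate_slices(assemble_stack(noise, seln, "exp"))
  expect_equal(length(flagged$flags$duplicates), 0)
})

test_that("LV length mismatch means off by more than one slice", {
  expect_false(check_lv_length(10, 0, 140, 14)$mismatch)
  expect_true(check_lv_length(10, 0, 155, 14)$mismatch)   # |140-155| > 10
  expect_false(check_lv_length(10, 0, 148, 14)$mismatch)  # 8 <= 10
  expect_error(check_lv_length(10, 0, -1, 14), "invalid length")
})

test_that("auto-selected frames always lie inside their state windows", {
  ph <- generate_cine_stack(small_resp(), small_cardiac(), small_geometry(),
                            n_slices = 3, n_frames = 240, noise_sd = 0.02,
                            seed = 14)
  rs <- respiratory_sort(ph$stack,
                         phantom_resp_roi(small_geometry(), small_resp()),
                         phantom_lv_roi(small_geometry(), small_cardiac(),
                                        small_resp()),
                         mode = "rest", states = c("exp", "insp"))
  for (i in seq_len(nrow(rs$selections))) {
    sel <- rs$selections[i, ]
    if (is.na(sel$ed_frame)) next
    ext <- rs$extrema[[sel$slice]]
    win <- state_windows(ext, "rest", n_frames = 240)
    win <- win[win$state == sel$state & win$extreme_frame == sel$anchor, ]
    expect_gte(sel$ed_frame, win$lo)
    expect_lte(sel$ed_frame, win$hi)
    expect_gte(sel$es_frame, win$lo)
    expect_lte(sel$es_frame, win$hi)
    expect_false(sel$ed_frame == sel$es_frame)
  }
})

test_that("in-package Otsu threshold agrees with the EBImage reference", {
  skip_if_not_installed("EBImage")
  set.seed(3)
  x <- c(rnorm(600, 0.2, 0.05), rnorm(400, 0.8, 0.05))
  ours <- respsort:::otsu_threshold(x)
  m <- matrix((x - min(x)) / diff(range(x)), 40, 25)
  ref <- EBImage::otsu(m, range = c(0, 1)) * diff(range(x)) + min(x)
  expect_equal(ours, ref, tolerance = 0.02)
})
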