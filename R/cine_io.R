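## Containers and I/O for real-time cine series, stacks, ROIs and masks.
##
## Conventions: frames are numeric matrices [row, col] with the top row
## superior; a series stores them as a 3-D array [row, col, frame].
## Pixel and frame indices are 1-based inclusive throughout (idiomatic R).
## Lengths in mm, areas in cm^2, volumes in ml, mass in g, time in ms.

#' Construct a real-time cine series
#'
#' A `cine_series` holds one slice's 2D+time image sequence together with
#' the geometry and timing metadata needed for quantification.
#'
#' @param frames numeric array `[row, col, frame]`, or a list of equally
#'   sized matrices (stacked in order).
#' @param pixel_spacing numeric length-2, (row, col) spacing in mm.
#' @param frame_interval frame-to-frame interval in ms.
#' @param slice_thickness slice thickness in mm.
#' @param slice_gap inter-slice gap in mm (default 0).
#' @param slice_location slice position along the stack axis in mm.
#' @param label free-text label.
#' @return An object of class `cine_series`.
#' @export
cine_series <- function(frames, pixel_spacing, frame_interval,
                        slice_thickness, slice_gap = 0,
                        slice_location = 0, label = "") {
  if (is.list(frames)) {
    shapes <- vapply(frames, dim, integer(2))
    if (any(shapes != shapes[, 1])) stop("inconsistent series: frame shapes differ")
    frames <- array(unlist(frames), dim = c(shapes[, 1], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("frames must be a [row, col, frame] array or list of matrices")
  if (dim(frames)[3] < 1) stop("series must contain at least one frame")
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2)
  if (any(pixel_spacing <= 0)) stop("incomplete geometry: pixel_spacing must be > 0")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("incomplete geometry: frame_interval must be > 0")
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop("incomplete geometry: slice_thickness must be > 0")
  if (slice_gap < 0) stop("incomplete geometry: slice_gap must be >= 0")
  structure(list(
    frames = frames,
    pixel_spacing = pixel_spacing,
    frame_interval = frame_interval,
    slice_thickness = slice_thickness,
    slice_gap = slice_gap,
    slice_location = slice_location,
    label = as.character(label)
  ), class = "cine_series")
}

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("cine_series '%s': %d frames of %d x %d px\n",
              x$label, d[3], d[1], d[2]))
  cat(sprintf("  pixel spacing %.2f x %.2f mm, frame interval %.1f ms\n",
              x$pixel_spacing[1], x$pixel_spacing[2], x$frame_interval))
  cat(sprintf("  slice: thickness %.1f mm, gap %.1f mm, location %.1f mm\n",
              x$slice_thickness, x$slice_gap, x$slice_location))
  invisible(x)
}

#' Number of frames in a cine series
#' @param series a `cine_series`.
#' @return Integer frame count.
#' @export
n_frames <- function(series) dim(series$frames)[3]

#' Construct a short-axis cine stack
#'
#' Orders slices base to apex by `slice_location` and checks that pixel
#' spacing is consistent across slices.
#'
#' @param slices list of [cine_series()] objects.
#' @return An object of class `cine_stack`.
#' @export
cine_stack <- function(slices) {
  if (length(slices) < 1) stop("stack too short")
  stopifnot(all(vapply(slices, inherits, logical(1), "cine_series")))
  locs <- vapply(slices, `[[`, numeric(1), "slice_location")
  if (anyDuplicated(locs)) stop("slice locations must be strictly monotone")
  slices <- slices[order(locs)]
  sp <- vapply(slices, `[[`, numeric(2), "pixel_spacing")
  if (any(abs(sp - sp[, 1]) > 1e-9))
    stop("inconsistent series: pixel spacing differs across slices")
  structure(list(slices = slices), class = "cine_stack")
}

#' @export
print.cine_stack <- function(x, ...) {
  cat(sprintf("cine_stack: %d slices (base to apex)\n", length(x$slices)))
  for (s in x$slices)
    cat(sprintf("  %-12s %4d frames  @ %.1f mm\n", s$label,
                n_frames(s), s$slice_location))
  invisible(x)
}

#' @export
length.cine_stack <- function(x) length(x$slices)

#' Define a rectangular respiratory (or lumen) region of interest
#'
#' Pixel indices are 1-based and inclusive on both ends. The ROI must
#' contain at least 64 pixels so that the diaphragm edge is resolvable.
#'
#' @param row_min,row_max,col_min,col_max inclusive pixel bounds.
#' @return An object of class `resp_roi`.
#' @export
resp_roi <- function(row_min, row_max, col_min, col_max) {
  v <- c(row_min, row_max, col_min, col_max)
  if (any(v != round(v)) || any(v < 1)) stop("ROI bounds must be positive integers")
  if (row_max < row_min || col_max < col_min) stop("ROI is empty")
  area <- (row_max - row_min + 1) * (col_max - col_min + 1)
  if (area < 64) stop("ROI too small: at least 64 px required")
  structure(list(row_min = row_min, row_max = row_max,
                 col_min = col_min, col_max = col_max),
            class = "resp_roi")
}

roi_dims <- function(roi) {
  c(roi$row_max - roi$row_min + 1, roi$col_max - roi$col_min + 1)
}

#' Crop an ROI from every frame and flatten to vectors
#'
#' Returns the sub-image sequence as an `N x P` matrix: one row per frame,
#' each frame's ROI flattened column-major (R native order) to a vector of
#' `P = n_rows * n_cols` intensities. A 40 x 40 ROI therefore yields
#' 1600-dimensional vectors.
#'
#' @param series a [cine_series()].
#' @param roi a [resp_roi()].
#' @return Numeric matrix with `n_frames(series)` rows, with attributes
#'   `roi_nrow`/`roi_ncol` recording the ROI shape.
#' @export
crop_roi <- function(series, roi) {
  stopifnot(inherits(series, "cine_series"), inherits(roi, "resp_roi"))
  d <- dim(series$frames)
  if (roi$row_max > d[1] || roi$col_max > d[2])
    stop("ROI outside image")
  sub <- series$frames[roi$row_min:roi$row_max,
                       roi$col_min:roi$col_max, , drop = FALSE]
  p <- dim(sub)[1] * dim(sub)[2]
  x <- t(matrix(sub, nrow = p))
  attr(x, "roi_nrow") <- dim(sub)[1]
  attr(x, "roi_ncol") <- dim(sub)[2]
  x
}

## ---- fixture format: plain-text CSV of flattened frames + JSON sidecar ----

fixture_paths <- function(prefix) {
  list(csv = paste0(prefix, ".csv"), json = paste0(prefix, ".json"))
}

#' Write a cine series to the text fixture format
#'
#' The fixture is a pair of files: `<prefix>.csv` holding one frame per
#' line (pixels flattened column-major, printed with 17 significant digits
#' so doubles round-trip exactly) and `<prefix>.json` holding the
#' geometry/timing metadata. Diff-able and dependency-free.
#'
#' @param series a [cine_series()].
#' @param prefix output path without extension.
#' @return The prefix, invisibly.
#' @export
write_cine_fixture <- function(series, prefix) {
  stopifnot(inherits(series, "cine_series"))
  p <- fixture_paths(prefix)
  d <- dim(series$frames)
  m <- matrix(series$frames, nrow = d[1] * d[2])  # one column per frame
  lines <- vapply(seq_len(d[3]), function(i)
    paste(sprintf("%.17g", m[, i]), collapse = ","), character(1))
  writeLines(lines, p$csv)
  meta <- list(format = "respsort-cine-fixture", version = 1L,
               nrow = d[1], ncol = d[2], n_frames = d[3],
               pixel_spacing = series$pixel_spacing,
               frame_interval = series$frame_interval,
               slice_thickness = series$slice_thickness,
               slice_gap = series$slice_gap,
               slice_location = series$slice_location,
               label = series$label)
  jsonlite::write_json(meta, p$json, auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

read_cine_fixture <- function(prefix) {
  p <- fixture_paths(prefix)
  if (!file.exists(p$json)) stop("fixture sidecar not found: ", p$json)
  meta <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  lines <- readLines(p$csv)
  if (length(lines) != meta$n_frames)
    stop("inconsistent series: frame count does not match sidecar")
  vals <- lapply(strsplit(lines, ",", fixed = TRUE), as.numeric)
  np <- meta$nrow * meta$ncol
  if (any(lengths(vals) != np))
    stop("inconsistent series: frame sizes differ")
  frames <- array(unlist(vals), dim = c(meta$nrow, meta$ncol, meta$n_frames))
  cine_series(frames,
              pixel_spacing = meta$pixel_spacing,
              frame_interval = meta$frame_interval,
              slice_thickness = meta$slice_thickness,
              slice_gap = meta$slice_gap,
              slice_location = meta$slice_location,
              label = meta$label)
}

#' Write a cine stack as a directory of per-slice fixtures
#'
#' @param stack a [cine_stack()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack_fixture <- function(stack, dir) {
  stopifnot(inherits(stack, "cine_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$slices))
    write_cine_fixture(stack$slices[[i]],
                       file.path(dir, sprintf("slice_%02d", i)))
  jsonlite::write_json(list(format = "respsort-stack-fixture",
                            n_slices = length(stack$slices)),
                       file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

read_stack_fixture <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "^slice_[0-9]+\\.json$",
                              full.names = TRUE))
  if (!length(sidecars)) stop("no slice fixtures found in ", dir)
  slices <- lapply(sub("\\.json$", "", sidecars), read_cine_fixture)
  cine_stack(slices)
}

## ---- NIfTI ----

read_cine_nifti <- function(path, frame_interval = NULL,
                            slice_thickness = NULL, slice_gap = 0,
                            label = basename(path)) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  d <- dim(img)
  if (length(d) == 4 && d[3] == 1) { dim(img) <- d[c(1, 2, 4)]; d <- dim(img) }
  if (length(d) != 3 && length(d) != 4)
    stop("incomplete geometry: expected 2D+time or 3D+time NIfTI")
  spacing <- hdr$pixdim[2:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("incomplete geometry: pixel spacing missing")
  if (is.null(slice_thickness)) {
    slice_thickness <- hdr$pixdim[4]
    if (!is.finite(slice_thickness) || slice_thickness <= 0)
      stop("incomplete geometry: slice thickness missing; supply slice_thickness")
  }
  if (is.null(frame_interval)) {
    dt <- hdr$pixdim[5]
    ## xyzt_units bits 8/16/24 encode s/ms/us for the temporal axis; an
    ## unset unit means the writer recorded no timing (NIfTI writers
    ## normalize an absent time step to pixdim = 1, so the unit is the
    ## only reliable signal)
    tunit <- bitwAnd(as.integer(hdr$xyzt_units), 56L)
    if (!is.finite(dt) || dt <= 0 || tunit == 0L)
      stop("incomplete geometry: frame interval missing; supply frame_interval")
    frame_interval <- switch(as.character(tunit),
                             "8" = dt * 1000, "16" = dt, "24" = dt / 1000)
  }
  mk <- function(arr, loc, lab)
    cine_series(arr, pixel_spacing = spacing, frame_interval = frame_interval,
                slice_thickness = slice_thickness, slice_gap = slice_gap,
                slice_location = loc, label = lab)
  if (length(d) == 3) return(mk(unclass(img)[, , , drop = FALSE], 0, label))
  slices <- lapply(seq_len(d[3]), function(z)
    mk(unclass(img)[, , z, ], (z - 1) * (slice_thickness + slice_gap),
       sprintf("%s_z%02d", label, z)))
  cine_stack(slices)
}

#' Read a cine series or stack
#'
#' Supported formats: the package's text fixture (`format = "fixture"`,
#' `path` is the prefix or a fixture directory) and NIfTI-1
#' (`format = "nifti"`). Missing timing/geometry metadata must be supplied
#' through the override arguments, otherwise reading fails with
#' "incomplete geometry". DICOM series are not supported: no DICOM reader
#' is available to this package.
#'
#' @param path file prefix, file, or fixture directory.
#' @param format one of `"fixture"`, `"nifti"`, `"dicom"`.
#' @param frame_interval,slice_thickness,slice_gap metadata overrides
#'   (NIfTI only).
#' @return A [cine_series()] or [cine_stack()].
#' @export
read_cine <- function(path, format = c("fixture", "nifti", "dicom"),
                      frame_interval = NULL, slice_thickness = NULL,
                      slice_gap = 0) {
  format <- match.arg(format)
  switch(format,
    fixture = if (dir.exists(path)) read_stack_fixture(path)
              else read_cine_fixture(sub("\\.(csv|json)$", "", path)),
    nifti = read_cine_nifti(path, frame_interval = frame_interval,
                            slice_thickness = slice_thickness,
                            slice_gap = slice_gap),
    dicom = stop("DICOM reading is not supported in this build; ",
                 "convert to NIfTI or the fixture format")
  )
}

#' Crop a series (or every slice of a stack) to a frame range
#'
#' Used for the acquisition-time experiments: re-running the pipeline on
#' the first half or quarter of the acquired frames.
#'
#' @param x a [cine_series()] or [cine_stack()].
#' @param frames integer frame indices to keep (in order).
#' @return Object of the same class with only the requested frames.
#' @export
crop_frames <- function(x, frames) {
  if (inherits(x, "cine_stack")) {
    x$slices <- lapply(x$slices, crop_frames, frames = frames)
    return(x)
  }
  stopifnot(inherits(x, "cine_series"))
  if (min(frames) < 1 || max(frames) > n_frames(x))
    stop("frame range outside series")
  x$frames <- x$frames[, , frames, drop = FALSE]
  x
}

#' Pixel area in cm^2 for a series
#' @param series a `cine_series`.
#' @return Scalar pixel area in cm^2.
#' @export
pixel_area_cm2 <- function(series) {
  prod(series$pixel_spacing) / 100
}
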