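#' Scanner acquisition frames
#'
#' A `scan_frame` holds one flatbed-scanner acquisition of a film piece:
#' three co-registered channel rasters in 16-bit transmission counts plus
#' resolution metadata.  Rasters are stored as a numeric `height x width x 3`
#' array (channel order red, green, blue); values must lie in `[0, 65535]`.
#'
#' @param data Numeric array `height x width x 3` of channel counts.
#' @param dpi Scan resolution in dots per inch (> 0); 300 dpi gives the
#'   0.085 mm pixel pitch typical of film protocols.
#' @param acquired_at Optional scan time in hours post-irradiation.
#' @param metadata Free-form named list (film piece id, clipping flags, ...).
#' @return An object of class `scan_frame`.
#' @export
scan_frame <- function(data, dpi = 300, acquired_at = NULL, metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L) {
    stop_pf("`data` must be a height x width x 3 numeric array")
  }
  if (any(!is.finite(data))) stop_pf("frame values must be finite")
  if (any(data < 0) || any(data > 65535)) {
    stop_pf("frame values must lie in [0, 65535]")
  }
  assert_scalar_num(dpi, "dpi", 0, strict_min = TRUE)
  structure(list(data = data, dpi = dpi, acquired_at = acquired_at,
                 metadata = metadata),
            class = "scan_frame")
}

#' @export
print.scan_frame <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scan_frame %d x %d px, 3 channels, %g dpi>\n", d[2], d[1], x$dpi))
  invisible(x)
}

frame_dims <- function(frame) dim(frame$data)[1:2]

#' Read and write film scans as 48-bit RGB TIFF
#'
#' `save_scan()` writes the three 16-bit channels as an uncompressed RGB
#' TIFF (counts are rounded to integers on write) and stores `dpi`,
#' `acquired_at` and metadata in a JSON sidecar `<path>.json`.  `load_scan()`
#' reads both back; a scan saved and re-loaded round-trips exactly.  Only
#' 16-bit RGB TIFFs are accepted on read.
#'
#' @param frame A [scan_frame()].
#' @param path TIFF file path.
#' @return `load_scan()` returns a [scan_frame()].
#' @export
save_scan <- function(frame, path) {
  stopifnot(inherits(frame, "scan_frame"))
  img <- round(frame$data) / 65535
  # tiff wants width x height x channel ordering identical to ours (row, col, ch)
  tiff::writeTIFF(img, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  side <- list(dpi = frame$dpi, acquired_at = frame$acquired_at,
               metadata = frame$metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_scan
#' @export
load_scan <- function(path) {
  if (!file.exists(path)) stop_pf("scan file not found: %s", path)
  img <- tiff::readTIFF(path, info = TRUE)
  info <- attributes(img)
  if (is.null(info$bits.per.sample) || info$bits.per.sample != 16L) {
    stop_pf("'%s' is not 16 bits/channel; film scans must be 48-bit RGB TIFF", path)
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop_pf("'%s' is not RGB; film scans must be 48-bit RGB TIFF", path)
  }
  data <- round(img[, , 1:3, drop = FALSE] * 65535)
  dpi <- 300; acquired_at <- NULL; metadata <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    dpi <- side$dpi %||% 300
    acquired_at <- side$acquired_at
    metadata <- as.list(side$metadata %||% list())
  }
  scan_frame(data, dpi = dpi, acquired_at = acquired_at, metadata = metadata)
}

#' Rectangular regions of interest
#'
#' ROIs use 0-based, half-open pixel coordinates: `x0` is the left column,
#' `y0` the top row, and the ROI covers columns `[x0, x0 + width)` and rows
#' `[y0, y0 + height)`.  Both extents must be at least 4 px so ROI statistics
#' are computed from >= 16 pixels.
#'
#' @param x0,y0 Top-left corner, 0-based pixels.
#' @param width,height Extent in pixels, each >= 4.
#' @return An object of class `film_roi`.
#' @export
roi <- function(x0, y0, width, height) {
  for (v in list(x0 = x0, y0 = y0)) assert_scalar_num(v, "corner", 0)
  if (width < 4 || height < 4) stop_pf("ROI width and height must be >= 4 px")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "film_roi")
}

#' @rdname roi
#' @description `central_roi()` returns the centered rectangle covering a
#' fraction (default 50 %) of each frame dimension — the "central film
#' region" convention that keeps cut edges out of the statistics.
#' @param frame A [scan_frame()].
#' @param fraction Fraction of each dimension covered, in (0, 1].
#' @export
central_roi <- function(frame, fraction = 0.5) {
  stopifnot(inherits(frame, "scan_frame"))
  if (fraction <= 0 || fraction > 1) stop_pf("`fraction` must be in (0, 1]")
  d <- frame_dims(frame)
  h <- max(4L, as.integer(round(d[1] * fraction)))
  w <- max(4L, as.integer(round(d[2] * fraction)))
  roi(x0 = floor((d[2] - w) / 2), y0 = floor((d[1] - h) / 2),
      width = w, height = h)
}

roi_index <- function(frame, roi) {
  d <- frame_dims(frame)
  if (roi$x0 + roi$width > d[2] || roi$y0 + roi$height > d[1]) {
    stop_pf("ROI [%d, %d) x [%d, %d) exceeds the %d x %d px frame",
            roi$x0, roi$x0 + roi$width, roi$y0, roi$y0 + roi$height,
            d[2], d[1])
  }
  list(rows = (roi$y0 + 1L):(roi$y0 + roi$height),
       cols = (roi$x0 + 1L):(roi$x0 + roi$width))
}

#' Per-channel ROI statistics
#'
#' Computes the mean, sample standard deviation and pixel count of each
#' channel over an ROI.  These are the `I0` / `I` estimators feeding the
#' netOD computation.
#'
#' @param frame A [scan_frame()].
#' @param roi A [roi()]; defaults to the central 50 % region.
#' @return A data.frame with columns `channel`, `mean`, `sd`, `n`.
#' @export
roi_stats <- function(frame, roi = central_roi(frame)) {
  stopifnot(inherits(frame, "scan_frame"), inherits(roi, "film_roi"))
  idx <- roi_index(frame, roi)
  out <- lapply(seq_along(CHANNELS), function(k) {
    px <- frame$data[idx$rows, idx$cols, k]
    data.frame(channel = CHANNELS[k], mean = mean(px), sd = stats::sd(px),
               n = length(px))
  })
  do.call(rbind, out)
}
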