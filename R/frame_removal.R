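# Detection of the bright tray frame with a Hough line transform and cropping
# to its margin-free interior.
#
# Coordinate conventions used throughout: row-major, 0-based, half-open
# intervals [min, max). The frame is assumed axis-aligned within a small tilt;
# the crop is always the largest axis-aligned rectangle strictly inside the
# four detected border lines, shrunk by a safety margin.

#' Edge detection by gradient magnitude with hysteresis
#'
#' Sobel gradient magnitude (normalised so a unit intensity step has magnitude
#' ~1) thresholded with hysteresis: pixels with magnitude >= `high` are strong
#' edges; weak pixels (>= `low`) are kept only if their 8-connected weak
#' component contains a strong pixel.
#'
#' @param image A grayscale [raster_image()].
#' @param low,high Hysteresis thresholds on \[0, 1\] intensities,
#'   `0 <= low < high <= 1`.
#' @return A [binary_mask()] of edge pixels.
#' @export
detect_edges <- function(image, low = 0.1, high = 0.3) {
  if (!inherits(image, "raster_image") || n_channels(image) != 1L)
    abort_validation("`image` must be a grayscale raster_image")
  if (!(low >= 0 && low < high && high <= 1))
    abort_validation("need 0 <= low < high <= 1")
  mag <- cpp_gradient_magnitude(image$pixels)
  strong <- mag >= high
  weak <- mag >= low
  if (!any(strong)) return(binary_mask(matrix(FALSE, nrow(mag), ncol(mag)), image$dpi))
  lab <- cpp_label(weak, 8L)
  keep <- sort(unique(lab[strong]))
  binary_mask(matrix(lab %in% keep, nrow(mag), ncol(mag)), image$dpi)
}

#' Hough line transform
#'
#' Accumulates edge pixels in the standard normal form
#' `rho = x*cos(theta) + y*sin(theta)` (x = 0-based column, y = 0-based row,
#' theta in \[0, pi)) and returns accumulator local maxima.
#'
#' A cell is a peak if its votes reach `min_votes` and are >= all of its 8
#' accumulator neighbours. Peaks are sorted by votes descending (ties by
#' theta then rho ascending).
#'
#' @param edges A [binary_mask()] of edge pixels.
#' @param rho_res Distance resolution in px.
#' @param theta_res Angle resolution in radians.
#' @param min_votes Minimum accumulator count for a line.
#' @return A data.frame with columns `rho`, `theta`, `votes`.
#' @export
hough_lines <- function(edges, rho_res = 1, theta_res = pi / 360, min_votes = 10) {
  if (!inherits(edges, "binary_mask")) abort_validation("`edges` must be a binary_mask")
  empty <- data.frame(rho = numeric(0), theta = numeric(0), votes = integer(0))
  pts <- which(edges$pixels, arr.ind = TRUE)
  if (nrow(pts) == 0) return(empty)
  h <- nrow(edges$pixels); w <- ncol(edges$pixels)
  ntheta <- max(1L, as.integer(round(pi / theta_res)))
  nrho_half <- as.integer(ceiling(sqrt(h^2 + w^2) / rho_res)) + 1L
  acc <- cpp_hough_accumulate(as.integer(pts[, 1] - 1L), as.integer(pts[, 2] - 1L),
                              nrho_half, rho_res, ntheta, theta_res)
  peaks <- hough_peaks(acc, min_votes)
  if (nrow(peaks) == 0) return(empty)
  data.frame(rho = (peaks$rho_idx - 1L - nrho_half) * rho_res,
             theta = (peaks$theta_idx - 1L) * theta_res,
             votes = peaks$votes)
}

# local maxima (>= all 8 neighbours, votes >= min_votes) of an accumulator,
# sorted by votes desc then theta, rho asc; shared by implementation and the
# documented peak definition
hough_peaks <- function(acc, min_votes) {
  nr <- nrow(acc); nc <- ncol(acc)
  pad <- matrix(-1L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- acc
  is_peak <- acc >= min_votes
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_peak <- is_peak & (acc >= pad[(2:(nr + 1)) + di, (2:(nc + 1)) + dj])
  }
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(rho_idx = integer(0), theta_idx = integer(0), votes = integer(0)))
  out <- data.frame(rho_idx = idx[, 1], theta_idx = idx[, 2], votes = acc[idx])
  out[order(-out$votes, out$theta_idx, out$rho_idx), , drop = FALSE]
}

# signed position of a line at the image center, along rows (horizontal lines)
# or columns (vertical lines)
line_center_position <- function(rho, theta, h, w, horizontal) {
  if (horizontal) (rho - ((w - 1) / 2) * cos(theta)) / sin(theta)
  else (rho - ((h - 1) / 2) * sin(theta)) / cos(theta)
}

# evaluate a near-horizontal line's row at a given column (or a near-vertical
# line's column at a given row)
line_eval <- function(rho, theta, coord, horizontal) {
  if (horizontal) (rho - coord * cos(theta)) / sin(theta)
  else (rho - coord * sin(theta)) / cos(theta)
}

#' Fit a rectangular frame from Hough lines
#'
#' Selects the outermost near-horizontal pair and near-vertical pair of lines
#' (maximal enclosed area consistent with an axis-aligned rectangle within
#' `max_tilt`), and computes the largest axis-aligned interior rectangle
#' strictly inside all four lines, shrunk by `safety_margin_px`.
#'
#' @param lines data.frame from [hough_lines()].
#' @param image_shape Integer vector `c(height, width)` in px.
#' @param max_tilt Maximum deviation of frame borders from the image axes, in
#'   radians (default 5 degrees).
#' @param safety_margin_px Extra inward shrink of the interior, in px.
#' @return An object of class `frame_geometry` with 0-based half-open interior
#'   bounds `row_min`, `row_max`, `col_min`, `col_max` and the four border
#'   lines.
#' @export
fit_frame <- function(lines, image_shape, max_tilt = 5 * pi / 180, safety_margin_px = 3) {
  h <- image_shape[1]; w <- image_shape[2]
  if (is.null(lines) || nrow(lines) == 0)
    abort_rm("frame not found: no candidate lines", "rootmorph_frame_error")
  dev_h <- abs(lines$theta - pi / 2)
  dev_v <- pmin(lines$theta, pi - lines$theta)
  hor <- lines[dev_h <= max_tilt, , drop = FALSE]
  ver <- lines[dev_v <= max_tilt, , drop = FALSE]
  if (nrow(hor) >= 2) {
    pos <- line_center_position(hor$rho, hor$theta, h, w, TRUE)
    hor <- hor[pos > -0.5 & pos < h - 0.5, , drop = FALSE]
  }
  if (nrow(ver) >= 2) {
    pos <- line_center_position(ver$rho, ver$theta, h, w, FALSE)
    ver <- ver[pos > -0.5 & pos < w - 0.5, , drop = FALSE]
  }
  if (nrow(hor) < 2 || nrow(ver) < 2)
    abort_rm(sprintf(
      "frame not found: %d near-horizontal and %d near-vertical candidate line(s)",
      nrow(hor), nrow(ver)), "rootmorph_frame_error")
  pos_h <- line_center_position(hor$rho, hor$theta, h, w, TRUE)
  pos_v <- line_center_position(ver$rho, ver$theta, h, w, FALSE)
  top <- hor[which.min(pos_h), ]; bottom <- hor[which.max(pos_h), ]
  left <- ver[which.min(pos_v), ]; right <- ver[which.max(pos_v), ]

  # worst-case line positions across the image extent -> strictly interior
  # axis-aligned rectangle
  row_min <- floor(max(line_eval(top$rho, top$theta, c(0, w - 1), TRUE))) + 1 + safety_margin_px
  row_max <- ceiling(min(line_eval(bottom$rho, bottom$theta, c(0, w - 1), TRUE))) - safety_margin_px
  col_min <- floor(max(line_eval(left$rho, left$theta, c(0, h - 1), FALSE))) + 1 + safety_margin_px
  col_max <- ceiling(min(line_eval(right$rho, right$theta, c(0, h - 1), FALSE))) - safety_margin_px
  row_min <- max(0, row_min); col_min <- max(0, col_min)
  row_max <- min(h, row_max); col_max <- min(w, col_max)
  if (!(row_min < row_max && col_min < col_max))
    abort_rm("frame not found: detected borders leave an empty interior",
             "rootmorph_frame_error")
  structure(list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max),
                 top = top, bottom = bottom, left = left, right = right),
            class = "frame_geometry")
}

#' @export
print.frame_geometry <- function(x, ...) {
  cat(sprintf("frame_geometry: interior rows [%d, %d), cols [%d, %d)\n",
              x$row_min, x$row_max, x$col_min, x$col_max))
  invisible(x)
}

#' Crop an image (or mask) to the frame interior
#'
#' Returns the interior sub-image. The cumulative offset of the crop origin is
#' kept in the `offset` attribute (0-based `c(row, col)`), so coordinates can
#' be mapped back to the source; crops compose additively.
#'
#' @param image A [raster_image()] or [binary_mask()].
#' @param frame A `frame_geometry` from [fit_frame()].
#' @return The cropped object (same class, dpi preserved).
#' @export
crop_interior <- function(image, frame) {
  is_mask <- inherits(image, "binary_mask")
  if (!is_mask && !inherits(image, "raster_image"))
    abort_validation("`image` must be a raster_image or binary_mask")
  sh <- dim(image$pixels)[1:2]
  if (frame$row_min < 0 || frame$col_min < 0 || frame$row_max > sh[1] || frame$col_max > sh[2] ||
      frame$row_min >= frame$row_max || frame$col_min >= frame$col_max)
    abort_validation("frame interior is out of image bounds")
  rows <- (frame$row_min + 1):frame$row_max
  cols <- (frame$col_min + 1):frame$col_max
  px <- if (is.matrix(image$pixels)) image$pixels[rows, cols, drop = FALSE]
        else image$pixels[rows, cols, , drop = FALSE]
  out <- if (is_mask) binary_mask(px, image$dpi) else raster_image(px, image$dpi)
  prev <- attr(image, "offset")
  if (is.null(prev)) prev <- c(0L, 0L)
  attr(out, "offset") <- prev + c(frame$row_min, frame$col_min)
  out
}
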