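# Loading tray image stacks and reducing them to one clean grayscale image.
#
# Inputs are pre-converted rasters (TIFF or PNG); camera-RAW decoding is a
# user responsibility upstream. The scale calibration (dots per inch) is a
# required input and is never read from file metadata.

#' Scale calibration
#'
#' Converts between pixels and physical units. `px_per_cm` is derived from
#' `dpi` as `dpi / 2.54` (2.54 cm per inch).
#'
#' @param dpi Dots per inch of the imaging setup, a positive number
#'   (around 450 for a stage-mounted camera over a DIN A4 tray).
#' @return An object of class `scale_calibration` with fields `dpi` and
#'   `px_per_cm`.
#' @export
#' @examples
#' scale_calibration(450)$px_per_cm # ~177.17 px per cm
scale_calibration <- function(dpi) {
  if (!is.numeric(dpi) || length(dpi) != 1 || !is.finite(dpi) || dpi <= 0)
    abort_validation("`dpi` must be a single positive finite number")
  structure(list(dpi = as.numeric(dpi), px_per_cm = as.numeric(dpi) / 2.54),
            class = "scale_calibration")
}

#' Raster image container
#'
#' A raster with intensities normalised to \[0, 1\] (grayscale matrix or
#' h x w x 3 RGB array) plus its scale calibration.
#'
#' @param pixels Numeric matrix (grayscale) or h x w x 3 array (RGB) with all
#'   values in \[0, 1\].
#' @param dpi Dots per inch (positive).
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, dpi) {
  if (is.matrix(pixels)) {
    nch <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] %in% c(1L, 3L)) {
    nch <- dim(pixels)[3]
    if (nch == 1L) pixels <- pixels[, , 1L, drop = TRUE]
  } else {
    abort_validation("`pixels` must be a matrix or an h x w x {1,3} array")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    abort_validation("intensities must lie in [0, 1] and contain no NA")
  calib <- scale_calibration(dpi)
  structure(list(pixels = pixels, dpi = calib$dpi), class = "raster_image")
}

n_channels <- function(image) if (is.matrix(image$pixels)) 1L else dim(image$pixels)[3]

#' Height and width of an image or mask, in pixels
#' @param image A [raster_image()] or [binary_mask()].
#' @return Integer vector `c(height_px, width_px)`.
#' @export
image_shape <- function(image) dim(image$pixels)[1:2]

#' @export
print.raster_image <- function(x, ...) {
  sh <- image_shape(x)
  cat(sprintf("raster_image: %d x %d px, %d channel(s), %.0f dpi\n",
              sh[1], sh[2], n_channels(x), x$dpi))
  invisible(x)
}

#' Tray image stack
#'
#' An ordered stack of co-registered exposures of one root tray. All images
#' must share dimensions, channel count and dpi.
#'
#' @param images List of [raster_image()] objects, length >= 1.
#' @param tray_id,plant_id Identifiers carried through to outputs.
#' @return An object of class `tray_stack`.
#' @export
tray_stack <- function(images, tray_id = "tray", plant_id = "plant") {
  if (!is.list(images) || length(images) < 1)
    abort_validation("`images` must be a nonempty list of raster_image objects")
  ref <- images[[1]]
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (!inherits(im, "raster_image"))
      abort_validation(sprintf("images[[%d]] is not a raster_image", i))
    if (!identical(image_shape(im), image_shape(ref)) ||
        n_channels(im) != n_channels(ref) || im$dpi != ref$dpi)
      abort_validation(sprintf(
        "images[[%d]] does not match the stack: %d x %d x %d @ %.0f dpi vs %d x %d x %d @ %.0f dpi",
        i, image_shape(im)[1], image_shape(im)[2], n_channels(im), im$dpi,
        image_shape(ref)[1], image_shape(ref)[2], n_channels(ref), ref$dpi))
  }
  structure(list(images = images, tray_id = tray_id, plant_id = plant_id),
            class = "tray_stack")
}

#' @export
print.tray_stack <- function(x, ...) {
  sh <- image_shape(x$images[[1]])
  cat(sprintf("tray_stack '%s' (plant '%s'): %d exposure(s), %d x %d px @ %.0f dpi\n",
              x$tray_id, x$plant_id, length(x$images), sh[1], sh[2], x$images[[1]]$dpi))
  invisible(x)
}

read_one_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
           tif = , tiff = tiff::readTIFF(path, all = TRUE),
           png = png::readPNG(path),
           abort_io(sprintf("unsupported image format '%s' for '%s' (use TIFF or PNG)", ext, path))),
    error = function(e) abort_io(sprintf("cannot read image '%s': %s", path, conditionMessage(e))))
  if (!is.list(px)) px <- list(px)
  lapply(px, function(p) {
    if (is.array(p) && length(dim(p)) == 3 && dim(p)[3] == 4L)
      p <- p[, , 1:3, drop = FALSE] # drop alpha
    p
  })
}

#' Load a tray image stack from files
#'
#' Reads TIFF (multi-page accepted, each page one exposure) and PNG files,
#' rescales intensities to \[0, 1\], and attaches the scale calibration.
#'
#' @param paths Character vector of file paths.
#' @param dpi Dots per inch of the imaging setup (required; never inferred
#'   from file metadata).
#' @param tray_id,plant_id Identifiers.
#' @return A [tray_stack()].
#' @export
load_stack <- function(paths, dpi, tray_id = "tray", plant_id = "plant") {
  if (length(paths) < 1) abort_validation("at least one path is required")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    abort_io(sprintf("file not found: %s", paste(missing, collapse = ", ")))
  pages <- unlist(lapply(paths, read_one_raster), recursive = FALSE)
  images <- lapply(pages, raster_image, dpi = dpi)
  shapes <- vapply(images, function(im) paste(image_shape(im), collapse = "x"), "")
  if (length(unique(shapes)) > 1)
    abort_validation(sprintf(
      "stack images have mismatched dimensions: %s",
      paste(sprintf("image %d is %s", seq_along(shapes), shapes), collapse = "; ")))
  tray_stack(images, tray_id = tray_id, plant_id = plant_id)
}

#' Median projection of an image stack
#'
#' Reduces the exposures of one tray to a single image by the pixel-wise
#' median across the stack (per channel). This temporal median removes
#' transient specks (dust, sensor impulse noise) while preserving edges.
#' Even-length stacks use the lower median (order statistic `ceil(n/2)`), so
#' every output value is an observed intensity.
#'
#' @param stack A [tray_stack()].
#' @return A [raster_image()] with the stack's dimensions and dpi.
#' @export
median_project <- function(stack) {
  if (!inherits(stack, "tray_stack") || length(stack$images) < 1)
    abort_validation("`stack` must be a nonempty tray_stack")
  n <- length(stack$images)
  nch <- n_channels(stack$images[[1]])
  sh <- image_shape(stack$images[[1]])
  if (n == 1) return(stack$images[[1]])
  project_channel <- function(ch) {
    arr <- array(0, dim = c(sh[1], sh[2], n))
    for (t in seq_len(n)) {
      px <- stack$images[[t]]$pixels
      arr[, , t] <- if (nch == 1L) px else px[, , ch]
    }
    cpp_stack_median(arr)
  }
  if (nch == 1L) {
    out <- project_channel(1L)
  } else {
    out <- array(0, dim = c(sh[1], sh[2], 3L))
    for (ch in 1:3) out[, , ch] <- project_channel(ch)
  }
  raster_image(out, dpi = stack$images[[1]]$dpi)
}

#' Convert an image to grayscale
#'
#' Three-channel images are reduced with the fixed luminance weights
#' (0.299, 0.587, 0.114); grayscale images pass through unchanged.
#'
#' @param image A [raster_image()].
#' @return A single-channel [raster_image()].
#' @export
to_grayscale <- function(image) {
  if (!inherits(image, "raster_image")) abort_validation("`image` must be a raster_image")
  nch <- n_channels(image)
  if (nch == 1L) return(image)
  if (nch != 3L) abort_validation(sprintf("unsupported channel count: %d", nch))
  px <- image$pixels
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  gray[gray > 1] <- 1
  gray[gray < 0] <- 0
  raster_image(gray, dpi = image$dpi)
}
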