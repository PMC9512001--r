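#' Raster image container
#'
#' A minimal container for a decoded photograph: a numeric array of
#' intensities in `[0, 1]` with dimensions `height_px x width_px` (single
#' channel) or `height_px x width_px x 3` (RGB, channel order red-green-blue).
#' All preprocessing steps of the fluorescein-pattern pipeline transform this
#' object.
#'
#' @param pixels Numeric matrix (grayscale) or 3-d array (RGB) of intensities
#'   in `[0, 1]`, rows = image rows, columns = image columns.
#' @return An object of class `raster_image` with fields `pixels`,
#'   `width_px`, `height_px` and `channels`.
#' @export
raster_image <- function(pixels) {
  if (!is.numeric(pixels)) {
    stop("`pixels` must be numeric", call. = FALSE)
  }
  d <- dim(pixels)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    stop("`pixels` must be a matrix or a 3-d array", call. = FALSE)
  }
  channels <- if (length(d) == 2L) 1L else d[3L]
  if (!channels %in% c(1L, 3L)) {
    stop("unsupported channel count: ", channels,
         " (expected 1 or 3)", call. = FALSE)
  }
  if (length(d) == 3L && channels == 1L) {
    pixels <- pixels[, , 1L]
    d <- dim(pixels)
  }
  if (d[1L] < 1L || d[2L] < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  rng <- range(pixels, finite = TRUE)
  if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9) {
    stop("intensities must lie in [0, 1]; observed range [",
         signif(rng[1L], 4), ", ", signif(rng[2L], 4), "]", call. = FALSE)
  }
  structure(
    list(
      pixels = pmin(pmax(pixels, 0), 1),
      width_px = as.integer(d[2L]),
      height_px = as.integer(d[1L]),
      channels = as.integer(channels)
    ),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, %d channel%s\n",
              x$width_px, x$height_px, x$channels,
              if (x$channels > 1L) "s" else ""))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) {
  c(x$height_px, x$width_px, x$channels)
}

# EBImage stores frames as width x height (x first); flip to the row-major
# height x width layout used throughout this package.
ebimage_to_array <- function(img) {
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2L) {
    t(px)
  } else {
    aperm(px, c(2L, 1L, 3L))
  }
}

array_to_ebimage <- function(pixels) {
  if (length(dim(pixels)) == 2L) {
    EBImage::Image(t(pixels), colormode = "Grayscale")
  } else {
    EBImage::Image(aperm(pixels, c(2L, 1L, 3L)), colormode = "Color")
  }
}

#' Load a fluorescein photograph
#'
#' Decodes a JPEG, PNG or TIFF file into a [raster_image] with intensities
#' normalised to `[0, 1]`. Images with an alpha channel are accepted and the
#' alpha plane is dropped; any other channel count beyond 1 (grayscale) or
#' 3 (RGB) is rejected.
#'
#' @param path Path to the image file.
#' @return A [raster_image].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) {
      stop("could not decode image '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  px <- ebimage_to_array(img)
  d <- dim(px)
  if (length(d) == 3L && d[3L] == 4L) px <- px[, , 1:3]     # drop alpha
  if (length(d) == 3L && d[3L] == 2L) px <- px[, , 1L]      # gray + alpha
  d <- dim(px)
  if (!is.null(d) && length(d) == 3L && !d[3L] %in% c(1L, 3L)) {
    stop("unsupported channel count in '", path, "': ", d[3L], call. = FALSE)
  }
  raster_image(pmin(pmax(px, 0), 1))
}

#' Proportionally resize an image to a standard width
#'
#' First pipeline step: the photograph is resized to a fixed working width
#' (1,000 px by default) with bilinear interpolation and antialiasing; the
#' height follows proportionally, rounded to the nearest pixel.
#'
#' @param img A [raster_image].
#' @param target_width Output width in pixels (default 1000).
#' @return A [raster_image] of width `target_width`.
#' @export
resize_to_standard_width <- function(img, target_width = 1000L) {
  stopifnot(inherits(img, "raster_image"))
  target_width <- as.integer(target_width)
  if (is.na(target_width) || target_width < 2L) {
    stop("`target_width` must be an integer >= 2", call. = FALSE)
  }
  target_height <- as.integer(round(img$height_px * target_width / img$width_px))
  if (target_width == img$width_px && target_height == img$height_px) {
    return(img)
  }
  out <- EBImage::resize(array_to_ebimage(img$pixels),
                         w = target_width, h = target_height,
                         filter = "bilinear", antialias = TRUE)
  raster_image(pmin(pmax(ebimage_to_array(out), 0), 1))
}

#' Keep only the green channel
#'
#' Fluorescein emission under blue light with a yellow barrier filter lives
#' almost entirely in the green channel; red and blue are discarded.
#' Single-channel input passes through unchanged.
#'
#' @param img A [raster_image].
#' @return A single-channel [raster_image].
#' @export
extract_green <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img$channels == 1L) {
    return(img)
  }
  raster_image(img$pixels[, , 2L])
}

#' Maximise image contrast
#'
#' Linear min-max stretch of a single-channel image so the output spans
#' exactly `[0, 1]`. The stretch is monotone, so edge positions downstream
#' are unaffected by it; it only standardises the intensity scale.
#'
#' @param img A single-channel [raster_image].
#' @return A [raster_image] with minimum 0 and maximum 1.
#' @export
maximize_contrast <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img$channels != 1L) {
    stop("contrast stretch expects a single-channel image; ",
         "call extract_green() first", call. = FALSE)
  }
  lo <- min(img$pixels)
  hi <- max(img$pixels)
  if (hi - lo <= .Machine$double.eps) {
    stop("degenerate contrast: image is constant and carries no pattern",
         call. = FALSE)
  }
  raster_image((img$pixels - lo) / (hi - lo))
}
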