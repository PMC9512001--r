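# Run code under a temporary RNG state so generators are reproducible
# without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic bull's eye fluorescein pattern
#'
#' Describes an idealised ortho-k fluorescein photograph as four concentric
#' boundary circles on a dark background, alternating dark/bright from the
#' centre out: dark central bearing, bright tear-reservoir ring, dark
#' alignment (mid-peripheral bearing) ring, bright edge-lift ring. The
#' bright rings must exceed every dark level by at least 0.2 so that all
#' eight boundary crossings produce detectable intensity steps. Optional
#' Gaussian blur, additive sensor noise and JPEG re-encoding emulate the
#' degradations of real slit-lamp photographs.
#'
#' @param width_px,height_px Image size in px.
#' @param cx,cy Pattern centre in 0-based px coordinates (defaults: image
#'   centre).
#' @param diameters Numeric length-4, strictly decreasing boundary diameters
#'   `d1 > d2 > d3 > d4` in px (lens edge, edge-lift/alignment,
#'   alignment/reservoir, reservoir/central-bearing).
#' @param levels Named numeric intensities in `[0, 1]` for `background`,
#'   `edge_lift_ring`, `alignment_ring`, `reservoir_ring`, `central_zone`.
#' @param blur_sigma Gaussian blur bandwidth in px (0 = none).
#' @param noise_sd SD of additive Gaussian noise (clipped to `[0, 1]`).
#' @param jpeg_quality Optional JPEG quality (1-100) for a lossy re-encode;
#'   `NULL` keeps the image lossless.
#' @param seed Seed for the noise generator.
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(width_px = 1000L, height_px = 600L,
                         cx = (width_px - 1) / 2, cy = (height_px - 1) / 2,
                         diameters = c(900, 820, 700, 400),
                         levels = c(background = 0.05, edge_lift_ring = 0.75,
                                    alignment_ring = 0.15,
                                    reservoir_ring = 0.9,
                                    central_zone = 0.1),
                         blur_sigma = 0, noise_sd = 0, jpeg_quality = NULL,
                         seed = 1L) {
  d <- as.numeric(diameters)
  if (length(d) != 4L || any(diff(d) >= 0) || d[4L] <= 0) {
    stop("`diameters` must be 4 strictly decreasing positive values",
         call. = FALSE)
  }
  if (cx - d[1L] / 2 < 0 || cx + d[1L] / 2 > width_px - 1) {
    stop("outer boundary leaves the image horizontally (cx = ", cx,
         ", d1 = ", d[1L], ", width = ", width_px, ")", call. = FALSE)
  }
  need <- c("background", "edge_lift_ring", "alignment_ring",
            "reservoir_ring", "central_zone")
  if (!all(need %in% names(levels))) {
    stop("`levels` must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  levels <- levels[need]
  if (any(levels < 0 | levels > 1)) {
    stop("intensity levels must lie in [0, 1]", call. = FALSE)
  }
  dark <- levels[c("background", "alignment_ring", "central_zone")]
  bright <- levels[c("reservoir_ring", "edge_lift_ring")]
  if (min(bright) - max(dark) < 0.2) {
    stop("bright rings must exceed every dark level by at least 0.2 ",
         "(edges would be undetectable)", call. = FALSE)
  }
  if (blur_sigma < 0 || noise_sd < 0) {
    stop("`blur_sigma` and `noise_sd` must be >= 0", call. = FALSE)
  }
  if (!is.null(jpeg_quality) &&
      (jpeg_quality < 1 || jpeg_quality > 100)) {
    stop("`jpeg_quality` must be in [1, 100] or NULL", call. = FALSE)
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         cx = cx, cy = cy, diameters = stats::setNames(d, paste0("d", 1:4)),
         levels = levels, blur_sigma = blur_sigma, noise_sd = noise_sd,
         jpeg_quality = jpeg_quality, seed = seed),
    class = "pattern_spec")
}

#' Render a synthetic fluorescein pattern with known ground truth
#'
#' Rasterises the concentric annuli of a [pattern_spec()] into an RGB image:
#' the green channel is piecewise constant over the zones (a pixel at radius
#' `r` from the centre belongs to the innermost zone with `r < d(k)/2`), and
#' the red and blue channels are a fixed 25% of green, emulating a
#' blue-light/yellow-filter photograph. Gaussian blur, seeded additive
#' noise (clipped to `[0, 1]`) and an optional JPEG encode/decode round trip
#' are then applied in that order. The true boundary crossings on the
#' horizontal meridian are `cx - d(k)/2` and `cx + d(k)/2`.
#'
#' @param spec A [pattern_spec()].
#' @return A list with `image` (a [raster_image]), `edges` (the ground-truth
#'   `edge_set`, provenance `"ground_truth"`) and `spec`.
#' @export
render_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  w <- spec$width_px
  h <- spec$height_px
  x <- seq_len(w) - 1L
  y <- seq_len(h) - 1L
  r2 <- outer((y - spec$cy)^2, (x - spec$cx)^2, `+`)
  radius <- sqrt(r2)
  lv <- spec$levels
  d <- spec$diameters
  green <- matrix(lv[["background"]], h, w)
  green[radius < d[["d1"]] / 2] <- lv[["edge_lift_ring"]]
  green[radius < d[["d2"]] / 2] <- lv[["alignment_ring"]]
  green[radius < d[["d3"]] / 2] <- lv[["reservoir_ring"]]
  green[radius < d[["d4"]] / 2] <- lv[["central_zone"]]

  px <- array(0, dim = c(h, w, 3L))
  px[, , 1L] <- 0.25 * green
  px[, , 2L] <- green
  px[, , 3L] <- 0.25 * green

  if (spec$blur_sigma > 0) {
    img <- EBImage::gblur(array_to_ebimage(px), sigma = spec$blur_sigma)
    px <- ebimage_to_array(img)
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       array(stats::rnorm(length(px), sd = spec$noise_sd),
                             dim = dim(px)))
    px <- px + noise
  }
  px <- pmin(pmax(px, 0), 1)
  if (!is.null(spec$jpeg_quality)) {
    tmp <- tempfile(fileext = ".jpg")
    on.exit(unlink(tmp), add = TRUE)
    EBImage::writeImage(array_to_ebimage(px), tmp,
                        quality = spec$jpeg_quality)
    px <- ebimage_to_array(suppressWarnings(EBImage::readImage(tmp)))
    px <- pmin(pmax(px, 0), 1)
  }

  truth <- sort(c(spec$cx - d / 2, spec$cx + d / 2))
  list(image = raster_image(px),
       edges = edge_set(truth, provenance = "ground_truth"),
       spec = spec)
}

#' Derive a synthetic pattern from a lens data sheet
#'
#' Maps the nominal lens geometry to boundary diameters in px at a given
#' scale: the outer boundary at `total_diameter_mm / scale`; the
#' edge-lift/alignment boundary at `(D0 + 2*D1 + 2*D2) / scale`; the
#' alignment/reservoir boundary at `(D0 + 2*D1) / scale`; and the central
#' bearing at `central_bearing_mm / scale`. The central bearing must be
#' narrower than the back optic zone diameter — the fluorescein contact zone
#' always sits inside the optic zone.
#'
#' @param lens A [lens_spec()].
#' @param central_bearing_mm Width of the dark central contact zone in mm.
#' @param mm_per_px Scale in mm per px.
#' @param width_px,height_px,cx,cy Image geometry, as in [pattern_spec()].
#' @param ... Further arguments (levels, blur, noise, seed) passed to
#'   [pattern_spec()].
#' @return A [pattern_spec()].
#' @export
pattern_from_lens <- function(lens, central_bearing_mm, mm_per_px,
                              width_px = 1000L, height_px = 600L,
                              cx = (width_px - 1) / 2,
                              cy = (height_px - 1) / 2, ...) {
  stopifnot(inherits(lens, "lens_spec"))
  if (!(mm_per_px > 0)) stop("`mm_per_px` must be > 0", call. = FALSE)
  if (!(central_bearing_mm > 0 && central_bearing_mm < lens$bozd_mm)) {
    stop("central bearing (", central_bearing_mm, " mm) must be positive ",
         "and narrower than the back optic zone diameter (", lens$bozd_mm,
         " mm)", call. = FALSE)
  }
  d_mm <- c(lens$total_diameter_mm,
            lens$bozd_mm + 2 * lens$reverse_width_mm +
              2 * lens$alignment_width_mm,
            lens$bozd_mm + 2 * lens$reverse_width_mm,
            central_bearing_mm)
  d_px <- d_mm / mm_per_px
  if (any(diff(d_px) >= 0)) {
    stop("lens geometry does not yield nested boundaries at this scale",
         call. = FALSE)
  }
  pattern_spec(width_px = width_px, height_px = height_px, cx = cx, cy = cy,
               diameters = d_px, ...)
}

#' Write a rendered pattern and its ground-truth sidecar
#'
#' Saves the image as PNG or JPEG (by file extension) together with a JSON
#' sidecar (`<image>.json`) recording the generating `pattern_spec` and the
#' true boundary crossings, so downstream measurements can be scored
#' against exact ground truth.
#'
#' @param rendered A list from [render_pattern()].
#' @param path Output image path ending in `.png`, `.jpg` or `.jpeg`.
#' @return Invisibly, a character vector of the two files written.
#' @export
write_pattern <- function(rendered, path) {
  stopifnot(is.list(rendered), inherits(rendered$image, "raster_image"))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "jpg", "jpeg")) {
    stop("`path` must end in .png, .jpg or .jpeg", call. = FALSE)
  }
  EBImage::writeImage(array_to_ebimage(rendered$image$pixels), path)
  spec <- rendered$spec
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(ground_truth_edges_px = rendered$edges$x,
         diameters_px = as.list(spec$diameters),
         center_px = c(spec$cx, spec$cy),
         size_px = c(spec$width_px, spec$height_px),
         levels = as.list(spec$levels),
         blur_sigma = spec$blur_sigma,
         noise_sd = spec$noise_sd,
         jpeg_quality = spec$jpeg_quality,
         seed = spec$seed),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(path, sidecar))
}
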