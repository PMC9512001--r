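#' Pipeline configuration
#'
#' Bundles the tunable parameters of the measurement pipeline with the
#' standard defaults: working width 1,000 px, meridian band 60 px, Gaussian
#' pre-smoothing sigma 2 px, peak prominence threshold 0.1 of the derivative
#' maximum, minimum peak separation 10 px.
#'
#' @param target_width Working image width in px.
#' @param band_height Meridian band height in px.
#' @param smoothing_sigma Profile pre-smoothing bandwidth in px (0 disables).
#' @param min_prominence_frac Peak prominence threshold, fraction of max.
#' @param min_separation_px Minimum peak spacing in px.
#' @param reduce Band reduction, `"mean"` or `"median"`.
#' @param refine_window Half-width (px) of the raw-derivative window used by
#'   [refine_peaks()] to re-localise peaks detected on the smoothed
#'   derivative; 0 disables refinement.
#' @param decentration_frac Centre-offset fraction that flags a decentred
#'   lens in automatic assignment.
#' @return A named list of validated parameters, class `ok_config`.
#' @export
ok_config <- function(target_width = 1000L, band_height = 60L,
                      smoothing_sigma = 2, min_prominence_frac = 0.1,
                      min_separation_px = 10L, reduce = c("mean", "median"),
                      refine_window = 3L, decentration_frac = 0.05) {
  reduce <- match.arg(reduce)
  if (target_width < 2L) stop("`target_width` must be >= 2", call. = FALSE)
  if (band_height < 1L) stop("`band_height` must be >= 1", call. = FALSE)
  if (smoothing_sigma < 0) stop("`smoothing_sigma` must be >= 0", call. = FALSE)
  if (!(min_prominence_frac > 0 && min_prominence_frac <= 1)) {
    stop("`min_prominence_frac` must be in (0, 1]", call. = FALSE)
  }
  if (min_separation_px < 1L) {
    stop("`min_separation_px` must be >= 1", call. = FALSE)
  }
  structure(
    list(target_width = as.integer(target_width),
         band_height = as.integer(band_height),
         smoothing_sigma = smoothing_sigma,
         min_prominence_frac = min_prominence_frac,
         min_separation_px = as.integer(min_separation_px),
         reduce = reduce,
         refine_window = as.integer(refine_window),
         decentration_frac = decentration_frac),
    class = "ok_config")
}

#' Measure the fluorescein zone widths in one photograph
#'
#' Runs the full pipeline on a cropped fluorescein photograph: proportional
#' resize to the working width, green-channel extraction, contrast stretch,
#' meridian-band averaging, absolute first derivative, peak detection, edge
#' assignment (automatic symmetry-based selection, or manual via
#' `chosen_indices`), the zone-width formulas, and calibration to mm against
#' the nominal lens diameter.
#'
#' @param x Path to a JPEG/PNG image, or a [raster_image].
#' @param lens A [lens_spec()] (or `NULL` to skip calibration).
#' @param config An [ok_config()].
#' @param chosen_indices Optional eight 0-based peak indices for manual
#'   assignment; `NULL` (default) selects edges automatically.
#' @param image_id Identifier recorded in the output (defaults to the file
#'   name, or `"image"` for in-memory input).
#' @return An object of class `ok_measurement`: a list with the calibrated
#'   `widths` (a `zone_widths`), `edges`, `peaks`, `profile`, `derivative`,
#'   `config` and `image_id`.
#' @export
measure_pattern <- function(x, lens = NULL, config = ok_config(),
                            chosen_indices = NULL, image_id = NULL) {
  stopifnot(inherits(config, "ok_config"))
  if (is.character(x)) {
    if (is.null(image_id)) image_id <- basename(x)
    img <- load_image(x)
  } else if (inherits(x, "raster_image")) {
    if (is.null(image_id)) image_id <- "image"
    img <- x
  } else {
    stop("`x` must be a file path or a raster_image", call. = FALSE)
  }

  img <- resize_to_standard_width(img, config$target_width)
  img <- extract_green(img)
  img <- maximize_contrast(img)
  band <- extract_meridian_band(img, config$band_height)
  profile <- compute_profile(band, reduce = config$reduce)
  deriv <- abs_first_derivative(profile, config$smoothing_sigma)
  peaks <- detect_peaks(deriv, config$min_prominence_frac,
                        config$min_separation_px)
  if (config$smoothing_sigma > 0 && config$refine_window > 0L) {
    raw <- abs_first_derivative(profile, 0)
    peaks <- refine_peaks(peaks, raw, config$refine_window)
  }

  edges <- if (is.null(chosen_indices)) {
    assign_edges_auto(peaks, image_width = config$target_width,
                      decentration_frac = config$decentration_frac)
  } else {
    assign_edges_manual(peaks, chosen_indices)
  }
  widths <- widths_from_edges(edges)
  if (!is.null(lens)) {
    widths <- calibrate(widths, lens)
  }
  structure(
    list(image_id = image_id, widths = widths, edges = edges, peaks = peaks,
         profile = profile, derivative = deriv, band = band, config = config),
    class = "ok_measurement")
}

#' @export
print.ok_measurement <- function(x, ...) {
  cat(sprintf("<ok_measurement> %s: %d peaks, edges %s\n", x$image_id,
              length(x$peaks$positions), x$edges$provenance[1L]))
  print(x$widths)
  invisible(x)
}

#' Measure a batch of photographs
#'
#' Applies [measure_pattern()] to each file, continuing past per-image
#' failures (a clinic folder should not be blocked by one bad photograph).
#'
#' @param paths Character vector of image paths.
#' @param lens A [lens_spec()] or `NULL`.
#' @param config An [ok_config()].
#' @param observer,method Labels copied into the output table.
#' @return A list with `measurements` (long data frame, one row per image
#'   and zone: `image_id`, `observer`, `method`, `zone`, `width_px`,
#'   `width_mm`, `mm_per_px`, `edge_provenance`) and `failures` (data frame
#'   of `image_id`, `error`).
#' @export
measure_batch <- function(paths, lens = NULL, config = ok_config(),
                          observer = 1L, method = "algorithm") {
  rows <- list()
  fails <- list()
  for (p in paths) {
    res <- tryCatch(measure_pattern(p, lens = lens, config = config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(image_id = basename(p), error = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    df <- as.data.frame(res$widths)
    df <- cbind(image_id = res$image_id, observer = observer,
                method = method, df)
    rows[[length(rows) + 1L]] <- df
  }
  list(
    measurements = if (length(rows)) do.call(rbind, rows) else
      data.frame(image_id = character(0), observer = integer(0),
                 method = character(0), zone = character(0),
                 width_px = numeric(0), width_mm = numeric(0),
                 mm_per_px = numeric(0), edge_provenance = character(0)),
    failures = if (length(fails)) do.call(rbind, fails) else
      data.frame(image_id = character(0), error = character(0)))
}
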