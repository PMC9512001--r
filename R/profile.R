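#' Extract the central horizontal-meridian band
#'
#' The fluorescein pattern along the horizontal meridian is, for a centred
#' lens, representative of the whole pattern; a band of rows (60 px by
#' default) centred on the image's horizontal midline is kept for analysis.
#' The band covers rows `[row_start, row_start + band_height)` in 0-based
#' coordinates with `row_start = floor((height - band_height) / 2)`.
#'
#' @param img A single-channel [raster_image].
#' @param band_height Number of rows in the band (default 60).
#' @return An object of class `meridian_band` with fields `pixels`
#'   (`band_height x width_px` matrix), `band_height` and `row_range`
#'   (0-based half-open `c(row_start, row_end)`).
#' @export
extract_meridian_band <- function(img, band_height = 60L) {
  stopifnot(inherits(img, "raster_image"))
  if (img$channels != 1L) {
    stop("meridian band extraction expects a single-channel image",
         call. = FALSE)
  }
  band_height <- as.integer(band_height)
  if (is.na(band_height) || band_height < 1L) {
    stop("`band_height` must be a positive integer", call. = FALSE)
  }
  if (img$height_px < band_height) {
    stop("image too small: height ", img$height_px,
         " px is below the requested band height ", band_height, " px",
         call. = FALSE)
  }
  row_start <- (img$height_px - band_height) %/% 2L   # 0-based
  rows <- seq.int(row_start + 1L, row_start + band_height)
  structure(
    list(
      pixels = img$pixels[rows, , drop = FALSE],
      band_height = band_height,
      row_range = c(row_start, row_start + band_height)
    ),
    class = "meridian_band"
  )
}

#' Collapse the meridian band to a 1-D intensity profile
#'
#' Each column of the band is reduced to a single intensity, by default the
#' mean over the band's rows (best noise suppression under additive Gaussian
#' noise); the median is available as a robust alternative.
#'
#' @param band A `meridian_band` from [extract_meridian_band()].
#' @param reduce Either `"mean"` (default) or `"median"`.
#' @return An object of class `intensity_profile`: a numeric vector of
#'   length `width_px` with attribute `x` giving the 0-based column index.
#' @export
compute_profile <- function(band, reduce = c("mean", "median")) {
  stopifnot(inherits(band, "meridian_band"))
  reduce <- match.arg(reduce)
  values <- switch(reduce,
    mean = colMeans(band$pixels),
    median = apply(band$pixels, 2L, stats::median)
  )
  structure(as.numeric(values),
            x = seq_along(values) - 1L,
            class = "intensity_profile")
}

#' Smooth a 1-D signal with a Gaussian kernel
#'
#' Discrete Gaussian convolution with kernel radius `ceiling(4 * sigma)` and
#' reflected boundary padding, so a constant signal is returned unchanged.
#' `sigma = 0` disables smoothing.
#'
#' @param x Numeric vector.
#' @param sigma Kernel standard deviation in samples.
#' @return Numeric vector of the same length as `x`.
#' @export
gaussian_smooth <- function(x, sigma) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0 || length(x) < 2L) {
    return(as.numeric(x))
  }
  radius <- as.integer(ceiling(4 * sigma))
  kernel <- stats::dnorm(seq.int(-radius, radius), sd = sigma)
  kernel <- kernel / sum(kernel)
  n <- length(x)
  # reflect-pad; reflection may repeat if the kernel outsizes the signal
  idx <- seq.int(-radius + 1L, n + radius)
  refl <- function(i, n) {
    i <- (i - 1L) %% (2L * n)
    ifelse(i < n, i + 1L, 2L * n - i)
  }
  padded <- x[refl(idx, n)]
  as.numeric(stats::convolve(padded, rev(kernel), type = "filter"))
}

#' Absolute first derivative of the intensity profile
#'
#' Computes `|profile[i+1] - profile[i]|` after an optional Gaussian
#' pre-smoothing of the profile (default `sigma = 2` px) that suppresses
#' JPEG-blocking and sensor noise. Element `i` (0-based) of the result is
#' attributed to column `i` of the resized image -- a uniform half-pixel
#' convention that cancels in all diameter differences.
#'
#' @param profile An `intensity_profile` (or plain numeric vector) of
#'   length >= 2.
#' @param smoothing_sigma Gaussian pre-smoothing bandwidth in px; 0 disables.
#' @return An object of class `derivative_profile`: a non-negative numeric
#'   vector of length `length(profile) - 1`.
#' @export
abs_first_derivative <- function(profile, smoothing_sigma = 2) {
  values <- as.numeric(profile)
  if (length(values) < 2L) {
    stop("profile must contain at least 2 samples", call. = FALSE)
  }
  values <- gaussian_smooth(values, smoothing_sigma)
  structure(abs(diff(values)),
            smoothing_sigma = smoothing_sigma,
            class = "derivative_profile")
}

# 0-based indices of local maxima; plateaus contribute their central sample.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        out <- c(out, (i + j) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out - 1L
}

# Topographic prominence of peak at 0-based index p: height above the higher
# of the two valley floors separating it from the nearest taller sample (or
# the signal end) on each side.
peak_prominence <- function(x, p) {
  i <- p + 1L
  h <- x[i]
  n <- length(x)
  left_min <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) {
    left_min <- min(left_min, x[j])
    j <- j - 1L
  }
  right_min <- h
  j <- i + 1L
  while (j <= n && x[j] <= h) {
    right_min <- min(right_min, x[j])
    j <- j + 1L
  }
  h - max(left_min, right_min)
}

#' Detect candidate edge peaks in the derivative profile
#'
#' Zone boundaries appear as local maxima of the absolute derivative. A
#' candidate must have topographic prominence of at least
#' `min_prominence_frac` times the derivative's global maximum, and accepted
#' peaks must be at least `min_separation_px` apart. When two candidates are
#' closer than the separation, the larger magnitude wins; exact ties go to
#' the smaller column index.
#'
#' @param deriv A `derivative_profile` (or numeric vector of non-negative
#'   values).
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   derivative maximum, in `(0, 1]` (default 0.1).
#' @param min_separation_px Minimum spacing between accepted peaks in px
#'   (default 10).
#' @return An object of class `peak_set`: a list with `positions` (0-based,
#'   strictly increasing), `magnitudes`, and the detection parameters.
#'   An all-zero derivative yields an empty peak set.
#' @export
detect_peaks <- function(deriv, min_prominence_frac = 0.1,
                         min_separation_px = 10L) {
  values <- as.numeric(deriv)
  if (any(values < 0)) {
    stop("derivative magnitudes must be non-negative", call. = FALSE)
  }
  if (!(min_prominence_frac > 0 && min_prominence_frac <= 1)) {
    stop("`min_prominence_frac` must be in (0, 1]", call. = FALSE)
  }
  min_separation_px <- as.integer(min_separation_px)
  if (is.na(min_separation_px) || min_separation_px < 1L) {
    stop("`min_separation_px` must be a positive integer", call. = FALSE)
  }

  empty <- structure(
    list(positions = integer(0), magnitudes = numeric(0),
         min_prominence_frac = min_prominence_frac,
         min_separation_px = min_separation_px),
    class = "peak_set")
  mx <- if (length(values)) max(values) else 0
  if (mx == 0) return(empty)

  cand <- local_maxima(values)
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(p) peak_prominence(values, p), numeric(1))
  keep <- prom >= min_prominence_frac * mx
  cand <- cand[keep]
  if (!length(cand)) return(empty)

  # greedy non-maximum suppression: strongest first, ties to smaller x
  mag <- values[cand + 1L]
  ord <- order(-mag, cand)
  accepted <- integer(0)
  for (k in ord) {
    if (all(abs(cand[k] - accepted) >= min_separation_px)) {
      accepted <- c(accepted, cand[k])
    }
  }
  accepted <- sort(accepted)
  structure(
    list(positions = accepted,
         magnitudes = values[accepted + 1L],
         min_prominence_frac = min_prominence_frac,
         min_separation_px = min_separation_px),
    class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak%s (prominence >= %.3g of max, separation >= %d px)\n",
              length(x$positions), if (length(x$positions) == 1L) "" else "s",
              x$min_prominence_frac, x$min_separation_px))
  if (length(x$positions)) {
    print(data.frame(index = seq_along(x$positions) - 1L,
                     x = x$positions,
                     magnitude = signif(x$magnitudes, 4)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Re-localise detected peaks on an unsmoothed derivative
#'
#' Gaussian pre-smoothing makes peak *detection* robust but biases peak
#' *position* inward on band-averaged circular edges: averaging over a
#' 60-px band spreads a boundary circle's crossing into a ramp whose raw
#' derivative is steepest at the true (outermost) edge, and smoothing pulls
#' the maximum toward the ramp centre. Each accepted peak is therefore
#' moved to the argmax of the raw (unsmoothed) derivative within a small
#' window around the detected position; ties go to the sample nearest the
#' detected position, then to the smaller column.
#'
#' @param peaks A `peak_set` detected on the smoothed derivative.
#' @param raw_deriv The derivative computed with `smoothing_sigma = 0`
#'   (same length signal).
#' @param window Half-width of the search window in px (default 3).
#' @return The `peak_set` with refined positions (still strictly
#'   increasing) and magnitudes taken from the raw derivative.
#' @export
refine_peaks <- function(peaks, raw_deriv, window = 3L) {
  stopifnot(inherits(peaks, "peak_set"))
  raw <- as.numeric(raw_deriv)
  window <- as.integer(window)
  if (window < 0L) stop("`window` must be >= 0", call. = FALSE)
  n <- length(raw)
  refined <- vapply(peaks$positions, function(p) {
    lo <- max(0L, p - window)
    hi <- min(n - 1L, p + window)
    idx <- lo:hi
    v <- raw[idx + 1L]
    best <- idx[v == max(v)]
    best[order(abs(best - p), best)][1L]
  }, numeric(1))
  if (any(diff(refined) <= 0)) {
    # refinement collided two peaks; keep the original positions
    return(peaks)
  }
  peaks$positions <- as.integer(refined)
  peaks$magnitudes <- raw[peaks$positions + 1L]
  peaks
}

#' Export a profile or derivative as a two-column data frame
#'
#' @param x An `intensity_profile`, `derivative_profile` or `peak_set`.
#' @return A data frame with columns `x` (0-based column) and `value`.
#' @export
as_xy <- function(x) {
  if (inherits(x, "peak_set")) {
    return(data.frame(x = x$positions, value = x$magnitudes))
  }
  data.frame(x = seq_along(as.numeric(x)) - 1L, value = as.numeric(x))
}
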