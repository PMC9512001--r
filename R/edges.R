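#' Reverse-geometry lens specification
#'
#' Nominal geometry of an orthokeratology lens as printed on the
#' manufacturer's data sheet: the total diameter, the back optic zone
#' diameter (BOZD, `D0`) and the annular widths of the reverse curve (`D1`),
#' alignment curve (`D2`) and edge lift (`D3`). Radii (`R0`-`R3`) are
#' accepted but not used by any computation. The geometry should close:
#' `total = D0 + 2 * (D1 + D2 + D3)`; [check_lens_geometry()] reports the
#' residual.
#'
#' @param total_diameter_mm Overall lens diameter in mm.
#' @param bozd_mm Back optic zone diameter `D0` in mm.
#' @param reverse_width_mm Reverse-curve annulus width `D1` in mm.
#' @param alignment_width_mm Alignment annulus width `D2` in mm.
#' @param edge_lift_width_mm Edge-lift annulus width `D3` in mm.
#' @param bozr_mm,reverse_radius_mm,alignment_radius_mm,peripheral_radius_mm
#'   Optional curve radii `R0`-`R3` in mm.
#' @return An object of class `lens_spec`.
#' @export
lens_spec <- function(total_diameter_mm, bozd_mm, reverse_width_mm,
                      alignment_width_mm, edge_lift_width_mm,
                      bozr_mm = NA_real_, reverse_radius_mm = NA_real_,
                      alignment_radius_mm = NA_real_,
                      peripheral_radius_mm = NA_real_) {
  widths <- c(total_diameter_mm = total_diameter_mm, bozd_mm = bozd_mm,
              reverse_width_mm = reverse_width_mm,
              alignment_width_mm = alignment_width_mm,
              edge_lift_width_mm = edge_lift_width_mm)
  if (any(!is.finite(widths)) || any(widths <= 0)) {
    bad <- names(widths)[!is.finite(widths) | widths <= 0]
    stop("lens dimensions must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- structure(
    list(total_diameter_mm = total_diameter_mm, bozd_mm = bozd_mm,
         reverse_width_mm = reverse_width_mm,
         alignment_width_mm = alignment_width_mm,
         edge_lift_width_mm = edge_lift_width_mm,
         bozr_mm = bozr_mm, reverse_radius_mm = reverse_radius_mm,
         alignment_radius_mm = alignment_radius_mm,
         peripheral_radius_mm = peripheral_radius_mm),
    class = "lens_spec")
  residual <- check_lens_geometry(out, quiet = TRUE)
  if (abs(residual) > 0.01) {
    warning(sprintf(
      "lens geometry does not close: total - (D0 + 2*(D1 + D2 + D3)) = %+.3f mm",
      residual), call. = FALSE)
  }
  out
}

#' @export
print.lens_spec <- function(x, ...) {
  cat(sprintf(
    "<lens_spec> total %.2f mm; D0 %.2f, D1 %.2f, D2 %.2f, D3 %.2f mm\n",
    x$total_diameter_mm, x$bozd_mm, x$reverse_width_mm,
    x$alignment_width_mm, x$edge_lift_width_mm))
  invisible(x)
}

#' Check lens geometry closure
#'
#' The nominal zone widths of a reverse-geometry lens must tile its total
#' diameter: `total = D0 + 2 * (D1 + D2 + D3)`. Returns the closure residual
#' `total - (D0 + 2 * (D1 + D2 + D3))` in mm and warns when it exceeds
#' 0.01 mm in magnitude.
#'
#' @param lens A [lens_spec()].
#' @param quiet Suppress the warning (default `FALSE`).
#' @return The residual in mm, invisibly visible (a plain number).
#' @export
check_lens_geometry <- function(lens, quiet = FALSE) {
  stopifnot(inherits(lens, "lens_spec"))
  needed <- c("total_diameter_mm", "bozd_mm", "reverse_width_mm",
              "alignment_width_mm", "edge_lift_width_mm")
  vals <- unlist(lens[needed])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("lens spec is missing or has non-positive required fields",
         call. = FALSE)
  }
  residual <- lens$total_diameter_mm -
    (lens$bozd_mm + 2 * (lens$reverse_width_mm + lens$alignment_width_mm +
                           lens$edge_lift_width_mm))
  if (!quiet && abs(residual) > 0.01) {
    warning(sprintf("lens geometry closure residual %+.3f mm exceeds 0.01 mm",
                    residual), call. = FALSE)
  }
  residual
}

#' Read a lens specification from a key-value file
#'
#' Accepts `key = value` or `key: value` lines (one per line, `#` comments
#' allowed). Keys follow the data-sheet naming: `total_diameter_mm` and
#' `D0`-`D3` (or the long names used by [lens_spec()]); radii `R0`-`R3`
#' optional.
#'
#' @param path Path to the config file.
#' @return A [lens_spec()].
#' @export
read_lens_spec <- function(path) {
  if (!file.exists(path)) {
    stop("lens spec file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad)) {
    stop("unparseable line in lens spec '", path, "': ", bad[[1L]],
         call. = FALSE)
  }
  vals <- stats::setNames(
    suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 3L))),
    vapply(kv, `[`, character(1), 2L))
  alias <- c(D0 = "bozd_mm", D1 = "reverse_width_mm", D2 = "alignment_width_mm",
             D3 = "edge_lift_width_mm", R0 = "bozr_mm",
             R1 = "reverse_radius_mm", R2 = "alignment_radius_mm",
             R3 = "peripheral_radius_mm")
  names(vals) <- ifelse(names(vals) %in% names(alias),
                        alias[names(vals)], names(vals))
  get <- function(key) if (key %in% names(vals)) unname(vals[[key]]) else NA_real_
  required <- c("total_diameter_mm", "bozd_mm", "reverse_width_mm",
                "alignment_width_mm", "edge_lift_width_mm")
  missing <- required[vapply(required, function(k) is.na(get(k)), logical(1))]
  if (length(missing)) {
    stop("lens spec '", path, "' is missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lens_spec(
    total_diameter_mm = get("total_diameter_mm"),
    bozd_mm = get("bozd_mm"),
    reverse_width_mm = get("reverse_width_mm"),
    alignment_width_mm = get("alignment_width_mm"),
    edge_lift_width_mm = get("edge_lift_width_mm"),
    bozr_mm = get("bozr_mm"),
    reverse_radius_mm = get("reverse_radius_mm"),
    alignment_radius_mm = get("alignment_radius_mm"),
    peripheral_radius_mm = get("peripheral_radius_mm"))
}

#' Eight zone-boundary crossings on the horizontal meridian
#'
#' The four concentric zone boundaries cross the horizontal meridian at
#' eight columns, ordered `L1 < L2 < L3 < L4 < R4 < R3 < R2 < R1`, where the
#' pair `(Lk, Rk)` belongs to boundary circle `k` (1 = lens outer edge,
#' 2 = edge-lift/alignment, 3 = alignment/reservoir, 4 = reservoir/central
#' bearing). Boundary diameters `d(k) = Rk - Lk` must be strictly nested.
#'
#' @param x Eight strictly increasing 0-based column positions (px).
#' @param provenance `"automatic"` or `"manual"`, recycled to length 8.
#' @return An object of class `edge_set` with fields `x`, `provenance` and
#'   `diameters_px` (named `d1`-`d4`).
#' @export
edge_set <- function(x, provenance = "automatic") {
  x <- as.numeric(x)
  if (length(x) != 8L) {
    stop("an edge set needs exactly 8 positions, got ", length(x),
         call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("edge positions must be strictly increasing", call. = FALSE)
  }
  d <- x[8:5] - x[1:4]                     # d(1)..d(4)
  if (any(diff(d) >= 0) || any(d <= 0)) {
    k <- which(diff(d) >= 0)[1L]
    stop(sprintf(
      "nesting violated: boundary %d diameter (%.1f px) must exceed boundary %d (%.1f px)",
      k, d[k], k + 1L, d[k + 1L]), call. = FALSE)
  }
  structure(
    list(x = x,
         provenance = rep_len(as.character(provenance), 8L),
         diameters_px = stats::setNames(d, paste0("d", 1:4))),
    class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat("<edge_set>", paste(round(x$x, 1), collapse = " "), "px\n")
  cat("  diameters:",
      paste(sprintf("d%d = %.1f", 1:4, x$diameters_px), collapse = ", "),
      sprintf(" [%s]\n", x$provenance[1L]))
  invisible(x)
}

# All nesting-consistent selections of 4 left + 4 right peaks, paired in
# nesting order; returns the one minimising the summed symmetry residual
# about the midline. Ties resolved by enumeration order (left combinations
# in lexicographic order, then right), which is deterministic.
best_nested_pairs <- function(left, right, mid) {
  lc <- utils::combn(sort(left), 4L)
  rc <- utils::combn(sort(right), 4L)
  best <- NULL
  best_score <- Inf
  for (i in seq_len(ncol(lc))) {
    l <- lc[, i]
    for (j in seq_len(ncol(rc))) {
      r <- rc[, j]                          # ascending; pair l[k] with r[5-k]
      score <- sum(abs((l + rev(r)) / 2 - mid))
      if (score < best_score - 1e-12) {
        best_score <- score
        best <- c(l, r)
      }
    }
  }
  list(x = best, score = best_score)
}

#' Automatically assign the eight zone-boundary edges
#'
#' Selects, from the detected derivative peaks, the eight that form four
#' nested symmetric pairs. Peaks are split at the image's vertical midline;
#' every choice of four left and four right peaks is paired in nesting order
#' and scored by its total symmetry residual, the sum over pairs of
#' `|(l + r)/2 - width/2|`. The global minimiser is returned (strict nesting
#' is implied by the ordered pairing). Selections whose implied lens centre
#' is off the midline by more than `decentration_frac` of the image width
#' are flagged with a warning, mirroring the clinical practice of discarding
#' photographs of decentred lenses.
#'
#' @param peaks A `peak_set` from [detect_peaks()] with at least 8 peaks.
#' @param image_width Width of the resized image in px.
#' @param decentration_frac Offset fraction that triggers the decentred-lens
#'   warning (default 0.05).
#' @return An `edge_set` flagged `"automatic"`, with attributes
#'   `symmetry_residual_px` (total residual) and `center_offset_px`.
#' @export
assign_edges_auto <- function(peaks, image_width, decentration_frac = 0.05) {
  stopifnot(inherits(peaks, "peak_set"))
  pos <- peaks$positions
  if (length(pos) < 8L) {
    stop("insufficient edges: ", length(pos), " peaks detected but 8 are ",
         "needed; use manual assignment or relax the detection thresholds",
         call. = FALSE)
  }
  mid <- image_width / 2
  left <- pos[pos < mid]
  right <- pos[pos >= mid]
  if (length(left) < 4L || length(right) < 4L) {
    stop("edge assignment failed: need at least 4 peaks on each side of ",
         "the midline (found ", length(left), " left, ", length(right),
         " right)", call. = FALSE)
  }
  sel <- best_nested_pairs(left, right, mid)
  if (is.null(sel$x)) {
    stop("edge assignment failed: no nesting-consistent selection of 4 ",
         "symmetric pairs exists", call. = FALSE)
  }
  out <- edge_set(sort(sel$x), provenance = "automatic")
  center <- mean(out$x)
  offset <- abs(center - mid)
  if (offset > decentration_frac * image_width) {
    warning(sprintf(
      "lens appears decentred: centre offset %.1f px exceeds %.0f%% of image width",
      offset, 100 * decentration_frac), call. = FALSE)
  }
  attr(out, "symmetry_residual_px") <- sel$score
  attr(out, "center_offset_px") <- offset
  out
}

#' Manually assign the eight zone-boundary edges
#'
#' Observer-driven selection: the observer inspects the detected peak list
#' (or the diagnostic plot) and names the eight peaks that are true zone
#' boundaries. Indices are 0-based, matching the printed peak list.
#'
#' @param peaks A `peak_set`.
#' @param chosen_indices Eight distinct 0-based indices into the peak list.
#' @return An `edge_set` flagged `"manual"`.
#' @export
assign_edges_manual <- function(peaks, chosen_indices) {
  stopifnot(inherits(peaks, "peak_set"))
  idx <- as.integer(chosen_indices)
  if (length(idx) != 8L) {
    stop("exactly 8 peak indices are required, got ", length(idx),
         call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("duplicate peak index: ", idx[duplicated(idx)][1L], call. = FALSE)
  }
  if (any(idx < 0L) || any(idx >= length(peaks$positions))) {
    stop("peak index out of range [0, ", length(peaks$positions) - 1L, "]",
         call. = FALSE)
  }
  edge_set(sort(peaks$positions[idx + 1L]), provenance = "manual")
}

#' Zone widths from the eight boundary crossings
#'
#' With boundary diameters `d(k) = Rk - Lk`, the horizontal widths are:
#' total diameter `d(1)`; edge lift `(d(1) - d(2))/2`; mid-peripheral
#' bearing `(d(2) - d(3))/2`; tear reservoir `(d(3) - d(4))/2`; central
#' bearing `d(4)`. Annular half-widths are kept at full (possibly
#' fractional) pixel precision. The widths close exactly:
#' `central + 2 * (reservoir + mid_peripheral + edge_lift) = total`.
#'
#' @param edges An `edge_set`.
#' @return An object of class `zone_widths` with the five widths in px
#'   (`*_px` fields); mm fields are `NA` until [calibrate()] is applied.
#' @export
widths_from_edges <- function(edges) {
  stopifnot(inherits(edges, "edge_set"))
  d <- edges$diameters_px
  px <- c(total_diameter = unname(d[1L]),
          edge_lift = unname(d[1L] - d[2L]) / 2,
          mid_peripheral = unname(d[2L] - d[3L]) / 2,
          tear_reservoir = unname(d[3L] - d[4L]) / 2,
          central_bearing = unname(d[4L]))
  structure(
    list(px = px,
         mm = stats::setNames(rep(NA_real_, 5L), names(px)),
         mm_per_px = NA_real_,
         lens = NULL,
         edges = edges),
    class = "zone_widths")
}

#' Calibrate zone widths from pixels to millimetres
#'
#' Anchors the pixel scale to the manufacturer's nominal total lens
#' diameter: `mm_per_px = total_diameter_mm / total_diameter_px`. By
#' construction the calibrated total diameter equals the nominal diameter;
#' the four zone widths follow linearly. Full precision is retained; round
#' only for presentation.
#'
#' @param widths A `zone_widths` from [widths_from_edges()].
#' @param lens A [lens_spec()] supplying the nominal diameter.
#' @return The `zone_widths` with `mm`, `mm_per_px` and `lens` filled in.
#' @export
calibrate <- function(widths, lens) {
  stopifnot(inherits(widths, "zone_widths"), inherits(lens, "lens_spec"))
  total_px <- widths$px[["total_diameter"]]
  if (!is.finite(total_px) || total_px <= 0) {
    stop("calibration impossible: measured total diameter is ", total_px,
         " px", call. = FALSE)
  }
  mm_per_px <- lens$total_diameter_mm / total_px
  widths$mm <- widths$px * mm_per_px
  widths$mm_per_px <- mm_per_px
  widths$lens <- lens
  widths
}

#' @export
print.zone_widths <- function(x, ...) {
  df <- data.frame(zone = names(x$px),
                   width_px = round(unname(x$px), 1))
  if (all(is.finite(x$mm))) {
    df$width_mm <- round(unname(x$mm), 2)
  }
  cat("<zone_widths>")
  if (is.finite(x$mm_per_px)) {
    cat(sprintf(" (%.4f mm/px)", x$mm_per_px))
  }
  cat("\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.zone_widths <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(zone = names(x$px),
             width_px = unname(x$px),
             width_mm = unname(x$mm),
             mm_per_px = x$mm_per_px,
             edge_provenance = x$edges$provenance[1L],
             stringsAsFactors = FALSE)
}
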