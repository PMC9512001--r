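# Shared fixtures: all test imagery is generated in code at run time.

# The study lens data sheet (nominal means).
table1_lens <- function() {
  lens_spec(total_diameter_mm = 10.89, bozd_mm = 6.79,
            reverse_width_mm = 0.60, alignment_width_mm = 0.85,
            edge_lift_width_mm = 0.60)
}

# A clean bull's eye centred at integer column 500 so the ground-truth
# crossings {50, 90, 150, 300, 700, 850, 910, 950} are exact.
std_pattern <- function(...) {
  pattern_spec(width_px = 1000L, height_px = 600L, cx = 500, cy = 300,
               diameters = c(900, 820, 700, 400), ...)
}

# Peak set built directly from positions (for edge-assignment tests).
make_peak_set <- function(positions, magnitudes = NULL) {
  positions <- sort(positions)
  if (is.null(magnitudes)) magnitudes <- rep(1, length(positions))
  structure(list(positions = positions, magnitudes = magnitudes,
                 min_prominence_frac = 0.1, min_separation_px = 10L),
            class = "peak_set")
}

# Independent brute-force oracle for automatic edge assignment: enumerate
# every 8-subset of the peaks, pair the sorted positions outermost-in,
# require each pair to straddle the midline, and minimise the summed
# symmetry residual. Deliberately coded differently from the package path
# (which enumerates 4-subsets per side).
oracle_assign_score <- function(positions, width) {
  mid <- width / 2
  best <- Inf
  subsets <- utils::combn(sort(positions), 8L)
  for (i in seq_len(ncol(subsets))) {
    x <- subsets[, i]
    if (!(x[4L] < mid && x[5L] >= mid)) next
    score <- sum(abs((x[1:4] + x[8:5]) / 2 - mid))
    if (score < best) best <- score
  }
  best
}

# Difference vector with exact mean m and SD s (n >= 3).
exact_moments <- function(m, s, n, seed = 1L) {
  set.seed(seed)
  d <- stats::rnorm(n)
  m + s * (d - mean(d)) / stats::sd(d)
}

# Long-format measurement table for n eyes: per-zone base widths plus
# seeded observer/method effects.
sim_table <- function(n_eyes = 26L, seed = 42L, method_offset = 0,
                      noise_sd = 0.05, constant = FALSE) {
  set.seed(seed)
  base <- c(central_bearing = 4.2, tear_reservoir = 1.7,
            mid_peripheral = 1.15, edge_lift = 0.48)
  rows <- list()
  for (zone in names(base)) {
    eye_w <- if (constant) rep(base[[zone]], n_eyes) else
      base[[zone]] + stats::rnorm(n_eyes, sd = 0.2 * base[[zone]])
    for (obs in 1:2) {
      for (method in c("algorithm", "imagej")) {
        w <- eye_w + if (method == "imagej") method_offset else 0
        if (!constant) w <- w + stats::rnorm(n_eyes, sd = noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          eye_id = sprintf("eye%02d", seq_len(n_eyes)),
          observer = obs, method = method, zone = zone,
          width_mm = pmax(w, 0.01), stringsAsFactors = FALSE)
      }
    }
  }
  okfluor:::as_measurement_table(do.call(rbind, rows))
}

# Two-sided paired-t p-value by direct numerical integration of the t
# density (oracle for stats::t.test).
p_by_integration <- function(t_stat, df) {
  tail <- stats::integrate(function(u) stats::dt(u, df),
                           lower = abs(t_stat), upper = Inf,
                           rel.tol = 1e-10)$value
  2 * tail
}
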