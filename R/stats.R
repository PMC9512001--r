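ZONES <- c("central_bearing", "tear_reservoir", "mid_peripheral", "edge_lift")
METHODS <- c("algorithm", "imagej")

#' Read a long-format measurement table
#'
#' Expects a CSV with columns `eye_id`, `observer` (1 or 2), `method`
#' (`algorithm` or `imagej`), `zone` (`central_bearing`, `tear_reservoir`,
#' `mid_peripheral`, `edge_lift`) and `width_mm`. Duplicate
#' (eye, observer, method, zone) keys and non-positive widths are rejected.
#'
#' @param path CSV path.
#' @return A data frame of class `measurement_table`.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "observer", "method", "zone", "width_mm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("measurement CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as_measurement_table(df[need])
}

#' Read a wide-format measurement table
#'
#' Accommodates spreadsheet layouts with one row per eye and one column per
#' zone x observer x method cell. The column mapping is a data frame with
#' columns `column`, `zone`, `observer`, `method`; by default columns are
#' expected to be named `<zone>_obs<observer>_<method>`, e.g.
#' `central_bearing_obs1_algorithm`.
#'
#' @param path CSV path; the first column (or an `eye_id` column) holds the
#'   eye identifier.
#' @param mapping Optional column-mapping data frame as described above.
#' @return A long data frame of class `measurement_table`.
#' @export
read_measurements_wide <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  id_col <- if ("eye_id" %in% names(df)) "eye_id" else names(df)[1L]
  if (is.null(mapping)) {
    grid <- expand.grid(zone = ZONES, observer = 1:2, method = METHODS,
                        stringsAsFactors = FALSE)
    mapping <- data.frame(
      column = sprintf("%s_obs%d_%s", grid$zone, grid$observer, grid$method),
      grid, stringsAsFactors = FALSE)
  }
  need <- c("column", "zone", "observer", "method")
  if (!all(need %in% names(mapping))) {
    stop("`mapping` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(mapping$column, names(df))
  if (length(absent)) {
    stop("wide table '", path, "' lacks mapped columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  long <- do.call(rbind, lapply(seq_len(nrow(mapping)), function(i) {
    data.frame(eye_id = df[[id_col]],
               observer = mapping$observer[i],
               method = mapping$method[i],
               zone = mapping$zone[i],
               width_mm = as.numeric(df[[mapping$column[i]]]),
               stringsAsFactors = FALSE)
  }))
  as_measurement_table(long)
}

as_measurement_table <- function(df) {
  df$observer <- as.integer(df$observer)
  key <- interaction(df$eye_id, df$observer, df$method, df$zone, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate (eye, observer, method, zone) keys in measurement table",
         call. = FALSE)
  }
  if (any(!is.finite(df$width_mm)) || any(df$width_mm <= 0)) {
    stop("all widths must be positive and finite", call. = FALSE)
  }
  bad <- setdiff(unique(df$zone), ZONES)
  if (length(bad)) {
    stop("unknown zone label(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(ZONES, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Paired-agreement summary for two sets of measurements
#'
#' Computes, for measurements `a` and `b` paired by eye, the Bland-Altman
#' agreement statistics: differences `d = a - b`, their mean and SD
#' (`n - 1` denominator), the 95% limits of agreement
#' `mean(d) +/- 1.96 * sd(d)`, a two-sided paired t-test of zero mean
#' difference, the Pearson correlation of `a` and `b`, and per-group
#' mean, SD and 95% CI of the mean.
#'
#' If the differences have zero variance the t statistic is undefined and
#' reported as `NA`; if either group is constant the correlation is
#' undefined and reported as `NA` (with a `note` explaining why).
#'
#' @param a,b Numeric vectors of equal length `>= 3`, paired by eye.
#' @param labels Length-2 character labels for the two groups; differences
#'   are always `first - second`.
#' @return An object of class `agreement_summary`.
#' @export
paired_summary <- function(a, b, labels = c("a", "b")) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length (paired design)", call. = FALSE)
  }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 3L) {
    stop("at least 3 complete pairs are required, got ", n, call. = FALSE)
  }
  d <- a - b
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  note <- character(0)

  if (sd_diff > 0) {
    tt <- stats::t.test(a, b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p_value <- tt$p.value
  } else {
    t_stat <- NA_real_
    p_value <- NA_real_
    note <- c(note, "differences have zero variance; t undefined")
  }
  if (stats::sd(a) > 0 && stats::sd(b) > 0) {
    ct <- stats::cor.test(a, b)
    pearson_r <- unname(ct$estimate)
    r_p_value <- ct$p.value
  } else {
    pearson_r <- NA_real_
    r_p_value <- NA_real_
    note <- c(note, "a group is constant; Pearson r undefined")
  }

  group_stats <- function(x) {
    m <- mean(x)
    s <- stats::sd(x)
    half <- stats::qt(0.975, n - 1L) * s / sqrt(n)
    c(mean = m, sd = s, ci_low = m - half, ci_high = m + half)
  }

  structure(
    list(n = n,
         labels = labels,
         mean_diff = mean_diff,
         sd_diff = sd_diff,
         loa_low = mean_diff - 1.96 * sd_diff,
         loa_high = mean_diff + 1.96 * sd_diff,
         t_stat = t_stat, df = n - 1L, p_value = p_value,
         pearson_r = pearson_r, r_p_value = r_p_value,
         group_a = group_stats(a), group_b = group_stats(b),
         differences = d, means = (a + b) / 2,
         note = note),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> %s - %s, n = %d\n",
              x$labels[1L], x$labels[2L], x$n))
  cat(sprintf("  difference %.3f +/- %.3f mm, LoA [%.2f, %.2f]\n",
              x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  paired t(%d) = %s, p = %s; r = %s\n", x$df,
              if (is.na(x$t_stat)) "NA" else sprintf("%.2f", x$t_stat),
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 2),
              if (is.na(x$pearson_r)) "NA" else sprintf("%.2f", x$pearson_r)))
  if (length(x$note)) cat("  note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' Confidence intervals for the limits of agreement
#'
#' The default `approximate` mode uses the Bland-Altman large-sample
#' standard error `SE = sd * sqrt(1/n + z^2 / (2 * (n - 1)))` with
#' `z = 1.96`, and `CI = limit +/- t_{n-1} * SE`. The `exact` mode inverts
#' the noncentral-t pivot for the quantile `mean + z * sd`: with
#' `T = sqrt(n) * (mean(d) - (mu + z * sigma)) / sd(d)` distributed as
#' noncentral t with `n - 1` df and noncentrality `-z * sqrt(n)`, the CI is
#' `mean - sd/sqrt(n) * q` over the appropriate noncentral-t quantiles.
#'
#' @param summary An `agreement_summary`.
#' @param level Confidence level (default 0.95).
#' @param mode `"approximate"` (default) or `"exact"`.
#' @return A list with `loa_low` and `loa_high`, each `c(lower, upper)`,
#'   plus `level` and `mode`.
#' @export
loa_confidence_interval <- function(summary, level = 0.95,
                                    mode = c("approximate", "exact")) {
  stopifnot(inherits(summary, "agreement_summary"))
  mode <- match.arg(mode)
  if (!(level > 0 && level < 1)) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  n <- summary$n
  s <- summary$sd_diff
  m <- summary$mean_diff
  alpha <- 1 - level
  z <- 1.96                                   # the LoA multiplier itself

  ci_one <- function(zk) {
    limit <- m + zk * s
    if (mode == "approximate") {
      se <- s * sqrt(1 / n + z^2 / (2 * (n - 1)))
      half <- stats::qt(1 - alpha / 2, n - 1L) * se
      c(lower = limit - half, upper = limit + half)
    } else {
      # qt warns that tail precision with large ncp is ~1e-8; ample here
      q <- suppressWarnings(stats::qt(c(1 - alpha / 2, alpha / 2),
                                      df = n - 1L, ncp = -zk * sqrt(n)))
      c(lower = m - s / sqrt(n) * q[1L],
        upper = m - s / sqrt(n) * q[2L])
    }
  }
  list(loa_low = ci_one(-z), loa_high = ci_one(z), level = level, mode = mode)
}

summary_to_row <- function(s, ci) {
  data.frame(
    n = s$n,
    mean_a = unname(s$group_a["mean"]), sd_a = unname(s$group_a["sd"]),
    mean_b = unname(s$group_b["mean"]), sd_b = unname(s$group_b["sd"]),
    mean_diff = s$mean_diff, sd_diff = s$sd_diff,
    loa_low = s$loa_low, loa_high = s$loa_high,
    loa_low_ci_lower = unname(ci$loa_low["lower"]),
    loa_low_ci_upper = unname(ci$loa_low["upper"]),
    loa_high_ci_lower = unname(ci$loa_high["lower"]),
    loa_high_ci_upper = unname(ci$loa_high["upper"]),
    t_stat = s$t_stat, df = s$df, p_value = s$p_value,
    pearson_r = s$pearson_r, r_p_value = s$r_p_value,
    stringsAsFactors = FALSE)
}

pick <- function(table, zone, method = NULL, observer = NULL) {
  sel <- table$zone == zone
  if (!is.null(method)) sel <- sel & table$method == method
  if (!is.null(observer)) sel <- sel & table$observer == observer
  table[sel, , drop = FALSE]
}

pair_by_eye <- function(x, y, what) {
  common <- intersect(x$eye_id, y$eye_id)
  missing <- setdiff(union(x$eye_id, y$eye_id), common)
  if (length(missing)) {
    stop("incomplete pairs for ", what, "; missing eyes: ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  }
  common <- sort(common)
  list(a = x$width_mm[match(common, x$eye_id)],
       b = y$width_mm[match(common, y$eye_id)])
}

#' Per-zone agreement report
#'
#' Reproduces the structure of the study-style agreement tables from a long
#' measurement table. Two comparisons are supported:
#'
#' * `"inter_observer"`: observer 1 vs observer 2, separately for each
#'   method and zone (differences are observer 1 - observer 2);
#' * `"inter_method"`: algorithm vs manual caliper (ImageJ-style)
#'   measurements, per zone, where each eye's value for a method is the mean
#'   of the two observers (differences are algorithm - imagej).
#'
#' @param table A `measurement_table`.
#' @param comparison `"inter_observer"` or `"inter_method"`.
#' @param ci_mode CI mode for the LoA, passed to
#'   [loa_confidence_interval()].
#' @return A data frame with one row per zone (and per method for the
#'   inter-observer comparison): group means/SDs, mean and SD of the
#'   differences, LoA with CIs, paired t, and Pearson r. The underlying
#'   `agreement_summary` objects are attached as attribute `"summaries"`.
#' @export
agreement_report <- function(table,
                             comparison = c("inter_observer", "inter_method"),
                             ci_mode = c("approximate", "exact")) {
  stopifnot(inherits(table, "measurement_table"))
  comparison <- match.arg(comparison)
  ci_mode <- match.arg(ci_mode)
  zones <- intersect(ZONES, unique(table$zone))
  rows <- list()
  summaries <- list()

  if (comparison == "inter_observer") {
    for (method in intersect(METHODS, unique(table$method))) {
      for (zone in zones) {
        o1 <- pick(table, zone, method = method, observer = 1L)
        o2 <- pick(table, zone, method = method, observer = 2L)
        pr <- pair_by_eye(o1, o2, paste(method, zone, "observer comparison"))
        s <- paired_summary(pr$a, pr$b,
                            labels = c("observer 1", "observer 2"))
        ci <- loa_confidence_interval(s, mode = ci_mode)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(zone = zone, method = method,
                           stringsAsFactors = FALSE),
                summary_to_row(s, ci))
        summaries[[paste(method, zone, sep = ".")]] <- s
      }
    }
  } else {
    for (zone in zones) {
      per_method <- lapply(METHODS, function(method) {
        sub <- pick(table, zone, method = method)
        if (!nrow(sub)) {
          stop("no '", method, "' measurements for zone ", zone,
               call. = FALSE)
        }
        agg <- stats::aggregate(width_mm ~ eye_id, data = sub, FUN = mean)
        agg
      })
      pr <- pair_by_eye(per_method[[1L]], per_method[[2L]],
                        paste(zone, "method comparison"))
      s <- paired_summary(pr$a, pr$b, labels = METHODS)
      ci <- loa_confidence_interval(s, mode = ci_mode)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(zone = zone, method = "algorithm - imagej",
                         stringsAsFactors = FALSE),
              summary_to_row(s, ci))
      summaries[[zone]] <- s
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summaries") <- summaries
  out
}
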