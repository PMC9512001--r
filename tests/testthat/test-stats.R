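test_that("paired summary reproduces hand-computed small cases", {
  a <- c(1, 2, 3, 4)
  b <- c(1, 2, 3, 5)
  s <- paired_summary(a, b)
  expect_equal(s$mean_diff, -0.25)
  expect_equal(s$sd_diff, 0.5)
  expect_equal(s$t_stat, -1)
  expect_equal(s$df, 3L)
  expect_equal(s$p_value, 0.3910022, tolerance = 1e-6)   # 2 * P(T3 < -1)
  expect_equal(s$loa_low, -0.25 - 1.96 * 0.5)
  expect_equal(s$loa_high, -0.25 + 1.96 * 0.5)

  expect_error(paired_summary(1:2, 2:3), "at least 3")
  expect_error(paired_summary(1:5, 1:4), "equal length")
})

test_that("t and p agree with numerical integration of the t density", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    a <- rnorm(n, mean = runif(1, -1, 1))
    b <- rnorm(n)
    s <- paired_summary(a, b)
    d <- a - b
    t_direct <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(s$t_stat, t_direct, tolerance = 1e-10)
    expect_equal(s$p_value, p_by_integration(t_direct, n - 1),
                 tolerance = 1e-6)
  }
})

test_that("identical and degenerate inputs are handled by convention", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  s <- paired_summary(x, x)
  expect_equal(s$mean_diff, 0)
  expect_equal(s$sd_diff, 0)
  expect_equal(s$loa_low, 0)
  expect_equal(s$loa_high, 0)
  expect_true(is.na(s$t_stat))
  expect_match(paste(s$note, collapse = " "), "zero variance")

  s2 <- paired_summary(rep(2, 5), c(1, 2, 1.5, 2.5, 2))
  expect_true(is.na(s2$pearson_r))
  expect_match(paste(s2$note, collapse = " "), "constant")
  expect_false(is.na(s2$t_stat))
})

test_that("swapping groups negates differences but keeps p and r", {
  set.seed(31)
  a <- rnorm(15, 2)
  b <- rnorm(15, 2.2)
  s_ab <- paired_summary(a, b)
  s_ba <- paired_summary(b, a)
  expect_equal(s_ba$mean_diff, -s_ab$mean_diff)
  expect_equal(s_ba$t_stat, -s_ab$t_stat)
  expect_equal(s_ba$loa_low, -s_ab$loa_high)
  expect_equal(s_ba$loa_high, -s_ab$loa_low)
  expect_equal(s_ba$p_value, s_ab$p_value)
  expect_equal(s_ba$pearson_r, s_ab$pearson_r)
})

test_that("rescaling the units scales the mm statistics but not t, p, r", {
  set.seed(32)
  a <- rnorm(12, 4, 0.5)
  b <- rnorm(12, 4, 0.5)
  s1 <- paired_summary(a, b)
  s10 <- paired_summary(10 * a, 10 * b)
  expect_equal(s10$mean_diff, 10 * s1$mean_diff)
  expect_equal(s10$sd_diff, 10 * s1$sd_diff)
  expect_equal(s10$loa_high, 10 * s1$loa_high)
  expect_equal(s10$t_stat, s1$t_stat)
  expect_equal(s10$p_value, s1$p_value)
  expect_equal(s10$pearson_r, s1$pearson_r)
})

test_that("limits of agreement reproduce the published summaries", {
  # between-software central bearing: mean -0.07, SD 0.28, n 26
  s <- paired_summary(exact_moments(-0.07, 0.28, 26), rep(0, 26))
  expect_equal(round(s$loa_low, 2), -0.62)

  # inter-observer central bearing: mean -0.16, SD 0.37, n 26
  s2 <- paired_summary(exact_moments(-0.16, 0.37, 26), rep(0, 26))
  expect_equal(round(s2$loa_high, 2), 0.57)
  ci <- loa_confidence_interval(s2)
  expect_lt(abs(ci$loa_high[["lower"]] - 0.31), 0.01)
  expect_lt(abs(ci$loa_high[["upper"]] - 0.83), 0.01)
})

test_that("LoA confidence intervals behave across modes and levels", {
  s <- paired_summary(exact_moments(-0.16, 0.37, 26), rep(0, 26))
  approx95 <- loa_confidence_interval(s, 0.95, "approximate")
  approx99 <- loa_confidence_interval(s, 0.99, "approximate")
  wid <- function(ci) ci[["upper"]] - ci[["lower"]]
  expect_gt(wid(approx99$loa_high), wid(approx95$loa_high))
  expect_gt(wid(approx99$loa_low), wid(approx95$loa_low))

  exact95 <- loa_confidence_interval(s, 0.95, "exact")
  # both intervals must cover the estimated limit itself
  expect_lt(exact95$loa_high[["lower"]], s$loa_high)
  expect_gt(exact95$loa_high[["upper"]], s$loa_high)
  expect_lt(exact95$loa_low[["lower"]], s$loa_low)
  expect_gt(exact95$loa_low[["upper"]], s$loa_low)
  # exact noncentral-t intervals are wider than the large-sample ones here
  expect_gt(wid(exact95$loa_high), 0)

  s0 <- paired_summary(rep(1, 5), rep(1, 5))
  ci0 <- loa_confidence_interval(s0)
  expect_equal(unname(ci0$loa_high), c(0, 0))

  expect_error(loa_confidence_interval(s, level = 1.5), "level")
})

test_that("measurement tables round-trip in long and wide layouts", {
  tab <- sim_table(n_eyes = 8, seed = 2)
  long_path <- tempfile(fileext = ".csv")
  utils::write.csv(tab, long_path, row.names = FALSE)
  back <- read_measurements(long_path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(sort(unique(back$zone)),
               sort(c("central_bearing", "tear_reservoir",
                      "mid_peripheral", "edge_lift")))

  # wide layout: one row per eye, one column per zone x observer x method
  wide <- reshape(transform(tab,
                            col = sprintf("%s_obs%d_%s", zone, observer,
                                          method))[, c("eye_id", "col",
                                                       "width_mm")],
                  idvar = "eye_id", timevar = "col", direction = "wide")
  names(wide) <- sub("^width_mm\\.", "", names(wide))
  wide_path <- tempfile(fileext = ".csv")
  utils::write.csv(wide, wide_path, row.names = FALSE)
  back_wide <- read_measurements_wide(wide_path)
  m1 <- back[order(back$eye_id, back$observer, back$method, back$zone), ]
  m2 <- back_wide[order(back_wide$eye_id, back_wide$observer,
                        back_wide$method, back_wide$zone), ]
  expect_equal(m1$width_mm, m2$width_mm)

  dup <- rbind(tab, tab[1, ])
  dup_path <- tempfile(fileext = ".csv")
  utils::write.csv(dup, dup_path, row.names = FALSE)
  expect_error(read_measurements(dup_path), "duplicate")
})

test_that("agreement report flags a pure method offset", {
  tab <- sim_table(n_eyes = 10, seed = 3, method_offset = 0.1,
                   constant = TRUE)
  rep_ <- agreement_report(tab, "inter_method")
  expect_equal(nrow(rep_), 4L)
  expect_equal(rep_$mean_diff, rep(-0.1, 4))
  expect_equal(rep_$sd_diff, rep(0, 4))
  expect_true(all(is.na(rep_$t_stat)))
  expect_true(all(is.na(rep_$pearson_r)))    # constant groups: r undefined
})

test_that("agreement report recovers a seeded mean difference", {
  set.seed(77)
  n <- 26
  eye <- sprintf("eye%02d", 1:n)
  base <- 4 + rnorm(n, sd = 0.5)
  diffs <- rnorm(n, mean = 0.05, sd = 0.2)
  tab <- okfluor:::as_measurement_table(rbind(
    data.frame(eye_id = eye, observer = 1, method = "algorithm",
               zone = "central_bearing", width_mm = base + diffs),
    data.frame(eye_id = eye, observer = 1, method = "imagej",
               zone = "central_bearing", width_mm = base)))
  rep_ <- agreement_report(tab, "inter_method")
  se <- rep_$sd_diff / sqrt(n)
  expect_lt(abs(rep_$mean_diff - 0.05), 3 * se)
})

test_that("inter-observer report runs per method and inter-method averages observers", {
  tab <- sim_table(n_eyes = 12, seed = 9)
  io <- agreement_report(tab, "inter_observer")
  expect_equal(nrow(io), 8L)                # 4 zones x 2 methods
  expect_setequal(unique(io$method), c("algorithm", "imagej"))

  im <- agreement_report(tab, "inter_method")
  expect_equal(nrow(im), 4L)
  # spot-check the observer-mean construction for one zone
  sub <- tab[tab$zone == "central_bearing", ]
  alg <- aggregate(width_mm ~ eye_id, sub[sub$method == "algorithm", ], mean)
  ij <- aggregate(width_mm ~ eye_id, sub[sub$method == "imagej", ], mean)
  expect_equal(im$mean_diff[im$zone == "central_bearing"],
               mean(alg$width_mm - ij$width_mm))

  # incomplete pairing is reported with the missing eyes
  broken <- tab[!(tab$eye_id == "eye01" & tab$observer == 2), ]
  class(broken) <- class(tab)
  expect_error(agreement_report(broken, "inter_observer"), "eye01")
})

test_that("bland-altman plot builds from a summary", {
  set.seed(4)
  s <- paired_summary(rnorm(20, 4, 0.4), rnorm(20, 4, 0.4))
  gp <- bland_altman_plot(s)
  expect_s3_class(gp, "ggplot")
})
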