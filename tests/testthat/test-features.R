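# The ten weekly mobility features and the five data subsets.

test_that("entropy matches direct summation and its uniform closed form", {
  expect_equal(mobility_entropy(1)$ENT, 0)
  expect_equal(mobility_entropy(1)$NENT, 0)
  e2 <- mobility_entropy(c(0.5, 0.5))
  expect_equal(e2$ENT, log(2), tolerance = 1e-12)
  expect_equal(e2$NENT, 1, tolerance = 1e-12)
  p <- c(0.5, 0.3, 0.2)
  expect_equal(mobility_entropy(p)$ENT, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(mobility_entropy(p)$ENT, 1.02965, tolerance = 1e-4)
  for (n in c(2, 5, 13)) {
    expect_equal(mobility_entropy(rep(1 / n, n))$ENT, log(n), tolerance = 1e-12)
  }
  expect_error(mobility_entropy(numeric(0)), "empty")
})

test_that("normalized entropy never exceeds 1 over random occupancies", {
  withr::with_seed(12, {
    vals <- replicate(1000, {
      n <- sample(2:20, 1)
      mobility_entropy(rexp(n))$NENT
    })
  })
  expect_lte(max(vals), 1)
  expect_gte(min(vals), 0)
})

test_that("location variance follows its closed form, floor and invariance", {
  expect_equal(location_variance(rep(1, 5), rep(2, 5)), log(1e-10))
  x <- c(0, 1, 2, 3)
  y <- c(0, 0, 0, 0)
  scale <- sqrt(1 / (var(x) + var(y)))
  expect_equal(location_variance(x * scale, y * scale), 0, tolerance = 1e-12)
  expect_equal(location_variance(x + 100, y - 50), location_variance(x, y))
  expect_true(is.na(location_variance(1, 1)))
})

test_that("total distance sums a closed path and skips gaps", {
  sq <- grid_fixture(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(total_distance(sq), 4)
  expect_equal(total_distance(grid_fixture(0, 0)), 0)
  dup <- grid_fixture(c(0, 1, 1, 0, 0, 0), c(0, 0, 1, 1, 0, 0))
  expect_equal(total_distance(dup), 4)
  gap <- grid_fixture(c(0, 1, NA, 5, 6), c(0, 0, NA, 0, 0))
  expect_equal(total_distance(gap), 2) # 0->1 and 5->6; the 1->5 jump spans a gap
})

test_that("Lomb-Scargle power equals the least-squares sinusoid-fit oracle", {
  withr::with_seed(9, {
    t_h <- sort(runif(100, 0, 24 * 7))
    y <- sin(2 * pi * t_h / 24) + 0.3 * rnorm(100)
  })
  freq <- seq(1 / 24.5, 1 / 23.5, length.out = 25)
  p <- lomb_scargle_power(t_h, y, freq)
  p0 <- ls_power_oracle(t_h, y, freq)
  expect_equal(p, p0, tolerance = 1e-9)
})

daily_pattern_week <- function(amp = 2, period_h = 24, base = 5, rot = 0) {
  n <- 7 * 288
  t_h <- (0:(n - 1)) / 12
  d <- base + amp * sin(2 * pi * t_h / period_h)
  g <- grid_fixture(d * cos(rot), d * sin(rot))
  g
}

test_that("a 24 h distance rhythm outscores a 12 h rhythm on DMD", {
  d24 <- diurnal_movement(daily_pattern_week(period_h = 24))$DMD
  d12 <- diurnal_movement(daily_pattern_week(period_h = 12))$DMD
  expect_gt(d24, d12)
})

test_that("DMD and the axis-sum DM are rotation invariant while DMN is
           direction sensitive", {
  g0 <- daily_pattern_week(rot = 0)
  g45 <- daily_pattern_week(rot = pi / 4)
  f0 <- diurnal_movement(g0)
  f45 <- diurnal_movement(g45)
  expect_equal(f45$DMD, f0$DMD, tolerance = 1e-9)
  # the band power is a quadratic form in the signal, so the lat+lon power
  # sum cannot change under rotation; the normalized-coordinate variant can
  expect_equal(f45$DM, f0$DM, tolerance = 1e-9)
  expect_gt(abs(f45$DMN - f0$DMN), 0.1)
})

test_that("scaling coordinates x10 shifts DM by ln(100), fixes DMN and DMD", {
  g <- daily_pattern_week()
  g10 <- g
  g10$x <- g$x * 10
  g10$y <- g$y * 10
  f <- diurnal_movement(g)
  f10 <- diurnal_movement(g10)
  expect_equal(f10$DM - f$DM, log(100), tolerance = 1e-9)
  expect_equal(f10$DMN, f$DMN, tolerance = 1e-9)
  expect_equal(f10$DMD, f$DMD, tolerance = 1e-9)
})

test_that("occupancy features count home, travel and cluster shares", {
  seg <- grid_fixture(c(rep(0, 216), rep(2, 72)), rep(0, 288))
  seg$transitioning <- FALSE
  clusters <- structure(list(K = 2L, centers = rbind(c(0, 0), c(2, 0)),
                             assignment = c(rep(1L, 216), rep(2L, 72)),
                             l = 0.4), class = "geomood_places")
  occ <- occupancy_features(seg, clusters)
  expect_equal(occ$HS, 75)
  expect_equal(occ$TT, 0)
  expect_equal(occ$NC, 2)
  # no center near the origin: an away-from-home week scores HS = 0
  far <- structure(list(K = 1L, centers = rbind(c(3, 0)),
                        assignment = rep(1L, 288), l = 0.4),
                   class = "geomood_places")
  expect_equal(occupancy_features(seg, far)$HS, 0)
})

test_that("home, other-cluster and transition shares sum to 100%", {
  coh <- generate_cohort(synthetic_config(n_participants = 1, weeks = 1,
                                          seed = 41, gap_rate_per_week = 0))
  g <- preprocess_trace(coh$traces)
  g <- infer_home(g)$grid
  seg <- segment_stationary(g)
  wk <- seg[week_start(seg$t) == MONDAY, ]
  obs <- wk[!is.na(wk$x), ]
  stat <- obs[!obs$transitioning, ]
  cl <- cluster_stationary(stat, seed = 2)
  occ <- occupancy_features(wk, cl)
  other <- 100 * sum(cl$assignment != which.min(rowSums(cl$centers^2))) /
    nrow(obs)
  expect_equal(occ$HS + other + occ$TT, 100, tolerance = 1e-9)
})

test_that("daily-exclusion rule matches the worked example and its limits", {
  d <- setNames(c(1, 1, 1, 1, 1, 1, 20),
                as.character(as.Date("2015-05-04") + 0:6))
  expect_equal(sd(d), 7.1813, tolerance = 1e-4)
  expect_equal(excluded_days(d, 1), names(d)[7])
  expect_equal(excluded_days(setNames(rep(3, 7), names(d)), 0), character(0))
  expect_equal(excluded_days(d, 1e6), character(0)) # alpha -> inf: base subset
  expect_equal(excluded_days(d[1], 1), character(0)) # < 2 recorded days
})

test_that("a full week at home yields the degenerate feature row", {
  g <- week_fixture(days_out = integer(0))
  seg <- segment_stationary(g)
  row <- geomood:::week_feature_row(seg, seed = 3)
  expect_equal(unname(row["HS_base"]), 100)
  expect_equal(unname(row["TT_base"]), 0)
  expect_equal(unname(row["NC_base"]), 1)
  expect_equal(unname(row["ENT_base"]), 0)
  expect_equal(unname(row["TD_base"]), 0)
  expect_equal(unname(row["LV_base"]), log(1e-10))
})

test_that("feature table has 50 canonical columns; identical weeks give
           identical rows; empty weekends propagate as missing", {
  g1 <- week_fixture(days_out = 1:3)
  g2 <- week_fixture(days_out = 1:3, start = MONDAY + 7 * 86400)
  tab <- extract_feature_table(dplyr::bind_rows(g1, g2), seed = 5)
  expect_equal(nrow(tab), 2)
  expect_equal(setdiff(names(tab), c("participant", "week_start")),
               feature_columns())
  expect_equal(as.numeric(tab[1, feature_columns()]),
               as.numeric(tab[2, feature_columns()]))
  # weekday-only data: weekend-subset features are missing
  wd_only <- week_fixture(days_out = 1:5)
  we <- as.integer(format(wd_only$t, "%u")) >= 6
  wd_only$x[we] <- NA
  wd_only$y[we] <- NA
  tab2 <- extract_feature_table(wd_only, seed = 5)
  expect_true(all(is.na(as.numeric(tab2[1, feature_columns(subsets = "we")]))))
  expect_false(anyNA(as.numeric(tab2[1, feature_columns(subsets = "base")])))
})

test_that("the median subset of identical constituents equals them and the
           optimized subset responds to alpha", {
  g <- week_fixture(days_out = integer(0)) # identical days
  seg <- segment_stationary(g)
  row <- geomood:::week_feature_row(seg, seed = 3)
  expect_equal(unname(row["HS_med"]), unname(row["HS_base"]))
  expect_equal(unname(row["NC_med"]), unname(row["NC_base"]))
  # one far-travel day: alpha = 1 excludes it, so opt-LV drops below base-LV
  far <- week_fixture(away = c(30, 0), days_out = 4)
  segf <- segment_stationary(far)
  rowf <- geomood:::week_feature_row(segf, seed = 3, alpha = 1)
  expect_lt(unname(rowf["LV_opt"]), unname(rowf["LV_base"]))
})

test_that("alpha optimization honors ties, degenerate labels and the grid", {
  withr::with_seed(5, {
    n <- 40
    weeks <- tibble::tibble(
      participant = rep(c("A", "B"), each = n / 2),
      week_start = rep(MONDAY + (0:(n / 2 - 1)) * 7 * 86400, 2)
    )
    labels <- dplyr::mutate(weeks, depressed = rep(c(TRUE, FALSE), n / 2))
    grid_a <- c(0, 0.5, 1)
    # the feature is identical across alphas and independent of the label,
    # so every alpha ties and the smallest must win
    vals <- dplyr::mutate(weeks, LV_opt = rnorm(n))
    oba <- tidyr::crossing(weeks, alpha = grid_a) |>
      dplyr::left_join(vals, by = c("participant", "week_start"))
  })
  a <- optimize_alpha(oba, labels, "LV", grid = grid_a)
  expect_equal(a, grid_a[1])
  expect_equal(optimize_alpha(oba, labels, "LV", grid = 0.75), 0.75)
  labels_one <- dplyr::mutate(labels, depressed = TRUE)
  expect_warning(mid <- optimize_alpha(oba, labels_one, "LV", grid = grid_a),
                 "degenerate")
  expect_equal(mid, 0.5)
})

test_that("alpha optimization keeps excluding a far-day outlier that makes
           depressed weeks mimic well weeks", {
  # well weeks: regular 40 km commute on 5 days (never excluded: the
  # commute is the norm); depressed weeks: home-bound except one 40 km
  # outlier day. Without exclusion (large alpha) both classes show large
  # LV; with the outlier excluded the classes separate.
  weeks <- purrr::map_dfr(1:10, function(i) {
    dep <- i %% 2 == 1
    g <- week_fixture(away = c(40, 0), days_out = if (dep) 4 else 1:5,
                      start = MONDAY + (i - 1) * 7 * 86400)
    g$participant <- paste0("P", (i - 1) %% 2 + 1)
    g
  })
  tab <- extract_feature_table(weeks, seed = 9, alpha_grid = c(0.5, 3))
  oba <- attr(tab, "opt_by_alpha")
  labels <- dplyr::distinct(tab[c("participant", "week_start")]) |>
    dplyr::mutate(depressed = .data$participant == "P1")
  a <- optimize_alpha(oba, labels, "LV", grid = c(0.5, 3))
  expect_equal(a, 0.5) # the alpha that still excludes the outlier day
})
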