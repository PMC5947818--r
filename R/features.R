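## The ten weekly mobility features (Table of features: ENT, NENT, LV, HS,
## TT, TD, NC, DM, DMN, DMD) computed over five data subsets (base, weekday,
## weekend, median, optimized daily exclusion), 50 values per labeled week.
## Natural logarithms throughout.

PSD_FLOOR <- 1e-10
LV_FLOOR <- 1e-10

#' Entropy and normalized entropy of cluster occupancy
#'
#' `ENT = -sum(p_i * log(p_i))` over the proportions of (stationary) time
#' spent in each place cluster, with `0 log 0 = 0`; `NENT = ENT / log(N)`
#' scales it to \[0, 1\] (defined as 0 for a single cluster).
#'
#' @param p Nonnegative occupancy weights (renormalized to sum to 1).
#' @return List with `ENT` (nats) and `NENT`.
#' @examples
#' mobility_entropy(c(0.5, 0.5)) # ENT = log 2, NENT = 1
#' @export
mobility_entropy <- function(p) {
  if (length(p) == 0) stop("empty occupancy vector", call. = FALSE)
  if (any(p < 0)) stop("occupancy weights must be nonnegative", call. = FALSE)
  p <- p / sum(p)
  nz <- p > 0
  ent <- -sum(p[nz] * log(p[nz]))
  n <- length(p)
  # clamp at the theoretical bound: the sum can overshoot log(n) by an ulp
  list(ENT = ent, NENT = if (n >= 2) min(1, ent / log(n)) else 0)
}

#' Location variance
#'
#' `LV = log(var(y) + var(x))` over the week's non-missing grid samples,
#' floored at 1e-10 km^2 so a constant trace stays finite.
#'
#' @param x,y Coordinates (km).
#' @return LV (log km^2), or NA for fewer than 2 samples.
#' @export
location_variance <- function(x, y) {
  if (length(x) < 2) return(NA_real_)
  log(max(var(x) + var(y), LV_FLOOR))
}

#' Total distance travelled
#'
#' Sum of Euclidean distances between consecutive non-missing grid samples;
#' segments spanning a missing run (non-adjacent grid slots) are skipped.
#'
#' @param grid Grid trace rows (columns `t`, `x`, `y`).
#' @return TD in km; NA with fewer than 2 non-missing samples, 0 for one...
#'   a single pair of coincident samples gives 0.
#' @export
total_distance <- function(grid) {
  g <- grid[!is.na(grid$x), ]
  if (nrow(g) == 0) return(NA_real_)
  if (nrow(g) == 1) return(0)
  adj <- diff(as.numeric(g$t)) <= GRID_STEP_S + 1e-6
  sum(sqrt(diff(g$x)^2 + diff(g$y)^2)[adj])
}

#' Lomb-Scargle periodogram power at given frequencies
#'
#' Classic Lomb formula with the phase offset tau, evaluated on a
#' mean-centred, possibly unevenly sampled series. The periodogram is left
#' unnormalized (no division by the series variance) so that, as intended
#' for the diurnal-movement features, the power scales with the magnitude
#' of the signal: for a pure sinusoid of amplitude A sampled at n points
#' the peak power approaches n A^2 / 4.
#'
#' @param t Sample times (hours).
#' @param y Signal values.
#' @param freq Frequencies (cycles per hour).
#' @return Power at each frequency.
#' @export
lomb_scargle_power <- function(t, y, freq) {
  yc <- y - mean(y)
  vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 * (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2))
  }, numeric(1))
}

#' Diurnal-movement spectral features
#'
#' Mean Lomb-Scargle power in the circadian wavelength band (23.5-24.5 h by
#' default, `n_freq` frequencies evenly spaced in frequency) of three
#' signals derived from the week's non-missing samples: raw km coordinates
#' (`DM = log(E_y + E_x)`), per-axis standardized coordinates (`DMN`), and
#' the standardized Euclidean distance from home (`DMD`). Band powers are
#' floored at 1e-10 before the log so constant signals stay finite.
#'
#' @param grid Grid trace rows, recentered so home is the origin.
#' @param band_h Wavelength band, hours.
#' @param n_freq Frequency-grid resolution in the band.
#' @return List with `DM`, `DMN`, `DMD`.
#' @export
diurnal_movement <- function(grid, band_h = c(23.5, 24.5), n_freq = 25) {
  g <- grid[!is.na(grid$x), ]
  if (nrow(g) < 3)
    return(list(DM = NA_real_, DMN = NA_real_, DMD = NA_real_))
  t_h <- (as.numeric(g$t) - as.numeric(g$t[1])) / 3600
  freq <- seq(1 / band_h[2], 1 / band_h[1], length.out = n_freq)
  band_e <- function(y) {
    if (sd(y) == 0) return(0)
    mean(lomb_scargle_power(t_h, y, freq))
  }
  stdz <- function(y) if (sd(y) == 0) rep(0, length(y)) else (y - mean(y)) / sd(y)
  dist_home <- sqrt(g$x^2 + g$y^2)
  list(
    DM = log(max(band_e(g$y) + band_e(g$x), PSD_FLOOR)),
    DMN = log(max(band_e(stdz(g$y)) + band_e(stdz(g$x)), PSD_FLOOR)),
    DMD = log(max(band_e(stdz(dist_home)), PSD_FLOOR))
  )
}

#' Occupancy features: home stay, transition time, cluster count
#'
#' `HS` is the percentage of non-missing grid samples assigned to the home
#' cluster (the cluster whose center lies nearest the origin, required
#' within `clusters$l` of it; a week spent wholly away from home scores 0).
#' `TT` is the percentage of non-missing samples flagged transitioning.
#' `NC` is the number of clusters.
#'
#' @param segmented Grid rows with a `transitioning` column (the week
#'   subset being measured).
#' @param clusters `geomood_places` fit of the subset's stationary samples.
#' @return List with `HS`, `TT` (percent) and `NC`.
#' @export
occupancy_features <- function(segmented, clusters) {
  obs <- !is.na(segmented$x)
  n_obs <- sum(obs)
  if (n_obs == 0) return(list(HS = NA_real_, TT = NA_real_, NC = NA_real_))
  tt <- 100 * sum(segmented$transitioning[obs]) / n_obs
  if (is.null(clusters)) return(list(HS = 0, TT = tt, NC = NA_real_))
  cd <- sqrt(clusters$centers[, 1]^2 + clusters$centers[, 2]^2)
  hc <- which.min(cd)
  hs <- if (cd[hc] <= clusters$l) {
    100 * sum(clusters$assignment == hc) / n_obs
  } else 0
  list(HS = hs, TT = tt, NC = as.numeric(clusters$K))
}

## All ten features on one (already subset) set of grid rows.
## `segmented` must carry the transitioning flag computed on the full week.
subset_features <- function(segmented, l = 0.4, seed = 1L,
                            band_h = c(23.5, 24.5), n_freq = 25) {
  out <- setNames(rep(NA_real_, length(FEATURE_NAMES)), FEATURE_NAMES)
  obs <- segmented[!is.na(segmented$x), ]
  if (nrow(obs) == 0) return(out)
  stat <- obs[!obs$transitioning, ]
  cl <- NULL
  if (nrow(stat) > 0) {
    cl <- cluster_stationary(stat, l = l, seed = seed)
    ent <- mobility_entropy(tabulate(cl$assignment, nbins = cl$K))
    out["ENT"] <- ent$ENT
    out["NENT"] <- ent$NENT
  }
  occ <- occupancy_features(segmented, cl)
  out["HS"] <- occ$HS
  out["TT"] <- occ$TT
  out["NC"] <- occ$NC
  out["LV"] <- location_variance(obs$x, obs$y)
  out["TD"] <- total_distance(segmented)
  dm <- diurnal_movement(segmented, band_h = band_h, n_freq = n_freq)
  out["DM"] <- dm$DM
  out["DMN"] <- dm$DMN
  out["DMD"] <- dm$DMD
  out
}

#' Per-day maximum distance from home
#'
#' @param week_grid One week of grid rows (home at origin).
#' @param tz Timezone defining day boundaries.
#' @return Named numeric vector (by local date) of daily maxima over
#'   non-missing samples; days without samples are absent.
#' @export
day_max_home_distance <- function(week_grid, tz = "UTC") {
  obs <- week_grid[!is.na(week_grid$x), ]
  if (nrow(obs) == 0) return(setNames(numeric(0), character(0)))
  d <- sqrt(obs$x^2 + obs$y^2)
  day <- as.character(local_date(obs$t, tz))
  tapply(d, day, max)
}

#' Days excluded by the optimized daily-exclusion rule
#'
#' A day is excluded when its maximum distance from home exceeds
#' `median(D) + alpha * sd(D)` over the week's recorded days. With fewer
#' than two recorded days nothing is excluded.
#'
#' @param d Named vector from [day_max_home_distance()].
#' @param alpha Exclusion multiplier.
#' @return Character vector of excluded day names.
#' @export
excluded_days <- function(d, alpha) {
  if (length(d) < 2) return(character(0))
  names(d)[d > median(d) + alpha * sd(d)]
}

## Compute the full 50-value feature row for one week.
## Returns the named vector; if alpha_grid is given, attaches an
## "opt_by_alpha" tibble with the ten optimized-subset features per alpha.
week_feature_row <- function(week_grid, tz = "UTC", l = 0.4, seed = 1L,
                             alpha = 1, alpha_grid = NULL,
                             band_h = c(23.5, 24.5), n_freq = 25) {
  wd <- local_wday(week_grid$t, tz)
  day <- as.character(local_date(week_grid$t, tz))
  feats <- function(rows, s_off) {
    subset_features(week_grid[rows, ], l = l, seed = child_seed(seed, s_off),
                    band_h = band_h, n_freq = n_freq)
  }
  base <- feats(rep(TRUE, nrow(week_grid)), 1)
  f_wd <- feats(wd <= 5, 2)
  f_we <- feats(wd >= 6, 3)
  days <- sort(unique(day))
  lodo <- lapply(seq_along(days), function(i) feats(day != days[i], 3 + i))
  med_mat <- rbind(base, f_wd, f_we, do.call(rbind, lodo))
  f_med <- apply(med_mat, 2, median, na.rm = TRUE)
  f_med[is.nan(f_med)] <- NA_real_
  d_i <- day_max_home_distance(week_grid, tz)
  opt_for_alpha <- function(a) {
    ex <- excluded_days(d_i, a)
    feats(!(day %in% ex), 11)
  }
  # distinct exclusion sets over the alpha grid share one evaluation
  opt_cache <- list()
  opt_row <- function(a) {
    key <- paste(sort(excluded_days(d_i, a)), collapse = "|")
    if (is.null(opt_cache[[paste0("k", key)]]))
      opt_cache[[paste0("k", key)]] <<- opt_for_alpha(a)
    opt_cache[[paste0("k", key)]]
  }
  f_opt <- opt_row(alpha)
  row <- c(setNames(base, paste0(FEATURE_NAMES, "_base")),
           setNames(f_wd, paste0(FEATURE_NAMES, "_wd")),
           setNames(f_we, paste0(FEATURE_NAMES, "_we")),
           setNames(f_med, paste0(FEATURE_NAMES, "_med")),
           setNames(f_opt, paste0(FEATURE_NAMES, "_opt")))
  if (!is.null(alpha_grid)) {
    by_alpha <- purrr::map_dfr(alpha_grid, function(a) {
      v <- opt_row(a)
      tibble::as_tibble(as.list(setNames(v, paste0(FEATURE_NAMES, "_opt")))) |>
        dplyr::mutate(alpha = a, .before = 1)
    })
    attr(row, "opt_by_alpha") <- by_alpha
  }
  row
}

## Does a week hold enough data to compute features?
week_sufficient <- function(week_grid, tz = "UTC",
                            min_day_coverage = 0.5, min_days = 4) {
  obs <- !is.na(week_grid$x)
  if (!any(obs)) return(FALSE)
  day <- as.character(local_date(week_grid$t, tz))
  per_day <- tapply(obs, day, mean)
  sum(per_day >= min_day_coverage, na.rm = TRUE) >= min_days
}

#' Extract the weekly feature table for a cohort
#'
#' Splits each participant's preprocessed, home-recentered grid trace into
#' ISO calendar weeks (Monday 00:00 local), applies the stationary
#' segmentation, drops weeks with insufficient data (fewer than `min_days`
#' days at `min_day_coverage` grid coverage), and computes the 50
#' feature-by-subset values per retained week.
#'
#' @param grids Combined grid-trace tibble (columns `participant`, `t`,
#'   `x`, `y`), already recentered so each participant's home is (0, 0).
#' @param tz Timezone for clock-time rules.
#' @param d Stationary speed threshold (km/h).
#' @param l Cluster separation threshold (km).
#' @param seed Seed for cluster initialization.
#' @param alpha Daily-exclusion multiplier used for the `_opt` columns.
#' @param alpha_grid Optional grid of alpha values; when given, the
#'   returned table carries an `opt_by_alpha` attribute with the
#'   optimized-subset features per alpha (input to [optimize_alpha()]).
#' @param min_day_coverage,min_days Week sufficiency rule.
#' @param band_h,n_freq Spectral band configuration for DM/DMN/DMD.
#' @return Tibble with `participant`, `week_start` and 50 feature columns;
#'   attribute `dropped` lists insufficient weeks.
#' @export
extract_feature_table <- function(grids, tz = "UTC", d = 1.5, l = 0.4,
                                  seed = 1L, alpha = 1, alpha_grid = NULL,
                                  min_day_coverage = 0.5, min_days = 4,
                                  band_h = c(23.5, 24.5), n_freq = 25) {
  dropped <- list()
  by_alpha <- list()
  rows <- list()
  pids <- unique(grids$participant)
  for (pi in seq_along(pids)) {
    g <- segment_stationary(grids[grids$participant == pids[pi], ], d = d)
    ws <- week_start(g$t, tz)
    for (w in unique(ws)) {
      wg <- g[ws == w, ]
      w_t <- as.POSIXct(w, origin = "1970-01-01", tz = "UTC")
      if (!week_sufficient(wg, tz, min_day_coverage, min_days)) {
        dropped[[length(dropped) + 1]] <-
          tibble::tibble(participant = pids[pi], week_start = w_t)
        next
      }
      row <- week_feature_row(wg, tz = tz, l = l,
                              seed = child_seed(seed, pi * 1000 + length(rows)),
                              alpha = alpha, alpha_grid = alpha_grid,
                              band_h = band_h, n_freq = n_freq)
      rows[[length(rows) + 1]] <-
        dplyr::bind_cols(tibble::tibble(participant = pids[pi], week_start = w_t),
                         tibble::as_tibble(as.list(row)))
      if (!is.null(alpha_grid)) {
        by_alpha[[length(by_alpha) + 1]] <-
          dplyr::bind_cols(tibble::tibble(participant = pids[pi], week_start = w_t),
                           attr(row, "opt_by_alpha"))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "dropped") <- dplyr::bind_rows(dropped)
  if (!is.null(alpha_grid)) attr(out, "opt_by_alpha") <- dplyr::bind_rows(by_alpha)
  out
}

#' Optimize the daily-exclusion multiplier alpha for one feature
#'
#' Grid search maximizing the training-set accuracy of a single-feature
#' logistic-regression classifier of the depressed label, as used to tune
#' the optimized daily-exclusion subset. Ties return the smallest alpha.
#' Intended to be run on training folds only.
#'
#' @param opt_by_alpha The `opt_by_alpha` attribute of
#'   [extract_feature_table()], restricted to training weeks.
#' @param labels Tibble with `participant`, `week_start`, `depressed`.
#' @param feature Feature abbreviation (e.g. `"LV"`).
#' @param grid Alpha grid (default `seq(0, 3, by = 0.25)`).
#' @return The selected alpha.
#' @export
optimize_alpha <- function(opt_by_alpha, labels, feature,
                           grid = seq(0, 3, by = 0.25)) {
  col <- paste0(feature, "_opt")
  df <- dplyr::inner_join(opt_by_alpha, labels,
                          by = c("participant", "week_start"))
  if (length(unique(df$depressed)) < 2) {
    warning("degenerate labels: returning midpoint alpha", call. = FALSE)
    return(grid[ceiling(length(grid) / 2)])
  }
  acc <- vapply(grid, function(a) {
    da <- df[abs(df$alpha - a) < 1e-9, c(col, "depressed")]
    da <- da[complete.cases(da), ]
    if (nrow(da) < 4 || length(unique(da$depressed)) < 2) return(NA_real_)
    fit <- suppressWarnings(
      stats::glm(depressed ~ ., data = da, family = stats::binomial())
    )
    mean((stats::fitted(fit) >= 0.5) == da$depressed)
  }, numeric(1))
  if (all(is.na(acc))) return(grid[ceiling(length(grid) / 2)])
  grid[which.max(acc)] # which.max takes the first (smallest alpha) on ties
}
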