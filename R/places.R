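## Stationary/transition segmentation, place clustering and home inference.
##
## Segmentation thresholds three 10-min moving averages of the instantaneous
## speed (centred, backward, forward) at d = 1.5 km/h; stationary samples
## are clustered with K-means++ where K grows from 1 while all cluster
## centers stay at least l = 0.4 km apart; home is the modal overnight
## (02:00-07:00) location, and traces are recentered so home is the origin.

#' Split grid samples into stationary and transitioning points
#'
#' For every non-missing grid sample, three moving averages of the
#' instantaneous (per-interval) speed are computed: centred over
#' \[t - 5 min, t + 5 min\], backward over \[t - 10 min, t\] and forward
#' over \[t, t + 10 min\]. Interval speeds are defined only between
#' adjacent non-missing grid slots; window means use whatever content
#' exists. A sample is transitioning when any of the three averages exceeds
#' `d`.
#'
#' @param grid Grid trace from [preprocess_trace()].
#' @param d Speed threshold, km/h.
#' @return The grid with columns `speed_cen`, `speed_back`, `speed_fwd`
#'   (km/h, NaN where the window is empty) and `transitioning` (logical, NA
#'   for missing samples).
#' @export
segment_stationary <- function(grid, d = 1.5) {
  n <- nrow(grid)
  v <- rep(NA_real_, max(0, n - 1)) # speed of interval (i, i+1)
  if (n >= 2) {
    ok <- !is.na(grid$x[-n]) & !is.na(grid$x[-1])
    dist <- sqrt(diff(grid$x)^2 + diff(grid$y)^2)
    v[ok] <- dist[ok] / (GRID_STEP_S / 3600)
  }
  win_mean <- function(idx) { # mean over interval indices, NA-aware
    vals <- v[idx[idx >= 1 & idx <= length(v)]]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NaN else mean(vals)
  }
  cen <- vapply(seq_len(n), function(i) win_mean(c(i - 1, i)), numeric(1))
  back <- vapply(seq_len(n), function(i) win_mean(c(i - 2, i - 1)), numeric(1))
  fwd <- vapply(seq_len(n), function(i) win_mean(c(i, i + 1)), numeric(1))
  exceeds <- function(m) !is.nan(m) & m > d
  trans <- exceeds(cen) | exceeds(back) | exceeds(fwd)
  trans[is.na(grid$x)] <- NA
  grid$speed_cen <- cen
  grid$speed_back <- back
  grid$speed_fwd <- fwd
  grid$transitioning <- trans
  grid
}

## K-means++ center initialization (D^2-weighted sequential seeding).
kmeanspp_init <- function(pts, k) {
  n <- nrow(pts)
  centers <- matrix(NA_real_, k, 2)
  centers[1, ] <- pts[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- (pts[, 1] - centers[1, 1])^2 + (pts[, 2] - centers[1, 2])^2
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j, ] <- pts[sample.int(n, 1), ]
      } else {
        pick <- sample.int(n, 1, prob = d2)
        centers[j, ] <- pts[pick, ]
      }
      d2 <- pmin(d2, (pts[, 1] - centers[j, 1])^2 + (pts[, 2] - centers[j, 2])^2)
    }
  }
  centers
}

#' Cluster stationary points into places by incremental K-means++
#'
#' K-means (K-means++ initialization) is fitted for K = 1, 2, ...; after
#' each fit the minimum pairwise Euclidean distance among centers is
#' checked, and the largest K whose centers all stay at least `l` apart is
#' accepted.
#'
#' @param points Tibble/data frame with columns `x`, `y` (stationary
#'   samples, km).
#' @param l Minimum center separation, km.
#' @param seed Integer seed (K-means++ seeding is random).
#' @param n_restart K-means restarts per K.
#' @return List of class `geomood_places` with elements `K`, `centers`
#'   (K x 2 matrix), `assignment` (per input point), `l`.
#' @export
cluster_stationary <- function(points, l = 0.4, seed = 1L, n_restart = 1L) {
  pts <- cbind(points$x, points$y)
  if (nrow(pts) == 0) stop("no stationary points to cluster", call. = FALSE)
  n_distinct <- nrow(unique(pts))
  withr::with_seed(seed, {
    fit1 <- list(centers = matrix(colMeans(pts), 1, 2),
                 cluster = rep(1L, nrow(pts)))
    accepted <- fit1
    K <- 1L
    while (K + 1L <= n_distinct) {
      k_try <- K + 1L
      best <- NULL
      for (r in seq_len(n_restart)) {
        init <- kmeanspp_init(pts, k_try)
        fit <- suppressWarnings(
          kmeans(pts, centers = init, iter.max = 100)
        )
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      sep <- min(dist(best$centers))
      if (sep < l) break
      accepted <- list(centers = unname(best$centers),
                       cluster = unname(best$cluster))
      K <- k_try
    }
    structure(list(K = K, centers = accepted$centers,
                   assignment = accepted$cluster, l = l),
              class = "geomood_places")
  })
}

#' Infer the home location and recenter a trace on it
#'
#' Per local day, the home candidate is the modal overnight location: the
#' most frequent 0.01 km coordinate bin among grid samples recorded in
#' \[02:00, 07:00\) local. The global home is the modal candidate over
#' days (ties broken by earliest occurrence), refined to the mean of the
#' contributing samples; all coordinates are shifted so home is (0, 0).
#'
#' @param grid Grid trace (one participant, full observation span).
#' @param tz Timezone for the overnight window.
#' @param bin_km Coordinate bin width for mode counting.
#' @return List with `home` (named numeric c(x, y)) and `grid` (recentered).
#' @export
infer_home <- function(grid, tz = "UTC", bin_km = 0.01) {
  hr <- local_clock_hour(grid$t, tz)
  night <- !is.na(grid$x) & hr >= 2 & hr < 7
  if (!any(night)) stop("home undeterminable: no overnight samples", call. = FALSE)
  ng <- grid[night, ]
  bx <- round(ng$x / bin_km) * bin_km
  by <- round(ng$y / bin_km) * bin_km
  key <- paste(bx, by)
  day <- local_date(ng$t, tz)
  # modal bin per day, earliest-occurring bin wins ties
  mode_first <- function(k) {
    tb <- table(factor(k, levels = unique(k)))
    names(tb)[which.max(tb)]
  }
  cand <- tapply(key, day, mode_first)
  home_key <- mode_first(as.vector(cand[order(names(cand))]))
  in_bin <- key == home_key
  home <- c(x = mean(ng$x[in_bin]), y = mean(ng$y[in_bin]))
  grid$x <- grid$x - home[["x"]]
  grid$y <- grid$y - home[["y"]]
  list(home = home, grid = grid)
}
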