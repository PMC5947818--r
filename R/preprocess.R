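## Preprocessing of raw traces: speed-based artifact filtering, median
## downsampling to a regular 12-samples-per-hour grid, and clock-time-rule
## gap imputation. Output traces are "grid traces": one row per 5-min grid
## slot from the first to the last recorded clock hour, missing slots
## carrying NA coordinates.

#' Preprocessing parameters
#'
#' All thresholds of the cleaning stage, surfaced with their defaults:
#' 100 km/h speed cut, 1 h epochs at 12 samples/h, 0.01 km stationary-epoch
#' SD, 5 min median window, 0.5 km imputation flank radius, 2 h (any time) /
#' 12 h (from 21:00) imputable gap lengths, and >= 3 identical flagged
#' coordinates defining an artifact burst.
#'
#' @param v_max Speed threshold, km/h.
#' @param stationary_sd_km Per-axis SD below which an hour epoch is
#'   collapsed to its mean.
#' @param impute_radius_km Maximum distance between gap flanks.
#' @param impute_max_h_day,impute_max_h_night Maximum imputable gap length
#'   (hours) any time / for gaps starting at or after `night_start`.
#' @param night_start Local clock hour (decimal) opening the long-gap
#'   imputation window.
#' @param burst_min_count Identical flagged coordinates that define a burst.
#' @param tz Timezone for clock-time rules.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(v_max = 100,
                              stationary_sd_km = 0.01,
                              impute_radius_km = 0.5,
                              impute_max_h_day = 2,
                              impute_max_h_night = 12,
                              night_start = 21,
                              burst_min_count = 3,
                              tz = "UTC") {
  p <- as.list(environment())
  stopifnot(v_max > 0, stationary_sd_km > 0, impute_radius_km > 0)
  structure(p, class = "preprocess_params")
}

#' Instantaneous speeds between consecutive fixes
#'
#' @param trace Time-sorted trace tibble.
#' @return Numeric vector of length `nrow(trace) - 1`, km/h (Euclidean
#'   distance / elapsed time).
#' @export
trace_speeds <- function(trace) {
  n <- nrow(trace)
  if (n < 2) return(numeric(0))
  dt_h <- diff(as.numeric(trace$t)) / 3600
  dist <- sqrt(diff(trace$x)^2 + diff(trace$y)^2)
  dist / dt_h
}

#' Remove high-speed artifact fixes
#'
#' A fix is flagged when its speed from the previous fix or to the next fix
#' exceeds `v_max`. Low-accuracy fixes share exact coordinates, so an exact
#' coordinate accumulating `burst_min_count` or more flagged fixes marks an
#' artifact location: every fix at such a coordinate is removed. Flagged
#' fixes at non-repeating coordinates are kept — they are ordinarily the
#' true fixes recorded either side of an interleaved artifact, and removing
#' them would discard genuine data.
#'
#' @param trace Time-sorted trace tibble (per participant).
#' @param params A [preprocess_params()].
#' @return List with `trace` (kept fixes), `removed` (dropped fixes) and
#'   `flagged` (logical over the input rows).
#' @export
filter_highspeed <- function(trace, params = preprocess_params()) {
  if (nrow(trace) < 2)
    return(list(trace = trace, removed = trace[0, ],
                flagged = logical(nrow(trace))))
  v <- trace_speeds(trace)
  fast <- v > params$v_max
  flagged <- c(fast, FALSE) | c(FALSE, fast)
  key <- paste(trace$x, trace$y)
  burst_keys <- names(which(table(key[flagged]) >= params$burst_min_count))
  drop <- key %in% burst_keys
  list(trace = dplyr::arrange(trace[!drop, ], .data$t),
       removed = trace[drop, ], flagged = flagged)
}

#' Downsample a trace to 12 samples per hour with a median filter
#'
#' Time is split into 1 h epochs aligned to clock hours. If the per-axis SD
#' of the fixes inside an epoch is below `stationary_sd_km` on both axes the
#' participant is taken as stationary and all 12 grid samples of the epoch
#' are set to the epoch mean; otherwise each grid sample (at :00, :05, ...)
#' takes the coordinate-wise median of the raw fixes within +/- 2.5 min.
#' Grid slots with no contributing fix, and whole epochs with no fixes, come
#' out as NA.
#'
#' @param trace Filtered trace tibble.
#' @param params A [preprocess_params()].
#' @return Grid trace: one row per 5-min slot spanning the trace's clock
#'   hours, NA coordinates for missing slots.
#' @export
downsample_trace <- function(trace, params = preprocess_params()) {
  empty <- tibble::tibble(participant = character(),
                          t = as.POSIXct(character(), tz = "UTC"),
                          x = numeric(), y = numeric())
  if (nrow(trace) == 0) return(empty)
  ts <- as.numeric(trace$t)
  hour0 <- floor(min(ts) / 3600) * 3600
  hour1 <- ceiling((max(ts) + 1) / 3600) * 3600
  grid_t <- seq(hour0, hour1 - GRID_STEP_S, by = GRID_STEP_S)
  slot_of_grid <- as.integer(round(grid_t / GRID_STEP_S))
  # nearest grid slot of each fix = +/- 2.5 min median window membership
  fix_slot <- as.integer(round(ts / GRID_STEP_S))
  fix_epoch <- as.integer(floor(ts / 3600))
  per_slot_x <- tapply(trace$x, fix_slot, median)
  per_slot_y <- tapply(trace$y, fix_slot, median)
  ep_stat <- tapply(seq_len(nrow(trace)), fix_epoch, function(i) {
    sdx <- if (length(i) > 1) sd(trace$x[i]) else 0
    sdy <- if (length(i) > 1) sd(trace$y[i]) else 0
    c(stationary = sdx < params$stationary_sd_km && sdy < params$stationary_sd_km,
      mx = mean(trace$x[i]), my = mean(trace$y[i]))
  })
  ep_ids <- as.integer(names(ep_stat))
  ep_mat <- do.call(rbind, ep_stat)
  x <- per_slot_x[as.character(slot_of_grid)]
  y <- per_slot_y[as.character(slot_of_grid)]
  grid_epoch <- as.integer(floor(grid_t / 3600))
  ei <- match(grid_epoch, ep_ids)
  stat <- !is.na(ei) & ep_mat[ifelse(is.na(ei), 1L, ei), "stationary"] == 1
  x[stat] <- ep_mat[ei[stat], "mx"]
  y[stat] <- ep_mat[ei[stat], "my"]
  tibble::tibble(
    participant = trace$participant[1],
    t = as.POSIXct(grid_t, origin = "1970-01-01", tz = "UTC"),
    x = as.vector(x, mode = "numeric"), y = as.vector(y, mode = "numeric")
  )
}

#' Impute eligible missing runs on the 5-min grid
#'
#' A run of NA slots is filled with the mean coordinate of its two flanking
#' samples iff the flanks lie within `impute_radius_km` of each other and
#' the run is (a) at most `impute_max_h_day` long at any time of day, or
#' (b) at most `impute_max_h_night` long and starts at or after
#' `night_start` local clock time. Runs at the edges of the grid (missing a
#' flank) are never filled.
#'
#' @param grid Grid trace from [downsample_trace()].
#' @param params A [preprocess_params()].
#' @return Grid trace with eligible runs filled.
#' @export
impute_gaps <- function(grid, params = preprocess_params()) {
  miss <- is.na(grid$x)
  if (!any(miss) || all(miss)) return(grid)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1 || i1 == nrow(grid)) next
    len_h <- r$lengths[k] * GRID_STEP_S / 3600
    fl <- i0 - 1L; fr <- i1 + 1L
    flank_dist <- sqrt((grid$x[fl] - grid$x[fr])^2 + (grid$y[fl] - grid$y[fr])^2)
    if (flank_dist > params$impute_radius_km) next
    start_hour <- local_clock_hour(grid$t[i0], params$tz)
    ok <- len_h <= params$impute_max_h_day ||
      (len_h <= params$impute_max_h_night && start_hour >= params$night_start)
    if (!ok) next
    grid$x[i0:i1] <- (grid$x[fl] + grid$x[fr]) / 2
    grid$y[i0:i1] <- (grid$y[fl] + grid$y[fr]) / 2
  }
  grid
}

#' Full preprocessing of one participant's raw trace
#'
#' Chains [filter_highspeed()], [downsample_trace()] and [impute_gaps()].
#'
#' @param trace Raw trace tibble (one participant).
#' @param params A [preprocess_params()].
#' @return Grid trace; attributes `n_removed` (filtered fixes) records the
#'   filtering stage's action.
#' @export
preprocess_trace <- function(trace, params = preprocess_params()) {
  f <- filter_highspeed(trace, params)
  g <- impute_gaps(downsample_trace(f$trace, params), params)
  attr(g, "n_removed") <- nrow(f$removed)
  g
}
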