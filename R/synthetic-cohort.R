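## Seeded synthetic cohort generator.
##
## Emulates the statistical structure the analysis assumes: a home anchor, a
## small set of recurrent places, diurnal routines with overnight home stays,
## uneven sampling, interleaved bursts of repeated inaccurate fixes, missing
## segments, and a two-state weekly mood process in which depressed weeks
## (QIDS >= 11) increase home stay and reduce place diversity, travel and
## routine regularity. Every generated quantity is recorded in a ground-truth
## ledger so each pipeline stage has an oracle.

#' Synthetic cohort configuration
#'
#' Defaults define the package's reference study conditions: 20 participants
#' followed for 10 calendar weeks with strong behavioral mood effects
#' (home-stay probability 0.55 well vs 0.90 depressed, weekly place pool 4
#' vs 2, departure-time jitter 0.75 h vs 2.5 h SD), a roughly 30% depressed
#' week fraction, 120 s mean sampling interval, two artifact bursts per day
#' at a 10 km offset, and two missing segments per week.
#'
#' @param n_participants Number of participants.
#' @param weeks Calendar weeks per participant.
#' @param n_places Recurrent places per participant (drawn in a 10 km disc).
#' @param baseline_qids_mean,baseline_qids_sd Well-week QIDS distribution
#'   (clamped to 0-10).
#' @param depressed_qids_mean,depressed_qids_sd Depressed-week QIDS
#'   distribution (clamped to 11-27).
#' @param depressed_week_fraction Stationary fraction of depressed weeks of
#'   the two-state weekly Markov mood chain.
#' @param depressed_persistence P(depressed -> depressed) of the chain.
#' @param home_stay_well,home_stay_depressed Probability that a day is spent
#'   entirely at home.
#' @param places_per_week_well,places_per_week_depressed Size of the weekly
#'   pool of distinct places visited.
#' @param visits_per_outing_well,visits_per_outing_depressed Places visited
#'   on a non-home day.
#' @param departure_jitter_well,departure_jitter_depressed SD (hours) of the
#'   departure time around 09:00 on outing days.
#' @param mean_interval_s,jitter_s Base sampling interval and its SD.
#' @param gps_noise_km Per-fix isotropic coordinate noise SD.
#' @param burst_rate_per_day Expected artifact bursts per day.
#' @param burst_len Fixes per burst (identical coordinates).
#' @param burst_offset_km Displacement of the burst coordinate from the
#'   concurrent true path.
#' @param burst_spacing_s Inter-fix spacing inside a burst (shorter than the
#'   base interval).
#' @param gap_rate_per_week Expected missing segments per week.
#' @param gap_min_h,gap_max_h Missing-segment length range (hours).
#' @param far_day_prob Probability per week of one unusually distant outing
#'   day (the outlier the optimized daily-exclusion subset targets).
#' @param far_day_km Distance of that outing.
#' @param travel_speed_kmh Straight-line travel speed between places.
#' @param start Cohort start (a Monday, 00:00 local).
#' @param tz Timezone of the cohort's clock-time rules.
#' @param seed Integer master seed; everything is deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_participants = 20,
                             weeks = 10,
                             n_places = 6,
                             baseline_qids_mean = 6, baseline_qids_sd = 2,
                             depressed_qids_mean = 16, depressed_qids_sd = 3,
                             depressed_week_fraction = 0.3,
                             depressed_persistence = 0.85,
                             home_stay_well = 0.55, home_stay_depressed = 0.9,
                             places_per_week_well = 4,
                             places_per_week_depressed = 2,
                             visits_per_outing_well = c(2, 3),
                             visits_per_outing_depressed = 1,
                             departure_jitter_well = 0.75,
                             departure_jitter_depressed = 2.5,
                             mean_interval_s = 120, jitter_s = 60,
                             gps_noise_km = 0.005,
                             burst_rate_per_day = 2, burst_len = 5,
                             burst_offset_km = 10, burst_spacing_s = 10,
                             gap_rate_per_week = 2, gap_min_h = 1, gap_max_h = 6,
                             far_day_prob = 0.1, far_day_km = 30,
                             travel_speed_kmh = 25,
                             start = as.POSIXct("2015-05-04 00:00:00", tz = "UTC"),
                             tz = "UTC",
                             seed = 1L) {
  cfg <- as.list(environment())
  cfg$start <- as.POSIXct(start, tz = tz)
  if (n_participants < 1 || weeks < 1 || n_places < 1)
    stop("counts must be positive", call. = FALSE)
  fr <- c(depressed_week_fraction, depressed_persistence,
          home_stay_well, home_stay_depressed, far_day_prob)
  if (any(fr < 0 | fr > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!(depressed_qids_mean >= 11 && baseline_qids_mean < 11))
    stop("depressed_qids_mean must be >= 11 > baseline_qids_mean", call. = FALSE)
  if (any(c(burst_rate_per_day, gap_rate_per_week) < 0))
    stop("rates must be nonnegative", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

## Draw `n` place coordinates uniformly in a disc of radius `r_km`,
## re-sampling until all places are >= min_sep from home and each other.
draw_places <- function(n, r_km = 10, min_sep = 1) {
  pts <- matrix(numeric(0), ncol = 2)
  guard <- 0
  while (nrow(pts) < n && guard < 10000) {
    guard <- guard + 1
    th <- runif(1, 0, 2 * pi)
    r <- r_km * sqrt(runif(1))
    cand <- c(r * cos(th), r * sin(th))
    if (sqrt(sum(cand^2)) < min_sep) next
    if (nrow(pts) > 0 &&
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) < min_sep) next
    pts <- rbind(pts, cand)
  }
  pts
}

## Simulate the two-state weekly mood chain; returns logical depressed flags.
simulate_mood_chain <- function(weeks, fraction, persistence) {
  if (fraction <= 0) return(rep(FALSE, weeks))
  if (fraction >= 1) return(rep(TRUE, weeks))
  p_wd <- min(0.95, fraction * (1 - persistence) / (1 - fraction))
  dep <- logical(weeks)
  dep[1] <- runif(1) < fraction
  for (w in seq_len(weeks)[-1]) {
    p <- if (dep[w - 1]) persistence else p_wd
    dep[w] <- runif(1) < p
  }
  dep
}

## Build the piecewise-linear movement schedule for one participant.
## Returns a data frame of segments (t0, t1 seconds from cohort start,
## endpoints, at-home flag) plus per-week scheduling truth.
build_schedule <- function(cfg, places, depressed) {
  weeks <- cfg$weeks
  segs <- vector("list", weeks * 7 + 1)
  si <- 0
  wk_places <- integer(0)
  week_truth <- vector("list", weeks)
  for (w in seq_len(weeks)) {
    dep <- depressed[w]
    pool_n <- min(nrow(places),
                  if (dep) cfg$places_per_week_depressed else cfg$places_per_week_well)
    pool <- sample(nrow(places), pool_n)
    far_week <- runif(1) < cfg$far_day_prob
    far_day <- if (far_week) sample(7, 1) else 0L
    far_theta <- runif(1, 0, 2 * pi)
    visited <- integer(0)
    far_used <- FALSE
    for (d in seq_len(7)) {
      day0 <- ((w - 1) * 7 + (d - 1)) * 86400
      p_home <- if (dep) cfg$home_stay_depressed else cfg$home_stay_well
      if (runif(1) < p_home) next # whole day at home (implicit)
      jit <- if (dep) cfg$departure_jitter_depressed else cfg$departure_jitter_well
      dep_h <- min(13, max(7.2, 9 + rnorm(1, 0, jit)))
      cur <- day0 + dep_h * 3600
      pos <- c(0, 0)
      nv <- if (dep) sample(rep(cfg$visits_per_outing_depressed, 2), 1)
            else sample(rep(cfg$visits_per_outing_well, 2), 1)
      targets <- sample(rep(pool, 2), min(nv, pool_n))
      for (k in seq_along(targets)) {
        dst <- places[targets[k], ]
        if (d == far_day && k == 1) {
          dst <- cfg$far_day_km * c(cos(far_theta), sin(far_theta))
          far_used <- TRUE
        } else {
          visited <- union(visited, targets[k])
        }
        tt <- sqrt(sum((dst - pos)^2)) / cfg$travel_speed_kmh * 3600
        if (cur + tt > day0 + 19.5 * 3600) break
        si <- si + 1
        segs[[si]] <- c(cur, cur + tt, pos, dst, 0)
        cur <- cur + tt
        dwell <- runif(1, 1.5, 3.5) * 3600
        dwell <- min(dwell, day0 + 20 * 3600 - cur)
        if (dwell > 0) {
          si <- si + 1
          segs[[si]] <- c(cur, cur + dwell, dst, dst, 0)
          cur <- cur + dwell
        }
        pos <- dst
      }
      if (any(pos != 0)) { # return home
        tt <- sqrt(sum(pos^2)) / cfg$travel_speed_kmh * 3600
        si <- si + 1
        segs[[si]] <- c(cur, cur + tt, pos, 0, 0, 0)
      }
    }
    week_truth[[w]] <- tibble::tibble(
      week = w, depressed = dep,
      n_places_week = length(visited),
      far_day = far_used
    )
  }
  segs <- segs[seq_len(si)]
  seg_df <- if (si > 0) {
    m <- do.call(rbind, segs)
    tibble::tibble(t0 = m[, 1], t1 = m[, 2], x0 = m[, 3], y0 = m[, 4],
                   x1 = m[, 5], y1 = m[, 6])
  } else {
    tibble::tibble(t0 = numeric(), t1 = numeric(), x0 = numeric(),
                   y0 = numeric(), x1 = numeric(), y1 = numeric())
  }
  # scheduled home-time fraction per week (time not inside any away segment)
  away <- vapply(seq_len(weeks), function(w) {
    lo <- (w - 1) * 7 * 86400; hi <- w * 7 * 86400
    if (nrow(seg_df) == 0) return(0)
    sum(pmax(0, pmin(seg_df$t1, hi) - pmax(seg_df$t0, lo)))
  }, numeric(1))
  wk <- dplyr::bind_rows(week_truth)
  wk$home_frac <- 1 - away / (7 * 86400)
  list(segments = seg_df, week_truth = wk)
}

## Evaluate the schedule position at arbitrary times (seconds from start).
schedule_position <- function(segments, tsec) {
  x <- rep(0, length(tsec))
  y <- rep(0, length(tsec))
  if (nrow(segments) == 0) return(cbind(x, y))
  idx <- findInterval(tsec, segments$t0)
  ok <- idx >= 1
  ok[ok] <- tsec[ok] < segments$t1[idx[ok]]
  i <- idx[ok]
  frac <- (tsec[ok] - segments$t0[i]) / (segments$t1[i] - segments$t0[i])
  x[ok] <- segments$x0[i] + frac * (segments$x1[i] - segments$x0[i])
  y[ok] <- segments$y0[i] + frac * (segments$y1[i] - segments$y0[i])
  cbind(x, y)
}

#' Inject same-coordinate artifact bursts into a clean trace
#'
#' Emulates the low-accuracy fixes real devices interleave with the true
#' path: each burst is a run of `burst_len` fixes sharing one identical
#' coordinate, displaced `burst_offset_km` from the concurrent true
#' position. Burst fixes are interleaved with the true stream — each is
#' emitted `burst_spacing_s` after one of `burst_len` consecutive true
#' fixes — so the assembled trace alternates true and artifact coordinates
#' at a spacing shorter than the base sampling interval, the temporal
#' signature the speed filter keys on. Added fixes carry `artifact = TRUE`.
#'
#' @param trace A clean trace tibble.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param n_bursts Burst count; default draws Poisson
#'   (`burst_rate_per_day` x trace span).
#' @return The trace with burst fixes interleaved, time-sorted.
#' @export
inject_artifacts <- function(trace, config, seed = config$seed, n_bursts = NULL) {
  if (!"artifact" %in% names(trace)) trace$artifact <- FALSE
  if (nrow(trace) <= config$burst_len) return(trace)
  withr::with_seed(seed, {
    span_d <- as.numeric(difftime(max(trace$t), min(trace$t), units = "days"))
    if (is.null(n_bursts))
      n_bursts <- rpois(1, config$burst_rate_per_day * span_d)
  })
  if (n_bursts == 0) return(trace)
  withr::with_seed(child_seed(seed, 1L), {
    tt <- as.numeric(trace$t)
    i0 <- sample.int(nrow(trace) - config$burst_len, n_bursts, replace = TRUE)
    th <- runif(n_bursts, 0, 2 * pi)
    bursts <- purrr::map_dfr(seq_len(n_bursts), function(b) {
      anchor <- i0[b]:(i0[b] + config$burst_len - 1)
      tibble::tibble(
        participant = trace$participant[1],
        t = as.POSIXct(tt[anchor] + config$burst_spacing_s,
                       origin = "1970-01-01", tz = "UTC"),
        x = trace$x[i0[b]] + config$burst_offset_km * cos(th[b]),
        y = trace$y[i0[b]] + config$burst_offset_km * sin(th[b]),
        artifact = TRUE
      )
    })
    out <- dplyr::arrange(dplyr::bind_rows(trace, bursts), .data$t)
    # overlapping bursts can land two artifacts on one instant; keep one so
    # fix times stay strictly increasing
    out[!duplicated(out$t), ]
  })
}

#' Generate a seeded synthetic cohort with ground truth
#'
#' Produces per-participant location traces and weekly QIDS responses with
#' the behavioral structure described in [synthetic_config()], plus a truth
#' ledger (`weeks`, `places`, `gaps`) against which every pipeline stage can
#' be checked. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `traces` (one tibble, fixes flagged
#'   `artifact`), `qids` (weekly responses) and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  t_origin <- as.numeric(config$start)
  parts <- purrr::map(seq_len(config$n_participants), function(i) {
    pid <- sprintf("P%02d", i)
    withr::with_seed(child_seed(config$seed, i), {
      places <- draw_places(config$n_places)
      depressed <- simulate_mood_chain(config$weeks, config$depressed_week_fraction,
                                       config$depressed_persistence)
      sched <- build_schedule(config, places, depressed)
      span <- config$weeks * 7 * 86400
      n_est <- ceiling(span / config$mean_interval_s * 1.2) + 10
      gaps_iv <- pmax(10, rnorm(n_est, config$mean_interval_s, config$jitter_s))
      tsec <- cumsum(gaps_iv)
      tsec <- tsec[tsec < span]
      pos <- schedule_position(sched$segments, tsec)
      trace <- tibble::tibble(
        participant = pid,
        t = as.POSIXct(tsec + t_origin, origin = "1970-01-01", tz = "UTC"),
        x = pos[, 1] + rnorm(length(tsec), 0, config$gps_noise_km),
        y = pos[, 2] + rnorm(length(tsec), 0, config$gps_noise_km),
        artifact = FALSE
      )
      trace <- inject_artifacts(trace, config, seed = child_seed(config$seed, i + 5000))
      # missing segments
      n_gaps <- rpois(1, config$gap_rate_per_week * config$weeks)
      gap_df <- tibble::tibble(participant = character(), gap_start = numeric(),
                               gap_end = numeric())
      if (n_gaps > 0) {
        gs <- runif(n_gaps, 0, span)
        gl <- runif(n_gaps, config$gap_min_h, config$gap_max_h) * 3600
        gap_df <- tibble::tibble(participant = pid, gap_start = gs + t_origin,
                                 gap_end = gs + gl + t_origin)
        keep <- rep(TRUE, nrow(trace))
        ts <- as.numeric(trace$t)
        for (g in seq_len(n_gaps))
          keep <- keep & !(ts >= gap_df$gap_start[g] & ts < gap_df$gap_end[g])
        trace <- trace[keep, ]
      }
      # QIDS scores and weekly responses
      wk <- sched$week_truth
      raw <- ifelse(wk$depressed,
                    rnorm(config$weeks, config$depressed_qids_mean,
                          config$depressed_qids_sd),
                    rnorm(config$weeks, config$baseline_qids_mean,
                          config$baseline_qids_sd))
      wk$qids <- as.integer(ifelse(wk$depressed,
                                   pmin(27, pmax(11, round(raw))),
                                   pmin(10, pmax(0, round(raw)))))
      wk$participant <- pid
      wk$week_start <- as.POSIXct((wk$week - 1) * 7 * 86400 + t_origin,
                                  origin = "1970-01-01", tz = "UTC")
      qids <- tibble::tibble(
        participant = pid,
        t = as.POSIXct(wk$week * 7 * 86400 - runif(config$weeks, 0, 48 * 3600) +
                         t_origin, origin = "1970-01-01", tz = "UTC"),
        score = wk$qids
      )
      list(trace = trace, qids = qids, weeks = wk,
           places = tibble::tibble(participant = pid,
                                   place = seq_len(nrow(places)),
                                   x = places[, 1], y = places[, 2]),
           gaps = gap_df)
    })
  })
  list(
    traces = dplyr::bind_rows(purrr::map(parts, "trace")),
    qids = dplyr::bind_rows(purrr::map(parts, "qids")),
    truth = list(
      weeks = dplyr::bind_rows(purrr::map(parts, "weeks")) |>
        dplyr::relocate("participant", "week", "week_start"),
      places = dplyr::bind_rows(purrr::map(parts, "places")),
      gaps = dplyr::bind_rows(purrr::map(parts, "gaps")),
      home = tibble::tibble(
        participant = sprintf("P%02d", seq_len(config$n_participants)),
        x = 0, y = 0)
    )
  )
}

#' Write a synthetic cohort to disk
#'
#' Per-participant trace and QIDS CSVs (degrees, about an arbitrary
#' reference) plus a `truth.json` ledger.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param ref_lat,ref_lon Geographic reference the km frame is unprojected
#'   about.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, ref_lat = 51.75, ref_lon = -1.25) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in unique(cohort$traces$participant)) {
    write_trace_csv(dplyr::filter(cohort$traces, .data$participant == pid),
                    file.path(dir, paste0(pid, "_trace.csv")),
                    reference = c(ref_lat, ref_lon))
    write_qids_csv(dplyr::filter(cohort$qids, .data$participant == pid),
                   file.path(dir, paste0(pid, "_qids.csv")))
  }
  truth <- cohort$truth
  truth$weeks$week_start <- format(truth$weeks$week_start,
                                   "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
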