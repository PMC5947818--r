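# Deterministic fixture builders shared across test files. Everything is
# generated in code; nothing is read from disk.

MONDAY <- as.POSIXct("2015-05-04 00:00:00", tz = "UTC") # a Monday

# A regular 5-min grid trace starting at `start`.
grid_fixture <- function(x, y, start = MONDAY, participant = "T") {
  n <- max(length(x), length(y))
  tibble::tibble(
    participant = participant,
    t = start + (seq_len(n) - 1) * 300,
    x = rep_len(x, n), y = rep_len(y, n)
  )
}

# A raw (ungridded) trace from offsets in seconds.
raw_fixture <- function(t_s, x, y, start = MONDAY, participant = "T") {
  tibble::tibble(participant = participant, t = start + t_s, x = x, y = y)
}

# One full-week grid (2016 slots) at home with an optional daily outing to
# `away` between `out_h` and `back_h` (instant jumps; no travel samples).
week_fixture <- function(away = c(2, 0), out_h = 9, back_h = 17,
                         days_out = 1:5, start = MONDAY) {
  n <- 7 * 288
  g <- grid_fixture(numeric(n), numeric(n), start = start)
  hr <- as.numeric(g$t - start, units = "hours") %% 24
  day <- floor(as.numeric(g$t - start, units = "days")) + 1
  out <- day %in% days_out & hr >= out_h & hr < back_h
  g$x[out] <- away[1]
  g$y[out] <- away[2]
  g
}

# Brute-force stationary segmentation oracle: direct evaluation of the three
# 10-min moving-average speeds from interval speeds (independent of the
# package's vectorized path).
brute_segment <- function(grid, d = 1.5) {
  n <- nrow(grid)
  v <- rep(NA_real_, n - 1)
  for (i in seq_len(n - 1)) {
    if (!is.na(grid$x[i]) && !is.na(grid$x[i + 1])) {
      v[i] <- sqrt((grid$x[i + 1] - grid$x[i])^2 +
                     (grid$y[i + 1] - grid$y[i])^2) / (300 / 3600)
    }
  }
  trans <- logical(n)
  for (i in seq_len(n)) {
    wins <- list(c(i - 1, i), c(i - 2, i - 1), c(i, i + 1))
    flags <- vapply(wins, function(w) {
      w <- w[w >= 1 & w <= n - 1]
      vals <- v[w]
      vals <- vals[!is.na(vals)]
      length(vals) > 0 && mean(vals) > d
    }, logical(1))
    trans[i] <- any(flags)
  }
  trans[is.na(grid$x)] <- NA
  trans
}

# Least-squares sinusoid-fit oracle for the Lomb-Scargle periodogram: the
# power at frequency f equals half the sum-of-squares reduction of fitting
# cos/sin regressors to the centred series.
ls_power_oracle <- function(t, y, freq) {
  yc <- y - mean(y)
  vapply(freq, function(f) {
    C <- cos(2 * pi * f * t)
    S <- sin(2 * pi * f * t)
    fit <- lm(yc ~ 0 + C + S)
    0.5 * (sum(yc^2) - sum(residuals(fit)^2))
  }, numeric(1))
}

# Memoized default-conditions cohort and its processed evaluation, shared by
# the acceptance tests (built once per test run).
.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- generate_cohort(synthetic_config(seed = 1))
  }
  .fixture_cache$cohort
}

default_eval <- function() {
  if (is.null(.fixture_cache$eval)) {
    coh <- default_cohort()
    .fixture_cache$eval <- process_cohort(coh$traces, coh$qids, seed = 1)
  }
  .fixture_cache$eval
}

ACC_FEATURES <- c("HS_base", "NENT_base", "NC_base", "TD_base", "DMD_base")

# Globally shuffle week scores (the permutation null destroying any
# association between features and labels).
shuffle_labels <- function(labels, seed) {
  withr::with_seed(seed, {
    idx <- !is.na(labels$score)
    labels$score[idx] <- sample(labels$score[idx])
  })
  labels$depressed <- labels$score >= 11
  labels
}
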