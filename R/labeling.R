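## Weekly QIDS labeling. A calendar week receives either the score of a
## single nearby response, or the mean of daily linear interpolants between
## surrounding responses, and is flagged depressed at the accepted moderate
## threshold of 11.

#' Binarize a QIDS score at the moderate-depression threshold
#'
#' @param score Numeric QIDS score(s), possibly interpolated.
#' @param threshold Clinical cutoff (default 11).
#' @return Logical: `score >= threshold`.
#' @export
binarize_qids <- function(score, threshold = 11) {
  score >= threshold
}

#' Label one calendar week from a QIDS response series
#'
#' If exactly one response falls within 3.5 days either side of the week,
#' its score is used. Otherwise, if at least two responses fall within
#' 7 days either side, the score is linearly interpolated between
#' consecutive responses, evaluated at local noon of each of the week's 7
#' days (held constant beyond the first/last response), and averaged.
#' Otherwise the week is unlabeled (NA score).
#'
#' @param responses Time-sorted tibble with `t`, `score` (one participant).
#' @param week A week start (Monday 00:00, POSIXct).
#' @param tz Timezone.
#' @param threshold Depression cutoff.
#' @return One-row tibble: `week_start`, `score`, `depressed`, `provenance`
#'   (`"single-response"`, `"interpolated"` or `"unlabeled"`).
#' @export
label_week <- function(responses, week, tz = "UTC", threshold = 11) {
  w0 <- as.numeric(week)
  w1 <- w0 + 7 * 86400
  ts <- as.numeric(responses$t)
  in_narrow <- ts >= w0 - 3.5 * 86400 & ts <= w1 + 3.5 * 86400
  in_wide <- ts >= w0 - 7 * 86400 & ts <= w1 + 7 * 86400
  score <- NA_real_
  prov <- "unlabeled"
  if (sum(in_narrow) == 1) {
    score <- as.numeric(responses$score[in_narrow])
    prov <- "single-response"
  } else if (sum(in_wide) >= 2) {
    rs <- responses[in_wide, ]
    midpoints <- w0 + (0:6) * 86400 + 12 * 3600
    vals <- approx(as.numeric(rs$t), rs$score, xout = midpoints,
                   rule = 2, ties = mean)$y
    score <- mean(vals)
    prov <- "interpolated"
  }
  tibble::tibble(
    week_start = week,
    score = score,
    depressed = if (is.na(score)) NA else binarize_qids(score, threshold),
    provenance = prov
  )
}

#' Label every calendar week of a cohort's QIDS series
#'
#' @param qids Tibble with `participant`, `t`, `score`.
#' @param weeks Optional tibble of `participant`, `week_start` rows to
#'   label; defaults to every week touched by each participant's responses.
#' @param tz Timezone.
#' @param threshold Depression cutoff.
#' @return Tibble: `participant`, `week_start`, `score`, `depressed`,
#'   `provenance`.
#' @export
label_weeks <- function(qids, weeks = NULL, tz = "UTC", threshold = 11) {
  if (is.null(weeks)) {
    weeks <- qids |>
      dplyr::mutate(week_start = week_start(.data$t, tz)) |>
      dplyr::distinct(.data$participant, .data$week_start)
  }
  purrr::map_dfr(split(weeks, weeks$participant), function(wk) {
    resp <- qids[qids$participant == wk$participant[1], ]
    out <- purrr::map_dfr(wk$week_start, label_week, responses = resp,
                          tz = tz, threshold = threshold)
    dplyr::mutate(out, participant = wk$participant[1], .before = 1)
  })
}
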