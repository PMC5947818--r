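## Reading, writing and projecting location traces and questionnaire series.
##
## A trace is an ordinary tibble with columns
##   participant (chr), t (POSIXct, UTC), x (km east of reference),
##   y (km north of reference)
## plus any extra columns (the synthetic generator adds an `artifact` flag).
## A QIDS series is a tibble with columns participant, t, score.

## Mean-earth-radius arc length of one degree, km/degree.
KM_PER_DEGREE <- 111.195

#' Project geographic degrees to a local planar km frame
#'
#' Equirectangular projection about a reference point: adequate (and exactly
#' invertible) at the city scale this pipeline operates on, where all
#' thresholds (0.01 km stationarity, 0.5 km imputation radius, 0.4 km cluster
#' separation, 100 km/h speed cut) presume metric planar distances.
#'
#' @param lat,lon Latitude/longitude in degrees.
#' @param ref_lat,ref_lon Reference point mapping to (0, 0).
#' @return Tibble with columns `x` (km east) and `y` (km north).
#' @examples
#' project_to_local_km(51.76, -1.26, 51.75, -1.26)
#' @export
project_to_local_km <- function(lat, lon, ref_lat, ref_lon) {
  stopifnot(length(ref_lat) == 1, length(ref_lon) == 1)
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(ref_lat) > 90))
    stop("latitude out of range [-90, 90]", call. = FALSE)
  if (any(abs(lon) > 180, na.rm = TRUE) || any(abs(ref_lon) > 180))
    stop("longitude out of range [-180, 180]", call. = FALSE)
  tibble::tibble(
    x = (lon - ref_lon) * KM_PER_DEGREE * cos(ref_lat * pi / 180),
    y = (lat - ref_lat) * KM_PER_DEGREE
  )
}

#' Invert the local planar projection back to degrees
#'
#' @param x,y Planar km offsets east/north of the reference.
#' @inheritParams project_to_local_km
#' @return Tibble with columns `lat` and `lon` in degrees.
#' @export
local_km_to_degrees <- function(x, y, ref_lat, ref_lon) {
  tibble::tibble(
    lat = ref_lat + y / KM_PER_DEGREE,
    lon = ref_lon + x / (KM_PER_DEGREE * cos(ref_lat * pi / 180))
  )
}

#' Validate and normalize a location trace
#'
#' Sorts by time, collapses duplicate timestamps to their coordinate mean,
#' and checks invariants (finite coordinates, strictly increasing times).
#'
#' @param df Data frame with columns `t`, `x`, `y` and optionally
#'   `participant`.
#' @param participant Participant id to attach if the column is absent.
#' @return A trace tibble with strictly increasing `t`.
#' @export
as_trace <- function(df, participant = NULL) {
  stopifnot(all(c("t", "x", "y") %in% names(df)))
  df <- tibble::as_tibble(df)
  if (!"participant" %in% names(df)) {
    df$participant <- if (is.null(participant)) NA_character_ else participant
  }
  if (nrow(df) == 0) {
    return(df[c("participant", "t", "x", "y",
                setdiff(names(df), c("participant", "t", "x", "y")))])
  }
  if (anyNA(df$t) || any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("trace contains non-finite timestamps or coordinates", call. = FALSE)
  df <- dplyr::arrange(df, .data$participant, .data$t)
  if (anyDuplicated(df[c("participant", "t")])) {
    df <- df |>
      dplyr::group_by(.data$participant, .data$t) |>
      dplyr::summarise(dplyr::across(dplyr::everything(),
                                     ~ if (is.numeric(.x)) mean(.x) else dplyr::first(.x)),
                       .groups = "drop")
  }
  dplyr::relocate(df, "participant", "t", "x", "y")
}

#' Read a location trace CSV
#'
#' Expects header columns `timestamp,latitude,longitude` with ISO-8601 UTC
#' timestamps. Degrees are projected to a local planar km frame about
#' `reference`; by default the first (earliest) fix of the file.
#'
#' @param path CSV file path.
#' @param reference Either `"first-fix"` (default) or a numeric
#'   `c(lat, lon)` pair in degrees.
#' @param participant Participant id; defaults to the file name stem.
#' @return A trace tibble (possibly empty), sorted by time, duplicate
#'   timestamps collapsed to their coordinate mean.
#' @export
read_trace_csv <- function(path, reference = "first-fix", participant = NULL) {
  if (is.null(participant))
    participant <- tools::file_path_sans_ext(basename(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(as_trace(tibble::tibble(t = as.POSIXct(character(), tz = "UTC"),
                                   x = numeric(), y = numeric()),
                    participant = participant))
  }
  need <- c("timestamp", "latitude", "longitude")
  if (!all(need %in% names(raw)))
    stop("trace CSV must have columns timestamp, latitude, longitude", call. = FALSE)
  t <- as.POSIXct(raw$timestamp, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  lat <- suppressWarnings(as.numeric(raw$latitude))
  lon <- suppressWarnings(as.numeric(raw$longitude))
  bad <- which(is.na(t) | is.na(lat) | is.na(lon))
  if (length(bad) > 0)
    stop(sprintf("malformed trace row at line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  if (identical(reference, "first-fix")) {
    i0 <- which.min(t)
    reference <- c(lat[i0], lon[i0])
  }
  xy <- project_to_local_km(lat, lon, reference[1], reference[2])
  tr <- as_trace(tibble::tibble(t = t, x = xy$x, y = xy$y), participant = participant)
  attr(tr, "reference") <- reference
  tr
}

#' Write a location trace CSV
#'
#' Inverse of [read_trace_csv()]: planar km coordinates are unprojected to
#' degrees about `reference` and written as
#' `timestamp,latitude,longitude`.
#'
#' @param trace Trace tibble.
#' @param path Output path.
#' @param reference Numeric `c(lat, lon)` reference in degrees.
#' @export
write_trace_csv <- function(trace, path, reference = c(0, 0)) {
  deg <- local_km_to_degrees(trace$x, trace$y, reference[1], reference[2])
  readr::write_csv(
    tibble::tibble(
      timestamp = format(trace$t, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC"),
      latitude = sprintf("%.12f", deg$lat),
      longitude = sprintf("%.12f", deg$lon)
    ),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read a weekly QIDS-SR16 response CSV
#'
#' Expects header columns `timestamp,score`; scores are integers 0-27.
#'
#' @param path CSV file path.
#' @param participant Participant id; defaults to the file name stem.
#' @return Tibble with columns `participant`, `t`, `score`, time-sorted.
#' @export
read_qids_csv <- function(path, participant = NULL) {
  if (is.null(participant))
    participant <- tools::file_path_sans_ext(basename(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0)
    return(tibble::tibble(participant = character(),
                          t = as.POSIXct(character(), tz = "UTC"),
                          score = integer()))
  if (!all(c("timestamp", "score") %in% names(raw)))
    stop("QIDS CSV must have columns timestamp, score", call. = FALSE)
  t <- as.POSIXct(raw$timestamp, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  score <- suppressWarnings(as.integer(raw$score))
  bad <- which(is.na(t) | is.na(score) | score < 0 | score > 27)
  if (length(bad) > 0)
    stop(sprintf("malformed QIDS row at line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  dplyr::arrange(tibble::tibble(participant = participant, t = t, score = score),
                 .data$t)
}

#' Write a QIDS response CSV
#' @param qids Tibble with columns `t`, `score`.
#' @param path Output path.
#' @export
write_qids_csv <- function(qids, path) {
  readr::write_csv(
    tibble::tibble(timestamp = format(qids$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   score = qids$score),
    path, progress = FALSE
  )
  invisible(path)
}
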