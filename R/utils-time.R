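## Clock-time helpers. All timestamps are stored as POSIXct (UTC internally);
## the rules that reference wall-clock time (overnight home window, the 9 pm
## imputation clause, weekday/weekend subsets, calendar weeks) evaluate the
## timestamp in a configurable local timezone.

GRID_STEP_S <- 300L # 5-min grid = 12 samples per hour

local_clock_hour <- function(t, tz = "UTC") {
  lt <- as.POSIXlt(t, tz = tz)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

local_date <- function(t, tz = "UTC") {
  as.Date(format(t, "%Y-%m-%d", tz = tz))
}

## ISO weekday 1 = Monday ... 7 = Sunday, in local time
local_wday <- function(t, tz = "UTC") {
  as.integer(format(t, "%u", tz = tz))
}

#' Monday 00:00 start of the calendar week containing a timestamp
#'
#' Weeks are ISO calendar weeks, Monday 00:00 local time. Used to assign
#' fixes, grid samples and questionnaire labels to analysis weeks.
#'
#' @param t POSIXct vector.
#' @param tz Timezone in which the week boundary is evaluated.
#' @return POSIXct vector of week starts (Monday 00:00 in `tz`).
#' @export
week_start <- function(t, tz = "UTC") {
  d <- local_date(t, tz)
  monday <- d - (as.integer(format(d, "%u")) - 1L)
  as.POSIXct(paste(monday, "00:00:00"), tz = tz)
}

## Derive a reproducible child seed from a base seed and an index,
## kept within 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}
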