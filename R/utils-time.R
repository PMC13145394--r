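#' Coerce to a UTC timestamp
#'
#' All timestamps in the package are `POSIXct` in UTC. Character input is
#' parsed as ISO-8601 (`"%Y-%m-%d %H:%M:%S"` or `"%Y-%m-%dT%H:%M:%S"`).
#'
#' @param x character, numeric (seconds since epoch) or `POSIXct`.
#' @return `POSIXct` vector with `tzone = "UTC"`.
#' @export
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  if (is.character(x)) {
    x <- gsub("T", " ", x, fixed = TRUE)
    out <- as.POSIXct(x, tz = "UTC",
                      tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                     "%Y-%m-%d"))
    return(out)
  }
  stop("cannot coerce to UTC timestamp: class ", paste(class(x), collapse = "/"))
}

#' Half-open 2-h window preceding a beep
#'
#' The block for a beep completed at time `t` is the half-open interval
#' `[t - hours, t)`: a sample at exactly `t - hours` belongs to the block, a
#' sample at exactly `t` does not. Anchoring at the beep and using half-open
#' intervals prevents double counting across adjacent beeps.
#'
#' @param beep_time `POSIXct` beep completion time.
#' @param hours window length in hours (default 2).
#' @return list with `start` and `end` (`POSIXct`, UTC).
#' @export
block_window <- function(beep_time, hours = 2) {
  beep_time <- as_utc(beep_time)
  list(start = beep_time - hours * 3600, end = beep_time)
}

# TRUE for timestamps inside the half-open window [start, end)
in_window <- function(ts, window) {
  ts >= window$start & ts < window$end
}

# Overlap (seconds) of event intervals [start, end] with half-open window
overlap_seconds <- function(ev_start, ev_end, window) {
  pmax(0, as.numeric(pmin(ev_end, window$end), units = "secs") -
         as.numeric(pmax(ev_start, window$start), units = "secs"))
}

# Local clock time under the package's fixed UTC-offset convention
local_time <- function(ts, tz_offset_h = 1) {
  as_utc(ts) + tz_offset_h * 3600
}

local_date <- function(ts, tz_offset_h = 1) {
  as.Date(local_time(ts, tz_offset_h), tz = "UTC")
}

local_hour <- function(ts, tz_offset_h = 1) {
  lt <- local_time(ts, tz_offset_h)
  as.integer(format(lt, "%H", tz = "UTC")) +
    as.integer(format(lt, "%M", tz = "UTC")) / 60
}
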