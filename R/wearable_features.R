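#' Clean a heart-rate stream
#'
#' Removes non-numeric readings and values outside the physiological range
#' of 30 to 220 bpm (bounds inclusive). Order is preserved; the number of
#' removed samples is attached as attribute `n_removed`.
#'
#' @param samples data.frame with columns `timestamp`, `bpm` (`bpm` may
#'   contain non-numeric junk if read from raw CSVs).
#' @return cleaned data.frame with attribute `n_removed`.
#' @export
clean_hr <- function(samples) {
  n0 <- nrow(samples)
  bpm <- suppressWarnings(as.numeric(samples$bpm))
  keep <- !is.na(bpm) & bpm >= 30 & bpm <= 220
  out <- samples[keep, , drop = FALSE]
  out$bpm <- bpm[keep]
  attr(out, "n_removed") <- n0 - nrow(out)
  out
}

#' Aggregate heart rate over one block
#'
#' Mean/min/max/std of cleaned samples falling in the half-open window, plus
#' minutes in three heart-rate zones: resting (<= 60 bpm), moderate (strictly
#' between 60 and 100) and vigorous (>= 100). The stream is a 10-min sampling
#' grid, so sample counts proxy time: zone minutes are
#' `block_length * count_in_zone / count_in_window`, which guarantees zone
#' minutes sum to the block length whenever any sample is present. The
#' standard deviation uses the population formula (n divisor); a single
#' sample gives std 0.
#'
#' @param samples cleaned HR data.frame (`timestamp`, `bpm`).
#' @param window a [block_window()] list.
#' @return one-row data.frame with `hr_mean`, `hr_min`, `hr_max`, `hr_std`,
#'   `hr_zone_resting`, `hr_zone_moderate`, `hr_zone_vigorous` (minutes) and
#'   `missing_hr`; numeric features `NA` when the window holds no sample.
#' @export
aggregate_hr <- function(samples, window) {
  block_min <- as.numeric(window$end - window$start, units = "mins")
  x <- samples$bpm[in_window(as_utc(samples$timestamp), window)]
  if (length(x) == 0) {
    return(data.frame(hr_mean = NA_real_, hr_min = NA_real_, hr_max = NA_real_,
                      hr_std = NA_real_, hr_zone_resting = NA_real_,
                      hr_zone_moderate = NA_real_, hr_zone_vigorous = NA_real_,
                      missing_hr = TRUE))
  }
  n <- length(x)
  data.frame(
    hr_mean = mean(x), hr_min = min(x), hr_max = max(x),
    hr_std = sqrt(mean((x - mean(x))^2)),
    hr_zone_resting = block_min * sum(x <= 60) / n,
    hr_zone_moderate = block_min * sum(x > 60 & x < 100) / n,
    hr_zone_vigorous = block_min * sum(x >= 100) / n,
    missing_hr = FALSE)
}

#' Clean a step-event stream
#'
#' Drops events with non-numeric or negative counts, zero or negative
#' durations, and implausible cadence: above 200 steps per minute, a rate
#' rare even in elite runners. A tally of removals by reason is attached as
#' attribute `removed_by_reason`.
#'
#' @param events data.frame with `start`, `end`, `steps`.
#' @return cleaned data.frame with attribute `removed_by_reason` (named
#'   integer vector: `non_numeric`, `negative`, `bad_duration`, `cadence`).
#' @export
clean_steps <- function(events) {
  steps <- suppressWarnings(as.numeric(events$steps))
  dur_min <- as.numeric(as_utc(events$end)) - as.numeric(as_utc(events$start))
  dur_min <- dur_min / 60
  non_numeric <- is.na(steps)
  negative <- !non_numeric & steps < 0
  bad_duration <- !non_numeric & !negative & dur_min <= 0
  cadence <- !non_numeric & !negative & !bad_duration & steps / dur_min > 200
  keep <- !(non_numeric | negative | bad_duration | cadence)
  out <- events[keep, , drop = FALSE]
  out$steps <- steps[keep]
  attr(out, "removed_by_reason") <- c(
    non_numeric = sum(non_numeric), negative = sum(negative),
    bad_duration = sum(bad_duration), cadence = sum(cadence))
  out
}

#' Clean an activity-event stream
#'
#' Keeps events with a strictly boolean flag, a recognized category and a
#' positive duration.
#'
#' @param events data.frame with `start`, `end`, `category`, `flag`.
#' @param categories closed set of valid categories.
#' @return cleaned data.frame with attribute `n_removed`.
#' @export
clean_activity <- function(events,
                           categories = c("walking", "running", "cycling",
                                          "sleep", "rest", "active")) {
  n0 <- nrow(events)
  flag <- events$flag
  ok_flag <- !is.na(flag) & (is.logical(flag) | flag %in% c(0, 1, TRUE, FALSE))
  dur <- as.numeric(as_utc(events$end)) - as.numeric(as_utc(events$start))
  keep <- ok_flag & events$category %in% categories & dur > 0
  out <- events[keep, , drop = FALSE]
  out$flag <- as.logical(out$flag)
  attr(out, "n_removed") <- n0 - nrow(out)
  out
}

#' Proportional-overlap aggregation of interval events into a block
#'
#' Each event contributes `value * |event intersect window| / |event|`: an
#' event fully inside the window contributes its full value, an event half
#' inside contributes half. Summing over any partition of time into blocks
#' covering all events conserves the total value exactly.
#'
#' @param events cleaned data.frame with `start`, `end` (positive duration).
#' @param window a [block_window()] list.
#' @param values numeric vector of per-event values (e.g. step counts, or
#'   event duration in minutes for activity states).
#' @return the weighted sum (0 for no events).
#' @export
aggregate_overlap <- function(events, window, values) {
  if (nrow(events) == 0) return(0)
  stopifnot(length(values) == nrow(events))
  ev_start <- as_utc(events$start); ev_end <- as_utc(events$end)
  dur <- as.numeric(ev_end) - as.numeric(ev_start)
  if (any(dur <= 0)) stop("zero-length event: clean events before aggregating")
  ov <- overlap_seconds(ev_start, ev_end, window)
  sum(values * ov / dur)
}

#' All wearable features for one block
#'
#' Combines HR aggregation, overlap-weighted steps and per-category activity
#' minutes over one half-open window, with missingness flags. `watch_off` is
#' TRUE exactly when HR, steps and activity are all absent in the window —
#' the signature of the watch not being worn.
#'
#' @param hr cleaned HR data.frame.
#' @param steps cleaned step-event data.frame.
#' @param activity cleaned activity-event data.frame.
#' @param window a [block_window()] list.
#' @param categories activity category set (fixed order of output columns).
#' @return one-row data.frame with the 14 wearable features
#'   (7 HR, `steps`, 6 `act_*` minutes) and flags `missing_hr`,
#'   `missing_steps`, `missing_activity`, `watch_off`.
#' @export
wearable_block_features <- function(hr, steps, activity, window,
                                    categories = c("walking", "running",
                                                   "cycling", "sleep",
                                                   "rest", "active")) {
  hr_feats <- aggregate_hr(hr, window)

  has_overlap <- function(ev) {
    nrow(ev) > 0 &&
      any(overlap_seconds(as_utc(ev$start), as_utc(ev$end), window) > 0)
  }
  missing_steps <- !has_overlap(steps)
  steps_total <- if (missing_steps) NA_real_ else
    aggregate_overlap(steps, window, steps$steps)

  missing_activity <- !has_overlap(activity)
  act <- setNames(rep(NA_real_, length(categories)),
                  paste0("act_", categories))
  if (!missing_activity) {
    dur_min <- (as.numeric(as_utc(activity$end)) -
                  as.numeric(as_utc(activity$start))) / 60
    for (i in seq_along(categories)) {
      sel <- activity$category == categories[i]
      act[i] <- aggregate_overlap(activity[sel, , drop = FALSE], window,
                                  dur_min[sel])
    }
  }
  out <- cbind(hr_feats[setdiff(names(hr_feats), "missing_hr")],
               data.frame(steps = steps_total), as.data.frame(as.list(act)))
  out$missing_hr <- hr_feats$missing_hr
  out$missing_steps <- missing_steps
  out$missing_activity <- missing_activity
  out$watch_off <- hr_feats$missing_hr && missing_steps && missing_activity
  out
}
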