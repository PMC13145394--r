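#' Momentary negative affect score from the eight EMA items
#'
#' The NA score is the arithmetic mean of the eight 1-7 items (downcast,
#' sad, anxious, nervous, irritable, angry, ashamed, dissatisfied with
#' oneself), hence a multiple of 1/8 in `[1, 7]`. There is no partial
#' scoring: any missing item makes the beep unanswered.
#'
#' @param items numeric vector (or 8-column matrix, one beep per row) of
#'   integers in 1-7.
#' @return numeric score(s); `NA` where any item is missing.
#' @export
compute_na <- function(items) {
  if (is.matrix(items) || is.data.frame(items)) {
    items <- as.matrix(items)
    stopifnot(ncol(items) == 8)
    bad <- !is.na(items) & (items < 1 | items > 7 | items != round(items))
    if (any(bad)) stop("items must be integers in [1, 7]")
    return(ifelse(rowSums(is.na(items)) > 0, NA_real_, rowMeans(items)))
  }
  stopifnot(length(items) == 8)
  if (anyNA(items)) return(NA_real_)
  if (any(items < 1 | items > 7 | items != round(items)))
    stop("items must be integers in [1, 7]")
  mean(items)
}

PASSIVE_FEATURES <- c("distance_km", "n_gps_points", "minutes_home",
                      "minutes_transition", "minutes_stationary",
                      "steps",
                      "act_walking", "act_running", "act_cycling",
                      "act_sleep", "act_rest", "act_active",
                      "hr_mean", "hr_min", "hr_max", "hr_std",
                      "hr_zone_resting", "hr_zone_moderate",
                      "hr_zone_vigorous")

CONTEXT_FEATURES <- c("assessment_hour", "time_of_day", "weekday", "weekend",
                      "season", "month", "temp_avg", "sunshine_h",
                      "precipitation_h")

PS_FEATURES <- c("age", "employable", "smartphone_type", "somatic_problems",
                 "psychotropic_medication", "prior_treatment")

#' Calendar/context features for beep timestamps
#'
#' Assessment hour and derived bins (local time under the fixed-offset
#' convention), weekday/weekend, meteorological season, month, and daily
#' weather joined on the beep's local calendar date. Time-of-day bins:
#' early morning 05-09, morning 09-12, afternoon 12-18, evening 18-23,
#' night 23-05.
#'
#' @param timestamps `POSIXct` beep times (UTC).
#' @param weather daily table with `date`, `temp_avg`, `sunshine_h`,
#'   `precipitation_h` (single-site convention: one table for everyone).
#' @param tz_offset_h fixed local-time offset from UTC (default +1).
#' @return data.frame of context features, one row per timestamp.
#' @export
context_features <- function(timestamps, weather, tz_offset_h = 1) {
  lt <- local_time(timestamps, tz_offset_h)
  hour <- as.integer(format(lt, "%H", tz = "UTC"))
  tod <- cut(hour, breaks = c(-1, 4, 8, 11, 17, 22, 24),
             labels = c("night", "early_morning", "morning", "afternoon",
                        "evening", "night2"))
  tod <- as.character(tod)
  tod[tod == "night2"] <- "night"
  wd <- format(lt, "%u", tz = "UTC")  # 1 = Monday
  weekday <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[as.integer(wd)]
  month <- as.integer(format(lt, "%m", tz = "UTC"))
  season <- c("winter", "winter", "spring", "spring", "spring", "summer",
              "summer", "summer", "fall", "fall", "fall", "winter")[month]
  date <- as.Date(lt, tz = "UTC")
  wrow <- match(date, weather$date)
  data.frame(assessment_hour = hour,
             time_of_day = factor(tod, levels = c("early_morning", "morning",
                                                  "afternoon", "evening",
                                                  "night")),
             weekday = factor(weekday, levels = c("Mon", "Tue", "Wed", "Thu",
                                                  "Fri", "Sat", "Sun")),
             weekend = weekday %in% c("Sat", "Sun"),
             season = factor(season, levels = c("spring", "summer", "fall",
                                                "winter")),
             month = month,
             temp_avg = weather$temp_avg[wrow],
             sunshine_h = weather$sunshine_h[wrow],
             precipitation_h = weather$precipitation_h[wrow])
}

#' Build per-beep blocks from a cohort's raw streams
#'
#' Runs the full preprocessing chain per participant: cleaning of the
#' wearable streams, GPS movement annotation, dwell attribution,
#' density-based clustering of stationary points (only when the participant
#' has at least `min_gps_points` points; below that, GPS features stay
#' missing and the inclusion filter later removes the participant), home
#' detection, then per-beep aggregation of all 19 passive features over the
#' half-open 2-h window before each beep, plus the NA label and context.
#'
#' @param bundle a `cohort_bundle` (typically after [inject_missingness()]).
#' @param min_gps_points minimum total GPS points for clustering (default
#'   50).
#' @return data.frame of blocks: ids, `timestamp`, `na_score`, `answered`,
#'   `travelling_flag`, the 19 passive features, context features, and
#'   missingness flags (`missing_hr`, `missing_steps`, `missing_activity`,
#'   `watch_off`, `missing_gps`, `home_is_fallback`, `n_gps_total`).
#' @export
build_blocks <- function(bundle, min_gps_points = 50) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  cfg <- bundle$config
  rows <- list()
  for (pid in names(bundle$streams)) {
    s <- bundle$streams[[pid]]
    hr <- clean_hr(s$hr)
    steps <- clean_steps(s$steps)
    activity <- clean_activity(s$activity)
    gps <- s$gps[order(as_utc(s$gps$timestamp)), , drop = FALSE]
    n_gps <- nrow(gps)
    gps <- annotate_movement(gps)
    gps <- attribute_dwell(gps)
    cs <- cluster_stationary(gps[gps$stationary, , drop = FALSE],
                             n_total_points = max(n_gps, 1))
    if (n_gps >= min_gps_points && nrow(cs$centroids) > 0) {
      cs <- find_home(cs, gps, tz_offset_h = cfg$tz_offset_h)
    }
    bp <- bundle$beeps[bundle$beeps$participant_id == pid, , drop = FALSE]
    feats <- lapply(seq_len(nrow(bp)), function(r) {
      w <- block_window(bp$timestamp[r], hours = cfg$beep_interval_h %||% 2)
      cbind(wearable_block_features(hr, steps, activity, w),
            mobility_features(gps, cs, w))
    })
    feats <- do.call(rbind, feats)
    items <- as.matrix(bp[, grep("^item_", names(bp)), drop = FALSE])
    rows[[pid]] <- cbind(
      data.frame(participant_id = pid, beep_id = bp$beep_id,
                 timestamp = bp$timestamp,
                 na_score = ifelse(bp$answered, rowMeans(items), NA_real_),
                 answered = bp$answered,
                 travelling_flag = bp$travelling_flag,
                 home_is_fallback = cs$home_is_fallback,
                 n_gps_total = n_gps,
                 stringsAsFactors = FALSE),
      feats)
  }
  blocks <- do.call(rbind, rows)
  rownames(blocks) <- NULL
  ctx <- context_features(blocks$timestamp, bundle$weather,
                          tz_offset_h = cfg$tz_offset_h)
  cbind(blocks, ctx)
}

#' Apply the structural-zero versus MCAR missingness policy
#'
#' Event-based features absent because no event happened get a structural
#' fill: 0 for distance travelled, number of GPS points, minutes in
#' transition, steps and all activity minutes; 120 for minutes at home and
#' minutes stationary (no location change in the block means the whole
#' block was spent at the last known place). Absences that indicate device
#' non-wear or technical failure are instead marked missing completely at
#' random (MCAR) for later in-fold imputation: all five GPS cells when GPS
#' is absent while the participant reported travelling in the last 2 h; all
#' 14 wearable cells when the watch was off (HR, steps and activity all
#' absent); the 7 HR cells when HR alone is absent (HR is sampled on a
#' grid, never event-based). The two mechanisms are disjoint by
#' construction: a structurally filled cell is never in the MCAR mask.
#'
#' @param blocks a [build_blocks()] data.frame.
#' @return list with `blocks` (features filled where structural) and
#'   `mcar_mask` (logical matrix, rows = blocks, cols = the 19 passive
#'   features; TRUE = impute).
#' @export
apply_missingness_policy <- function(blocks) {
  gps_cols <- c("distance_km", "n_gps_points", "minutes_home",
                "minutes_transition", "minutes_stationary")
  hr_cols <- c("hr_mean", "hr_min", "hr_max", "hr_std", "hr_zone_resting",
               "hr_zone_moderate", "hr_zone_vigorous")
  act_cols <- grep("^act_", PASSIVE_FEATURES, value = TRUE)
  mask <- matrix(FALSE, nrow(blocks), length(PASSIVE_FEATURES),
                 dimnames = list(NULL, PASSIVE_FEATURES))

  for (r in seq_len(nrow(blocks))) {
    if (isTRUE(blocks$missing_gps[r])) {
      if (isTRUE(blocks$travelling_flag[r])) {
        mask[r, gps_cols] <- TRUE
      } else {
        blocks[r, c("distance_km", "n_gps_points", "minutes_transition")] <- 0
        blocks[r, c("minutes_home", "minutes_stationary")] <- 120
      }
    } else if (is.na(blocks$minutes_home[r])) {
      # GPS present but no home cluster could be established
      mask[r, "minutes_home"] <- TRUE
    }
    if (isTRUE(blocks$watch_off[r])) {
      mask[r, c(hr_cols, "steps", act_cols)] <- TRUE
    } else {
      if (isTRUE(blocks$missing_hr[r])) mask[r, hr_cols] <- TRUE
      if (isTRUE(blocks$missing_steps[r])) blocks$steps[r] <- 0
      if (isTRUE(blocks$missing_activity[r])) blocks[r, act_cols] <- 0
    }
  }
  list(blocks = blocks, mcar_mask = mask)
}

#' Ordered participant inclusion filters
#'
#' Excludes participants, in this order: (1) fewer than `min_days` calendar
#' days with at least `min_beeps_per_day` answered beeps; (2) fewer than
#' `min_gps_points` total GPS points over the burst; (3) GPS missing while
#' travelling in more than half of their available (answered) blocks;
#' (4) after removing rows missing all passive features (watch off and GPS
#' absent), rule (1) re-checked. Returns the retained blocks and an ordered
#' exclusion log.
#'
#' @param blocks blocks from [build_blocks()] (policy not yet required).
#' @param min_days,min_beeps_per_day,min_gps_points,max_travel_missing_frac
#'   rule thresholds (defaults 7, 4, 50, 0.5).
#' @param tz_offset_h local-time offset used to define calendar days.
#' @return list with `blocks` (included participants, rows missing all
#'   passive features removed), `included` (ids), `exclusion_log`
#'   (data.frame `participant_id`, `reason`, `rule_order`).
#' @export
apply_inclusion_filters <- function(blocks, min_days = 7,
                                    min_beeps_per_day = 4,
                                    min_gps_points = 50,
                                    max_travel_missing_frac = 0.5,
                                    tz_offset_h = 1) {
  log <- list()
  exclude <- function(ids, reason, ord) {
    for (id in ids)
      log[[length(log) + 1]] <<- data.frame(participant_id = id,
                                            reason = reason,
                                            rule_order = ord,
                                            stringsAsFactors = FALSE)
  }
  days_ok <- function(bl) {
    ans <- bl[bl$answered & !is.na(bl$na_score), , drop = FALSE]
    if (nrow(ans) == 0) return(stats::setNames(logical(0), character(0)))
    ans$day <- local_date(ans$timestamp, tz_offset_h)
    tab <- table(ans$participant_id, ans$day)
    good_days <- rowSums(tab >= min_beeps_per_day)
    good_days >= min_days
  }

  # rule 1: enough answered beeps
  ok1 <- days_ok(blocks)
  all_ids <- unique(blocks$participant_id)
  fail1 <- setdiff(all_ids, names(ok1)[ok1])
  exclude(fail1, "beeps", 1L)
  blocks <- blocks[!blocks$participant_id %in% fail1, , drop = FALSE]

  # rule 2: enough GPS points over the burst
  gp <- tapply(blocks$n_gps_total, blocks$participant_id, max)
  fail2 <- names(gp)[gp < min_gps_points]
  exclude(fail2, "gps_count", 2L)
  blocks <- blocks[!blocks$participant_id %in% fail2, , drop = FALSE]

  # rule 3: travelling while GPS missing in too many available blocks
  avail <- blocks[blocks$answered, , drop = FALSE]
  frac <- tapply(avail$missing_gps & avail$travelling_flag,
                 avail$participant_id, mean)
  fail3 <- names(frac)[!is.na(frac) & frac > max_travel_missing_frac]
  exclude(fail3, "gps_mcar", 3L)
  blocks <- blocks[!blocks$participant_id %in% fail3, , drop = FALSE]

  # rule 4: drop rows missing all passive features, re-check rule 1
  all_missing <- blocks$watch_off & blocks$missing_gps
  blocks <- blocks[!all_missing, , drop = FALSE]
  ok4 <- days_ok(blocks)
  fail4 <- setdiff(unique(blocks$participant_id), names(ok4)[ok4])
  exclude(fail4, "beeps_after_row_removal", 4L)
  blocks <- blocks[!blocks$participant_id %in% fail4, , drop = FALSE]

  ex_log <- if (length(log)) do.call(rbind, log) else
    data.frame(participant_id = character(0), reason = character(0),
               rule_order = integer(0), stringsAsFactors = FALSE)
  list(blocks = blocks, included = unique(blocks$participant_id),
       exclusion_log = ex_log)
}

#' Assemble the model-ready dataset
#'
#' One row per answered beep with a complete label, canonically sorted by
#' (participant, timestamp). The feature matrix holds the 19 passive + 9
#' context time-varying features and, in the `with_PS` variant, the 6
#' person-stable features. The travelling flag is used only by the
#' missingness policy, never as a feature, keeping the predictor set
#' entirely passive.
#'
#' @param policy result of [apply_missingness_policy()] applied to filtered
#'   blocks.
#' @param participants person-stable data.frame.
#' @param variant `"passive_only"` or `"with_PS"`.
#' @return object of class `assembled_dataset`: list with `X` (data.frame),
#'   `y`, `groups`, `timestamp`, `mcar_mask` (over the passive numeric
#'   columns of `X`), `variant`, `feature_info`.
#' @export
assemble_dataset <- function(policy, participants,
                             variant = c("passive_only", "with_PS")) {
  variant <- match.arg(variant)
  blocks <- policy$blocks
  mask <- policy$mcar_mask
  keep <- blocks$answered & !is.na(blocks$na_score)
  blocks <- blocks[keep, , drop = FALSE]
  mask <- mask[keep, , drop = FALSE]
  if (anyDuplicated(blocks[, c("participant_id", "timestamp")]))
    stop("duplicate (participant, beep timestamp) rows")
  ord <- order(blocks$participant_id, blocks$timestamp)
  blocks <- blocks[ord, , drop = FALSE]
  mask <- mask[ord, , drop = FALSE]

  X <- blocks[, c(PASSIVE_FEATURES, CONTEXT_FEATURES), drop = FALSE]
  if (variant == "with_PS") {
    prow <- match(blocks$participant_id, participants$participant_id)
    X <- cbind(X, participants[prow, PS_FEATURES, drop = FALSE])
  }
  rownames(X) <- NULL
  out <- list(X = X, y = blocks$na_score,
              groups = blocks$participant_id,
              timestamp = blocks$timestamp,
              mcar_mask = mask, variant = variant,
              feature_info = list(passive = PASSIVE_FEATURES,
                                  context = CONTEXT_FEATURES,
                                  ps = if (variant == "with_PS") PS_FEATURES
                                       else character(0)))
  class(out) <- "assembled_dataset"
  out
}

#' @export
print.assembled_dataset <- function(x, ...) {
  cat("<assembled_dataset> ", length(x$y), " rows, ",
      ncol(x$X), " features (", x$variant, "), ",
      length(unique(x$groups)), " participants\n", sep = "")
  invisible(x)
}

#' Simulate a model-ready dataset directly from the mixed model
#'
#' Draws `(X, y, groups)` straight from
#' `y = mu + b_i + f(X) + eps` without sensor emission: features are
#' independent standard normals, `f` is linear (`X %*% beta`) or a smooth
#' nonlinear function of the first features, `b_i ~ N(0, sigma_b^2)` and
#' `eps ~ N(0, sigma_eps^2)` i.i.d. Used for parameter-recovery and
#' benchmark-calibration checks, where closed forms require continuous
#' (un-gridded) labels; the full cohort generator is the fidelity path.
#'
#' @param n_participants,n_per_person cohort shape.
#' @param n_features number of features (columns of `X`).
#' @param beta numeric effect vector (recycled/padded to `n_features`).
#' @param mu,sigma_b,sigma_eps mixed-model parameters.
#' @param nonlinear if TRUE, `f(X) = beta_scale * (sin(pi x1) + x2^2 - 1)`
#'   style smooth signal instead of a linear one.
#' @param beta_scale scale of the nonlinear signal.
#' @param seed RNG seed.
#' @return `assembled_dataset` (numeric features, empty MCAR mask) with the
#'   ground truth attached as attribute `truth` (list `b`, `f_values`).
#' @export
simulate_modeling_dataset <- function(n_participants, n_per_person,
                                      n_features = 5, beta = numeric(0),
                                      mu = 0, sigma_b = 1, sigma_eps = 0.5,
                                      nonlinear = FALSE, beta_scale = 1,
                                      seed = 1L) {
  set.seed(seed)
  n <- n_participants * n_per_person
  ids <- rep(sprintf("P%03d", seq_len(n_participants)), each = n_per_person)
  X <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(NULL, paste0("x", seq_len(n_features))))
  f <- if (nonlinear) {
    beta_scale * (sin(pi * X[, 1]) + 0.5 * X[, 2]^2 - 0.5 +
                    if (n_features >= 3) 0.5 * X[, 3] else 0)
  } else if (length(beta)) {
    as.numeric(X[, seq_along(beta), drop = FALSE] %*% beta)
  } else 0
  b <- rnorm(n_participants, 0, sigma_b)
  names(b) <- unique(ids)
  y <- mu + b[ids] + f + rnorm(n, 0, sigma_eps)
  ts <- as_utc("2025-03-02 08:00:00") +
    rep(seq_len(n_per_person) * 7200, times = n_participants)
  out <- list(X = as.data.frame(X), y = y, groups = ids, timestamp = ts,
              mcar_mask = matrix(FALSE, n, n_features,
                                 dimnames = list(NULL, colnames(X))),
              variant = "passive_only",
              feature_info = list(passive = colnames(X),
                                  context = character(0), ps = character(0)))
  class(out) <- "assembled_dataset"
  attr(out, "truth") <- list(b = b, f_values = f + mu)
  out
}
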