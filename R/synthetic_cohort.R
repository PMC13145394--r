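#' Configuration for the synthetic EMA + sensing cohort
#'
#' Defines the generative model for a cohort of participants observed over a
#' 14-day EMA burst with passive sensing. Labels follow a random-intercept
#' model on the 1-7 negative-affect (NA) scale:
#' `latent = mu + b_i + sum_f beta_f * z_f(window) + circadian(t) + eps_t`,
#' with `b_i ~ N(0, sigma_b^2)`, AR(1) residuals `eps_t` with stationary SD
#' `sigma_eps` and lag-1 autocorrelation `rho`, and `z_f` the cohort-
#' standardized true feature value in the 2-h window before the beep. The
#' observed score is the mean of eight 1-7 Likert items, each obtained by
#' rounding `latent + N(0, sigma_item^2)` and clamping to 1-7, so labels live
#' on the 1/8 grid and inherit the discreteness and mild right skew of real
#' EMA scores.
#'
#' Defaults emulate a clinical outpatient cohort: grand mean 2.89 with total
#' SD near 1.09, split into between-person (`sigma_b = 0.8`) and
#' within-person (`sigma_eps = 0.7`) components (ICC about .57).
#'
#' @param n_participants number of participants (> 0).
#' @param n_days study days (default 14).
#' @param beeps_per_day EMA prompts per day (default 8).
#' @param beep_interval_h spacing between prompts in hours (default 2), with
#'   uniform jitter of +/- 0.5 h per prompt.
#' @param mu grand-mean NA on the 1-7 scale.
#' @param sigma_b SD of person intercepts (>= 0).
#' @param sigma_eps stationary SD of the AR(1) residual (>= 0).
#' @param rho lag-1 autocorrelation of residuals, in `[0, 1)`.
#' @param beta named numeric vector mapping true-feature names (subset of
#'   `minutes_home`, `minutes_transition`, `minutes_stationary`,
#'   `distance_km`, `steps`, `hr_mean`) to standardized effect weights.
#' @param sigma_item SD of item-level deviation around the latent beep score
#'   before rounding (default 0.9); 0 makes all eight items identical.
#' @param circadian_amp amplitude of a single time-of-day sinusoid (default
#'   0; the functional form is a modeling convenience, not an empirical
#'   claim).
#' @param p_skip_beep probability a beep goes unanswered.
#' @param p_watch_off probability per block that all wearable streams are
#'   absent (watch not worn).
#' @param p_gps_drop probability per block that GPS is absent despite the
#'   phone being carried.
#' @param tz_offset_h fixed local-time offset from UTC (default +1, Berlin).
#' @param start_date first study day (local), ISO date string.
#' @param seed integer RNG seed; a fixed seed gives byte-identical cohorts
#'   (R's default Mersenne-Twister generator).
#' @return validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants,
                             n_days = 14,
                             beeps_per_day = 8,
                             beep_interval_h = 2,
                             mu = 2.89,
                             sigma_b = 0.8,
                             sigma_eps = 0.7,
                             rho = 0.3,
                             beta = numeric(0),
                             sigma_item = 0.9,
                             circadian_amp = 0,
                             p_skip_beep = 0.2,
                             p_watch_off = 0.1,
                             p_gps_drop = 0.05,
                             tz_offset_h = 1,
                             start_date = "2025-03-02",
                             seed = 1L) {
  stopifnot(is.numeric(n_participants), length(n_participants) == 1)
  if (n_participants < 1) stop("n_participants must be positive")
  if (n_days * beeps_per_day < 1) stop("need at least one beep")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (sigma_b < 0 || sigma_eps < 0 || sigma_item < 0)
    stop("variance components must be non-negative")
  probs <- c(p_skip_beep = p_skip_beep, p_watch_off = p_watch_off,
             p_gps_drop = p_gps_drop)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  allowed <- c("minutes_home", "minutes_transition", "minutes_stationary",
               "distance_km", "steps", "hr_mean")
  if (length(beta) && !all(names(beta) %in% allowed))
    stop("beta names must be among: ", paste(allowed, collapse = ", "))
  out <- list(n_participants = as.integer(n_participants),
              n_days = as.integer(n_days),
              beeps_per_day = as.integer(beeps_per_day),
              beep_interval_h = beep_interval_h, mu = mu,
              sigma_b = sigma_b, sigma_eps = sigma_eps, rho = rho,
              beta = beta, sigma_item = sigma_item,
              circadian_amp = circadian_amp,
              p_skip_beep = p_skip_beep, p_watch_off = p_watch_off,
              p_gps_drop = p_gps_drop, tz_offset_h = tz_offset_h,
              start_date = start_date, seed = as.integer(seed))
  class(out) <- "synthetic_config"
  out
}

# ---- internal timeline machinery ------------------------------------------

# Move d meters from (lat, lon) along a bearing (radians); equirectangular
# step, adequate at the <10 km scale of a daily excursion.
offset_latlon <- function(lat, lon, d_m, bearing) {
  dlat <- d_m * cos(bearing) / 111320
  dlon <- d_m * sin(bearing) / (111320 * cos(lat * pi / 180))
  c(lat + dlat, lon + dlon)
}

# Daily segment plan for one participant: alternating home stays, transits
# and away stays. Returns a data.frame of segments covering the whole study.
make_timeline <- function(home, anchors, study_start, n_days, tz_offset_h) {
  segs <- list()
  day0 <- as_utc(study_start) - tz_offset_h * 3600  # local midnight in UTC
  for (d in seq_len(n_days)) {
    day_start <- day0 + (d - 1) * 86400
    n_exc <- sample(0:2, 1, prob = c(0.25, 0.5, 0.25))
    cursor <- day_start
    day_end <- day_start + 86400
    if (n_exc > 0) {
      departs <- sort(runif(n_exc, 8.5, 17)) * 3600 + as.numeric(day_start)
      for (k in seq_len(n_exc)) {
        dep <- as_utc(departs[k])
        if (dep <= cursor + 600) next
        a <- anchors[sample(nrow(anchors), 1), ]
        dist_m <- haversine_m(home[1], home[2], a$lat, a$lon)
        speed <- if (dist_m < 1500) runif(1, 1.3, 1.7) else runif(1, 6, 10)
        mode <- if (speed < 2) "walk" else "vehicle"
        travel_s <- dist_m / speed
        stay_s <- runif(1, 45, 150) * 60
        back_at <- dep + 2 * travel_s + stay_s
        if (as.numeric(back_at) > as.numeric(day_end) - 3600) next
        segs[[length(segs) + 1]] <- data.frame(
          start = cursor, end = dep, type = "home",
          lat = home[1], lon = home[2], lat2 = NA, lon2 = NA,
          speed_mps = 0, mode = "stay")
        segs[[length(segs) + 1]] <- data.frame(
          start = dep, end = dep + travel_s, type = "transit",
          lat = home[1], lon = home[2], lat2 = a$lat, lon2 = a$lon,
          speed_mps = speed, mode = mode)
        segs[[length(segs) + 1]] <- data.frame(
          start = dep + travel_s, end = dep + travel_s + stay_s,
          type = "away", lat = a$lat, lon = a$lon, lat2 = NA, lon2 = NA,
          speed_mps = 0, mode = "stay")
        segs[[length(segs) + 1]] <- data.frame(
          start = dep + travel_s + stay_s, end = back_at, type = "transit",
          lat = a$lat, lon = a$lon, lat2 = home[1], lon2 = home[2],
          speed_mps = speed, mode = mode)
        cursor <- back_at
      }
    }
    segs[[length(segs) + 1]] <- data.frame(
      start = cursor, end = day_end, type = "home",
      lat = home[1], lon = home[2], lat2 = NA, lon2 = NA,
      speed_mps = 0, mode = "stay")
  }
  out <- do.call(rbind, segs)
  out$start <- as_utc(out$start); out$end <- as_utc(out$end)
  out[order(out$start), ]
}

#' Emit an event-based GPS trace from a segment plan
#'
#' Mimics an operating system that records a point whenever a location
#' change is detected: during transit segments, points are emitted every
#' 30-90 s along the (short-range) straight path; during stays, sparse
#' check-ins are emitted every 15-45 min by day and every 40-80 min by night
#' (local 20:00-06:00), each with small Gaussian positional jitter.
#'
#' @param segments data.frame of movement segments with columns `start`,
#'   `end`, `type` (`home`/`away`/`transit`), `lat`, `lon`, `lat2`, `lon2`,
#'   `speed_mps` (as produced by the cohort generator; a single stay segment
#'   suffices for a participant who never moves).
#' @param jitter_m SD of positional jitter in meters (default 8).
#' @param tz_offset_h local-time offset used for the day/night check-in
#'   cadence.
#' @return data.frame `timestamp`, `lat`, `lon`, time-sorted.
#' @export
generate_gps_trace <- function(segments, jitter_m = 8, tz_offset_h = 1) {
  stopifnot(all(abs(segments$lat) <= 90), all(abs(segments$lon) <= 180))
  pts <- list()
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    dur <- as.numeric(s$end) - as.numeric(s$start)
    if (dur <= 0) next
    if (s$type == "transit") {
      t <- as.numeric(s$start)
      times <- c()
      while (t < as.numeric(s$end)) {
        times <- c(times, t)
        t <- t + runif(1, 30, 90)
      }
      frac <- (times - as.numeric(s$start)) / dur
      lat <- s$lat + frac * (s$lat2 - s$lat)
      lon <- s$lon + frac * (s$lon2 - s$lon)
    } else {
      t <- as.numeric(s$start) + runif(1, 0, 120)
      times <- c()
      while (t < as.numeric(s$end)) {
        times <- c(times, t)
        h <- local_hour(as_utc(t), tz_offset_h)
        gap <- if (h >= 20 || h < 6) runif(1, 40, 80) else runif(1, 15, 45)
        t <- t + gap * 60
      }
      lat <- rep(s$lat, length(times)); lon <- rep(s$lon, length(times))
    }
    if (!length(times)) next
    jlat <- rnorm(length(times), 0, jitter_m) / 111320
    jlon <- rnorm(length(times), 0, jitter_m) /
      (111320 * cos(s$lat * pi / 180))
    pts[[length(pts) + 1]] <- data.frame(timestamp = as_utc(times),
                                         lat = lat + jlat, lon = lon + jlon)
  }
  if (!length(pts))
    return(data.frame(timestamp = as_utc(numeric(0)), lat = numeric(0),
                      lon = numeric(0)))
  out <- do.call(rbind, pts)
  out[order(out$timestamp), ]
}

# True (noise-free) block features from the segment plan + step events.
true_block_features <- function(segments, step_events, hr_rest, windows,
                                tz_offset_h) {
  n <- length(windows)
  out <- data.frame(minutes_home = numeric(n), minutes_transition = numeric(n),
                    minutes_stationary = numeric(n), distance_km = numeric(n),
                    steps = numeric(n), hr_mean = numeric(n))
  seg_start <- as_utc(segments$start); seg_end <- as_utc(segments$end)
  # per-segment expected heart rate above rest
  hr_off <- ifelse(segments$type == "transit",
                   ifelse(segments$mode == "walk", 30, 8),
                   ifelse(segments$type == "away", 4, 0))
  for (j in seq_len(n)) {
    w <- windows[[j]]
    ov_min <- overlap_seconds(seg_start, seg_end, w) / 60
    out$minutes_home[j] <- sum(ov_min[segments$type == "home"])
    out$minutes_transition[j] <- sum(ov_min[segments$type == "transit"])
    out$minutes_stationary[j] <- sum(ov_min[segments$type != "transit"])
    out$distance_km[j] <- sum(ov_min[segments$type == "transit"] * 60 *
                                segments$speed_mps[segments$type == "transit"]) / 1000
    out$steps[j] <- if (nrow(step_events))
      aggregate_overlap(step_events, w, step_events$steps) else 0
    tot <- sum(ov_min)
    out$hr_mean[j] <- hr_rest +
      if (tot > 0) sum(ov_min * hr_off) / tot else 0
  }
  out
}

# ---- cohort generation ----------------------------------------------------

#' Generate a synthetic cohort with known ground truth
#'
#' Builds, for each participant: a person-stable record, a home plus a small
#' set of "away" anchor locations, a daily movement timeline, event-based
#' sensor streams emitted from that timeline (GPS trace, 10-min heart-rate
#' samples, step events, activity events), an EMA beep schedule, and NA
#' labels drawn from the configured random-intercept model. The full ground
#' truth (person intercepts, effect weights, latent labels, true window
#' features, movement indicator per block) is recorded so downstream stages
#' can be validated against it. Deterministic for a fixed `config$seed`.
#'
#' The returned bundle is fully observed; apply [inject_missingness()] to
#' obtain the skipped-beep / watch-off / GPS-dropout mechanisms.
#'
#' @param config a [synthetic_config()].
#' @return object of class `cohort_bundle`: list with `config`,
#'   `participants` (person-stable data.frame), `streams` (per-participant
#'   list of `gps`, `hr`, `steps`, `activity` data.frames), `beeps`
#'   (data.frame with 8 item columns, `travelling_flag`, `answered`),
#'   `weather` (daily table), `truth` (ground truth), `missing_log` (empty
#'   until missingness is injected).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cfg <- config
  ids <- sprintf("P%03d", seq_len(cfg$n_participants))
  study_start <- as_utc(paste(cfg$start_date, "00:00:00"))

  participants <- data.frame(
    participant_id = ids,
    age = round(runif(cfg$n_participants, 18, 65)),
    employable = runif(cfg$n_participants) < 0.8,
    smartphone_type = sample(c("iPhone", "Android"), cfg$n_participants,
                             replace = TRUE, prob = c(0.55, 0.45)),
    somatic_problems = runif(cfg$n_participants) < 0.45,
    psychotropic_medication = runif(cfg$n_participants) < 0.35,
    prior_treatment = sample(c("none", "outpatient", "inpatient"),
                             cfg$n_participants, replace = TRUE,
                             prob = c(0.36, 0.36, 0.28)),
    stringsAsFactors = FALSE)

  b_i <- rnorm(cfg$n_participants, 0, cfg$sigma_b)
  names(b_i) <- ids

  streams <- vector("list", cfg$n_participants)
  names(streams) <- ids
  beep_list <- list()
  truth_feat <- list()
  timelines <- vector("list", cfg$n_participants)
  hr_rest_all <- round(rnorm(cfg$n_participants, 65, 5))
  n_beeps <- cfg$n_days * cfg$beeps_per_day

  for (i in seq_len(cfg$n_participants)) {
    home <- c(52.52 + rnorm(1, 0, 0.03), 13.41 + rnorm(1, 0, 0.05))
    n_anchor <- sample(2:4, 1)
    anchors <- do.call(rbind, lapply(seq_len(n_anchor), function(k) {
      p <- offset_latlon(home[1], home[2], runif(1, 400, 4000),
                         runif(1, 0, 2 * pi))
      data.frame(lat = p[1], lon = p[2])
    }))
    tl <- make_timeline(home, anchors, study_start, cfg$n_days,
                        cfg$tz_offset_h)
    timelines[[i]] <- tl

    # beep schedule: beeps_per_day prompts starting 08:00 local, spaced
    # beep_interval_h apart, each jittered uniformly by +/- 0.5 h
    beep_times <- as_utc(unlist(lapply(seq_len(cfg$n_days), function(d) {
      base_h <- 8 + (seq_len(cfg$beeps_per_day) - 1) * cfg$beep_interval_h
      h <- base_h + runif(cfg$beeps_per_day, -0.5, 0.5)
      as.numeric(study_start) + (d - 1) * 86400 +
        (h - cfg$tz_offset_h) * 3600
    })))

    # sensor emission
    gps <- generate_gps_trace(tl, tz_offset_h = cfg$tz_offset_h)
    hr_t <- seq(as.numeric(study_start), by = 600,
                length.out = cfg$n_days * 144)
    seg_idx <- findInterval(hr_t, as.numeric(tl$start))
    seg_idx[seg_idx < 1] <- 1
    type <- tl$type[seg_idx]; mode <- tl$mode[seg_idx]
    lh <- local_hour(as_utc(hr_t), cfg$tz_offset_h)
    asleep <- type == "home" & (lh >= 23 | lh < 7)
    bpm <- hr_rest_all[i] +
      ifelse(type == "transit", ifelse(mode == "walk", 30, 8),
             ifelse(type == "away", 4, 0)) -
      ifelse(asleep, 8, 0) + rnorm(length(hr_t), 0, 3)
    hr <- data.frame(timestamp = as_utc(hr_t),
                     bpm = pmin(185, pmax(35, round(bpm))))

    # step events: walking transits plus short home bouts
    st <- list()
    walk <- tl[tl$type == "transit" & tl$mode == "walk", , drop = FALSE]
    if (nrow(walk)) {
      dur_min <- as.numeric(walk$end - walk$start, units = "mins")
      st[[1]] <- data.frame(start = walk$start, end = walk$end,
                            steps = round(105 * dur_min *
                                            runif(nrow(walk), 0.95, 1.05)))
    }
    bouts <- list()
    for (d in seq_len(cfg$n_days)) {
      nb <- sample(2:5, 1)
      t0 <- as.numeric(study_start) + (d - 1) * 86400 +
        runif(nb, 7.5, 21.5) * 3600
      dur <- runif(nb, 2, 6) * 60
      bouts[[d]] <- data.frame(start = as_utc(t0), end = as_utc(t0 + dur),
                               steps = round(70 * dur / 60))
    }
    st[[length(st) + 1]] <- do.call(rbind, bouts)
    steps_ev <- do.call(rbind, st)
    steps_ev <- steps_ev[order(steps_ev$start), ]

    # activity events: nightly sleep, walking bouts/transits, vehicle
    # transits as "active", stays as "rest"
    act <- list()
    for (d in seq_len(cfg$n_days)) {
      s0 <- as.numeric(study_start) + (d - 1) * 86400 + (23 - cfg$tz_offset_h) * 3600
      act[[length(act) + 1]] <- data.frame(
        start = as_utc(s0), end = as_utc(s0 + 8 * 3600),
        category = "sleep", flag = TRUE)
    }
    if (nrow(walk))
      act[[length(act) + 1]] <- data.frame(start = walk$start, end = walk$end,
                                           category = "walking", flag = TRUE)
    bt <- do.call(rbind, bouts)
    act[[length(act) + 1]] <- data.frame(start = bt$start, end = bt$end,
                                         category = "walking", flag = TRUE)
    veh <- tl[tl$type == "transit" & tl$mode == "vehicle", , drop = FALSE]
    if (nrow(veh))
      act[[length(act) + 1]] <- data.frame(start = veh$start, end = veh$end,
                                           category = "active", flag = TRUE)
    stays <- tl[tl$type == "away", , drop = FALSE]
    if (nrow(stays))
      act[[length(act) + 1]] <- data.frame(start = stays$start,
                                           end = stays$end,
                                           category = "rest", flag = TRUE)
    activity <- do.call(rbind, act)
    activity <- activity[order(activity$start), ]

    streams[[i]] <- list(gps = gps, hr = hr, steps = steps_ev,
                         activity = activity)

    windows <- lapply(beep_times, block_window)
    tf <- true_block_features(tl, steps_ev, hr_rest_all[i], windows,
                              cfg$tz_offset_h)
    tf$participant_id <- ids[i]
    tf$beep_id <- seq_len(n_beeps)
    truth_feat[[i]] <- tf
    beep_list[[i]] <- data.frame(participant_id = ids[i],
                                 beep_id = seq_len(n_beeps),
                                 timestamp = beep_times,
                                 stringsAsFactors = FALSE)
  }

  truth_feat <- do.call(rbind, truth_feat)
  beeps <- do.call(rbind, beep_list)

  # standardized true features -> latent labels
  feat_names <- c("minutes_home", "minutes_transition", "minutes_stationary",
                  "distance_km", "steps", "hr_mean")
  z <- scale(as.matrix(truth_feat[, feat_names]))
  z[is.nan(z)] <- 0
  signal <- if (length(cfg$beta))
    as.numeric(z[, names(cfg$beta), drop = FALSE] %*% cfg$beta) else 0

  lh <- local_hour(beeps$timestamp, cfg$tz_offset_h)
  circ <- cfg$circadian_amp * sin(2 * pi * (lh - 8) / 24)

  eps <- unlist(lapply(split(seq_len(nrow(beeps)), beeps$participant_id),
                       function(rows) {
    m <- length(rows)
    e <- numeric(m)
    e[1] <- rnorm(1, 0, cfg$sigma_eps)
    if (m > 1) {
      innov <- rnorm(m - 1, 0, cfg$sigma_eps * sqrt(1 - cfg$rho^2))
      for (t in 2:m) e[t] <- cfg$rho * e[t - 1] + innov[t - 1]
    }
    e
  })[unique(beeps$participant_id)])

  latent <- cfg$mu + b_i[beeps$participant_id] + signal + circ + eps
  item_names <- c("downcast", "sad", "anxious", "nervous", "irritable",
                  "angry", "ashamed", "dissatisfied")
  items <- vapply(seq_along(item_names), function(j)
    pmin(7, pmax(1, round(latent + rnorm(length(latent), 0, cfg$sigma_item)))),
    numeric(nrow(beeps)))
  colnames(items) <- paste0("item_", item_names)
  beeps <- cbind(beeps, as.data.frame(items))
  beeps$travelling_flag <- truth_feat$minutes_transition > 0
  beeps$answered <- TRUE

  dates <- seq(as.Date(cfg$start_date), by = 1, length.out = cfg$n_days)
  yday <- as.integer(format(dates, "%j"))
  weather <- data.frame(
    date = dates,
    temp_avg = round(10 + 9 * sin(2 * pi * (yday - 105) / 365) +
                       rnorm(cfg$n_days, 0, 2.5), 1),
    sunshine_h = round(pmax(0, 6 + 4 * sin(2 * pi * (yday - 105) / 365) +
                              rnorm(cfg$n_days, 0, 2)), 1),
    precipitation_h = round(pmax(0, rnorm(cfg$n_days, 1.5, 2))))

  truth <- list(person_intercepts = b_i, beta = cfg$beta,
                latent_labels = data.frame(
                  participant_id = beeps$participant_id,
                  beep_id = beeps$beep_id, latent = latent,
                  moved_in_block = truth_feat$minutes_transition > 0),
                true_features = truth_feat,
                timelines = setNames(timelines, ids))

  out <- list(config = cfg, participants = participants, streams = streams,
              beeps = beeps, weather = weather, truth = truth,
              missing_log = data.frame(participant_id = character(0),
                                       beep_id = integer(0),
                                       mechanism = character(0),
                                       stringsAsFactors = FALSE))
  class(out) <- "cohort_bundle"
  out
}

#' NA label of a beep (mean of the eight items)
#'
#' @param bundle a `cohort_bundle`.
#' @return numeric vector of NA scores (NA for unanswered beeps).
#' @export
beep_na_scores <- function(bundle) {
  items <- as.matrix(bundle$beeps[, grep("^item_", names(bundle$beeps))])
  ifelse(bundle$beeps$answered, rowMeans(items), NA_real_)
}

#' Inject the cohort's missingness mechanisms
#'
#' Applies, independently per (participant, beep) block: with probability
#' `p_watch_off`, removal of all heart-rate samples in the block window and
#' all step/activity events overlapping it; with `p_gps_drop`, removal of
#' all GPS points in the window (the beep's travelling flag already records
#' whether movement was simulated); with `p_skip_beep`, removal of the
#' beep's items (beep unanswered). Ground-truth records are never touched;
#' every removal is appended to `missing_log`. Deterministic: seeded from
#' `config$seed + 8191`.
#'
#' @param bundle a fully populated `cohort_bundle`.
#' @param config a `synthetic_config`; defaults to `bundle$config`.
#' @return the modified `cohort_bundle`.
#' @export
inject_missingness <- function(bundle, config = bundle$config) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  cfg <- config
  set.seed(cfg$seed + 8191L)
  log <- list()
  item_cols <- grep("^item_", names(bundle$beeps))
  for (r in seq_len(nrow(bundle$beeps))) {
    pid <- bundle$beeps$participant_id[r]
    w <- block_window(bundle$beeps$timestamp[r])
    u <- runif(3)
    if (u[1] < cfg$p_watch_off) {
      s <- bundle$streams[[pid]]
      s$hr <- s$hr[!in_window(s$hr$timestamp, w), , drop = FALSE]
      drop_ev <- function(ev) ev[overlap_seconds(as_utc(ev$start),
                                                 as_utc(ev$end), w) <= 0, ,
                                 drop = FALSE]
      s$steps <- drop_ev(s$steps)
      s$activity <- drop_ev(s$activity)
      bundle$streams[[pid]] <- s
      log[[length(log) + 1]] <- data.frame(
        participant_id = pid, beep_id = bundle$beeps$beep_id[r],
        mechanism = "watch_off", stringsAsFactors = FALSE)
    }
    if (u[2] < cfg$p_gps_drop) {
      g <- bundle$streams[[pid]]$gps
      bundle$streams[[pid]]$gps <- g[!in_window(g$timestamp, w), ,
                                     drop = FALSE]
      log[[length(log) + 1]] <- data.frame(
        participant_id = pid, beep_id = bundle$beeps$beep_id[r],
        mechanism = "gps_drop", stringsAsFactors = FALSE)
    }
    if (u[3] < cfg$p_skip_beep) {
      bundle$beeps$answered[r] <- FALSE
      bundle$beeps[r, item_cols] <- NA_integer_
      log[[length(log) + 1]] <- data.frame(
        participant_id = pid, beep_id = bundle$beeps$beep_id[r],
        mechanism = "skip_beep", stringsAsFactors = FALSE)
    }
  }
  if (length(log))
    bundle$missing_log <- rbind(bundle$missing_log, do.call(rbind, log))
  bundle
}
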