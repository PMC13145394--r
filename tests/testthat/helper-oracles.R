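# Independent oracles and small fixture builders used across tests.

# Spherical law of cosines: an independent great-circle formula.
oracle_slc_m <- function(lat1, lon1, lat2, lon2, R = 6371000) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  arg <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  R * acos(pmin(1, pmax(-1, arg)))
}

# Brute-force DBSCAN written independently of the package implementation:
# explicit neighbor counting, iterative core expansion, border points joined
# to the cluster of their earliest-timestamp core neighbor. 0 = noise.
oracle_dbscan <- function(lat, lon, ts, eps_m, min_samples) {
  n <- length(lat)
  if (n == 0) return(list(labels = integer(0), core = logical(0)))
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    d <- oracle_hav(lat[i], lon[i], lat, lon)
    neigh[[i]] <- which(d <= eps_m)
  }
  core <- vapply(neigh, length, integer(1)) >= min_samples
  labels <- integer(n)
  cid <- 0L
  for (s in order(ts)) {
    if (!core[s] || labels[s] != 0L) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      p <- stack[[1]]; stack <- stack[-1]
      if (labels[p] != 0L) next
      labels[p] <- cid
      stack <- c(stack, Filter(function(q) core[q] && labels[q] == 0L,
                               neigh[[p]]))
    }
  }
  for (b in which(!core)) {
    cn <- Filter(function(q) core[q], neigh[[b]])
    if (length(cn)) labels[b] <- labels[cn[which.min(ts[cn])]]
  }
  list(labels = labels, core = core)
}

# plain haversine for the oracle's distances (kept local so the oracle does
# not call package internals)
oracle_hav <- function(lat1, lon1, lat2, lon2, R = 6371000) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  a <- sin((lat2 - lat1) * pi / 360)^2 +
    cos(p1) * cos(p2) * sin((lon2 - lon1) * pi / 360)^2
  2 * R * asin(sqrt(pmin(1, a)))
}

# Canonical form of a cluster labeling: relabel clusters by first appearance
# so two labelings can be compared up to permutation.
canonical_labels <- function(labels) {
  out <- integer(length(labels))
  map <- integer(0)
  nxt <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == 0L) next
    key <- as.character(labels[i])
    if (is.na(map[key] %||% NA)) {
      nxt <- nxt + 1L
      map[key] <- nxt
    }
    out[i] <- map[key]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# Build one row of a blocks data.frame (the build_blocks() output contract)
# with sensible defaults, for policy/filter tests.
toy_block <- function(participant_id, beep_id, timestamp,
                      na_score = 3, answered = TRUE,
                      travelling_flag = FALSE, missing_gps = FALSE,
                      missing_hr = FALSE, missing_steps = FALSE,
                      missing_activity = FALSE, watch_off = FALSE,
                      n_gps_total = 100) {
  hr <- if (missing_hr) NA_real_ else 70
  gps <- if (missing_gps) NA_real_ else 1
  df <- data.frame(
    participant_id = participant_id, beep_id = beep_id,
    timestamp = as_utc(timestamp), na_score = na_score, answered = answered,
    travelling_flag = travelling_flag, home_is_fallback = FALSE,
    n_gps_total = n_gps_total,
    distance_km = gps, n_gps_points = if (missing_gps) NA_real_ else 4,
    minutes_home = if (missing_gps) NA_real_ else 90,
    minutes_transition = if (missing_gps) NA_real_ else 10,
    minutes_stationary = if (missing_gps) NA_real_ else 100,
    steps = if (missing_steps) NA_real_ else 500,
    act_walking = if (missing_activity) NA_real_ else 10,
    act_running = if (missing_activity) NA_real_ else 0,
    act_cycling = if (missing_activity) NA_real_ else 0,
    act_sleep = if (missing_activity) NA_real_ else 0,
    act_rest = if (missing_activity) NA_real_ else 50,
    act_active = if (missing_activity) NA_real_ else 5,
    hr_mean = hr, hr_min = hr, hr_max = hr, hr_std = if (missing_hr) NA_real_ else 3,
    hr_zone_resting = if (missing_hr) NA_real_ else 60,
    hr_zone_moderate = if (missing_hr) NA_real_ else 60,
    hr_zone_vigorous = if (missing_hr) NA_real_ else 0,
    missing_hr = missing_hr, missing_steps = missing_steps,
    missing_activity = missing_activity, watch_off = watch_off,
    missing_gps = missing_gps,
    stringsAsFactors = FALSE)
  df
}

# attach context columns so toy blocks can flow into assemble_dataset()
with_context <- function(blocks) {
  wx <- data.frame(date = unique(as.Date(blocks$timestamp)),
                   temp_avg = 10, sunshine_h = 5, precipitation_h = 1)
  cbind(blocks, context_features(blocks$timestamp, wx))
}

# a stay-point trace: n points at (lat, lon) + jitter, one every `gap_min`
stay_trace <- function(n, lat, lon, start = "2025-03-03 08:00:00",
                       gap_min = 20, jitter_m = 5, seed = 1) {
  set.seed(seed)
  ts <- as_utc(start) + (seq_len(n) - 1) * gap_min * 60
  data.frame(timestamp = ts,
             lat = lat + rnorm(n, 0, jitter_m) / 111320,
             lon = lon + rnorm(n, 0, jitter_m) /
               (111320 * cos(lat * pi / 180)))
}
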