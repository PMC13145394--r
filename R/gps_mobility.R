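#' Great-circle distance between coordinate pairs (haversine)
#'
#' Distance in meters on a sphere of radius 6,371,000 m:
#' `2 R asin(sqrt(a))` with
#' `a = sin^2(dphi/2) + cos(phi1) cos(phi2) sin^2(dlambda/2)`.
#' The radius matches the clustering convention in which a 100 m radius is
#' expressed as the central angle `100/6371000`.
#'
#' Vectorized over all four arguments (usual recycling rules).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return numeric vector of distances in meters.
#' @export
#' @examples
#' haversine_m(52.521992, 13.413244, 52.521992, 13.413244) # 0
haversine_m <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE),
            all(abs(lon1) <= 180, na.rm = TRUE), all(abs(lon2) <= 180, na.rm = TRUE))
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

#' Annotate a GPS trace with movement state
#'
#' For each consecutive pair of points computes the great-circle distance,
#' elapsed time and speed, and classifies the later point as stationary when
#' its speed is strictly below walking speed (1.4 m/s) AND the distance to
#' the previous point is strictly below 150 m. The first point inherits the
#' label of the first pair. Pairs with zero elapsed time are flagged
#' degenerate and excluded from speed computation (speed `NA`); a degenerate
#' point keeps the previous point's movement state.
#'
#' @param points data.frame with columns `timestamp` (POSIXct/coercible),
#'   `lat`, `lon`, sorted by time.
#' @param speed_thresh_mps stationary speed threshold (default 1.4).
#' @param dist_thresh_m stationary distance threshold (default 150).
#' @return `points` with added columns `distance_m`, `dt_s`, `speed_mps`,
#'   `stationary`, `degenerate`.
#' @export
annotate_movement <- function(points, speed_thresh_mps = 1.4,
                              dist_thresh_m = 150) {
  stopifnot(all(c("timestamp", "lat", "lon") %in% names(points)))
  n <- nrow(points)
  points$timestamp <- as_utc(points$timestamp)
  if (n == 0) {
    points$distance_m <- numeric(0); points$dt_s <- numeric(0)
    points$speed_mps <- numeric(0); points$stationary <- logical(0)
    points$degenerate <- logical(0)
    return(points)
  }
  if (is.unsorted(points$timestamp)) stop("points must be time-sorted")
  dist <- c(NA_real_, haversine_m(points$lat[-n], points$lon[-n],
                                  points$lat[-1], points$lon[-1]))
  dt <- c(NA_real_, diff(as.numeric(points$timestamp)))
  degen <- !is.na(dt) & dt == 0
  speed <- ifelse(degen | is.na(dt), NA_real_, dist / dt)
  stationary <- !is.na(speed) & speed < speed_thresh_mps & dist < dist_thresh_m
  # first point inherits the first pair's label; degenerate points inherit
  # the previous point's state
  if (n >= 2) stationary[1] <- stationary[2]
  if (n == 1) stationary[1] <- TRUE
  for (i in seq_len(n)[-1]) {
    if (degen[i]) stationary[i] <- stationary[i - 1]
  }
  points$distance_m <- dist
  points$dt_s <- dt
  points$speed_mps <- speed
  points$stationary <- stationary
  points$degenerate <- degen
  points
}

#' Attribute dwell time to event-based GPS points
#'
#' Event-based traces emit a point only when the location changes, so the
#' time "represented" by a point is taken as the gap to the next point,
#' capped (default 30 min) so that a single point cannot claim hours of a
#' silent gap. The last point gets zero dwell.
#'
#' @param points time-sorted GPS data.frame with `timestamp`.
#' @param cap_min dwell cap in minutes.
#' @return `points` with added numeric column `dwell_min`.
#' @export
attribute_dwell <- function(points, cap_min = 30) {
  n <- nrow(points)
  points$timestamp <- as_utc(points$timestamp)
  if (n == 0) {
    points$dwell_min <- numeric(0)
    return(points)
  }
  gaps <- c(diff(as.numeric(points$timestamp)) / 60, 0)
  points$dwell_min <- pmin(gaps, cap_min)
  points
}

#' Density-based clustering of stationary GPS points
#'
#' DBSCAN over stationary points with great-circle distances expressed as
#' central angles in radians, so that `eps = 100/6371000` corresponds to a
#' 100 m neighborhood radius. `min_samples` is normalized to the person's
#' total number of GPS points: `max(2, ceiling(min_frac * n_total_points))`.
#' A point's eps-neighborhood includes the point itself.
#'
#' Clusters are the connected components of core points (core points within
#' eps of each other are connected); a border point (non-core with at least
#' one core neighbor) joins the cluster of its earliest-timestamp core
#' neighbor. This construction is invariant to input order up to cluster
#' relabeling; cluster ids are assigned by the earliest timestamp of any
#' member core point (id 1 = oldest).
#'
#' @param stationary_points data.frame with `timestamp`, `lat`, `lon` for the
#'   stationary points only.
#' @param n_total_points the person's total number of GPS points (the
#'   min_samples normalizer).
#' @param eps neighborhood radius as a central angle in radians
#'   (default `100/6371000`, i.e. 100 m).
#' @param min_frac fraction of total points defining `min_samples`
#'   (default 0.03).
#' @return object of class `cluster_set`: list with `assignments` (integer,
#'   0 = noise), `is_core` (logical), `min_samples_used`, `eps_used`,
#'   `centroids` (data.frame id/lat/lon/n_points), `home_id` (NA until
#'   [find_home()] is applied), `home_is_fallback`.
#' @export
cluster_stationary <- function(stationary_points, n_total_points,
                               eps = 100 / 6371000, min_frac = 0.03) {
  min_samples <- max(2L, as.integer(ceiling(min_frac * n_total_points)))
  n <- nrow(stationary_points)
  empty <- list(assignments = integer(n), is_core = logical(n),
                min_samples_used = min_samples, eps_used = eps,
                centroids = data.frame(id = integer(0), lat = numeric(0),
                                       lon = numeric(0), n_points = integer(0)),
                home_id = NA_integer_, home_is_fallback = FALSE)
  class(empty) <- "cluster_set"
  if (n == 0) return(empty)

  ts <- as.numeric(as_utc(stationary_points$timestamp))
  eps_m <- eps * EARTH_RADIUS_M
  # pairwise distance matrix; cohorts at burst scale keep n in the thousands
  lat <- stationary_points$lat; lon <- stationary_points$lon
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    haversine_m(lat[i], lon[i], lat[j], lon[j]))
  nb <- d <= eps_m          # neighborhood includes self (diagonal is 0)
  is_core <- rowSums(nb) >= min_samples

  assignments <- integer(n)  # 0 = noise
  if (any(is_core)) {
    # connected components of the core-core adjacency graph
    comp <- integer(n); comp[] <- 0L
    core_idx <- which(is_core)
    cid <- 0L
    for (s in core_idx[order(ts[core_idx])]) {
      if (comp[s] != 0L) next
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        reach <- which(nb[p, ] & is_core & comp == 0L)
        comp[reach] <- cid
        queue <- c(queue, reach)
      }
    }
    assignments[is_core] <- comp[is_core]
    # border points: earliest-timestamp core neighbor decides the cluster
    border <- which(!is_core)
    for (b in border) {
      cores_near <- which(nb[b, ] & is_core)
      if (length(cores_near)) {
        assignments[b] <- assignments[cores_near[which.min(ts[cores_near])]]
      }
    }
  }

  ids <- sort(unique(assignments[assignments > 0]))
  centroids <- do.call(rbind, lapply(ids, function(id) {
    m <- assignments == id
    data.frame(id = id, lat = mean(lat[m]), lon = mean(lon[m]),
               n_points = sum(m))
  }))
  if (is.null(centroids))
    centroids <- data.frame(id = integer(0), lat = numeric(0),
                            lon = numeric(0), n_points = integer(0))
  out <- list(assignments = assignments, is_core = is_core,
              min_samples_used = min_samples, eps_used = eps,
              centroids = centroids, home_id = NA_integer_,
              home_is_fallback = FALSE)
  class(out) <- "cluster_set"
  out
}

#' Detect the home cluster by night occupancy
#'
#' A night is the local-time interval 20:00 (day d) to 06:00 (day d+1); local
#' time is UTC plus a fixed configurable offset. A night counts toward a
#' cluster when the participant's maximal dwell within that night belongs to
#' the cluster (event-based traces rarely cover a full night, so the
#' dominant-dwell cluster stands in for "where the night was spent"). The
#' home cluster must hold at least `min_nights` nights AND at least
#' `min_night_frac` of all assessed nights (nights with any clustered
#' stationary dwell). If no cluster qualifies, the fallback is the most
#' frequently visited cluster, operationalized as greatest total dwell
#' minutes (ties: most member points, then lowest id).
#'
#' @param cluster_set a [cluster_stationary()] result for the stationary
#'   points in `points[points$stationary, ]`.
#' @param points the full annotated, dwell-attributed trace (all points, in
#'   time order) with columns `timestamp`, `stationary`, `dwell_min`.
#' @param tz_offset_h fixed local-time offset from UTC in hours (default +1).
#' @param min_nights minimum qualifying nights (default 4).
#' @param min_night_frac minimum share of assessed nights (default 0.5).
#' @return the `cluster_set` with `home_id`, `home_is_fallback` and a
#'   `night_counts` table filled in; `home_id` is `NA` when there are no
#'   clusters at all.
#' @export
find_home <- function(cluster_set, points, tz_offset_h = 1,
                      min_nights = 4, min_night_frac = 0.5) {
  cs <- cluster_set
  cs$night_counts <- integer(0)
  cs$n_assessed_nights <- 0L
  if (nrow(cs$centroids) == 0) {
    cs$home_id <- NA_integer_
    cs$home_is_fallback <- FALSE
    return(cs)
  }
  st <- points[points$stationary, , drop = FALSE]
  stopifnot(nrow(st) == length(cs$assignments))
  st$cluster <- cs$assignments
  st <- st[st$cluster > 0, , drop = FALSE]

  night_of <- function(ts) {
    # label each timestamp with the date whose 20:00 starts its night, or NA
    lt <- local_time(ts, tz_offset_h)
    h <- local_hour(ts, tz_offset_h)
    d <- as.Date(lt, tz = "UTC")
    out <- rep(as.Date(NA), length(ts))
    out[h >= 20] <- d[h >= 20]
    out[h < 6] <- d[h < 6] - 1
    out
  }

  home <- NA_integer_; fallback <- FALSE
  if (nrow(st) > 0) {
    st$night <- night_of(st$timestamp)
    nt <- st[!is.na(st$night), , drop = FALSE]
    if (nrow(nt) > 0) {
      dwell_by <- aggregate(dwell_min ~ night + cluster, data = nt, FUN = sum)
      nights <- split(dwell_by, dwell_by$night)
      winner <- vapply(nights, function(df) {
        df <- df[order(-df$dwell_min, df$cluster), , drop = FALSE]
        df$cluster[1]
      }, integer(1))
      n_assessed <- length(winner)
      counts <- table(factor(winner, levels = cs$centroids$id))
      cs$night_counts <- setNames(as.integer(counts), names(counts))
      cs$n_assessed_nights <- n_assessed
      qual <- cs$centroids$id[counts >= min_nights &
                                counts >= min_night_frac * n_assessed]
      if (length(qual)) {
        # most nights, then lowest id
        qc <- counts[as.character(qual)]
        home <- qual[order(-as.integer(qc), qual)][1]
      }
    }
  }
  if (is.na(home)) {
    # fallback: greatest total dwell; ties -> most points, then lowest id
    tot <- vapply(cs$centroids$id, function(id)
      sum(st$dwell_min[st$cluster == id]), numeric(1))
    ord <- order(-tot, -cs$centroids$n_points, cs$centroids$id)
    home <- cs$centroids$id[ord[1]]
    fallback <- TRUE
  }
  cs$home_id <- as.integer(home)
  cs$home_is_fallback <- fallback
  cs
}

#' Per-block GPS mobility features
#'
#' For the half-open 2-h window preceding a beep: distance travelled (km,
#' summed over consecutive in-window point pairs; the segment crossing the
#' window boundary is excluded), number of GPS points, and dwell-minute sums
#' for stationary, non-stationary (transition) and home-cluster points. Each
#' point's dwell is additionally clipped at the window end so that a block
#' cannot accumulate more minutes than it contains.
#'
#' @param points annotated + dwell-attributed full trace (time-sorted).
#' @param cluster_set a [find_home()]-completed cluster set for the trace's
#'   stationary points.
#' @param window a [block_window()] list.
#' @return one-row data.frame: `distance_km`, `n_gps_points`, `minutes_home`,
#'   `minutes_transition`, `minutes_stationary`, `missing_gps`. Numeric
#'   features are `NA` when no point falls in the window (`missing_gps`
#'   TRUE) .
#' @export
mobility_features <- function(points, cluster_set, window) {
  cluster_of <- rep(0L, nrow(points))
  if (nrow(points) > 0 && length(cluster_set$assignments) > 0) {
    cluster_of[points$stationary] <- cluster_set$assignments
  }
  inw <- in_window(as_utc(points$timestamp), window)
  if (!any(inw)) {
    return(data.frame(distance_km = NA_real_, n_gps_points = NA_real_,
                      minutes_home = NA_real_, minutes_transition = NA_real_,
                      minutes_stationary = NA_real_, missing_gps = TRUE))
  }
  p <- points[inw, , drop = FALSE]
  cl <- cluster_of[inw]
  n <- nrow(p)
  dist_km <- if (n >= 2) {
    sum(haversine_m(p$lat[-n], p$lon[-n], p$lat[-1], p$lon[-1])) / 1000
  } else 0
  to_end <- as.numeric(window$end) - as.numeric(as_utc(p$timestamp))
  dwell <- pmin(p$dwell_min, to_end / 60)
  home_id <- cluster_set$home_id
  minutes_home <- if (is.na(home_id)) NA_real_ else
    sum(dwell[p$stationary & cl == home_id])
  data.frame(distance_km = dist_km,
             n_gps_points = as.numeric(n),
             minutes_home = minutes_home,
             minutes_transition = sum(dwell[!p$stationary]),
             minutes_stationary = sum(dwell[p$stationary]),
             missing_gps = FALSE)
}
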