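test_that("haversine identity, symmetry and antipodal limit", {
  expect_equal(haversine_m(52.521992, 13.413244, 52.521992, 13.413244), 0)
  expect_equal(haversine_m(0, 0, 0, 180), pi * 6371000, tolerance = 1e-9)
  a <- haversine_m(52.5220, 13.4132, 48.1374, 11.5755)
  b <- haversine_m(48.1374, 11.5755, 52.5220, 13.4132)
  expect_identical(a, b)
})

test_that("haversine agrees with an independent great-circle formula", {
  d1 <- haversine_m(52.5220, 13.4132, 52.5230, 13.4132)
  d2 <- oracle_slc_m(52.5220, 13.4132, 52.5230, 13.4132)
  expect_lt(abs(d1 - d2) / d2, 1e-3)
})

test_that("haversine satisfies the triangle inequality on random triples", {
  set.seed(5)
  for (i in 1:1000) {
    lat <- runif(3, -80, 80); lon <- runif(3, -180, 180)
    d12 <- haversine_m(lat[1], lon[1], lat[2], lon[2])
    d23 <- haversine_m(lat[2], lon[2], lat[3], lon[3])
    d13 <- haversine_m(lat[1], lon[1], lat[3], lon[3])
    expect_lte(d13, d12 + d23 + 1e-6)
  }
})

test_that("movement annotation applies the strict stationary conjunction", {
  mk <- function(d_m, dt_s) {
    # two points dt_s apart, d_m meters due north
    data.frame(timestamp = as_utc("2025-03-03 12:00:00") + c(0, dt_s),
               lat = c(52.52, 52.52 + d_m / 111320), lon = 13.41)
  }
  # speed 1.0, distance 100 -> stationary
  a <- annotate_movement(mk(100, 100))
  expect_true(all(a$stationary))
  expect_equal(a$speed_mps[2], 1.0, tolerance = 0.01)
  # "below walking speed" is strict: a point moving exactly at the
  # threshold speed is not stationary
  p <- mk(140, 100)
  sp <- annotate_movement(p)$speed_mps[2]
  a <- annotate_movement(p, speed_thresh_mps = sp)
  expect_false(a$stationary[2])
  expect_true(annotate_movement(p, speed_thresh_mps = sp + 1e-9)$stationary[2])
  # slow but far: 0.5 m/s over 200 m -> not stationary (conjunction)
  a <- annotate_movement(mk(200, 400))
  expect_false(a$stationary[2])
  # first point inherits the first pair's label
  expect_equal(a$stationary[1], a$stationary[2])
})

test_that("duplicate timestamps are flagged degenerate, not given speeds", {
  p <- data.frame(timestamp = as_utc("2025-03-03 12:00:00") + c(0, 60, 60),
                  lat = c(52.52, 52.5201, 52.5202), lon = 13.41)
  a <- annotate_movement(p)
  expect_true(a$degenerate[3])
  expect_true(is.na(a$speed_mps[3]))
})

test_that("dense single blob forms one cluster containing every point", {
  tr <- stay_trace(100, 52.52, 13.41, jitter_m = 6)
  cs <- cluster_stationary(tr, n_total_points = 100)
  expect_equal(nrow(cs$centroids), 1)
  expect_true(all(cs$assignments == 1))
  expect_equal(cs$min_samples_used, 3)  # ceil(0.03 * 100)
})

test_that("two distant blobs give exactly two clusters", {
  a <- stay_trace(40, 52.52, 13.41, seed = 1)
  b <- stay_trace(40, 52.529, 13.41, start = "2025-03-03 22:00:00", seed = 2)
  tr <- rbind(a, b)
  cs <- cluster_stationary(tr, n_total_points = 80)
  expect_equal(nrow(cs$centroids), 2)
  expect_equal(length(unique(cs$assignments[1:40])), 1)
  expect_equal(length(unique(cs$assignments[41:80])), 1)
  expect_false(cs$assignments[1] == cs$assignments[41])
})

test_that("min_samples is floored at 2 and clustering is order-invariant", {
  tr <- stay_trace(30, 52.52, 13.41)
  cs <- cluster_stationary(tr, n_total_points = 30)
  expect_equal(cs$min_samples_used, 2)
  set.seed(3)
  perm <- sample(nrow(tr))
  cs_p <- cluster_stationary(tr[perm, ], n_total_points = 30)
  expect_equal(canonical_labels(cs_p$assignments[order(perm)]),
               canonical_labels(cs$assignments))
})

test_that("no stationary points yields an empty cluster set", {
  cs <- cluster_stationary(stay_trace(0, 52.52, 13.41)[0, ], 100)
  expect_equal(nrow(cs$centroids), 0)
  expect_true(is.na(cs$home_id))
})

night_trace <- function(n_nights, lat, lon, day0 = "2025-03-03",
                        per_night = 4, seed = 1) {
  # points at 22:00, 23:30, 01:00, 02:30 local each night
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_nights), function(d) {
    t0 <- as_utc(paste(as.Date(day0) + d - 1, "21:00:00"))  # 22:00 local
    data.frame(timestamp = t0 + (seq_len(per_night) - 1) * 5400,
               lat = lat + rnorm(per_night, 0, 5) / 111320,
               lon = lon + rnorm(per_night, 0, 5) / 111320)
  }))
}

prep_trace <- function(tr) attribute_dwell(annotate_movement(tr))

test_that("a cluster dominating 10 of 14 nights is the home, not a fallback", {
  home <- night_trace(10, 52.52, 13.41)
  # daytime visits to a second place on the remaining days
  away <- stay_trace(25, 52.53, 13.45, start = "2025-03-13 10:00:00",
                     gap_min = 25, seed = 9)
  tr <- prep_trace(rbind(home, away)[order(rbind(home, away)$timestamp), ])
  cs <- cluster_stationary(tr[tr$stationary, ], n_total_points = nrow(tr))
  cs <- find_home(cs, tr)
  expect_false(cs$home_is_fallback)
  hc <- cs$centroids[cs$centroids$id == cs$home_id, ]
  expect_lt(haversine_m(hc$lat, hc$lon, 52.52, 13.41), 100)
})

test_that("3+3 nights qualify no home; fallback picks the top-dwell cluster", {
  a <- night_trace(3, 52.52, 13.41, day0 = "2025-03-03")
  b <- night_trace(3, 52.55, 13.47, day0 = "2025-03-07")
  # cluster b also gets daytime-only dwell so it wins the fallback
  extra <- stay_trace(30, 52.55, 13.47, start = "2025-03-10 09:00:00",
                      gap_min = 15, seed = 4)
  tr <- rbind(a, b, extra)
  tr <- prep_trace(tr[order(tr$timestamp), ])
  cs <- cluster_stationary(tr[tr$stationary, ], n_total_points = nrow(tr))
  cs <- find_home(cs, tr)
  expect_true(cs$home_is_fallback)
  hc <- cs$centroids[cs$centroids$id == cs$home_id, ]
  expect_lt(haversine_m(hc$lat, hc$lon, 52.55, 13.47), 100)
})

test_that("mobility features sum dwell by movement class within the window", {
  tr <- stay_trace(7, 52.52, 13.41, start = "2025-03-03 08:00:00",
                   gap_min = 20, jitter_m = 2)
  tr <- prep_trace(tr)
  cs <- cluster_stationary(tr[tr$stationary, ], n_total_points = 60)
  cs <- find_home(cs, tr)
  w <- block_window(as_utc("2025-03-03 10:00:00"))
  f <- mobility_features(tr, cs, w)
  expect_false(f$missing_gps)
  expect_equal(f$minutes_transition, 0)
  expect_equal(f$minutes_home, f$minutes_stationary)
  expect_lte(f$minutes_stationary, 120 + 1e-9)
  expect_lt(f$distance_km, 0.1)
  # empty window
  f0 <- mobility_features(tr, cs, block_window(as_utc("2025-03-05 10:00:00")))
  expect_true(f0$missing_gps)
  expect_true(is.na(f0$distance_km))
})

test_that("a straight excursion recovers its planned distance and speed", {
  # 3.6 km at 5 m/s = 12 min of movement inside one window
  seg <- data.frame(start = as_utc("2025-03-03 08:30:00"),
                    end = as_utc("2025-03-03 08:42:00"),
                    type = "transit", lat = 52.52, lon = 13.41,
                    lat2 = 52.52 + 3600 / 111320, lon2 = 13.41,
                    speed_mps = 5, mode = "vehicle")
  set.seed(8)
  tr <- generate_gps_trace(seg, jitter_m = 2)
  a <- prep_trace(tr)
  # recomputed speeds match the plan
  sp <- a$speed_mps[is.finite(a$speed_mps)]
  expect_true(all(abs(sp - 5) / 5 < 0.2))
  cs <- cluster_stationary(a[a$stationary, , drop = FALSE], nrow(a))
  f <- mobility_features(a, cs, block_window(as_utc("2025-03-03 10:00:00")))
  expect_equal(f$distance_km, 3.6, tolerance = 0.1)
  expect_equal(f$minutes_transition, 12, tolerance = 1.5)
})

test_that("a participant without excursions stays within 100 m of home", {
  seg <- data.frame(start = as_utc("2025-03-03 00:00:00"),
                    end = as_utc("2025-03-06 00:00:00"),
                    type = "home", lat = 52.52, lon = 13.41,
                    lat2 = NA, lon2 = NA, speed_mps = 0, mode = "stay")
  set.seed(2)
  tr <- generate_gps_trace(seg)
  expect_gt(nrow(tr), 50)
  expect_true(all(haversine_m(tr$lat, tr$lon, 52.52, 13.41) < 100))
})

test_that("planted home nights are recovered end-to-end from the trace", {
  # 14 nights at home plus daily daytime away stays
  segs <- do.call(rbind, lapply(0:13, function(d) {
    day <- as_utc("2025-03-03 00:00:00") + d * 86400
    rbind(
      data.frame(start = day, end = day + 10 * 3600, type = "home",
                 lat = 52.52, lon = 13.41, lat2 = NA, lon2 = NA,
                 speed_mps = 0, mode = "stay"),
      data.frame(start = day + 10 * 3600, end = day + 14 * 3600,
                 type = "away", lat = 52.535, lon = 13.43, lat2 = NA,
                 lon2 = NA, speed_mps = 0, mode = "stay"),
      data.frame(start = day + 14 * 3600, end = day + 86400, type = "home",
                 lat = 52.52, lon = 13.41, lat2 = NA, lon2 = NA,
                 speed_mps = 0, mode = "stay"))
  }))
  set.seed(21)
  tr <- prep_trace(generate_gps_trace(segs))
  cs <- cluster_stationary(tr[tr$stationary, , drop = FALSE], nrow(tr))
  cs <- find_home(cs, tr)
  expect_false(cs$home_is_fallback)
  hc <- cs$centroids[cs$centroids$id == cs$home_id, ]
  expect_lt(haversine_m(hc$lat, hc$lon, 52.52, 13.41), 100)
})

test_that("minutes at home never exceed stationary minutes", {
  set.seed(31)
  for (i in 1:5) {
    tr <- rbind(stay_trace(40, 52.52, 13.41, seed = i),
                stay_trace(10, 52.53, 13.44,
                           start = "2025-03-03 22:00:00", seed = i + 50))
    tr <- prep_trace(tr[order(tr$timestamp), ])
    cs <- find_home(cluster_stationary(tr[tr$stationary, ], nrow(tr)), tr)
    w <- block_window(as_utc("2025-03-03 12:00:00"), hours = 12)
    f <- mobility_features(tr, cs, w)
    expect_lte(f$minutes_home, f$minutes_stationary + 1e-9)
  }
})
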