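#' Run the full pipeline on a synthetic cohort
#'
#' generate -> inject missingness -> clean/aggregate features -> inclusion
#' filters -> missingness policy -> assemble -> evaluate all registered
#' models in both scenarios -> report. The default feature-outcome coupling
#' is weak (small standardized weights on home time, steps, transition time
#' and mean heart rate), reflecting a regime where most predictable variance
#' sits in stable person differences.
#'
#' @param n_participants cohort size (default 30).
#' @param seed master seed for generation, splitting and model fits.
#' @param beta named effect weights passed to [synthetic_config()].
#' @param config optionally a ready-made [synthetic_config()] (overrides
#'   `n_participants`, `seed`, `beta`).
#' @param registry model registry (default all eleven models).
#' @param ... further arguments to [synthetic_config()].
#' @return list: `results` (model x scenario metrics), `report` (Markdown),
#'   `dataset`, `exclusion_log`, `icc` (empirical intraclass correlation of
#'   the labels), `config`.
#' @export
run_pipeline <- function(n_participants = 30, seed = 1L,
                         beta = c(minutes_home = 0.12, steps = -0.08,
                                  minutes_transition = 0.05, hr_mean = 0.08),
                         config = NULL, registry = model_registry(), ...) {
  cfg <- config %||% synthetic_config(n_participants = n_participants,
                                      beta = beta, seed = seed, ...)
  bundle <- generate_cohort(cfg)
  bundle <- inject_missingness(bundle)
  blocks <- build_blocks(bundle)
  filt <- apply_inclusion_filters(blocks, tz_offset_h = cfg$tz_offset_h)
  pol <- apply_missingness_policy(filt$blocks)
  # the policy mask must align with the filtered blocks
  ds <- assemble_dataset(pol, bundle$participants, variant = "with_PS")
  results <- run_scenarios(ds, registry = registry, seed = seed)
  vc <- label_variance_components(ds$y, ds$groups)
  list(results = results, report = format_report(results), dataset = ds,
       exclusion_log = filt$exclusion_log, icc = vc$icc,
       variance_components = vc, config = cfg)
}

#' Empirical variance components of the labels
#'
#' One-way ANOVA (method-of-moments) decomposition of the outcome into
#' between-person and within-person variance, and the implied intraclass
#' correlation `sigma_b^2 / (sigma_b^2 + sigma_w^2)`.
#'
#' @param y numeric outcome.
#' @param groups participant ids.
#' @return list `sigma2_b`, `sigma2_w`, `icc`.
#' @export
label_variance_components <- function(y, groups) {
  groups <- as.character(groups)
  n_i <- table(groups)
  m <- length(n_i)
  sw <- unlist(lapply(split(y, groups), function(v) v - mean(v)))
  sigma2_w <- sum(sw^2) / (length(y) - m)
  gm <- mean(y)
  msb <- sum(as.numeric(n_i) * (tapply(y, groups, mean) - gm)^2) / (m - 1)
  n0 <- (length(y) - sum(as.numeric(n_i)^2) / length(y)) / (m - 1)
  sigma2_b <- max(0, (msb - sigma2_w) / n0)
  list(sigma2_b = sigma2_b, sigma2_w = sigma2_w,
       icc = sigma2_b / (sigma2_b + sigma2_w))
}

# ---- cohort I/O -----------------------------------------------------------

fmt_ts <- function(ts) format(as_utc(ts), "%Y-%m-%dT%H:%M:%S", tz = "UTC")

write_stream_csv <- function(df, path, header_note) {
  con <- file(path, "w")
  writeLines(paste0("# ", header_note), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Write a cohort bundle to plain-text files
#'
#' One CSV per stream per participant (`<dir>/<id>/gps.csv`, `hr.csv`,
#' `steps.csv`, `activity.csv`), plus `beeps.csv`, `weather.csv`,
#' `person_stable.csv` and `ground_truth.json` at the top level. All
#' timestamps are ISO-8601 UTC; each stream file carries a header comment
#' documenting the half-open block convention.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  note <- paste("timestamps UTC ISO-8601; blocks are half-open [beep-2h,",
                "beep) anchored at the beep completion time")
  for (pid in names(bundle$streams)) {
    pd <- file.path(dir, pid)
    dir.create(pd, showWarnings = FALSE)
    s <- bundle$streams[[pid]]
    g <- s$gps; g$timestamp <- fmt_ts(g$timestamp)
    names(g)[1] <- "timestamp_utc"
    write_stream_csv(g, file.path(pd, "gps.csv"), note)
    h <- s$hr; h$timestamp <- fmt_ts(h$timestamp)
    names(h)[1] <- "timestamp_utc"
    write_stream_csv(h, file.path(pd, "hr.csv"), note)
    st <- s$steps; st$start <- fmt_ts(st$start); st$end <- fmt_ts(st$end)
    write_stream_csv(st, file.path(pd, "steps.csv"), note)
    a <- s$activity; a$start <- fmt_ts(a$start); a$end <- fmt_ts(a$end)
    write_stream_csv(a, file.path(pd, "activity.csv"), note)
  }
  b <- bundle$beeps; b$timestamp <- fmt_ts(b$timestamp)
  write_stream_csv(b, file.path(dir, "beeps.csv"), note)
  write.csv(bundle$weather, file.path(dir, "weather.csv"), row.names = FALSE)
  write.csv(bundle$participants, file.path(dir, "person_stable.csv"),
            row.names = FALSE)
  truth <- bundle$truth
  truth$timelines <- NULL  # plan internals are not part of the contract
  truth$person_intercepts <- as.list(truth$person_intercepts)
  truth$beta <- as.list(truth$beta)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, POSIXt = "ISO8601")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory written by [write_cohort()].
#' @return a `cohort_bundle` (without config or timelines; streams, beeps,
#'   weather, person-stable table and ground truth restored).
#' @export
read_cohort <- function(dir) {
  rd <- function(path) read.csv(path, comment.char = "#",
                                stringsAsFactors = FALSE)
  participants <- read.csv(file.path(dir, "person_stable.csv"),
                           stringsAsFactors = FALSE)
  ids <- participants$participant_id
  streams <- lapply(ids, function(pid) {
    pd <- file.path(dir, pid)
    g <- rd(file.path(pd, "gps.csv"))
    names(g)[names(g) == "timestamp_utc"] <- "timestamp"
    g$timestamp <- as_utc(g$timestamp)
    h <- rd(file.path(pd, "hr.csv"))
    names(h)[names(h) == "timestamp_utc"] <- "timestamp"
    h$timestamp <- as_utc(h$timestamp)
    st <- rd(file.path(pd, "steps.csv"))
    st$start <- as_utc(st$start); st$end <- as_utc(st$end)
    a <- rd(file.path(pd, "activity.csv"))
    a$start <- as_utc(a$start); a$end <- as_utc(a$end)
    list(gps = g, hr = h, steps = st, activity = a)
  })
  names(streams) <- ids
  beeps <- rd(file.path(dir, "beeps.csv"))
  beeps$timestamp <- as_utc(beeps$timestamp)
  beeps$answered <- as.logical(beeps$answered)
  beeps$travelling_flag <- as.logical(beeps$travelling_flag)
  weather <- read.csv(file.path(dir, "weather.csv"),
                      stringsAsFactors = FALSE)
  weather$date <- as.Date(weather$date)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  out <- list(config = NULL, participants = participants, streams = streams,
              beeps = beeps, weather = weather, truth = truth,
              missing_log = data.frame(participant_id = character(0),
                                       beep_id = integer(0),
                                       mechanism = character(0)))
  class(out) <- "cohort_bundle"
  out
}

#' Write a per-participant cluster report
#'
#' JSON with one record per cluster: centroid, total dwell minutes, night
#' counts and the home flag.
#'
#' @param cluster_set a [find_home()]-completed `cluster_set`.
#' @param points the dwell-attributed annotated trace.
#' @param path output path.
#' @export
write_cluster_report <- function(cluster_set, points, path) {
  st <- points[points$stationary, , drop = FALSE]
  st$cluster <- cluster_set$assignments
  recs <- lapply(seq_len(nrow(cluster_set$centroids)), function(i) {
    id <- cluster_set$centroids$id[i]
    list(id = id,
         centroid = list(lat = cluster_set$centroids$lat[i],
                         lon = cluster_set$centroids$lon[i]),
         n_points = cluster_set$centroids$n_points[i],
         dwell_min = sum(st$dwell_min[st$cluster == id]),
         nights = unname(cluster_set$night_counts[as.character(id)] %||%
                           0L),
         is_home = identical(id, cluster_set$home_id))
  })
  jsonlite::write_json(
    list(clusters = recs, home_id = cluster_set$home_id,
         home_is_fallback = cluster_set$home_is_fallback,
         min_samples = cluster_set$min_samples_used,
         eps_radians = cluster_set$eps_used),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
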