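test_that("the NA score is the item mean on the 1/8 grid", {
  expect_equal(compute_na(rep(1L, 8)), 1.0)
  expect_equal(compute_na(c(2, 2, 2, 2, 4, 4, 4, 4)), 3.0)
  expect_equal(compute_na(rep(7L, 8)), 7.0)
  expect_true(is.na(compute_na(c(1, 2, 3, 4, 5, 6, 7, NA))))
  expect_error(compute_na(c(0, 2, 3, 4, 5, 6, 7, 1)), "1, 7")
  expect_error(compute_na(c(1.5, 2, 3, 4, 5, 6, 7, 1)), "integers")
  m <- rbind(rep(2L, 8), c(rep(3L, 4), rep(4L, 4)))
  expect_equal(compute_na(m), c(2, 3.5))
})

test_that("context features bin local time, calendar and weather correctly", {
  wx <- data.frame(date = as.Date(c("2025-03-03", "2025-07-15")),
                   temp_avg = c(5, 25), sunshine_h = c(2, 10),
                   precipitation_h = c(3, 0))
  # 2025-03-03 is a Monday; 07:30 UTC = 08:30 local (+1)
  ts <- as_utc(c("2025-03-03 07:30:00", "2025-07-15 21:30:00"))
  cx <- context_features(ts, wx)
  expect_equal(cx$assessment_hour, c(8, 22))
  expect_equal(as.character(cx$time_of_day), c("early_morning", "evening"))
  expect_equal(as.character(cx$weekday), c("Mon", "Tue"))
  expect_equal(cx$weekend, c(FALSE, FALSE))
  expect_equal(as.character(cx$season), c("spring", "summer"))
  expect_equal(cx$temp_avg, c(5, 25))
  # night wraps 23-05
  cx2 <- context_features(as_utc("2025-03-03 23:30:00"), wx)  # 00:30 local
  expect_equal(as.character(cx2$time_of_day), "night")
})

test_that("the missingness policy separates structural fills from MCAR", {
  ts <- as_utc("2025-03-03 10:00:00")
  gps_cols <- c("distance_km", "n_gps_points", "minutes_home",
                "minutes_transition", "minutes_stationary")
  hr_cols <- c("hr_mean", "hr_min", "hr_max", "hr_std", "hr_zone_resting",
               "hr_zone_moderate", "hr_zone_vigorous")
  act_cols <- paste0("act_", c("walking", "running", "cycling", "sleep",
                               "rest", "active"))

  # no GPS, not travelling -> structural fills 0 / 120
  bl <- toy_block("A", 1, ts, missing_gps = TRUE, travelling_flag = FALSE)
  out <- apply_missingness_policy(bl)
  expect_equal(out$blocks$distance_km, 0)
  expect_equal(out$blocks$n_gps_points, 0)
  expect_equal(out$blocks$minutes_transition, 0)
  expect_equal(out$blocks$minutes_home, 120)
  expect_equal(out$blocks$minutes_stationary, 120)
  expect_false(any(out$mcar_mask))

  # no GPS while travelling -> all five GPS cells marked for imputation
  bl <- toy_block("A", 2, ts, missing_gps = TRUE, travelling_flag = TRUE)
  out <- apply_missingness_policy(bl)
  expect_true(all(out$mcar_mask[1, gps_cols]))
  expect_true(all(is.na(out$blocks[1, gps_cols])))

  # truth table over the 2^3 wearable presence patterns
  pat <- expand.grid(hr = c(TRUE, FALSE), st = c(TRUE, FALSE),
                     ac = c(TRUE, FALSE))
  for (i in seq_len(nrow(pat))) {
    p <- pat[i, ]
    bl <- toy_block("A", i, ts + i * 7200, missing_hr = !p$hr,
                    missing_steps = !p$st, missing_activity = !p$ac,
                    watch_off = !p$hr && !p$st && !p$ac)
    out <- apply_missingness_policy(bl)
    if (!p$hr && !p$st && !p$ac) {
      # watch off: everything wearable is MCAR
      expect_true(all(out$mcar_mask[1, c(hr_cols, "steps", act_cols)]))
    } else {
      # watch worn: HR absence is MCAR, event absences are structural zeros
      expect_equal(unname(out$mcar_mask[1, "hr_mean"]), !p$hr)
      if (!p$st) expect_equal(out$blocks$steps, 0)
      if (!p$ac) expect_true(all(out$blocks[1, act_cols] == 0))
      expect_false(any(out$mcar_mask[1, c("steps", act_cols)]))
    }
    # disjointness: no cell is both filled and masked
    filled <- !is.na(out$blocks[1, c(hr_cols, "steps", act_cols)])
    expect_false(any(filled & out$mcar_mask[1, c(hr_cols, "steps",
                                                 act_cols)]))
  }
})

make_participant_blocks <- function(id, n_days = 10, beeps_per_day = 5,
                                    answered = TRUE, n_gps_total = 100,
                                    travel_missing = 0) {
  ts <- as_utc("2025-03-03 08:00:00") +
    rep((seq_len(n_days) - 1) * 86400, each = beeps_per_day) +
    rep(seq_len(beeps_per_day) * 7200, times = n_days)
  n <- length(ts)
  bl <- do.call(rbind, lapply(seq_len(n), function(i)
    toy_block(id, i, ts[i], answered = answered,
              n_gps_total = n_gps_total,
              missing_gps = i <= travel_missing,
              travelling_flag = i <= travel_missing)))
  bl
}

test_that("inclusion filters fire in their documented order", {
  ok <- make_participant_blocks("OK")
  few_beeps <- make_participant_blocks("FB", n_days = 5)     # rule 1
  few_gps <- make_participant_blocks("FG", n_gps_total = 49) # rule 2
  travel <- make_participant_blocks("TR", travel_missing = 30) # rule 3 (60%)
  blocks <- rbind(ok, few_beeps, few_gps, travel)
  res <- apply_inclusion_filters(blocks)
  expect_equal(res$included, "OK")
  expect_equal(res$exclusion_log$participant_id, c("FB", "FG", "TR"))
  expect_equal(res$exclusion_log$reason, c("beeps", "gps_count", "gps_mcar"))
  expect_equal(res$exclusion_log$rule_order, 1:3)
})

test_that("boundary participants survive the day and GPS-count rules", {
  # exactly 7 days x 4 answered beeps and exactly 50 GPS points: included
  b <- make_participant_blocks("B", n_days = 7, beeps_per_day = 4,
                               n_gps_total = 50)
  res <- apply_inclusion_filters(b)
  expect_equal(res$included, "B")
  # 49 points: excluded with reason gps_count
  b49 <- make_participant_blocks("C", n_days = 7, beeps_per_day = 4,
                                 n_gps_total = 49)
  res <- apply_inclusion_filters(b49)
  expect_equal(res$exclusion_log$reason, "gps_count")
})

test_that("rule 4 re-checks beep coverage after dropping all-missing rows", {
  # 7x4 coverage, but one day's beeps lose all passive data -> 6 good days
  b <- make_participant_blocks("D", n_days = 7, beeps_per_day = 4)
  first_day <- as.Date(b$timestamp) == as.Date("2025-03-03")
  b$watch_off[first_day] <- TRUE
  b$missing_gps[first_day] <- TRUE
  res <- apply_inclusion_filters(b)
  expect_equal(nrow(res$blocks), 0)
  expect_equal(res$exclusion_log$reason, "beeps_after_row_removal")
  expect_equal(res$exclusion_log$rule_order, 4L)
})

test_that("assembly orders rows canonically and controls the PS block", {
  parts <- data.frame(participant_id = c("A", "B"), age = c(30, 40),
                      employable = c(TRUE, FALSE),
                      smartphone_type = c("iPhone", "Android"),
                      somatic_problems = c(FALSE, TRUE),
                      psychotropic_medication = c(FALSE, FALSE),
                      prior_treatment = c("none", "inpatient"),
                      stringsAsFactors = FALSE)
  ts <- as_utc("2025-03-03 08:00:00") + 1:3 * 7200
  bl <- rbind(
    do.call(rbind, lapply(1:3, function(i) toy_block("A", i, ts[i]))),
    do.call(rbind, lapply(1:3, function(i) toy_block("B", i, ts[i]))))
  bl <- with_context(bl)
  pol <- apply_missingness_policy(bl)
  ds <- assemble_dataset(pol, parts, variant = "passive_only")
  expect_equal(length(ds$y), 6)
  expect_equal(ncol(ds$X), 28)
  ds_ps <- assemble_dataset(pol, parts, variant = "with_PS")
  expect_equal(ncol(ds_ps$X), 34)
  expect_equal(setdiff(names(ds_ps$X), names(ds$X)),
               c("age", "employable", "smartphone_type", "somatic_problems",
                 "psychotropic_medication", "prior_treatment"))
  # shuffled input -> identical dataset after canonical sort
  perm <- sample(nrow(bl))
  pol2 <- list(blocks = pol$blocks[perm, ], mcar_mask = pol$mcar_mask[perm, ])
  ds2 <- assemble_dataset(pol2, parts, variant = "passive_only")
  expect_equal(ds2$X, ds$X)
  expect_equal(ds2$y, ds$y)
  # unanswered beeps are dropped
  bl$answered[1] <- FALSE; bl$na_score[1] <- NA
  ds3 <- assemble_dataset(apply_missingness_policy(bl), parts,
                          variant = "passive_only")
  expect_equal(length(ds3$y), 5)
  # duplicates rejected
  pol_dup <- list(blocks = rbind(pol$blocks, pol$blocks[1, ]),
                  mcar_mask = rbind(pol$mcar_mask, pol$mcar_mask[1, ]))
  expect_error(assemble_dataset(pol_dup, parts, "passive_only"), "duplicate")
})

test_that("every assembled row's window strictly precedes its label", {
  b <- inject_missingness(generate_cohort(
    synthetic_config(12, n_days = 8, seed = 13)))
  blocks <- build_blocks(b)
  filt <- apply_inclusion_filters(blocks)
  ds <- assemble_dataset(apply_missingness_policy(filt$blocks),
                         b$participants, "passive_only")
  # features aggregate [t-2h, t): the label timestamp bounds its window
  expect_true(all(block_window(ds$timestamp[1])$end == ds$timestamp[1]))
  expect_gt(length(ds$y), 0)
  # filter log reconciles with input count
  expect_equal(length(filt$included) + length(unique(
    filt$exclusion_log$participant_id)), 12)
})
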