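test_that("correct-corner visit rates are exact on hand-built logs", {
  ev <- pp_day_events(1, 10, 4)
  lv <- learning_visit_rates(ev, "PP", correct_corner = 1)
  expect_equal(lv$rate[lv$day == 1], 0.4)
  expect_true(all(is.na(lv$rate[lv$day != 1])))
  expect_equal(learning_visit_rates(pp_day_events(2, 6, 6), "PP", 1)$rate[2], 1)
  expect_equal(learning_visit_rates(pp_day_events(3, 6, 0), "PP", 1)$rate[3], 0)
  expect_error(learning_visit_rates(ev, "PP", correct_corner = 7), "corner")
})

test_that("premature-trial rate counts trials, not pokes", {
  types <- c(rep("premature", 4), "premature3", rep("correct", 15))
  ev <- srtt_day_events(4, 0.5, types)
  imp <- srtt_impulsivity(ev)
  expect_equal(imp$rate[imp$day == 4], 5 / 20) # the 3-poke trial counts once
  # zero-trial day is missing
  expect_true(is.na(imp$rate[imp$day == 9]))
})

test_that("attention metrics match hand counts at one stimulus duration", {
  types <- c(rep("premature", 5), rep("correct", 9), rep("miss", 6))
  ev <- srtt_day_events(5, 0.5, types)
  att <- srtt_attention(ev)
  a5 <- att[att$duration == 0.5, ]
  expect_equal(a5$correct, 9 / 20)
  expect_equal(a5$correct_np, 9 / 15)
  expect_equal(a5$premature, 5 / 20)
  expect_equal(a5$omission_error, 6 / 15)
  expect_equal(a5$omission_trial, 0)
  expect_true(all(is.na(att$correct[att$duration != 0.5])))
})

test_that("one omission error among ten non-premature trials gives 0.1", {
  ev <- srtt_day_events(6, 1, c(rep("correct", 9), "miss"))
  att <- srtt_attention(ev)
  expect_equal(att$omission_error[att$duration == 1], 0.1)
})

test_that("omission trials are visits with no nose-poke", {
  ev <- srtt_day_events(5, 0.3, c("omission", "omission", rep("correct", 6)))
  att <- srtt_attention(ev)
  expect_equal(att$omission_trial[att$duration == 0.3], 2 / 8)
})

test_that("avoided-corner nose-poke error rate is exact", {
  ev <- pa_period_events("learning", 40, 8)
  pa <- avoidance_error_rates(ev, avoided_corner = 2)
  expect_equal(pa$rate[pa$period == "learning"], 0.2)
  expect_true(is.na(pa$rate[pa$period == "baseline"]))
  expect_error(avoidance_error_rates(ev, avoided_corner = NULL), "corner")
})

test_that("delay-discounting rates normalize per visit", {
  ev <- dd_day_events(7, 6, n_visits = 30, pokes_per_visit = 2,
                      licks_per_visit = 3)
  dd <- dd_rates(ev)
  expect_equal(dd$np_rate[dd$delay == 6], 2)
  expect_equal(dd$lick_rate[dd$delay == 6], 3)
  # a mouse drinking only water licks 0 times at the saccharin side
  water <- dplyr::bind_rows(lapply(seq_along(c(0, 0.1, 1:8)), function(k) {
    dd_day_events(k, c(0, 0.1, 1:8)[k], 5, 1, 2, lick_side = "L")
  }))
  ddw <- dd_rates(water)
  expect_true(all(ddw$lick_rate == 0))
  expect_true(all(ddw$np_rate == 1))
})

test_that("extraction emits exactly the schema features with task-wise NA", {
  ev <- pp_day_events(1, 10, 4)
  ft <- extract_features(ev)
  expect_setequal(feature_cols(ft), default_schema()$feature_id)
  expect_equal(ft$pp_day1, 0.4)
  non_pp <- setdiff(feature_cols(ft), paste0("pp_day", 1:7))
  expect_true(all(is.na(unlist(ft[non_pp]))))
})

test_that("conservation and subset invariants hold on a simulated cohort", {
  ev <- simulate_event_cohort(sim_config(n_wt = 3, n_ki = 3, seed = 8,
                                         visits = 40, effect = "phase1"))
  tr <- cagecog:::srtt_trials(ev)
  # premature + non-premature = total trials, per mouse-day
  agg <- dplyr::count(dplyr::group_by(tr, mouse_id, day), premature)
  tot <- dplyr::summarise(dplyr::group_by(tr, mouse_id, day), n = dplyr::n())
  expect_equal(sum(agg$n), sum(tot$n))
  ft <- build_feature_table(ev)
  for (s in c("0.3", "0.5", "1")) {
    a <- ft[[paste0("srtt_correct_np_", s, "s")]]
    b <- ft[[paste0("srtt_correct_", s, "s")]]
    ok <- !is.na(a) & !is.na(b)
    expect_true(all(a[ok] >= b[ok]))
  }
  rates <- default_schema()$feature_id[default_schema()$kind == "rate"]
  rv <- unlist(ft[rates])
  expect_true(all(rv >= 0 & rv <= 1, na.rm = TRUE))
  counts <- default_schema()$feature_id[default_schema()$kind == "count"]
  expect_true(all(unlist(ft[counts]) >= 0, na.rm = TRUE))
})

test_that("build_feature_table is deterministic in row order and strict on input", {
  ev <- simulate_event_cohort(sim_config(n_wt = 2, n_ki = 2, seed = 5,
                                         visits = 8))
  ft1 <- build_feature_table(ev)
  shuffled <- withr::with_seed(1, ev[sample(nrow(ev)), ])
  # within-session event order matters for trial reconstruction, so reorder
  # only whole mice: bind the per-mouse blocks in reverse
  blocks <- split(ev, ev$mouse_id)
  ft2 <- build_feature_table(dplyr::bind_rows(rev(blocks)))
  expect_identical(ft1, ft2)
  expect_equal(nrow(ft1), 4)
  expect_error(build_feature_table(list()), "empty")
  expect_error(build_feature_table(ev[0, ]), "empty")
  expect_error(build_feature_table(list(blocks[[1]], blocks[[1]])), "duplicate")
  expect_false(is.null(shuffled)) # silence lint: shuffled kept for clarity
})

test_that("a 27-mouse phase-1 cohort yields a 27 x 60 feature matrix", {
  ev <- simulate_event_cohort(sim_config(seed = 6, visits = 6))
  ft <- build_feature_table(ev)
  expect_equal(nrow(ft), 27)
  expect_length(feature_cols(ft), 60)
})

test_that("missingness filter drops strictly-majority-missing features", {
  tab <- simulate_feature_table(sim_config(n_wt = 13, n_ki = 14, seed = 9,
                                           effect = "null"))
  tab$pp_day1[1:15] <- NA # 15/27 = 0.556 missing -> dropped
  tab$pp_day2[1:13] <- NA # 13/27 = 0.481 missing -> kept
  out <- missingness_filter(tab)
  expect_false("pp_day1" %in% feature_cols(out))
  expect_true("pp_day2" %in% feature_cols(out))
  expect_true("pp_day1" %in% attr(out, "dropped"))
  clean <- tab
  clean[feature_cols(clean)] <- lapply(clean[feature_cols(clean)],
                                       function(v) ifelse(is.na(v), 0, v))
  expect_equal(feature_cols(missingness_filter(clean)), feature_cols(clean))
  allna <- tab
  allna[feature_cols(allna)] <- NA_real_
  expect_error(missingness_filter(allna), "all features")
})

test_that("zero-visit sessions flag the parameter missing", {
  # a DD session with visits only at one delay leaves other delays NA
  ev <- dd_day_events(1, 3, 10, 1, 1)
  dd <- dd_rates(ev)
  expect_false(is.na(dd$np_rate[dd$delay == 3]))
  expect_true(all(is.na(dd$np_rate[dd$delay != 3])))
})
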