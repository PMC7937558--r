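#' Daily correct-corner visit rates (place preference / reversal)
#'
#' For each task day, the fraction of corner visits that hit the mouse's
#' assigned correct corner; the day is missing when the mouse made no visits.
#' These rates index spatial learning (PP) and learning flexibility after the
#' rewarded corner moves diagonally (PPR).
#'
#' @param events A cohort event-log tibble.
#' @param task `"PP"` or `"PPR"`.
#' @param correct_corner The corner (1-4) assigned as correct for this task.
#' @param days Days to report (default 1-7).
#' @return A tibble `mouse_id`, `phase`, `day`, `rate` (NA when no visits).
#' @export
learning_visit_rates <- function(events, task = c("PP", "PPR"),
                                 correct_corner, days = 1:7) {
  task <- match.arg(task)
  if (missing(correct_corner) || is.null(correct_corner) ||
      !correct_corner %in% 1:4) {
    rlang::abort("`correct_corner` must be a corner in 1..4")
  }
  ev <- dplyr::filter(events, .data$task == !!task,
                      .data$event == "visit_start", .data$day %in% days)
  out <- dplyr::summarise(
    dplyr::group_by(ev, .data$mouse_id, .data$phase, .data$day),
    rate = mean(.data$corner == correct_corner), .groups = "drop"
  )
  complete_grid(out, events, days = days, value = "rate")
}

# reconstruct serial-reaction-time trials: one trial per visit
srtt_trials <- function(events) {
  ev <- dplyr::filter(events, .data$task == "SRTT")
  ev <- dplyr::group_by(ev, .data$mouse_id, .data$phase, .data$day)
  ev <- dplyr::mutate(ev, trial = cumsum(.data$event == "visit_start"))
  tr <- dplyr::summarise(
    dplyr::group_by(ev, .data$mouse_id, .data$phase, .data$day, .data$trial),
    duration = .data$condition[1],
    t_led = suppressWarnings(min(.data$time_s[.data$event == "led_on"])),
    t_open = suppressWarnings(min(.data$time_s[.data$event == "door_open"])),
    t_close = suppressWarnings(min(.data$time_s[.data$event == "door_close"])),
    n_pokes = sum(.data$event == "nosepoke"),
    first_poke = suppressWarnings(min(.data$time_s[.data$event == "nosepoke"])),
    premature = n_pokes > 0 &&
      any(.data$time_s[.data$event == "nosepoke"] > first_poke &
            .data$time_s[.data$event == "nosepoke"] < t_led),
    correct = any(.data$event == "lick" & .data$time_s >= t_open &
                    .data$time_s <= t_close),
    .groups = "drop"
  )
  dplyr::mutate(tr,
                initiated = .data$n_pokes > 0,
                opened = is.finite(.data$t_open),
                omission_trial = !.data$initiated,
                omission_error = .data$initiated & !.data$premature &
                  .data$opened & !.data$correct)
}

#' Daily premature-trial rates (serial reaction time, impulsivity)
#'
#' A trial is one corner visit in an SRTT session; it counts as premature when
#' the mouse nose-pokes again during the imposed waiting period, i.e. after
#' the trial-initiating poke and before the LED cue (any repeat poke, if the
#' trial aborted before the cue). The rate is per trial, not per poke.
#'
#' @param events A cohort event-log tibble.
#' @param days Task days to report (default 1-10).
#' @return A tibble `mouse_id`, `phase`, `day`, `rate` (NA when no trials).
#' @export
srtt_impulsivity <- function(events, days = 1:10) {
  tr <- srtt_trials(events)
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(tr, .data$day %in% days),
                    .data$mouse_id, .data$phase, .data$day),
    rate = mean(.data$premature), .groups = "drop"
  )
  complete_grid(out, events, days = days, value = "rate")
}

#' Attention metrics on SRTT days 5-7, by stimulus duration
#'
#' Five metrics per LED/door stimulus duration (0.3, 0.5, 1 s), computed over
#' days 5-7: premature-trial rate; omission-error rate (door opened but the
#' mouse never licked before it closed, over non-premature trials);
#' omission-trial rate (visits with no nose-poke at all, over visits); correct
#' rate over all trials; and correct rate over non-premature trials. A trial
#' is correct when a lick lands inside the door-open window; premature trials
#' abort before the door opens, so they never count as correct — which is what
#' makes the non-premature correct rate dominate the all-trial one.
#'
#' @param events A cohort event-log tibble.
#' @param days Attention-task days (default 5-7).
#' @return A tibble `mouse_id`, `phase`, `duration`, `premature`,
#'   `omission_error`, `omission_trial`, `correct`, `correct_np`. Metrics with
#'   a zero denominator are NA.
#' @export
srtt_attention <- function(events, days = 5:7) {
  tr <- dplyr::filter(srtt_trials(events), .data$day %in% days,
                      !is.na(.data$duration))
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- dplyr::summarise(
    dplyr::group_by(tr, .data$mouse_id, .data$phase, .data$duration),
    n_trials = dplyr::n(),
    n_np = sum(!.data$premature),
    n_prem = sum(.data$premature),
    n_omerr = sum(.data$omission_error),
    n_omtr = sum(.data$omission_trial),
    n_corr = sum(.data$correct),
    premature = rate(n_prem, n_trials),
    omission_error = rate(n_omerr, n_np),
    omission_trial = rate(n_omtr, n_trials),
    correct = rate(n_corr, n_trials),
    correct_np = rate(n_corr, n_np),
    .groups = "drop"
  )
  grid <- tidyr::expand_grid(mouse_phases(events), duration = srtt_durations())
  out <- dplyr::left_join(grid, out, by = c("mouse_id", "phase", "duration"))
  dplyr::select(out, "mouse_id", "phase", "duration", "premature",
                "omission_error", "omission_trial", "correct", "correct_np")
}

#' Avoided-corner nose-poke error rates (place avoidance)
#'
#' Per period (baseline, learning, retention, extinction): nose-pokes at the
#' air-puff-paired corner over nose-pokes at all corners; missing when the
#' mouse made no nose-pokes in the period. Retention and extinction rates
#' quantify aversive memory after the puff contingency is removed.
#'
#' @param events A cohort event-log tibble.
#' @param avoided_corner The corner (1-4) paired with the air puff.
#' @return A tibble `mouse_id`, `phase`, `period`, `rate`.
#' @export
avoidance_error_rates <- function(events, avoided_corner) {
  if (missing(avoided_corner) || is.null(avoided_corner) ||
      !avoided_corner %in% 1:4) {
    rlang::abort("`avoided_corner` must be a corner in 1..4")
  }
  ev <- dplyr::filter(events, .data$task == "PA", .data$event == "nosepoke")
  out <- dplyr::summarise(
    dplyr::group_by(ev, .data$mouse_id, .data$phase, .data$period),
    rate = mean(.data$corner == avoided_corner), .groups = "drop"
  )
  grid <- tidyr::expand_grid(mouse_phases(events), period = pa_periods())
  dplyr::left_join(grid, out, by = c("mouse_id", "phase", "period"))
}

#' Per-delay saccharin nose-poke and lick rates (delay discounting)
#'
#' In the delay-discounting task the saccharin bottle's door opens only after
#' a delay (0-8 s past the nose-poke) while water is immediate; persistent
#' nose-pokes and licks at the saccharin side index compulsive behavior.
#' Rates are normalized per visit within each delay condition: saccharin-side
#' nose-pokes (licks) over visits in that delay's sessions; missing when there
#' were no visits.
#'
#' @param events A cohort event-log tibble.
#' @param sacc_side Bottle side (`"L"`/`"R"`) holding the saccharin solution.
#' @return A tibble `mouse_id`, `phase`, `delay`, `np_rate`, `lick_rate`.
#' @export
dd_rates <- function(events, sacc_side = "R") {
  stopifnot(sacc_side %in% c("L", "R"))
  ev <- dplyr::filter(events, .data$task == "DD")
  if (nrow(ev) > 0 &&
      any(ev$event %in% c("nosepoke", "lick") & is.na(ev$side))) {
    rlang::abort("delay-discounting nose-pokes/licks must carry a bottle side")
  }
  out <- dplyr::summarise(
    dplyr::group_by(ev, .data$mouse_id, .data$phase, delay = .data$condition),
    n_visits = sum(.data$event == "visit_start"),
    np_rate = ifelse(n_visits > 0,
                     sum(.data$event == "nosepoke" & .data$side == sacc_side,
                         na.rm = TRUE) / n_visits, NA_real_),
    lick_rate = ifelse(n_visits > 0,
                       sum(.data$event == "lick" & .data$side == sacc_side,
                           na.rm = TRUE) / n_visits, NA_real_),
    .groups = "drop"
  )
  grid <- tidyr::expand_grid(mouse_phases(events), delay = dd_delays())
  out <- dplyr::left_join(grid, out, by = c("mouse_id", "phase", "delay"))
  dplyr::select(out, -"n_visits")
}

mouse_phases <- function(events) {
  dplyr::distinct(events, .data$mouse_id, .data$phase)
}

complete_grid <- function(out, events, days, value) {
  grid <- tidyr::expand_grid(mouse_phases(events), day = as.integer(days))
  dplyr::left_join(grid, out, by = c("mouse_id", "phase", "day"))
}

#' Default corner assignments for the cohort
#'
#' The correct corner for place preference, its diagonal for the reversal, and
#' the air-puff corner for place avoidance. The synthetic cohort generator
#' uses the same convention.
#'
#' @return Named integer vector with entries `PP`, `PPR`, `PA`.
#' @export
default_corners <- function() c(PP = 1L, PPR = 3L, PA = 2L)

#' Extract the full behavioral feature table from an event log
#'
#' Dispatches to the five task extractors and assembles one row per
#' (mouse, phase) with exactly the schema's feature columns; cells whose
#' denominator was empty (no visits/trials/pokes for that mouse, day or
#' condition) are missing.
#'
#' @param events A cohort event-log tibble (validated; see
#'   [validate_event_log()]).
#' @param schema Feature schema, see [default_schema()].
#' @param corners Named corner assignments, see [default_corners()].
#' @param sacc_side Saccharin bottle side in the delay-discounting task.
#' @return A feature table: tibble with columns `mouse_id`, `genotype`,
#'   `sex`, `phase`, then the schema features, rows ordered by
#'   (mouse_id, phase).
#' @export
extract_features <- function(events, schema = default_schema(),
                             corners = default_corners(), sacc_side = "R") {
  stopifnot(all(c("PP", "PPR", "PA") %in% names(corners)))
  if (nrow(events) == 0) rlang::abort("empty event log")
  num_from_id <- function(ids, prefix) {
    as.numeric(sub(prefix, "", ids, fixed = TRUE))
  }
  sch <- split(schema, schema$group)
  long <- list()
  for (task in c("PP", "PPR")) {
    g <- if (task == "PP") sch[["1"]] else sch[["2"]]
    days <- as.integer(num_from_id(g$feature_id, paste0(tolower(task), "_day")))
    lv <- learning_visit_rates(events, task, corners[[task]], days = days)
    lv$feature_id <- paste0(tolower(task), "_day", lv$day)
    long[[task]] <- dplyr::select(lv, "mouse_id", "phase", "feature_id",
                                  value = "rate")
  }
  g3_days <- as.integer(num_from_id(sch[["3"]]$feature_id, "srtt_prem_day"))
  imp <- srtt_impulsivity(events, days = g3_days)
  imp$feature_id <- paste0("srtt_prem_day", imp$day)
  long$imp <- dplyr::select(imp, "mouse_id", "phase", "feature_id",
                            value = "rate")
  att <- srtt_attention(events)
  att_long <- tidyr::pivot_longer(
    att, c("premature", "omission_error", "omission_trial",
           "correct", "correct_np"),
    names_to = "metric", values_to = "value"
  )
  att_prefix <- c(premature = "srtt_prem_", omission_error = "srtt_omierr_",
                  omission_trial = "srtt_omitrial_", correct = "srtt_correct_",
                  correct_np = "srtt_correct_np_")
  att_long$feature_id <- paste0(att_prefix[att_long$metric],
                                format_num(att_long$duration), "s")
  long$att <- dplyr::select(att_long, "mouse_id", "phase", "feature_id",
                            "value")
  pa <- avoidance_error_rates(events, corners[["PA"]])
  pa$feature_id <- paste0("pa_", pa$period)
  long$pa <- dplyr::select(pa, "mouse_id", "phase", "feature_id",
                           value = "rate")
  dd <- dd_rates(events, sacc_side = sacc_side)
  dd_long <- tidyr::pivot_longer(dd, c("np_rate", "lick_rate"),
                                 names_to = "metric", values_to = "value")
  dd_long$feature_id <- paste0(
    ifelse(dd_long$metric == "np_rate", "dd_np_", "dd_lick_"),
    format_num(dd_long$delay), "s"
  )
  long$dd <- dplyr::select(dd_long, "mouse_id", "phase", "feature_id", "value")

  all_long <- dplyr::filter(dplyr::bind_rows(long),
                            .data$feature_id %in% schema$feature_id)
  meta <- dplyr::distinct(events, .data$mouse_id, .data$phase,
                          .data$genotype, .data$sex)
  grid <- tidyr::expand_grid(dplyr::distinct(meta, .data$mouse_id, .data$phase),
                             feature_id = schema$feature_id)
  all_long <- dplyr::left_join(grid, all_long,
                               by = c("mouse_id", "phase", "feature_id"))
  wide <- tidyr::pivot_wider(all_long, names_from = "feature_id",
                             values_from = "value")
  wide <- dplyr::left_join(wide, meta, by = c("mouse_id", "phase"))
  out <- dplyr::select(wide, dplyr::all_of(c(meta_cols(), schema$feature_id)))
  dplyr::arrange(out, .data$mouse_id, .data$phase)
}

#' Assemble a cohort feature table
#'
#' Thin wrapper over [extract_features()] that accepts either one cohort
#' event tibble or a list of per-mouse event tibbles, rejects duplicate
#' (mouse, phase) entries across list elements, and returns rows in
#' deterministic (mouse_id, phase) order.
#'
#' @inheritParams extract_features
#' @param cohort A cohort event tibble, or a list of event tibbles.
#' @return A feature table tibble.
#' @export
build_feature_table <- function(cohort, schema = default_schema(),
                                corners = default_corners(), sacc_side = "R") {
  if (is.data.frame(cohort)) {
    events <- cohort
  } else {
    if (length(cohort) == 0) rlang::abort("empty cohort")
    keys <- lapply(cohort, function(x) {
      unique(paste(x$mouse_id, x$phase))
    })
    all_keys <- unlist(keys)
    if (anyDuplicated(all_keys)) {
      rlang::abort(paste0("duplicate (mouse_id, phase) across cohort logs: ",
                          all_keys[duplicated(all_keys)][1]))
    }
    events <- dplyr::bind_rows(cohort)
  }
  if (nrow(events) == 0) rlang::abort("empty cohort")
  extract_features(events, schema, corners, sacc_side)
}

#' Drop features unavailable for most of the cohort
#'
#' Removes every feature whose missing-cell fraction strictly exceeds
#' `max_missing_fraction` (default: unavailable for more than half of the
#' sample); remaining missing cells are retained — imputation is a
#' training-fold concern in [cross_validate()], so no information leaks from
#' held-out animals.
#'
#' @param table A feature table.
#' @param max_missing_fraction Strict threshold on the per-feature missing
#'   fraction.
#' @return The filtered feature table, with the dropped feature ids in
#'   `attr(, "dropped")`.
#' @export
missingness_filter <- function(table, max_missing_fraction = 0.5) {
  feats <- feature_cols(table)
  frac <- vapply(table[feats], function(v) mean(is.na(v)), numeric(1))
  drop <- feats[frac > max_missing_fraction]
  keep <- setdiff(feats, drop)
  if (length(keep) == 0) rlang::abort("all features exceed the missingness threshold")
  out <- dplyr::select(table, dplyr::all_of(c(meta_cols(), keep)))
  attr(out, "dropped") <- drop
  out
}
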