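#' Effect profiles for synthetic cohorts
#'
#' An effect profile gives, per schema feature, the wild-type mean, knock-in
#' mean, common SD and missingness probability used by the cohort generators.
#' The named presets mirror where the genotype contrast concentrates in each
#' testing window: in the early phase the knock-in line shows compulsive
#' persistence toward the delayed saccharin reward (higher delay-discounting
#' nose-poke and lick rates, groups 10-11) with a hint of reduced reversal
#' learning on day 1; in the later phase reversal-learning correct-visit rates
#' (group 2) drop in the knock-in line while the delay-discounting contrast
#' persists. Planted effects use a standardized mean difference `d`
#' (default 1.2); baseline means/SDs are generator conventions, since the
#' source plots report the pattern rather than the numbers.
#'
#' @param preset One of `"null"` (no genotype effect), `"phase1"`, `"phase2"`.
#' @param schema A feature schema, see [default_schema()].
#' @param d Standardized mean difference planted on affected features.
#' @return A tibble with columns `feature_id`, `group`, `task`, `kind`,
#'   `mean_wt`, `mean_ki`, `sd`, `miss_prob`.
#' @export
effect_profile <- function(preset = c("null", "phase1", "phase2"),
                           schema = default_schema(), d = 1.2) {
  preset <- match.arg(preset)
  base_mean <- c(`1` = 0.5, `2` = 0.5, `3` = 0.3, `4` = 0.3, `5` = 0.2,
                 `6` = 0.2, `7` = 0.45, `8` = 0.6, `9` = 0.25, `10` = 1.5,
                 `11` = 4.0)
  base_sd <- c(`1` = 0.15, `2` = 0.15, `3` = 0.15, `4` = 0.15, `5` = 0.1,
               `6` = 0.1, `7` = 0.15, `8` = 0.15, `9` = 0.1, `10` = 0.5,
               `11` = 1.5)
  prof <- dplyr::mutate(
    schema,
    mean_wt = unname(base_mean[as.character(.data$group)]),
    sd = unname(base_sd[as.character(.data$group)]),
    miss_prob = ifelse(.data$group %in% c(3L, 10L), 0.1, 0),
    shift = 0
  )
  if (preset == "phase1") {
    prof$shift[prof$group %in% c(10L, 11L)] <- d
    prof$shift[prof$feature_id == "ppr_day1"] <- -d
  } else if (preset == "phase2") {
    prof$shift[prof$group == 2L] <- -d
    prof$shift[prof$group %in% c(10L, 11L)] <- d
  }
  prof$mean_ki <- prof$mean_wt + prof$shift * prof$sd
  prof$shift <- NULL
  dplyr::select(prof, "feature_id", "group", "task", "kind",
                "mean_wt", "mean_ki", "sd", "miss_prob")
}

#' Configure a synthetic cohort
#'
#' Cohort sizes default, per testing window, to the two-phase aging design
#' the package targets:
#' 13 WT / 14 KI in phase 1 (ages 8-12 months), 14/15 in phase 2 (13-17
#' months), and 10/10 mice observed in both phases.
#'
#' @param n_wt,n_ki Group sizes (each >= 2). `NULL` uses the phase default.
#' @param phase `1`, `2`, or `"both"`.
#' @param effect A preset name (`"null"`, `"phase1"`, `"phase2"`, `"both"`)
#'   or an effect-profile tibble from [effect_profile()]. `"both"` applies the
#'   phase-1 preset to phase-1 rows and the phase-2 preset to phase-2 rows.
#' @param level `"feature"` or `"event"`: which generator the config drives.
#' @param seed Integer seed; the generators are pure functions of the config.
#' @param visits Event-level sessions' size: visits (or trials/pokes) per
#'   task-day session.
#' @param schema Feature schema the cohort follows.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_wt = NULL, n_ki = NULL, phase = 1,
                       effect = "null", level = c("feature", "event"),
                       seed = 1L, visits = 50L, schema = default_schema()) {
  phase <- as.character(phase)
  if (!phase %in% c("1", "2", "both")) {
    rlang::abort("`phase` must be 1, 2, or \"both\"")
  }
  defaults <- list(`1` = c(13L, 14L), `2` = c(14L, 15L), both = c(10L, 10L))
  if (is.null(n_wt)) n_wt <- defaults[[phase]][1]
  if (is.null(n_ki)) n_ki <- defaults[[phase]][2]
  if (n_wt < 2 || n_ki < 2) rlang::abort("group sizes must be >= 2")
  if (is.character(effect)) {
    if (!effect %in% c("null", "phase1", "phase2", "both")) {
      rlang::abort(paste0("unknown effect preset: ", effect))
    }
  } else if (!is.data.frame(effect)) {
    rlang::abort("`effect` must be a preset name or an effect-profile tibble")
  }
  structure(list(n_wt = as.integer(n_wt), n_ki = as.integer(n_ki),
                 phase = phase, effect = effect, level = match.arg(level),
                 seed = as.integer(seed), visits = as.integer(visits),
                 schema = schema),
            class = "sim_config")
}

#' Null (no-effect) cohort configuration
#'
#' Convenience wrapper: a [sim_config()] whose effect profile has identical
#' WT and KI means for every feature, for type-I-error and chance-level
#' calibration.
#'
#' @inheritParams sim_config
#' @return A `sim_config`.
#' @export
null_config <- function(n_wt = NULL, n_ki = NULL, phase = 1, seed = 1L) {
  sim_config(n_wt, n_ki, phase = phase, effect = "null", seed = seed)
}

# resolve the effect argument to one profile per phase
resolve_profiles <- function(config) {
  phases <- if (config$phase == "both") c("1", "2") else config$phase
  get_one <- function(ph) {
    if (is.data.frame(config$effect)) return(config$effect)
    if (config$effect == "both") {
      return(effect_profile(paste0("phase", ph), schema = config$schema))
    }
    effect_profile(config$effect, schema = config$schema)
  }
  stats::setNames(lapply(phases, get_one), phases)
}

cohort_mice <- function(config) {
  ids <- c(sprintf("wt%02d", seq_len(config$n_wt)),
           sprintf("ki%02d", seq_len(config$n_ki)))
  tibble::tibble(
    mouse_id = ids,
    genotype = rep(c("WT", "KI"), c(config$n_wt, config$n_ki)),
    sex = c(rep_len(c("M", "F"), config$n_wt), rep_len(c("M", "F"), config$n_ki))
  )
}

clip_kind <- function(v, kind) {
  ifelse(kind == "rate", pmin(pmax(v, 0), 1), pmax(v, 0))
}

#' Simulate a feature-level cohort table
#'
#' Draws each mouse's feature vector independently, feature `f` for genotype
#' `g` from Normal(mean_g(f), SD(f)); rate-kind features are clipped to
#' \[0,1\], per-visit counts to >= 0; cells are then masked missing with the
#' profile's per-feature probability. Identical config (including seed) gives
#' an identical table.
#'
#' @param config A [sim_config()].
#' @return A feature table: tibble with `mouse_id`, `genotype`, `sex`,
#'   `phase`, then the schema's feature columns.
#' @examples
#' tab <- simulate_feature_table(sim_config(effect = "phase1", seed = 7))
#' dim(tab)
#' @export
simulate_feature_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  profiles <- resolve_profiles(config)
  mice <- cohort_mice(config)
  withr::with_seed(config$seed, {
    blocks <- list()
    for (ph in names(profiles)) {
      prof <- profiles[[ph]]
      vals <- matrix(NA_real_, nrow(mice), nrow(prof),
                     dimnames = list(NULL, prof$feature_id))
      for (i in seq_len(nrow(mice))) {
        mu <- if (mice$genotype[i] == "WT") prof$mean_wt else prof$mean_ki
        v <- clip_kind(stats::rnorm(nrow(prof), mu, prof$sd), prof$kind)
        v[stats::runif(nrow(prof)) < prof$miss_prob] <- NA_real_
        vals[i, ] <- v
      }
      blocks[[ph]] <- tibble::new_tibble(
        c(list(mouse_id = mice$mouse_id, genotype = mice$genotype,
               sex = mice$sex, phase = rep(as.integer(ph), nrow(mice))),
          as.list(as.data.frame(vals))),
        nrow = nrow(mice))
    }
    dplyr::arrange(dplyr::bind_rows(blocks), .data$mouse_id, .data$phase)
  })
}

#' Simulate an event-level cohort
#'
#' Generates a full cohort event log whose feature extraction recovers, up to
#' binomial/Poisson noise, per-mouse target values drawn exactly as in
#' [simulate_feature_table()]. Per task and session: place-preference and
#' reversal visits hit the correct corner with probability equal to the
#' mouse's target daily rate; serial-reaction-time trials are driven by the
#' omission-trial, premature-trial and lick-given-open primitives (so the
#' correct-rate features of groups 7-8 emerge from those primitives, with the
#' lick probability inverted from the group-8 target); place-avoidance
#' nose-pokes hit the avoided corner with the target period rate; and
#' delay-discounting saccharin nose-pokes and licks are Poisson counts per
#' visit with the target per-visit rates. Sessions backing features with a
#' nonzero missingness probability are skipped with that probability.
#'
#' Correct corners are corner 1 (PP), corner 3 (its diagonal, PPR) and the
#' avoided corner is corner 2; the saccharin bottle is side `"R"`.
#'
#' @param config A [sim_config()] (any `level`; `visits` sets session size).
#' @return A cohort event-log tibble in canonical column order, one row per
#'   event, passing [validate_event_log()].
#' @export
simulate_event_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  profiles <- resolve_profiles(config)
  mice <- cohort_mice(config)
  withr::with_seed(config$seed, {
    out <- list()
    for (ph in names(profiles)) {
      prof <- profiles[[ph]]
      for (i in seq_len(nrow(mice))) {
        mu <- if (mice$genotype[i] == "WT") prof$mean_wt else prof$mean_ki
        tg <- stats::setNames(clip_kind(stats::rnorm(nrow(prof), mu, prof$sd),
                                        prof$kind), prof$feature_id)
        miss <- stats::setNames(prof$miss_prob, prof$feature_id)
        ev <- sim_mouse_events(tg, miss, config$visits)
        ev$mouse_id <- mice$mouse_id[i]
        ev$genotype <- mice$genotype[i]
        ev$sex <- mice$sex[i]
        ev$phase <- as.integer(ph)
        out[[length(out) + 1]] <- ev
      }
    }
    dplyr::select(dplyr::bind_rows(out), dplyr::all_of(event_log_cols()))
  })
}

# one mouse-phase worth of events given its target feature values
sim_mouse_events <- function(tg, miss, nv) {
  pieces <- list()
  tget <- function(id, default = NA_real_) {
    if (id %in% names(tg)) unname(tg[[id]]) else default
  }
  # place preference and reversal: 7 days each
  for (task in c("PP", "PPR")) {
    cc <- if (task == "PP") 1L else 3L
    pre <- if (task == "PP") "pp_day" else "ppr_day"
    for (d in 1:7) {
      pieces[[length(pieces) + 1]] <-
        sim_pp_session(task, d, tget(paste0(pre, d)), cc, nv)
    }
  }
  # serial reaction time: 10 days, attention structure on days 5-7
  for (d in 1:10) {
    id3 <- paste0("srtt_prem_day", d)
    p_miss <- if (id3 %in% names(miss)) miss[[id3]] else 0
    if (stats::runif(1) < p_miss) next
    pieces[[length(pieces) + 1]] <-
      sim_srtt_session(d, nv, tg, day_prem = tget(id3, default = 0.3))
  }
  # place avoidance: one session per period
  for (per in pa_periods()) {
    pieces[[length(pieces) + 1]] <-
      sim_pa_session(per, tget(paste0("pa_", per)), avoided = 2L, nv)
  }
  # delay discounting: one session per delay condition
  delays <- dd_delays()
  for (k in seq_along(delays)) {
    del <- delays[k]
    np_id <- paste0("dd_np_", format_num(del), "s")
    p_miss <- if (np_id %in% names(miss)) miss[[np_id]] else 0
    if (stats::runif(1) < p_miss) next
    pieces[[length(pieces) + 1]] <- sim_dd_session(
      day = k, delay = del,
      np_rate = tget(np_id, default = 1.5),
      lick_rate = tget(paste0("dd_lick_", format_num(del), "s"), default = 4),
      nv = nv
    )
  }
  dplyr::bind_rows(pieces)
}

blank_events <- function(task, day, period, time_s, event, corner, side,
                         condition) {
  # times on a millisecond grid: canonical doubles that survive CSV round-trips
  tibble::tibble(task = task, day = as.integer(day), period = period,
                 time_s = round(time_s, 3), event = event,
                 corner = as.integer(corner), side = side,
                 condition = condition)
}

sim_pp_session <- function(task, day, rate, cc, nv) {
  correct <- stats::runif(nv) < rate
  corner <- ifelse(correct, cc,
                   sample(setdiff(1:4, cc), nv, replace = TRUE))
  t0 <- (seq_len(nv) - 1) * 10
  ev <- dplyr::bind_rows(
    blank_events(task, day, NA, t0, "visit_start", corner, NA, NA),
    blank_events(task, day, NA, t0 + 1, "nosepoke", corner, NA, NA),
    blank_events(task, day, NA, t0[correct] + 2, "lick", corner[correct], NA, NA),
    blank_events(task, day, NA, t0 + 4, "visit_end", corner, NA, NA)
  )
  dplyr::arrange(ev, .data$time_s)
}

sim_srtt_session <- function(day, nv, tg, day_prem) {
  durs <- srtt_durations()[rep_len(1:3, nv)]
  waits <- srtt_waits()[rep_len(rep(1:3, each = 3), nv)]
  attn <- day %in% 5:7
  dl <- format_num(durs)
  p_om <- if (attn) unname(tg[paste0("srtt_omitrial_", dl, "s")]) else rep(0.15, nv)
  p_pre <- if (attn) unname(tg[paste0("srtt_prem_", dl, "s")]) else rep(day_prem, nv)
  c8 <- if (attn) unname(tg[paste0("srtt_correct_np_", dl, "s")]) else rep(0.7, nv)
  # invert the correct-from-non-premature target to a lick-given-open
  # probability: non-premature trials include omission trials
  q <- pmin(1, c8 * (p_om + (1 - p_om) * (1 - p_pre)) /
              pmax(1e-9, (1 - p_om) * (1 - p_pre)))
  om <- stats::runif(nv) < p_om
  init <- !om
  prem <- init & stats::runif(nv) < p_pre
  normal <- init & !prem
  licked <- normal & stats::runif(nv) < q
  t0 <- (seq_len(nv) - 1) * 20
  t_led <- t0 + 1 + waits
  t_open <- t_led + 0.05
  t_close <- t_open + durs
  ev <- dplyr::bind_rows(
    blank_events("SRTT", day, NA, t0, "visit_start", 1L, NA, durs),
    blank_events("SRTT", day, NA, t0[init] + 1, "nosepoke", 1L, NA, durs[init]),
    blank_events("SRTT", day, NA, t0[prem] + 1.4, "nosepoke", 1L, NA, durs[prem]),
    blank_events("SRTT", day, NA, t_led[normal], "led_on", 1L, NA, durs[normal]),
    blank_events("SRTT", day, NA, t_open[normal], "door_open", 1L, NA, durs[normal]),
    blank_events("SRTT", day, NA, t_open[licked] + durs[licked] / 2, "lick",
                 1L, NA, durs[licked]),
    blank_events("SRTT", day, NA, t_close[normal], "door_close", 1L, NA,
                 durs[normal]),
    blank_events("SRTT", day, NA,
                 ifelse(normal, t_close + 0.5, t0 + 3), "visit_end", 1L, NA, durs)
  )
  dplyr::arrange(ev, .data$time_s)
}

sim_pa_session <- function(period, rate, avoided, nv) {
  hit <- stats::runif(nv) < rate
  corner <- ifelse(hit, avoided,
                   sample(setdiff(1:4, avoided), nv, replace = TRUE))
  t0 <- (seq_len(nv) - 1) * 10
  puffed <- hit & period == "learning"
  ev <- dplyr::bind_rows(
    blank_events("PA", 1L, period, t0, "visit_start", corner, NA, NA),
    blank_events("PA", 1L, period, t0 + 1, "nosepoke", corner, NA, NA),
    blank_events("PA", 1L, period, t0[puffed] + 1.2, "airpuff", corner[puffed],
                 NA, NA),
    blank_events("PA", 1L, period, t0 + 2, "visit_end", corner, NA, NA)
  )
  dplyr::arrange(ev, .data$time_s)
}

sim_dd_session <- function(day, delay, np_rate, lick_rate, nv) {
  kn <- stats::rpois(nv, np_rate)
  kl <- stats::rpois(nv, lick_rate)
  kw <- stats::rpois(nv, 1) # water-bottle licks, opposite side
  t0 <- (seq_len(nv) - 1) * 20
  ev <- dplyr::bind_rows(
    blank_events("DD", day, NA, t0, "visit_start", 4L, NA, delay),
    blank_events("DD", day, NA, rep(t0, kn) + sequence(kn) * 0.05, "nosepoke",
                 4L, "R", delay),
    blank_events("DD", day, NA, rep(t0, kl) + 2 + sequence(kl) * 0.05, "lick",
                 4L, "R", delay),
    blank_events("DD", day, NA, rep(t0, kw) + 5 + sequence(kw) * 0.05, "lick",
                 4L, "L", delay),
    blank_events("DD", day, NA, t0 + 9, "visit_end", 4L, NA, delay)
  )
  dplyr::arrange(ev, .data$time_s)
}
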