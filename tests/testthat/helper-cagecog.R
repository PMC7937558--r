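# hand-built event fixtures and brute-force oracles

mk_events <- function(task, day, time_s, event, corner,
                      period = NA_character_, side = NA_character_,
                      condition = NA_real_, mouse_id = "m1",
                      genotype = "WT", sex = "M", phase = 1L) {
  n <- length(time_s)
  tibble::tibble(
    mouse_id = rep_len(mouse_id, n), genotype = rep_len(genotype, n),
    sex = rep_len(sex, n), phase = rep_len(as.integer(phase), n),
    task = rep_len(task, n), day = rep_len(as.integer(day), n),
    period = rep_len(period, n), time_s = time_s,
    event = event, corner = rep_len(as.integer(corner), n),
    side = rep_len(side, n), condition = rep_len(condition, n)
  )
}

# one place-preference day: n visits, k to the correct corner
pp_day_events <- function(day, n, k, correct_corner = 1L, task = "PP", ...) {
  corner <- c(rep(correct_corner, k), rep(setdiff(1:4, correct_corner)[1], n - k))
  t0 <- (seq_len(n) - 1) * 10
  dplyr::bind_rows(
    mk_events(task, day, t0, "visit_start", corner, ...),
    mk_events(task, day, t0 + 4, "visit_end", corner, ...)
  ) |> dplyr::arrange(time_s)
}

# one SRTT trial of a given type starting at t0
srtt_trial_events <- function(day, t0, duration, type, wait = 2, ...) {
  mk <- function(off, event) mk_events("SRTT", day, t0 + off, event, 1L,
                                       condition = duration, ...)
  switch(type,
    omission = dplyr::bind_rows(mk(0, "visit_start"), mk(3, "visit_end")),
    premature = dplyr::bind_rows(mk(0, "visit_start"), mk(1, "nosepoke"),
                                 mk(1.4, "nosepoke"), mk(3, "visit_end")),
    premature3 = dplyr::bind_rows(mk(0, "visit_start"), mk(1, "nosepoke"),
                                  mk(1.2, "nosepoke"), mk(1.3, "nosepoke"),
                                  mk(3, "visit_end")),
    correct = dplyr::bind_rows(mk(0, "visit_start"), mk(1, "nosepoke"),
                               mk(1 + wait, "led_on"),
                               mk(1.05 + wait, "door_open"),
                               mk(1.05 + wait + duration / 2, "lick"),
                               mk(1.05 + wait + duration, "door_close"),
                               mk(2 + wait + duration, "visit_end")),
    miss = dplyr::bind_rows(mk(0, "visit_start"), mk(1, "nosepoke"),
                            mk(1 + wait, "led_on"),
                            mk(1.05 + wait, "door_open"),
                            mk(1.05 + wait + duration, "door_close"),
                            mk(2 + wait + duration, "visit_end")),
    stop("unknown trial type")
  )
}

srtt_day_events <- function(day, duration, types, ...) {
  t0 <- (seq_along(types) - 1) * 20
  dplyr::bind_rows(purrr::map2(t0, types, function(t, ty) {
    srtt_trial_events(day, t, duration, ty, ...)
  })) |> dplyr::arrange(time_s)
}

pa_period_events <- function(period, n, k, avoided = 2L, ...) {
  corner <- c(rep(avoided, k), rep(setdiff(1:4, avoided)[1], n - k))
  t0 <- (seq_len(n) - 1) * 10
  dplyr::bind_rows(
    mk_events("PA", 1L, t0, "visit_start", corner, period = period, ...),
    mk_events("PA", 1L, t0 + 1, "nosepoke", corner, period = period, ...),
    mk_events("PA", 1L, t0 + 2, "visit_end", corner, period = period, ...)
  ) |> dplyr::arrange(time_s)
}

dd_day_events <- function(day, delay, n_visits, pokes_per_visit,
                          licks_per_visit, lick_side = "R", ...) {
  t0 <- (seq_len(n_visits) - 1) * 20
  ev <- list(
    mk_events("DD", day, t0, "visit_start", 4L, condition = delay, ...),
    mk_events("DD", day, t0 + 9, "visit_end", 4L, condition = delay, ...)
  )
  if (pokes_per_visit > 0) {
    ev <- c(ev, list(mk_events("DD", day,
                               rep(t0, each = pokes_per_visit) +
                                 seq_len(pokes_per_visit) * 0.1,
                               "nosepoke", 4L, side = "R",
                               condition = delay, ...)))
  }
  if (licks_per_visit > 0) {
    ev <- c(ev, list(mk_events("DD", day,
                               rep(t0, each = licks_per_visit) + 2 +
                                 seq_len(licks_per_visit) * 0.1,
                               "lick", 4L, side = lick_side,
                               condition = delay, ...)))
  }
  dplyr::bind_rows(ev) |> dplyr::arrange(time_s)
}

# exhaustive single-feature threshold search: every midpoint x both directions
oracle_rule <- function(v, y) {
  ki <- y == "KI"
  u <- sort(unique(v))
  if (length(u) == 1) {
    maj_ki <- sum(ki) > sum(!ki)
    return(list(threshold = if (maj_ki) u - 1 else u,
                direction = "ki_gt_wt",
                accuracy = max(sum(ki), sum(!ki)) / length(y)))
  }
  thr <- (u[-length(u)] + u[-1]) / 2
  best <- list(accuracy = -1)
  for (tr in thr) {
    for (dir in c("ki_gt_wt", "ki_lt_wt")) {
      pred <- if (dir == "ki_gt_wt") v > tr else v < tr
      acc <- mean(pred == ki)
      better <- acc > best$accuracy ||
        (acc == best$accuracy && tr < best$threshold) ||
        (acc == best$accuracy && tr == best$threshold &&
           dir == "ki_gt_wt" && best$direction == "ki_lt_wt")
      if (better) best <- list(threshold = tr, direction = dir, accuracy = acc)
    }
  }
  best
}

oracle_vote <- function(rules, X) {
  n <- nrow(X)
  out <- character(n)
  for (i in seq_len(n)) {
    votes <- 0
    for (r in seq_len(nrow(rules))) {
      v <- X[i, rules$feature_id[r]]
      hit <- if (rules$direction[r] == "ki_gt_wt") v > rules$threshold[r] else v < rules$threshold[r]
      votes <- votes + hit
    }
    out[i] <- if (votes > nrow(rules) / 2) "KI" else "WT"
  }
  out
}

# textbook pooled-variance t statistic
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# tiny two-feature separable feature table for classifier tests
toy_table <- function(n_per = 10, gap = 3, seed = 42, sd = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      mouse_id = sprintf("m%02d", 1:(2 * n_per)),
      genotype = rep(c("WT", "KI"), each = n_per),
      sex = rep_len(c("M", "F"), 2 * n_per),
      phase = 1L,
      f1 = rnorm(2 * n_per, rep(c(0, gap), each = n_per), sd),
      f2 = rnorm(2 * n_per, rep(c(0, gap), each = n_per), sd)
    )
  })
}
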