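#' Read a cohort event log from CSV
#'
#' Event logs hold the raw automated-cage record for a cohort: timestamped
#' corner visits, nose-pokes, licks, LED/door and air-puff events, one row per
#' event, with task/day/period/condition labels. The canonical CSV header is
#' `mouse_id,genotype,sex,phase,task,day,period,time_s,event,corner,side,condition`
#' (UTF-8, LF, "." decimal separator; empty string for absent
#' period/side/condition).
#'
#' Enumerations are checked at read time: unknown task or event codes, corners
#' outside 1-4, genotypes outside WT/KI and negative times are rejected with
#' the offending line numbers. Structural invariants (visit pairing, time
#' monotonicity, side labels) are checked separately by [validate_event_log()].
#'
#' @param path Path to the CSV file (or a connection readr accepts).
#' @return A tibble with the twelve canonical columns, rows in file order.
#' @seealso [write_event_log()], [validate_event_log()]
#' @export
read_event_log <- function(path) {
  spec <- readr::cols(
    mouse_id = readr::col_character(), genotype = readr::col_character(),
    sex = readr::col_character(), phase = readr::col_integer(),
    task = readr::col_character(), day = readr::col_integer(),
    period = readr::col_character(), time_s = readr::col_double(),
    event = readr::col_character(), corner = readr::col_integer(),
    side = readr::col_character(), condition = readr::col_double()
  )
  log <- readr::read_csv(path, col_types = spec, na = "", progress = FALSE,
                         lazy = FALSE)
  probs <- readr::problems(log)
  if (nrow(probs) > 0) {
    rlang::abort(paste0(
      "Malformed event CSV: parse failure at line(s) ",
      paste(utils::head(unique(probs$row), 5) + 1L, collapse = ", "),
      " (", probs$expected[1], " vs. ", probs$actual[1], ")"
    ))
  }
  if (!identical(names(log), event_log_cols())) {
    rlang::abort(paste0("Event CSV must have header: ",
                        paste(event_log_cols(), collapse = ",")))
  }
  check_enum <- function(ok, what) {
    if (any(!ok)) {
      rlang::abort(paste0("Invalid ", what, " at line(s) ",
                          paste(utils::head(which(!ok), 5) + 1L, collapse = ", ")))
    }
  }
  if (nrow(log) > 0) {
    check_enum(log$genotype %in% c("WT", "KI"), "genotype")
    check_enum(log$sex %in% c("M", "F"), "sex")
    check_enum(log$phase %in% c(1L, 2L), "phase")
    check_enum(log$task %in% task_codes(), "task code")
    check_enum(log$event %in% event_codes(), "event code")
    check_enum(!is.na(log$day) & log$day >= 1L, "day")
    check_enum(!is.na(log$corner) & log$corner %in% 1:4, "corner")
    check_enum(!is.na(log$time_s) & log$time_s >= 0, "time_s")
    check_enum(is.na(log$side) | log$side %in% c("L", "R"), "side")
    check_enum(is.na(log$period) | log$period %in% pa_periods(), "period")
  }
  log
}

event_log_cols <- function() {
  c("mouse_id", "genotype", "sex", "phase", "task", "day", "period",
    "time_s", "event", "corner", "side", "condition")
}

#' Write a cohort event log to canonical CSV
#'
#' Emits the canonical event CSV ([read_event_log()] inverts it exactly on
#' files this writer produced). Absent period/side/condition cells are written
#' as empty strings; output is deterministic for equal inputs.
#'
#' @param log An event-log tibble as returned by [read_event_log()] or
#'   [simulate_event_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(identical(names(log), event_log_cols()))
  readr::write_csv(log, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate the structural invariants of an event log
#'
#' Checks, per (mouse, task, day, period) session: non-decreasing `time_s`;
#' every `visit_end` paired with an open `visit_start` at the same corner (and
#' no dangling opens); delay-discounting nose-pokes and licks carrying a
#' bottle side (`L`/`R`); and air-puffs confined to the place-avoidance task.
#' Violations are returned as data, not raised.
#'
#' @param log An event-log tibble.
#' @return A tibble of violations with columns `row` (1-based row index into
#'   `log`), `rule` and `message`; zero rows when the log is well formed.
#' @export
validate_event_log <- function(log) {
  stopifnot(identical(names(log), event_log_cols()))
  bad <- list()
  add <- function(rows, rule, msg) {
    if (length(rows) > 0) {
      bad[[length(bad) + 1]] <<- tibble::tibble(row = as.integer(rows),
                                                rule = rule, message = msg)
    }
  }
  idx <- seq_len(nrow(log))
  puff <- idx[log$event == "airpuff" & log$task != "PA"]
  add(puff, "airpuff_task", "airpuff outside the place-avoidance task")
  dd_side <- idx[log$task == "DD" & log$event %in% c("lick", "nosepoke") &
                   is.na(log$side)]
  add(dd_side, "dd_side", "delay-discounting lick/nose-poke without a bottle side")

  key <- paste(log$mouse_id, log$task, log$day, ifelse(is.na(log$period), "", log$period))
  for (grp in split(idx, key)) {
    t <- log$time_s[grp]
    nonmono <- grp[-1][diff(t) < 0]
    add(nonmono, "time_monotone", "time_s decreases within a session")
    open <- integer(0) # stack of corners with an open visit
    for (i in grp) {
      ev <- log$event[i]
      if (ev == "visit_start") {
        open <- c(open, log$corner[i])
      } else if (ev == "visit_end") {
        if (length(open) == 0) {
          add(i, "visit_pairing", "visit_end without a preceding visit_start")
        } else {
          if (open[length(open)] != log$corner[i]) {
            add(i, "visit_pairing", "visit_end corner differs from its visit_start")
          }
          open <- open[-length(open)]
        }
      }
    }
  }
  if (length(bad) == 0) {
    tibble::tibble(row = integer(0), rule = character(0), message = character(0))
  } else {
    dplyr::arrange(dplyr::bind_rows(bad), .data$row)
  }
}
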