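#' The canonical 60-parameter behavioral feature schema
#'
#' The automated-cage battery yields 60 behavioral parameters in 11 groups:
#' daily correct-corner visit rates for place preference (group 1, 7 days) and
#' its reversal (group 2, 7 days); daily premature-trial rates in the serial
#' reaction time task (group 3, 8 of the 10 task days); attention metrics on
#' SRTT days 5-7 split by LED/door stimulus duration 0.3, 0.5 and 1 s
#' (groups 4-8: premature-trial rate, omission-error rate, omission-trial
#' rate, correct rate from all trials, correct rate from non-premature
#' trials); place-avoidance nose-poke error rates for the baseline, learning,
#' retention and extinction periods (group 9); and delay-discounting nose-poke
#' (group 10, 9 of the 10 delays) and lick (group 11, all 10 delays) rates at
#' the saccharin side, normalized per visit.
#'
#' Groups 3 and 10 carry reduced counts because in cohorts of this size some
#' day/delay cells are typically unavailable for more than half the animals;
#' which days and delays survive is configurable, and [missingness_filter()]
#' re-derives the drop from the data at hand.
#'
#' @param srtt_days Integer vector of SRTT task days retained in group 3.
#'   Default `3:10` (the earliest training days are the sparsest).
#' @param dd_np_delays Numeric vector of delay conditions (seconds) retained
#'   in group 10. Default drops the near-zero 0.1 s delay.
#' @return A tibble with one row per feature and columns `feature_id`,
#'   `group` (1-11), `task` (`PP`, `PPR`, `SRTT`, `PA`, `DD`), `descriptor`
#'   (human-readable day/duration/period/delay) and `kind` (`rate` in
#'   \[0,1\] or `count` per visit, >= 0).
#' @examples
#' sch <- default_schema()
#' nrow(sch) # 60
#' dplyr::count(sch, group)
#' @export
default_schema <- function(srtt_days = 3:10, dd_np_delays = c(0, 1:8)) {
  stopifnot(length(srtt_days) == 8, all(srtt_days %in% 1:10),
            length(dd_np_delays) == 9, all(dd_np_delays %in% dd_delays()))
  durations <- srtt_durations()
  dur_lab <- function(prefix) {
    tibble::tibble(
      feature_id = paste0(prefix, format_num(durations), "s"),
      descriptor = paste0("stimulus duration ", format_num(durations), " s")
    )
  }
  g4 <- dur_lab("srtt_prem_");      g5 <- dur_lab("srtt_omierr_")
  g6 <- dur_lab("srtt_omitrial_");  g7 <- dur_lab("srtt_correct_")
  g8 <- dur_lab("srtt_correct_np_")
  periods <- pa_periods()
  dplyr::bind_rows(
    tibble::tibble(feature_id = paste0("pp_day", 1:7), group = 1L, task = "PP",
                   descriptor = paste0("day ", 1:7), kind = "rate"),
    tibble::tibble(feature_id = paste0("ppr_day", 1:7), group = 2L, task = "PPR",
                   descriptor = paste0("day ", 1:7), kind = "rate"),
    tibble::tibble(feature_id = paste0("srtt_prem_day", srtt_days), group = 3L,
                   task = "SRTT", descriptor = paste0("day ", srtt_days),
                   kind = "rate"),
    tibble::tibble(feature_id = g4$feature_id, group = 4L, task = "SRTT",
                   descriptor = g4$descriptor, kind = "rate"),
    tibble::tibble(feature_id = g5$feature_id, group = 5L, task = "SRTT",
                   descriptor = g5$descriptor, kind = "rate"),
    tibble::tibble(feature_id = g6$feature_id, group = 6L, task = "SRTT",
                   descriptor = g6$descriptor, kind = "rate"),
    tibble::tibble(feature_id = g7$feature_id, group = 7L, task = "SRTT",
                   descriptor = g7$descriptor, kind = "rate"),
    tibble::tibble(feature_id = g8$feature_id, group = 8L, task = "SRTT",
                   descriptor = g8$descriptor, kind = "rate"),
    tibble::tibble(feature_id = paste0("pa_", periods), group = 9L, task = "PA",
                   descriptor = paste0(periods, " period"), kind = "rate"),
    tibble::tibble(feature_id = paste0("dd_np_", format_num(dd_np_delays), "s"),
                   group = 10L, task = "DD",
                   descriptor = paste0("delay ", format_num(dd_np_delays), " s"),
                   kind = "count"),
    tibble::tibble(feature_id = paste0("dd_lick_", format_num(dd_delays()), "s"),
                   group = 11L, task = "DD",
                   descriptor = paste0("delay ", format_num(dd_delays()), " s"),
                   kind = "count")
  )
}

# enumerations shared across modules ----------------------------------------

srtt_durations <- function() c(0.3, 0.5, 1)
srtt_waits <- function() c(1, 2, 4)
dd_delays <- function() c(0, 0.1, 1, 2, 3, 4, 5, 6, 7, 8)
pa_periods <- function() c("baseline", "learning", "retention", "extinction")
task_codes <- function() c("PP", "PPR", "SRTT", "PA", "DD")
event_codes <- function() c("visit_start", "visit_end", "nosepoke", "led_on",
                            "door_open", "door_close", "lick", "airpuff")

format_num <- function(x) {
  # "0.1" not "0.10", "1" not "1.0": stable ids for numeric descriptors
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE),
         character(1))
}

#' Metadata columns of a feature table
#'
#' @return Character vector of the non-feature columns every feature table
#'   carries: `mouse_id`, `genotype`, `sex`, `phase`.
#' @export
meta_cols <- function() c("mouse_id", "genotype", "sex", "phase")

#' Feature columns of a feature table
#'
#' @param table A feature table (tibble with [meta_cols()] then features).
#' @return Character vector of feature column names, in table order.
#' @export
feature_cols <- function(table) setdiff(names(table), meta_cols())
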