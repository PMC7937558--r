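#' Pooled-variance two-sample t test
#'
#' Student's t with the pooled variance estimate, so the degrees of freedom
#' are n1 + n2 - 2 (25 for a 13-vs-14 cohort, 27 for 14-vs-15). Missing
#' values are dropped per sample. Zero pooled variance is reported as a
#' degenerate result rather than an infinite statistic.
#'
#' @param x,y Numeric samples (x is conventionally the KI group when used for
#'   genotype contrasts; the `direction` field reads as sign(mean_x - mean_y)).
#' @return A one-row tibble: `t`, `df`, `p` (two-sided), `mean_x`, `mean_y`,
#'   `direction` (`"x_gt_y"`, `"x_lt_y"`, `"none"`), `degenerate`.
#' @examples
#' pooled_two_sample_t(c(1, 2, 3), c(2, 3, 4)) # t = -1.2247, df = 4
#' @export
pooled_two_sample_t <- function(x, y) {
  r <- pooled_t_stats(x, y)
  d <- r[["mean_x"]] - r[["mean_y"]]
  tibble::tibble(t = r[["t"]], df = as.integer(r[["df"]]), p = r[["p"]],
                 mean_x = r[["mean_x"]], mean_y = r[["mean_y"]],
                 direction = if (d > 0) "x_gt_y" else if (d < 0) "x_lt_y" else "none",
                 degenerate = r[["degenerate"]] == 1)
}

# closed-form pooled t, fast path shared by the per-feature screen
pooled_t_stats <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    rlang::abort("both samples need >= 2 non-missing values")
  }
  mx <- mean(x); my <- mean(y)
  df <- n1 + n2 - 2
  sp2 <- (sum((x - mx)^2) + sum((y - my)^2)) / df
  if (sp2 == 0) {
    tv <- if (mx == my) 0 else NA_real_
    return(c(t = tv, df = df, p = if (!is.na(tv)) 1 else NA_real_,
             mean_x = mx, mean_y = my, degenerate = 1))
  }
  tv <- (mx - my) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(t = tv, df = df, p = 2 * stats::pt(-abs(tv), df),
    mean_x = mx, mean_y = my, degenerate = 0)
}

#' Per-feature genotype t statistics
#'
#' Runs the pooled two-sample t test (KI vs WT) for every feature of a
#' feature table; no multiple-testing correction is applied (single-feature
#' screening convention), so at threshold `alpha` about `alpha * m` false
#' positives are expected under the null — the result carries that count as
#' context.
#'
#' @param table A feature table (both genotypes present).
#' @return A tibble, one row per feature: `feature_id`, `t`, `df`, `p`,
#'   `mean_wt`, `mean_ki`, `direction` (`"ki_gt_wt"`/`"ki_lt_wt"`/`"none"`),
#'   `degenerate`. Features with fewer than 2 values in either genotype get
#'   NA statistics. The expected null false-positive count at alpha = 0.05 is
#'   in `attr(, "expected_false_positives")`.
#' @export
genotype_tests <- function(table) {
  stopifnot(all(c("WT", "KI") %in% table$genotype))
  feats <- feature_cols(table)
  is_ki <- table$genotype == "KI"
  m <- length(feats)
  t_o <- numeric(m); df_o <- integer(m); p_o <- numeric(m)
  mw <- numeric(m); mk <- numeric(m); dir_o <- character(m); deg <- logical(m)
  for (i in seq_len(m)) {
    v <- table[[feats[i]]]
    ki <- v[is_ki]; wt <- v[!is_ki]
    if (sum(!is.na(ki)) < 2 || sum(!is.na(wt)) < 2) {
      t_o[i] <- NA; df_o[i] <- NA; p_o[i] <- NA
      mw[i] <- NA; mk[i] <- NA; dir_o[i] <- "none"; deg[i] <- NA
      next
    }
    r <- pooled_t_stats(ki, wt)
    t_o[i] <- r[["t"]]; df_o[i] <- as.integer(r[["df"]]); p_o[i] <- r[["p"]]
    mw[i] <- r[["mean_y"]]; mk[i] <- r[["mean_x"]]
    d <- r[["mean_x"]] - r[["mean_y"]]
    dir_o[i] <- if (d > 0) "ki_gt_wt" else if (d < 0) "ki_lt_wt" else "none"
    deg[i] <- r[["degenerate"]] == 1
  }
  res <- tibble::new_tibble(list(feature_id = feats, t = t_o, df = df_o,
                                 p = p_o, mean_wt = mw, mean_ki = mk,
                                 direction = dir_o, degenerate = deg),
                            nrow = m)
  attr(res, "expected_false_positives") <- 0.05 * length(feats)
  res
}

#' Significant between-genotype feature set
#'
#' Features whose (uncorrected) pooled-t p value falls strictly below `alpha`,
#' optionally restricted to one effect direction — the directional variants
#' back the KI>WT and KI<WT selection regimes of the threshold-vote control
#' analysis.
#'
#' @param table A feature table.
#' @param alpha Significance threshold (strict).
#' @param direction_filter `"any"`, `"ki_gt_wt"` or `"ki_lt_wt"`.
#' @return The per-feature test tibble (see [genotype_tests()]) with a
#'   `significant` logical column; the selected ids are in
#'   `attr(, "features")`.
#' @export
significant_feature_set <- function(table, alpha = 0.05,
                                    direction_filter = c("any", "ki_gt_wt",
                                                         "ki_lt_wt")) {
  direction_filter <- match.arg(direction_filter)
  res <- genotype_tests(table)
  sig <- !is.na(res$p) & res$p < alpha
  if (direction_filter != "any") sig <- sig & res$direction == direction_filter
  res$significant <- sig
  attr(res, "features") <- res$feature_id[sig]
  attr(res, "alpha") <- alpha
  res
}

#' One-sample t test on paired phase differences
#'
#' For mice observed in both testing windows, tests the per-mouse
#' phase2 - phase1 differences of a feature against zero (df = n - 1; 17 for
#' 18 paired animals). All-equal nonzero differences (zero variance) are
#' flagged degenerate.
#'
#' @param diffs Numeric vector of per-mouse phase differences.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_phase_t <- function(diffs) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2) rlang::abort("need >= 2 non-missing differences")
  if (stats::var(diffs) == 0) {
    zero <- mean(diffs) == 0
    return(tibble::tibble(t = if (zero) 0 else NA_real_,
                          df = length(diffs) - 1L,
                          p = if (zero) 1 else NA_real_,
                          mean_diff = mean(diffs), degenerate = TRUE))
  }
  ht <- stats::t.test(diffs, mu = 0)
  tibble::tibble(t = unname(ht$statistic), df = as.integer(ht$parameter),
                 p = ht$p.value, mean_diff = mean(diffs), degenerate = FALSE)
}
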