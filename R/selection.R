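#' Screen every feature alone (starter search)
#'
#' Cross-validates each usable feature by itself and ranks by mean accuracy;
#' ties go to the larger absolute genotype t statistic, then schema (column)
#' order. The top-ranked feature is the starter that seeds the stepwise loop.
#' With the planted phase-1 effects the starter lands in the delay-discounting
#' groups (or the reversal-learning day-1 feature), matching where the
#' genotype contrast concentrates.
#'
#' @param table A feature table.
#' @param trainer `"mlp"` or `"threshold"`.
#' @param cv A [cv_config()] (the same folds score every candidate).
#' @param net A [net_config()].
#' @param features Candidate features (default: all with at least one
#'   observed value).
#' @return A ranked tibble `rank`, `feature_id`, `mean_accuracy`,
#'   `sd_accuracy`, `abs_t`; the starter id is in `attr(, "starter")`.
#' @export
single_feature_screen <- function(table, trainer = c("mlp", "threshold"),
                                  cv = cv_config(), net = net_config(init_seed = NA),
                                  features = usable_features(table)) {
  trainer <- match.arg(trainer)
  tt <- genotype_tests(dplyr::select(table,
                                     dplyr::all_of(c(meta_cols(), features))))
  abs_t <- stats::setNames(abs(tt$t), tt$feature_id)
  res <- purrr::map_dfr(features, function(f) {
    r <- cross_validate(table, f, trainer, cv, net, keep_predictions = FALSE)
    tibble::tibble(feature_id = f, mean_accuracy = r$mean_accuracy,
                   sd_accuracy = r$sd_accuracy)
  })
  res$abs_t <- unname(abs_t[res$feature_id])
  res$schema_order <- match(res$feature_id, features)
  res <- res[order(-res$mean_accuracy,
                   -ifelse(is.na(res$abs_t), -Inf, res$abs_t),
                   res$schema_order), ]
  res$rank <- seq_len(nrow(res))
  res <- dplyr::select(tibble::as_tibble(res), "rank", "feature_id",
                       "mean_accuracy", "sd_accuracy", "abs_t")
  attr(res, "starter") <- res$feature_id[1]
  res
}

usable_features <- function(table) {
  feats <- feature_cols(table)
  feats[vapply(table[feats], function(v) any(!is.na(v)), logical(1))]
}

#' Stepwise forward feature selection under cross-validation
#'
#' Greedy forward selection: starting from the single best feature (the
#' starter), each step re-scores every remaining feature added to the current
#' subset with [cross_validate()] and keeps the one with the highest mean
#' accuracy (ties: larger absolute genotype t, then schema order). The loop
#' stops once the running best accuracy has failed to improve for `patience`
#' consecutive additions (or candidates are exhausted); the optimum is read
#' off the recorded trace with [optimum_subset()].
#'
#' Because the same cross-validation score both selects and evaluates, the
#' optimum accuracy carries selection optimism — under a null cohort it sits
#' above chance. [nested_selection_cv()] provides the unbiased counterpart.
#'
#' @inheritParams single_feature_screen
#' @param patience Consecutive non-improving steps tolerated before stopping.
#' @param max_steps Optional hard cap on the number of steps (NULL = none).
#' @return A `cage_trace`: tibble `step`, `feature_id`, `mean_accuracy`,
#'   `sd_accuracy` with attributes `starter`, `trainer`.
#' @export
stepwise_select <- function(table, trainer = c("mlp", "threshold"),
                            cv = cv_config(), net = net_config(init_seed = NA),
                            patience = 3L, max_steps = NULL,
                            features = usable_features(table)) {
  trainer <- match.arg(trainer)
  if (length(features) < 2) rlang::abort("need >= 2 usable features")
  screen <- single_feature_screen(table, trainer, cv, net, features)
  tt <- genotype_tests(dplyr::select(table,
                                     dplyr::all_of(c(meta_cols(), features))))
  abs_t <- stats::setNames(abs(tt$t), tt$feature_id)
  starter <- attr(screen, "starter")
  sel <- starter
  st <- screen[screen$feature_id == starter, ]
  trace <- tibble::tibble(step = 1L, feature_id = starter,
                          mean_accuracy = st$mean_accuracy,
                          sd_accuracy = st$sd_accuracy)
  best <- st$mean_accuracy
  stall <- 0L
  cap <- if (is.null(max_steps)) length(features) else min(max_steps, length(features))
  while (length(sel) < cap && stall < patience) {
    remaining <- setdiff(features, sel)
    if (length(remaining) == 0) break
    scores <- vapply(remaining, function(f) {
      cross_validate(table, c(sel, f), trainer, cv, net,
                     keep_predictions = FALSE)$mean_accuracy
    }, numeric(1))
    tb <- ifelse(is.na(abs_t[remaining]), -Inf, abs_t[remaining])
    pick <- order(-scores, -tb, match(remaining, features))[1]
    chosen <- remaining[pick]
    r <- cross_validate(table, c(sel, chosen), trainer, cv, net,
                        keep_predictions = FALSE)
    sel <- c(sel, chosen)
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = length(sel), feature_id = chosen,
      mean_accuracy = r$mean_accuracy, sd_accuracy = r$sd_accuracy))
    if (r$mean_accuracy > best) {
      best <- r$mean_accuracy
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  structure(trace, starter = starter, trainer = trainer,
            class = c("cage_trace", class(trace)))
}

#' Optimum prefix of a stepwise selection trace
#'
#' The selected subset is the trace prefix with the maximal cross-validated
#' mean accuracy; on ties the smallest prefix wins (fewer features for the
#' same accuracy).
#'
#' @param trace A `cage_trace` from [stepwise_select()].
#' @return A list: `features`, `mean_accuracy`, `sd_accuracy`, `step`.
#' @export
optimum_subset <- function(trace) {
  if (nrow(trace) == 0) rlang::abort("empty selection trace")
  k <- which.max(trace$mean_accuracy) # first maximum = smallest prefix
  list(features = trace$feature_id[seq_len(k)],
       mean_accuracy = trace$mean_accuracy[k],
       sd_accuracy = trace$sd_accuracy[k],
       step = as.integer(k))
}

#' Nested (selection-inside-folds) accuracy estimate
#'
#' Re-runs the whole stepwise selection inside each outer training fold and
#' scores the resulting subset on the untouched outer test fold. This removes
#' the selection optimism of the trace's own estimate: under a null cohort
#' it concentrates around chance (0.5).
#'
#' @inheritParams stepwise_select
#' @param outer_k Outer stratified folds.
#' @return A list: `accuracy` (overall held-out), `fold_accuracies`,
#'   `subsets` (features selected per outer fold).
#' @export
nested_selection_cv <- function(table, trainer = c("mlp", "threshold"),
                                cv = cv_config(), net = net_config(init_seed = NA),
                                outer_k = 5L, patience = 3L, max_steps = NULL) {
  trainer <- match.arg(trainer)
  y <- as.character(table$genotype)
  n <- nrow(table)
  idx_by_class <- split(seq_len(n), y)
  idx_by_class <- idx_by_class[order(vapply(idx_by_class, min, numeric(1)))]
  if (min(lengths(idx_by_class)) < outer_k) {
    rlang::abort("a genotype has fewer animals than outer_k")
  }
  feats <- usable_features(table)
  X <- as.matrix(table[feats])
  storage.mode(X) <- "double"
  withr::with_seed(cv$seed + 1L, {
    fold_of <- integer(n)
    for (cls in idx_by_class) {
      fold_of[cls] <- sample(rep_len(seq_len(outer_k), length(cls)))
    }
    inner_seeds <- sample.int(1e6, outer_k)
  })
  correct <- logical(n)
  fold_acc <- numeric(outer_k)
  subsets <- vector("list", outer_k)
  for (j in seq_len(outer_k)) {
    tr <- which(fold_of != j); te <- which(fold_of == j)
    inner_cv <- cv
    inner_cv$seed <- inner_seeds[j]
    inner_tab <- table[tr, , drop = FALSE]
    trace <- stepwise_select(inner_tab, trainer, inner_cv, net,
                             patience = patience, max_steps = max_steps,
                             features = usable_features(inner_tab))
    opt <- optimum_subset(trace)
    subsets[[j]] <- opt$features
    med <- impute_fit(X[tr, opt$features, drop = FALSE])
    Xtr <- impute_apply(med, X[tr, opt$features, drop = FALSE])
    Xte <- impute_apply(med, X[te, opt$features, drop = FALSE])
    pred <- withr::with_seed(inner_seeds[j] + 1L, {
      if (trainer == "mlp") {
        if (cv$standardize) {
          tf <- standardize_fit(Xtr)
          Xtr <- standardize_apply(tf, Xtr)
          Xte <- standardize_apply(tf, Xte)
        }
        m <- train_mlp(Xtr, y[tr], net_config(init_seed = NA))
        predict_mlp(m, Xte)
      } else {
        rules <- fit_threshold_rules(Xtr, y[tr])
        predict_threshold_vote(rules, Xte)
      }
    })
    correct[te] <- pred == y[te]
    fold_acc[j] <- mean(pred == y[te])
  }
  list(accuracy = mean(correct), fold_accuracies = fold_acc, subsets = subsets)
}
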