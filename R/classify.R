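#' Network configuration for the feed-forward classifier
#'
#' A deliberately small fully connected network suited to cohorts of fewer
#' than 30 animals: one hidden layer of logistic units trained by
#' quasi-Newton optimization with an L2 weight penalty (backed by
#' [nnet::nnet()]). The topology is an artifact default and is not tuned.
#'
#' @param hidden Hidden-layer size (>= 1).
#' @param max_epochs Optimizer iteration cap.
#' @param l2_penalty Weight decay.
#' @param init_seed Seed for weight initialization; `NA` draws initial weights
#'   from the current RNG stream (used inside [cross_validate()], whose own
#'   seed then governs everything).
#' @return A `net_config` list.
#' @export
net_config <- function(hidden = 8L, max_epochs = 500L, l2_penalty = 1e-3,
                       init_seed = 1L) {
  stopifnot(length(hidden) == 1, hidden >= 1, max_epochs >= 1, l2_penalty >= 0)
  structure(list(hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs),
                 l2_penalty = l2_penalty, init_seed = init_seed),
            class = "net_config")
}

#' Cross-validation configuration
#'
#' Default scheme is stratified 5-fold cross-validation repeated 20 times;
#' the reported spread is the SD of the per-repeat accuracies (a
#' mean +/- SD summary accuracy). Leave-one-out is
#' available for very small cohorts, with the SD taken over folds.
#'
#' @param scheme `"repeated_stratified_kfold"` or `"loocv"`.
#' @param k Folds per repeat (>= 2 and at most the smaller genotype count).
#' @param repeats Number of repeats.
#' @param seed Integer seed; fixes folds, imputation order and network
#'   initialization, so results are bit-reproducible.
#' @param standardize Z-score features on training-fold statistics (network
#'   path only; threshold rules work on the raw scale).
#' @return A `cv_config` list.
#' @export
cv_config <- function(scheme = c("repeated_stratified_kfold", "loocv"),
                      k = 5L, repeats = 20L, seed = 1L, standardize = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(k >= 2, repeats >= 1)
  structure(list(scheme = scheme, k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "cv_config")
}

#' Leakage-safe standardization
#'
#' `standardize_fit()` learns per-column mean/SD from training rows only;
#' `standardize_apply()` z-scores any compatible matrix with those statistics.
#' Zero-variance columns map to 0 rather than NaN.
#'
#' @param train Numeric training matrix (>= 2 rows).
#' @return `standardize_fit()`: a transform list; `standardize_apply()`: the
#'   transformed matrix.
#' @export
standardize_fit <- function(train) {
  if (is.null(dim(train)) || nrow(train) < 2) {
    rlang::abort("training matrix needs >= 2 rows")
  }
  list(mean = colMeans(train), sd = apply(train, 2, stats::sd))
}

#' @rdname standardize_fit
#' @param transform A transform from `standardize_fit()`.
#' @param x Matrix to transform with the training statistics.
#' @export
standardize_apply <- function(transform, x) {
  out <- sweep(x, 2, transform$mean, "-")
  s <- transform$sd
  s[s == 0 | is.na(s)] <- Inf # constant columns -> exactly 0
  sweep(out, 2, s, "/")
}

impute_fit <- function(train) {
  med <- apply(train, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  med
}

impute_apply <- function(med, x) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

#' Train the small feed-forward network
#'
#' @param X Numeric feature matrix, no missing values (impute upstream).
#' @param y Labels: factor or character with classes `WT` and `KI`.
#' @param cfg A [net_config()].
#' @return A `cage_mlp` model object.
#' @export
train_mlp <- function(X, y, cfg = net_config()) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2) rlang::abort("training labels contain one class only")
  if (any(is.na(X))) rlang::abort("missing values in X; impute before training")
  if (!is.na(cfg$init_seed)) set.seed(cfg$init_seed)
  y01 <- as.numeric(y == "KI")
  fit <- nnet::nnet(x = X, y = y01, size = cfg$hidden,
                    decay = cfg$l2_penalty, maxit = cfg$max_epochs,
                    entropy = TRUE, trace = FALSE)
  structure(list(fit = fit, features = colnames(X)), class = "cage_mlp")
}

#' Predict genotypes with a trained network
#'
#' The label is the class with the larger output score; an exact tie goes to
#' `WT`.
#'
#' @param model A `cage_mlp` from [train_mlp()].
#' @param X Matrix with the model's feature columns.
#' @return Character vector of `"WT"`/`"KI"` labels.
#' @export
predict_mlp <- function(model, X) {
  X <- as.matrix(X)
  if (!identical(colnames(X), model$features)) {
    rlang::abort("prediction columns do not match the trained model")
  }
  if (nrow(X) == 0) return(character(0))
  p <- as.vector(stats::predict(model$fit, X))
  ifelse(p > 0.5, "KI", "WT")
}

#' Fit per-feature threshold rules
#'
#' The control (non-neural) classifier: each feature gets a cut-off with a
#' direction — `ki_gt_wt` labels KI above the threshold, `ki_lt_wt` below
#' (equality always votes WT). Candidate thresholds are the midpoints between
#' consecutive sorted unique training values; the rule maximizing training
#' accuracy wins, ties resolved toward the smaller threshold and the
#' `ki_gt_wt` direction. An all-equal feature yields a degenerate
#' majority-class rule.
#'
#' @param X Training matrix (no missing values).
#' @param y Training labels (`WT`/`KI`).
#' @param features Columns to fit (default all).
#' @return A tibble of rules: `feature_id`, `threshold`, `direction`,
#'   `train_accuracy`, `degenerate`.
#' @export
fit_threshold_rules <- function(X, y, features = colnames(X)) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2) rlang::abort("both classes must be present")
  n <- length(y)
  ki <- y == "KI"
  K <- sum(ki); W <- n - K
  m <- length(features)
  thr_out <- numeric(m); dir_out <- character(m)
  acc_out <- numeric(m); deg_out <- logical(m)
  for (fi in seq_len(m)) {
    v <- X[, features[fi]]
    ord <- order(v)
    vs <- v[ord]; ks <- ki[ord]
    bnd <- which(vs[-n] < vs[-1])
    if (length(bnd) == 0) { # all-equal feature: degenerate majority rule
      if (K > W) {
        thr_out[fi] <- vs[1] - 1; acc_out[fi] <- K / n
      } else {
        thr_out[fi] <- vs[1]; acc_out[fi] <- W / n
      }
      dir_out[fi] <- "ki_gt_wt"; deg_out[fi] <- TRUE
      next
    }
    cum_ki <- cumsum(ks); cum_wt <- cumsum(!ks)
    thr <- (vs[bnd] + vs[bnd + 1]) / 2
    acc_gt <- (K - cum_ki[bnd] + cum_wt[bnd]) / n
    acc_lt <- (cum_ki[bnd] + W - cum_wt[bnd]) / n
    best <- max(acc_gt, acc_lt)
    # ties: smaller threshold first, then the ki_gt_wt direction
    i_gt <- which(acc_gt == best); i_lt <- which(acc_lt == best)
    t_gt <- if (length(i_gt)) thr[i_gt[1]] else Inf
    t_lt <- if (length(i_lt)) thr[i_lt[1]] else Inf
    if (t_gt <= t_lt) {
      thr_out[fi] <- t_gt; dir_out[fi] <- "ki_gt_wt"
    } else {
      thr_out[fi] <- t_lt; dir_out[fi] <- "ki_lt_wt"
    }
    acc_out[fi] <- best; deg_out[fi] <- FALSE
  }
  tibble::new_tibble(list(feature_id = features, threshold = thr_out,
                          direction = dir_out, train_accuracy = acc_out,
                          degenerate = deg_out), nrow = m)
}

#' Majority-vote prediction from threshold rules
#'
#' Each rule votes per animal; the label is KI iff strictly more than half of
#' the rules vote KI (an exact split goes to WT).
#'
#' @param rules Rules from [fit_threshold_rules()] (non-empty).
#' @param X Matrix containing every rule's feature column.
#' @return Character vector of `"WT"`/`"KI"` labels.
#' @export
predict_threshold_vote <- function(rules, X) {
  if (nrow(rules) == 0) rlang::abort("no rules to vote with")
  X <- as.matrix(X)
  missing_f <- setdiff(rules$feature_id, colnames(X))
  if (length(missing_f) > 0) {
    rlang::abort(paste0("feature absent from X: ", missing_f[1]))
  }
  if (nrow(X) == 0) return(character(0))
  votes <- matrix(FALSE, nrow(X), nrow(rules))
  for (r in seq_len(nrow(rules))) {
    v <- X[, rules$feature_id[r]]
    votes[, r] <- if (rules$direction[r] == "ki_gt_wt") {
      v > rules$threshold[r]
    } else {
      v < rules$threshold[r]
    }
  }
  ifelse(rowSums(votes) > nrow(rules) / 2, "KI", "WT")
}

#' Cross-validated genotype classification accuracy
#'
#' Scores a feature subset with either classifier under genotype-stratified
#' cross-validation. Per fold, missing cells are imputed with the training
#' fold's medians and (network path) features are z-scored on training-fold
#' statistics, so no information from held-out animals reaches training.
#' Repeated k-fold reports mean +/- SD of per-repeat accuracies; LOOCV
#' reports them over folds.
#'
#' @param table A feature table.
#' @param features Character vector of feature columns to use (non-empty).
#' @param trainer `"mlp"` or `"threshold"`.
#' @param cv A [cv_config()].
#' @param net A [net_config()] (network path).
#' @param include_sex Append a 0/1 sex input (1 = male).
#' @param keep_predictions Keep the per-animal prediction table (disable in
#'   tight selection loops).
#' @return A `cage_cv` object: `mean_accuracy`, `sd_accuracy`, `accuracies`
#'   (per repeat or per fold), `predictions`, `scheme`, `n`.
#' @export
cross_validate <- function(table, features, trainer = c("mlp", "threshold"),
                           cv = cv_config(), net = net_config(init_seed = NA),
                           include_sex = FALSE, keep_predictions = TRUE) {
  trainer <- match.arg(trainer)
  if (length(features) == 0) rlang::abort("feature subset is empty")
  stopifnot(all(features %in% names(table)))
  y <- as.character(table$genotype)
  stopifnot(all(y %in% c("WT", "KI")))
  X <- as.matrix(table[features])
  storage.mode(X) <- "double"
  if (include_sex) X <- cbind(X, sex = as.numeric(table$sex == "M"))
  n <- nrow(X)
  idx_by_class <- split(seq_len(n), y)
  # iterate class blocks by row position, not label, so that relabelling the
  # classes leaves fold assignment (and hence accuracy) unchanged
  idx_by_class <- idx_by_class[order(vapply(idx_by_class, min, numeric(1)))]
  if (cv$scheme == "repeated_stratified_kfold" &&
      min(lengths(idx_by_class)) < cv$k) {
    rlang::abort(paste0("a genotype has fewer than k = ", cv$k,
                        " animals; use scheme = \"loocv\""))
  }
  net_cv <- net
  net_cv$init_seed <- NA # inits come from the CV seed stream

  fit_fold <- function(tr_idx, te_idx) {
    med <- impute_fit(X[tr_idx, , drop = FALSE])
    Xtr <- impute_apply(med, X[tr_idx, , drop = FALSE])
    Xte <- impute_apply(med, X[te_idx, , drop = FALSE])
    if (trainer == "mlp") {
      if (cv$standardize) {
        tf <- standardize_fit(Xtr)
        Xtr <- standardize_apply(tf, Xtr)
        Xte <- standardize_apply(tf, Xte)
      }
      m <- train_mlp(Xtr, y[tr_idx], net_cv)
      predict_mlp(m, Xte)
    } else {
      rules <- fit_threshold_rules(Xtr, y[tr_idx])
      predict_threshold_vote(rules, Xte)
    }
  }

  preds <- list()
  withr::with_seed(cv$seed, {
    if (cv$scheme == "loocv") {
      accs <- numeric(n)
      for (i in seq_len(n)) {
        p <- fit_fold(setdiff(seq_len(n), i), i)
        accs[i] <- as.numeric(p == y[i])
        if (keep_predictions) {
          preds[[length(preds) + 1]] <- tibble::tibble(
            rep = 1L, fold = i, row = i, mouse_id = table$mouse_id[i],
            truth = y[i], pred = p)
        }
      }
    } else {
      accs <- numeric(cv$repeats)
      for (r in seq_len(cv$repeats)) {
        fold_of <- integer(n)
        for (cls in idx_by_class) {
          fold_of[cls] <- sample(rep_len(seq_len(cv$k), length(cls)))
        }
        pred_all <- character(n)
        for (j in seq_len(cv$k)) {
          te <- which(fold_of == j)
          pred_all[te] <- fit_fold(which(fold_of != j), te)
        }
        accs[r] <- mean(pred_all == y)
        if (keep_predictions) {
          preds[[length(preds) + 1]] <- tibble::tibble(
            rep = r, fold = fold_of, row = seq_len(n),
            mouse_id = table$mouse_id, truth = y, pred = pred_all)
        }
      }
    }
  })
  structure(list(
    mean_accuracy = mean(accs),
    sd_accuracy = if (length(accs) > 1) stats::sd(accs) else 0,
    accuracies = accs,
    predictions = if (keep_predictions) dplyr::bind_rows(preds) else NULL,
    scheme = cv$scheme, n = n, trainer = trainer, features = features
  ), class = "cage_cv")
}

#' @export
print.cage_cv <- function(x, ...) {
  cat(sprintf("Cross-validated accuracy (%s, %s): %.1f%% +/- %.1f%% (n = %d, %d features)\n",
              x$trainer, x$scheme, 100 * x$mean_accuracy,
              100 * x$sd_accuracy, x$n, length(x$features)))
  invisible(x)
}
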