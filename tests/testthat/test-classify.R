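test_that("standardization uses training statistics only", {
  withr::with_seed(5, {
    train <- matrix(rnorm(40, 10, 2), 20, 2,
                    dimnames = list(NULL, c("a", "b")))
  })
  tf <- standardize_fit(train)
  z <- standardize_apply(tf, train)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  # a held-out block shifted by +100 lands far from 0: the transform did not
  # re-fit on the test data (leakage sentinel)
  zs <- standardize_apply(tf, train + 100)
  expect_true(all(zs > 10))
  const <- matrix(1, 5, 1, dimnames = list(NULL, "c"))
  zc <- standardize_apply(standardize_fit(const), const)
  expect_true(all(zc == 0) && all(is.finite(zc)))
})

test_that("the network learns a separable toy problem deterministically", {
  tab <- toy_table(n_per = 10, gap = 3)
  X <- as.matrix(tab[c("f1", "f2")])
  m1 <- train_mlp(X, tab$genotype, net_config(init_seed = 7))
  m2 <- train_mlp(X, tab$genotype, net_config(init_seed = 7))
  expect_identical(m1$fit$wts, m2$fit$wts)
  expect_equal(mean(predict_mlp(m1, X) == tab$genotype), 1)
  expect_error(train_mlp(X, rep("KI", 20), net_config()), "one class")
  expect_error(predict_mlp(m1, X[, 1, drop = FALSE]), "match")
  expect_length(predict_mlp(m1, X[0, , drop = FALSE]), 0)
})

test_that("identical rows with conflicting labels cap training accuracy at 1/2", {
  X <- matrix(rep(c(0, 1), each = 6), 12, 1, dimnames = list(NULL, "f"))
  y <- rep(c("WT", "KI", "WT", "KI"), each = 3) # each x value split 50/50
  m <- train_mlp(X, y, net_config(init_seed = 2))
  expect_equal(mean(predict_mlp(m, X) == y), 0.5)
})

test_that("mirrored data with swapped labels gives swapped predictions", {
  tab <- toy_table(n_per = 8, gap = 3)
  X <- as.matrix(tab[c("f1", "f2")])
  y <- tab$genotype
  y_sw <- ifelse(y == "WT", "KI", "WT")
  m <- train_mlp(X, y, net_config(init_seed = 3))
  m_sw <- train_mlp(-X, y_sw, net_config(init_seed = 3))
  expect_equal(mean(predict_mlp(m, X) == y), 1)
  expect_equal(mean(predict_mlp(m_sw, -X) == y_sw), 1)
})

test_that("threshold rules separate a clean two-point-per-class feature", {
  X <- matrix(c(0.1, 0.2, 0.8, 0.9), 4, 1, dimnames = list(NULL, "f"))
  y <- c("WT", "WT", "KI", "KI")
  r <- fit_threshold_rules(X, y)
  expect_equal(r$direction, "ki_gt_wt")
  expect_gt(r$threshold, 0.2); expect_lt(r$threshold, 0.8)
  expect_equal(r$train_accuracy, 1)
  # label swap flips the direction
  r2 <- fit_threshold_rules(X, rev(y))
  expect_equal(r2$direction, "ki_lt_wt")
  expect_equal(r2$train_accuracy, 1)
})

test_that("threshold fitting equals the exhaustive midpoint oracle", {
  withr::with_seed(17, {
    for (i in 1:60) {
      n <- sample(4:12, 1)
      y <- sample(rep(c("WT", "KI"), length.out = n))
      if (length(unique(y)) < 2) next
      v <- round(rnorm(n), sample(0:2, 1)) # ties likely at low precision
      X <- matrix(v, n, 1, dimnames = list(NULL, "f"))
      got <- fit_threshold_rules(X, y)
      want <- oracle_rule(v, y)
      expect_equal(got$train_accuracy, want$accuracy)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$direction, want$direction)
    }
  })
})

test_that("degenerate all-equal features fall back to the majority class", {
  X <- matrix(2, 5, 1, dimnames = list(NULL, "f"))
  r <- fit_threshold_rules(X, c("KI", "KI", "KI", "WT", "WT"))
  expect_true(r$degenerate)
  expect_equal(r$train_accuracy, 3 / 5)
  pred <- predict_threshold_vote(r, X)
  expect_true(all(pred == "KI"))
})

test_that("the vote combines rules with ties to WT", {
  rules <- tibble::tibble(feature_id = c("a", "b", "c"),
                          threshold = c(0.5, 0.5, 0.5),
                          direction = "ki_gt_wt",
                          train_accuracy = 1, degenerate = FALSE)
  X <- matrix(c(1, 1, 0, 1, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(predict_threshold_vote(rules, X), c("KI", "WT")) # 2/3 vs 1/3
  r4 <- dplyr::bind_rows(rules, tibble::tibble(
    feature_id = "d", threshold = 0.5, direction = "ki_gt_wt",
    train_accuracy = 1, degenerate = FALSE))
  X4 <- matrix(c(1, 1, 0, 0), 1, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  expect_equal(predict_threshold_vote(r4, X4), "WT") # exact half -> WT
  expect_error(predict_threshold_vote(rules, X[, 1:2]), "absent")
})

test_that("vote prediction equals the brute-force vote oracle", {
  withr::with_seed(23, {
    for (i in 1:40) {
      n <- sample(4:12, 1); p <- sample(1:4, 1)
      y <- sample(rep(c("WT", "KI"), length.out = n))
      X <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("f", seq_len(p))))
      rules <- fit_threshold_rules(X, y)
      expect_equal(predict_threshold_vote(rules, X), oracle_vote(rules, X))
    }
  })
})

test_that("cross-validation is deterministic and leakage-safe by construction", {
  tab <- toy_table(n_per = 10, gap = 2.5)
  cvc <- cv_config(repeats = 4, seed = 31)
  r1 <- cross_validate(tab, c("f1", "f2"), "threshold", cvc)
  r2 <- cross_validate(tab, c("f1", "f2"), "threshold", cvc)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_identical(r1$predictions, r2$predictions)
  expect_equal(r1$mean_accuracy, mean(r1$accuracies))
  expect_equal(r1$sd_accuracy, sd(r1$accuracies))
  # label swap leaves accuracy unchanged: same folds, mirrored rule.
  # (an odd rule count avoids vote ties, whose WT convention is asymmetric)
  sw <- tab
  sw$genotype <- ifelse(tab$genotype == "WT", "KI", "WT")
  r1f <- cross_validate(tab, "f1", "threshold", cvc)
  r3 <- cross_validate(sw, "f1", "threshold", cvc)
  expect_equal(r3$accuracies, r1f$accuracies)
})

test_that("a zero-variance feature scores the majority-class proportion", {
  tab <- toy_table(n_per = 5)
  tab$flat <- 1
  r <- cross_validate(tab, "flat", "threshold", cv_config(repeats = 2, seed = 1))
  expect_equal(r$mean_accuracy, 0.5) # balanced classes
})

test_that("LOOCV on a tiny perfect problem is exact", {
  tab <- tibble::tibble(mouse_id = paste0("m", 1:4),
                        genotype = c("WT", "WT", "KI", "KI"),
                        sex = "M", phase = 1L,
                        f = c(0, 0.1, 10, 10.1))
  r <- cross_validate(tab, "f", "threshold",
                      cv_config(scheme = "loocv", seed = 2))
  expect_equal(r$mean_accuracy, 1)
  expect_equal(r$sd_accuracy, 0)
})

test_that("stratified folds demand k at most the smaller class", {
  tab <- toy_table(n_per = 3)
  expect_error(cross_validate(tab, "f1", "threshold",
                              cv_config(k = 5, seed = 1)),
               "loocv")
})

test_that("fold-wise imputation uses training medians", {
  tab <- toy_table(n_per = 6, gap = 4)
  tab$f1[c(1, 7)] <- NA
  r <- cross_validate(tab, c("f1", "f2"), "threshold",
                      cv_config(k = 3, repeats = 2, seed = 9))
  expect_gt(r$mean_accuracy, 0.9) # NAs imputed, signal preserved
})

test_that("the sex input node can be appended", {
  tab <- toy_table(n_per = 6, gap = 3)
  r <- cross_validate(tab, c("f1", "f2"), "threshold",
                      cv_config(repeats = 2, seed = 4), include_sex = TRUE)
  expect_gt(r$mean_accuracy, 0.8)
})
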