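test_that("a perfectly separating feature is the starter", {
  tab <- toy_table(n_per = 8, gap = 6, sd = 0.5)
  tab$noise <- withr::with_seed(2, rnorm(16))
  scr <- single_feature_screen(tab, "threshold",
                               cv_config(repeats = 2, seed = 3))
  expect_equal(scr$rank[scr$feature_id %in% c("f1", "f2")], c(1L, 2L))
  expect_equal(scr$mean_accuracy[1], 1)
  expect_true(attr(scr, "starter") %in% c("f1", "f2"))
})

test_that("stepwise stops after patience once accuracy saturates", {
  tab <- toy_table(n_per = 8, gap = 6, sd = 0.5)
  tab$n1 <- withr::with_seed(4, rnorm(16))
  tab$n2 <- withr::with_seed(5, rnorm(16))
  tab$n3 <- withr::with_seed(6, rnorm(16))
  tr <- stepwise_select(tab, "threshold", cv_config(repeats = 2, seed = 3),
                        patience = 3)
  expect_equal(tr$mean_accuracy[1], 1) # redundant perfect features: step 1 maxes
  expect_equal(nrow(tr), 1 + 3)        # then exactly `patience` extra steps
  opt <- optimum_subset(tr)
  expect_equal(opt$step, 1)
  expect_equal(opt$mean_accuracy, 1)
})

test_that("the optimum prefix takes the first maximum", {
  fake <- tibble::tibble(step = 1:4, feature_id = c("a", "b", "c", "d"),
                         mean_accuracy = c(0.7, 0.9, 0.9, 0.85),
                         sd_accuracy = 0)
  fake <- structure(fake, starter = "a", trainer = "threshold",
                    class = c("cage_trace", class(fake)))
  opt <- optimum_subset(fake)
  expect_equal(opt$features, c("a", "b"))
  expect_equal(opt$step, 2)
  mono <- dplyr::mutate(fake, mean_accuracy = c(0.6, 0.7, 0.8, 0.9))
  expect_equal(optimum_subset(mono)$features, c("a", "b", "c", "d"))
  expect_error(optimum_subset(fake[0, ]), "empty")
})

test_that("trace structure invariants hold on simulated cohorts", {
  tab <- missingness_filter(
    simulate_feature_table(sim_config(n_wt = 8, n_ki = 8, effect = "phase1",
                                      seed = 41)))
  cvc <- cv_config(repeats = 2, seed = 11, k = 4)
  tr <- stepwise_select(tab, "threshold", cvc, max_steps = 10)
  expect_false(anyDuplicated(tr$feature_id) > 0)
  expect_lte(nrow(tr), length(feature_cols(tab)))
  expect_equal(tr$feature_id[1], attr(tr, "starter"))
  expect_equal(tr$step, seq_len(nrow(tr)))
  opt <- optimum_subset(tr)
  expect_gte(opt$mean_accuracy, tr$mean_accuracy[1])
  # determinism
  tr2 <- stepwise_select(tab, "threshold", cvc, max_steps = 10)
  expect_identical(tibble::as_tibble(tr), tibble::as_tibble(tr2))
})

test_that("with planted effects the starter lands in an affected group", {
  tab <- missingness_filter(
    simulate_feature_table(sim_config(effect = "phase1", seed = 77)))
  scr <- single_feature_screen(tab, "threshold",
                               cv_config(repeats = 3, seed = 7))
  starter <- attr(scr, "starter")
  planted <- grepl("^dd_", starter) || starter == "ppr_day1"
  expect_true(planted)
})

test_that("nested evaluation scores honest held-out accuracy", {
  tab <- toy_table(n_per = 10, gap = 4)
  tab$n1 <- withr::with_seed(8, rnorm(20))
  nn <- nested_selection_cv(tab, "threshold",
                            cv_config(repeats = 1, seed = 13),
                            outer_k = 5, max_steps = 4)
  expect_gte(nn$accuracy, 0.8) # real signal survives nesting
  expect_length(nn$fold_accuracies, 5)
  expect_length(nn$subsets, 5)
  expect_error(nested_selection_cv(toy_table(n_per = 3), outer_k = 5),
               "outer_k")
})

test_that("selection-optimism: optimum exceeds chance on one null cohort", {
  # the trace's own estimate re-uses the selection CV, so under a null
  # cohort it drifts above 0.5 (the nested estimate is the honest one)
  tab <- missingness_filter(simulate_feature_table(null_config(seed = 61)))
  tr <- stepwise_select(tab, "threshold", cv_config(repeats = 2, seed = 5),
                        max_steps = 6)
  expect_gt(optimum_subset(tr)$mean_accuracy, 0.5)
})

test_that("tidy/glance/autoplot work on traces and CV results", {
  tab <- toy_table(n_per = 6, gap = 4)
  cvc <- cv_config(repeats = 3, seed = 2)
  tr <- stepwise_select(tab, "threshold", cvc, patience = 1)
  g <- glance(tr)
  expect_equal(g$optimum_accuracy, optimum_subset(tr)$mean_accuracy)
  expect_s3_class(autoplot(tr), "ggplot")
  r <- cross_validate(tab, "f1", "threshold", cvc)
  expect_equal(nrow(tidy(r)), 3)
  expect_equal(glance(r)$n_features, 1)
})
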