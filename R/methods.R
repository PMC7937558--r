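#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x A `cage_cv` from [cross_validate()].
#' @param ... Unused.
#' @return Per-repeat (or per-fold) accuracies as a tibble.
#' @export
tidy.cage_cv <- function(x, ...) {
  tibble::tibble(index = seq_along(x$accuracies), accuracy = x$accuracies)
}

#' @rdname tidy.cage_cv
#' @return `glance()`: one-row summary with mean/SD accuracy, scheme,
#'   trainer, cohort and subset sizes.
#' @export
glance.cage_cv <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
                 scheme = x$scheme, trainer = x$trainer, n = x$n,
                 n_features = length(x$features))
}

#' Tidy a stepwise selection trace
#'
#' @param x A `cage_trace` from [stepwise_select()].
#' @param ... Unused.
#' @return The step-by-step trace as a plain tibble.
#' @export
tidy.cage_trace <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.cage_trace
#' @return `glance()`: one row with the starter, optimum step and optimum
#'   accuracy.
#' @export
glance.cage_trace <- function(x, ...) {
  opt <- optimum_subset(x)
  tibble::tibble(starter = attr(x, "starter"), trainer = attr(x, "trainer"),
                 n_steps = nrow(x), optimum_step = opt$step,
                 optimum_accuracy = opt$mean_accuracy,
                 optimum_sd = opt$sd_accuracy)
}

#' Tidy a report
#'
#' @param x A `cage_report` from [run_experiment()].
#' @param ... Unused.
#' @return The cells tibble without list columns.
#' @export
tidy.cage_report <- function(x, ...) {
  dplyr::select(x$cells, -"features")
}

#' Plot a stepwise selection trace
#'
#' Cross-validated mean accuracy against the number of selected features,
#' with a +/- SD ribbon and the optimum prefix marked.
#'
#' @param object A `cage_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cage_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  opt <- optimum_subset(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$mean_accuracy - .data$sd_accuracy),
      ymax = pmin(1, .data$mean_accuracy + .data$sd_accuracy)),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::annotate("point", x = opt$step, y = opt$mean_accuracy,
                      shape = 8, size = 3) +
    ggplot2::labs(x = "features selected", y = "cross-validated accuracy",
                  title = "Stepwise forward selection",
                  subtitle = paste0("starter: ", attr(object, "starter"))) +
    ggplot2::ylim(0, 1)
}

#' Plot the experiment grid of a report
#'
#' Mean cross-validated accuracy with SD error bars per selection regime and
#' classifier, faceted by phase.
#'
#' @param object A `cage_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cage_report <- function(object, ...) {
  df <- dplyr::filter(object$cells, !.data$failed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$regime, y = .data$mean_accuracy,
                                   fill = .data$classifier)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$mean_accuracy - .data$sd_accuracy),
      ymax = pmin(1, .data$mean_accuracy + .data$sd_accuracy)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$phase), labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "cross-validated accuracy") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot per-feature genotype contrasts
#'
#' Group means with SD bands per feature group, the visual companion of
#' [genotype_tests()] (significant features marked).
#'
#' @param table A feature table.
#' @param groups Schema groups to show (default all).
#' @param schema Feature schema.
#' @return A ggplot object.
#' @export
plot_feature_profile <- function(table, groups = 1:11,
                                 schema = default_schema()) {
  feats <- intersect(schema$feature_id[schema$group %in% groups],
                     feature_cols(table))
  long <- tidyr::pivot_longer(
    dplyr::select(table, dplyr::all_of(c("genotype", feats))),
    dplyr::all_of(feats), names_to = "feature_id", values_to = "value")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$genotype, .data$feature_id),
    m = mean(.data$value, na.rm = TRUE),
    s = stats::sd(.data$value, na.rm = TRUE), .groups = "drop")
  summ$feature_id <- factor(summ$feature_id, levels = feats)
  summ <- dplyr::left_join(summ,
                           dplyr::select(schema, "feature_id", "group"),
                           by = "feature_id")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$feature_id, y = .data$m,
                                     color = .data$genotype,
                                     group = .data$genotype)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$s,
                                      ymax = .data$m + .data$s,
                                      fill = .data$genotype),
                         alpha = 0.15, color = NA) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "parameter value") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}
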