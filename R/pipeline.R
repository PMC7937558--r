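#' Combine a two-phase feature table into one "both phases" table
#'
#' Restricts to mice observed in both testing windows and concatenates each
#' mouse's phase-1 and phase-2 feature vectors side by side, prefixing the
#' feature names `p1_` / `p2_`. The `phase` column of the result is 0,
#' marking the combined table.
#'
#' @param table A feature table containing phases 1 and 2.
#' @return A feature table with one row per mouse present in both phases.
#' @export
both_phase_table <- function(table) {
  t1 <- dplyr::filter(table, .data$phase == 1L)
  t2 <- dplyr::filter(table, .data$phase == 2L)
  common <- intersect(t1$mouse_id, t2$mouse_id)
  if (length(common) == 0) rlang::abort("no mouse appears in both phases")
  feats <- feature_cols(table)
  t1 <- t1[match(common, t1$mouse_id), ]
  t2 <- t2[match(common, t2$mouse_id), ]
  out <- dplyr::select(t1, dplyr::all_of(c("mouse_id", "genotype", "sex")))
  out$phase <- 0L
  f1 <- t1[feats]; names(f1) <- paste0("p1_", feats)
  f2 <- t2[feats]; names(f2) <- paste0("p2_", feats)
  dplyr::bind_cols(out, f1, f2)
}

experiment_regimes <- function() {
  c("stepwise", "significant_any", "significant_ki_gt_wt",
    "significant_ki_lt_wt", "all")
}

#' Run the full classification experiment grid
#'
#' Orchestrates the end-to-end analysis over phases x feature-selection
#' regimes x classifiers: load or simulate the cohort, drop mostly-missing
#' features, pick each regime's feature set (stepwise selection; significant
#' between-genotype features, optionally restricted to one direction; or all
#' surviving features), and score it with cross-validation. Cells that cannot
#' be computed (e.g. an empty significant set in a null cohort) are marked
#' failed with a reason and the run continues.
#'
#' @param data A feature table tibble (with a `phase` column), or an effect
#'   preset name (`"null"`, `"phase1"`, `"phase2"`, `"both"`) to simulate
#'   cohorts at the default cohort sizes (13/14, 14/15, 10/10).
#' @param phases Subset of `c("1", "2", "both")`.
#' @param regimes Subset of `r paste0('c("', paste(experiment_regimes(), collapse = '", "'), '")')`.
#' @param classifiers Subset of `c("mlp", "threshold")`.
#' @param include_sex Add the 0/1 sex input node.
#' @param alpha Significance threshold for the significant-feature regimes.
#' @param cv,net Cross-validation and network configurations; each grid cell
#'   derives its own seed from `seed` for full determinism.
#' @param patience,max_steps Stepwise stopping controls, see
#'   [stepwise_select()].
#' @param seed Master seed (simulation and all cell seeds derive from it).
#' @return A `cage_report`: cells tibble plus per-phase genotype statistics
#'   and provenance (`seed`, config hash).
#' @export
run_experiment <- function(data, phases = "1",
                           regimes = experiment_regimes(),
                           classifiers = c("mlp", "threshold"),
                           include_sex = FALSE, alpha = 0.05,
                           cv = cv_config(), net = net_config(init_seed = NA),
                           patience = 3L, max_steps = NULL, seed = 1L) {
  phases <- as.character(phases)
  stopifnot(length(phases) >= 1, all(phases %in% c("1", "2", "both")),
            length(regimes) >= 1, all(regimes %in% experiment_regimes()),
            length(classifiers) >= 1, all(classifiers %in% c("mlp", "threshold")))
  tables <- list()
  for (ph in phases) {
    if (is.character(data)) {
      eff <- if (data %in% c("null", "both")) data else data
      cfg <- sim_config(phase = ph, effect = eff,
                        seed = seed + 101L * match(ph, c("1", "2", "both")))
      tab <- simulate_feature_table(cfg)
    } else {
      tab <- data
    }
    tables[[ph]] <- if (ph == "both") {
      both_phase_table(tab)
    } else {
      dplyr::filter(tab, .data$phase == as.integer(ph))
    }
  }
  cells <- list()
  stats_by_phase <- list()
  cell_i <- 0L
  for (ph in phases) {
    tab <- missingness_filter(tables[[ph]])
    stats_by_phase[[ph]] <- significant_feature_set(tab, alpha)
    for (regime in regimes) {
      for (clf in classifiers) {
        cell_i <- cell_i + 1L
        cell_cv <- cv
        cell_cv$seed <- seed + 1000L * cell_i
        cell <- tryCatch({
          if (regime == "stepwise") {
            trace <- stepwise_select(tab, clf, cell_cv, net,
                                     patience = patience, max_steps = max_steps)
            opt <- optimum_subset(trace)
            list(features = opt$features, mean = opt$mean_accuracy,
                 sd = opt$sd_accuracy)
          } else {
            feats <- if (regime == "all") {
              feature_cols(tab)
            } else {
              dirf <- sub("significant_", "", regime)
              attr(significant_feature_set(tab, alpha, dirf), "features")
            }
            if (length(feats) == 0) rlang::abort("empty feature set for regime")
            r <- cross_validate(tab, feats, clf, cell_cv, net,
                                include_sex = include_sex,
                                keep_predictions = FALSE)
            list(features = feats, mean = r$mean_accuracy, sd = r$sd_accuracy)
          }
        }, error = function(e) conditionMessage(e))
        if (is.character(cell)) {
          cells[[cell_i]] <- tibble::tibble(
            phase = ph, regime = regime, classifier = clf,
            include_sex = include_sex, failed = TRUE, reason = cell,
            n_features = NA_integer_, features = list(character(0)),
            mean_accuracy = NA_real_, sd_accuracy = NA_real_)
        } else {
          cells[[cell_i]] <- tibble::tibble(
            phase = ph, regime = regime, classifier = clf,
            include_sex = include_sex, failed = FALSE, reason = NA_character_,
            n_features = length(cell$features), features = list(cell$features),
            mean_accuracy = cell$mean, sd_accuracy = cell$sd)
        }
      }
    }
  }
  config <- list(phases = phases, regimes = regimes,
                 classifiers = classifiers, include_sex = include_sex,
                 alpha = alpha, cv = unclass(cv), net = unclass(net),
                 patience = as.integer(patience),
                 max_steps = if (is.null(max_steps)) NA_integer_ else as.integer(max_steps),
                 input = if (is.character(data)) data else "feature_table")
  structure(list(cells = dplyr::bind_rows(cells), stats = stats_by_phase,
                 config = config, seed = as.integer(seed),
                 config_hash = rlang::hash(config)),
            class = "cage_report")
}

#' Rank the grid cells of a report
#'
#' Summarizes accuracy per (phase, regime, classifier) cell, ranked within
#' phase by mean accuracy, then smaller SD, then smaller subset — so the
#' comparisons of interest (stepwise vs. significant vs. all; network vs.
#' threshold spread) read off directly. Flags the lowest-spread cell per
#' phase.
#'
#' @param report A `cage_report`.
#' @return A tibble of non-failed cells with `rank` and `lowest_sd` columns.
#' @export
compare_methods <- function(report) {
  cells <- dplyr::filter(report$cells, !.data$failed)
  if (nrow(cells) == 0) rlang::abort("no successful cells to compare")
  cells <- dplyr::arrange(cells, .data$phase, dplyr::desc(.data$mean_accuracy),
                          .data$sd_accuracy, .data$n_features)
  cells <- dplyr::mutate(
    dplyr::group_by(cells, .data$phase),
    rank = dplyr::row_number(),
    lowest_sd = .data$sd_accuracy == min(.data$sd_accuracy)
  )
  dplyr::select(dplyr::ungroup(cells), "phase", "rank", "regime",
                "classifier", "include_sex", "n_features", "mean_accuracy",
                "sd_accuracy", "lowest_sd")
}

report_json_string <- function(report) {
  cells <- report$cells
  payload <- list(
    seed = report$seed,
    config_hash = report$config_hash,
    config = report$config,
    cells = lapply(seq_len(nrow(cells)), function(i) {
      list(phase = cells$phase[i], regime = cells$regime[i],
           classifier = cells$classifier[i],
           include_sex = cells$include_sex[i], failed = cells$failed[i],
           reason = cells$reason[i], n_features = cells$n_features[i],
           features = as.list(cells$features[[i]]),
           mean_accuracy = cells$mean_accuracy[i],
           sd_accuracy = cells$sd_accuracy[i])
    })
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null", null = "null"))
}

#' Render a report to JSON and/or Markdown
#'
#' The JSON rendering is complete and machine-readable ([report_from_json()]
#' inverts it); the Markdown rendering is a human summary table. Both are
#' deterministic for a given report.
#'
#' @param report A `cage_report`.
#' @param json_path,md_path Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
render_report <- function(report, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path)) {
    writeLines(report_json_string(report), json_path)
  }
  if (!is.null(md_path)) {
    cells <- report$cells
    lines <- c(
      "# Genotype classification report", "",
      paste0("Seed: ", report$seed, "  |  config hash: ", report$config_hash), "",
      "| phase | regime | classifier | sex input | features | accuracy | sd |",
      "|---|---|---|---|---|---|---|",
      vapply(seq_len(nrow(cells)), function(i) {
        if (cells$failed[i]) {
          sprintf("| %s | %s | %s | %s | - | failed: %s | - |",
                  cells$phase[i], cells$regime[i], cells$classifier[i],
                  cells$include_sex[i], cells$reason[i])
        } else {
          sprintf("| %s | %s | %s | %s | %d | %.3f | %.3f |",
                  cells$phase[i], cells$regime[i], cells$classifier[i],
                  cells$include_sex[i], cells$n_features[i],
                  cells$mean_accuracy[i], cells$sd_accuracy[i])
        }
      }, character(1))
    )
    writeLines(lines, md_path)
  }
  invisible(report)
}

#' Read a report back from its JSON rendering
#'
#' @param path Path to a JSON file written by [render_report()].
#' @return A `cage_report` (round-trips byte-identically through
#'   [render_report()]).
#' @export
report_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cells <- dplyr::bind_rows(lapply(x$cells, function(cl) {
    tibble::tibble(
      phase = cl$phase, regime = cl$regime, classifier = cl$classifier,
      include_sex = cl$include_sex, failed = cl$failed,
      reason = if (is.null(cl$reason)) NA_character_ else cl$reason,
      n_features = if (is.null(cl$n_features)) NA_integer_ else as.integer(cl$n_features),
      features = list(as.character(unlist(cl$features))),
      mean_accuracy = if (is.null(cl$mean_accuracy)) NA_real_ else cl$mean_accuracy,
      sd_accuracy = if (is.null(cl$sd_accuracy)) NA_real_ else cl$sd_accuracy)
  }))
  cfg <- x$config
  config <- list(
    phases = as.character(unlist(cfg$phases)),
    regimes = as.character(unlist(cfg$regimes)),
    classifiers = as.character(unlist(cfg$classifiers)),
    include_sex = cfg$include_sex, alpha = cfg$alpha,
    cv = cfg$cv, net = cfg$net, patience = as.integer(cfg$patience),
    max_steps = if (is.null(cfg$max_steps)) NA_integer_ else as.integer(cfg$max_steps),
    input = cfg$input)
  structure(list(cells = cells, stats = NULL, config = config,
                 seed = as.integer(x$seed), config_hash = x$config_hash),
            class = "cage_report")
}

#' @export
print.cage_report <- function(x, ...) {
  cat("Genotype classification report (seed", x$seed, ")\n")
  print(dplyr::select(x$cells, -"features"))
  invisible(x)
}
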