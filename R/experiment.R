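# Experiment orchestration: the feature-selection x classifier x
# ROI-dilation sweep, and a full simulate -> fit -> extract -> sweep study.

#' Dilation sweep over one task
#'
#' For each dilation level 0..`max_turns`: dilate every drawn ROI, extract
#' the 21-feature table, run ReliefF selection with the positive-weight
#' rule on the level's table, and evaluate each classifier with stratified
#' cross-validation (SMOTE inside training folds). If the best accuracy is
#' still rising at `max_turns` the sweep adaptively extends one further
#' level.
#'
#' @param cohort a `phantom_cohort` (or any list of cases with
#'   `truth$drawn_roi` and `label`).
#' @param task task name (see [task_labels()]).
#' @param classifiers character vector of classifier kinds, or a list of
#'   [classifier_spec()]s.
#' @param max_turns maximum dilation level swept before the adaptive check
#'   (default 3).
#' @param seed master seed.
#' @param maps_list optional per-case map lists (defaults to truth maps).
#' @param levels texture quantization levels.
#' @param relieff_k ReliefF neighbour count.
#' @param use_smote balance training folds (default TRUE).
#' @param freeze_selection reuse the level-0 selected feature set at every
#'   level instead of re-selecting per level (default FALSE).
#' @param adaptive extend past `max_turns` while accuracy still rises.
#' @param n_folds cross-validation folds.
#' @return object of class `sweep_result`: `grid` (data.frame with task,
#'   classifier, dilation_level, mean_accuracy), `results` (eval_result
#'   list), `selected` (features kept per level), `best` (best grid row),
#'   `seed`.
#' @export
run_dilation_sweep <- function(cohort, task, classifiers = c("svm_rbf",
                                                             "knn",
                                                             "gaussian_nb"),
                               max_turns = 3L, seed = 1L, maps_list = NULL,
                               levels = 32L, relieff_k = 10L,
                               use_smote = TRUE, freeze_selection = FALSE,
                               adaptive = TRUE, n_folds = 5L) {
  if (max_turns < 1) stop("max_turns must be >= 1")
  specs <- lapply(classifiers, function(cl)
    if (inherits(cl, "classifier_spec")) cl else classifier_spec(cl))
  if (is.null(maps_list)) maps_list <- lapply(cohort, truth_maps)

  results <- list()
  selected <- list()
  grid <- data.frame()
  frozen <- NULL

  eval_level <- function(lev) {
    tab <- cohort_feature_table(cohort, dilation = lev,
                                maps_list = maps_list, levels = levels)
    lab <- task_labels(task, tab$label)
    keep_rows <- !is.na(lab)
    feats <- if (freeze_selection && !is.null(frozen)) frozen
    else {
      w <- suppressWarnings(
        relieff(tab[keep_rows, canonical_features()], lab[keep_rows],
                k = relieff_k))
      sel <- tryCatch(select_positive(w), error = function(e) NULL)
      if (is.null(sel)) {
        warning("level ", lev, ": no positive ReliefF weight; ",
                "keeping all features")
        canonical_features()
      } else sel$kept
    }
    if (freeze_selection && is.null(frozen)) frozen <<- feats
    selected[[as.character(lev)]] <<- feats
    for (sp in specs) {
      ev <- suppressWarnings(
        cross_validate(tab, task, sp, seed = derive_seed(seed, lev),
                       use_smote = use_smote, n_folds = n_folds,
                       features = feats))
      ev$dilation_level <- as.integer(lev)
      results[[paste(task, sp$kind, lev, sep = "/")]] <<- ev
      grid <<- rbind(grid, data.frame(task = task, classifier = sp$kind,
                                      dilation_level = as.integer(lev),
                                      mean_accuracy = ev$mean_accuracy,
                                      stringsAsFactors = FALSE))
    }
  }

  for (lev in 0:max_turns) eval_level(lev)
  if (adaptive) {
    top <- function(lev) max(grid$mean_accuracy[grid$dilation_level == lev])
    if (top(max_turns) > top(max_turns - 1)) eval_level(max_turns + 1L)
  }
  best_row <- grid[which.max(grid$mean_accuracy), ]
  structure(list(grid = grid, results = results, selected = selected,
                 best = best_row, task = task, seed = as.integer(seed)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result %s: levels 0..%d>\n", x$task,
              max(x$grid$dilation_level)))
  print(x$grid, row.names = FALSE)
  cat(sprintf("best: %s at level %d (accuracy %.4f)\n", x$best$classifier,
              x$best$dilation_level, x$best$mean_accuracy))
  invisible(x)
}

#' Run the full synthetic study
#'
#' Simulates a phantom cohort, derives parameter maps (fitted from the raw
#' series, or the truth grids), and runs the dilation sweep for each
#' requested task, writing JSON results, CSV feature tables and
#' accuracy-vs-dilation plots.
#'
#' @param config a [phantom_config()], or the path of a YAML file whose
#'   top-level keys are `phantom` (arguments of [phantom_config()]) and
#'   `study` (arguments below).
#' @param out_dir output directory (created if needed).
#' @param tasks tasks to sweep.
#' @param classifiers classifier kinds.
#' @param map_source `"fitted"` (fit maps from simulated signal series) or
#'   `"truth"` (use the generator's truth grids).
#' @param max_turns sweep depth.
#' @param levels texture quantization levels.
#' @param use_smote balance training folds.
#' @return named list of `sweep_result`s (one per task), invisibly;
#'   side-effect files under `out_dir`.
#' @export
run_full_study <- function(config = phantom_config(), out_dir = tempdir(),
                           tasks = c("sig_vs_nonsig", "g34_vs_g43plus",
                                     "three_class"),
                           classifiers = c("svm_rbf", "knn", "gaussian_nb"),
                           map_source = c("fitted", "truth"),
                           max_turns = 3L, levels = 32L, use_smote = TRUE) {
  map_source <- match.arg(map_source)
  if (is.character(config)) config <- read_study_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- gen_cohort(config, signals = map_source == "fitted")
  maps_list <- if (map_source == "fitted")
    lapply(cohort, fitted_maps) else lapply(cohort, truth_maps)

  out <- list()
  for (task in tasks) {
    sw <- run_dilation_sweep(cohort, task, classifiers,
                             max_turns = max_turns, seed = config$seed,
                             maps_list = maps_list, levels = levels,
                             use_smote = use_smote)
    out[[task]] <- sw
    utils::write.csv(sw$grid,
                     file.path(out_dir, paste0("accuracy_", task, ".csv")),
                     row.names = FALSE)
    tab0 <- cohort_feature_table(cohort, 0L, maps_list, levels)
    utils::write.csv(tab0,
                     file.path(out_dir, paste0("features_", task,
                                               "_level0.csv")),
                     row.names = FALSE)
    plot_file <- file.path(out_dir, paste0("accuracy_", task, ".png"))
    grDevices::png(plot_file, width = 700, height = 500)
    plot_sweep(sw)
    grDevices::dev.off()
  }
  report <- lapply(out, function(sw)
    list(grid = sw$grid, selected = sw$selected,
         best = as.list(sw$best), seed = sw$seed))
  jsonlite::write_json(report, file.path(out_dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Accuracy-versus-dilation plot of a sweep
#'
#' One line per classifier; synthetic-cohort results only.
#'
#' @param sw a `sweep_result`.
#' @return invisibly NULL; draws on the active device.
#' @export
plot_sweep <- function(sw) {
  g <- sw$grid
  cls <- unique(g$classifier)
  levs <- sort(unique(g$dilation_level))
  acc <- sapply(cls, function(cl)
    g$mean_accuracy[g$classifier == cl][order(g$dilation_level[g$classifier == cl])])
  graphics::matplot(levs, acc, type = "b", pch = 19, lty = 1,
                    xlab = "ROI dilation turns", ylab = "mean CV accuracy",
                    main = paste0(sw$task, " (synthetic cohort)"),
                    ylim = c(0, 1))
  graphics::legend("bottomright", legend = cls, col = seq_along(cls),
                   pch = 19, lty = 1, bty = "n")
  invisible(NULL)
}
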