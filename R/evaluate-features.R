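#' Wrapper feature evaluation over a cohort
#'
#' The main entry point of the package: runs the wrapper feature-evaluation
#' framework over an FMG cohort. For every participant and candidate
#' feature, an RBF-kernel SVM is evaluated by round-wise three-fold
#' cross-validation (train on two rounds, test on the held-out round), with
#' hyperparameters chosen by an inner stratified grid search maximizing AUC.
#' Per-participant fold means are then averaged across participants, and
#' each feature is compared against the raw-signal baseline with a
#' one-tailed paired t-test.
#'
#' @param cohort a list of [fmg_session()] objects (e.g. from
#'   [generate_cohort()]); sessions are grouped by participant and each
#'   participant must contribute exactly 3 rounds.
#' @param features character vector of feature names to evaluate; include
#'   \code{"raw"} to obtain p-values against the raw baseline.
#' @param spec an [window_spec()].
#' @param threshold labeling threshold (ADC counts) or \code{NULL} for the
#'   per-round data-driven default.
#' @param grid hyperparameter lattice, see [default_grid()].
#' @param inner_folds inner CV folds of the grid search.
#' @param max_train training-rows cap per fold (stratified subsampling).
#' @param seed integer seed controlling fold assignment and subsampling.
#' @return An object of class \code{"fmg_evaluation"} wrapping the
#'   aggregated [aggregate_report()] plus the evaluation settings; it has
#'   \code{print}, \code{summary} and \code{plot} methods.
#' @export
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n_participants = 2, n_objects = 1, seed = 7)
#' cohort <- generate_cohort(cfg)
#' ev <- evaluate_features(cohort, features = c("raw", "lf"),
#'                         grid = list(cost = 1, gamma = 1 / 32),
#'                         inner_folds = 3, max_train = 600, seed = 7)
#' print(ev)
#' }
evaluate_features <- function(cohort,
                              features = c("raw", "mav", "rms", "lf", "pf", "ar"),
                              spec = window_spec(),
                              threshold = NULL,
                              grid = default_grid(),
                              inner_folds = 10L,
                              max_train = 2000L,
                              seed = 1L) {
  features <- match.arg(features, c("raw", "mav", "rms", "lf", "pf", "ar"),
                        several.ok = TRUE)
  pids <- vapply(cohort, function(s) as.character(s$participant_id), character(1))
  folds <- list()
  for (pp in unique(pids)) {
    sessions <- cohort[pids == pp]
    for (ft in features) {
      folds[[length(folds) + 1L]] <- cross_validate_participant(
        sessions, ft, spec = spec, threshold = threshold, grid = grid,
        inner_folds = inner_folds, max_train = max_train,
        seed = seed + 7919L * match(pp, unique(pids)))
    }
  }
  folds <- do.call(rbind, folds)
  report <- aggregate_report(folds)
  structure(list(report = report,
                 features = features,
                 window = spec,
                 grid = grid,
                 inner_folds = inner_folds,
                 max_train = max_train,
                 threshold = threshold,
                 seed = seed,
                 n_participants = length(unique(pids))),
            class = "fmg_evaluation")
}

#' @export
print.fmg_evaluation <- function(x, ...) {
  print(x$report, ...)
  invisible(x)
}

#' @export
summary.fmg_evaluation <- function(object, ...) {
  cat("FMG wrapper feature evaluation\n")
  cat(sprintf("  window: %d samples, stride %d\n",
              object$window$size, object$window$stride))
  cat(sprintf("  grid: %d cost x %d gamma points, %d inner folds, max_train %s\n",
              length(object$grid$cost), length(object$grid$gamma),
              object$inner_folds, format(object$max_train)))
  cat(sprintf("  threshold: %s, seed %d\n\n",
              if (is.null(object$threshold)) "auto (per round)"
              else format(object$threshold), object$seed))
  print(object$report)
  cat("\nPer-participant AUC:\n")
  print(round(object$report$participant_auc, 3))
  invisible(object)
}

#' Plot per-feature AUC with spread across participants
#'
#' Dot plot of the mean AUC per feature (ordered as in the report) with
#' one-standard-deviation whiskers across participants; the raw baseline is
#' marked by a dashed reference line.
#'
#' @param x an \code{fmg_evaluation}.
#' @param ... passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.fmg_evaluation <- function(x, ...) {
  tab <- x$report$table
  k <- nrow(tab)
  ylim <- range(c(tab$mean_auc - tab$sd_auc, tab$mean_auc + tab$sd_auc, 0.5, 1))
  graphics::plot(seq_len(k), tab$mean_auc, xaxt = "n", xlab = "Feature",
                 ylab = "AUC", ylim = ylim, pch = 19,
                 main = "Grasp detection AUC by feature", ...)
  graphics::axis(1, at = seq_len(k), labels = toupper(tab$feature))
  graphics::arrows(seq_len(k), tab$mean_auc - tab$sd_auc,
                   seq_len(k), tab$mean_auc + tab$sd_auc,
                   angle = 90, code = 3, length = 0.05)
  if ("raw" %in% tab$feature) {
    graphics::abline(h = tab$mean_auc[tab$feature == "raw"], lty = 2,
                     col = "grey40")
  }
  invisible(x)
}
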