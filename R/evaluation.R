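#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive instance receives a
#' higher score than a randomly chosen negative one, with ties counted one
#' half — equivalent to the trapezoidal area under the ROC curve. Computed
#' from midranks, so it is exact for any tie structure and invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores numeric vector of continuous classifier scores (larger =
#'   more grasp-like).
#' @param labels binary vector (1 = positive/grasp) of the same length.
#' @return AUC in \code{[0, 1]}.
#' @export
#' @examples
#' compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default RBF-SVM hyperparameter lattice
#'
#' The conventional coarse log-spaced lattice for LIBSVM grid searches:
#' cost \eqn{2^{-5}, 2^{-3}, \ldots, 2^{15}} and gamma
#' \eqn{2^{-15}, 2^{-13}, \ldots, 2^{3}}.
#'
#' @return list with numeric vectors \code{cost} and \code{gamma}.
#' @export
default_grid <- function() {
  list(cost = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# cyclically across folds.
stratified_folds <- function(y, k, seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

svm_decision_values <- function(model, x) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pos_side <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  d <- as.numeric(dv[, 1])
  if (pos_side != "1") d <- -d
  list(decision = d, predicted = as.character(pr))
}

fit_rbf_svm <- function(x, y, cost, gamma) {
  e1071::svm(x = x, y = factor(y, levels = c("0", "1")),
             type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Selects the (cost, gamma) pair maximizing mean inner-fold AUC under
#' stratified, seeded k-fold cross-validation within the training data.
#' Ties (within 1e-12) are broken toward the smallest cost, then the
#' smallest gamma, preferring smoother models.
#'
#' @param x numeric feature matrix (already standardized).
#' @param y binary label vector (0/1); both classes must be present.
#' @param grid list with \code{cost} and \code{gamma} vectors.
#' @param inner_folds number of inner folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return list with \code{cost}, \code{gamma} and \code{inner_auc} (the
#'   winning mean inner-fold AUC).
#' @export
grid_search_rbf_svm <- function(x, y, grid = default_grid(),
                                inner_folds = 10L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training data must contain both classes", call. = FALSE)
  if (!length(grid$cost) || !length(grid$gamma)) stop("grid is empty", call. = FALSE)
  k <- min(inner_folds, min(table(y)))
  if (k < 2L) stop("too few samples per class for inner cross-validation", call. = FALSE)
  fold <- stratified_folds(y, k, seed)
  combos <- expand.grid(cost = sort(grid$cost), gamma = sort(grid$gamma))
  combos <- combos[order(combos$cost, combos$gamma), , drop = FALSE]
  mean_auc <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    aucs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      model <- fit_rbf_svm(x[tr, , drop = FALSE], y[tr],
                           combos$cost[ci], combos$gamma[ci])
      dv <- svm_decision_values(model, x[!tr, , drop = FALSE])$decision
      aucs[f] <- compute_auc(dv, y[!tr])
    }
    mean_auc[ci] <- mean(aucs)
  }
  best <- which(mean_auc >= max(mean_auc) - 1e-12)[1]  # combos pre-sorted
  list(cost = combos$cost[best], gamma = combos$gamma[best],
       inner_auc = mean_auc[best])
}

standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1    # constant columns map to 0
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd, "/"))
}

stratified_subsample <- function(y, max_n, seed) {
  n <- length(y)
  if (n <= max_n) return(seq_len(n))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  keep <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    take <- max(1L, round(max_n * length(idx) / n))
    keep <- c(keep, idx[sample.int(length(idx), min(take, length(idx)))])
  }
  sort(keep)
}

#' Evaluate one cross-validation fold
#'
#' Standardizes columns by training-set mean and standard deviation
#' (constant columns map to zero), selects hyperparameters by inner grid
#' search, trains the final RBF-SVM on the training set, and scores the test
#' set: AUC from the continuous decision values, accuracy from the predicted
#' class. A single-class test set yields \code{auc = NA} with
#' \code{auc_defined = FALSE} (accuracy is still reported).
#'
#' @param train_x,train_y training feature matrix and binary labels.
#' @param test_x,test_y test feature matrix and binary labels.
#' @param grid hyperparameter lattice, see [default_grid()].
#' @param inner_folds inner CV folds for the grid search.
#' @param max_train cap on training rows; larger training sets are reduced
#'   by seeded stratified subsampling before standardization and fitting
#'   (set \code{Inf} to train on everything).
#' @param seed integer seed.
#' @return list with \code{cost}, \code{gamma}, \code{auc}, \code{accuracy},
#'   \code{n_test}, \code{auc_defined}.
#' @export
evaluate_fold <- function(train_x, train_y, test_x, test_y,
                          grid = default_grid(), inner_folds = 10L,
                          max_train = 2000L, seed = 1L) {
  train_y <- as.integer(train_y); test_y <- as.integer(test_y)
  if (nrow(train_x) == 0L || nrow(test_x) == 0L) stop("empty train or test set", call. = FALSE)
  if (length(unique(train_y)) < 2L) stop("training data must contain both classes", call. = FALSE)
  keep <- stratified_subsample(train_y, max_train, seed)
  train_x <- train_x[keep, , drop = FALSE]; train_y <- train_y[keep]
  z <- standardize_train_test(train_x, test_x)
  sel <- grid_search_rbf_svm(z$train, train_y, grid = grid,
                             inner_folds = inner_folds, seed = seed)
  model <- fit_rbf_svm(z$train, train_y, sel$cost, sel$gamma)
  out <- svm_decision_values(model, z$test)
  auc_defined <- length(unique(test_y)) == 2L
  list(cost = sel$cost, gamma = sel$gamma,
       auc = if (auc_defined) compute_auc(out$decision, test_y) else NA_real_,
       accuracy = mean(out$predicted == as.character(test_y)),
       n_test = length(test_y),
       auc_defined = auc_defined)
}

#' Round-wise cross-validation for one participant
#'
#' Each of the participant's three recording rounds is held out in turn;
#' the classifier is trained on the two remaining rounds. Labels are derived
#' per round from the thumb channel, and features are extracted per round
#' before pooling, so windows never span round boundaries.
#'
#' @param sessions list of exactly 3 [fmg_session()] objects (the rounds of
#'   one participant).
#' @param feature feature name, see [extract_feature_matrix()].
#' @param spec an [window_spec()].
#' @param threshold labeling threshold in ADC counts, or \code{NULL} to use
#'   [suggest_threshold()] per round.
#' @param grid,inner_folds,max_train,seed passed to [evaluate_fold()]; the
#'   per-fold seed is derived from \code{seed} and the held-out round.
#' @return data frame of 3 fold results (one per held-out round) with
#'   columns \code{participant}, \code{held_out_round}, \code{feature},
#'   \code{cost}, \code{gamma}, \code{auc}, \code{accuracy}, \code{n_test}.
#' @export
cross_validate_participant <- function(sessions, feature, spec = window_spec(),
                                       threshold = NULL, grid = default_grid(),
                                       inner_folds = 10L, max_train = 2000L,
                                       seed = 1L) {
  if (length(sessions) != 3L) stop("round-wise cross-validation needs exactly 3 rounds", call. = FALSE)
  rounds <- vapply(sessions, function(s) s$round_index, integer(1))
  if (anyDuplicated(rounds)) stop("sessions must have distinct round indices", call. = FALSE)
  fm <- lapply(sessions, function(s) {
    thr <- if (is.null(threshold)) suggest_threshold(s$thumb) else threshold
    extract_feature_matrix(s, label_from_thumb(s$thumb, thr), feature, spec)
  })
  res <- vector("list", 3L)
  for (i in seq_along(sessions)) {
    train_idx <- setdiff(seq_along(sessions), i)
    train_x <- do.call(rbind, lapply(fm[train_idx], function(f) f$values))
    train_y <- unlist(lapply(fm[train_idx], function(f) f$labels))
    fold <- evaluate_fold(train_x, train_y, fm[[i]]$values, fm[[i]]$labels,
                          grid = grid, inner_folds = inner_folds,
                          max_train = max_train,
                          seed = seed * 131L + rounds[i])
    res[[i]] <- data.frame(
      participant = as.character(sessions[[i]]$participant_id),
      held_out_round = rounds[i], feature = feature,
      cost = fold$cost, gamma = fold$gamma, auc = fold$auc,
      accuracy = fold$accuracy, n_test = fold$n_test,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' One-tailed paired t-test for AUC improvement
#'
#' Tests whether a feature's per-participant AUCs exceed the raw-signal
#' AUCs: on differences \eqn{d_i = feature_i - raw_i},
#' \eqn{t = \bar d / (s_d/\sqrt{m})} with \eqn{m - 1} degrees of freedom,
#' one-tailed for \eqn{H_1: \bar d > 0}. All-zero differences are degenerate
#' and return \eqn{p = 0.5} by convention with a flag.
#'
#' @param feature_aucs,raw_aucs per-participant AUC vectors of equal length
#'   (at least 2).
#' @return list with \code{p_value}, \code{statistic}, \code{df},
#'   \code{degenerate}.
#' @export
paired_one_tailed_t <- function(feature_aucs, raw_aucs) {
  if (length(feature_aucs) != length(raw_aucs) || length(feature_aucs) < 2L) {
    stop("paired test needs two equal-length vectors of length >= 2", call. = FALSE)
  }
  d <- feature_aucs - raw_aucs
  if (all(d == 0)) {
    return(list(p_value = 0.5, statistic = NA_real_,
                df = length(d) - 1L, degenerate = TRUE))
  }
  m <- length(d)
  se <- stats::sd(d) / sqrt(m)
  if (se <= 10 * .Machine$double.eps * abs(mean(d))) {
    # constant nonzero differences up to rounding: t is effectively infinite
    return(list(p_value = if (mean(d) > 0) 0 else 1,
                statistic = sign(mean(d)) * Inf,
                df = m - 1L, degenerate = TRUE))
  }
  tstat <- mean(d) / se
  list(p_value = stats::pt(tstat, df = m - 1L, lower.tail = FALSE),
       statistic = tstat, df = m - 1L, degenerate = FALSE)
}

#' Aggregate fold results into an evaluation report
#'
#' Two-stage averaging: each participant's AUC (and accuracy) is the mean of
#' their three folds, then means and standard deviations are taken across
#' participants. Each feature is compared with the raw-signal baseline by a
#' one-tailed paired t-test on the per-participant AUCs. Features are
#' ordered by decreasing mean AUC; the raw row carries no p-value.
#'
#' @param folds data frame of fold results as produced by
#'   [cross_validate_participant()] (rows for all features, participants and
#'   rounds; the grid must be complete).
#' @return An object of class \code{"fmg_report"}: list with \code{table}
#'   (per-feature summary), \code{participant_auc} and
#'   \code{participant_accuracy} (participant x feature matrices) and
#'   \code{folds}.
#' @export
aggregate_report <- function(folds) {
  needed <- c("participant", "held_out_round", "feature", "auc", "accuracy")
  if (!all(needed %in% names(folds))) stop("malformed fold results", call. = FALSE)
  features <- unique(folds$feature)
  participants <- unique(folds$participant)
  grid <- expand.grid(participant = participants, feature = features,
                      stringsAsFactors = FALSE)
  counts <- with(folds, table(participant, feature))
  gaps <- character(0)
  for (i in seq_len(nrow(grid))) {
    cnt <- tryCatch(counts[grid$participant[i], grid$feature[i]], error = function(e) 0L)
    if (cnt != 3L) {
      gaps <- c(gaps, sprintf("%s/%s (%d folds)", grid$participant[i],
                              grid$feature[i], cnt))
    }
  }
  if (length(gaps)) {
    stop(sprintf("incomplete fold grid: %s", paste(gaps, collapse = "; ")),
         call. = FALSE)
  }
  p_auc <- matrix(NA_real_, length(participants), length(features),
                  dimnames = list(participants, features))
  p_acc <- p_auc
  for (ft in features) {
    for (pp in participants) {
      sel <- folds$feature == ft & folds$participant == pp
      p_auc[pp, ft] <- mean(folds$auc[sel])
      p_acc[pp, ft] <- mean(folds$accuracy[sel])
    }
  }
  tab <- data.frame(feature = features,
                    mean_auc = colMeans(p_auc),
                    sd_auc = apply(p_auc, 2, stats::sd),
                    mean_accuracy = colMeans(p_acc),
                    sd_accuracy = apply(p_acc, 2, stats::sd),
                    p_value_vs_raw = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if ("raw" %in% features && length(participants) >= 2L) {
    for (i in seq_len(nrow(tab))) {
      if (tab$feature[i] == "raw") next
      tab$p_value_vs_raw[i] <-
        paired_one_tailed_t(p_auc[, tab$feature[i]], p_auc[, "raw"])$p_value
    }
  }
  tab <- tab[order(-tab$mean_auc), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, participant_auc = p_auc,
                 participant_accuracy = p_acc, folds = folds),
            class = "fmg_report")
}

#' @export
print.fmg_report <- function(x, digits = 3, ...) {
  cat("Wrapper feature evaluation (round-wise 3-fold CV, RBF-SVM)\n")
  cat(sprintf("%d participants, %d features\n\n",
              nrow(x$participant_auc), nrow(x$table)))
  tab <- x$table
  out <- data.frame(
    Feature = toupper(tab$feature),
    AUC = sprintf("%.*f ± %.*f", digits, tab$mean_auc, digits, tab$sd_auc),
    `Accuracy (%)` = sprintf("%.2f ± %.2f", 100 * tab$mean_accuracy,
                             100 * tab$sd_accuracy),
    `P value` = ifelse(is.na(tab$p_value_vs_raw), "N/A",
                       sprintf("%.*f", digits, tab$p_value_vs_raw)),
    check.names = FALSE, stringsAsFactors = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}
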