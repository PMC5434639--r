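test_that("AUC equals the concordant-pair probability with half-weight ties", {
  expect_equal(compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(compute_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(compute_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(compute_auc(1:4, rep(1, 4)), "both classes")

  set.seed(13)
  for (i in 1:50) {
    n <- sample(4:200, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:2, 1))   # induce ties
    expect_equal(compute_auc(scores, labels),
                 oracle_auc_allpairs(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  scores <- rnorm(80); labels <- rep(0:1, 40)
  a <- compute_auc(scores, labels)
  expect_equal(compute_auc(exp(scores), labels), a)
  expect_equal(compute_auc(2 * scores - 7, labels), a)
  expect_equal(compute_auc(rank(scores), labels), a)
})

test_that("grid search returns single points and breaks separable ties downward", {
  b <- make_blobs(n_per_class = 30, sep = 10, seed = 2)
  single <- grid_search_rbf_svm(b$x, b$y, grid = list(cost = 4, gamma = 0.25),
                                inner_folds = 3, seed = 1)
  expect_equal(single$cost, 4)
  expect_equal(single$gamma, 0.25)

  sel <- grid_search_rbf_svm(b$x, b$y,
                             grid = list(cost = c(8, 2, 32), gamma = c(0.5, 0.125)),
                             inner_folds = 3, seed = 1)
  expect_equal(sel$inner_auc, 1)          # every point separates the blobs
  expect_equal(sel$cost, 2)               # smallest cost ...
  expect_equal(sel$gamma, 0.125)          # ... then smallest gamma
  expect_error(grid_search_rbf_svm(b$x, rep(1, length(b$y)), tiny_grid),
               "both classes")
})

test_that("shuffled labels drive the selected inner AUC to chance", {
  set.seed(7)
  x <- matrix(rnorm(300 * 2), ncol = 2)
  y <- sample(rep(0:1, 150))
  sel <- grid_search_rbf_svm(x, y, grid = small_grid, inner_folds = 5, seed = 3)
  expect_lt(abs(sel$inner_auc - 0.5), 0.12)
})

test_that("a fold on separable data scores perfectly when tested on itself", {
  b <- make_blobs(n_per_class = 40, sep = 10, seed = 4)
  f <- evaluate_fold(b$x, b$y, b$x, b$y, grid = tiny_grid, inner_folds = 3, seed = 1)
  expect_equal(f$auc, 1)
  expect_equal(f$accuracy, 1)
  expect_true(f$auc_defined)
  expect_equal(f$n_test, 80)
})

test_that("degenerate folds are guarded", {
  b <- make_blobs(n_per_class = 30, sep = 10, seed = 6)
  xconst <- cbind(b$x, 5)                 # constant column survives scaling
  f <- evaluate_fold(xconst, b$y, xconst, b$y, grid = tiny_grid,
                     inner_folds = 3, seed = 1)
  expect_equal(f$auc, 1)
  # single-class test set: AUC undefined but accuracy reported
  pos <- b$y == 1
  f1 <- evaluate_fold(b$x, b$y, b$x[pos, ], b$y[pos], grid = tiny_grid,
                      inner_folds = 3, seed = 1)
  expect_false(f1$auc_defined)
  expect_true(is.na(f1$auc))
  expect_equal(f1$accuracy, 1)
  expect_error(evaluate_fold(b$x, rep(0, length(b$y)), b$x, b$y,
                             grid = tiny_grid), "both classes")
})

test_that("round-wise cross-validation yields one fold per held-out round", {
  cfg <- tiny_config(seed = 9)
  co <- generate_cohort(cfg)
  res <- cross_validate_participant(co, "mav", grid = tiny_grid,
                                    inner_folds = 3, max_train = 500, seed = 2)
  expect_equal(nrow(res), 3)
  expect_setequal(res$held_out_round, 1:3)
  expect_true(all(res$auc > 0.5))        # default gains are detectable
  expect_error(cross_validate_participant(co[1:2], "mav"), "exactly 3")
})

test_that("the paired one-tailed t-test matches the t-distribution oracle", {
  raw <- c(1, 1, 1); feat <- raw + c(1, 2, 3)   # d = (1,2,3)
  res <- paired_one_tailed_t(feat, raw)
  tstat <- mean(c(1, 2, 3)) / (sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(res$statistic, tstat)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 1 - pt(tstat, df = 2))
  expect_equal(res$p_value, 0.03709, tolerance = 1e-3)

  same <- paired_one_tailed_t(c(0.8, 0.9), c(0.8, 0.9))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 0.5)

  worse <- paired_one_tailed_t(c(0.5, 0.6, 0.55), c(0.8, 0.9, 0.85))
  expect_gt(worse$p_value, 0.5)
  expect_error(paired_one_tailed_t(1, 1), "length >= 2")
})

test_that("aggregation averages in two stages and orders features by AUC", {
  folds <- expand.grid(participant = c("a", "b"), held_out_round = 1:3,
                       feature = c("raw", "lf"), stringsAsFactors = FALSE)
  folds$auc <- 0.8; folds$accuracy <- 0.9
  rep1 <- aggregate_report(folds)
  expect_equal(rep1$table$mean_auc, c(0.8, 0.8))
  expect_equal(rep1$table$sd_auc, c(0, 0))

  folds$auc <- ifelse(folds$participant == "a", 0.9, 0.7)
  folds$auc[folds$feature == "raw"] <- folds$auc[folds$feature == "raw"] - 0.05
  rep2 <- aggregate_report(folds)
  lf_row <- rep2$table[rep2$table$feature == "lf", ]
  expect_equal(lf_row$mean_auc, 0.8)
  expect_equal(lf_row$sd_auc, sd(c(0.9, 0.7)))
  expect_equal(rep2$table$feature, c("lf", "raw"))   # ordered by mean AUC
  expect_true(is.na(rep2$table$p_value_vs_raw[rep2$table$feature == "raw"]))
  expect_false(is.na(lf_row$p_value_vs_raw))

  # permuting participants leaves the report unchanged
  set.seed(1)
  perm <- folds[sample(nrow(folds)), ]
  rep3 <- aggregate_report(perm)
  expect_equal(rep3$table, rep2$table)
  expect_equal(rep3$participant_auc[rownames(rep2$participant_auc),
                                    colnames(rep2$participant_auc)],
               rep2$participant_auc)

  expect_error(aggregate_report(folds[-1, ]), "incomplete fold grid")
})

test_that("evaluation of a seeded cohort is reproducible bit for bit", {
  cfg <- synthetic_config(n_participants = 2, n_objects = 1, seed = 21)
  co <- generate_cohort(cfg)
  run <- function() evaluate_features(co, features = c("raw", "mav"),
                                      grid = tiny_grid, inner_folds = 3,
                                      max_train = 400, seed = 5)
  e1 <- run(); e2 <- run()
  expect_identical(e1$report$table, e2$report$table)
  expect_identical(e1$report$folds, e2$report$folds)
  expect_s3_class(e1, "fmg_evaluation")
  expect_output(print(e1), "Feature")
})
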