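# Shared fixtures and independent oracles for the test suite.

# A small but structurally complete synthetic configuration.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_participants = 1L, n_rounds = 3L, n_objects = 1L, seed = 42L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# Reduced SVM settings used throughout: single/small lattice, few inner folds.
tiny_grid <- list(cost = 1, gamma = 1 / 32)
small_grid <- list(cost = 2^c(0, 4), gamma = 2^c(-6, -3))

# Brute-force AUC: all positive-negative pairs, ties counted one half.
oracle_auc_allpairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct normal-equations polynomial fit on the abscissa i = 1..n.
oracle_polyfit <- function(window, degree) {
  n <- length(window)
  i <- seq_len(n)
  X <- sapply(0:degree, function(p) i^p)
  beta <- solve(t(X) %*% X, t(X) %*% window)
  resid <- window - X %*% beta
  list(coef = as.numeric(beta), residual = sum(resid^2))
}

# Biased autocovariance of a demeaned series at a given lag.
oracle_autocov <- function(y, lag) {
  y <- y - mean(y)
  n <- length(y)
  sum(y[seq_len(n - lag)] * y[seq.int(1 + lag, n)]) / n
}

# Two well-separated Gaussian blobs in d dimensions.
make_blobs <- function(n_per_class = 40, d = 2, sep = 8, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

# A random valid session (for round-trip properties).
random_session <- function(n = 30, seed = 1, with_events = TRUE) {
  set.seed(seed)
  ev <- NULL
  if (with_events && n >= 10) {
    ev <- data.frame(kind = c("movement_only", "neutral", "grasp_move"),
                     object = c(1L, NA_integer_, 1L),
                     start = c(1L, 4L, 6L), end = c(3L, 5L, 10L),
                     grasp_start = c(NA, NA, 7L), grasp_end = c(NA, NA, 9L),
                     stringsAsFactors = FALSE)
  }
  fmg_session(participant_id = sample(1:99, 1), round_index = sample(1:3, 1),
              sampling_rate = 10,
              fmg = matrix(sample(0:1023, n * 16, replace = TRUE), n, 16),
              thumb = sample(0:1023, n, replace = TRUE),
              events = ev)
}
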