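#' Sliding-window specification
#'
#' Windows are symmetrically centered on the sample they describe: the
#' feature value for sample \eqn{i} is computed from the \code{size} samples
#' centered at \eqn{i}. The default of 5 samples corresponds to 0.5 s at the
#' band's 10 Hz sampling rate, and a stride of 1 gives an 80\% (four of
#' five samples) overlap between successive windows.
#'
#' @param size window length in samples; must be odd so a center exists.
#' @param stride distance between successive window centers, samples.
#' @return An object of class \code{"fmg_window"}.
#' @export
window_spec <- function(size = 5L, stride = 1L) {
  size <- as.integer(size); stride <- as.integer(stride)
  if (size < 1L || size %% 2L == 0L) stop("window size must be odd and >= 1", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  structure(list(size = size, stride = stride), class = "fmg_window")
}

#' Enumerate centered windows of a series
#'
#' Every sample that admits a full symmetric window becomes a window center;
#' boundary samples without full context are dropped (no padding). With
#' stride 1 the first center is \code{(n+1)/2}, the last \code{N-(n-1)/2},
#' and there are \code{N-n+1} windows.
#'
#' @param series numeric vector of length N.
#' @param spec an [window_spec()].
#' @return list with \code{centers} (sample indices) and \code{windows}
#'   (matrix, one window per row in chronological order).
#' @export
extract_windows <- function(series, spec = window_spec()) {
  N <- length(series); n <- spec$size
  if (N < n) stop("series shorter than window", call. = FALSE)
  W <- stats::embed(series, n)[, n:1, drop = FALSE]  # chronological columns
  half <- (n - 1L) %/% 2L
  centers <- seq.int(half + 1L, N - half)
  keep <- seq.int(1L, length(centers), by = spec$stride)
  list(centers = centers[keep], windows = W[keep, , drop = FALSE])
}

#' Mean absolute value of a window
#'
#' Captures the overall FMG activity of a channel inside the window:
#' \eqn{MAV = n^{-1}\sum_{i=1}^{n} |y_i|}.
#'
#' @param window numeric vector, length >= 1.
#' @return scalar MAV.
#' @export
mav <- function(window) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  mean(abs(window))
}

#' Root mean square of a window
#'
#' Captures the power of the signal inside the window:
#' \eqn{RMS = \sqrt{n^{-1}\sum_{i=1}^{n} y_i^2}}.
#'
#' @param window numeric vector, length >= 1.
#' @return scalar RMS.
#' @export
rms <- function(window) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  sqrt(mean(window^2))
}

#' Linear trend fit of a window
#'
#' Least-squares coefficients \eqn{(a, b)} minimizing
#' \eqn{\sum_{i=1}^{n} [y_i - (a + b i)]^2}. The slope tracks the change in
#' force over the window (e.g. during the ramp into or out of a grasp); the
#' residual is the sum of squared errors of the fit.
#'
#' @param window numeric vector, length >= 2.
#' @return list of class \code{"fmg_fit"} with \code{a}, \code{b},
#'   \code{residual}.
#' @export
linear_fit <- function(window) {
  n <- length(window)
  if (n < 2) stop("linear fit needs at least 2 samples", call. = FALSE)
  X <- cbind(1, seq_len(n))
  fit <- stats::lm.fit(X, window)
  structure(list(a = unname(fit$coefficients[1]),
                 b = unname(fit$coefficients[2]),
                 residual = sum(fit$residuals^2)),
            class = "fmg_fit")
}

#' Parabolic trend fit of a window
#'
#' Least-squares coefficients \eqn{(a, b, c)} minimizing
#' \eqn{\sum_{i=1}^{n} [y_i - (a + b i + c i^2)]^2}; the quadratic term
#' admits curvature (non-linear force trends) within the window. By nesting,
#' its residual never exceeds the linear fit's on the same window.
#'
#' @param window numeric vector, length >= 3.
#' @return list of class \code{"fmg_fit"} with \code{a}, \code{b}, \code{c},
#'   \code{residual}.
#' @export
parabolic_fit <- function(window) {
  n <- length(window)
  if (n < 3) stop("parabolic fit needs at least 3 samples", call. = FALSE)
  i <- seq_len(n)
  X <- cbind(1, i, i^2)
  fit <- stats::lm.fit(X, window)
  structure(list(a = unname(fit$coefficients[1]),
                 b = unname(fit$coefficients[2]),
                 c = unname(fit$coefficients[3]),
                 residual = sum(fit$residuals^2)),
            class = "fmg_fit")
}

# Biased sample autocovariances of a demeaned window, lags 0..maxlag, as a
# matrix with one window per row.
autocov_rows <- function(W, maxlag) {
  n <- ncol(W)
  Wc <- W - rowMeans(W)
  R <- matrix(0, nrow(W), maxlag + 1L)
  for (l in 0:maxlag) {
    R[, l + 1L] <- rowSums(Wc[, seq_len(n - l), drop = FALSE] *
                             Wc[, seq.int(1L + l, n), drop = FALSE]) / n
  }
  R
}

# Levinson-Durbin recursion, vectorized across rows of an autocovariance
# matrix R (columns = lags 0..p). Returns AR coefficients in the prediction
# convention y_t = sum_i a_i y_{t-i} + e, the innovation variance, and
# degeneracy flags. A small diagonal jitter regularizes the near-singular
# systems that arise when the order approaches the window length.
levinson_batch <- function(R, order, jitter = 1e-10) {
  m <- nrow(R)
  r0 <- R[, 1] + jitter
  degenerate <- R[, 1] <= jitter
  A <- matrix(0, m, order)
  E <- r0
  ok <- !degenerate
  for (k in seq_len(order)) {
    acc <- if (k > 1) {
      rowSums(A[, 1:(k - 1), drop = FALSE] * R[, k:2, drop = FALSE])
    } else 0
    kk <- numeric(m)
    good <- ok & E > jitter * pmax(r0, 1)
    kk[good] <- (R[good, k + 1L] - if (k > 1) acc[good] else 0) / E[good]
    degenerate <- degenerate | (ok & !good)
    ok <- good
    if (k > 1) {
      A[, 1:(k - 1)] <- A[, 1:(k - 1), drop = FALSE] -
        kk * A[, (k - 1):1, drop = FALSE]
    }
    A[, k] <- kk
    E <- pmax(E * (1 - kk^2), 0)
  }
  A[degenerate, ] <- 0
  E[R[, 1] <= jitter] <- 0
  list(coefficients = A, innovation_variance = E, degenerate = degenerate)
}

#' Autoregressive fit of a window (Yule-Walker)
#'
#' Models the window as \eqn{y_t = \sum_{i=1}^{p} a_i y_{t-i} + \epsilon}
#' and estimates the coefficients from the Yule-Walker equations built on
#' the window's biased sample autocovariances (Levinson-Durbin solve with a
#' small diagonal jitter, since order \code{n-1} on \code{n} samples is
#' near-singular by construction). The default order is one below the window
#' length. Zero-variance or ill-conditioned windows return all-zero
#' coefficients with a degeneracy flag rather than failing.
#'
#' @param window numeric vector, length >= 2.
#' @param order AR order; default \code{length(window) - 1}.
#' @return list of class \code{"fmg_ar"} with \code{coefficients} (length
#'   \code{order}), \code{innovation_variance} and \code{degenerate}.
#' @export
ar_fit <- function(window, order = length(window) - 1L) {
  n <- length(window)
  if (n < 2) stop("AR fit needs at least 2 samples", call. = FALSE)
  order <- as.integer(order)
  if (order < 1L || order > n - 1L) stop("order must be in [1, n-1]", call. = FALSE)
  R <- autocov_rows(matrix(window, 1), order)
  res <- levinson_batch(R, order)
  structure(list(coefficients = as.numeric(res$coefficients[1, ]),
                 innovation_variance = res$innovation_variance[1],
                 degenerate = res$degenerate[1]),
            class = "fmg_ar")
}

feature_dim <- function(feature, size) {
  switch(feature,
         raw = 1L, mav = 1L, rms = 1L, lf = 2L, pf = 3L,
         ar = size - 1L,
         stop(sprintf("unknown feature '%s'", feature), call. = FALSE))
}

feature_component_names <- function(feature, size) {
  switch(feature,
         raw = "raw", mav = "mav", rms = "rms",
         lf = c("a", "b"), pf = c("a", "b", "c"),
         ar = sprintf("ar%d", seq_len(size - 1L)))
}

# One channel's feature values over all windows (rows of W chronological).
channel_feature_values <- function(W, feature) {
  n <- ncol(W)
  switch(feature,
         raw = W[, (n + 1L) %/% 2L, drop = FALSE],
         mav = matrix(rowMeans(abs(W)), ncol = 1),
         rms = matrix(sqrt(rowMeans(W^2)), ncol = 1),
         lf = {
           X <- cbind(1, seq_len(n))
           H <- solve(crossprod(X), t(X))      # 2 x n hat projector
           W %*% t(H)
         },
         pf = {
           i <- seq_len(n)
           X <- cbind(1, i, i^2)
           H <- solve(crossprod(X), t(X))
           W %*% t(H)
         },
         ar = {
           R <- autocov_rows(W, n - 1L)
           levinson_batch(R, n - 1L)$coefficients
         })
}

#' Per-session feature matrix
#'
#' Applies one feature extractor to every centered window of each of the 16
#' FMG channels independently and concatenates the per-channel values
#' column-wise, so each row describes one window center across the whole
#' band. Rows carry the grasp label of their center sample. The \code{"raw"}
#' baseline returns the center sample itself, so all feature matrices —
#' including raw — share identical row alignment and count
#' (\code{N - size + 1} rows at stride 1).
#'
#' Windows are computed within the session's contiguous recording and may
#' cross task boundaries; only the recording edges are trimmed. No filtering
#' is applied before or after extraction.
#'
#' @param session an [fmg_session()].
#' @param labels an [label_from_thumb()] result for the same session.
#' @param feature one of \code{"raw"}, \code{"mav"}, \code{"rms"},
#'   \code{"lf"}, \code{"pf"}, \code{"ar"}.
#' @param spec an [window_spec()].
#' @return An object of class \code{"fmg_features"}: list with
#'   \code{feature}, \code{values} (rows = window centers, columns =
#'   \code{16 * d} with per-channel dimension d), \code{centers},
#'   \code{labels} (binary vector aligned to rows) and \code{window}.
#' @export
extract_feature_matrix <- function(session, labels, feature,
                                   spec = window_spec()) {
  validate_session(session)
  feature <- match.arg(feature, c("raw", "mav", "rms", "lf", "pf", "ar"))
  if (!inherits(labels, "fmg_labels")) stop("labels must come from label_from_thumb()", call. = FALSE)
  N <- nrow(session$fmg)
  if (length(labels$labels) != N) stop("labels length must match session length", call. = FALSE)
  n <- spec$size
  if (N < n) stop("series shorter than window", call. = FALSE)
  d <- feature_dim(feature, n)
  comp <- feature_component_names(feature, n)
  blocks <- vector("list", 16L)
  centers <- NULL
  for (k in 1:16) {
    win <- extract_windows(as.numeric(session$fmg[, k]), spec)
    centers <- win$centers
    vals <- channel_feature_values(win$windows, feature)
    colnames(vals) <- sprintf("ch%02d_%s", k, comp)
    blocks[[k]] <- vals
  }
  values <- do.call(cbind, blocks)
  structure(list(feature = feature,
                 values = values,
                 centers = centers,
                 labels = labels$labels[centers],
                 window = spec,
                 participant_id = session$participant_id,
                 round_index = session$round_index),
            class = "fmg_features")
}

#' @export
print.fmg_features <- function(x, ...) {
  cat(sprintf("FMG feature matrix '%s': %d windows x %d columns (window %d, stride %d)\n",
              x$feature, nrow(x$values), ncol(x$values),
              x$window$size, x$window$stride))
  invisible(x)
}
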