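#' Binary grasp labels from the thumb sensor
#'
#' Ground truth for the two-class grasp detection problem comes from a force
#' sensor taped to the thumb: every grasp type in the protocol involves
#' active thumb opposition, so thumb force marks object-in-hand samples.
#' A sample is labeled grasp when its thumb reading strictly exceeds the
#' threshold — no smoothing, no debouncing, no minimum duration — so the
#' downstream false-positive analysis sees the raw labeling.
#'
#' @param thumb vector of thumb-sensor ADC counts.
#' @param threshold ADC counts; must be \code{>= 0}. The strict comparison
#'   means a zero threshold never fires on a silent (all-zero) sensor.
#' @return An object of class \code{"fmg_labels"}: list with \code{labels}
#'   (integer 0/1 vector, 1 = grasp) and \code{threshold}.
#' @seealso [suggest_threshold()]
#' @export
#' @examples
#' label_from_thumb(c(0, 0, 400, 500, 0), threshold = 100)$labels
label_from_thumb <- function(thumb, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  structure(list(labels = as.integer(thumb > threshold),
                 threshold = threshold),
            class = "fmg_labels")
}

#' Suggest a labeling threshold from the thumb signal
#'
#' The experimenter-tuned threshold of a live recording is not available for
#' simulated or archived data, so a simple data-driven default is provided:
#' the midpoint between the 10th and 90th percentiles of the thumb values,
#' which lands between the silent and the pressed plateaus of a bimodal
#' thumb trace. Callers may always override it.
#'
#' @param thumb non-empty vector of thumb-sensor ADC counts.
#' @return threshold in ADC counts. For a constant trace the maximum value
#'   is returned with a warning (all samples then label 0 under the strict
#'   comparison).
#' @export
suggest_threshold <- function(thumb) {
  if (length(thumb) == 0) stop("thumb vector is empty", call. = FALSE)
  q <- stats::quantile(thumb, c(0.1, 0.9), names = FALSE, type = 7)
  if (q[1] == q[2] && min(thumb) == max(thumb)) {
    warning("constant thumb signal; returning its maximum (all labels 0)")
    return(max(thumb))
  }
  (q[1] + q[2]) / 2
}
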