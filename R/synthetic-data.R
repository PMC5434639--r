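#' Configuration for the synthetic FMG cohort generator
#'
#' Builds a validated configuration describing a simulated data-collection
#' study: a cohort of participants, each recorded over several identical
#' rounds in which six objects are grasped and moved between shelf targets,
#' interleaved with matching movement-without-grasp actions.
#'
#' The generated signal model per FMG channel \eqn{k} is
#' \deqn{x_k(t) = baseline_k + drift_k(t) + movement\_gain_k\, m(t) +
#'   grasp\_gain_k\, g(t) + \epsilon_k(t)}
#' where \eqn{g(t)} is a trapezoidal grasp-force profile (linear ramp up,
#' hold, linear ramp down) inside each grasp interval, \eqn{m(t)} is a smooth
#' motion bump spanning every action (grasp-and-move and movement-only
#' actions share the same motion profile, mirroring a protocol in which
#' movement-only actions retrace the grasp trajectories with an empty hand),
#' \eqn{drift_k} is a Gaussian random walk emulating slow slackening or
#' tightening of the sensor band, and \eqn{\epsilon_k} is white Gaussian
#' noise. All channels are quantized to integer ADC counts in
#' \code{[0, adc_max]}. A thumb-mounted sensor responds only during grasp
#' intervals and provides the ground-truth labeling signal.
#'
#' @param n_participants number of participants in the cohort.
#' @param n_rounds recording rounds per participant; per-participant channel
#'   gains are drawn once and shared across rounds, so rounds differ only in
#'   noise, drift and motion-amplitude realizations.
#' @param n_objects number of objects (grasp types) per round.
#' @param actions_per_object grasp-and-move actions per object; an equal
#'   number of movement-only actions precedes them.
#' @param sampling_rate sampling rate in Hz.
#' @param adc_max full-scale ADC count (10-bit converter by default).
#' @param grasp_gain length-16 template of peak grasp responses per channel,
#'   in ADC counts; per-participant gains are drawn log-normally around this
#'   template (see \code{gain_spread}).
#' @param movement_gain length-16 template of peak movement-artifact
#'   responses per channel, ADC counts.
#' @param ramp_up_s,hold_s,ramp_down_s durations (seconds) of the three
#'   stages of the grasp force trapezoid.
#' @param transit_s total duration (seconds) of inter-position motion within
#'   an action (split evenly before and after the grasp interval).
#' @param gap_s duration (seconds) of the neutral pause after each action.
#' @param noise_sd additive white noise standard deviation, ADC counts.
#' @param drift_step_sd per-sample standard deviation of the random-walk
#'   baseline drift, ADC counts.
#' @param baseline resting level per channel, ADC counts (scalar recycled to
#'   16 channels).
#' @param thumb_peak peak thumb-sensor response during a grasp, ADC counts.
#' @param gain_spread log-scale standard deviation of the per-participant
#'   log-normal gain multipliers (0 makes gains identical to the templates).
#' @param seed integer seed; identical configuration + seed reproduces the
#'   cohort bit for bit. Sub-streams are derived per (participant, round) so
#'   individual sessions are reproducible in isolation.
#'
#' @return An object of class \code{"fmg_config"} (a validated list).
#' @seealso [generate_protocol()], [synthesize_signal()], [generate_cohort()]
#' @export
#' @examples
#' cfg <- synthetic_config(n_participants = 1, n_objects = 1, seed = 42)
#' ev <- generate_protocol(cfg)
#' table(ev$kind)
synthetic_config <- function(n_participants = 10,
                             n_rounds = 3,
                             n_objects = 6,
                             actions_per_object = 16,
                             sampling_rate = 10,
                             adc_max = 1023,
                             grasp_gain = default_grasp_gain(),
                             movement_gain = rep(2, 16),
                             ramp_up_s = 0.5,
                             hold_s = 2.0,
                             ramp_down_s = 0.5,
                             transit_s = 2.0,
                             gap_s = 1.0,
                             noise_sd = 8,
                             drift_step_sd = 0.5,
                             baseline = 300,
                             thumb_peak = 500,
                             gain_spread = 0.25,
                             seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_rounds = as.integer(n_rounds),
    n_objects = as.integer(n_objects),
    actions_per_object = as.integer(actions_per_object),
    sampling_rate = sampling_rate,
    adc_max = as.integer(adc_max),
    grasp_gain = rep_len(grasp_gain, 16L),
    movement_gain = rep_len(movement_gain, 16L),
    ramp_up_s = ramp_up_s, hold_s = hold_s, ramp_down_s = ramp_down_s,
    transit_s = transit_s, gap_s = gap_s,
    noise_sd = noise_sd, drift_step_sd = drift_step_sd,
    baseline = rep_len(baseline, 16L),
    thumb_peak = thumb_peak,
    gain_spread = gain_spread,
    seed = as.integer(seed)
  )
  class(cfg) <- "fmg_config"
  validate_config(cfg)
  cfg
}

#' Default per-channel grasp-gain template
#'
#' Peak grasp response per channel, ADC counts. The profile decays around the
#' band: sensors over the flexor tendon bundle respond strongly, sensors on
#' the dorsal side barely at all, which is the typical spatial pattern of a
#' wrist-worn force-sensing band.
#'
#' @return numeric vector of length 16.
#' @export
default_grasp_gain <- function() {
  c(20, 18, 15, 12, 10, 7, 6, 4, 3, 2, 2, 2, 1, 1, 1, 1)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "fmg_config"))
  if (cfg$n_participants < 0 || cfg$n_rounds < 0 || cfg$n_objects < 0 ||
      cfg$actions_per_object < 0) {
    stop("configuration error: counts must be non-negative", call. = FALSE)
  }
  durs <- c(cfg$ramp_up_s, cfg$hold_s, cfg$ramp_down_s, cfg$transit_s, cfg$gap_s)
  if (any(durs <= 0)) stop("configuration error: all durations must be > 0", call. = FALSE)
  if (cfg$sampling_rate <= 0) stop("configuration error: sampling_rate must be > 0", call. = FALSE)
  if (any(cfg$grasp_gain < 0) || any(cfg$movement_gain < 0)) {
    stop("configuration error: gains must be >= 0", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$drift_step_sd < 0) {
    stop("configuration error: noise_sd and drift_step_sd must be >= 0", call. = FALSE)
  }
  if (any(cfg$baseline < 0) || any(cfg$baseline > cfg$adc_max)) {
    stop("configuration error: baseline must lie in [0, adc_max]", call. = FALSE)
  }
  invisible(cfg)
}

# Derived sub-stream seeds: deterministic, distinct per (participant, round),
# and < 2^31. round = 0 is reserved for the participant-level gain draw.
substream_seed <- function(seed, participant, round = 0L) {
  (abs(as.integer(seed)) %% 100000L) * 20011L +
    as.integer(participant) * 131L + as.integer(round)
}

# samples for a duration in seconds (exact at the simulator's default rates)
n_samples <- function(seconds, fs) as.integer(round(seconds * fs))

#' Generate the task schedule for one recording round
#'
#' Lays out the round deterministically: for each object, a block of
#' movement-only actions followed by a block of grasp-and-move actions, every
#' action followed by a neutral pause. The schedule depends only on the
#' configuration's counts and durations — never on the seed — so two
#' configurations differing only by seed share identical schedules.
#'
#' @param config an [synthetic_config()] object.
#' @param participant,round identifiers carried through for bookkeeping; the
#'   schedule itself is identical across participants and rounds.
#' @return A data frame of task events with columns \code{kind}
#'   (\code{"movement_only"}, \code{"grasp_move"}, \code{"neutral"}),
#'   \code{object} (1-based index, \code{NA} for neutral),
#'   \code{start}/\code{end} (1-based inclusive sample indices) and
#'   \code{grasp_start}/\code{grasp_end} (the grasp-active interval, strictly
#'   inside grasp-and-move events, \code{NA} otherwise).
#' @export
generate_protocol <- function(config, participant = 1L, round = 1L) {
  validate_config(config)
  fs <- config$sampling_rate
  n_up <- n_samples(config$ramp_up_s, fs)
  n_hold <- n_samples(config$hold_s, fs)
  n_down <- n_samples(config$ramp_down_s, fs)
  n_transit <- n_samples(config$transit_s, fs)
  n_gap <- n_samples(config$gap_s, fs)
  n_pre <- n_transit %/% 2L
  n_post <- n_transit - n_pre
  n_grasp <- n_up + n_hold + n_down
  n_action <- n_pre + n_grasp + n_post   # same span for both action kinds

  k <- config$actions_per_object
  rows_per_obj <- 4L * k                 # (action + gap) x (movement + grasp)
  n_rows <- config$n_objects * rows_per_obj
  kind <- character(n_rows); object <- integer(n_rows)
  start <- integer(n_rows); end <- integer(n_rows)
  gstart <- rep(NA_integer_, n_rows); gend <- rep(NA_integer_, n_rows)

  cursor <- 1L; r <- 0L
  add <- function(kd, obj, len, gs = NA_integer_, ge = NA_integer_) {
    r <<- r + 1L
    kind[r] <<- kd; object[r] <<- obj
    start[r] <<- cursor; end[r] <<- cursor + len - 1L
    gstart[r] <<- gs; gend[r] <<- ge
    cursor <<- cursor + len
  }
  for (obj in seq_len(config$n_objects)) {
    for (i in seq_len(k)) {
      add("movement_only", obj, n_action)
      add("neutral", NA_integer_, n_gap)
    }
    for (i in seq_len(k)) {
      gs <- cursor + n_pre
      add("grasp_move", obj, n_action, gs, gs + n_grasp - 1L)
      add("neutral", NA_integer_, n_gap)
    }
  }
  ev <- data.frame(kind = kind, object = object, start = start, end = end,
                   grasp_start = gstart, grasp_end = gend,
                   stringsAsFactors = FALSE)[seq_len(r), , drop = FALSE]
  attr(ev, "participant") <- as.integer(participant)
  attr(ev, "round") <- as.integer(round)
  ev
}

# Trapezoidal grasp force profile over one grasp interval. Strictly positive
# on every sample of the interval so that thumb activity and the designed
# grasp interval coincide exactly in the noise-free limit.
grasp_profile <- function(n_up, n_hold, n_down) {
  c(seq_len(n_up) / n_up, rep(1, n_hold), (n_down:1) / (n_down + 1))
}

# Raised-cosine motion bump over an action span.
motion_bump <- function(len) {
  0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
}

#' Synthesize one session from a task schedule
#'
#' Realizes the signal model (see [synthetic_config()]) over the events of
#' one round. Per-participant channel gains are drawn from a sub-stream that
#' depends only on (seed, participant), so every round of a participant uses
#' the same gains; noise, drift and per-action motion amplitudes come from a
#' (seed, participant, round) sub-stream.
#'
#' @param events schedule from [generate_protocol()].
#' @param config an [synthetic_config()] object.
#' @param participant,round identifiers (also select the random sub-streams).
#' @return An [fmg_session()] object with the events attached; the drawn
#'   per-participant \code{grasp_gain} and \code{movement_gain} vectors are
#'   stored as attributes of the session for inspection.
#' @export
synthesize_signal <- function(events, config, participant = 1L, round = 1L) {
  validate_config(config)
  if (nrow(events) > 0) {
    events <- events[order(events$start), , drop = FALSE]
    if (any(events$start[-1] <= events$end[-nrow(events)])) {
      stop("events must be ordered and non-overlapping", call. = FALSE)
    }
  }
  N <- if (nrow(events)) max(events$end) else 0L

  # participant-level gains (shared across rounds)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(substream_seed(config$seed, participant, 0L))
  mult_g <- exp(stats::rnorm(16, 0, config$gain_spread))
  mult_m <- exp(stats::rnorm(16, 0, config$gain_spread))
  grasp_gain <- config$grasp_gain * mult_g
  movement_gain <- config$movement_gain * mult_m

  # round-level realizations
  set.seed(substream_seed(config$seed, participant, round))
  is_action <- events$kind %in% c("grasp_move", "movement_only")
  amps <- stats::runif(sum(is_action), 0.7, 1.3)

  g <- numeric(N); m <- numeric(N)
  ai <- 0L
  for (i in seq_len(nrow(events))) {
    if (!is_action[i]) next
    ai <- ai + 1L
    span <- events$start[i]:events$end[i]
    m[span] <- amps[ai] * motion_bump(length(span))
    if (events$kind[i] == "grasp_move") {
      gs <- events$grasp_start[i]; ge <- events$grasp_end[i]
      fs <- config$sampling_rate
      g[gs:ge] <- grasp_profile(n_samples(config$ramp_up_s, fs),
                                n_samples(config$hold_s, fs),
                                n_samples(config$ramp_down_s, fs))
    }
  }

  if (N > 0) {
    drift <- apply(matrix(stats::rnorm(N * 16, 0, config$drift_step_sd), N, 16), 2, cumsum)
    drift <- matrix(drift, N, 16)
    noise <- matrix(stats::rnorm(N * 16, 0, config$noise_sd), N, 16)
    fmg <- rep(config$baseline, each = N) + drift +
      outer(m, movement_gain) + outer(g, grasp_gain) + noise
    fmg <- matrix(pmin(pmax(round(fmg), 0), config$adc_max), N, 16)
    thumb <- pmin(pmax(round(config$thumb_peak * g +
                               stats::rnorm(N, 0, config$noise_sd)), 0), config$adc_max)
  } else {
    fmg <- matrix(integer(0), 0, 16)
    thumb <- integer(0)
  }

  s <- fmg_session(participant_id = participant, round_index = round,
                   sampling_rate = config$sampling_rate,
                   fmg = fmg, thumb = thumb, events = events)
  attr(s, "grasp_gain") <- grasp_gain
  attr(s, "movement_gain") <- movement_gain
  s
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a full synthetic cohort
#'
#' One session per (participant, round). Channel gains are drawn once per
#' participant and reused across that participant's rounds; rounds differ
#' only in their noise, drift and motion-amplitude realizations. Schedules
#' are identical across the whole cohort.
#'
#' @param config an [synthetic_config()] object.
#' @return A list of [fmg_session()] objects of class \code{"fmg_cohort"},
#'   named \code{p<participant>_r<round>}.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  sessions <- vector("list", config$n_participants * config$n_rounds)
  nms <- character(length(sessions))
  i <- 0L
  for (p in seq_len(config$n_participants)) {
    for (r in seq_len(config$n_rounds)) {
      i <- i + 1L
      ev <- generate_protocol(config, p, r)
      sessions[[i]] <- synthesize_signal(ev, config, p, r)
      nms[i] <- sprintf("p%02d_r%d", p, r)
    }
  }
  names(sessions) <- nms
  structure(sessions, class = "fmg_cohort", config = config)
}

#' @export
print.fmg_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("FMG synthetic cohort: %d sessions (%d participants x %d rounds)\n",
              length(x), cfg$n_participants, cfg$n_rounds))
  if (length(x)) {
    cat(sprintf("  %d samples/session at %g Hz, %d objects, %d+%d actions/object\n",
                nrow(x[[1]]$fmg), cfg$sampling_rate, cfg$n_objects,
                cfg$actions_per_object, cfg$actions_per_object))
  }
  invisible(x)
}
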