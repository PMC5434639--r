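#' FMG session container
#'
#' One participant-round recording from a 16-channel force-sensing band plus
#' a thumb-mounted labeling sensor, sampled at a common rate. Values are
#' integer ADC counts from a 10-bit converter.
#'
#' @param participant_id participant identifier.
#' @param round_index recording round (1-based).
#' @param sampling_rate sampling rate in Hz.
#' @param fmg N x 16 integer matrix of ADC counts, channels in columns.
#' @param thumb length-N integer vector of thumb-sensor ADC counts.
#' @param events optional task-event data frame (see [generate_protocol()]).
#' @param adc_max full-scale count used for validation.
#' @return An object of class \code{"fmg_session"}.
#' @export
fmg_session <- function(participant_id, round_index, sampling_rate,
                        fmg, thumb, events = NULL, adc_max = 1023) {
  fmg <- as.matrix(fmg)
  storage.mode(fmg) <- "integer"
  thumb <- as.integer(thumb)
  s <- structure(list(participant_id = participant_id,
                      round_index = as.integer(round_index),
                      sampling_rate = sampling_rate,
                      fmg = fmg, thumb = thumb, events = events),
                 class = "fmg_session")
  validate_session(s, adc_max = adc_max)
  s
}

#' Validate an FMG session
#'
#' Checks the session invariants: exactly 16 FMG channels, thumb vector of
#' matching length, all values integral and within \code{[0, adc_max]}, and
#' a round index present.
#'
#' @param session an \code{fmg_session}.
#' @param adc_max full-scale ADC count.
#' @return the session, invisibly; errors describe the violated invariant.
#' @export
validate_session <- function(session, adc_max = 1023) {
  if (!inherits(session, "fmg_session")) stop("not an fmg_session", call. = FALSE)
  if (ncol(session$fmg) != 16L) {
    stop(sprintf("fmg matrix must have 16 columns, found %d", ncol(session$fmg)),
         call. = FALSE)
  }
  if (nrow(session$fmg) != length(session$thumb)) {
    stop("fmg row count must equal thumb length", call. = FALSE)
  }
  vals <- c(session$fmg, session$thumb)
  if (anyNA(vals)) stop("session contains missing values", call. = FALSE)
  if (length(vals) && (min(vals) < 0L || max(vals) > adc_max)) {
    stop(sprintf("session values must lie in [0, %d]", adc_max), call. = FALSE)
  }
  if (is.null(session$round_index) || is.na(session$round_index)) {
    stop("round_index is required", call. = FALSE)
  }
  invisible(session)
}

#' @export
print.fmg_session <- function(x, ...) {
  cat(sprintf("FMG session: participant %s, round %d, %d samples @ %g Hz\n",
              as.character(x$participant_id), x$round_index,
              nrow(x$fmg), x$sampling_rate))
  invisible(x)
}

session_channel_names <- sprintf("ch%02d", 1:16)

#' Write an FMG session to CSV
#'
#' Schema: \code{sample,participant,round,ch01..ch16,thumb,event_kind,object}
#' with a header row, comma separators and LF line endings. The event
#' annotation columns are derived per sample from the session's events
#' (empty where no event covers the sample); they are annotations only —
#' labels always come from the thumb channel.
#'
#' @param session a valid [fmg_session()].
#' @param path output file path.
#' @param adc_max full-scale count used for validation before writing.
#' @return \code{path}, invisibly.
#' @export
write_session <- function(session, path, adc_max = 1023) {
  validate_session(session, adc_max = adc_max)
  N <- nrow(session$fmg)
  kind <- rep("", N); object <- rep(NA_integer_, N)
  ev <- session$events
  if (!is.null(ev) && nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      span <- ev$start[i]:ev$end[i]
      kind[span] <- ev$kind[i]
      object[span] <- ev$object[i]
    }
  }
  df <- data.frame(sample = seq_len(N),
                   participant = rep(as.character(session$participant_id), N),
                   round = rep(session$round_index, N),
                   stringsAsFactors = FALSE)
  fmg <- session$fmg
  colnames(fmg) <- session_channel_names
  if (N == 0) {
    df <- cbind(df, as.data.frame(fmg),
                thumb = integer(0), event_kind = character(0), object = integer(0))
  } else {
    df <- cbind(df, as.data.frame(fmg),
                thumb = session$thumb, event_kind = kind, object = object)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n",
                   na = "")
  invisible(path)
}

#' Read an FMG session from CSV
#'
#' Reads and validates a file written in the [write_session()] schema.
#' Missing required columns, non-integer cells and out-of-range values are
#' reported with the offending column and data row.
#'
#' @param path CSV file path.
#' @param sampling_rate sampling rate to attach (Hz); the schema carries no
#'   timestamps, sample index plus rate suffice.
#' @param adc_max full-scale ADC count for range validation.
#' @return a validated [fmg_session()]; task events are reconstructed from
#'   the annotation columns when present.
#' @export
read_session <- function(path, sampling_rate = 10, adc_max = 1023) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("participant" %in% names(df)) df$participant <- as.character(df$participant)
  if ("event_kind" %in% names(df)) {
    df$event_kind <- as.character(df$event_kind)
    df$event_kind[is.na(df$event_kind)] <- ""
  }
  if ("object" %in% names(df)) df$object <- as.integer(df$object)
  required <- c("sample", "participant", "round", session_channel_names, "thumb")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(fmg_session(participant_id = NA_character_, round_index = 1L,
                       sampling_rate = sampling_rate,
                       fmg = matrix(integer(0), 0, 16), thumb = integer(0),
                       adc_max = adc_max))
  }
  num_cols <- c(session_channel_names, "thumb")
  for (cn in num_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))
      stop(sprintf("non-numeric value in column %s at data row %d",
                   cn, if (length(bad)) bad[1] else 1L), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column %s at data row %d",
                   cn, which(is.na(v))[1]), call. = FALSE)
    }
    if (any(v != floor(v))) {
      stop(sprintf("non-integer value in column %s at data row %d",
                   cn, which(v != floor(v))[1]), call. = FALSE)
    }
    if (any(v < 0 | v > adc_max)) {
      bad <- which(v < 0 | v > adc_max)[1]
      stop(sprintf("out-of-range value in column %s at data row %d (must lie in [0, %d])",
                   cn, bad, adc_max), call. = FALSE)
    }
  }
  fmg <- as.matrix(df[, session_channel_names, drop = FALSE])
  dimnames(fmg) <- NULL
  events <- NULL
  if (all(c("event_kind", "object") %in% names(df)) && nrow(df) > 0) {
    events <- events_from_annotations(df$event_kind, df$object)
  }
  participant <- if (nrow(df)) df$participant[1] else NA_character_
  round_index <- if (nrow(df)) df$round[1] else 1L
  fmg_session(participant_id = participant, round_index = round_index,
              sampling_rate = sampling_rate, fmg = fmg,
              thumb = df$thumb, events = events, adc_max = adc_max)
}

# Reconstruct the event table from per-sample annotations: one event per
# maximal run of a constant (kind, object) pair; unannotated samples yield
# no event.
events_from_annotations <- function(kind, object) {
  N <- length(kind)
  if (N == 0) return(NULL)
  obj_key <- ifelse(is.na(object), "", as.character(object))
  key <- paste(kind, obj_key, sep = "\r")
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- kind[starts] != ""
  if (!any(keep)) return(NULL)
  data.frame(kind = kind[starts[keep]],
             object = object[starts[keep]],
             start = starts[keep], end = ends[keep],
             grasp_start = NA_integer_, grasp_end = NA_integer_,
             stringsAsFactors = FALSE)
}
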