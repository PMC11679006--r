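#' Build and validate an event table
#'
#' Events are annotated intervals on the trial clock: `FOG` episodes, `TURN`
#' and `STAND` segments. Times are seconds from trial start.
#'
#' @param kind character vector, each element one of `"FOG"`, `"TURN"`,
#'   `"STAND"`.
#' @param start,end numeric vectors of interval bounds in seconds;
#'   `start < end` elementwise.
#' @return A `data.frame` with columns `kind`, `start`, `end`, sorted by
#'   `start` within kind, of class `fog_events`.
#' @examples
#' fog_events(kind = c("FOG", "TURN"), start = c(10, 2), end = c(12, 4))
#' @export
fog_events <- function(kind = character(), start = numeric(), end = numeric()) {
  ev <- data.frame(kind = as.character(kind), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  validate_events(ev)
}

#' @rdname fog_events
#' @param events a data.frame with columns `kind`, `start`, `end`.
#' @export
validate_events <- function(events) {
  req <- c("kind", "start", "end")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    stop("event table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad_kind <- setdiff(unique(events$kind), EVENT_KINDS)
  if (length(bad_kind)) {
    stop("unknown event kind(s): ", paste(bad_kind, collapse = ", "))
  }
  if (any(!is.finite(events$start)) || any(!is.finite(events$end))) {
    stop("event start/end must be finite numbers")
  }
  if (any(events$start >= events$end)) {
    i <- which(events$start >= events$end)[1L]
    stop(sprintf("start < end violated for %s interval [%g, %g]",
                 events$kind[i], events$start[i], events$end[i]))
  }
  events <- events[order(events$start, events$end), , drop = FALSE]
  ## same-kind intervals must not overlap
  for (k in unique(events$kind)) {
    e <- events[events$kind == k, , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      stop("overlapping ", k, " intervals")
    }
  }
  rownames(events) <- NULL
  class(events) <- c("fog_events", "data.frame")
  events
}

#' Derive per-sample gait-state labels from annotated events
#'
#' Samples inside a FOG interval are labelled `FOG` (interval start inclusive,
#' end inclusive of the last on-grid sample). Samples within the `pre_fog`
#' seconds immediately preceding a FOG onset that are not themselves inside any
#' FOG interval are labelled `PREFOG`; FOG takes precedence when episodes are
#' closer together than `pre_fog`. Everything else is `NONFOG`. Turn and stand
#' events do not affect the labels.
#'
#' @param events event table as returned by [fog_events()].
#' @param times numeric vector of sample times (seconds).
#' @param pre_fog length of the pre-FOG precursor window in seconds
#'   (default 2).
#' @return character vector of labels, one per element of `times`.
#' @examples
#' t <- seq(0, 20, by = 0.01)
#' lab <- derive_sample_labels(fog_events("FOG", 10, 12), t)
#' table(lab)
#' @export
derive_sample_labels <- function(events, times, pre_fog = 2.0) {
  events <- validate_events(events)
  labels <- rep("NONFOG", length(times))
  fog <- events[events$kind == "FOG", , drop = FALSE]
  if (nrow(fog) == 0L) return(labels)
  eps <- 1e-9
  for (i in seq_len(nrow(fog))) {
    pre <- times >= fog$start[i] - pre_fog - eps & times < fog$start[i] - eps
    labels[pre] <- "PREFOG"
  }
  for (i in seq_len(nrow(fog))) {
    inside <- times >= fog$start[i] - eps & times <= fog$end[i] + eps
    labels[inside] <- "FOG"
  }
  labels
}

#' Transfer video-rate labels to the pressure-data clock
#'
#' Annotation tracks scored on 30 Hz video are moved to the 100 Hz pressure
#' samples by nearest-in-time assignment: each target sample takes the label of
#' the closest video frame, ties broken toward the earlier frame. Labels are
#' categorical, so nearest-neighbour assignment is the categorical counterpart
#' of interpolating to the closest data point.
#'
#' @param frame_times numeric vector of video frame times (seconds), sorted.
#' @param frame_labels vector of labels, one per frame.
#' @param target_times numeric vector of pressure sample times, sorted.
#' @return vector of labels, one per target time.
#' @export
resample_labels <- function(frame_times, frame_labels, target_times) {
  if (length(frame_times) == 0L) stop("empty label track")
  if (length(frame_times) != length(frame_labels)) {
    stop("frame_times and frame_labels lengths differ")
  }
  ## index of nearest frame; findInterval gives the frame at or before t
  lo <- findInterval(target_times, frame_times)
  lo[lo < 1L] <- 1L
  hi <- pmin(lo + 1L, length(frame_times))
  d_lo <- abs(target_times - frame_times[lo])
  d_hi <- abs(frame_times[hi] - target_times)
  ## strict < : on a tie the earlier frame (lo) wins
  pick <- ifelse(d_hi < d_lo, hi, lo)
  frame_labels[pick]
}
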