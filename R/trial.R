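#' Construct a single-trial record
#'
#' A trial is one walk of the test path: two per-foot 100 Hz signal tracks,
#' the event annotations, and per-sample gait-state labels derived from the
#' FOG events.
#'
#' Each foot track is a list with numeric elements `force` (total ground
#' reaction force, arbitrary linear units), `cop_x` (mediolateral COP, mm,
#' positive lateral) and `cop_y` (anteroposterior COP, mm, positive anterior),
#' all of the same length as `times`. Grid-form tracks instead carry a
#' `pressure` matrix (frames x sensels) plus `sensel_x`/`sensel_y` coordinate
#' vectors (mm); see [emit_grid()] and [compute_cop()].
#'
#' @param participant_id,trial_id identifiers.
#' @param times sample times in seconds, uniform at `fs`.
#' @param left,right per-foot tracks (see Details).
#' @param events event table ([fog_events()]).
#' @param fs sampling rate, Hz.
#' @param pre_fog pre-FOG precursor length (s) used to derive labels.
#' @return An object of class `fog_trial`.
#' @export
fog_trial <- function(participant_id, trial_id, times, left, right,
                      events = fog_events(), fs = 100, pre_fog = 2.0) {
  n <- length(times)
  if (n < 2L) stop("a trial needs at least 2 samples")
  step <- diff(times)
  if (any(abs(step - 1 / fs) > 1e-6)) {
    stop("times: non-uniform time step (expected 1/", fs, " s)")
  }
  for (side in list(left = left, right = right)) {
    len <- if (!is.null(side$force)) length(side$force) else nrow(side$pressure)
    if (!identical(as.integer(len), as.integer(n))) {
      stop("foot track length does not match times")
    }
  }
  events <- validate_events(events)
  trial <- structure(list(
    participant_id = participant_id,
    trial_id = trial_id,
    fs = fs,
    times = as.numeric(times),
    left = left,
    right = right,
    events = events,
    sample_labels = derive_sample_labels(events, times, pre_fog = pre_fog)
  ), class = "fog_trial")
  trial
}

#' @export
print.fog_trial <- function(x, ...) {
  dur <- length(x$times) / x$fs
  nfog <- sum(x$events$kind == "FOG")
  cat(sprintf("<fog_trial> %s/%s: %.1f s @ %g Hz, %d FOG episode(s), labels: %s\n",
              x$participant_id, x$trial_id, dur, x$fs, nfog,
              paste(sprintf("%s=%d", names(table(x$sample_labels)),
                            as.integer(table(x$sample_labels))), collapse = " ")))
  invisible(x)
}

#' Trial duration in seconds
#' @param trial a `fog_trial`.
#' @export
trial_duration <- function(trial) length(trial$times) / trial$fs

#' Construct a participant record
#'
#' @param id participant identifier.
#' @param trials list of [fog_trial()] objects.
#' @param age years; `years_since_diagnosis` years since PD diagnosis.
#' @param years_since_diagnosis,nfogq,updrs3 clinical metadata (optional;
#'   NFOG-Q 0-28, UPDRS-III 0-56).
#' @return An object of class `fog_participant`; `froze` is derived: `TRUE`
#'   iff any trial contains a FOG interval.
#' @export
fog_participant <- function(id, trials, age = NA_real_,
                            years_since_diagnosis = NA_real_,
                            nfogq = NA_real_, updrs3 = NA_real_) {
  froze <- any(vapply(trials, function(tr) any(tr$events$kind == "FOG"), logical(1)))
  structure(list(id = id, age = age,
                 years_since_diagnosis = years_since_diagnosis,
                 nfogq = nfogq, updrs3 = updrs3,
                 froze = froze, trials = trials),
            class = "fog_participant")
}

#' Construct a dataset (cohort of participants)
#'
#' @param name dataset label.
#' @param participants list of [fog_participant()] objects with unique ids.
#' @return An object of class `fog_dataset`.
#' @export
fog_dataset <- function(name, participants) {
  ids <- vapply(participants, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate participant ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(name = name, participants = participants), class = "fog_dataset")
}

#' @export
print.fog_dataset <- function(x, ...) {
  froze <- vapply(x$participants, `[[`, logical(1), "froze")
  cat(sprintf("<fog_dataset> %s: %d participants (%d freezers)\n",
              x$name, length(x$participants), sum(froze)))
  invisible(x)
}

#' Ids of participants in a dataset
#' @param ds a `fog_dataset`.
#' @export
participant_ids <- function(ds) vapply(ds$participants, `[[`, character(1), "id")

#' Remove participants from a dataset
#'
#' Builds dataset modifications of the kind used in outlier analyses: drop
#' named participants (for instance, one participant who froze far more than
#' the rest), drop all non-freezers, or both. The input dataset is untouched.
#'
#' @param ds a `fog_dataset`.
#' @param exclude_ids character vector of participant ids to drop; must all be
#'   present in `ds`.
#' @param exclude_nonfreezers if `TRUE`, also drop every participant with
#'   `froze = FALSE`.
#' @param name optional name for the filtered dataset.
#' @return A new `fog_dataset`.
#' @export
filter_dataset <- function(ds, exclude_ids = character(),
                           exclude_nonfreezers = FALSE, name = NULL) {
  ids <- participant_ids(ds)
  unknown <- setdiff(exclude_ids, ids)
  if (length(unknown)) stop("unknown participant id(s): ",
                            paste(unknown, collapse = ", "))
  keep <- !(ids %in% exclude_ids)
  if (exclude_nonfreezers) {
    froze <- vapply(ds$participants, `[[`, logical(1), "froze")
    keep <- keep & froze
  }
  fog_dataset(name %||% ds$name, ds$participants[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-participant testing summary with mean/SD row
#'
#' One row per participant: number of trials, total trial duration, number of
#' FOG episodes and total FOG duration; a final `Mean (SD)` row aggregates
#' each column. See [summarize_cohort_rows()] for the aggregation rules.
#'
#' @param ds a `fog_dataset`.
#' @return A `data.frame`; the last row holds the column means, with the
#'   sample standard deviations in attribute `"sd"` alongside per-column `n`.
#' @export
cohort_summary <- function(ds) {
  if (length(ds$participants) == 0L) stop("empty dataset")
  rows <- do.call(rbind, lapply(ds$participants, function(p) {
    durs <- vapply(p$trials, trial_duration, numeric(1))
    fog <- lapply(p$trials, function(tr) tr$events[tr$events$kind == "FOG", , drop = FALSE])
    data.frame(
      participant = p$id,
      n_trials = length(p$trials),
      total_duration = sum(durs),
      n_fog = sum(vapply(fog, nrow, integer(1))),
      total_fog_duration = sum(vapply(fog, function(e) sum(e$end - e$start), numeric(1))),
      stringsAsFactors = FALSE
    )
  }))
  summarize_cohort_rows(rows)
}

#' Append a mean/SD summary row to a per-participant table
#'
#' Aggregates every numeric column of a per-participant table: mean and sample
#' standard deviation (denominator n-1), computed over the non-missing entries
#' of each column. Columns missing for some participants (e.g. MTD target-zone
#' duration for non-freezers, or an unrecorded clinical score) contribute only
#' their observed values, with the per-column `n` recorded. With a single
#' observed value the SD is undefined and reported as `NA`.
#'
#' @param rows `data.frame`, one row per participant; non-numeric columns are
#'   carried through with `""` in the summary row.
#' @return `rows` plus a final `Mean (SD)` row; attributes `"mean"`, `"sd"`
#'   and `"n"` give the per-column aggregates as named numeric vectors.
#' @export
summarize_cohort_rows <- function(rows) {
  if (nrow(rows) == 0L) stop("empty cohort table")
  num <- vapply(rows, is.numeric, logical(1))
  mu <- vapply(rows[num], function(x) mean(x[!is.na(x)]), numeric(1))
  sdv <- vapply(rows[num], function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else stats::sd(x)
  }, numeric(1))
  nn <- vapply(rows[num], function(x) sum(!is.na(x)), numeric(1))
  summary_row <- rows[1, , drop = FALSE]
  summary_row[!num] <- ""
  summary_row[num] <- as.list(mu)
  summary_row[[1]][1] <- if (is.numeric(rows[[1]])) summary_row[[1]][1] else "Mean (SD)"
  out <- rbind(rows, summary_row)
  rownames(out) <- NULL
  attr(out, "mean") <- mu
  attr(out, "sd") <- sdv
  attr(out, "n") <- nn
  out
}
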