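#' Candidate model trigger decisions from a window classification stream
#'
#' A model trigger decision (MTD) fires when `run_len` (default 3) consecutive
#' windows are classified as the target class; the MTD instant is the end time
#' of the last window of the run. Within a longer run, every window from the
#' `run_len`-th onward emits a candidate (the no-cue interval then thins
#' them; see [apply_no_cue()]).
#'
#' @param classes character vector of window classes in time order.
#' @param ends numeric vector of window end times (s), same length.
#' @param run_len number of consecutive target windows required.
#' @return numeric vector of candidate MTD instants.
#' @export
detect_mtds <- function(classes, ends, run_len = 3) {
  stopifnot(length(classes) == length(ends))
  run <- 0L
  out <- numeric()
  for (i in seq_along(classes)) {
    run <- if (classes[i] == "TARGET") run + 1L else 0L
    if (run >= run_len) out <- c(out, ends[i])
  }
  out
}

#' Suppress MTDs inside the no-cue interval
#'
#' Greedy left-to-right thinning: a candidate is kept iff no already-kept MTD
#' lies within the preceding `interval` seconds. In a cueing device this is the
#' refractory period after a cue is delivered.
#'
#' @param instants sorted candidate MTD instants (s).
#' @param interval no-cue interval (s).
#' @return `data.frame` with columns `instant` and `kept`.
#' @export
apply_no_cue <- function(instants, interval = 2.5) {
  kept <- logical(length(instants))
  last_kept <- -Inf
  for (i in seq_along(instants)) {
    if (instants[i] - last_kept >= interval) {
      kept[i] <- TRUE
      last_kept <- instants[i]
    }
  }
  data.frame(instant = instants, kept = kept)
}

#' MTD target zones for each FOG episode
#'
#' The zone in which an MTD counts as a true positive for an episode runs from
#' up to `zone_len` (default 6) seconds before onset through the episode's
#' end. The zone start is pushed later by events overlapping the initial
#' prediction window: past FOG episodes truncate it at their end, and turn or
#' stand intervals truncate it at their end plus `post_event_delay` (default
#' 1 s), so that false positives during turning or standing are not read as
#' early predictions of an unrelated upcoming episode. The start is clipped to
#' the trial start and never exceeds the onset.
#'
#' @param events event table ([fog_events()]); zones are built for its FOG
#'   rows.
#' @param trial_start trial start time (s).
#' @param zone_len initial prediction-zone length (s).
#' @param post_event_delay delay after turn/stand events (s).
#' @return `data.frame`: `episode`, `zone_start`, `onset`, `zone_end`.
#' @export
build_target_zones <- function(events, trial_start = 0, zone_len = 6,
                               post_event_delay = 1) {
  events <- validate_events(events)
  fog <- events[events$kind == "FOG", , drop = FALSE]
  other <- events[events$kind != "FOG", , drop = FALSE]
  if (nrow(fog) == 0L) {
    return(data.frame(episode = integer(), zone_start = numeric(),
                      onset = numeric(), zone_end = numeric()))
  }
  zone_start <- vapply(seq_len(nrow(fog)), function(i) {
    onset <- fog$start[i]
    zs <- max(onset - zone_len, trial_start)
    overlap_fog <- fog$end[fog$end <= onset + 1e-9 & fog$end > zs]
    if (length(overlap_fog)) zs <- max(zs, max(overlap_fog))
    overlap_ev <- other$end[other$start < onset & other$end > zs - post_event_delay]
    if (length(overlap_ev)) zs <- max(zs, max(overlap_ev) + post_event_delay)
    min(zs, onset)
  }, numeric(1))
  data.frame(episode = seq_len(nrow(fog)), zone_start = zone_start,
             onset = fog$start, zone_end = fog$end)
}

#' Classify kept MTDs as true positive, false positive, or ignored
#'
#' An MTD inside any episode's target zone is a true positive matched to that
#' episode (earliest matching episode when zones touch). Outside all zones, an
#' MTD during a stand interval or its gait-initiation tail (the first
#' `gait_init` seconds of walking after standing) is ignored; anything else is
#' a false positive.
#'
#' @param instants kept MTD instants (s).
#' @param zones zone table from [build_target_zones()].
#' @param stands data.frame of stand intervals (`start`, `end`), possibly
#'   empty.
#' @param gait_init gait-initiation grace period after a stand (s).
#' @return `data.frame`: `instant`, `status` (`"TP"`, `"FP"`,
#'   `"IGNORED_STAND_OR_INIT"`), `matched_episode` (NA unless TP).
#' @export
classify_mtds <- function(instants, zones, stands = NULL, gait_init = 1) {
  status <- character(length(instants))
  matched <- rep(NA_integer_, length(instants))
  for (i in seq_along(instants)) {
    t <- instants[i]
    hit <- which(zones$zone_start - 1e-9 <= t & t <= zones$zone_end + 1e-9)
    if (length(hit)) {
      status[i] <- "TP"
      matched[i] <- zones$episode[hit[1L]]
    } else if (!is.null(stands) && nrow(stands) &&
               any(stands$start - 1e-9 <= t & t <= stands$end + gait_init + 1e-9)) {
      status[i] <- "IGNORED_STAND_OR_INIT"
    } else {
      status[i] <- "FP"
    }
  }
  data.frame(instant = instants, status = status, matched_episode = matched)
}

#' Per-episode prediction/detection outcomes
#'
#' An episode is predicted when a matched true-positive MTD fires before
#' onset, detected when one fires between onset and the episode end, and
#' identified when either holds. The identification delay (ID) is the first
#' true-positive instant minus the onset: negative for prediction, positive
#' for detection.
#'
#' @param zones zone table from [build_target_zones()].
#' @param mtds classified MTD table from [classify_mtds()].
#' @return `data.frame`: `episode`, `onset`, `identified`, `predicted`,
#'   `detected`, `id_delay` (NA when not identified).
#' @export
episode_outcomes <- function(zones, mtds) {
  if (nrow(zones) == 0L) {
    return(data.frame(episode = integer(), onset = numeric(),
                      identified = logical(), predicted = logical(),
                      detected = logical(), id_delay = numeric()))
  }
  tp <- mtds[mtds$status == "TP", , drop = FALSE]
  out <- lapply(seq_len(nrow(zones)), function(i) {
    m <- tp[!is.na(tp$matched_episode) & tp$matched_episode == zones$episode[i], ,
            drop = FALSE]
    onset <- zones$onset[i]
    predicted <- any(m$instant < onset)
    detected <- any(m$instant >= onset & m$instant <= zones$zone_end[i] + 1e-9)
    data.frame(episode = zones$episode[i], onset = onset,
               identified = predicted || detected,
               predicted = predicted, detected = detected,
               id_delay = if (nrow(m)) min(m$instant) - onset else NA_real_)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Window-level sensitivity and specificity
#'
#' Pooled over the supplied windows: sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), in percent. A metric whose class is absent from the truth is
#' `NA`.
#'
#' @param pred,truth aligned class vectors (`"TARGET"`/`"NONTARGET"`).
#' @return named numeric vector `c(sensitivity, specificity)` in percent.
#' @export
window_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pos <- truth == "TARGET"
  sens <- if (any(pos)) 100 * sum(pred[pos] == "TARGET") / sum(pos) else NA_real_
  spec <- if (any(!pos)) 100 * sum(pred[!pos] == "NONTARGET") / sum(!pos) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Normalized histogram of identification delays
#'
#' Bins first-identification delays into fixed `bin`-second intervals starting
#' at `start` (default -6 s, the maximal prediction-zone length) and divides by
#' the number of identified episodes, so the bars sum to 1.
#'
#' @param id_delays numeric identification delays (s), NAs dropped.
#' @param bin bin width (s).
#' @param start left edge of the first bin (s).
#' @return `data.frame`: `bin_start`, `bin_end`, `fraction`.
#' @export
id_histogram <- function(id_delays, bin = 1, start = -6) {
  id_delays <- id_delays[!is.na(id_delays)]
  if (!length(id_delays)) stop("no identified episodes to bin")
  k <- floor((id_delays - start) / bin)
  edges <- seq(min(0, min(k)), max(k))
  counts <- vapply(edges, function(e) sum(k == e), numeric(1))
  data.frame(bin_start = start + edges * bin,
             bin_end = start + (edges + 1) * bin,
             fraction = counts / length(id_delays))
}

#' Episode-level evaluation of one trial's window classifications
#'
#' Runs the full trigger pipeline: candidate MTDs from the predicted window
#' stream, no-cue suppression, target zones from the trial's annotations, MTD
#' classification, and per-episode outcomes.
#'
#' @param trial a `fog_trial`.
#' @param pred predicted window classes, aligned with `windows`.
#' @param windows window table from [make_windows()].
#' @param config evaluation constants, see [fog_config()].
#' @return list: `mtds` (all candidates with kept/status), `zones`,
#'   `outcomes`, `n_fp`.
#' @export
evaluate_trial <- function(trial, pred, windows, config = fog_config()) {
  cand <- detect_mtds(pred, windows$end, run_len = config$mtd_run_len)
  cued <- apply_no_cue(cand, interval = config$no_cue)
  zones <- build_target_zones(trial$events, trial_start = trial$times[1],
                              zone_len = config$target_zone,
                              post_event_delay = config$post_event_delay)
  stands <- trial$events[trial$events$kind == "STAND", , drop = FALSE]
  cls <- classify_mtds(cued$instant[cued$kept], zones, stands,
                       gait_init = config$gait_init)
  list(mtds = cls, zones = zones,
       outcomes = episode_outcomes(zones, cls),
       n_fp = sum(cls$status == "FP"))
}

#' Assemble a performance report
#'
#' @param pred,truth pooled window class vectors.
#' @param outcomes pooled episode outcome table ([episode_outcomes()]).
#' @param fp_per_trial per-participant false-positive rates (FPs divided by
#'   that participant's trial count).
#' @return list of class `fog_metrics` with `sensitivity`, `specificity`,
#'   `pct_identified`, `pct_predicted`, `pct_detected`, `mean_id`, `fp_rate`,
#'   `n_windows`, `n_episodes`.
#' @export
metrics_report <- function(pred, truth, outcomes, fp_per_trial = numeric()) {
  wm <- window_metrics(pred, truth)
  n_ep <- nrow(outcomes)
  structure(list(
    sensitivity = unname(wm["sensitivity"]),
    specificity = unname(wm["specificity"]),
    pct_identified = if (n_ep) 100 * mean(outcomes$identified) else NA_real_,
    pct_predicted = if (n_ep) 100 * mean(outcomes$predicted) else NA_real_,
    pct_detected = if (n_ep) 100 * mean(outcomes$detected) else NA_real_,
    mean_id = if (any(outcomes$identified)) {
      mean(outcomes$id_delay[outcomes$identified])
    } else {
      NA_real_
    },
    fp_rate = if (length(fp_per_trial)) mean(fp_per_trial) else NA_real_,
    n_windows = length(pred), n_episodes = n_ep), class = "fog_metrics")
}

#' @export
print.fog_metrics <- function(x, ...) {
  cat(sprintf(paste0("<fog_metrics> sens %.2f%% spec %.2f%% | identified %.2f%% ",
                     "(predicted %.2f%%, detected %.2f%%) | mean ID %+.2f s | ",
                     "FP/trial %.2f [%d windows, %d episodes]\n"),
              x$sensitivity, x$specificity, x$pct_identified, x$pct_predicted,
              x$pct_detected, x$mean_id, x$fp_rate, x$n_windows, x$n_episodes))
  invisible(x)
}

#' Leave-one-freezer-out cross-validation
#'
#' One fold per participant who froze: the fold's model is trained on every
#' other participant (freezers and all non-freezers alike) and evaluated on the
#' held-out freezer's windows and episodes. Non-freezers are never held out.
#' Window metrics are pooled across folds; episode outcomes are pooled; the
#' false-positive rate is FPs per walking trial, computed per held-out
#' participant.
#'
#' @param ds a `fog_dataset`.
#' @param config pipeline constants ([fog_config()]).
#' @param seed integer seed for ensemble training (per-fold seeds derived).
#' @param features precomputed [dataset_features()] table (computed if
#'   `NULL`).
#' @return list of class `fog_crossval`: `report` (pooled [metrics_report()]),
#'   `folds` (per-fold reports), `outcomes`, `windows` (pooled truth/pred),
#'   `fp_per_trial`.
#' @export
lofo_crossval <- function(ds, config = fog_config(), seed = 1, features = NULL) {
  froze <- vapply(ds$participants, `[[`, logical(1), "froze")
  if (sum(froze) < 2L) stop("leave-one-freezer-out needs at least 2 freezers")
  if (is.null(features)) {
    features <- dataset_features(ds, delta = config$reversal_delta,
                                 wavelet_level = config$wavelet_level)
  }
  fn <- feature_names()
  freezer_ids <- participant_ids(ds)[froze]
  pooled_pred <- character()
  pooled_truth <- character()
  outcomes <- list()
  fp_per_trial <- numeric()
  folds <- list()
  for (k in seq_along(freezer_ids)) {
    fid <- freezer_ids[k]
    train <- features[features$participant_id != fid, , drop = FALSE]
    ens <- fit_rusboost(train[fn], train$class,
                        n_learners = config$n_learners,
                        max_splits = config$max_splits,
                        sampling_ratio = config$sampling_ratio,
                        learn_rate = config$learn_rate,
                        seed = round_seed(seed, 1000L + k))
    p <- ds$participants[[which(participant_ids(ds) == fid)]]
    fold_pred <- character()
    fold_truth <- character()
    fold_out <- list()
    n_fp <- 0L
    for (tr in p$trials) {
      wins <- make_windows(tr, win = config$window, shift = config$shift)
      tf <- features[features$participant_id == fid &
                       features$trial_id == tr$trial_id, , drop = FALSE]
      pred <- predict_class(predict_score(ens, tf[fn]), config$score_threshold)
      ev <- evaluate_trial(tr, pred, wins, config)
      fold_pred <- c(fold_pred, pred)
      fold_truth <- c(fold_truth, tf$class)
      fold_out[[length(fold_out) + 1L]] <- ev$outcomes
      n_fp <- n_fp + ev$n_fp
    }
    fold_out <- do.call(rbind, fold_out)
    fp_rate <- n_fp / length(p$trials)
    folds[[fid]] <- metrics_report(fold_pred, fold_truth, fold_out, fp_rate)
    pooled_pred <- c(pooled_pred, fold_pred)
    pooled_truth <- c(pooled_truth, fold_truth)
    outcomes[[fid]] <- fold_out
    fp_per_trial <- c(fp_per_trial, fp_rate)
  }
  outcomes <- do.call(rbind, outcomes)
  structure(list(report = metrics_report(pooled_pred, pooled_truth, outcomes,
                                         fp_per_trial),
                 folds = folds, outcomes = outcomes,
                 windows = data.frame(truth = pooled_truth, pred = pooled_pred,
                                      stringsAsFactors = FALSE),
                 fp_per_trial = stats::setNames(fp_per_trial, freezer_ids)),
            class = "fog_crossval")
}

#' @export
print.fog_crossval <- function(x, ...) {
  cat(sprintf("<fog_crossval> %d folds, pooled:\n", length(x$folds)))
  print(x$report)
  invisible(x)
}
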