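#' Slice a trial into overlapping windows
#'
#' Windows are `win` seconds long, start on a `shift`-second grid aligned to
#' the trial start, and only windows that lie fully inside the trial are
#' emitted: `floor((T - win)/shift) + 1` windows for a trial of duration `T`.
#' Each window is labelled `TARGET` when every sample in it is pre-FOG or FOG,
#' otherwise `NONTARGET` (any non-FOG sample disqualifies it).
#'
#' @param trial a `fog_trial`.
#' @param win window length, s.
#' @param shift step between consecutive window starts, s.
#' @return `data.frame` with columns `start`, `end`, `i0`, `i1` (1-based
#'   sample index range) and `class`.
#' @export
make_windows <- function(trial, win = 1.0, shift = 0.2) {
  n <- length(trial$times)
  win_n <- as.integer(round(win * trial$fs))
  shift_n <- as.integer(round(shift * trial$fs))
  if (n < win_n) stop(sprintf("trial shorter than one window (%.2f s < %.2f s)",
                              n / trial$fs, win))
  starts <- seq.int(1L, n - win_n + 1L, by = shift_n)
  cls <- vapply(starts, function(i0) {
    classify_window(trial$sample_labels[i0:(i0 + win_n - 1L)])
  }, character(1))
  data.frame(start = (starts - 1L) / trial$fs,
             end = (starts - 1L + win_n) / trial$fs,
             i0 = starts, i1 = starts + win_n - 1L,
             class = cls, stringsAsFactors = FALSE)
}

#' Window class from its sample labels
#'
#' `TARGET` iff every sample label is `PREFOG` or `FOG`; a single `NONFOG`
#' sample makes the window `NONTARGET`.
#'
#' @param labels character vector of per-sample labels covering the window.
#' @return `"TARGET"` or `"NONTARGET"`.
#' @export
classify_window <- function(labels) {
  if (all(labels != "NONFOG")) "TARGET" else "NONTARGET"
}

#' Count direction reversals of the AP COP trajectory
#'
#' Counts direction changes detected as alternating local extrema whose
#' excursion from the previously accepted extremum exceeds the hysteresis
#' `delta` (suppresses sensor noise). Only valid samples are considered and the
#' detector resets across invalid runs, so reversals are never counted across a
#' swing-phase gap.
#'
#' @param x AP COP segment (mm).
#' @param valid logical mask (default all valid).
#' @param delta hysteresis, mm.
#' @return integer reversal count (0 for constant, monotone, or all-invalid
#'   segments).
#' @export
count_ap_reversals <- function(x, valid = rep(TRUE, length(x)), delta = 1.0) {
  total <- 0L
  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    total <- total + reversal_count_run(x[starts[r]:ends[r]], delta)
  }
  total
}

reversal_count_run <- function(x, delta) {
  if (length(x) < 2L) return(0L)
  count <- 0L
  dir <- 0L
  ext <- x[1]
  for (v in x[-1]) {
    if (dir == 0L) {
      if (abs(v - ext) > delta) {
        dir <- if (v > ext) 1L else -1L
        ext <- v
      }
    } else if (dir == 1L) {
      if (v > ext) {
        ext <- v
      } else if (ext - v > delta) {
        count <- count + 1L
        dir <- -1L
        ext <- v
      }
    } else {
      if (v < ext) {
        ext <- v
      } else if (v - ext > delta) {
        count <- count + 1L
        dir <- 1L
        ext <- v
      }
    }
  }
  count
}

#' Dominant frequency of a segment by FFT
#'
#' The segment is mean-removed and its magnitude spectrum computed without
#' zero-padding (1 Hz resolution on a 1 s, 100-sample segment). The returned
#' frequency is the maximum-magnitude bin excluding DC, up to Nyquist; ties go
#' to the lowest frequency. A zero (constant) segment has no spectral content;
#' the lowest non-DC bin is returned with attribute `degenerate = TRUE`.
#'
#' @param x numeric segment, gaps already filled.
#' @param fs sampling rate, Hz.
#' @return frequency in Hz (bin index times `fs/length(x)`).
#' @export
dominant_frequency <- function(x, fs = 100) {
  n <- length(x)
  mags <- Mod(stats::fft(x - mean(x)))
  half <- mags[2:(n %/% 2 + 1L)]          # bins 1 .. Nyquist
  f <- (fs / n) * seq_along(half)
  if (max(half) <= 0) {
    out <- f[1]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  f[which.max(half)]                       # which.max takes the first maximum
}

#' Mean wavelet approximation-coefficient power
#'
#' Daubechies-4 decomposition at `level` (symmetric padding); returns the mean
#' of the squared approximation coefficients. The segment is mean-removed by
#' default so the feature is invariant to a constant AP offset (foot placement
#' in the insole frame); power then scales quadratically with signal amplitude.
#'
#' @param x numeric segment, gaps already filled.
#' @param level decomposition depth.
#' @param remove_mean subtract the segment mean first.
#' @return mean squared approximation coefficient (mm^2 scale).
#' @export
wavelet_approx_power <- function(x, level = 4, remove_mean = TRUE) {
  if (remove_mean) x <- x - mean(x)
  mean(dwt_approx(x, level = level)^2)
}

#' The 8-feature vector for each window of a trial
#'
#' Per foot (left then right in each pair): number of AP COP reversals
#' (`rev_ap`), dominant frequency of ML and AP COP velocity (`dom_ml`,
#' `dom_ap`, Hz), and mean wavelet approximation-coefficient power of AP COP
#' position (`wav_ap`, mm^2). A foot with no valid sample in a window
#' contributes 0 for its four features and sets the window's `degenerate`
#' flag.
#'
#' @param trial a `fog_trial`.
#' @param windows window table from [make_windows()] (computed if `NULL`).
#' @param cop precomputed [prepare_cop()] result (computed if `NULL`).
#' @param delta reversal hysteresis, mm.
#' @param wavelet_level wavelet decomposition depth.
#' @return `data.frame`: `participant_id`, `trial_id`, `start`, `class`,
#'   `rev_ap_l`, `rev_ap_r`, `dom_ml_l`, `dom_ml_r`, `dom_ap_l`, `dom_ap_r`,
#'   `wav_ap_l`, `wav_ap_r`, `degenerate`.
#' @export
extract_features <- function(trial, windows = NULL, cop = NULL, delta = 1.0,
                             wavelet_level = 4) {
  if (is.null(windows)) windows <- make_windows(trial)
  if (is.null(cop)) cop <- prepare_cop(trial)
  nw <- nrow(windows)
  feat <- matrix(0, nw, 8)
  degenerate <- logical(nw)
  for (w in seq_len(nw)) {
    idx <- windows$i0[w]:windows$i1[w]
    for (s in 1:2) {
      side <- cop[[s]]
      if (!any(side$valid[idx])) {
        degenerate[w] <- TRUE       # features for this foot stay 0
        next
      }
      feat[w, s] <- count_ap_reversals(side$cop_y[idx], side$valid[idx], delta)
      feat[w, s + 2] <- dominant_frequency(side$vel_x[idx], trial$fs)
      feat[w, s + 4] <- dominant_frequency(side$vel_y[idx], trial$fs)
      feat[w, s + 6] <- wavelet_approx_power(side$cop_y[idx], level = wavelet_level)
    }
  }
  colnames(feat) <- c("rev_ap_l", "rev_ap_r", "dom_ml_l", "dom_ml_r",
                      "dom_ap_l", "dom_ap_r", "wav_ap_l", "wav_ap_r")
  cbind(data.frame(participant_id = trial$participant_id,
                   trial_id = trial$trial_id,
                   start = windows$start, end = windows$end,
                   class = windows$class, stringsAsFactors = FALSE),
        as.data.frame(feat), degenerate = degenerate)
}

#' Feature names used by the classifier
#' @export
feature_names <- function() {
  c("rev_ap_l", "rev_ap_r", "dom_ml_l", "dom_ml_r",
    "dom_ap_l", "dom_ap_r", "wav_ap_l", "wav_ap_r")
}

#' Feature matrix for every trial in a dataset
#'
#' @param ds a `fog_dataset`.
#' @param ... passed to [extract_features()].
#' @return one `data.frame` of window rows across all participants and trials.
#' @export
dataset_features <- function(ds, ...) {
  out <- lapply(ds$participants, function(p) {
    do.call(rbind, lapply(p$trials, extract_features, ...))
  })
  do.call(rbind, out)
}
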