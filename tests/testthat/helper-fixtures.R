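# Shared builders for small in-code fixtures.

# Minimal signal-form trial: constant load split, flat COP, given duration.
flat_trial <- function(duration = 10, events = fog_events(), fs = 100,
                       participant_id = "T", trial_id = "T01") {
  n <- as.integer(duration * fs)
  times <- (seq_len(n) - 1) / fs
  side <- function(off) list(force = rep(350, n),
                             cop_x = rep(off, n), cop_y = rep(0, n),
                             valid = rep(TRUE, n))
  fog_trial(participant_id, trial_id, times, side(-30), side(30),
            events = events, fs = fs)
}

# Skeleton trial object for windowing tests (no signals needed).
label_trial <- function(labels, fs = 100) {
  n <- length(labels)
  structure(list(times = (seq_len(n) - 1) / fs, fs = fs,
                 sample_labels = labels),
            class = "fog_trial")
}

# Independent DWT oracle: per-output-index double summation over an explicitly
# symmetric-extended signal (no vectorized shifting; independent of dwt_approx).
oracle_dwt_level <- function(x, lo) {
  L <- length(lo)
  n <- length(x)
  ext <- c(x[(L - 1):1], x, x[n:(n - L + 2)])
  n_out <- (n + L - 1) %/% 2
  out <- numeric(n_out)
  for (k in seq_len(n_out)) {
    acc <- 0
    for (j in seq_len(L)) {
      acc <- acc + lo[j] * ext[2 * k + L - j]
    }
    out[k] <- acc
  }
  out
}

oracle_wavelet_power <- function(x, level = 4, lo) {
  for (i in seq_len(level)) x <- oracle_dwt_level(x, lo)
  mean(x^2)
}

# db4 low-pass filter recomputed for the oracle from the standard published
# constants (independent copy, higher-precision source than the package's).
oracle_db4 <- rev(c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
                    -0.02798376941698385, -0.18703481171888114,
                    0.030841381835986965, 0.032883011666982945,
                    -0.010597401784997278))

# Brute-force DFT magnitude argmax (no fft).
oracle_domfreq <- function(x, fs = 100) {
  n <- length(x)
  x <- x - mean(x)
  t <- seq_len(n) - 1
  best_k <- 1
  best_m <- -1
  for (k in seq_len(n %/% 2)) {
    re <- sum(x * cos(2 * pi * k * t / n))
    im <- sum(x * sin(2 * pi * k * t / n))
    m <- sqrt(re^2 + im^2)
    if (m > best_m + 1e-9) {
      best_m <- m
      best_k <- k
    }
  }
  fs * best_k / n
}

# Brute-force MTD scan: for every index, check directly whether the run_len
# windows ending here are all TARGET, then greedily thin by the no-cue rule.
oracle_mtds <- function(classes, ends, run_len = 3, no_cue = 2.5) {
  cand <- numeric()
  for (i in seq_along(classes)) {
    if (i >= run_len && all(classes[(i - run_len + 1):i] == "TARGET")) {
      cand <- c(cand, ends[i])
    }
  }
  kept <- numeric()
  for (t in cand) {
    if (!length(kept) || t - kept[length(kept)] >= no_cue) kept <- c(kept, t)
  }
  list(candidates = cand, kept = kept)
}
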