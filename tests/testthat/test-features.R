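test_that("window slicing follows the 0.2 s grid and the count formula", {
  tr <- label_trial(rep("NONFOG", 300))
  w <- make_windows(tr)
  expect_equal(nrow(w), 11)
  expect_equal(w$start, seq(0, 2, by = 0.2))
  expect_equal(w$end - w$start, rep(1, 11))
  expect_equal(nrow(make_windows(label_trial(rep("NONFOG", 100)))), 1)
  expect_error(make_windows(label_trial(rep("NONFOG", 90))), "shorter than one window")
})

test_that("a window is TARGET only when every sample is pre-FOG or FOG", {
  expect_equal(classify_window(rep("FOG", 100)), "TARGET")
  expect_equal(classify_window(c(rep("PREFOG", 40), rep("FOG", 60))), "TARGET")
  expect_equal(classify_window(c(rep("FOG", 99), "NONFOG")), "NONTARGET")
  expect_equal(classify_window(rep("NONFOG", 100)), "NONTARGET")
})

test_that("AP reversal counting matches extrema with hysteresis", {
  t <- (0:99) / 100
  expect_equal(count_ap_reversals(10 * t), 0)          # monotone ramp
  expect_equal(count_ap_reversals(rep(3, 100)), 0)     # constant
  expect_equal(count_ap_reversals(10 * sin(2 * pi * 2 * t)), 4)  # 2 Hz, amp 10
  # sub-hysteresis wiggle is ignored
  expect_equal(count_ap_reversals(0.4 * sin(2 * pi * 5 * t), delta = 1), 0)
  # detector resets across invalid runs: two monotone valid runs -> 0
  x <- c(1:50, 50:1) / 10
  valid <- c(rep(TRUE, 50), rep(FALSE, 0), rep(TRUE, 50))
  valid[48:53] <- FALSE
  expect_equal(count_ap_reversals(x, valid), 0)
  expect_equal(count_ap_reversals(x, rep(FALSE, 100)), 0)
})

test_that("dominant frequency picks the largest non-DC bin, low tie-break", {
  t <- (0:99) / 100
  expect_equal(dominant_frequency(sin(2 * pi * 5 * t)), 5)
  expect_equal(dominant_frequency(sin(2 * pi * 3 * t) + 2 * sin(2 * pi * 7 * t)), 7)
  # offset does not matter (mean removal)
  expect_equal(dominant_frequency(40 + sin(2 * pi * 5 * t)), 5)
  const <- dominant_frequency(rep(1, 100))
  expect_equal(as.numeric(const), 1)
  expect_true(isTRUE(attr(const, "degenerate")))
  # agreement with brute-force DFT argmax
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(100)
    expect_equal(dominant_frequency(x), oracle_domfreq(x))
  }
})

test_that("wavelet approximation power matches the independent DWT oracle", {
  # frozen external reference (PyWavelets db4, level 4, symmetric mode) for a
  # 2 Hz unit sinusoid sampled 1 s at 100 Hz
  x <- sin(2 * pi * 2 * (0:99) / 100)
  cA <- dwt_approx(x, level = 4)
  expect_length(cA, 12)
  expect_equal(cA[1:4], c(1.11503795, 1.09170269, 0.98122855, 1.19719393),
               tolerance = 1e-7)
  expect_equal(wavelet_approx_power(rep(0, 100)), 0)
  # without mean removal a constant c has power 2^level * c^2
  expect_equal(wavelet_approx_power(rep(3, 100), remove_mean = FALSE), 16 * 9)
  # with mean removal the feature is offset invariant
  expect_equal(wavelet_approx_power(x + 57), wavelet_approx_power(x))
  # quadratic homogeneity
  expect_equal(wavelet_approx_power(2 * x), 4 * wavelet_approx_power(x))
  # independent convolution oracle on random segments
  set.seed(11)
  for (i in 1:20) {
    z <- rnorm(100)
    expect_equal(wavelet_approx_power(z, remove_mean = FALSE),
                 oracle_wavelet_power(z, 4, oracle_db4), tolerance = 1e-10)
  }
})

test_that("feature extraction flags degenerate feet and reads simulator truth", {
  cfg <- sim_config(duration = 20, tremble_freq = 6,
                    phenotype_mix = c(trembling = 1, akinetic = 0))
  sim <- simulate_trial(cfg, seed = 101, n_episodes = 1)
  feats <- extract_features(sim$trial)
  expect_true(all(feature_names() %in% names(feats)))
  ep <- sim$truth
  inside <- feats$start >= ep$start[1] & feats$end <= ep$end[1]
  if (sum(inside) >= 2) {
    expect_equal(median(feats$dom_ap_l[inside]), 6)
    expect_equal(median(feats$dom_ap_r[inside]), 6)
  }
  # walking windows live in the locomotor band
  walking <- feats$class == "NONTARGET" & !inside
  expect_lte(median(feats$dom_ap_l[walking]), 3)

  # a foot without any valid sample yields zeros and the degenerate flag
  tr <- flat_trial(3)
  tr$left$force[] <- 0           # left always below 5% of total
  feats0 <- extract_features(tr)
  expect_true(all(feats0$degenerate))
  expect_true(all(feats0$rev_ap_l == 0 & feats0$wav_ap_l == 0 &
                    feats0$dom_ap_l == 0 & feats0$dom_ml_l == 0))
  expect_false(any(feats0$dom_ap_r != 0 & is.na(feats0$dom_ap_r)))
})

test_that("features except wavelet power are offset invariant by construction", {
  sim <- simulate_trial(sim_config(duration = 6), seed = 31)
  f1 <- extract_features(sim$trial)
  shifted <- sim$trial
  shifted$left$cop_y <- shifted$left$cop_y + 25
  shifted$right$cop_y <- shifted$right$cop_y + 25
  f2 <- extract_features(shifted)
  for (col in feature_names()) {
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-9)
  }
})
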