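test_that("MTD candidates fire at the 3rd and later windows of target runs", {
  ends <- seq(0.2, by = 0.2, length.out = 6) + 0.8   # window ends on the grid
  expect_equal(detect_mtds(c("TARGET", "TARGET", "TARGET", "NONTARGET",
                             "NONTARGET", "NONTARGET"), ends), ends[3])
  expect_equal(detect_mtds(c("TARGET", "TARGET", "NONTARGET", "TARGET",
                             "TARGET", "NONTARGET"), ends), numeric())
  run5 <- detect_mtds(rep("TARGET", 5), ends[1:5])
  expect_equal(run5, ends[3:5])
  expect_equal(diff(run5), rep(0.2, 2))
})

test_that("no-cue suppression keeps MTDs at least 2.5 s apart", {
  nc <- apply_no_cue(c(2.0, 3.5))
  expect_equal(nc$kept, c(TRUE, FALSE))
  expect_equal(apply_no_cue(c(2.0, 4.6))$kept, c(TRUE, TRUE))
  expect_equal(apply_no_cue(7.7)$kept, TRUE)
  # property: kept instants always >= 2.5 s apart, greedily from the left
  set.seed(4)
  for (i in 1:50) {
    cand <- sort(round(runif(30, 0, 40) / 0.2) * 0.2)
    kept <- apply_no_cue(cand)$instant[apply_no_cue(cand)$kept]
    if (length(kept) > 1) expect_true(all(diff(kept) >= 2.5 - 1e-9))
  }
})

test_that("target zones start 6 s before onset, adjusted for prior events", {
  z <- build_target_zones(fog_events("FOG", 10, 14))
  expect_equal(z$zone_start, 4)
  expect_equal(z$zone_end, 14)
  # turn ending at 6 s pushes the start to 7 s (1 s post-event delay)
  z2 <- build_target_zones(fog_events(c("TURN", "FOG"), c(4, 10), c(6, 14)))
  expect_equal(z2$zone_start, 7)
  # onset near the trial start clips to 0
  z3 <- build_target_zones(fog_events("FOG", 3, 5))
  expect_equal(z3$zone_start, 0)
  # a preceding FOG truncates at its end with no extra delay
  z4 <- build_target_zones(fog_events(c("FOG", "FOG"), c(5, 10), c(7.5, 12)))
  expect_equal(z4$zone_start, c(0, 7.5))
  # invariant: onset - zone_start <= 6 always
  set.seed(6)
  for (i in 1:30) {
    on <- sort(runif(3, 5, 40))
    on <- on[c(TRUE, diff(on) > 3)]
    ev <- fog_events(c(rep("FOG", length(on)), "TURN", "STAND"),
                     c(on, 1, 2.5), c(on + 1, 2, 4))
    z <- build_target_zones(ev)
    expect_true(all(z$onset - z$zone_start <= 6 + 1e-9))
    expect_true(all(z$zone_start <= z$onset))
  }
})

test_that("MTDs classify as TP in zones, ignored near stands, FP elsewhere", {
  zones <- build_target_zones(fog_events("FOG", 20, 24))
  stands <- data.frame(start = 5, end = 8)
  cls <- classify_mtds(c(18, 8.5, 12), zones, stands)
  expect_equal(cls$status, c("TP", "IGNORED_STAND_OR_INIT", "FP"))
  expect_equal(cls$matched_episode, c(1L, NA_integer_, NA_integer_))
  # inside the stand itself is also ignored
  expect_equal(classify_mtds(6, zones, stands)$status, "IGNORED_STAND_OR_INIT")
  # 1.5 s after the stand ends is walking again -> FP
  expect_equal(classify_mtds(9.5, zones, stands)$status, "FP")
})

test_that("episode outcomes separate prediction from detection", {
  zones <- build_target_zones(fog_events("FOG", 20, 24))
  both <- episode_outcomes(zones, data.frame(
    instant = c(19, 20.4), status = "TP", matched_episode = 1L))
  expect_true(both$predicted && both$detected && both$identified)
  expect_equal(both$id_delay, -1)
  det <- episode_outcomes(zones, data.frame(
    instant = 20.6, status = "TP", matched_episode = 1L))
  expect_false(det$predicted)
  expect_true(det$detected)
  expect_equal(det$id_delay, 0.6)
  none <- episode_outcomes(zones, data.frame(
    instant = numeric(), status = character(), matched_episode = integer()))
  expect_false(none$identified)
  expect_true(is.na(none$id_delay))
})

test_that("window metrics pool a plain confusion matrix", {
  expect_equal(window_metrics(rep("TARGET", 4), rep("TARGET", 4))[["sensitivity"]], 100)
  wm <- window_metrics(c("TARGET", "NONTARGET", "NONTARGET", "TARGET"),
                       c("TARGET", "TARGET", "NONTARGET", "NONTARGET"))
  expect_equal(unname(wm), c(50, 50))
  all_neg <- window_metrics(rep("NONTARGET", 6),
                            c(rep("TARGET", 3), rep("NONTARGET", 3)))
  expect_equal(all_neg[["sensitivity"]], 0)
  expect_true(is.na(window_metrics(rep("TARGET", 3), rep("TARGET", 3))[["specificity"]]))
})

test_that("identification-delay histograms bin from -6 s and normalize", {
  h1 <- id_histogram(rep(-0.5, 4))
  expect_equal(sum(h1$fraction), 1)
  expect_equal(h1$fraction[h1$bin_start == -1], 1)
  h2 <- id_histogram(c(-1.2, 0.3, 0.4))
  expect_equal(h2$fraction[h2$bin_start == -2], 1 / 3)
  expect_equal(h2$fraction[h2$bin_start == 0], 2 / 3)
  expect_equal(sum(h2$fraction), 1)
  expect_error(id_histogram(NA_real_), "no identified episodes")
})

test_that("published performance rows satisfy the identified-episode bounds", {
  for (name in c("model_performance", "modified_performance")) {
    perf <- reference_table(name)
    expect_true(all(pmax(perf$pct_predicted, perf$pct_detected) <=
                      perf$pct_identified + 1e-9))
    expect_true(all(perf$pct_identified <=
                      perf$pct_predicted + perf$pct_detected + 1e-9))
  }
})

test_that("leave-one-freezer-out holds out each freezer exactly once", {
  cfg <- sim_config(duration = 25)
  ds <- simulate_cohort(3, 2, 3, cfg = cfg, seed = 17)
  feats <- dataset_features(ds)
  cv <- lofo_crossval(ds, seed = 17, features = feats)
  froze <- vapply(ds$participants, `[[`, logical(1), "froze")
  expect_equal(names(cv$folds), participant_ids(ds)[froze])
  # non-freezer windows never appear in the pooled test windows
  expect_equal(nrow(cv$windows),
               sum(feats$participant_id %in% participant_ids(ds)[froze]))
  r <- cv$report
  expect_true(max(r$pct_predicted, r$pct_detected) <= r$pct_identified + 1e-9)
  expect_true(r$pct_identified <= r$pct_predicted + r$pct_detected + 1e-9)
  expect_error(lofo_crossval(simulate_cohort(1, 2, 2, cfg = cfg, seed = 1)),
               "at least 2 freezers")
})
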