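# Cohort shaped like the first collection wave: 11 participants of whom 7
# froze, built from the shipped reference exam table with tiny placeholder
# trials.
reference_shaped_cohort <- function() {
  exam <- reference_table("dataset1_exam")
  participants <- lapply(seq_len(nrow(exam)), function(i) {
    ev <- if (exam$froze[i]) fog_events("FOG", 3, 4.5) else fog_events()
    fog_participant(exam$participant[i], list(flat_trial(10, ev)),
                    nfogq = exam$nfogq[i], updrs3 = exam$updrs3[i])
  })
  fog_dataset("wave1-shaped", participants)
}

test_that("dataset filtering reproduces the outlier-removal cohort sizes", {
  ds <- reference_shaped_cohort()
  expect_length(ds$participants, 11)
  expect_equal(sum(vapply(ds$participants, `[[`, logical(1), "froze")), 7)
  expect_length(filter_dataset(ds, "P07")$participants, 10)
  expect_length(filter_dataset(ds, exclude_nonfreezers = TRUE)$participants, 7)
  expect_length(filter_dataset(ds, "P07", exclude_nonfreezers = TRUE)$participants, 6)
  expect_error(filter_dataset(ds, "P99"), "unknown participant id")
  # no-op filter returns an equal dataset and leaves the original untouched
  same <- filter_dataset(ds, character(), FALSE)
  expect_equal(participant_ids(same), participant_ids(ds))
  expect_length(ds$participants, 11)
})

test_that("cohort summaries recompute the published testing aggregates", {
  t6 <- summarize_cohort_rows(reference_table("dataset1_testing"))
  mu <- attr(t6, "mean")
  expect_equal(mu[["n_fog"]], 32.91, tolerance = 0.011)
  expect_equal(mu[["total_duration"]], 1345.20, tolerance = 0.011)
  # zone duration is only recorded for the 7 freezers evaluated
  expect_equal(attr(t6, "n")[["mtd_zone_duration"]], 7)
  expect_equal(mu[["mtd_zone_duration"]], 154.20, tolerance = 0.011)
})

test_that("summary means agree with an independent brute-force pass", {
  ds <- simulate_cohort(3, 2, 3, cfg = sim_config(duration = 15), seed = 23)
  cs <- cohort_summary(ds)
  mu <- attr(cs, "mean")
  # brute force over participants
  for (col in c("n_trials", "total_duration", "n_fog", "total_fog_duration")) {
    acc <- 0
    for (p in ds$participants) {
      val <- switch(col,
        n_trials = length(p$trials),
        total_duration = sum(sapply(p$trials, function(tr) length(tr$times) / tr$fs)),
        n_fog = sum(sapply(p$trials, function(tr) sum(tr$events$kind == "FOG"))),
        total_fog_duration = sum(sapply(p$trials, function(tr) {
          e <- tr$events
          sum(e$end[e$kind == "FOG"] - e$start[e$kind == "FOG"])
        })))
      acc <- acc + val
    }
    expect_equal(mu[[col]], acc / length(ds$participants), tolerance = 1e-9)
  }
  expect_error(cohort_summary(fog_dataset("empty", list())), "empty dataset")
})

test_that("a single-participant summary has an undefined SD", {
  rows <- data.frame(participant = "A", n_trials = 5, total = 12.5)
  s <- summarize_cohort_rows(rows)
  expect_true(all(is.na(attr(s, "sd"))))
  expect_equal(attr(s, "mean")[["n_trials"]], 5)
})

test_that("demographics aggregates follow the sample-SD convention", {
  d1 <- summarize_cohort_rows(reference_table("dataset1_demographics"))
  expect_equal(attr(d1, "mean")[["years_since_diagnosis"]], 10.45, tolerance = 0.005)
  expect_equal(attr(d1, "sd")[["years_since_diagnosis"]], 5.01, tolerance = 0.005)
  expect_equal(attr(d1, "sd")[["age"]], 5.80, tolerance = 0.005)
  d2 <- summarize_cohort_rows(reference_table("dataset2_demographics"))
  expect_equal(attr(d2, "mean")[["age"]], 71.50, tolerance = 0.005)
  expect_equal(attr(d2, "sd")[["age"]], 6.95, tolerance = 0.005)
  expect_equal(attr(d2, "mean")[["years_since_diagnosis"]], 10.90, tolerance = 0.005)
  expect_equal(attr(d2, "sd")[["years_since_diagnosis"]], 6.05, tolerance = 0.005)
})
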