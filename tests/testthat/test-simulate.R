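test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  a <- simulate_trial(sim_config(duration = 10), seed = 77)
  b <- simulate_trial(sim_config(duration = 10), seed = 77)
  expect_identical(a$trial$left$force, b$trial$left$force)
  expect_identical(a$trial$right$cop_y, b$trial$right$cop_y)
  expect_identical(as.data.frame(a$trial$events), as.data.frame(b$trial$events))
  c_ <- simulate_trial(sim_config(duration = 10), seed = 78)
  expect_false(identical(a$trial$left$force, c_$trial$left$force))
})

test_that("trials without episodes are entirely non-FOG", {
  sim <- simulate_trial(sim_config(duration = 15, episode_rate = 0), seed = 5)
  expect_true(all(sim$trial$sample_labels == "NONFOG"))
  expect_false(any(sim$trial$events$kind == "FOG"))
})

test_that("swing-phase samples are invalid under the 5% rule", {
  sim <- simulate_trial(sim_config(duration = 20, episode_rate = 0), seed = 13)
  tr <- sim$trial
  walking <- rep(TRUE, length(tr$times))
  for (i in seq_len(nrow(tr$events))) {
    walking[tr$times >= tr$events$start[i] - 0.5 & tr$times <= tr$events$end[i] + 0.5] <- FALSE
  }
  # during walking, at any instant at most one foot carries the load:
  # swing samples (minority-load foot) must be >95% invalid
  swing_l <- walking & tr$left$force < tr$right$force
  expect_gt(mean(!tr$left$valid[swing_l & tr$left$force < 0.2 * tr$right$force]), 0.95)
  # stance samples are valid
  stance_l <- walking & tr$left$force > 5 * tr$right$force
  expect_gt(mean(tr$left$valid[stance_l]), 0.99)
})

test_that("pre-FOG precursors label exactly 2 s when preceded by walking", {
  cfg <- sim_config(duration = 30)
  sim <- simulate_trial(cfg, seed = 19, n_episodes = 1)
  ep <- sim$truth
  expect_equal(nrow(ep), 1)
  n_pre <- sum(sim$trial$sample_labels == "PREFOG")
  expect_equal(n_pre, 2 * cfg$fs, tolerance = 0.02)
})

test_that("trembling episodes put the configured frequency into the features", {
  cfg <- sim_config(duration = 30, tremble_freq = 6,
                    phenotype_mix = c(trembling = 1, akinetic = 0))
  sim <- simulate_trial(cfg, seed = 29, n_episodes = 2)
  cop <- prepare_cop(sim$trial)
  hits <- 0
  total <- 0
  for (i in seq_len(nrow(sim$truth))) {
    s0 <- sim$truth$start[i]
    e0 <- sim$truth$end[i]
    if (e0 - s0 < 1.2) next
    idx <- which(sim$trial$times >= s0 + 0.1 & sim$trial$times < s0 + 1.1)[1:100]
    total <- total + 1
    if (dominant_frequency(cop$left$vel_y[idx]) == 6) hits <- hits + 1
  }
  expect_gt(total, 0)
  expect_equal(hits, total)
})

test_that("cohort composition and freezer flags are exact", {
  ds <- simulate_cohort(7, 4, 2, cfg = sim_config(duration = 12), seed = 3)
  expect_length(ds$participants, 11)
  froze <- vapply(ds$participants, `[[`, logical(1), "froze")
  expect_equal(sum(froze), 7)
  expect_identical(froze, c(rep(TRUE, 7), rep(FALSE, 4)))
  # reproducible episode counts
  ds2 <- simulate_cohort(7, 4, 2, cfg = sim_config(duration = 12), seed = 3)
  n_ep <- function(d) vapply(d$participants, function(p) {
    sum(vapply(p$trials, function(tr) sum(tr$events$kind == "FOG"), integer(1)))
  }, integer(1))
  expect_identical(n_ep(ds), n_ep(ds2))
})

test_that("grid emission preserves the COP to well under 0.1 mm", {
  sim <- simulate_trial(sim_config(duration = 4), seed = 11)
  grid <- emit_grid(sim$trial)
  cop <- compute_cop(grid$left$pressure, grid$left$sensel_x, grid$left$sensel_y)
  loaded <- grid$left$pressure %*% rep(1, ncol(grid$left$pressure)) > 0
  expect_lt(max(abs(cop[loaded, "cop_x"] - sim$trial$left$cop_x[loaded])), 0.1)
  expect_lt(max(abs(cop[loaded, "cop_y"] - sim$trial$left$cop_y[loaded])), 0.1)
  # zero-force frame -> all-zero sensels
  tr0 <- flat_trial(2)
  tr0$left$force[5] <- 0
  g0 <- emit_grid(tr0)
  expect_equal(sum(g0$left$pressure[5, ]), 0)
  # single-sensel layout forces the COP onto that sensel
  g1 <- emit_grid(flat_trial(2), sensel_x = 0, sensel_y = 0)
  cop1 <- compute_cop(g1$left$pressure, g1$left$sensel_x, g1$left$sensel_y)
  expect_true(all(cop1[, "cop_x"] == 0))
  # a COP outside the hull is refused
  expect_error(emit_grid(sim$trial, sensel_x = c(-1, 1), sensel_y = c(-1, 1)),
               "outside sensel hull")
})
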