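#' Simulator configuration
#'
#' Parameters of the two-foot plantar-pressure gait simulator. Defaults are
#' chosen as study-like walking-trial conditions: 100 Hz sampling, ~50 s
#' trials, cadence 1.8 steps/s with single-support stance and 0.1 s
#' double-support load crossfades, a 150 mm heel-to-toe AP COP excursion, and
#' FOG episodes at about 1.5 per trial with log-normal durations. Pre-FOG
#' precursors are festination-like (cadence inflated, steps shortened, ramped
#' linearly over the 2 s before onset). Trembling episodes oscillate the COP
#' at `tremble_freq` (within the 3-8 Hz freezing band); akinetic episodes hold
#' the COP static under load.
#'
#' @param fs sampling rate, Hz.
#' @param duration trial length, s.
#' @param cadence steps per second (both feet combined).
#' @param ap_excursion stance heel-to-toe AP COP travel, mm.
#' @param ml_sway within-stance ML COP sway amplitude, mm.
#' @param foot_offset lateral distance of each foot's COP from the midline, mm.
#' @param tremble_freq trembling-FOG oscillation frequency, Hz (3-8).
#' @param tremble_amp trembling-FOG AP oscillation amplitude, mm.
#' @param episode_rate expected FOG episodes per trial (0 for non-freezers).
#' @param ep_meanlog,ep_sdlog log-normal episode-duration parameters (s).
#' @param prefog_cadence_gain cadence multiplier reached at FOG onset.
#' @param prefog_excursion_shrink AP excursion multiplier reached at onset.
#' @param phenotype_mix probabilities for trembling vs akinetic episodes.
#' @param force_scale nominal two-foot total ground reaction force.
#' @param force_noise force noise SD.
#' @param cop_noise COP noise SD, mm.
#' @param double_support load crossfade length, s.
#' @param swing_residual fraction of total force left on the swing foot
#'   (below the 5% validity rule).
#' @param pre_fog pre-FOG label window, s.
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(fs = 100, duration = 50, cadence = 1.8,
                       ap_excursion = 150, ml_sway = 5, foot_offset = 30,
                       tremble_freq = 6, tremble_amp = 8,
                       episode_rate = 1.5, ep_meanlog = log(2.5), ep_sdlog = 0.5,
                       prefog_cadence_gain = 1.8, prefog_excursion_shrink = 0.4,
                       phenotype_mix = c(trembling = 0.5, akinetic = 0.5),
                       force_scale = 700, force_noise = 5, cop_noise = 1.0,
                       double_support = 0.1, swing_residual = 0.02,
                       pre_fog = 2.0) {
  stopifnot(tremble_freq >= 3, tremble_freq <= 8, episode_rate >= 0,
            tremble_amp >= 0, cop_noise >= 0, force_noise >= 0)
  structure(as.list(environment()), class = c("sim_config", "list"))
}

## deterministic sub-seed helper shared with the boosting code
sim_seed <- function(seed, counter) round_seed(seed, counter)

## segment schedule: stand, then walking interleaved with turns, stands and
## FOG episodes until the trial is full
build_schedule <- function(cfg, n_episodes) {
  segs <- list(list(kind = "stand", dur = stats::runif(1, 2, 4)))
  t <- segs[[1]]$dur
  eps <- n_episodes
  while (t < cfg$duration) {
    ## shorter walks while episodes are pending so every requested episode
    ## reliably fits into the trial
    wd <- if (eps > 0) stats::runif(1, 4, 7) else stats::runif(1, 5, 9)
    segs <- c(segs, list(list(kind = "walk", dur = wd)))
    t <- t + wd
    if (t >= cfg$duration) break
    if (eps > 0) {
      d <- min(max(stats::rlnorm(1, cfg$ep_meanlog, cfg$ep_sdlog), 1), 15)
      phen <- sample(names(cfg$phenotype_mix), 1, prob = cfg$phenotype_mix)
      segs <- c(segs, list(list(kind = "fog", dur = d, phenotype = phen)))
      eps <- eps - 1
      t <- t + d
    } else {
      u <- stats::runif(1)
      if (u < 0.5) {
        d <- stats::runif(1, 1.5, 2.5)
        segs <- c(segs, list(list(kind = "turn", dur = d)))
        t <- t + d
      } else if (u < 0.7) {
        d <- stats::runif(1, 2, 3)
        segs <- c(segs, list(list(kind = "stand", dur = d)))
        t <- t + d
      }
    }
  }
  segs
}

## double-support load crossfade as a function of gait phase w in [0,1):
## left foot loaded over [0, 0.5), crossfades of phase-width d at 0 and 0.5
load_share <- function(w, d) {
  ifelse(w < d, w / d,
         ifelse(w < 0.5, 1,
                ifelse(w < 0.5 + d, 1 - (w - 0.5) / d, 0)))
}

#' Simulate one two-foot plantar-pressure walking trial
#'
#' Generates alternating single-support gait (the stance foot carries ~100% of
#' load while its AP COP progresses heel to toe; the swing foot retains only a
#' residual force, invalid under the 5% rule), turn and stand segments,
#' festination-like pre-FOG precursors, and trembling or akinetic FOG
#' episodes, with Gaussian force and COP noise throughout. Event intervals
#' (FOG/TURN/STAND) are emitted as ground truth and per-sample labels derived
#' from them.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; identical seeds give bit-identical trials.
#' @param participant_id,trial_id identifiers stored in the trial.
#' @param n_episodes number of FOG episodes to place (default Poisson with
#'   mean `cfg$episode_rate`).
#' @return list with elements `trial` (a `fog_trial`) and `truth`
#'   (segment table with per-segment regime and phenotype tags).
#' @export
simulate_trial <- function(cfg = sim_config(), seed = 1,
                           participant_id = "S01", trial_id = "T01",
                           n_episodes = NULL) {
  set.seed(seed)
  if (is.null(n_episodes)) n_episodes <- stats::rpois(1, cfg$episode_rate)
  segs <- build_schedule(cfg, n_episodes)
  n <- as.integer(round(cfg$duration * cfg$fs))
  times <- (seq_len(n) - 1L) / cfg$fs
  share <- numeric(n)           # left-foot load share before residual floor
  ly <- numeric(n); lx <- numeric(n); ry <- numeric(n); rx <- numeric(n)
  events <- list()
  truth <- list()
  phase <- 0
  t0 <- 0
  for (si in seq_along(segs)) {
    seg <- segs[[si]]
    t1 <- min(t0 + seg$dur, cfg$duration)
    i0 <- floor(t0 * cfg$fs) + 1L
    i1 <- min(floor(t1 * cfg$fs - 1e-9) + 1L, n)
    if (i1 < i0) break
    idx <- i0:i1
    tt <- times[idx]
    next_fog <- si < length(segs) && segs[[si + 1]]$kind == "fog"
    if (seg$kind %in% c("walk", "turn")) {
      base_c <- cfg$cadence * if (seg$kind == "turn") 0.7 else 1
      c_eff <- rep(base_c, length(idx))
      e_eff <- rep(cfg$ap_excursion, length(idx))
      if (next_fog) {
        r <- pmax(0, (tt - (t1 - cfg$pre_fog)) / cfg$pre_fog)
        c_eff <- base_c * (1 + (cfg$prefog_cadence_gain - 1) * r)
        e_eff <- cfg$ap_excursion *
          (1 - (1 - cfg$prefog_excursion_shrink) * r)
      }
      phi <- phase + cumsum(c_eff / 2) / cfg$fs
      w <- phi %% 1
      d <- pmin(cfg$double_support * c_eff / 2, 0.2)
      share[idx] <- load_share(w, d)
      u_l <- pmin(w / 0.55, 1)
      u_r <- pmin(((w + 0.5) %% 1) / 0.55, 1)
      ly[idx] <- e_eff * (u_l - 0.5)
      ry[idx] <- e_eff * (u_r - 0.5)
      ml_amp <- cfg$ml_sway * if (seg$kind == "turn") 2 else 1
      lx[idx] <- -cfg$foot_offset + ml_amp * sin(2 * pi * w)
      rx[idx] <- cfg$foot_offset + ml_amp * sin(2 * pi * w + pi)
      phase <- phi[length(phi)]
      if (seg$kind == "turn") events <- c(events, list(c("TURN", t0, t1)))
    } else if (seg$kind == "stand") {
      share[idx] <- 0.5
      ph1 <- stats::runif(1, 0, 2 * pi)
      ph2 <- stats::runif(1, 0, 2 * pi)
      ly[idx] <- 4 * sin(2 * pi * 0.4 * tt + ph1)
      ry[idx] <- 4 * sin(2 * pi * 0.4 * tt + ph1 + 0.3)
      lx[idx] <- -cfg$foot_offset + 2 * sin(2 * pi * 0.3 * tt + ph2)
      rx[idx] <- cfg$foot_offset + 2 * sin(2 * pi * 0.3 * tt + ph2 + pi)
      phase <- 0
      events <- c(events, list(c("STAND", t0, t1)))
    } else {                    # fog
      share[idx] <- 0.5
      if (seg$phenotype == "trembling") {
        osc <- sin(2 * pi * cfg$tremble_freq * (tt - t0))
        osc90 <- cos(2 * pi * cfg$tremble_freq * (tt - t0))
        ly[idx] <- cfg$tremble_amp * osc
        ry[idx] <- cfg$tremble_amp * 0.9 * osc
        lx[idx] <- -cfg$foot_offset + 0.5 * cfg$tremble_amp * osc90
        rx[idx] <- cfg$foot_offset - 0.5 * cfg$tremble_amp * osc90
      } else {                  # akinetic: static loaded COP
        ly[idx] <- 0
        ry[idx] <- 0
        lx[idx] <- -cfg$foot_offset
        rx[idx] <- cfg$foot_offset
      }
      phase <- 0
      events <- c(events, list(c("FOG", t0, t1)))
      truth[[length(truth) + 1L]] <- data.frame(
        start = t0, end = t1, phenotype = seg$phenotype)
    }
    t0 <- t1
  }
  ## residual swing load keeps the swing foot below the 5% validity rule
  s <- cfg$swing_residual + (1 - 2 * cfg$swing_residual) * share
  w_tot <- cfg$force_scale + stats::rnorm(n, 0, cfg$force_noise)
  l_force <- pmax(w_tot * s + stats::rnorm(n, 0, cfg$force_noise), 0)
  r_force <- pmax(w_tot * (1 - s) + stats::rnorm(n, 0, cfg$force_noise), 0)
  lx <- lx + stats::rnorm(n, 0, cfg$cop_noise)
  ly <- ly + stats::rnorm(n, 0, cfg$cop_noise)
  rx <- rx + stats::rnorm(n, 0, cfg$cop_noise)
  ry <- ry + stats::rnorm(n, 0, cfg$cop_noise)
  mask <- validity_mask(l_force, r_force)
  ev <- if (length(events)) {
    fog_events(kind = vapply(events, `[`, character(1), 1),
               start = as.numeric(vapply(events, `[`, character(1), 2)),
               end = as.numeric(vapply(events, `[`, character(1), 3)))
  } else {
    fog_events()
  }
  trial <- fog_trial(participant_id, trial_id, times,
                     left = list(force = l_force, cop_x = lx, cop_y = ly,
                                 valid = mask$left),
                     right = list(force = r_force, cop_x = rx, cop_y = ry,
                                  valid = mask$right),
                     events = ev, fs = cfg$fs, pre_fog = cfg$pre_fog)
  episodes <- if (length(truth)) {
    do.call(rbind, truth)
  } else {
    data.frame(start = numeric(), end = numeric(), phenotype = character())
  }
  list(trial = trial, truth = episodes)
}

#' Simulate a cohort of participants
#'
#' Per-participant gait parameters are jittered around the template config
#' (cadence, AP excursion, trembling frequency/amplitude, episode rate);
#' non-freezers get an episode rate of 0. Every freezer's first trial carries
#' at least one episode so the freezer/non-freezer split is exact. All
#' randomness derives from `seed` through per-participant and per-trial
#' sub-seeds.
#'
#' @param n_freezers,n_nonfreezers cohort composition.
#' @param trials_per_participant walking trials per participant.
#' @param cfg template [sim_config()].
#' @param seed integer root seed.
#' @param name dataset name.
#' @param dir optional directory; when given, trials and a cohort manifest are
#'   written there via [write_cohort()].
#' @return a `fog_dataset`.
#' @export
simulate_cohort <- function(n_freezers = 7, n_nonfreezers = 4,
                            trials_per_participant = 10, cfg = sim_config(),
                            seed = 1, name = "synthetic", dir = NULL) {
  n_total <- n_freezers + n_nonfreezers
  participants <- vector("list", n_total)
  for (p in seq_len(n_total)) {
    pseed <- sim_seed(seed, p)
    set.seed(pseed)
    freezer <- p <= n_freezers
    pcfg <- cfg
    pcfg$cadence <- max(cfg$cadence + stats::rnorm(1, 0, 0.15), 1.0)
    pcfg$ap_excursion <- max(cfg$ap_excursion + stats::rnorm(1, 0, 15), 60)
    pcfg$tremble_freq <- sample(4:7, 1)
    pcfg$tremble_amp <- max(cfg$tremble_amp + stats::rnorm(1, 0, 1.5), 3)
    pcfg$episode_rate <- if (freezer) {
      max(cfg$episode_rate + stats::rnorm(1, 0, 0.4), 0.4)
    } else {
      0
    }
    id <- sprintf("S%02d", p)
    trials <- lapply(seq_len(trials_per_participant), function(tr) {
      tseed <- sim_seed(pseed, tr)
      n_ep <- NULL
      if (freezer && tr == 1L) {
        set.seed(tseed)
        n_ep <- max(1L, stats::rpois(1, pcfg$episode_rate))
      }
      simulate_trial(pcfg, seed = tseed, participant_id = id,
                     trial_id = sprintf("T%02d", tr), n_episodes = n_ep)$trial
    })
    set.seed(pseed)
    participants[[p]] <- fog_participant(
      id, trials,
      age = round(stats::rnorm(1, 72, 6)),
      years_since_diagnosis = round(max(stats::rnorm(1, 10, 5), 1)),
      nfogq = if (freezer) round(stats::runif(1, 10, 28)) else round(stats::runif(1, 2, 10)),
      updrs3 = round(stats::runif(1, 6, 30)))
  }
  ds <- fog_dataset(name, participants)
  if (!is.null(dir)) write_cohort(ds, dir)
  ds
}

#' Project a signal-form trial onto a pressure-sensel grid
#'
#' Distributes each frame's foot force over a rectangular sensel grid by
#' bilinear weighting within the grid cell containing the COP, so that
#' [compute_cop()] recovers the intended COP (to well under 0.1 mm). The COP
#' must lie inside the sensel hull.
#'
#' @param trial a signal-form `fog_trial`.
#' @param sensel_x,sensel_y sorted vectors of sensel grid coordinates (mm);
#'   the grid is their Cartesian product.
#' @return a grid-form `fog_trial`.
#' @export
emit_grid <- function(trial, sensel_x = c(-90, 0, 90), sensel_y = c(-120, 0, 120)) {
  grid <- expand.grid(x = sensel_x, y = sensel_y)
  sides <- lapply(list(trial$left, trial$right), function(side) {
    press <- matrix(0, length(side$force), nrow(grid))
    for (i in seq_along(side$force)) {
      f <- side$force[i]
      if (f <= 0) next
      press[i, ] <- bilinear_frame(side$cop_x[i], side$cop_y[i], f,
                                   sensel_x, sensel_y, grid)
    }
    list(pressure = press, sensel_x = grid$x, sensel_y = grid$y)
  })
  fog_trial(trial$participant_id, trial$trial_id, trial$times,
            left = sides[[1]], right = sides[[2]],
            events = trial$events, fs = trial$fs)
}

bilinear_frame <- function(cx, cy, f, xs, ys, grid) {
  if (length(xs) == 1L && length(ys) == 1L) {
    out <- numeric(nrow(grid)); out[1] <- f
    return(out)
  }
  if (cx < min(xs) || cx > max(xs) || cy < min(ys) || cy > max(ys)) {
    stop(sprintf("COP (%.1f, %.1f) outside sensel hull", cx, cy))
  }
  ix <- max(1L, min(findInterval(cx, xs), length(xs) - 1L))
  iy <- max(1L, min(findInterval(cy, ys), length(ys) - 1L))
  tx <- if (length(xs) > 1L) (cx - xs[ix]) / (xs[ix + 1L] - xs[ix]) else 0
  ty <- if (length(ys) > 1L) (cy - ys[iy]) / (ys[iy + 1L] - ys[iy]) else 0
  out <- numeric(nrow(grid))
  put <- function(xi, yi, wgt) {
    k <- which(grid$x == xs[xi] & grid$y == ys[yi])
    out[k] <<- out[k] + f * wgt
  }
  put(ix, iy, (1 - tx) * (1 - ty))
  put(min(ix + 1L, length(xs)), iy, tx * (1 - ty))
  put(ix, min(iy + 1L, length(ys)), (1 - tx) * ty)
  put(min(ix + 1L, length(xs)), min(iy + 1L, length(ys)), tx * ty)
  out
}
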