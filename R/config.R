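#' Pipeline configuration
#'
#' Bundles every numeric constant of the pipeline so a run is fully auditable.
#' The defaults are the protocol values: 1 s windows shifted by 0.2 s, a 2 s
#' pre-FOG precursor, the 5% force-validity rule, MTDs from 3 consecutive
#' target windows, a 6 s initial prediction target zone with a 1 s delay after
#' turn/stand events, a 2.5 s no-cue interval, a 1 s gait-initiation grace
#' period, and a 100-tree RUSBoost ensemble of 5-split trees.
#'
#' @param window window length (s).
#' @param shift window start step (s).
#' @param pre_fog pre-FOG precursor length (s).
#' @param validity_threshold foot-force fraction for COP validity.
#' @param mtd_run_len consecutive target windows per MTD.
#' @param target_zone initial prediction-zone length (s).
#' @param post_event_delay zone delay after turn/stand events (s).
#' @param no_cue refractory interval between kept MTDs (s).
#' @param gait_init grace period after standing (s).
#' @param n_learners,max_splits,sampling_ratio,learn_rate,score_threshold
#'   ensemble parameters (see [fit_rusboost()]).
#' @param reversal_delta AP reversal hysteresis (mm).
#' @param wavelet_level wavelet decomposition depth.
#' @param seed default root seed.
#' @return named list of class `fog_config`.
#' @export
fog_config <- function(window = 1.0, shift = 0.2, pre_fog = 2.0,
                       validity_threshold = 0.05, mtd_run_len = 3,
                       target_zone = 6.0, post_event_delay = 1.0,
                       no_cue = 2.5, gait_init = 1.0,
                       n_learners = 100, max_splits = 5, sampling_ratio = 1,
                       learn_rate = 0.1, score_threshold = 0.5,
                       reversal_delta = 1.0, wavelet_level = 4, seed = 1) {
  cfg <- list(window = window, shift = shift, pre_fog = pre_fog,
              validity_threshold = validity_threshold,
              mtd_run_len = mtd_run_len, target_zone = target_zone,
              post_event_delay = post_event_delay, no_cue = no_cue,
              gait_init = gait_init, n_learners = n_learners,
              max_splits = max_splits, sampling_ratio = sampling_ratio,
              learn_rate = learn_rate, score_threshold = score_threshold,
              reversal_delta = reversal_delta, wavelet_level = wavelet_level,
              seed = seed)
  stopifnot(all(vapply(cfg[c("window", "shift", "pre_fog", "target_zone",
                             "post_event_delay", "no_cue", "gait_init")],
                       function(x) x > 0, logical(1))))
  structure(cfg, class = c("fog_config", "list"))
}
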