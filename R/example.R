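#' A compact example study with known ground truth
#'
#' Returns a ready-to-run scaled-down study: an 8-channel, 250 Hz, 2-s-epoch
#' two-group design (12 responders, 9 non-responders, 3 sessions, both
#' states, 24-30 epochs per recording) with the two canonical injected
#' effects - alpha-band connectivity that decreases from week 1 to week 12
#' in responders and increases in non-responders, and coarse-scale
#' complexity that drops early (baseline to week 1) in responders but not in
#' non-responders - plus an [analysis_config()] with grids matched to the
#' reduced design. Useful for examples, tests and pipeline validation;
#' substitute [cohort_design()] defaults for a full-size cohort.
#'
#' @param n_per_group Group sizes.
#' @param epochs_range Epochs per recording.
#' @param n_perm,n_boot Resampling sizes for the bundled config.
#' @param seed Base seed.
#' @return List with `design`, `effects`, `config`.
#' @export
example_study <- function(n_per_group = c(responder = 12, nonresponder = 9),
                          epochs_range = c(24, 30),
                          n_perm = 200, n_boot = 200, seed = 1L) {
  channels <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")
  design <- cohort_design(
    n_per_group = n_per_group,
    epochs_range = epochs_range,
    sampling_rate = 250,
    epoch_length = 2,
    channel_labels = channels,
    seed = seed
  )
  alpha_pairs <- tibble::tibble(
    chan_a = c("F3", "F4", "F3", "C3", "F4", "F3"),
    chan_b = c("C3", "C4", "F4", "C4", "C3", "C4")
  )
  effects <- list(
    effect_spec(
      "wpli", band = c(8, 12), pairs = alpha_pairs,
      profile = list(
        responder = c(baseline = 0.08, week1 = 0.25, week12 = 0.03),
        nonresponder = c(baseline = 0.08, week1 = 0.03, week12 = 0.25)
      ),
      phase_lag = pi / 2, states = "EC"
    ),
    effect_spec(
      "mse", band = c(5, 10), channels = c("P3", "P4", "O1", "O2"),
      states = "EO",
      profile = list(
        responder = c(baseline = 0.4, week1 = 0, week12 = 0),
        nonresponder = c(baseline = 0.4, week1 = 0.4, week12 = 0)
      )
    )
  )
  config <- analysis_config(
    fourier = fourier_grid(2, 20, 0.5),
    morlet = morlet_grid(6, 14, 1),
    mse = mse_params(max_scale = 10),
    rating_bands = list(alpha = c(8, 12), beta = NULL),
    n_perm = n_perm, n_boot = n_boot, seed = seed
  )
  list(design = design, effects = effects, config = config)
}
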