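#' Cohort design for the synthetic EEG generator
#'
#' Describes a two-group longitudinal resting-state EEG study: group sizes,
#' assessment sessions, recording states, epoch counts, montage, sampling and
#' an age covariate model. Defaults mirror a 25/18 responder/non-responder
#' cohort recorded in eyes-closed and eyes-open states at baseline and after
#' 1 and 12 weeks of treatment: 28 channels, 500 Hz, 2-s epochs, 63-113
#' artifact-free epochs per recording, responders on average younger.
#'
#' @param n_per_group Named integer vector of group sizes (each >= 2).
#' @param sessions Ordered session labels.
#' @param states Recording-state labels.
#' @param epochs_range Integer range; epoch counts per recording are drawn
#'   uniformly from it.
#' @param sampling_rate Hz.
#' @param epoch_length Seconds; `sampling_rate * epoch_length` must be a
#'   whole number of samples.
#' @param channel_labels Montage labels (no duplicates).
#' @param age_model Named list (per group) of `c(mean =, sd =)` for the age
#'   covariate; draws are truncated to 18-65 years.
#' @param seed Integer seed for [generate_cohort()].
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = c(responder = 25, nonresponder = 18),
                          sessions = c("baseline", "week1", "week12"),
                          states = c("EC", "EO"),
                          epochs_range = c(63, 113),
                          sampling_rate = 500,
                          epoch_length = 2,
                          channel_labels = default_montage(),
                          age_model = list(responder = c(mean = 35, sd = 10),
                                           nonresponder = c(mean = 45, sd = 10)),
                          seed = 1L) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 2),
            !is.null(names(n_per_group)))
  n_samp <- sampling_rate * epoch_length
  if (abs(n_samp - round(n_samp)) > 1e-9 || n_samp < 8) {
    stop("sampling_rate * epoch_length must be a whole sample count",
         call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("duplicate channel labels", call. = FALSE)
  }
  stopifnot(all(names(n_per_group) %in% names(age_model)),
            length(epochs_range) == 2, epochs_range[1] <= epochs_range[2])
  structure(
    list(n_per_group = n_per_group, sessions = sessions, states = states,
         epochs_range = as.integer(epochs_range),
         sampling_rate = sampling_rate, epoch_length = epoch_length,
         n_samples = as.integer(round(n_samp)),
         channel_labels = channel_labels, age_model = age_model,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Injectable group-by-session effect
#'
#' Specifies ground-truth structure for the generator. For `"wpli"` effects,
#' target channel pairs share a band-limited oscillator with a nonzero phase
#' lag; the (group, session) profile scales the coupling strength. For
#' `"mse"` effects, the profile shifts the 1/f-vs-white noise mixture of the
#' target channels (more 1/f raises coarse-scale entropy).
#'
#' @param feature_kind `"wpli"` or `"mse"`.
#' @param band For wpli: frequency band `c(lo, hi)` in Hz (the oscillator sits
#'   at the band centre). For mse: target timescale range (bookkeeping only).
#' @param pairs For wpli: tibble/data.frame with `chan_a`, `chan_b`.
#' @param channels For mse: character vector of target channels.
#' @param profile Named list: one named numeric vector of effect magnitudes
#'   per group, names = sessions.
#' @param phase_lag Radians, for wpli couplings; must not be 0 mod pi.
#' @param osc_spacing Frequency spacing (Hz) of the shared oscillators laid
#'   across a wpli effect's band.
#' @param states Recording states the effect applies to (`NULL` = all);
#'   state-specific effects mirror designs where connectivity and
#'   complexity changes are expressed most strongly in different states.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(feature_kind = c("wpli", "mse"), band = NULL,
                        pairs = NULL, channels = NULL, profile,
                        phase_lag = pi / 2, osc_spacing = 0.5,
                        states = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (feature_kind == "wpli") {
    stopifnot(!is.null(band), !is.null(pairs))
    lag_mod <- abs(phase_lag %% pi)
    if (min(lag_mod, pi - lag_mod) < 1e-6) {
      stop("phase_lag must avoid 0 and pi (zero-lag coupling is invisible to WPLI)",
           call. = FALSE)
    }
  } else {
    stopifnot(!is.null(channels))
  }
  stopifnot(all(vapply(profile, function(p) all(is.finite(p)), logical(1))))
  structure(list(feature_kind = feature_kind, band = band, pairs = pairs,
                 channels = channels, profile = profile,
                 phase_lag = phase_lag, osc_spacing = osc_spacing,
                 states = states),
            class = "effect_spec")
}

#' Synthesize one EEG-like epoch
#'
#' Each channel is a sum of shared sinusoids (one per oscillator, with a
#' random per-epoch base phase common to the oscillator's channels and
#' channel-specific phase offsets; coupling strength scales the shared
#' amplitude), independent 1/f noise and independent white noise, plus an
#' optional common zero-lag source on all channels (a volume-conduction
#' stressor that WPLI should ignore).
#'
#' @param spec List with `n_channels`; optional `oscillators` (list of lists
#'   with `freq` (Hz), `strength`, `channels` (indices), `offsets` (radians,
#'   same length), optional `amplitude`); optional per-channel `pink_weight` /
#'   `white_weight` vectors (recycled); optional scalar `common_zero_lag`.
#' @param n_samples Samples per epoch (>= 1).
#' @param sampling_rate Hz; oscillator frequencies must be below Nyquist.
#' @param seed Optional integer; given a seed the result is reproducible.
#' @return Numeric matrix `channels x samples`.
#' @export
synthesize_epoch <- function(spec, n_samples, sampling_rate, seed = NULL) {
  if (n_samples < 1) stop("zero-length epoch", call. = FALSE)
  with_seed(seed, {
    nc <- spec$n_channels
    t <- (seq_len(n_samples) - 1) / sampling_rate
    pw <- rep_len(spec$pink_weight %||% 0.5, nc)
    ww <- rep_len(spec$white_weight %||% 0.5, nc)
    out <- matrix(0, nc, n_samples)
    for (ch in seq_len(nc)) {
      out[ch, ] <- pw[ch] * pink_noise(n_samples) +
        ww[ch] * stats::rnorm(n_samples)
    }
    for (osc in spec$oscillators %||% list()) {
      if (osc$freq >= sampling_rate / 2) {
        stop("oscillator frequency at or above Nyquist", call. = FALSE)
      }
      amp <- (osc$amplitude %||% 1) * osc$strength
      if (amp == 0) next
      phase0 <- stats::runif(1, 0, 2 * pi)
      for (k in seq_along(osc$channels)) {
        ch <- osc$channels[k]
        out[ch, ] <- out[ch, ] +
          amp * sin(2 * pi * osc$freq * t + phase0 + osc$offsets[k])
      }
    }
    cz <- spec$common_zero_lag %||% 0
    if (cz > 0) {
      src <- pink_noise(n_samples)
      out <- out + matrix(cz * src, nc, n_samples, byrow = TRUE)
    }
    out
  })
}

#' 1/f ("pink") noise
#'
#' Spectrally shaped gaussian noise with power density proportional to 1/f,
#' standardized to zero mean and unit SD.
#'
#' @param n Length in samples.
#' @return Numeric vector.
#' @export
pink_noise <- function(n) {
  nfft <- stats::nextn(max(n, 2), 2)
  f <- stats::fft(stats::rnorm(nfft))
  k <- seq_len(nfft) - 1
  cyc <- pmin(k, nfft - k)                 # two-sided frequency index
  scale <- 1 / sqrt(pmax(cyc, 1))
  scale[1] <- 0                            # drop DC
  x <- Re(stats::fft(f * scale, inverse = TRUE))[seq_len(n)] / nfft
  (x - mean(x)) / sqrt(mean((x - mean(x))^2))
}

#' Generate a synthetic EEG cohort with known structure
#'
#' Produces one epoched recording per participant, session and state, with
#' the supplied effects applied according to each participant's assigned
#' profile. A `deviant_fraction` of participants per group is assigned the
#' opposite group's effect profile, emulating individuals who do not follow
#' their group's pattern; the returned ground truth records each
#' participant's intended pattern.
#'
#' @param design A [cohort_design()].
#' @param effects List of [effect_spec()] objects.
#' @param deviant_fraction Fraction (0-1) of each group assigned the opposite
#'   group's profile.
#' @param noise Base noise mixture, list with `pink` and `white` weights.
#' @param common_zero_lag Amplitude of an optional common zero-lag source.
#' @param seed Integer; defaults to `design$seed`.
#' @return A list of class `eeg_cohort`: `recordings` (tibble, one row per
#'   recording, epoch tensors in the `data` list-column), `ground_truth`
#'   (tibble with per-participant pattern labels), `design`, `effects`.
#' @export
generate_cohort <- function(design, effects = list(), deviant_fraction = 0,
                            noise = list(pink = 0.5, white = 0.5),
                            common_zero_lag = 0, seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(seed)) stop("a seed is required for reproducible generation",
                          call. = FALSE)
  for (ef in effects) validate_effect_targets(ef, design)
  groups <- names(design$n_per_group)
  with_seed(seed, {
    participants <- tibble::tibble(
      participant = unlist(lapply(groups, function(g) {
        sprintf("%s_%02d", substr(g, 1, 1), seq_len(design$n_per_group[[g]]))
      })),
      group = rep(groups, design$n_per_group)
    )
    participants$age <- vapply(participants$group, function(g) {
      am <- design$age_model[[g]]
      a <- stats::rnorm(1, am[["mean"]], am[["sd"]])
      while (a < 18 || a > 65) a <- stats::rnorm(1, am[["mean"]], am[["sd"]])
      a
    }, numeric(1))
    participants$profile_group <- participants$group
    for (g in groups) {
      in_g <- which(participants$group == g)
      n_dev <- round(deviant_fraction * length(in_g))
      if (n_dev > 0) {
        dev <- sample(in_g, n_dev)
        participants$profile_group[dev] <- setdiff(groups, g)
      }
    }

    rows <- list()
    for (i in seq_len(nrow(participants))) {
      p <- participants[i, ]
      for (sess in design$sessions) {
        for (st in design$states) {
          n_ep <- sample(seq(design$epochs_range[1], design$epochs_range[2]), 1)
          spec <- epoch_spec_for(design, effects, p$profile_group, sess, st,
                                 noise, common_zero_lag)
          dat <- array(0, dim = c(n_ep, length(design$channel_labels),
                                  design$n_samples))
          for (e in seq_len(n_ep)) {
            dat[e, , ] <- synthesize_epoch(spec, design$n_samples,
                                           design$sampling_rate)
          }
          rows[[length(rows) + 1]] <- tibble::tibble(
            participant = p$participant, group = p$group,
            profile_group = p$profile_group, session = sess, state = st,
            age = p$age, n_epochs = n_ep, data = list(dat),
            sampling_rate = design$sampling_rate
          )
        }
      }
    }
    ground_truth <- tibble::tibble(
      participant = participants$participant,
      group = participants$group,
      age = participants$age,
      pattern = ifelse(participants$profile_group == participants$group,
                       "own", "opposite"),
      profile_group = participants$profile_group
    )
    structure(
      list(recordings = dplyr::bind_rows(rows), ground_truth = ground_truth,
           design = design, effects = effects, seed = seed),
      class = "eeg_cohort"
    )
  })
}

# Build the per-epoch signal spec for one (profile_group, session) cell.
epoch_spec_for <- function(design, effects, profile_group, session, state,
                           noise, common_zero_lag) {
  nc <- length(design$channel_labels)
  pink_w <- rep(noise$pink, nc)
  white_w <- rep(noise$white, nc)
  oscillators <- list()
  for (ef in effects) {
    if (!is.null(ef$states) && !(state %in% ef$states)) next
    mag <- ef$profile[[profile_group]][[session]]
    if (ef$feature_kind == "wpli") {
      if (mag == 0) next
      # band-limited coupling: each pair shares one oscillator per grid step
      # across the band, so the effect spans it like real narrow-band rhythms
      freqs <- seq(ef$band[1], ef$band[2], by = ef$osc_spacing %||% 0.5)
      for (r in seq_len(nrow(ef$pairs))) {
        ia <- match(ef$pairs$chan_a[r], design$channel_labels)
        ib <- match(ef$pairs$chan_b[r], design$channel_labels)
        for (fq in freqs) {
          oscillators[[length(oscillators) + 1]] <- list(
            freq = fq, strength = mag,
            channels = c(ia, ib), offsets = c(0, ef$phase_lag)
          )
        }
      }
    } else {
      idx <- match(ef$channels, design$channel_labels)
      pink_w[idx] <- pmin(pmax(pink_w[idx] + mag, 0.02), 2)
      white_w[idx] <- pmin(pmax(white_w[idx] - mag, 0.02), 2)
    }
  }
  list(n_channels = nc, oscillators = oscillators, pink_weight = pink_w,
       white_weight = white_w, common_zero_lag = common_zero_lag)
}

validate_effect_targets <- function(ef, design) {
  if (ef$feature_kind == "wpli") {
    chans <- unique(c(ef$pairs$chan_a, ef$pairs$chan_b))
  } else {
    chans <- ef$channels
  }
  missing <- setdiff(chans, design$channel_labels)
  if (length(missing)) {
    stop("effect targets unknown channels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  missing_sess <- setdiff(design$sessions,
                          unique(unlist(lapply(ef$profile, names))))
  if (length(missing_sess)) {
    stop("effect profile missing sessions: ",
         paste(missing_sess, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat("<eeg_cohort> ", nrow(x$ground_truth), " participants, ",
      nrow(x$recordings), " recordings (",
      length(x$design$sessions), " sessions x ",
      length(x$design$states), " states)\n", sep = "")
  invisible(x)
}

# Evaluate code with a temporarily fixed RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
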