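#' Across-epoch cross-spectra by tapered Fourier transform
#'
#' Extracts complex Fourier coefficients per epoch and channel on a 0.5
#' Hz-spaced grid and forms cross-spectra for every channel pair. Bins at or
#' below the grid's Hanning boundary use a single Hanning taper (one
#' observation per epoch); higher bins use dpss multitapers with 2 Hz
#' smoothing (one observation per epoch and taper, 7 tapers for 2-s epochs).
#'
#' @param data Numeric array `epochs x channels x samples`.
#' @param sampling_rate Sampling rate in Hz.
#' @param grid A [fourier_grid()].
#' @param channel_labels Optional channel labels; defaults to `ch1..chn`.
#' @return A `cross_spectra` object: complex array `values`
#'   (`obs x freq x pair`), logical `valid` mask (`obs x freq`), the grid,
#'   the pair table and an observation-info tibble.
#' @export
fourier_cross_spectra <- function(data, sampling_rate, grid = fourier_grid(),
                                  channel_labels = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (any(!is.finite(data))) stop("non-finite samples in input", call. = FALSE)
  n_epoch <- dim(data)[1]
  n_chan <- dim(data)[2]
  n_samp <- dim(data)[3]
  t_len <- n_samp / sampling_rate
  freq <- grid$freq
  if (max(freq) >= sampling_rate / 2) {
    stop("grid extends to or beyond Nyquist", call. = FALSE)
  }
  bin_idx <- freq * t_len + 1
  if (any(abs(bin_idx - round(bin_idx)) > 1e-8)) {
    stop("epoch length does not support the requested grid spacing",
         call. = FALSE)
  }
  bin_idx <- as.integer(round(bin_idx))
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n_chan))
  pairs <- enumerate_pairs(channel_labels)
  n_pair <- nrow(pairs)

  is_dpss <- grid$taper == "dpss"
  smoothing <- attr(grid, "smoothing") %||% 2
  nw <- smoothing * t_len
  k_tap <- max(1L, as.integer(2 * nw - 1))
  han <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_samp) - 1) / (n_samp - 1))
  tapers_all <- cbind(han / sqrt(sum(han^2)),
                      if (any(is_dpss)) dpss_tapers(n_samp, nw, k_tap))
  n_tap_tot <- ncol(tapers_all)

  n_obs <- n_epoch * n_tap_tot
  values <- array(complex(real = NA_real_), dim = c(n_obs, length(freq), n_pair))
  valid <- matrix(FALSE, n_obs, length(freq))
  obs_info <- tibble::tibble(
    epoch = rep(seq_len(n_epoch), each = n_tap_tot),
    taper = rep(c("hanning", if (n_tap_tot > 1) paste0("dpss", seq_len(k_tap))),
                times = n_epoch)
  )

  ia <- pairs$idx_a
  ib <- pairs$idx_b
  for (e in seq_len(n_epoch)) {
    x <- t(data[e, , , drop = TRUE])        # samples x channels
    if (n_chan == 1) x <- matrix(x, ncol = 1)
    for (tp in seq_len(n_tap_tot)) {
      obs <- (e - 1) * n_tap_tot + tp
      coefs <- stats::mvfft(x * tapers_all[, tp])[bin_idx, , drop = FALSE]
      values[obs, , ] <- coefs[, ia, drop = FALSE] *
        Conj(coefs[, ib, drop = FALSE])
      if (tp == 1) valid[obs, !is_dpss] <- TRUE else valid[obs, is_dpss] <- TRUE
    }
  }
  new_cross_spectra(values, valid, grid, pairs, obs_info, kind = "epoch_taper")
}

new_cross_spectra <- function(values, valid, grid, pairs, obs_info, kind) {
  structure(
    list(values = values, valid = valid, grid = grid, pairs = pairs,
         obs_info = obs_info, kind = kind),
    class = "cross_spectra"
  )
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat("<cross_spectra> ", dim(x$values)[1], " obs x ", nrow(x$grid),
      " freq x ", nrow(x$pairs), " pairs (", x$kind, ")\n", sep = "")
  invisible(x)
}

#' Weighted phase lag index from a cross-spectrum set
#'
#' For each frequency and channel pair, WPLI = |sum Im(X)| / sum |Im(X)| over
#' valid observations. Phase differences concentrated away from 0/pi give
#' values near 1; inconsistent or zero-lag coupling gives values near 0. When
#' the denominator is exactly zero (all observations purely real, e.g.
#' zero-lag coupling) the value is set to 0 and flagged.
#'
#' @param cs A `cross_spectra` object.
#' @param meta Optional named list of metadata carried into the result.
#' @return A `connectivity_matrix`: `values` and logical `flagged` matrices
#'   (`freq x pair`), the grid, pair table and metadata.
#' @export
wpli_from_cross_spectra <- function(cs, meta = list()) {
  stopifnot(inherits(cs, "cross_spectra"))
  n_freq <- nrow(cs$grid)
  n_pair <- nrow(cs$pairs)
  if (dim(cs$values)[1] == 0) stop("empty observation set", call. = FALSE)
  vals <- matrix(0, n_freq, n_pair)
  flagged <- matrix(FALSE, n_freq, n_pair)
  im <- Im(cs$values)
  for (f in seq_len(n_freq)) {
    ok <- which(cs$valid[, f])
    if (length(ok) == 0) {
      flagged[f, ] <- TRUE
      next
    }
    imf <- matrix(im[ok, f, ], nrow = length(ok), ncol = n_pair)
    num <- abs(colSums(imf))
    den <- colSums(abs(imf))
    zero <- den == 0
    vals[f, ] <- ifelse(zero, 0, num / ifelse(zero, 1, den))
    flagged[f, ] <- zero
  }
  new_connectivity_matrix(vals, flagged, cs$grid, cs$pairs, meta)
}

new_connectivity_matrix <- function(values, flagged, grid, pairs, meta) {
  structure(
    list(values = values, flagged = flagged, grid = grid, pairs = pairs,
         meta = meta),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x$grid), " freq x ", nrow(x$pairs),
      " pairs; ", sum(x$flagged), " flagged\n", sep = "")
  invisible(x)
}

#' Across-epoch WPLI for one recording
#'
#' Convenience wrapper: tapered Fourier cross-spectra pooled over epochs (and
#' tapers), then [wpli_from_cross_spectra()].
#'
#' @inheritParams fourier_cross_spectra
#' @param meta Metadata list stored in the result.
#' @return A `connectivity_matrix`.
#' @export
wpli_across_epochs <- function(data, sampling_rate, grid = fourier_grid(),
                               channel_labels = NULL, meta = list()) {
  cs <- fourier_cross_spectra(data, sampling_rate, grid, channel_labels)
  wpli_from_cross_spectra(cs, meta = meta)
}

#' Morlet wavelet cross-spectra within one epoch
#'
#' Convolves each channel with complex Morlet wavelets (cycle count rising
#' linearly across the grid, 3 cycles at 4 Hz to 7 at 50 Hz by default) and
#' forms per-time-point cross-spectra. Time points within half the wavelet
#' support (3 gaussian SDs) of either epoch edge are masked invalid for that
#' frequency.
#'
#' @param epoch Numeric matrix `channels x samples`.
#' @param sampling_rate Hz.
#' @param grid A [morlet_grid()].
#' @param channel_labels Optional labels.
#' @return A `cross_spectra` object with observations = time points.
#' @export
morlet_cross_spectra <- function(epoch, sampling_rate, grid = morlet_grid(),
                                 channel_labels = NULL) {
  stopifnot(is.matrix(epoch))
  if (any(!is.finite(epoch))) stop("non-finite samples in input", call. = FALSE)
  n_chan <- nrow(epoch)
  n_samp <- ncol(epoch)
  freq <- grid$freq
  if (max(freq) >= sampling_rate / 2) {
    stop("grid extends to or beyond Nyquist", call. = FALSE)
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n_chan))
  pairs <- enumerate_pairs(channel_labels)
  n_pair <- nrow(pairs)

  values <- array(complex(real = 0), dim = c(n_samp, length(freq), n_pair))
  valid <- matrix(FALSE, n_samp, length(freq))
  ia <- pairs$idx_a
  ib <- pairs$idx_b

  for (f in seq_along(freq)) {
    w <- morlet_wavelet(freq[f], grid$cycles[f], sampling_rate)
    h <- (length(w) - 1L) %/% 2L
    if (2 * h + 1 > n_samp) {
      stop("epoch shorter than the wavelet at ", freq[f], " Hz", call. = FALSE)
    }
    coefs <- matrix(complex(real = 0), n_samp, n_chan)
    for (ch in seq_len(n_chan)) {
      coefs[, ch] <- conv_same_complex(epoch[ch, ], w)
    }
    values[, f, ] <- coefs[, ia, drop = FALSE] * Conj(coefs[, ib, drop = FALSE])
    mask_n <- min(h, n_samp)
    ok <- rep(TRUE, n_samp)
    ok[seq_len(mask_n)] <- FALSE
    ok[n_samp - seq_len(mask_n) + 1L] <- FALSE
    valid[, f] <- ok
  }
  obs_info <- tibble::tibble(time = (seq_len(n_samp) - 1) / sampling_rate)
  new_cross_spectra(values, valid, grid, pairs, obs_info, kind = "time_point")
}

# Complex Morlet wavelet truncated at +/- 3 gaussian SDs, unit energy.
morlet_wavelet <- function(freq, cycles, sampling_rate) {
  sigma_t <- cycles / (2 * pi * freq)
  h <- ceiling(3 * sigma_t * sampling_rate)
  t <- (-h:h) / sampling_rate
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# 'same'-mode complex convolution via FFT.
conv_same_complex <- function(x, w) {
  n <- length(x)
  h <- (length(w) - 1L) %/% 2L
  nfft <- stats::nextn(n + length(w) - 1L, 2)
  fx <- stats::fft(c(x, rep(0, nfft - n)))
  fw <- stats::fft(c(w, rep(complex(real = 0), nfft - length(w))))
  conv <- stats::fft(fx * fw, inverse = TRUE) / nfft
  conv[(h + 1L):(h + n)]
}

#' Single-epoch WPLI for one recording
#'
#' Applies the within-epoch Morlet estimator to every epoch and returns one
#' connectivity matrix per epoch plus their across-epoch average (used to
#' confirm the single-epoch estimator reproduces group-level results).
#'
#' @param data Numeric array `epochs x channels x samples`.
#' @param sampling_rate Hz.
#' @param grid A [morlet_grid()].
#' @param channel_labels Optional labels.
#' @param meta Metadata list.
#' @return List with `per_epoch` (list of `connectivity_matrix`) and
#'   `average` (`connectivity_matrix`, mean over epochs).
#' @export
wpli_single_epoch <- function(data, sampling_rate, grid = morlet_grid(),
                              channel_labels = NULL, meta = list()) {
  stopifnot(length(dim(data)) == 3)
  n_epoch <- dim(data)[1]
  per_epoch <- vector("list", n_epoch)
  acc <- NULL
  for (e in seq_len(n_epoch)) {
    ep <- data[e, , , drop = TRUE]
    if (is.null(dim(ep))) ep <- matrix(ep, nrow = dim(data)[2])
    cs <- morlet_cross_spectra(ep, sampling_rate, grid, channel_labels)
    cm <- wpli_from_cross_spectra(cs, meta = c(meta, list(epoch = e)))
    per_epoch[[e]] <- cm
    acc <- if (is.null(acc)) cm$values else acc + cm$values
  }
  avg <- new_connectivity_matrix(
    acc / n_epoch,
    Reduce(`|`, lapply(per_epoch, function(m) m$flagged)),
    per_epoch[[1]]$grid, per_epoch[[1]]$pairs,
    c(meta, list(estimator = "morlet_average"))
  )
  list(per_epoch = per_epoch, average = avg)
}

#' Tidy a connectivity matrix into long format
#'
#' @param x A `connectivity_matrix`.
#' @param ... Unused.
#' @return Tibble with `freq`, `chan_a`, `chan_b`, `wpli`, `flagged`.
#' @method tidy connectivity_matrix
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  tibble::tibble(
    freq = rep(x$grid$freq, times = nrow(x$pairs)),
    chan_a = rep(x$pairs$chan_a, each = nrow(x$grid)),
    chan_b = rep(x$pairs$chan_b, each = nrow(x$grid)),
    wpli = as.vector(x$values),
    flagged = as.vector(x$flagged)
  )
}

#' Heatmap of a connectivity matrix
#'
#' @param object A `connectivity_matrix`.
#' @param ... Unused.
#' @return A ggplot: channel pairs by frequency, fill = WPLI.
#' @method autoplot connectivity_matrix
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  d <- tidy(object)
  d$pair <- paste(d$chan_a, d$chan_b, sep = "-")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$pair,
                                  fill = .data$wpli)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Channel pair", fill = "WPLI")
}
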