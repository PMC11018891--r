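#' Default 28-channel resting-state montage
#'
#' Channel labels of the 10-20 montage used throughout the package defaults.
#'
#' @return Character vector of 28 channel labels.
#' @export
default_montage <- function() {
  c(
    "Fp1", "Fp2", "F3", "F4", "F7", "F8", "FC1", "FC2", "FC5", "FC6",
    "C3", "C4", "CP1", "CP2", "CP5", "CP6", "P3", "P4", "P7", "P8",
    "T7", "T8", "O1", "O2", "Fz", "Cz", "Pz", "Oz"
  )
}

#' Enumerate unordered channel pairs
#'
#' All unique unordered pairs of a channel montage, ordered lexicographically
#' by (first index, second index). A 28-channel montage yields 378 pairs.
#'
#' @param channel_labels Character vector of unique channel labels.
#' @return A tibble with one row per pair: `pair` (index), `chan_a`, `chan_b`,
#'   `idx_a`, `idx_b` (indices into `channel_labels`, `idx_a < idx_b`).
#' @export
#' @examples
#' nrow(enumerate_pairs(default_montage())) # 378
enumerate_pairs <- function(channel_labels) {
  if (length(channel_labels) < 2) {
    stop("need at least 2 channel labels", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("duplicate channel labels", call. = FALSE)
  }
  n <- length(channel_labels)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # upper.tri ordering is column-major; reorder to row-major (lexicographic)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  tibble::tibble(
    pair = seq_len(nrow(idx)),
    chan_a = channel_labels[idx[, 1L]],
    chan_b = channel_labels[idx[, 2L]],
    idx_a = as.integer(idx[, 1L]),
    idx_b = as.integer(idx[, 2L])
  )
}

#' Frequency grids for the WPLI estimators
#'
#' `fourier_grid()` builds the across-epoch estimator grid: 0.5 Hz-spaced bins
#' (default 1-50 Hz, 99 bins) with a Hanning taper at low frequencies and
#' dpss multitapers (2 Hz half-bandwidth, 7 tapers for 2-s epochs) at high
#' frequencies. `morlet_grid()` builds the within-epoch estimator grid
#' (default 4-50 Hz) with wavelet cycle counts increasing linearly from 3
#' cycles at 4 Hz to 7 cycles at 50 Hz.
#'
#' @param fmin,fmax Grid limits in Hz.
#' @param step Bin spacing in Hz.
#' @param hanning_max Highest frequency (Hz) analysed with the single Hanning
#'   taper; bins above it use dpss multitapers.
#' @param smoothing Multitaper half-bandwidth in Hz.
#' @return A tibble with class `"freq_grid"`: columns `freq` and, depending on
#'   method, `taper` (`"hanning"`/`"dpss"`) or `cycles`; attributes `method`
#'   and (fourier) `smoothing`.
#' @export
fourier_grid <- function(fmin = 1, fmax = 50, step = 0.5,
                         hanning_max = 30.5, smoothing = 2) {
  freq <- seq(fmin, fmax, by = step)
  stopifnot(length(freq) >= 1, all(diff(freq) > 0))
  g <- tibble::tibble(
    freq = freq,
    taper = ifelse(freq <= hanning_max, "hanning", "dpss")
  )
  structure(g, method = "fourier", smoothing = smoothing,
            class = c("freq_grid", class(g)))
}

#' @rdname fourier_grid
#' @param cycles_from,cycles_to Wavelet cycle counts at `cycle_fmin` and
#'   `cycle_fmax`; interpolated linearly in between.
#' @param cycle_fmin,cycle_fmax Frequencies (Hz) anchoring the cycle ramp.
#' @export
morlet_grid <- function(fmin = 4, fmax = 50, step = 0.5,
                        cycles_from = 3, cycles_to = 7,
                        cycle_fmin = 4, cycle_fmax = 50) {
  if (fmin < cycle_fmin) {
    stop("morlet grid frequencies below ", cycle_fmin,
         " Hz are not supported", call. = FALSE)
  }
  freq <- seq(fmin, fmax, by = step)
  cycles <- cycles_from +
    (cycles_to - cycles_from) * (freq - cycle_fmin) / (cycle_fmax - cycle_fmin)
  g <- tibble::tibble(freq = freq, cycles = cycles)
  structure(g, method = "morlet", class = c("freq_grid", class(g)))
}

grid_method <- function(grid) attr(grid, "method") %||% "fourier"

`%||%` <- function(a, b) if (is.null(a)) b else a
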