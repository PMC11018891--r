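#' Multiscale entropy parameters
#'
#' @param m Template length (default 2).
#' @param r_fraction Similarity criterion as a fraction of the scale-1 series'
#'   standard deviation (default 0.5). The absolute tolerance is fixed per
#'   epoch and channel and reused at every scale.
#' @param max_scale Coarsest timescale (default 20; 40 ms resolution at
#'   500 Hz).
#' @param min_points Minimum coarse-grained series length (default 50).
#' @return A list of class `mse_params`.
#' @export
mse_params <- function(m = 2, r_fraction = 0.5, max_scale = 20,
                       min_points = 50) {
  stopifnot(m >= 1, r_fraction > 0, max_scale >= 1, min_points >= m + 2)
  structure(list(m = as.integer(m), r_fraction = r_fraction,
                 max_scale = as.integer(max_scale),
                 min_points = as.integer(min_points)),
            class = "mse_params")
}

#' Coarse-grain a time series
#'
#' Averages non-overlapping blocks of `scale` consecutive samples; trailing
#' remainder samples are discarded. Scale 1 returns the series unchanged.
#'
#' @param series Numeric vector.
#' @param scale Integer scale factor >= 1.
#' @return Numeric vector of length `floor(length(series) / scale)`.
#' @export
#' @examples
#' coarse_grain(c(1, 3, 5, 7), 2) # c(2, 6)
coarse_grain <- function(series, scale) {
  scale <- as.integer(scale)
  stopifnot(scale >= 1)
  n <- length(series)
  if (scale > n) stop("scale exceeds series length", call. = FALSE)
  if (scale == 1L) return(series)
  n_out <- n %/% scale
  colMeans(matrix(series[seq_len(n_out * scale)], nrow = scale))
}

#' Sample entropy of a series
#'
#' SampEn(m, r) = -ln(A / B), where B counts template pairs of length `m`
#' within Chebyshev distance `r` (self-matches excluded) and A the same for
#' length `m + 1`. Undefined (returned as `NA`) when either count is zero.
#'
#' @param series Numeric vector, length >= m + 2.
#' @param m Template length.
#' @param r Absolute similarity tolerance (> 0).
#' @return Non-negative scalar, or `NA_real_` when undefined.
#' @export
sample_entropy <- function(series, m = 2, r) {
  if (r <= 0) stop("r must be positive", call. = FALSE)
  if (length(series) < m + 2) stop("series shorter than m + 2", call. = FALSE)
  cnt <- sampen_counts_cpp(as.numeric(series), as.integer(m), r)
  if (cnt[1] == 0 || cnt[2] == 0) return(NA_real_)
  -log(cnt[1] / cnt[2])
}

#' Multiscale entropy for one recording
#'
#' Computes sample entropy for every epoch, channel and timescale. The
#' tolerance r is `r_fraction` times the population SD of each epoch and
#' channel's scale-1 (raw) series and is held fixed across scales. Per-epoch
#' matrices are averaged over epochs, ignoring undefined (masked) entries.
#'
#' @param data Numeric array `epochs x channels x samples`.
#' @param params An [mse_params()] object.
#' @param channel_labels Optional channel labels.
#' @param meta Metadata list stored in results.
#' @return List with `per_epoch` (list of `mse_matrix`) and `average`
#'   (`mse_matrix`; mask true where all epochs were undefined).
#' @export
mse_for_recording <- function(data, params = mse_params(),
                              channel_labels = NULL, meta = list()) {
  stopifnot(length(dim(data)) == 3)
  n_epoch <- dim(data)[1]
  n_chan <- dim(data)[2]
  n_samp <- dim(data)[3]
  if (n_samp %/% params$max_scale < params$min_points) {
    stop("epoch too short: scale ", params$max_scale, " leaves fewer than ",
         params$min_points, " points", call. = FALSE)
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n_chan))
  per_epoch <- vector("list", n_epoch)
  for (e in seq_len(n_epoch)) {
    vals <- matrix(NA_real_, n_chan, params$max_scale,
                   dimnames = list(channel_labels, NULL))
    for (ch in seq_len(n_chan)) {
      x <- data[e, ch, ]
      sdx <- sqrt(mean((x - mean(x))^2))
      if (sdx == 0) next
      r <- params$r_fraction * sdx
      for (s in seq_len(params$max_scale)) {
        vals[ch, s] <- sample_entropy(coarse_grain(x, s), params$m, r)
      }
    }
    per_epoch[[e]] <- new_mse_matrix(vals, is.na(vals), channel_labels,
                                     c(meta, list(epoch = e)))
  }
  stack <- array(unlist(lapply(per_epoch, function(m) m$values)),
                 dim = c(n_chan, params$max_scale, n_epoch))
  avg <- apply(stack, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  dimnames(avg) <- list(channel_labels, NULL)
  list(
    per_epoch = per_epoch,
    average = new_mse_matrix(avg, is.na(avg), channel_labels,
                             c(meta, list(epoch = "averaged")))
  )
}

new_mse_matrix <- function(values, mask, channel_labels, meta) {
  structure(list(values = values, mask = mask,
                 channel_labels = channel_labels, meta = meta),
            class = "mse_matrix")
}

#' @export
print.mse_matrix <- function(x, ...) {
  cat("<mse_matrix> ", nrow(x$values), " channels x ", ncol(x$values),
      " scales; ", sum(x$mask), " undefined\n", sep = "")
  invisible(x)
}

#' Tidy an MSE matrix into long format
#'
#' @param x An `mse_matrix`.
#' @param ... Unused.
#' @return Tibble with `channel`, `scale`, `sampen`, `undefined`.
#' @method tidy mse_matrix
#' @export
tidy.mse_matrix <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channel_labels, times = ncol(x$values)),
    scale = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    sampen = as.vector(x$values),
    undefined = as.vector(x$mask)
  )
}

#' MSE curves per channel
#'
#' @param object An `mse_matrix`.
#' @param ... Unused.
#' @return A ggplot of sample entropy against timescale, one line per channel.
#' @method autoplot mse_matrix
#' @export
autoplot.mse_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scale, y = .data$sampen,
                                  group = .data$channel,
                                  colour = .data$channel)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Timescale", y = "Sample entropy", colour = "Channel")
}
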