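#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` dpss tapers of length `n` with time-half-bandwidth
#' product `nw`, via the symmetric tridiagonal eigenproblem whose eigenvectors
#' are the Slepian sequences. Tapers are unit-energy; even-order tapers are
#' oriented to have positive mean, odd-order ones a positive leading lobe.
#'
#' For the default across-epoch WPLI settings (2-s epochs, 2 Hz smoothing)
#' `nw = 4` and `k = 2 * nw - 1 = 7`.
#'
#' @param n Taper length in samples.
#' @param nw Time-half-bandwidth product (T times W).
#' @param k Number of tapers to return.
#' @return An `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 4, k = 7) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  key <- paste(n, nw, k, sep = "_")
  cached <- .dpss_cache[[key]]
  if (!is.null(cached)) return(cached)
  w <- nw / n
  t <- seq_len(n) - 1
  dg <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- t[-1] * (n - t[-1]) / 2
  m <- diag(dg)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- od
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- od
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) v[, j] <- -v[, j]
    } else if (v[2, j] - v[1, j] < 0) {
      v[, j] <- -v[, j]
    }
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
  }
  .dpss_cache[[key]] <- v
  v
}

.dpss_cache <- new.env(parent = emptyenv())
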