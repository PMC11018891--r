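# Independent oracles, written as literal transcriptions of the defining
# formulas. They deliberately share no code with the package internals.

# Brute-force sample entropy: direct template-pair counting.
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0
  B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Literal WPLI formula over a vector of imaginary cross-spectrum values.
oracle_wpli <- function(im) abs(sum(im)) / sum(abs(im))

# Singular values and right singular vectors from an eigen-decomposition of
# the cross-product matrix.
oracle_svd <- function(x) {
  e <- eigen(crossprod(x), symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  list(d = sqrt(pmax(e$values, 0)), v = e$vectors, keep = keep)
}

# Build a cross_spectra object holding given imaginary parts (one frequency,
# one pair) without going through any estimator.
cs_from_im <- function(im, re = rep(0, length(im))) {
  vals <- array(complex(real = re, imaginary = im),
                dim = c(length(im), 1, 1))
  eegpls:::new_cross_spectra(
    values = vals,
    valid = matrix(TRUE, length(im), 1),
    grid = fourier_grid(10, 10),
    pairs = enumerate_pairs(c("a", "b")),
    obs_info = tibble::tibble(epoch = seq_along(im)),
    kind = "epoch_taper"
  )
}

# Bare feature_matrix builder for PLS-level tests.
make_group_fm <- function(n_per_group = c(8, 8), n_feat = 50, effect = 0,
                          effect_cols = seq_len(min(10, n_feat)),
                          sessions = c("baseline", "week1", "week12"),
                          groups = c("responder", "nonresponder"),
                          seed = 1, ages = NULL) {
  set.seed(seed)
  n <- sum(n_per_group)
  rows <- expand.grid(session = sessions,
                      participant = sprintf("p%02d", seq_len(n)),
                      stringsAsFactors = FALSE)
  rows$group <- rep(rep(groups, n_per_group), each = length(sessions))
  vals <- matrix(rnorm(nrow(rows) * n_feat), nrow(rows), n_feat)
  if (effect != 0) {
    sgn_s <- ifelse(rows$session == "week1", 1,
                    ifelse(rows$session == "week12", -1, 0))
    sgn_g <- ifelse(rows$group == groups[1], 1, -1)
    vals[, effect_cols] <- vals[, effect_cols] + effect * sgn_s * sgn_g
  }
  meta <- tibble::tibble(
    group = rows$group, participant = rows$participant,
    session = rows$session, condition = rows$session
  )
  if (!is.null(ages)) meta$age <- ages[match(meta$participant,
                                             sprintf("p%02d", seq_len(n)))]
  eegpls:::new_feature_matrix(
    vals, meta,
    tibble::tibble(kind = "sim", label = paste0("f", seq_len(n_feat))),
    "group-level"
  )
}

# Single-participant (epochs x sessions) feature matrix.
make_individual_fm <- function(epochs_per_session = c(20, 20, 20),
                               n_feat = 40, effect = 0,
                               effect_cols = seq_len(min(8, n_feat)),
                               sessions = c("baseline", "week1", "week12"),
                               seed = 1) {
  set.seed(seed)
  sess <- rep(sessions, epochs_per_session)
  vals <- matrix(rnorm(length(sess) * n_feat), length(sess), n_feat)
  if (effect != 0) {
    sgn <- ifelse(sess == "week1", 1, ifelse(sess == "week12", -1, 0))
    vals[, effect_cols] <- vals[, effect_cols] + effect * sgn
  }
  eegpls:::new_feature_matrix(
    vals,
    tibble::tibble(group = "self", participant = "self", session = sess,
                   condition = sess,
                   epoch = unlist(lapply(epochs_per_session, seq_len))),
    tibble::tibble(kind = "sim", label = paste0("f", seq_len(n_feat))),
    "single-participant"
  )
}

# Two-channel epoched recording with a fixed 10 Hz pi/2-lag coupling.
coupled_recording <- function(n_epochs, strength = 1, noise = 0,
                              fs = 250, n_samp = 500, seed = 1) {
  set.seed(seed)
  dat <- array(0, dim = c(n_epochs, 2, n_samp))
  t <- (seq_len(n_samp) - 1) / fs
  for (e in seq_len(n_epochs)) {
    p0 <- runif(1, 0, 2 * pi)
    dat[e, 1, ] <- strength * sin(2 * pi * 10 * t + p0) +
      noise * rnorm(n_samp)
    dat[e, 2, ] <- strength * sin(2 * pi * 10 * t + p0 + pi / 2) +
      noise * rnorm(n_samp)
  }
  dat
}
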