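two_group_design <- function(n = c(responder = 2, nonresponder = 2),
                             epochs = c(3, 3), seed = 1) {
  cohort_design(
    n_per_group = n, epochs_range = epochs, sampling_rate = 125,
    epoch_length = 2, channel_labels = c("F3", "F4", "P3", "P4"),
    seed = seed
  )
}

test_that("epoch synthesis is deterministic and respects its contract", {
  spec <- list(
    n_channels = 2,
    oscillators = list(list(freq = 12.5, strength = 1, channels = c(1, 2),
                            offsets = c(0, pi / 2))),
    pink_weight = 0, white_weight = 0
  )
  a <- synthesize_epoch(spec, 500, 250, seed = 4)
  b <- synthesize_epoch(spec, 500, 250, seed = 4)
  expect_identical(a, b)
  # noiseless shared oscillator: phase difference is constantly pi/2,
  # i.e. channel 2 is the quarter-period (5-sample) advance of channel 1
  expect_equal(dim(a), c(2, 500))
  shift <- 250 / 12.5 / 4
  expect_equal(a[2, 1:(500 - shift)], a[1, (shift + 1):500],
               tolerance = 1e-10)
  expect_error(synthesize_epoch(spec, 0, 250), "zero-length")
  spec$oscillators[[1]]$freq <- 200
  expect_error(synthesize_epoch(spec, 500, 250), "Nyquist")
})

test_that("uncoupled channels show near-zero across-epoch WPLI", {
  spec <- list(n_channels = 2, oscillators = list(),
               pink_weight = 0.5, white_weight = 0.5)
  dat <- array(0, dim = c(60, 2, 250))
  set.seed(9)
  for (e in 1:60) dat[e, , ] <- synthesize_epoch(spec, 250, 125)
  cm <- wpli_across_epochs(dat, 125, fourier_grid(2, 30))
  expect_lt(mean(cm$values), 0.25)
})

test_that("cohort generation is deterministic with full bookkeeping", {
  d <- two_group_design()
  c1 <- generate_cohort(d, seed = 5)
  c2 <- generate_cohort(d, seed = 5)
  expect_identical(c1$recordings$data, c2$recordings$data)
  expect_identical(c1$ground_truth, c2$ground_truth)
  # 4 participants x 3 sessions x 2 states
  expect_equal(nrow(c1$recordings), 24)
  expect_true(all(c1$ground_truth$age >= 18 & c1$ground_truth$age <= 65))
  expect_true(all(c1$ground_truth$pattern == "own"))
  expect_error(generate_cohort(d, seed = NULL), "seed")
})

test_that("deviant fraction flags the seeded share of each group", {
  d <- cohort_design(
    n_per_group = c(responder = 20, nonresponder = 4),
    epochs_range = c(2, 2), sampling_rate = 125, epoch_length = 2,
    channel_labels = c("F3", "F4"), sessions = "baseline", states = "EC",
    seed = 2
  )
  co <- generate_cohort(d, deviant_fraction = 0.5, seed = 3)
  gt <- co$ground_truth
  expect_equal(sum(gt$pattern == "opposite" & gt$group == "responder"), 10)
  expect_equal(sum(gt$pattern == "opposite" & gt$group == "nonresponder"), 2)
})

test_that("coupling strength raises WPLI monotonically at the target band", {
  d <- two_group_design(epochs = c(25, 25), seed = 7)
  wpli_at_10 <- vapply(c(0.02, 0.08, 0.3), function(s) {
    ef <- effect_spec(
      "wpli", band = c(10, 10),
      pairs = tibble::tibble(chan_a = "F3", chan_b = "F4"),
      profile = list(responder = c(baseline = s, week1 = s, week12 = s),
                     nonresponder = c(baseline = s, week1 = s, week12 = s))
    )
    co <- generate_cohort(d, list(ef), seed = 21)
    recs <- co$recordings[co$recordings$state == "EC" &
                            co$recordings$session == "baseline", ]
    g <- fourier_grid(8, 12)
    mean(vapply(seq_len(nrow(recs)), function(i) {
      cm <- wpli_across_epochs(recs$data[[i]], 125, g, d$channel_labels)
      cm$values[g$freq == 10, cm$pairs$chan_a == "F3" &
                  cm$pairs$chan_b == "F4"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(wpli_at_10) > 0))
})

test_that("white-noise fraction trades fine-scale for coarse-scale entropy", {
  set.seed(31)
  n <- 2000
  white <- rnorm(n)
  pinkish <- pink_noise(n)
  r_w <- 0.5 * sd(white) * sqrt((n - 1) / n)
  r_p <- 0.5 * sd(pinkish) * sqrt((n - 1) / n)
  s1_white <- sample_entropy(coarse_grain(white, 1), 2, r_w)
  s20_white <- sample_entropy(coarse_grain(white, 20), 2, r_w)
  s1_pink <- sample_entropy(coarse_grain(pinkish, 1), 2, r_p)
  s20_pink <- sample_entropy(coarse_grain(pinkish, 20), 2, r_p)
  expect_gt(s1_white, s1_pink)   # white noise most irregular at scale 1
  expect_gt(s20_pink, s20_white) # 1/f retains coarse-scale irregularity
})
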