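# Minimal fitted-LV stand-ins for deterministic similarity tests.
fake_lv <- function(v, bsr, p = 0.01, contrast = pls_contrast(c(0, 1, -1)),
                    condition_means = NULL, cols = NULL) {
  p_feat <- length(v)
  structure(
    list(d = sqrt(sum(v^2)), u = contrast$unit, v = v, p = p, bsr = bsr,
         se = rep(1, p_feat),
         condition_means = condition_means %||%
           matrix(0, length(contrast$unit), p_feat),
         cols = cols %||% tibble::tibble(kind = "sim",
                                         label = paste0("f", seq_len(p_feat))),
         contrast = contrast,
         conditions = paste0("c", seq_along(contrast$unit)),
         settings = list()),
    class = "nonrotated_pls"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group pattern extraction masks by |BSR| with nesting", {
  v <- rnorm(150)
  bsr <- c(rep(5, 100), rep(0, 50))
  lv <- fake_lv(v, bsr)
  pat <- extract_group_pattern(lv, bsr_threshold = 2)
  expect_equal(sum(pat$mask), 100)
  expect_equal(pat$loadings, v[1:100])
  bsr2 <- c(rep(5, 40), rep(2.5, 60), rep(0, 50))
  pat2 <- extract_group_pattern(fake_lv(v, bsr2), bsr_threshold = 2)
  pat31 <- extract_group_pattern(fake_lv(v, bsr2), bsr_threshold = 3.1)
  expect_true(all(which(pat31$mask) %in% which(pat2$mask)))
  expect_error(extract_group_pattern(fake_lv(v, rep(1, 150))),
               "fewer than 10")
})

test_that("individual assessment categorizes correlations per the cutoffs", {
  set.seed(3)
  v_group <- rnorm(80)
  bsr <- c(rep(4, 50), rep(0, 30))
  pattern <- extract_group_pattern(fake_lv(v_group, bsr))
  # identical loadings: r = 1
  rec <- assess_individual(fake_lv(v_group, bsr), pattern)
  expect_equal(rec$r, 1)
  expect_equal(rec$category, "moderate_strong")
  # negated loadings: r = -1
  rec_neg <- assess_individual(fake_lv(-v_group, bsr), pattern)
  expect_equal(rec_neg$r, -1)
  expect_equal(rec_neg$category, "negative")
  # non-significant individuals are excluded, r absent
  rec_ns <- assess_individual(fake_lv(v_group, bsr, p = 0.2), pattern)
  expect_true(is.na(rec_ns$r))
  expect_equal(rec_ns$category, "negligible_or_none")
  # contrast mismatch (opposite direction saliences) excludes too
  flipped <- fake_lv(v_group, bsr, contrast = pls_contrast(c(0, -1, 1)))
  rec_fl <- assess_individual(flipped, pattern)
  expect_false(rec_fl$matched)
  expect_equal(rec_fl$category, "negligible_or_none")
})

test_that("the r = .4 boundary is inclusive for moderate-strong", {
  # construct loadings with exact target correlations against the pattern
  n <- 64
  za <- rep(c(1, -1), n / 2)
  zb <- rep(c(1, 1, -1, -1), n / 4) # orthogonal to za, both zero-mean
  bsr <- rep(4, n)
  pattern <- extract_group_pattern(fake_lv(za, bsr))
  mk_r <- function(r) r * za + sqrt(1 - r^2) * zb
  for (case in list(list(r = 0.45, cat = "moderate_strong"),
                    list(r = 0.2, cat = "weak_positive"),
                    list(r = 0, cat = "negligible_or_none"),
                    list(r = -0.3, cat = "negative"))) {
    rec <- assess_individual(fake_lv(mk_r(case$r), bsr), pattern)
    expect_equal(rec$r, case$r, tolerance = 1e-12)
    expect_equal(rec$category, case$cat)
  }
  # boundary semantics: r = .4 inclusive for moderate-strong, the .1
  # boundaries belong to negligible
  categorize <- eegpls:::similarity_category
  expect_equal(categorize(0.4), "moderate_strong")
  expect_equal(categorize(0.39999), "weak_positive")
  expect_equal(categorize(0.1), "negligible_or_none")
  expect_equal(categorize(-0.1), "negligible_or_none")
  expect_equal(categorize(-0.100001), "negative")
  expect_equal(categorize(NA_real_), "negligible_or_none")
  # invariance to positive rescaling of either vector
  rec_a <- assess_individual(fake_lv(5 * mk_r(0.5), bsr), pattern)
  expect_equal(rec_a$r, 0.5, tolerance = 1e-12)
})

test_that("rating rules read signed stable changes in their windows", {
  cols <- tibble::tibble(
    kind = "wpli",
    freq = rep(seq(6, 30, by = 2), times = 2),
    chan_a = rep(c("F3", "F4"), each = 13),
    chan_b = rep(c("C3", "C4"), each = 13),
    label = paste0("f", 1:26)
  )
  alpha_idx <- which(cols$freq >= 8 & cols$freq <= 14)
  beta_idx <- which(cols$freq >= 18 & cols$freq <= 30)
  mk <- function(alpha_change, beta_change) {
    cm <- matrix(0, 3, 26) # baseline, week1, week12
    cm[2, alpha_idx] <- alpha_change / 2
    cm[3, alpha_idx] <- -alpha_change / 2
    cm[2, beta_idx] <- beta_change / 2
    cm[3, beta_idx] <- -beta_change / 2
    bsr <- rep(0, 26)
    bsr[c(alpha_idx, beta_idx)] <- 4
    fake_lv(cm[2, ] - cm[3, ], bsr, condition_means = cm, cols = cols)
  }
  rules <- wpli_rating_rules("lv")
  # alpha decrease + beta increase: responder only
  r1 <- rule_based_rating(mk(1, -1), rules)
  expect_true(r1$fits_responder_rule)
  expect_false(r1$fits_nonresponder_rule)
  # alpha decrease + beta decrease: both patterns
  r2 <- rule_based_rating(mk(1, 1), rules)
  expect_true(r2$fits_responder_rule)
  expect_true(r2$fits_nonresponder_rule)
  # no stable change anywhere: neither
  r3 <- rule_based_rating(fake_lv(rep(0, 26), rep(0, 26),
                                  condition_means = matrix(0, 3, 26),
                                  cols = cols), rules)
  expect_false(r3$fits_responder_rule)
  expect_false(r3$fits_nonresponder_rule)
  # empty window errors
  bad <- wpli_rating_rules("lv", alpha = c(100, 110))
  expect_error(rule_based_rating(mk(1, 0), bad), "empty rule window")
})

test_that("cohort summaries partition into percentages", {
  recs <- tibble::tibble(
    participant = paste0("p", 1:4),
    group = c("responder", "responder", "nonresponder", "nonresponder"),
    p_value = 0.01, matched = TRUE,
    r = c(0.8, 0.2, 0.0, -0.5),
    category = c("moderate_strong", "weak_positive", "negligible_or_none",
                 "negative")
  )
  s <- summarize_cohort(recs)
  overall <- s[s$group == "overall", ]
  expect_equal(overall$pct, rep(25, 4))
  expect_equal(sum(overall$pct), 100, tolerance = 0.1)
  # all excluded
  recs2 <- recs
  recs2$category <- "negligible_or_none"
  s2 <- summarize_cohort(recs2)
  expect_equal(
    s2$pct[s2$group == "overall" & s2$category == "negligible_or_none"], 100
  )
  # rating scheme: own-vs-opposite split uses the group label
  recs$fits_responder_rule <- c(TRUE, TRUE, TRUE, FALSE)
  recs$fits_nonresponder_rule <- c(FALSE, TRUE, FALSE, FALSE)
  s3 <- summarize_cohort(recs)
  rat <- s3[s3$scheme == "rating" & s3$group == "overall", ]
  expect_equal(rat$n[rat$category == "own_only"], 1)     # p1
  expect_equal(rat$n[rat$category == "both"], 1)         # p2
  expect_equal(rat$n[rat$category == "opposite_only"], 1) # p3
  expect_equal(rat$n[rat$category == "neither"], 1)      # p4
})
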