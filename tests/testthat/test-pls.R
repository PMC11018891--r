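test_that("cell mean-centering matches hand arithmetic", {
  fm <- make_group_fm(c(2, 2), n_feat = 3, seed = 2)
  # overwrite feature 1 with cell-structured values: g1 cells 0, g2 cells 1
  fm$values[, 1] <- ifelse(fm$rows$group == "responder", 0, 1)
  mc <- mean_center_cells(fm)
  expect_equal(unname(mc$centered[, 1]),
               c(-0.5, -0.5, -0.5, 0.5, 0.5, 0.5))
  expect_equal(max(abs(colMeans(mc$centered))), 0, tolerance = 1e-12)
  # identical data in every cell: all-zero centered matrix
  fm$values <- matrix(rep(fm$values[1, ], each = nrow(fm$values)),
                      nrow(fm$values))
  expect_equal(max(abs(mean_center_cells(fm)$centered)), 0)
})

test_that("decomposition matches an independent eigen-decomposition oracle", {
  set.seed(4)
  for (k in 1:5) {
    x <- matrix(rnorm(9), 3, 3)
    fit <- pls_decompose(x)
    o <- oracle_svd(x)
    expect_equal(fit$d, o$d[1:3], tolerance = 1e-10)
    for (i in which(o$keep)) {
      expect_equal(abs(sum(fit$v[, i] * o$v[, i])), 1, tolerance = 1e-10)
    }
    expect_equal(sum(fit$pcce), 100, tolerance = 1e-10)
  }
})

test_that("a rank-one matrix yields one LV carrying all the covariance", {
  u0 <- c(2, -1, -1) / sqrt(6)
  v0 <- rnorm(30)
  v0 <- v0 / sqrt(sum(v0^2))
  fit <- pls_decompose(3.7 * outer(u0, v0))
  expect_equal(fit$d[1], 3.7, tolerance = 1e-10)
  expect_equal(fit$pcce[1], 100, tolerance = 1e-10)
  expect_equal(abs(sum(fit$u[, 1] * u0)), 1, tolerance = 1e-10)
  # sign convention: largest-magnitude salience is positive
  expect_gt(fit$u[which.max(abs(fit$u[, 1])), 1], 0)
})

test_that("LVs reconstruct the centered matrix and are orthogonal", {
  fm <- make_group_fm(c(5, 4), n_feat = 40, effect = 0.8, seed = 6)
  mc <- mean_center_cells(fm)
  fit <- pls_decompose(mc)
  recon <- fit$u %*% diag(fit$d) %*% t(fit$v)
  expect_equal(max(abs(recon - mc$centered)), 0, tolerance = 1e-10)
  expect_equal(crossprod(fit$u), diag(length(fit$d)), tolerance = 1e-10)
  expect_equal(crossprod(fit$v), diag(length(fit$d)), tolerance = 1e-10)
})

test_that("brain scores are the dot products with the singular image", {
  fm <- make_group_fm(c(2, 2), n_feat = 5, seed = 7)
  v <- c(0, 1, 0, 0, 0)
  sc <- brain_scores(v, fm)
  expect_equal(sc$score, fm$values[, 2])
  fm$values[3, ] <- 0
  expect_equal(brain_scores(rnorm(5), fm)$score[3], 0)
  expect_error(brain_scores(rnorm(4), fm), "dimension")
})

test_that("permutation p-values are deterministic and floor at 1/(n+1)", {
  fm <- make_group_fm(c(6, 6), n_feat = 30, effect = 2, seed = 8)
  p1 <- permutation_pvalues(fm, n_perm = 99, seed = 42)
  p2 <- permutation_pvalues(fm, n_perm = 99, seed = 42)
  expect_identical(p1, p2)
  expect_equal(p1$p[1], 1 / 100) # huge injected effect: minimum attainable
  fm0 <- make_group_fm(c(6, 6), n_feat = 30, effect = 0, seed = 9)
  p0 <- permutation_pvalues(fm0, n_perm = 99, seed = 43)
  expect_gt(p0$p[1], 0.05)
})

test_that("scaling the matrix scales singular values but not p or loadings", {
  fm <- make_group_fm(c(5, 5), n_feat = 25, effect = 1, seed = 10)
  fm2 <- fm
  fm2$values <- 3 * fm2$values
  r1 <- pls_group(fm, n_perm = 60, n_boot = 40, seed = 3)
  r2 <- pls_group(fm2, n_perm = 60, n_boot = 40, seed = 3)
  expect_equal(r2$fit$d, 3 * r1$fit$d, tolerance = 1e-10)
  # restrict to LVs with nonzero singular value (grand-mean centering makes
  # the last one a null-space vector with arbitrary basis)
  k <- which(r1$fit$d > 1e-8)
  expect_identical(r1$p[k], r2$p[k])
  sgn <- sign(colSums(r1$fit$v * r2$fit$v))
  expect_equal(sweep(r2$fit$v, 2, sgn, `*`)[, k], r1$fit$v[, k],
               tolerance = 1e-10)
  expect_equal(sign(r2$bsr[, 1] * sgn[1]), sign(r1$bsr[, 1]))
})

test_that("bootstrap ratios flag injected elements and shrink with n", {
  fm <- make_group_fm(c(8, 8), n_feat = 60, effect = 1.2,
                      effect_cols = 1:12, seed = 11)
  fit <- pls_decompose(mean_center_cells(fm))
  boot <- bootstrap_stability(fm, fit, n_boot = 100, seed = 5)
  expect_gte(mean(abs(boot$bsr[1:12, 1]) >= 3.1), 0.8)
  expect_lt(mean(abs(boot$bsr[13:60, 1]) >= 3.1), 0.05)
  boot2 <- bootstrap_stability(fm, fit, n_boot = 100, seed = 5)
  expect_identical(boot$bsr, boot2$bsr)
  # duplicated cohort: standard errors shrink, ratios grow
  dup <- fm
  dup$values <- rbind(fm$values, fm$values)
  dup$rows <- dplyr::bind_rows(fm$rows, dplyr::mutate(
    fm$rows, participant = paste0(participant, "b")
  ))
  dup <- eegpls:::new_feature_matrix(dup$values, dup$rows, fm$cols,
                                     fm$provenance)
  fit_d <- pls_decompose(mean_center_cells(dup))
  boot_d <- bootstrap_stability(dup, fit_d, n_boot = 100, seed = 5)
  expect_gt(median(abs(boot_d$bsr[1:12, 1])), median(abs(boot$bsr[1:12, 1])))
})

test_that("bootstrap replicate saliences align with the original", {
  fm <- make_group_fm(c(8, 8), n_feat = 60, effect = 2, seed = 12)
  res <- pls_group(fm, n_perm = 50, n_boot = 60, seed = 2)
  expect_gt(res$fit$pcce[1], 70)
  # stable injected pattern: tight brain-score CIs around separated means
  sm <- res$score_means[res$score_means$lv == 1, ]
  expect_true(all(sm$lower <= sm$mean_score & sm$mean_score <= sm$upper))
})

test_that("contrasts must be zero-sum and non-degenerate", {
  expect_error(pls_contrast(c(1, 1, -1)), "sum to zero")
  expect_error(pls_contrast(c(0, 0, 0)), "zero")
  ct <- pls_contrast(c(1, 1, -2))
  expect_equal(sum(ct$unit^2), 1)
})

test_that("non-rotated PLS reduces to the closed form for two conditions", {
  set.seed(14)
  sess <- rep(c("a", "b"), each = 25)
  vals <- matrix(rnorm(50 * 12), 50, 12)
  vals[sess == "a", 1:4] <- vals[sess == "a", 1:4] + 1.5
  fm <- eegpls:::new_feature_matrix(
    vals,
    tibble::tibble(group = "self", participant = "self", session = sess,
                   condition = sess, epoch = rep(1:25, 2)),
    tibble::tibble(kind = "sim", label = paste0("f", 1:12)),
    "single-participant"
  )
  lv <- nonrotated_pls(fm, pls_contrast(c(1, -1)), n_perm = 50, n_boot = 40,
                       seed = 6)
  md <- colMeans(vals[sess == "a", ]) - colMeans(vals[sess == "b", ])
  expect_equal(lv$d, sqrt(sum(md^2)) / sqrt(2), tolerance = 1e-10)
  expect_equal(lv$v, md / sqrt(sum(md^2)), tolerance = 1e-10)
})

test_that("non-rotated PLS finds an injected session change", {
  fm <- make_individual_fm(c(20, 20, 20), effect = 1.5, seed = 15)
  lv <- nonrotated_pls(fm, pls_contrast(c(0, 1, -1)), n_perm = 100,
                       n_boot = 60, seed = 7)
  expect_lt(lv$p, 0.05)
  # week1-high / week12-low injection with positive week-1 weight:
  # loadings at injected elements are positive
  expect_true(all(lv$v[1:8] > 0))
  expect_gt(min(abs(lv$bsr[1:8])), 2)
  # flat condition means: singular value near zero, p near 1
  fm0 <- make_individual_fm(c(20, 20, 20), effect = 0, seed = 16)
  lv0 <- nonrotated_pls(fm0, pls_contrast(c(0, 1, -1)), n_perm = 100,
                        n_boot = 40, seed = 8)
  expect_gt(lv0$p, 0.2)
  expect_lt(lv0$d, lv$d)
  lv0b <- nonrotated_pls(fm0, pls_contrast(c(0, 1, -1)), n_perm = 100,
                         n_boot = 40, seed = 8)
  expect_identical(lv0$v, lv0b$v)
  expect_identical(lv0$p, lv0b$p)
})

test_that("permutation p-values are calibrated on null data", {
  # reduced-size null calibration: rejection rate of LV1 near alpha
  set.seed(20)
  n_sim <- 60
  rej <- vapply(seq_len(n_sim), function(s) {
    fm <- make_group_fm(c(8, 8), n_feat = 50, effect = 0, seed = 1000 + s)
    permutation_pvalues(fm, n_perm = 60, seed = s)$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0)
  expect_lte(mean(rej), 0.15)
})
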