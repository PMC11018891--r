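#' Zero-sum condition contrast
#'
#' @param weights Numeric condition weights summing to zero, not all zero
#'   (e.g. `c(0, 1, -1)` for a week1-vs-week12 change).
#' @param conditions Optional condition labels (same length).
#' @return A list of class `pls_contrast` holding `raw` and `unit`
#'   (unit-norm) weights.
#' @export
pls_contrast <- function(weights, conditions = NULL) {
  if (abs(sum(weights)) > 1e-10) stop("contrast must sum to zero", call. = FALSE)
  if (all(weights == 0)) stop("contrast is all zero", call. = FALSE)
  if (!is.null(conditions)) stopifnot(length(conditions) == length(weights))
  structure(list(raw = weights, unit = weights / sqrt(sum(weights^2)),
                 conditions = conditions),
            class = "pls_contrast")
}

cell_mean_matrix <- function(values, group, condition, groups, conditions) {
  cells <- expand.grid(condition = conditions, group = groups,
                       stringsAsFactors = FALSE)[, c("group", "condition")]
  key <- paste(group, condition, sep = "\r")
  cell_key <- paste(cells$group, cells$condition, sep = "\r")
  counts <- table(key)[cell_key]
  if (anyNA(counts) || any(counts == 0)) stop("empty cell", call. = FALSE)
  sums <- rowsum(values, key)[cell_key, , drop = FALSE]
  list(means = sums / as.numeric(counts), cells = tibble::as_tibble(cells))
}

#' Mean-center the group-by-condition cell means
#'
#' Averages the feature matrix within each (group, condition) cell, then
#' subtracts, per feature, the unweighted grand mean of the cell means. This
#' centering exposes group, condition and interaction effects together in
#' the subsequent SVD.
#'
#' @param fm A `feature_matrix` whose rows carry `group` and `condition`.
#' @param groups,conditions Optional orderings; default to first appearance.
#' @return List: `centered` ((groups x conditions) x features matrix),
#'   `cells` (tibble), `grand` (subtracted per-feature means).
#' @export
mean_center_cells <- function(fm, groups = unique(fm$rows$group),
                              conditions = unique(fm$rows$condition)) {
  stopifnot(inherits(fm, "feature_matrix"))
  cm <- cell_mean_matrix(fm$values, fm$rows$group, fm$rows$condition,
                         groups, conditions)
  grand <- colMeans(cm$means)
  centered <- sweep(cm$means, 2, grand)
  list(centered = centered, cells = cm$cells, grand = grand)
}

#' Singular value decomposition into latent variables
#'
#' Decomposes a mean-centered cell matrix into latent variables (LVs), each a
#' triplet of singular value, design saliences (one weight per group x
#' condition cell) and element loadings (the singular image). LVs are ordered
#' by decreasing singular value; each LV's percentage of crossblock
#' covariance explained is `100 * s_i^2 / sum(s_j^2)`. Sign convention: the
#' largest-magnitude design salience of each LV is positive.
#'
#' @param centered Output of [mean_center_cells()], or a plain matrix.
#' @return A `pls_fit`: `u` (saliences), `d` (singular values), `v`
#'   (loadings), `pcce`, `cells`, `grand`.
#' @export
pls_decompose <- function(centered) {
  if (is.list(centered) && !is.null(centered$centered)) {
    cells <- centered$cells
    grand <- centered$grand
    x <- centered$centered
  } else {
    x <- centered
    cells <- tibble::tibble(cell = paste0("row", seq_len(nrow(x))))
    grand <- NULL
  }
  if (any(!is.finite(x))) stop("non-finite input", call. = FALSE)
  s <- svd(x)
  k <- length(s$d)
  for (i in seq_len(k)) {
    j <- which.max(abs(s$u[, i]))
    if (s$u[j, i] < 0) {
      s$u[, i] <- -s$u[, i]
      s$v[, i] <- -s$v[, i]
    }
  }
  tot <- sum(s$d^2)
  structure(
    list(u = s$u, d = s$d, v = s$v,
         pcce = if (tot > 0) 100 * s$d^2 / tot else rep(0, k),
         cells = cells, grand = grand),
    class = "pls_fit"
  )
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("<pls_fit> ", length(x$d), " LVs; singular values: ",
      paste(signif(head(x$d, 5), 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Brain scores: projection of observations on an LV's singular image
#'
#' @param v Loading vector (length = number of features), e.g. one column of
#'   a `pls_fit`'s `v`.
#' @param fm The `feature_matrix` whose rows are scored.
#' @return Tibble: row metadata plus `score` (dot product of the row with
#'   the loadings).
#' @export
brain_scores <- function(v, fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(v) != ncol(fm$values)) stop("dimension mismatch", call. = FALSE)
  out <- fm$rows
  out$score <- as.vector(fm$values %*% v)
  out
}

shuffle_rows <- function(rows) {
  # shuffle condition labels within every participant AND reassign
  # participants to groups preserving group sizes
  out <- rows
  for (p in unique(rows$participant)) {
    i <- which(rows$participant == p)
    out$condition[i] <- rows$condition[sample(i)]
  }
  ptab <- unique(rows[, c("participant", "group")])
  new_group <- ptab$group[sample(nrow(ptab))]
  out$group <- new_group[match(rows$participant, ptab$participant)]
  out
}

#' Permutation p-values for the latent variables
#'
#' Each permutation shuffles condition labels within every participant and
#' reassigns participants to groups (preserving group sizes), then repeats
#' the full mean-centering and SVD. The add-one estimator
#' `p_i = (1 + #(s_perm_i >= s_obs_i)) / (n_perm + 1)` is used, so p is
#' never zero.
#'
#' @param fm A group-level `feature_matrix`.
#' @param n_perm Number of permutations (default 500).
#' @param seed Integer seed.
#' @param groups,conditions Optional cell orderings.
#' @return List: `p` (per LV), `observed` singular values, `perm_d`
#'   (n_perm x k matrix of permuted singular values).
#' @export
permutation_pvalues <- function(fm, n_perm = 500, seed = 1,
                                groups = unique(fm$rows$group),
                                conditions = unique(fm$rows$condition)) {
  stopifnot(n_perm >= 1)
  sizes <- table(unique(fm$rows[, c("participant", "group")])$group)
  if (any(sizes < 2)) stop("each group needs >= 2 participants", call. = FALSE)
  obs <- pls_decompose(mean_center_cells(fm, groups, conditions))
  k <- length(obs$d)
  with_seed(seed, {
    perm_d <- matrix(NA_real_, n_perm, k)
    for (b in seq_len(n_perm)) {
      rows_p <- shuffle_rows(fm$rows)
      cm <- cell_mean_matrix(fm$values, rows_p$group, rows_p$condition,
                             groups, conditions)
      centered <- sweep(cm$means, 2, colMeans(cm$means))
      perm_d[b, ] <- svd(centered, nu = 0, nv = 0)$d[seq_len(k)]
    }
    p <- vapply(seq_len(k), function(i) {
      (1 + sum(perm_d[, i] >= obs$d[i])) / (n_perm + 1)
    }, numeric(1))
    list(p = p, observed = obs$d, perm_d = perm_d)
  })
}

procrustes_rotation <- function(u_rep, u_ref) {
  m <- crossprod(u_rep, u_ref)
  s <- svd(m)
  s$u %*% t(s$v)
}

#' Bootstrap stability: bootstrap ratios and brain-score CIs
#'
#' Participants are resampled with replacement within group (original group
#' sizes kept); each replicate is re-centered and re-decomposed, and its LVs
#' are aligned to the original by orthogonal Procrustes rotation of the
#' design saliences (resolving sign/order indeterminacy). The bootstrap
#' ratio of an element is its original loading divided by the bootstrap
#' standard error of the aligned replicate loadings; |BSR| >= 3.1
#' corresponds to roughly a 99 percent confidence interval, |BSR| > 2 to 95
#' percent. Condition-mean brain-score confidence intervals are the
#' 2.5/97.5 percentiles of the replicate condition means.
#'
#' @param fm A group-level `feature_matrix`.
#' @param fit The original `pls_fit`.
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @param groups,conditions Optional cell orderings.
#' @return List: `bsr` (features x LV matrix), `se`, `score_ci` (tibble of
#'   per-cell brain-score means and CIs per LV).
#' @export
bootstrap_stability <- function(fm, fit, n_boot = 200, seed = 1,
                                groups = unique(fm$rows$group),
                                conditions = unique(fm$rows$condition)) {
  stopifnot(n_boot >= 2)
  ptab <- unique(fm$rows[, c("participant", "group")])
  if (any(table(ptab$group) < 2)) {
    stop("each group needs >= 2 participants", call. = FALSE)
  }
  k <- length(fit$d)
  p_feat <- nrow(fit$v)
  cell_key <- paste(fit$cells$group, fit$cells$condition, sep = "\r")
  with_seed(seed, {
    v_reps <- array(NA_real_, c(p_feat, k, n_boot))
    score_reps <- array(NA_real_, c(nrow(fit$cells), k, n_boot))
    for (b in seq_len(n_boot)) {
      for (attempt in 1:10) {
        picked <- unlist(lapply(groups, function(g) {
          ids <- ptab$participant[ptab$group == g]
          sample(ids, length(ids), replace = TRUE)
        }))
        idx <- unlist(lapply(picked, function(id) {
          which(fm$rows$participant == id)
        }))
        vals <- fm$values[idx, , drop = FALSE]
        grp <- fm$rows$group[idx]
        cond <- fm$rows$condition[idx]
        ok <- tryCatch({
          cm <- cell_mean_matrix(vals, grp, cond, groups, conditions)
          TRUE
        }, error = function(e) FALSE)
        if (ok) break
        if (attempt == 10) stop("bootstrap replicate with empty cell",
                                call. = FALSE)
      }
      centered <- sweep(cm$means, 2, colMeans(cm$means))
      s <- svd(centered)
      kk <- min(k, length(s$d))
      rot <- procrustes_rotation(s$u[, seq_len(kk), drop = FALSE],
                                 fit$u[, seq_len(kk), drop = FALSE])
      v_reps[, seq_len(kk), b] <- s$v[, seq_len(kk), drop = FALSE] %*% rot
      # replicate brain scores on the resampled rows, per cell
      sc <- vals %*% (s$v[, seq_len(kk), drop = FALSE] %*% rot)
      key <- paste(grp, cond, sep = "\r")
      means <- rowsum(sc, key)[cell_key, , drop = FALSE] /
        as.numeric(table(key)[cell_key])
      score_reps[, seq_len(kk), b] <- means
    }
    se <- apply(v_reps, c(1, 2), stats::sd)
    bsr <- fit$v / ifelse(se == 0, NA_real_, se)
    obs_scores <- NULL
    score_ci <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      ci <- apply(score_reps[, i, , drop = FALSE], 1, stats::quantile,
                  probs = c(0.025, 0.975), na.rm = TRUE)
      tibble::tibble(
        lv = i, group = fit$cells$group, condition = fit$cells$condition,
        lower = ci[1, ], upper = ci[2, ]
      )
    }))
    list(bsr = bsr, se = se, score_ci = score_ci)
  })
}

#' Mean-centered task PLS with permutation and bootstrap inference
#'
#' One-call group analysis: cell-mean centering, SVD, permutation p-values,
#' bootstrap ratios and brain-score condition means with confidence
#' intervals.
#'
#' @inheritParams permutation_pvalues
#' @param n_boot Bootstrap replicates.
#' @param boot_seed,perm_seed Seeds for the two resampling stages (default
#'   derived from `seed`).
#' @param seed Base seed.
#' @return A `pls_result` object; see [tidy.pls_result()] and
#'   [glance.pls_result()].
#' @export
pls_group <- function(fm, n_perm = 500, n_boot = 200, seed = 1,
                      perm_seed = seed + 1L, boot_seed = seed + 2L,
                      groups = unique(fm$rows$group),
                      conditions = unique(fm$rows$condition)) {
  fit <- pls_decompose(mean_center_cells(fm, groups, conditions))
  perm <- permutation_pvalues(fm, n_perm, perm_seed, groups, conditions)
  boot <- bootstrap_stability(fm, fit, n_boot, boot_seed, groups, conditions)
  score_means <- dplyr::bind_rows(lapply(seq_along(fit$d), function(i) {
    sc <- brain_scores(fit$v[, i], fm)
    agg <- dplyr::summarise(
      dplyr::group_by(sc, .data$group, .data$condition),
      mean_score = mean(.data$score), .groups = "drop"
    )
    agg$lv <- i
    agg
  }))
  score_means <- dplyr::left_join(score_means, boot$score_ci,
                                  by = c("lv", "group", "condition"))
  structure(
    list(fit = fit, p = perm$p, perm = perm, bsr = boot$bsr, se = boot$se,
         score_means = score_means, fm_rows = fm$rows, cols = fm$cols,
         settings = list(n_perm = n_perm, n_boot = n_boot, seed = seed)),
    class = "pls_result"
  )
}

#' @export
print.pls_result <- function(x, ...) {
  cat("<pls_result> LVs:\n")
  print(glance(x))
  invisible(x)
}

#' Tidy latent-variable summaries
#'
#' @param x A `pls_result`.
#' @param ... Unused.
#' @return One row per LV: singular value, PCCE, permutation p.
#' @method tidy pls_result
#' @export
tidy.pls_result <- function(x, ...) {
  tibble::tibble(
    lv = seq_along(x$fit$d),
    singular_value = x$fit$d,
    pcce = x$fit$pcce,
    p_value = x$p
  )
}

#' @rdname tidy.pls_result
#' @method glance pls_result
#' @export
glance.pls_result <- function(x, ...) {
  tibble::tibble(
    n_lv = length(x$fit$d),
    lv1_singular_value = x$fit$d[1],
    lv1_pcce = x$fit$pcce[1],
    lv1_p = x$p[1],
    n_perm = x$settings$n_perm,
    n_boot = x$settings$n_boot
  )
}

#' Condition-mean brain scores with bootstrap CIs
#'
#' @param object A `pls_result`.
#' @param lv Which latent variable to plot.
#' @param ... Unused.
#' @return A ggplot of per-cell mean brain scores with 95 percent bootstrap
#'   intervals.
#' @method autoplot pls_result
#' @export
autoplot.pls_result <- function(object, lv = 1, ...) {
  d <- object$score_means[object$score_means$lv == lv, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$mean_score,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.2) +
    ggplot2::labs(x = "Condition", y = paste0("Brain score (LV", lv, ")"))
}

#' Non-rotated (contrast-driven) PLS
#'
#' Instead of estimating design saliences by SVD, a predefined zero-sum
#' contrast over conditions is applied: the element loadings are the
#' contrast-weighted sum of the grand-mean-centered condition means, the
#' singular value is their norm, and the design salience vector is the
#' unit-norm contrast. Significance comes from permuting condition labels
#' across observations (epochs are exchangeable under the null); stability
#' from bootstrap resampling of observations within condition.
#'
#' @param fm A `feature_matrix` (typically single-participant: rows =
#'   epochs, conditions = sessions).
#' @param contrast A [pls_contrast()] (length = number of conditions).
#' @param n_perm,n_boot Resampling sizes.
#' @param seed Base seed.
#' @param conditions Condition order; defaults to first appearance.
#' @return A `nonrotated_pls` object: `d` (singular value), `u` (unit
#'   contrast), `v` (unit loadings), `p`, `bsr`, `se`, `condition_means`
#'   (centered), `score_means`, `cols`, `contrast`.
#' @export
nonrotated_pls <- function(fm, contrast, n_perm = 500, n_boot = 200,
                           seed = 1, conditions = unique(fm$rows$condition)) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(contrast, "pls_contrast"))
  if (length(contrast$unit) != length(conditions)) {
    stop("contrast length does not match number of conditions", call. = FALSE)
  }
  cond <- factor(fm$rows$condition, levels = conditions)
  if (any(table(cond) < 2)) {
    stop("each condition needs >= 2 observations", call. = FALSE)
  }
  w <- contrast$unit
  stat <- function(values, cond_f) {
    cm <- rowsum(values, cond_f)[conditions, , drop = FALSE] /
      as.numeric(table(cond_f)[conditions])
    centered <- sweep(cm, 2, colMeans(cm))
    raw <- as.vector(t(centered) %*% w)
    list(d = sqrt(sum(raw^2)), raw = raw, centered = centered)
  }
  obs <- stat(fm$values, cond)
  v <- if (obs$d > 0) obs$raw / obs$d else obs$raw
  with_seed(seed, {
    perm_d <- vapply(seq_len(n_perm), function(b) {
      stat(fm$values, cond[sample(length(cond))])$d
    }, numeric(1))
    p <- (1 + sum(perm_d >= obs$d)) / (n_perm + 1)
    v_reps <- matrix(NA_real_, length(v), n_boot)
    score_reps <- matrix(NA_real_, length(conditions), n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(conditions, function(cc) {
        i <- which(cond == cc)
        sample(i, length(i), replace = TRUE)
      }))
      sb <- stat(fm$values[idx, , drop = FALSE], cond[idx])
      vb <- if (sb$d > 0) sb$raw / sb$d else sb$raw
      v_reps[, b] <- vb
      sc <- as.vector(fm$values[idx, , drop = FALSE] %*% vb)
      score_reps[, b] <- vapply(seq_along(conditions), function(ci) {
        mean(sc[cond[idx] == conditions[ci]])
      }, numeric(1))
    }
    se <- apply(v_reps, 1, stats::sd)
    bsr <- v / ifelse(se == 0, NA_real_, se)
    scores <- as.vector(fm$values %*% v)
    score_means <- tibble::tibble(
      condition = conditions,
      mean_score = vapply(conditions, function(cc) mean(scores[cond == cc]),
                          numeric(1)),
      lower = apply(score_reps, 1, stats::quantile, 0.025, na.rm = TRUE),
      upper = apply(score_reps, 1, stats::quantile, 0.975, na.rm = TRUE)
    )
    structure(
      list(d = obs$d, u = w, v = v, p = p, bsr = bsr, se = se,
           condition_means = obs$centered, score_means = score_means,
           cols = fm$cols, contrast = contrast, conditions = conditions,
           settings = list(n_perm = n_perm, n_boot = n_boot, seed = seed)),
      class = "nonrotated_pls"
    )
  })
}

#' @export
print.nonrotated_pls <- function(x, ...) {
  cat("<nonrotated_pls> contrast (", paste(x$contrast$raw, collapse = ", "),
      "); s = ", signif(x$d, 4), ", p = ", signif(x$p, 3), "\n", sep = "")
  invisible(x)
}

#' @method glance nonrotated_pls
#' @export
glance.nonrotated_pls <- function(x, ...) {
  tibble::tibble(singular_value = x$d, p_value = x$p,
                 n_perm = x$settings$n_perm, n_boot = x$settings$n_boot)
}
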