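#' Extract the stable group pattern from a fitted LV
#'
#' Restricts an LV's element loadings to the elements whose bootstrap ratio
#' exceeds a stability threshold (|BSR| > 2 by default, roughly a 95 percent
#' confidence interval). Individual analyses are later correlated with the
#' group loadings over exactly this mask.
#'
#' @param result A `pls_result` (group analysis) or `nonrotated_pls`.
#' @param lv LV index (for `pls_result`).
#' @param bsr_threshold Stability threshold on |BSR|.
#' @param contrast The [pls_contrast()] this pattern answers to (taken from
#'   the object when available).
#' @return A `group_pattern`: `loadings` (masked), `mask`, `cols`,
#'   `threshold`, `contrast`.
#' @export
extract_group_pattern <- function(result, lv = 1, bsr_threshold = 2,
                                  contrast = NULL) {
  if (inherits(result, "pls_result")) {
    v <- result$fit$v[, lv]
    bsr <- result$bsr[, lv]
    cols <- result$cols
    if (!is.null(contrast)) {
      u <- result$fit$u[, lv]
      # align the group loadings with the declared contrast (the SVD sign
      # convention is arbitrary with respect to it)
      if (length(u) == length(contrast$unit) &&
          sum(u * contrast$unit) < 0) {
        v <- -v
        bsr <- -bsr
      }
    }
  } else if (inherits(result, "nonrotated_pls")) {
    v <- result$v
    bsr <- result$bsr
    cols <- result$cols
    contrast <- contrast %||% result$contrast
  } else {
    stop("unsupported result object", call. = FALSE)
  }
  mask <- !is.na(bsr) & abs(bsr) > bsr_threshold
  if (sum(mask) < 10) {
    stop("fewer than 10 stable elements at |BSR| > ", bsr_threshold,
         call. = FALSE)
  }
  structure(
    list(loadings = v[mask], mask = mask, cols = cols,
         threshold = bsr_threshold, contrast = contrast, source_lv = lv),
    class = "group_pattern"
  )
}

#' @export
print.group_pattern <- function(x, ...) {
  cat("<group_pattern> ", sum(x$mask), "/", length(x$mask),
      " elements stable at |BSR| > ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Correlation-based similarity of one individual to a group pattern
#'
#' An individual whose non-rotated PLS is non-significant (p >= alpha) or
#' whose design saliences do not align with the group contrast (non-positive
#' dot product) is recorded as showing no correlation with the group
#' pattern. Otherwise the Pearson correlation between the group pattern's
#' stable loadings and the individual's loadings at the same elements is
#' categorized: r >= .4 moderate-strong; .1 < r < .4 weak positive;
#' -.1 <= r <= .1 negligible; r < -.1 negative.
#'
#' @param individual_lv A `nonrotated_pls` fitted with the pattern's
#'   contrast.
#' @param pattern A [extract_group_pattern()] result.
#' @param alpha Individual significance level (default .05).
#' @param participant,group Optional identifiers carried into the record.
#' @return One-row tibble: participant, group, `p_value`, `matched`, `r`
#'   (NA when excluded), `category`.
#' @export
assess_individual <- function(individual_lv, pattern, alpha = 0.05,
                              participant = NA_character_,
                              group = NA_character_) {
  stopifnot(inherits(individual_lv, "nonrotated_pls"),
            inherits(pattern, "group_pattern"))
  if (length(individual_lv$v) != length(pattern$mask)) {
    stop("feature grid mismatch between individual and group pattern",
         call. = FALSE)
  }
  matched <- TRUE
  if (!is.null(pattern$contrast)) {
    matched <- sum(individual_lv$u * pattern$contrast$unit) > 0
  }
  sig <- individual_lv$p < alpha
  if (!sig || !matched) {
    return(tibble::tibble(
      participant = participant, group = group, p_value = individual_lv$p,
      matched = matched, r = NA_real_, category = "negligible_or_none"
    ))
  }
  v_ind <- individual_lv$v
  if (!is.null(pattern$contrast) &&
      sum(individual_lv$u * pattern$contrast$unit) < 0) {
    v_ind <- -v_ind
  }
  a <- pattern$loadings
  b <- v_ind[pattern$mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in loadings over the stable mask", call. = FALSE)
  }
  r <- stats::cor(a, b)
  tibble::tibble(
    participant = participant, group = group, p_value = individual_lv$p,
    matched = matched, r = r, category = similarity_category(r)
  )
}

similarity_category <- function(r) {
  if (is.na(r)) return("negligible_or_none")
  if (r >= 0.4) "moderate_strong"
  else if (r > 0.1) "weak_positive"
  else if (r >= -0.1) "negligible_or_none"
  else "negative"
}

#' Rule windows over feature grids
#'
#' Helpers returning window functions for [rating_rule()]: a frequency band
#' over all channel pairs (WPLI grids) or a timescale range, optionally
#' restricted to channels (MSE grids).
#'
#' @param freq_range,scale_range Inclusive limits.
#' @param channels Optional channel subset (MSE).
#' @return A function mapping a column-metadata tibble to a logical mask.
#' @export
wpli_window <- function(freq_range) {
  force(freq_range)
  function(cols) cols$freq >= freq_range[1] & cols$freq <= freq_range[2]
}

#' @rdname wpli_window
#' @export
mse_window <- function(scale_range, channels = NULL) {
  force(scale_range); force(channels)
  function(cols) {
    m <- cols$scale >= scale_range[1] & cols$scale <= scale_range[2]
    if (!is.null(channels)) m <- m & cols$channel %in% channels
    m
  }
}

#' A single rating rule
#'
#' Evaluates a contrast-weighted change (`weights` over conditions) of the
#' centered condition means, averaged over the stable elements inside a
#' window, against a sign requirement. `"none"` requires the absence of a
#' meaningful change.
#'
#' @param lv Name of the LV (in the named list handed to
#'   [rule_based_rating()]) whose condition means and BSR map are read.
#' @param window A window function (see [wpli_window()]).
#' @param weights Numeric contrast over conditions (in the LV's condition
#'   order).
#' @param requirement One of `"positive"`, `"negative"`, `"nonzero"`,
#'   `"none"`.
#' @return A `rating_rule` list.
#' @export
rating_rule <- function(lv, window, weights,
                        requirement = c("positive", "negative", "nonzero",
                                        "none")) {
  structure(list(lv = lv, window = window, weights = weights,
                 requirement = match.arg(requirement)),
            class = "rating_rule")
}

eval_rating_rule <- function(rule, lvs, bsr_threshold, min_frac, effect_frac) {
  lv <- lvs[[rule$lv]]
  if (is.null(lv)) stop("rule references unknown LV '", rule$lv, "'",
                        call. = FALSE)
  win <- rule$window(lv$cols)
  if (!any(win)) stop("empty rule window", call. = FALSE)
  stable <- !is.na(lv$bsr) & abs(lv$bsr) > bsr_threshold & win
  f_all <- as.vector(rule$weights %*% lv$condition_means)
  need <- max(1L, ceiling(min_frac * sum(win)))
  meaningful <- FALSE
  direction <- 0
  if (sum(stable) >= need) {
    effect <- mean(f_all[stable])
    # reference scale: overall size of condition differences in the window,
    # so a flat session profile is not judged against its own noise
    ref <- sqrt(mean(lv$condition_means[, win]^2))
    if (ref > 0 && abs(effect) >= effect_frac * ref) {
      meaningful <- TRUE
      direction <- sign(effect)
    }
  }
  switch(rule$requirement,
         positive = meaningful && direction > 0,
         negative = meaningful && direction < 0,
         nonzero = meaningful,
         none = !meaningful)
}

#' Automated rule-based pattern rating
#'
#' A deterministic analogue of visual rating of individual outcome patterns:
#' each group pattern is encoded as rules over band/scale windows requiring
#' a direction of stable change, and an individual is flagged as fitting the
#' responder and/or non-responder pattern. Either, both or neither flag may
#' be true, reproducing the four rating categories (own-only, both,
#' opposite-only, neither).
#'
#' @param lvs A `nonrotated_pls` or named list of them (rules name which
#'   they read).
#' @param rules List with elements `responder` and `nonresponder`, each a
#'   list with optional `any_of` and `all_of` lists of [rating_rule()]s; see
#'   [wpli_rating_rules()] and [mse_rating_rules()].
#' @param bsr_threshold Stability threshold (default 2).
#' @param min_frac Minimum fraction of a window that must be stable for a
#'   change to count (default 0.01).
#' @param effect_frac Minimum magnitude of the mean stable change, as a
#'   fraction of the RMS of the window's centered condition means, for it to
#'   be "meaningful".
#' @return Tibble with `fits_responder_rule` and `fits_nonresponder_rule`.
#' @export
rule_based_rating <- function(lvs, rules, bsr_threshold = 2,
                              min_frac = 0.01, effect_frac = 0.75) {
  if (inherits(lvs, "nonrotated_pls")) lvs <- list(lv = lvs)
  fits <- vapply(c("responder", "nonresponder"), function(side) {
    rs <- rules[[side]]
    all_ok <- all(vapply(rs$all_of %||% list(), eval_rating_rule,
                         logical(1), lvs = lvs, bsr_threshold = bsr_threshold,
                         min_frac = min_frac, effect_frac = effect_frac))
    any_rules <- rs$any_of %||% list()
    any_ok <- if (length(any_rules) == 0) TRUE else {
      any(vapply(any_rules, eval_rating_rule, logical(1), lvs = lvs,
                 bsr_threshold = bsr_threshold, min_frac = min_frac,
                 effect_frac = effect_frac))
    }
    all_ok && any_ok
  }, logical(1))
  tibble::tibble(fits_responder_rule = fits[["responder"]],
                 fits_nonresponder_rule = fits[["nonresponder"]])
}

#' Default rating rules for connectivity patterns
#'
#' Responders: stable decrease in alpha and/or increase in beta WPLI from
#' week 1 to week 12; non-responders the reverse. With a week1-minus-week12
#' contrast, a decrease appears as positive loadings.
#'
#' @param lv Name of the WPLI LV in the list handed to
#'   [rule_based_rating()].
#' @param alpha,beta Band limits in Hz; either may be `NULL` when the
#'   analysis grid does not cover it.
#' @param weights Week1-minus-week12 contrast in the LV's condition order.
#' @return A rules list for [rule_based_rating()].
#' @export
wpli_rating_rules <- function(lv = "lv", alpha = c(8, 14), beta = c(18, 30),
                              weights = c(0, 1, -1)) {
  band_rules <- function(alpha_req, beta_req) {
    rules <- list()
    if (!is.null(alpha)) {
      rules <- c(rules, list(rating_rule(lv, wpli_window(alpha), weights,
                                         alpha_req)))
    }
    if (!is.null(beta)) {
      rules <- c(rules, list(rating_rule(lv, wpli_window(beta), weights,
                                         beta_req)))
    }
    if (length(rules) == 0) stop("no rating bands defined", call. = FALSE)
    rules
  }
  list(
    responder = list(any_of = band_rules("positive", "negative")),
    nonresponder = list(any_of = band_rules("negative", "positive"))
  )
}

#' Default rating rules for complexity patterns
#'
#' Responders: a stable early (baseline to week 1) decrease in coarse-scale
#' entropy. Non-responders: no meaningful early change but some change from
#' week 1 to week 12.
#'
#' @param early_lv,late_lv Names of the LVs carrying the early-change and
#'   late-change stability maps.
#' @param coarse Timescale window.
#' @param early_weights,late_weights Condition contrasts for
#'   baseline-minus-week1 and week1-minus-week12 change.
#' @return A rules list for [rule_based_rating()].
#' @export
mse_rating_rules <- function(early_lv = "responder_contrast",
                             late_lv = "nonresponder_contrast",
                             coarse = c(10, 20),
                             early_weights = c(1, -1, 0),
                             late_weights = c(0, 1, -1)) {
  list(
    responder = list(all_of = list(
      rating_rule(early_lv, mse_window(coarse), early_weights, "positive")
    )),
    nonresponder = list(all_of = list(
      rating_rule(late_lv, mse_window(coarse), early_weights, "none"),
      rating_rule(late_lv, mse_window(coarse), late_weights, "nonzero")
    ))
  )
}

#' Cohort-level similarity summary
#'
#' Percentages per correlation category (and, when rule flags are present,
#' per rating category: own-only, both, opposite-only, neither), per group
#' and overall.
#'
#' @param records Tibble of [assess_individual()] rows (optionally with
#'   rating flags bound on).
#' @return Long tibble: `scheme`, `group`, `category`, `n`, `pct`.
#' @export
summarize_cohort <- function(records) {
  stopifnot(nrow(records) >= 1)
  cat_levels <- c("moderate_strong", "weak_positive", "negligible_or_none",
                  "negative")
  tally <- function(df, grp) {
    n_tot <- nrow(df)
    counts <- table(factor(df$category, levels = cat_levels))
    tibble::tibble(scheme = "correlation", group = grp,
                   category = cat_levels, n = as.integer(counts),
                   pct = 100 * as.integer(counts) / n_tot)
  }
  out <- dplyr::bind_rows(
    tally(records, "overall"),
    dplyr::bind_rows(lapply(unique(records$group), function(g) {
      tally(records[records$group == g, ], g)
    }))
  )
  if (all(c("fits_responder_rule", "fits_nonresponder_rule") %in%
          names(records)) && !anyNA(records$group)) {
    own <- ifelse(records$group == "responder",
                  records$fits_responder_rule, records$fits_nonresponder_rule)
    opp <- ifelse(records$group == "responder",
                  records$fits_nonresponder_rule, records$fits_responder_rule)
    rating_cat <- dplyr::case_when(
      own & !opp ~ "own_only",
      own & opp ~ "both",
      !own & opp ~ "opposite_only",
      TRUE ~ "neither"
    )
    rl <- c("own_only", "both", "opposite_only", "neither")
    tally_r <- function(idx, grp) {
      counts <- table(factor(rating_cat[idx], levels = rl))
      tibble::tibble(scheme = "rating", group = grp, category = rl,
                     n = as.integer(counts),
                     pct = 100 * as.integer(counts) / sum(idx))
    }
    out <- dplyr::bind_rows(
      out, tally_r(rep(TRUE, nrow(records)), "overall"),
      dplyr::bind_rows(lapply(unique(records$group), function(g) {
        tally_r(records$group == g, g)
      }))
    )
  }
  out
}

#' Stacked-bar view of a similarity summary
#'
#' @param object Output of [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot, one bar per group, stacked by category percentage.
#' @export
plot_similarity_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$pct,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = NULL, y = "% of participants", fill = "Category")
}
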