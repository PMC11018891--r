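#' Analysis configuration
#'
#' Collects every tunable of the study flow: which recording state feeds
#' each feature kind (eyes-closed for connectivity, eyes-open for
#' complexity by default, the states showing the strongest effects), the
#' estimator grids, PLS settings (500 permutations, 200 bootstrap
#' replicates, alpha .05, Bonferroni-corrected follow-up alpha .025, BSR
#' thresholds 2 and 3.1), the predefined individual contrasts, and seeds.
#'
#' @param wpli_state,mse_state Recording state analysed per feature kind.
#' @param fourier [fourier_grid()] for across-epoch WPLI.
#' @param morlet [morlet_grid()] for single-epoch WPLI.
#' @param mse [mse_params()] for multiscale entropy.
#' @param wpli_contrast Session contrast for individual WPLI analyses.
#' @param mse_contrasts Named list of session contrasts for individual MSE
#'   analyses (one per hypothesized group pattern).
#' @param n_perm,n_boot Resampling sizes.
#' @param alpha,followup_alpha,strict_alpha Significance levels: omnibus and
#'   individual, per-group follow-ups (Bonferroni over two groups), and the
#'   stricter individual threshold reported alongside.
#' @param bsr_threshold,bsr_strict Stability thresholds (~95 and ~99
#'   percent).
#' @param rating_bands Frequency bands (`alpha`, `beta`; either may be
#'   `NULL`) used by the automated connectivity rating rules.
#' @param regress_age Regress the age covariate out of group-level matrices.
#' @param seed Base seed; stage seeds are derived deterministically.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(wpli_state = "EC", mse_state = "EO",
                            fourier = fourier_grid(), morlet = morlet_grid(),
                            mse = mse_params(),
                            wpli_contrast = c(0, 1, -1),
                            mse_contrasts = list(
                              responder_contrast = c(1, 0, -1),
                              nonresponder_contrast = c(1, 1, -2)
                            ),
                            n_perm = 500, n_boot = 200,
                            alpha = 0.05, followup_alpha = 0.025,
                            strict_alpha = 0.001,
                            bsr_threshold = 2, bsr_strict = 3.1,
                            rating_bands = list(alpha = c(8, 14),
                                                beta = c(18, 30)),
                            regress_age = TRUE, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, followup_alpha > 0, followup_alpha < 1)
  structure(
    list(wpli_state = wpli_state, mse_state = mse_state, fourier = fourier,
         morlet = morlet, mse = mse, wpli_contrast = wpli_contrast,
         mse_contrasts = mse_contrasts, n_perm = n_perm, n_boot = n_boot,
         alpha = alpha, followup_alpha = followup_alpha,
         strict_alpha = strict_alpha, bsr_threshold = bsr_threshold,
         bsr_strict = bsr_strict, rating_bands = rating_bands,
         regress_age = regress_age, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Group-level features for a cohort
#'
#' Across-epoch WPLI (Fourier/multitaper) for the configured connectivity
#' state and epoch-averaged MSE for the configured complexity state, one
#' feature grid per participant and session.
#'
#' @param cohort An `eeg_cohort`.
#' @param config An [analysis_config()].
#' @return List of two tibbles (`wpli`, `mse`) ready for
#'   [assemble_group_matrix()].
#' @export
group_features <- function(cohort, config = analysis_config()) {
  labs <- cohort$design$channel_labels
  one_kind <- function(state, fun) {
    recs <- cohort$recordings[cohort$recordings$state == state, ]
    if (nrow(recs) == 0) stop("no recordings for state ", state, call. = FALSE)
    recs$values <- purrr::map(seq_len(nrow(recs)), function(i) {
      fun(recs$data[[i]], recs$sampling_rate[i])
    })
    recs[, c("participant", "group", "session", "age", "values")]
  }
  list(
    wpli = one_kind(config$wpli_state, function(d, sr) {
      wpli_across_epochs(d, sr, config$fourier, labs)
    }),
    mse = one_kind(config$mse_state, function(d, sr) {
      mse_for_recording(d, config$mse, labs)$average
    })
  )
}

subset_feature_matrix <- function(fm, idx) {
  new_feature_matrix(fm$values[idx, , drop = FALSE], fm$rows[idx, ],
                     fm$cols, fm$provenance)
}

# Do the LV's design saliences express a group-by-condition interaction?
# Operationalized as a non-constant group difference of the session profiles.
salience_interaction <- function(fit, lv = 1, tol = 1e-8) {
  cells <- fit$cells
  if (!"group" %in% names(cells)) return(FALSE)
  gs <- unique(cells$group)
  if (length(gs) < 2) return(FALSE)
  u <- fit$u[, lv]
  d <- u[cells$group == gs[1]] - u[cells$group == gs[2]]
  d <- d - mean(d)
  max(abs(d)) > tol
}

#' Omnibus and follow-up group PLS analyses
#'
#' For each feature kind: assembles the group matrix (one row per
#' participant and session), regresses out age, runs the omnibus
#' two-group-by-sessions mean-centered PLS, and - when LV1 is significant
#' and its saliences express a group-by-session interaction - per-group
#' follow-up analyses judged at the Bonferroni-corrected level.
#'
#' @param cohort An `eeg_cohort`.
#' @param config An [analysis_config()].
#' @param features Optional precomputed [group_features()].
#' @return A `group_analysis` list with one bundle per feature kind:
#'   `fm`, `omnibus` (`pls_result`), `interaction`, `followups` (per-group
#'   `pls_result`s or NULL), `followup_significant`.
#' @export
run_group_analysis <- function(cohort, config = analysis_config(),
                               features = NULL) {
  features <- features %||% group_features(cohort, config)
  sessions <- cohort$design$sessions
  out <- list()
  offset <- 0L
  for (kind in c("wpli", "mse")) {
    fm <- assemble_group_matrix(features[[kind]], kind, sessions)
    if (config$regress_age) fm <- regress_out_age(fm)
    omni <- pls_group(fm, config$n_perm, config$n_boot,
                      seed = config$seed + offset)
    gate <- omni$p[1] < config$alpha && salience_interaction(omni$fit)
    followups <- NULL
    followup_significant <- NULL
    if (gate) {
      groups <- unique(fm$rows$group)
      followups <- lapply(groups, function(g) {
        pls_group(subset_feature_matrix(fm, which(fm$rows$group == g)),
                  config$n_perm, config$n_boot,
                  seed = config$seed + offset + 10L)
      })
      names(followups) <- groups
      followup_significant <- vapply(followups, function(r) {
        r$p[1] < config$followup_alpha
      }, logical(1))
    }
    out[[kind]] <- list(fm = fm, omnibus = omni, interaction = gate,
                        followups = followups,
                        followup_significant = followup_significant)
    offset <- offset + 100L
  }
  structure(c(out, list(config = config)), class = "group_analysis")
}

#' @export
print.group_analysis <- function(x, ...) {
  for (kind in c("wpli", "mse")) {
    b <- x[[kind]]
    cat(kind, ": LV1 p = ", signif(b$omnibus$p[1], 3),
        ", PCCE = ", round(b$omnibus$fit$pcce[1], 1), "%",
        if (b$interaction) " [interaction -> follow-ups run]", "\n", sep = "")
  }
  invisible(x)
}

individual_features_one <- function(recs, labs, config, kind) {
  # per-epoch feature objects for one participant, one state
  rows <- list()
  for (i in seq_len(nrow(recs))) {
    dat <- recs$data[[i]]
    sr <- recs$sampling_rate[i]
    per_epoch <- if (kind == "wpli") {
      wpli_single_epoch(dat, sr, config$morlet, labs)
    } else {
      mse_for_recording(dat, config$mse, labs)
    }
    rows[[i]] <- tibble::tibble(
      session = recs$session[i],
      epoch = seq_along(per_epoch$per_epoch),
      values = per_epoch$per_epoch
    )
    attr(rows[[i]], "average") <- per_epoch$average
  }
  averages <- lapply(rows, attr, "average")
  list(per_epoch = dplyr::bind_rows(rows),
       averages = tibble::tibble(session = recs$session, values = averages))
}

#' Single-participant analyses and group-to-individual similarity
#'
#' Runs, per participant, non-rotated PLS on single-epoch features with the
#' predefined session contrasts (connectivity: week1-vs-week12; complexity:
#' one contrast per hypothesized group pattern), assesses each individual's
#' loading pattern against the stable group patterns of their own and the
#' opposite group, applies the automated rating rules, and summarizes the
#' cohort. Connectivity group patterns are derived from per-group PLS on
#' the epoch-averaged single-epoch WPLI (so the feature grids match);
#' complexity patterns come from the group follow-up analyses. If the
#' required group result is missing or non-significant the feature kind is
#' reported as not assessable rather than silently defaulted.
#'
#' @param cohort An `eeg_cohort`.
#' @param config An [analysis_config()].
#' @param group_results A [run_group_analysis()] result.
#' @return An `individual_analysis` list: per feature kind a `status`,
#'   `records` (one row per participant), `summary`, `patterns`; plus
#'   `strict_counts` (participants significant at the stricter alpha).
#' @export
run_individual_analysis <- function(cohort, config, group_results) {
  stopifnot(inherits(group_results, "group_analysis"))
  design <- cohort$design
  sessions <- design$sessions
  labs <- design$channel_labels
  gt <- cohort$ground_truth
  groups <- unique(gt$group)

  out <- list(wpli = list(status = "ok"), mse = list(status = "ok"))

  # ---- single-epoch features -------------------------------------------
  feats <- list(wpli = list(), mse = list())
  avg_rows <- list()
  for (pid in gt$participant) {
    prow <- gt[gt$participant == pid, ]
    for (kind in c("wpli", "mse")) {
      st <- if (kind == "wpli") config$wpli_state else config$mse_state
      recs <- cohort$recordings[cohort$recordings$participant == pid &
                                  cohort$recordings$state == st, ]
      f <- individual_features_one(recs, labs, config, kind)
      feats[[kind]][[pid]] <- f$per_epoch
      if (kind == "wpli") {
        avg <- f$averages
        avg$participant <- pid
        avg$group <- prow$group
        avg$age <- prow$age
        avg_rows[[pid]] <- avg
      }
    }
  }

  # ---- group patterns ---------------------------------------------------
  wpli_contrast <- pls_contrast(config$wpli_contrast)
  patterns <- list(wpli = NULL, mse = NULL)
  if (group_results$wpli$omnibus$p[1] >= config$alpha) {
    out$wpli$status <- "not_assessable: omnibus connectivity LV1 not significant"
  } else {
    avg_fm_rows <- dplyr::bind_rows(avg_rows)
    pat <- tryCatch({
      fm_avg <- assemble_group_matrix(avg_fm_rows, "wpli", sessions)
      if (config$regress_age) fm_avg <- regress_out_age(fm_avg)
      pats <- lapply(groups, function(g) {
        res <- pls_group(subset_feature_matrix(fm_avg,
                                               which(fm_avg$rows$group == g)),
                         config$n_perm, config$n_boot,
                         seed = config$seed + 300L)
        if (res$p[1] >= config$followup_alpha) {
          stop("group ", g, " averaged single-epoch LV1 not significant")
        }
        extract_group_pattern(res, 1, config$bsr_threshold, wpli_contrast)
      })
      names(pats) <- groups
      pats
    }, error = function(e) e)
    if (inherits(pat, "error")) {
      out$wpli$status <- paste("not_assessable:", conditionMessage(pat))
    } else {
      patterns$wpli <- pat
    }
  }
  mse_pat <- tryCatch({
    if (is.null(group_results$mse$followups)) {
      stop("no significant complexity group follow-ups")
    }
    pats <- lapply(groups, function(g) {
      res <- group_results$mse$followups[[g]]
      if (!isTRUE(group_results$mse$followup_significant[[g]])) {
        stop("complexity follow-up for ", g, " not significant")
      }
      cname <- if (g == groups[1]) names(config$mse_contrasts)[1] else
        names(config$mse_contrasts)[2]
      extract_group_pattern(res, 1, config$bsr_threshold,
                            pls_contrast(config$mse_contrasts[[cname]]))
    })
    names(pats) <- groups
    pats
  }, error = function(e) e)
  if (inherits(mse_pat, "error")) {
    out$mse$status <- paste("not_assessable:", conditionMessage(mse_pat))
  } else {
    patterns$mse <- mse_pat
  }

  # ---- per-participant non-rotated PLS + similarity ---------------------
  wpli_records <- list()
  mse_records <- list()
  strict_wpli <- 0L
  strict_mse <- 0L
  for (i in seq_len(nrow(gt))) {
    pid <- gt$participant[i]
    grp <- gt$group[i]
    opp <- setdiff(groups, grp)
    seed_i <- config$seed + 1000L + i

    if (out$wpli$status == "ok") {
      fmi <- assemble_individual_matrix(feats$wpli[[pid]], sessions)
      lv <- nonrotated_pls(fmi, wpli_contrast, config$n_perm, config$n_boot,
                           seed = seed_i)
      rec <- assess_individual(lv, patterns$wpli[[grp]], config$alpha,
                               participant = pid, group = grp)
      rec_opp <- assess_individual(lv, patterns$wpli[[opp]], config$alpha)
      rec$r_opposite <- rec_opp$r
      rec$category_opposite <- rec_opp$category
      rules <- wpli_rating_rules(
        "lv", alpha = config$rating_bands$alpha,
        beta = config$rating_bands$beta, weights = config$wpli_contrast
      )
      rec <- dplyr::bind_cols(rec, rule_based_rating(
        list(lv = lv), rules, config$bsr_threshold
      ))
      if (lv$p < config$strict_alpha) strict_wpli <- strict_wpli + 1L
      wpli_records[[pid]] <- rec
    }

    if (out$mse$status == "ok") {
      fmi <- assemble_individual_matrix(feats$mse[[pid]], sessions)
      lvs <- lapply(config$mse_contrasts, function(w) {
        nonrotated_pls(fmi, pls_contrast(w), config$n_perm, config$n_boot,
                       seed = seed_i)
      })
      own_lv <- if (grp == groups[1]) lvs[[1]] else lvs[[2]]
      opp_lv <- if (grp == groups[1]) lvs[[2]] else lvs[[1]]
      rec <- assess_individual(own_lv, patterns$mse[[grp]], config$alpha,
                               participant = pid, group = grp)
      rec_opp <- assess_individual(opp_lv, patterns$mse[[opp]], config$alpha)
      rec$r_opposite <- rec_opp$r
      rec$category_opposite <- rec_opp$category
      rec <- dplyr::bind_cols(rec, rule_based_rating(
        lvs, mse_rating_rules(names(config$mse_contrasts)[1],
                              names(config$mse_contrasts)[2],
                              coarse = c(max(2, config$mse$max_scale %/% 2),
                                         config$mse$max_scale)),
        config$bsr_threshold
      ))
      if (own_lv$p < config$strict_alpha) strict_mse <- strict_mse + 1L
      mse_records[[pid]] <- rec
    }
  }

  for (kind in c("wpli", "mse")) {
    recs <- if (kind == "wpli") wpli_records else mse_records
    if (out[[kind]]$status == "ok" && length(recs)) {
      out[[kind]]$records <- dplyr::bind_rows(recs)
      out[[kind]]$summary <- summarize_cohort(out[[kind]]$records)
      out[[kind]]$patterns <- patterns[[kind]]
    }
  }
  out$strict_counts <- c(wpli = strict_wpli, mse = strict_mse)
  out$config <- config
  structure(out, class = "individual_analysis")
}

#' @export
print.individual_analysis <- function(x, ...) {
  for (kind in c("wpli", "mse")) {
    cat(kind, ": ", x[[kind]]$status, sep = "")
    if (x[[kind]]$status == "ok") {
      ms <- x[[kind]]$summary
      own <- ms$pct[ms$scheme == "correlation" & ms$group == "overall" &
                      ms$category == "moderate_strong"]
      cat(" - ", round(own, 1), "% moderate-strong own-group correlations",
          sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' End-to-end study run on a synthetic cohort
#'
#' Generates a cohort, runs the group analyses, then the individual
#' analyses and similarity summaries.
#'
#' @param design A [cohort_design()].
#' @param effects List of [effect_spec()]s.
#' @param config An [analysis_config()].
#' @param deviant_fraction Passed to [generate_cohort()].
#' @param ... Further arguments to [generate_cohort()].
#' @return A `study_result` list: `cohort`, `group`, `individual`.
#' @export
run_study <- function(design, effects, config = analysis_config(),
                      deviant_fraction = 0, ...) {
  cohort <- generate_cohort(design, effects,
                            deviant_fraction = deviant_fraction, ...)
  group <- run_group_analysis(cohort, config)
  individual <- run_individual_analysis(cohort, config, group)
  structure(list(cohort = cohort, group = group, individual = individual),
            class = "study_result")
}
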