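#' Write / read a cohort as a self-describing directory container
#'
#' Each recording becomes one 32-bit-real binary payload (epochs x channels
#' x samples, column-major) plus a JSON sidecar describing its shape and
#' attributes (`sampling_rate`, `channel_labels`, `group`, `session`,
#' `state`, `age`). Ground truth and design metadata are stored as JSON at
#' the container root.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Target directory (created if needed).
#' @return `dir` invisibly (write); an `eeg_cohort` (read). Note payloads
#'   are single precision, so reread samples agree to float32 resolution.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- cohort$recordings
  for (i in seq_len(nrow(recs))) {
    stem <- file.path(dir, paste(recs$participant[i], recs$session[i],
                                 recs$state[i], sep = "_"))
    dat <- recs$data[[i]]
    con <- file(paste0(stem, ".bin"), "wb")
    writeBin(as.vector(dat), con, size = 4)
    close(con)
    jsonlite::write_json(
      list(dim = dim(dat), sampling_rate = recs$sampling_rate[i],
           channel_labels = cohort$design$channel_labels,
           participant = recs$participant[i], group = recs$group[i],
           session = recs$session[i], state = recs$state[i],
           age = recs$age[i]),
      paste0(stem, ".json"), digits = NA, auto_unbox = TRUE
    )
  }
  jsonlite::write_json(cohort$ground_truth, file.path(dir, "ground_truth.json"),
                       digits = NA)
  jsonlite::write_json(
    cohort$design[setdiff(names(cohort$design), "age_model")],
    file.path(dir, "design.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  sidecars <- setdiff(list.files(dir, pattern = "\\.json$", full.names = TRUE),
                      file.path(dir, c("ground_truth.json", "design.json")))
  rows <- lapply(sidecars, function(js) {
    meta <- jsonlite::read_json(js, simplifyVector = TRUE)
    bin <- sub("\\.json$", ".bin", js)
    con <- file(bin, "rb")
    vec <- readBin(con, numeric(), n = prod(meta$dim), size = 4)
    close(con)
    tibble::tibble(
      participant = meta$participant, group = meta$group,
      session = meta$session, state = meta$state, age = meta$age,
      n_epochs = meta$dim[1], data = list(array(vec, dim = meta$dim)),
      sampling_rate = meta$sampling_rate
    )
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    tibble::as_tibble(jsonlite::read_json(gt_path, simplifyVector = TRUE))
  }
  design <- jsonlite::read_json(file.path(dir, "design.json"),
                                simplifyVector = TRUE)
  structure(list(recordings = dplyr::bind_rows(rows), ground_truth = gt,
                 design = design),
            class = "eeg_cohort")
}

#' Export a feature grid as long-format TSV
#'
#' Writes [tidy()] output of a `connectivity_matrix` or `mse_matrix` with
#' identifying metadata columns prepended.
#'
#' @param x The feature object.
#' @param path Output file.
#' @param meta Named list of metadata (participant, session, state, ...)
#'   repeated on every row.
#' @return `path` invisibly.
#' @export
export_features_tsv <- function(x, path, meta = list()) {
  d <- tidy(x)
  for (nm in rev(names(meta))) {
    d <- dplyr::bind_cols(stats::setNames(tibble::tibble(meta[[nm]]), nm), d)
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a latent-variable result to JSON
#'
#' Scalars (singular value, p, PCCE where available), the contrast,
#' condition-mean brain scores with CIs; loading and BSR maps go to a TSV
#' alongside when `maps = TRUE`.
#'
#' @param x A `pls_result` or `nonrotated_pls`.
#' @param path Output JSON path.
#' @param lv LV index for `pls_result` maps.
#' @param maps Also write a `.maps.tsv` with loadings and BSR per element.
#' @return `path` invisibly.
#' @export
write_lv_json <- function(x, path, lv = 1, maps = TRUE) {
  if (inherits(x, "pls_result")) {
    payload <- list(
      kind = "mean_centered_pls",
      singular_values = x$fit$d, pcce = x$fit$pcce, p_values = x$p,
      saliences = stats::setNames(
        as.data.frame(x$fit$u),
        paste0("lv", seq_len(ncol(x$fit$u)))
      ),
      cells = x$fit$cells, score_means = x$score_means,
      settings = x$settings
    )
    v <- x$fit$v[, lv]
    bsr <- x$bsr[, lv]
    labels <- x$cols$label
  } else if (inherits(x, "nonrotated_pls")) {
    payload <- list(
      kind = "nonrotated_pls", singular_value = x$d, p_value = x$p,
      contrast_raw = x$contrast$raw, contrast_unit = x$contrast$unit,
      conditions = x$conditions, score_means = x$score_means,
      settings = x$settings
    )
    v <- x$v
    bsr <- x$bsr
    labels <- x$cols$label
  } else {
    stop("unsupported object", call. = FALSE)
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  if (maps) {
    utils::write.table(
      data.frame(label = labels, loading = v, bsr = bsr),
      sub("\\.json$", ".maps.tsv", path),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}
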