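#' @title PLS-ready feature matrices
#' @description A `feature_matrix` stacks per-recording feature grids
#'   (WPLI frequency x pair, or MSE channel x scale) into an observations x
#'   features matrix with complete row and column metadata, the layout the
#'   PLS routines consume.
#' @name feature_matrix
NULL

feature_values <- function(x) {
  if (inherits(x, "connectivity_matrix") || inherits(x, "mse_matrix")) {
    x$values
  } else if (is.matrix(x)) {
    x
  } else {
    stop("unsupported feature object", call. = FALSE)
  }
}

feature_cols <- function(x, kind) {
  if (inherits(x, "connectivity_matrix")) {
    tibble::tibble(
      kind = kind,
      freq = rep(x$grid$freq, times = nrow(x$pairs)),
      chan_a = rep(x$pairs$chan_a, each = nrow(x$grid)),
      chan_b = rep(x$pairs$chan_b, each = nrow(x$grid)),
      label = paste0(rep(x$pairs$chan_a, each = nrow(x$grid)), "-",
                     rep(x$pairs$chan_b, each = nrow(x$grid)), "@",
                     rep(x$grid$freq, times = nrow(x$pairs)))
    )
  } else if (inherits(x, "mse_matrix")) {
    ns <- ncol(x$values)
    tibble::tibble(
      kind = kind,
      channel = rep(x$channel_labels, times = ns),
      scale = rep(seq_len(ns), each = length(x$channel_labels)),
      label = paste0(rep(x$channel_labels, times = ns), "@s",
                     rep(seq_len(ns), each = length(x$channel_labels)))
    )
  } else {
    tibble::tibble(kind = kind, label = paste0("f", seq_len(length(x))))
  }
}

new_feature_matrix <- function(values, rows, cols, provenance) {
  stopifnot(nrow(values) == nrow(rows), ncol(values) == nrow(cols))
  structure(list(values = values, rows = rows, cols = cols,
                 provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " x ", ncol(x$values), " (",
      x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Assemble the group-level feature matrix
#'
#' Stacks one feature grid per participant and session into a matrix with
#' one row per participant x session, ordered group-major, then participant,
#' then session. Feature grids are flattened column-major (frequency fastest
#' for WPLI, channel fastest for MSE); the column order is recorded in the
#' result's column metadata.
#'
#' @param features Tibble with columns `participant`, `group`, `session`,
#'   optionally `age`, and a list-column `values` of `connectivity_matrix`,
#'   `mse_matrix` or plain matrix objects on identical grids.
#' @param feature_kind Label stored in the column metadata.
#' @param sessions Session order; defaults to order of first appearance.
#' @return A `feature_matrix` with provenance `"group-level"`.
#' @export
assemble_group_matrix <- function(features, feature_kind = "feature",
                                  sessions = unique(features$session)) {
  stopifnot(all(c("participant", "group", "session", "values") %in%
                  names(features)))
  counts <- table(features$participant)
  if (any(counts != length(sessions))) {
    bad <- names(counts)[counts != length(sessions)]
    stop("participants missing sessions: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(features$group)
  features <- features[order(match(features$group, groups),
                             features$participant,
                             match(features$session, sessions)), ]
  mats <- lapply(features$values, feature_values)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1) {
    stop("inconsistent feature grids across recordings", call. = FALSE)
  }
  values <- do.call(rbind, lapply(mats, as.vector))
  cols <- feature_cols(features$values[[1]], feature_kind)
  rows <- tibble::tibble(
    group = features$group,
    participant = features$participant,
    session = features$session
  )
  if ("age" %in% names(features)) rows$age <- features$age
  rows$condition <- rows$session
  new_feature_matrix(values, rows, cols, "group-level")
}

#' Regress the age covariate out of a group-level feature matrix
#'
#' Per feature column, fits ordinary least squares of the value on
#' participant age (pooled over groups and sessions, one fit per column) and
#' replaces the column by its residuals plus the column's original mean, so
#' features keep their scale while their linear age dependence is removed.
#' Slopes and intercepts are retained in `$age_fit`.
#'
#' @param fm A group-level `feature_matrix`.
#' @param ages Optional named vector (participant -> age); defaults to the
#'   `age` column of the row metadata.
#' @return The adjusted `feature_matrix`.
#' @export
regress_out_age <- function(fm, ages = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(ages)) {
    if (!"age" %in% names(fm$rows)) stop("no ages available", call. = FALSE)
    age <- fm$rows$age
  } else {
    age <- unname(ages[fm$rows$participant])
  }
  if (anyNA(age)) stop("missing ages", call. = FALSE)
  if (stats::sd(age) == 0) {
    stop("constant age vector: slope undefined", call. = FALSE)
  }
  x <- cbind(intercept = 1, age = age)
  fit <- stats::lm.fit(x, fm$values)
  grand <- colMeans(fm$values)
  fm$values <- fit$residuals + matrix(grand, nrow(fm$values),
                                      ncol(fm$values), byrow = TRUE)
  fm$age_fit <- tibble::tibble(
    label = fm$cols$label,
    intercept = fit$coefficients[1, ],
    slope = fit$coefficients[2, ]
  )
  fm
}

#' Assemble a single-participant feature matrix
#'
#' One row per epoch, grouped by session (sessions are the PLS conditions);
#' columns flattened exactly as in [assemble_group_matrix()].
#'
#' @param features Tibble for one participant with columns `session`,
#'   `epoch` and list-column `values`.
#' @param sessions Session order; defaults to order of first appearance.
#' @return A `feature_matrix` with provenance `"single-participant"`.
#' @export
assemble_individual_matrix <- function(features,
                                       sessions = unique(features$session)) {
  stopifnot(all(c("session", "epoch", "values") %in% names(features)))
  counts <- table(factor(features$session, levels = sessions))
  if (any(counts < 2)) {
    stop("each session needs at least 2 epochs", call. = FALSE)
  }
  features <- features[order(match(features$session, sessions),
                             features$epoch), ]
  mats <- lapply(features$values, feature_values)
  values <- do.call(rbind, lapply(mats, as.vector))
  cols <- feature_cols(features$values[[1]], "feature")
  rows <- tibble::tibble(
    group = "self",
    participant = if ("participant" %in% names(features)) {
      features$participant
    } else "self",
    session = features$session,
    epoch = features$epoch
  )
  rows$condition <- rows$session
  new_feature_matrix(values, rows, cols, "single-participant")
}

#' Write / read a feature matrix as TSV plus JSON metadata
#'
#' Values are written with 17 significant digits (bit-exact round trip for
#' doubles); row and column metadata go to a JSON sidecar.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path for the TSV (the sidecar gets `.json` appended).
#' @return `path`, invisibly (write) or the restored object (read).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  m <- format(fm$values, digits = 17, scientific = TRUE, trim = TRUE)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(rows = fm$rows, cols = fm$cols, provenance = fm$provenance),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                        colClasses = "numeric"))
  dimnames(values) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_feature_matrix(values, tibble::as_tibble(meta$rows),
                     tibble::as_tibble(meta$cols), meta$provenance)
}
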