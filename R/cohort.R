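#' Stress-test cohort
#'
#' A `stress_cohort` holds long-format stress-test records: one row per
#' (subject, difficulty cell, repetition) with a fixed-length numeric feature
#' vector, plus optional per-subject clinical anchor scores and a group label.
#'
#' Difficulty is an ordered tuple of non-negative integer coordinates, one per
#' difficulty domain (e.g. treadmill speed level and incline level). The
#' partial order "harder than" is the componentwise order on these tuples.
#'
#' @param subject vector of subject identifiers, one per record.
#' @param difficulty integer matrix (records x domains) of difficulty
#'   coordinates; a vector is treated as a single domain.
#' @param repetition integer repetition index (>= 1) within a difficulty cell.
#' @param features numeric matrix (records x p) of stress-test features.
#' @param anchors optional data frame of per-subject clinical anchor scores,
#'   one row per subject, with a `subject` column; higher values must mean
#'   more severe.
#' @param group optional per-subject label (e.g. `"healthy"` / `"affected"`),
#'   either a named vector (names = subject ids) or a `group` column in
#'   `anchors`.
#'
#' @return An object of class `stress_cohort` with components `subject`,
#'   `difficulty`, `repetition`, `features`, `subjects`, `cells` (one row per
#'   (subject, difficulty) cell), `cell_idx` (record -> cell), `rep_count`
#'   (repetitions per cell), `anchors`, `group`.
#' @export
stress_cohort <- function(subject, difficulty, repetition, features,
                          anchors = NULL, group = NULL) {
  if (is.vector(difficulty)) difficulty <- matrix(difficulty, ncol = 1L)
  difficulty <- as.matrix(difficulty)
  if (is.vector(features)) features <- matrix(features, ncol = 1L)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- length(subject)
  if (nrow(difficulty) != n || nrow(features) != n || length(repetition) != n)
    stop("subject, difficulty, repetition and features must have one row per record")
  if (any(difficulty != round(difficulty)) || any(difficulty < 0))
    stop("difficulty coordinates must be non-negative integers")
  storage.mode(difficulty) <- "integer"
  repetition <- as.integer(repetition)
  if (any(repetition < 1L)) stop("repetition indices must be >= 1")
  bad <- which(!apply(is.finite(features), 1L, all))
  if (length(bad))
    stop("non-finite feature values in record row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (is.null(colnames(difficulty)))
    colnames(difficulty) <- paste0("d", seq_len(ncol(difficulty)))

  subject <- as.character(subject)
  subjects <- unique(subject)
  subj_idx <- match(subject, subjects)

  diff_key <- apply(difficulty, 1L, paste, collapse = ",")
  cell_key <- paste(subj_idx, diff_key, sep = "|")
  triple_key <- paste(cell_key, repetition, sep = "|")
  if (anyDuplicated(triple_key)) {
    dup <- which(duplicated(triple_key))
    stop("duplicate (subject, difficulty, repetition) triples at row(s): ",
         paste(utils::head(dup, 10L), collapse = ", "))
  }

  cell_levels <- unique(cell_key)
  cell_idx <- match(cell_key, cell_levels)
  first <- match(cell_levels, cell_key)
  cells <- data.frame(subject = subj_idx[first], stringsAsFactors = FALSE)
  cells <- cbind(cells, as.data.frame(difficulty[first, , drop = FALSE]))
  cells$diff_key <- diff_key[first]
  rep_count <- tabulate(cell_idx, nbins = length(cell_levels))

  if (!is.null(anchors)) {
    anchors <- as.data.frame(anchors)
    if (!"subject" %in% names(anchors))
      stop("anchors must contain a 'subject' column")
    anchors$subject <- as.character(anchors$subject)
    if (anyDuplicated(anchors$subject))
      stop("anchors must have one row per subject")
    missing_s <- setdiff(subjects, anchors$subject)
    if (length(missing_s))
      stop("anchors missing subject(s): ",
           paste(utils::head(missing_s, 5L), collapse = ", "))
    anchors <- anchors[match(subjects, anchors$subject), , drop = FALSE]
    rownames(anchors) <- NULL
    if (is.null(group) && "group" %in% names(anchors)) group <- anchors$group
  }
  if (!is.null(group)) {
    if (!is.null(names(group))) group <- group[subjects]
    if (length(group) != length(subjects))
      stop("group must supply one label per subject")
    group <- as.character(group)
  }

  structure(list(
    subject = subject, difficulty = difficulty, repetition = repetition,
    features = features, subjects = subjects, subj_idx = subj_idx,
    cells = cells, cell_idx = cell_idx, rep_count = rep_count,
    anchors = anchors, group = group
  ), class = "stress_cohort")
}

#' @export
print.stress_cohort <- function(x, ...) {
  cat("Stress-test cohort:", length(x$subject), "records,",
      length(x$subjects), "subjects,", ncol(x$difficulty),
      "difficulty domain(s),", ncol(x$features), "features\n")
  if (!is.null(x$anchors))
    cat("Clinical anchors:",
        paste(setdiff(names(x$anchors), c("subject", "group")),
              collapse = ", "), "\n")
  if (!is.null(x$group)) {
    tab <- table(x$group)
    cat("Groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Column mapping for cohort CSV files
#'
#' @param id_col subject-id column name.
#' @param rep_col repetition column name.
#' @param difficulty_cols character vector of difficulty coordinate columns,
#'   in domain order.
#' @param feature_cols character vector of feature columns.
#' @param anchor_cols optional anchor-score columns (in a per-subject table).
#' @param group_col optional group-label column.
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(id_col = "subject", rep_col = "rep",
                          difficulty_cols = c("d1", "d2"),
                          feature_cols = NULL,
                          anchor_cols = NULL, group_col = NULL) {
  structure(list(id_col = id_col, rep_col = rep_col,
                 difficulty_cols = difficulty_cols,
                 feature_cols = feature_cols,
                 anchor_cols = anchor_cols, group_col = group_col),
            class = "cohort_config")
}

#' Read a cohort from CSV
#'
#' Reads long-format records (one row per subject x difficulty cell x
#' repetition). Rows with non-finite features and duplicated triples are
#' rejected with an informative error.
#'
#' @param path CSV file of records (comma separated, header row, UTF-8).
#' @param config a [cohort_config()] naming the columns. If `feature_cols` is
#'   `NULL`, all columns not otherwise mapped are taken as features.
#' @param anchors_path optional CSV of per-subject anchor scores; must contain
#'   `config$id_col` plus `config$anchor_cols` (and `config$group_col` if
#'   given).
#' @return A [stress_cohort()].
#' @export
read_cohort <- function(path, config = cohort_config(), anchors_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c(config$id_col, config$rep_col, config$difficulty_cols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file is missing mapped column(s): ",
         paste(miss, collapse = ", "))
  feat_cols <- config$feature_cols
  if (is.null(feat_cols)) feat_cols <- setdiff(names(df), need)
  miss <- setdiff(feat_cols, names(df))
  if (length(miss))
    stop("cohort file is missing feature column(s): ",
         paste(miss, collapse = ", "))

  anchors <- NULL
  group <- NULL
  if (!is.null(anchors_path)) {
    adf <- utils::read.csv(anchors_path, check.names = FALSE)
    if (!config$id_col %in% names(adf))
      stop("anchors file is missing column: ", config$id_col)
    keep <- if (is.null(config$anchor_cols)) names(adf)  # take all columns
            else intersect(c(config$id_col, config$anchor_cols,
                             config$group_col), names(adf))
    anchors <- adf[, keep, drop = FALSE]
    names(anchors)[keep == config$id_col] <- "subject"
    if (!is.null(config$group_col) && config$group_col %in% names(anchors))
      names(anchors)[names(anchors) == config$group_col] <- "group"
  }

  stress_cohort(
    subject = df[[config$id_col]],
    difficulty = as.matrix(df[, config$difficulty_cols, drop = FALSE]),
    repetition = df[[config$rep_col]],
    features = as.matrix(df[, feat_cols, drop = FALSE]),
    anchors = anchors, group = group
  )
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writes one row per record with subject,
#' repetition, difficulty and feature columns. Full-precision floats are
#' written so a read/write round trip preserves records exactly.
#'
#' @param cohort a [stress_cohort()].
#' @param path output CSV path.
#' @param config a [cohort_config()] giving the column names to write.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = cohort_config()) {
  df <- data.frame(cohort$subject, cohort$repetition,
                   stringsAsFactors = FALSE)
  names(df) <- c(config$id_col, config$rep_col)
  dmat <- cohort$difficulty
  colnames(dmat) <- config$difficulty_cols
  fmat <- cohort$features
  df <- cbind(df, as.data.frame(dmat), as.data.frame(fmat))
  utils::write.csv(format_df_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# format numerics at full double precision, locale-independent
format_df_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Per-cell score surface
#'
#' Attaches per-record scores to a cohort and computes the repetition-mean
#' score for every (subject, difficulty) cell. Higher scores encode worse
#' performance / greater severity.
#'
#' @param record_scores numeric vector, one score per record in `cohort`.
#' @param cohort a [stress_cohort()].
#' @return An object of class `score_surface` with `record_scores`,
#'   `cell_means` (one per cell, aligned with `cohort$cells`) and the cohort's
#'   cell table.
#' @export
score_surface <- function(record_scores, cohort) {
  stopifnot(length(record_scores) == length(cohort$subject))
  cm <- cell_means(record_scores, cohort)
  structure(list(record_scores = as.numeric(record_scores),
                 cell_means = cm, cells = cohort$cells,
                 subjects = cohort$subjects),
            class = "score_surface")
}

#' Repetition-mean scores per difficulty cell
#'
#' @param record_scores numeric vector of per-record scores.
#' @param cohort a [stress_cohort()].
#' @return Numeric vector of cell means aligned with `cohort$cells`.
#' @export
cell_means <- function(record_scores, cohort) {
  stopifnot(length(record_scores) == length(cohort$subject))
  sums <- numeric(nrow(cohort$cells))
  agg <- rowsum(as.numeric(record_scores), cohort$cell_idx, reorder = FALSE)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  sums / cohort$rep_count
}

#' @export
print.score_surface <- function(x, ...) {
  cat("Score surface:", length(x$record_scores), "record scores over",
      nrow(x$cells), "cells;",
      "cell-mean range [", format(min(x$cell_means), digits = 4), ",",
      format(max(x$cell_means), digits = 4), "]\n")
  invisible(x)
}

# cells of a subset of subjects (indices into cohort$subjects)
subject_cells <- function(cohort, subj) {
  which(cohort$cells$subject %in% subj)
}
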