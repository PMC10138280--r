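#' Healthy reference performance plane
#'
#' The normative surface against which individual performance planes are
#' measured: for each difficulty cell, the median (and SD) of the healthy
#' training subjects' repetition-mean scores.
#'
#' @param surface a [score_surface()] of the training subjects.
#' @param healthy character vector of healthy subject ids (or integer indices
#'   into the surface's subject list).
#' @return An object of class `reference_plane`: data frame with one row per
#'   difficulty cell (`diff_key`, `median`, `sd`, `n`).
#' @export
build_reference <- function(surface, healthy) {
  stopifnot(inherits(surface, "score_surface"))
  if (is.character(healthy)) healthy <- match(healthy, surface$subjects)
  if (anyNA(healthy)) stop("unknown healthy subject id(s)")
  cells <- surface$cells
  is_h <- cells$subject %in% healthy
  uncovered <- setdiff(unique(cells$diff_key), unique(cells$diff_key[is_h]))
  if (length(uncovered))
    stop("difficulty cell(s) with no healthy subject: ",
         paste(uncovered, collapse = "; "))
  cm <- surface$cell_means[is_h]
  key <- cells$diff_key[is_h]
  med <- tapply(cm, key, stats::median)
  sds <- tapply(cm, key, function(x) if (length(x) > 1L) stats::sd(x) else 0)
  n <- tapply(cm, key, length)
  out <- data.frame(diff_key = names(med), median = as.numeric(med),
                    sd = as.numeric(sds), n = as.integer(n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("reference_plane", "data.frame")
  out
}

#' Aggregate per-difficulty scores into a reserve-capacity index
#'
#' Collapses each subject's performance plane into one number measuring its
#' distance above the healthy reference plane. With higher scores encoding
#' worse performance, a larger index means a larger performance deficit,
#' i.e. lower reserve capacity.
#'
#' Methods, applied to the per-cell differences `delta_d = Fbar^d - ref_d`
#' over the cells a subject shares with the reference:
#' \describe{
#'   \item{`mean`}{mean of all differences.}
#'   \item{`trimmed_mean`}{mean after trimming `trim` from each tail.}
#'   \item{`positive_mean`}{mean of the positive differences (0 if none).}
#'   \item{`sd_positive_mean`}{mean of the differences exceeding the
#'     reference cell's SD (0 if none).}
#' }
#'
#' @param surface a [score_surface()] of the subjects to index.
#' @param ref a [build_reference()] plane.
#' @param method aggregation method (see above).
#' @param trim trim fraction per tail for `trimmed_mean` (default 0.1).
#' @return Named numeric vector of indices, one per subject in `surface`.
#' @export
aggregate_index <- function(surface, ref,
                            method = c("mean", "trimmed_mean",
                                       "positive_mean", "sd_positive_mean"),
                            trim = 0.1) {
  method <- match.arg(method)
  stopifnot(inherits(surface, "score_surface"),
            inherits(ref, "reference_plane"))
  cells <- surface$cells
  at <- match(cells$diff_key, ref$diff_key)
  shared <- !is.na(at)
  delta <- surface$cell_means[shared] - ref$median[at[shared]]
  ref_sd <- ref$sd[at[shared]]
  subj <- cells$subject[shared]
  idx_one <- function(d, s) switch(method,
    mean = mean(d),
    trimmed_mean = mean(d, trim = trim),
    positive_mean = if (any(d > 0)) mean(d[d > 0]) else 0,
    sd_positive_mean = if (any(d > s)) mean(d[d > s]) else 0)
  groups <- split(seq_along(delta), subj)
  out <- vapply(groups, function(g) idx_one(delta[g], ref_sd[g]), numeric(1L))
  present <- as.integer(names(groups))
  missing_subj <- setdiff(seq_along(surface$subjects), present)
  if (length(missing_subj))
    stop("subject(s) share no difficulty cell with the reference plane: ",
         paste(surface$subjects[missing_subj], collapse = ", "))
  stats::setNames(as.numeric(out), surface$subjects[present])
}

#' Write per-subject indices to CSV
#'
#' @param index named numeric vector from [aggregate_index()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  df <- data.frame(subject_id = names(index), index = sprintf("%.17g", index))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
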