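#' Subset a cohort to selected subjects
#'
#' @param cohort a [stress_cohort()].
#' @param subjects character vector of subject ids to keep.
#' @return A [stress_cohort()] containing only those subjects' records.
#' @export
subset_cohort <- function(cohort, subjects) {
  keep <- cohort$subject %in% subjects
  if (!any(keep)) stop("no records left after subsetting")
  anchors <- cohort$anchors
  if (!is.null(anchors)) anchors <- anchors[anchors$subject %in% subjects, ,
                                            drop = FALSE]
  group <- cohort$group
  if (!is.null(group)) {
    names(group) <- cohort$subjects
    group <- group[intersect(cohort$subjects, subjects)]
  }
  stress_cohort(cohort$subject[keep],
                cohort$difficulty[keep, , drop = FALSE],
                cohort$repetition[keep],
                cohort$features[keep, , drop = FALSE],
                anchors = anchors, group = group)
}

# all (cell_i, cell_j) sharing a difficulty cell, for a given set of ordered
# subject pairs (matrix/data.frame with columns i, j of subject indices)
expand_common_cells <- function(cohort, pairs) {
  if (nrow(pairs) == 0L)
    return(list(pairs = data.frame(i = integer(), j = integer()),
                elem = data.frame(pair = integer(), cell_i = integer(),
                                  cell_j = integer()),
                n_dropped = 0L))
  cells <- cohort$cells
  n_subj <- length(cohort$subjects)
  want <- (pairs$i - 1L) * n_subj + pairs$j
  by_key <- split(seq_len(nrow(cells)), cells$diff_key)
  elem_i <- elem_j <- code <- vector("list", length(by_key))
  for (g in seq_along(by_key)) {
    rows <- by_key[[g]]
    if (length(rows) < 2L) next
    grid <- expand.grid(a = rows, b = rows)
    si <- cells$subject[grid$a]; sj <- cells$subject[grid$b]
    keep <- match((si - 1L) * n_subj + sj, want, nomatch = 0L) > 0L
    elem_i[[g]] <- grid$a[keep]
    elem_j[[g]] <- grid$b[keep]
    code[[g]] <- (si[keep] - 1L) * n_subj + sj[keep]
  }
  elem_i <- unlist(elem_i); elem_j <- unlist(elem_j); code <- unlist(code)
  pair_of <- match(code, want)
  present <- sort(unique(pair_of))
  n_dropped <- nrow(pairs) - length(present)
  pairs <- pairs[present, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       elem = data.frame(pair = match(pair_of, present),
                         cell_i = elem_i, cell_j = elem_j),
       n_dropped = n_dropped)
}

#' Between-subject ordered pairs from a known severity (oracle rule)
#'
#' Emits every ordered subject pair (i, j) with `severity[i] > severity[j]`;
#' ties produce no pair in either orientation. Each pair carries the set of
#' difficulty cells both subjects completed; pairs with no common cell are
#' dropped (their count is recorded).
#'
#' @param cohort a [stress_cohort()].
#' @param severity numeric vector of per-subject severities, either named by
#'   subject id or aligned with `cohort$subjects`.
#' @param max_pairs optional cap; if fewer than all pairs, a uniform random
#'   subsample of this size is kept (seeded by `seed`).
#' @param seed integer seed used only when subsampling.
#' @return A list with `pairs` (data frame of subject indices `i`, `j`, i the
#'   more severe), `elem` (one row per pair x common cell) and `n_dropped`.
#' @export
build_between_oracle <- function(cohort, severity, max_pairs = Inf,
                                 seed = 1L) {
  n <- length(cohort$subjects)
  if (!is.null(names(severity))) severity <- severity[cohort$subjects]
  if (length(severity) != n || any(!is.finite(severity)))
    stop("severity must give one finite value per subject")
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  grid <- grid[severity[grid$i] > severity[grid$j], , drop = FALSE]
  if (nrow(grid) > max_pairs) {
    set.seed(seed)
    grid <- grid[sample.int(nrow(grid), max_pairs), , drop = FALSE]
  }
  rownames(grid) <- NULL
  expand_common_cells(cohort, grid)
}

#' Between-subject ordered pairs from noisy clinical anchors (observed rule)
#'
#' Pair (i, j) is emitted iff subject i exceeds subject j on *every* anchor
#' score by more than `margin` standard-deviation units, where each anchor's
#' SD is its sample standard deviation over this cohort. Anchors must be
#' oriented so that higher means more severe.
#'
#' @param cohort a [stress_cohort()] carrying anchors (or pass `anchors`).
#' @param anchors optional data frame / matrix of per-subject anchor scores
#'   aligned with `cohort$subjects` (non-numeric and `subject`/`group`
#'   columns are ignored).
#' @param margin ordering margin in SD units (default 1).
#' @return As [build_between_oracle()].
#' @export
build_between_observed <- function(cohort, anchors = NULL, margin = 1) {
  if (is.null(anchors)) anchors <- cohort$anchors
  if (is.null(anchors)) stop("no anchor scores available")
  anchors <- as.data.frame(anchors)
  anchors <- anchors[, setdiff(names(anchors), c("subject", "group")),
                     drop = FALSE]
  anchors <- anchors[, vapply(anchors, is.numeric, logical(1L)), drop = FALSE]
  if (ncol(anchors) == 0L) stop("no numeric anchor columns")
  n <- length(cohort$subjects)
  if (nrow(anchors) != n) stop("anchors must have one row per subject")
  ok <- matrix(TRUE, n, n)
  for (a in anchors) {
    s <- stats::sd(a)
    if (!is.finite(s) || s == 0)
      stop("anchor with zero variance: the SD-margin ordering rule degenerates")
    ok <- ok & (outer(a, a, "-") > margin * s)
  }
  diag(ok) <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  grid <- data.frame(i = idx[, 1L], j = idx[, 2L])
  expand_common_cells(cohort, grid)
}

#' Within-subject ordered difficulty pairs
#'
#' For every subject and every difficulty domain, holds the other domain(s)
#' fixed and orders the completed levels of the varying domain: the higher
#' level is the harder member of the pair. On a complete 3x3 grid this yields
#' 18 ordered pairs per subject.
#'
#' @param cohort a [stress_cohort()].
#' @return A list with `elem` (one row per ordered pair: `subject`,
#'   `cell_hard`, `cell_easy`) and `w_size` (pairs per subject).
#' @export
build_within <- function(cohort) {
  cells <- cohort$cells
  k <- ncol(cohort$difficulty)
  dom_cols <- colnames(cohort$difficulty)
  out <- vector("list", k)
  for (v in seq_len(k)) {
    other <- dom_cols[-v]
    key <- if (length(other))
      do.call(paste, c(cells[c("subject", other)], sep = "|"))
    else as.character(cells$subject)
    lev <- cells[[dom_cols[v]]]
    groups <- split(seq_len(nrow(cells)), key)
    hard <- easy <- vector("list", length(groups))
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      if (length(rows) < 2L) next
      rows <- rows[order(lev[rows])]
      cmb <- utils::combn(length(rows), 2L)
      hard[[g]] <- rows[cmb[2L, ]]   # higher level = harder
      easy[[g]] <- rows[cmb[1L, ]]
    }
    out[[v]] <- data.frame(cell_hard = unlist(hard), cell_easy = unlist(easy))
  }
  elem <- do.call(rbind, out)
  if (is.null(elem) || nrow(elem) == 0L)
    return(list(elem = data.frame(subject = integer(), cell_hard = integer(),
                                  cell_easy = integer()),
                w_size = integer(length(cohort$subjects))))
  elem <- data.frame(subject = cells$subject[elem$cell_hard],
                     cell_hard = elem$cell_hard, cell_easy = elem$cell_easy)
  elem <- elem[order(elem$subject, elem$cell_hard, elem$cell_easy), ]
  rownames(elem) <- NULL
  list(elem = elem,
       w_size = tabulate(elem$subject, nbins = length(cohort$subjects)))
}

#' Repetition sets
#'
#' Groups record indices by (subject, difficulty) cell.
#'
#' @param cohort a [stress_cohort()].
#' @return A list of integer record-index vectors, one per cell, aligned with
#'   `cohort$cells`.
#' @export
build_repetitions <- function(cohort) {
  unname(split(seq_along(cohort$cell_idx),
               factor(cohort$cell_idx, levels = seq_len(nrow(cohort$cells)))))
}

#' Ordering structures for the scoring objective
#'
#' Builds the three set structures the objective consumes: the between-subject
#' set with common-difficulty cells, the within-subject difficulty pairs, and
#' the repetition sets.
#'
#' @param cohort a [stress_cohort()].
#' @param between `"observed"` (SD-margin rule on anchors), `"oracle"`
#'   (requires `severity`), or `"none"`.
#' @param severity per-subject severity for the oracle rule.
#' @param anchors anchors for the observed rule (defaults to the cohort's).
#' @param margin SD margin for the observed rule.
#' @return An object of class `order_sets` with components `between`,
#'   `within`, `repetitions`.
#' @export
order_sets <- function(cohort,
                       between = c("observed", "oracle", "none"),
                       severity = NULL, anchors = NULL, margin = 1) {
  between <- match.arg(between)
  bet <- switch(between,
    observed = build_between_observed(cohort, anchors, margin),
    oracle = {
      if (is.null(severity)) stop("oracle between-set needs `severity`")
      build_between_oracle(cohort, severity)
    },
    none = expand_common_cells(cohort, data.frame(i = integer(),
                                                  j = integer())))
  structure(list(between = bet, within = build_within(cohort),
                 repetitions = build_repetitions(cohort),
                 n_records = length(cohort$subject)),
            class = "order_sets")
}

#' @export
print.order_sets <- function(x, ...) {
  cat("Order sets: |B| =", nrow(x$between$pairs),
      "pairs (", nrow(x$between$elem), "pair-cell comparisons,",
      x$between$n_dropped, "dropped );",
      "within pairs =", nrow(x$within$elem), ";",
      "repetition cells =", length(x$repetitions), "\n")
  invisible(x)
}
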