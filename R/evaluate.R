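#' Concordance of an ordered set with fitted scores
#'
#' Fraction of elementary ordered comparisons correctly reconstructed by the
#' score surface: for the between-subject set, every (pair, common cell)
#' comparison; for the within-subject set, every (subject, difficulty pair)
#' comparison. A comparison counts 1 when the severe / harder member's
#' cell-mean score is strictly greater, 0.5 on an exact tie, 0 otherwise.
#'
#' @param surface a [score_surface()].
#' @param sets an [order_sets()] (or a bare between/within set list).
#' @param which `"between"` or `"within"`.
#' @return Concordance fraction in `[0, 1]`.
#' @export
concordance <- function(surface, sets, which = c("between", "within")) {
  which <- match.arg(which)
  cm <- surface$cell_means
  set <- if (inherits(sets, "order_sets")) sets[[which]] else sets
  elem <- set$elem
  if (is.null(elem) || nrow(elem) == 0L)
    stop("empty ", which, " comparison set: concordance undefined")
  d <- if (which == "between") cm[elem$cell_i] - cm[elem$cell_j]
       else cm[elem$cell_hard] - cm[elem$cell_easy]
  mean((d > 0) + 0.5 * (d == 0))
}

#' Mean repetition standard deviation
#'
#' Reporting counterpart of the repeated-measures loss term: the sample SD of
#' record scores within each (subject, difficulty) cell, averaged over a
#' subject's cells and then over subjects. Cells with a single repetition are
#' skipped.
#'
#' @param record_scores numeric vector of per-record scores.
#' @param cohort a [stress_cohort()].
#' @return Mean repetition SD; error if no cell has at least 2 repetitions.
#' @export
mean_repetition_sd <- function(record_scores, cohort) {
  stopifnot(length(record_scores) == length(cohort$subject))
  multi <- which(cohort$rep_count >= 2L)
  if (!length(multi))
    stop("no difficulty cell has 2 or more repetitions: repetition SD undefined")
  cm <- cell_means(record_scores, cohort)
  resid2 <- (record_scores - cm[cohort$cell_idx])^2
  ss <- accumulate_at(nrow(cohort$cells), cohort$cell_idx, resid2)
  sds <- sqrt(ss[multi] / (cohort$rep_count[multi] - 1L))
  per_subject <- tapply(sds, cohort$cells$subject[multi], mean)
  mean(per_subject)
}

# coerce labels to 0/1 integer with both classes present
as_binary_label <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (length(u) != 2L)
    stop("labels must contain exactly two classes (got ", length(u), ")")
  as.integer(labels == u[2L])
}

#' Rank-based AUC
#'
#' Probability that a randomly chosen positive subject outranks a randomly
#' chosen negative one (ties count one half); equivalent to the
#' Wilcoxon-Mann-Whitney statistic.
#'
#' @param scores numeric per-subject scores (higher = more likely positive).
#' @param labels binary labels (0/1, logical, or two-level factor; the
#'   higher level is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as_binary_label(labels)
  stopifnot(length(scores) == length(y))
  r <- rank(scores)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' AUC with stratified bootstrap confidence interval
#'
#' Percentile interval over seeded bootstrap resamples drawn within each
#' class (stratified), so every resample retains both classes.
#'
#' @inheritParams auc
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param level coverage (default 0.95).
#' @param seed integer seed.
#' @return A list with `auc`, `lower`, `upper`, `level`, `n_boot`.
#' @export
auc_bootstrap_ci <- function(scores, labels, n_boot = 2000L, level = 0.95,
                             seed = 1L) {
  y <- as_binary_label(labels)
  point <- auc(scores, y)
  pos <- which(y == 1L); neg <- which(y == 0L)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auc(scores[idx], y[idx])
  }, numeric(1L))
  alpha <- (1 - level) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  list(auc = point, lower = qs[1L], upper = qs[2L], level = level,
       n_boot = n_boot)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided test that two classifiers scored on the same subjects have equal
#' AUC, using the structural-components (placement-value) variance estimator
#' for the difference of correlated Wilcoxon statistics.
#'
#' @param scores_a,scores_b numeric score vectors for the two classifiers,
#'   aligned subject-by-subject.
#' @param labels binary labels (see [auc()]).
#' @return A list with `auc_a`, `auc_b`, `statistic` (z), `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_label(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  pos <- which(y == 1L); neg <- which(y == 0L)
  m <- length(pos); n <- length(neg)
  if (m < 2L || n < 2L) stop("need at least 2 subjects in each class")
  placements <- function(s) {
    psi <- outer(s[pos], s[neg], function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), theta = mean(psi))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(var_diff) || var_diff <= 0) {
    if (abs(pa$theta - pb$theta) > 0)
      warning("degenerate DeLong variance with unequal AUCs; p set to 1")
    return(list(auc_a = pa$theta, auc_b = pb$theta, statistic = 0,
                p_value = 1))
  }
  z <- (pa$theta - pb$theta) / sqrt(var_diff)
  list(auc_a = pa$theta, auc_b = pb$theta, statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Harmonic mean p-value
#'
#' Unweighted harmonic-mean combination `k / sum(1 / p_i)` of `k` dependent
#' p-values. This is the headline combination statistic; the
#' asymptotically-exact Landau-tail correction is not applied.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return The combined value.
#' @export
harmonic_mean_p <- function(p) {
  if (!length(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  length(p) / sum(1 / p)
}
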