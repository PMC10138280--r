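#' Huber-smoothed hinge loss
#'
#' A once-differentiable approximation to the hinge `max(0, c)`: zero below
#' `-h`, the quadratic `(c + h)^2 / (4h)` on `(-h, h)`, and linear (`c`)
#' above `h`. Used to penalise violated or weakly-satisfied ordering margins.
#'
#' @param c numeric vector of margin arguments.
#' @param h half-width of the quadratic region (> 0, default 0.5).
#' @return Loss values, same length as `c`.
#' @export
huber_hinge <- function(c, h = 0.5) {
  stopifnot(h > 0)
  ifelse(c <= -h, 0,
         ifelse(c >= h, c, (c + h)^2 / (4 * h)))
}

#' @rdname huber_hinge
#' @details `huber_hinge_grad()` is the first derivative: 0, `(c + h)/(2h)`,
#'   and 1 on the three branches (continuous at both breakpoints).
#' @export
huber_hinge_grad <- function(c, h = 0.5) {
  stopifnot(h > 0)
  ifelse(c <= -h, 0,
         ifelse(c >= h, 1, (c + h) / (2 * h)))
}

# second derivative: 1/(2h) inside the quadratic region, else 0
huber_hinge_hess <- function(c, h = 0.5) {
  ifelse(c > -h & c < h, 1 / (2 * h), 0)
}

#' Loss parameters
#'
#' @param h Huber half-width (default 0.5).
#' @param lambda_B weight of the between-subject term (default 1).
#' @param lambda_W weight of the within-subject term (default 1).
#' @param lambda_R weight of the repeated-measures term (default 1).
#' @return A list of class `loss_control`.
#' @export
loss_control <- function(h = 0.5, lambda_B = 1, lambda_W = 1, lambda_R = 1) {
  stopifnot(h > 0, lambda_B >= 0, lambda_W >= 0, lambda_R >= 0)
  structure(list(h = h, lambda_B = lambda_B, lambda_W = lambda_W,
                 lambda_R = lambda_R), class = "loss_control")
}

# sum `vals` into an accumulator of length n at positions idx
accumulate_at <- function(n, idx, vals) {
  out <- numeric(n)
  if (length(idx)) {
    a <- rowsum(vals, idx, reorder = FALSE)
    out[as.integer(rownames(a))] <- a[, 1L]
  }
  out
}

# resolve a score_surface or raw record-score vector to cell means
as_cell_means <- function(surface, cohort) {
  if (inherits(surface, "score_surface")) surface$cell_means
  else cell_means(surface, cohort)
}

#' Between-subject ordering term
#'
#' Average Huber-hinge penalty `L_h(1 - (Fbar_i^d - Fbar_j^d))` over ordered
#' subject pairs and their common difficulty cells: the more severe subject's
#' repetition-mean score should exceed the healthier subject's by the unit
#' margin at every shared cell.
#'
#' @param surface a [score_surface()] (or raw record scores with `cohort`).
#' @param between a between-set as built by [build_between_oracle()] /
#'   [build_between_observed()].
#' @param h Huber half-width.
#' @param cohort needed only when `surface` is a raw score vector.
#' @return The term value (0, with a warning, if the set is empty).
#' @export
between_term <- function(surface, between, h = 0.5, cohort = NULL) {
  cm <- as_cell_means(surface, cohort)
  elem <- between$elem
  if (nrow(elem) == 0L) {
    warning("empty between-subject set; between term is 0")
    return(0)
  }
  n_pairs <- nrow(between$pairs)
  d_size <- tabulate(elem$pair, nbins = n_pairs)
  w <- 1 / (n_pairs * d_size[elem$pair])
  margin <- 1 - (cm[elem$cell_i] - cm[elem$cell_j])
  sum(w * huber_hinge(margin, h))
}

#' Within-subject difficulty term
#'
#' Average Huber-hinge penalty over each subject's ordered difficulty pairs:
#' the harder cell's repetition-mean score should exceed the easier cell's by
#' the unit margin. Subjects with no pairs are excluded from the outer
#' average.
#'
#' @param surface a [score_surface()] (or raw record scores with `cohort`).
#' @param within a within-set as built by [build_within()].
#' @inheritParams between_term
#' @return The term value (0, with a warning, if every subject's set is
#'   empty).
#' @export
within_term <- function(surface, within, h = 0.5, cohort = NULL) {
  cm <- as_cell_means(surface, cohort)
  elem <- within$elem
  if (nrow(elem) == 0L) {
    warning("all within-subject sets empty; within term is 0")
    return(0)
  }
  n_used <- sum(within$w_size > 0)
  w <- 1 / (n_used * within$w_size[elem$subject])
  margin <- 1 - (cm[elem$cell_hard] - cm[elem$cell_easy])
  sum(w * huber_hinge(margin, h))
}

#' Repeated-measures variance term
#'
#' Mean over subjects of the mean over their difficulty cells of the
#' population variance (denominator = number of repetitions) of the
#' per-record scores within the cell. Penalises inconsistent scoring of a
#' subject's repeated trials.
#'
#' @param record_scores numeric vector, one score per record.
#' @param cohort a [stress_cohort()].
#' @return The term value.
#' @export
repeated_term <- function(record_scores, cohort) {
  cm <- cell_means(record_scores, cohort)
  resid <- record_scores - cm[cohort$cell_idx]
  n_d <- tabulate(cohort$cells$subject, nbins = length(cohort$subjects))
  n_subj <- sum(n_d > 0)
  w_cell <- 1 / (n_subj * n_d[cohort$cells$subject])
  w_rec <- (w_cell / cohort$rep_count)[cohort$cell_idx]
  sum(w_rec * resid^2)
}

#' Composite scoring objective
#'
#' `C = lambda_B * L_B + lambda_W * L_W + lambda_R * L_R`, the criterion the
#' scoring function is trained to minimise. Convex and once-differentiable in
#' the vector of record scores.
#'
#' @param record_scores numeric vector, one score per record.
#' @param cohort a [stress_cohort()].
#' @param sets an [order_sets()] built from the same cohort.
#' @param params a [loss_control()].
#' @return A list with `value` and the components `between`, `within`,
#'   `repeated` (unweighted term values).
#' @export
steps_objective <- function(record_scores, cohort, sets,
                            params = loss_control()) {
  stopifnot(inherits(sets, "order_sets"),
            sets$n_records == length(record_scores))
  surf_cm <- cell_means(record_scores, cohort)
  fake_surface <- structure(list(cell_means = surf_cm),
                            class = "score_surface")
  l_b <- if (nrow(sets$between$elem))
    between_term(fake_surface, sets$between, params$h) else 0
  l_w <- if (nrow(sets$within$elem))
    within_term(fake_surface, sets$within, params$h) else 0
  l_r <- if (params$lambda_R > 0) repeated_term(record_scores, cohort) else 0
  list(value = params$lambda_B * l_b + params$lambda_W * l_w +
         params$lambda_R * l_r,
       between = l_b, within = l_w, repeated = l_r)
}

#' Exact gradient of the scoring objective
#'
#' Analytic per-record gradient of [steps_objective()] with respect to the
#' record scores. The ordering terms act on cell means, so their contribution
#' is spread over a cell's repetitions with weight `1 / |R_i^d|`; the
#' repeated-measures term contributes `2 (F - Fbar) / |R_i^d|` per record
#' (scaled by the subject/cell averaging weights).
#'
#' @inheritParams steps_objective
#' @return Numeric gradient vector, one entry per record.
#' @export
steps_gradient <- function(record_scores, cohort, sets,
                           params = loss_control()) {
  stopifnot(inherits(sets, "order_sets"),
            sets$n_records == length(record_scores))
  n_cells <- nrow(cohort$cells)
  cm <- cell_means(record_scores, cohort)
  grad_cell <- numeric(n_cells)

  bel <- sets$between$elem
  if (nrow(bel) && params$lambda_B > 0) {
    n_pairs <- nrow(sets$between$pairs)
    d_size <- tabulate(bel$pair, nbins = n_pairs)
    w <- params$lambda_B / (n_pairs * d_size[bel$pair])
    margin <- 1 - (cm[bel$cell_i] - cm[bel$cell_j])
    g <- w * huber_hinge_grad(margin, params$h)
    grad_cell <- grad_cell +
      accumulate_at(n_cells, c(bel$cell_i, bel$cell_j), c(-g, g))
  }

  wel <- sets$within$elem
  if (nrow(wel) && params$lambda_W > 0) {
    n_used <- sum(sets$within$w_size > 0)
    w <- params$lambda_W / (n_used * sets$within$w_size[wel$subject])
    margin <- 1 - (cm[wel$cell_hard] - cm[wel$cell_easy])
    g <- w * huber_hinge_grad(margin, params$h)
    grad_cell <- grad_cell +
      accumulate_at(n_cells, c(wel$cell_hard, wel$cell_easy), c(-g, g))
  }

  grad <- (grad_cell / cohort$rep_count)[cohort$cell_idx]

  if (params$lambda_R > 0) {
    resid <- record_scores - cm[cohort$cell_idx]
    n_d <- tabulate(cohort$cells$subject, nbins = length(cohort$subjects))
    n_subj <- sum(n_d > 0)
    w_cell <- 1 / (n_subj * n_d[cohort$cells$subject])
    w_rec <- (w_cell / cohort$rep_count)[cohort$cell_idx]
    grad <- grad + params$lambda_R * 2 * w_rec * resid
  }
  grad
}
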