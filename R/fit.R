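#' Boosting / optimisation control parameters
#'
#' @param n_iter maximum number of boosting stages (default 50).
#' @param step_mode `"fixed"` (constant step, default, matching a
#'   non-optimised unit step) or `"line-search"` (1-D minimisation of the
#'   objective along each new stage).
#' @param step the fixed step size (default 1; ignored under line search).
#' @param tol stopping tolerance: boosting stops when the objective improves
#'   by less than `tol` (default 1e-4).
#' @param maxdepth maximum depth of each regression-tree weak learner
#'   (default 3).
#' @param minbucket minimum number of records per leaf (default 10).
#' @param seed integer seed fixed before fitting so any internal tie-breaking
#'   is reproducible.
#' @return A list of class `boost_control`.
#' @export
boost_control <- function(n_iter = 50L, step_mode = c("fixed", "line-search"),
                          step = 1, tol = 1e-4, maxdepth = 3L,
                          minbucket = 10L, seed = 1L) {
  step_mode <- match.arg(step_mode)
  stopifnot(n_iter >= 1L, tol >= 0, step > 0, maxdepth >= 1L)
  structure(list(n_iter = as.integer(n_iter), step_mode = step_mode,
                 step = step, tol = tol, maxdepth = as.integer(maxdepth),
                 minbucket = as.integer(minbucket), seed = as.integer(seed)),
            class = "boost_control")
}

#' Fit a stress-test performance scoring function
#'
#' Learns a scoring function `F(x)` of the stress-test feature vector that
#' (i) ranks more severe subjects above healthier ones at shared difficulty
#' cells, (ii) ranks harder difficulty cells above easier ones within each
#' subject, and (iii) keeps repeated trials of the same cell close, by
#' minimising the composite Huber-hinge objective of [steps_objective()].
#' Higher scores mean worse performance.
#'
#' Two optimisers are available: stagewise gradient boosting of shallow
#' regression trees fitted to the negated objective gradient
#' (`method = "gbrt"`), and a linear score `F(x) = w'x` optimised by a damped
#' Newton-Raphson search (`method = "linear"`).
#'
#' @param cohort a [stress_cohort()] of training records.
#' @param sets an [order_sets()] built from `cohort`.
#' @param method `"gbrt"` or `"linear"`.
#' @param loss a [loss_control()].
#' @param control a [boost_control()]; for `method = "linear"` only `n_iter`,
#'   `tol` and `seed` are used.
#' @return An object of class `steps_model` with components `kind`, `stages`
#'   (list of rpart trees with step sizes, for gbrt), `weights` (for linear),
#'   `history` (objective value per iteration, starting at the all-zero
#'   score), `objective` (final component values), `converged`.
#' @examples
#' sim <- simulate_cohort(n_subjects = 30, noise_ratio = 100, seed = 1)
#' train <- subset_cohort(sim$cohort, sim$train_ids)
#' sets <- order_sets(train, between = "observed")
#' fit <- steps(train, sets, control = boost_control(n_iter = 5))
#' fit
#' @export
steps <- function(cohort, sets, method = c("gbrt", "linear"),
                  loss = loss_control(), control = boost_control()) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "stress_cohort"), inherits(sets, "order_sets"))
  if (sets$n_records != length(cohort$subject))
    stop("order sets were not built from this cohort")
  fit <- switch(method,
                gbrt = fit_gbrt(cohort, sets, loss, control),
                linear = fit_linear(cohort, sets, loss, control))
  fit$call <- match.call()
  fit$feature_names <- colnames(cohort$features)
  fit$p <- ncol(cohort$features)
  fit$loss <- loss
  fit$control <- control
  class(fit) <- "steps_model"
  fit
}

fit_gbrt <- function(cohort, sets, loss, control) {
  set.seed(control$seed)
  featdf <- as.data.frame(cohort$features)
  n <- length(cohort$subject)
  scores <- numeric(n)
  obj <- steps_objective(scores, cohort, sets, loss)
  history <- obj$value
  stages <- list()
  rpc <- rpart::rpart.control(maxdepth = control$maxdepth,
                              minbucket = control$minbucket,
                              minsplit = 2L * control$minbucket,
                              cp = 0, xval = 0, maxsurrogate = 0,
                              maxcompete = 0)
  converged <- FALSE
  for (m in seq_len(control$n_iter)) {
    y <- -steps_gradient(scores, cohort, sets, loss)
    dat <- cbind(data.frame(.y = y), featdf)
    tree <- rpart::rpart(.y ~ ., data = dat, method = "anova", control = rpc)
    g <- unname(stats::predict(tree, featdf))
    if (control$step_mode == "line-search") {
      rho <- stats::optimize(function(r)
        steps_objective(scores + r * g, cohort, sets, loss)$value,
        interval = c(0, 10), tol = 1e-4)$minimum
    } else rho <- control$step
    new_scores <- scores + rho * g
    new_obj <- steps_objective(new_scores, cohort, sets, loss)
    if (control$step_mode == "line-search" &&
        new_obj$value > utils::tail(history, 1L)) {
      converged <- TRUE          # a minimising step would not improve: stop,
      break                      # discarding the stage
    }
    improvement <- utils::tail(history, 1L) - new_obj$value
    stages[[m]] <- list(tree = tree, rho = rho)
    scores <- new_scores
    obj <- new_obj
    history <- c(history, new_obj$value)
    if (improvement < control$tol) { converged <- TRUE; break }
  }
  list(kind = "tree-ensemble", stages = stages, weights = NULL,
       history = history, objective = obj, train_scores = scores,
       converged = converged)
}

fit_linear <- function(cohort, sets, loss, control,
                       max_halvings = 30L) {
  X <- cohort$features
  p <- ncol(X)
  w <- numeric(p)
  obj_of <- function(w) steps_objective(as.numeric(X %*% w), cohort, sets,
                                        loss)
  obj <- obj_of(w)
  history <- obj$value
  converged <- FALSE
  for (it in seq_len(max(control$n_iter, 100L))) {
    scores <- as.numeric(X %*% w)
    g_rec <- steps_gradient(scores, cohort, sets, loss)
    g <- as.numeric(crossprod(X, g_rec))
    if (max(abs(g)) < max(control$tol, 1e-8)) { converged <- TRUE; break }
    H <- linear_hessian(scores, cohort, sets, loss, X)
    ridge <- 1e-8 * sum(diag(H)) / p
    if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-8
    step <- tryCatch(solve(H + diag(ridge, p), g),
                     error = function(e) g / max(diag(H) + ridge))
    t_step <- 1
    improved <- FALSE
    for (hlv in seq_len(max_halvings)) {
      cand <- w - t_step * step
      cand_obj <- obj_of(cand)
      if (cand_obj$value <= obj$value) {
        w <- cand; obj <- cand_obj; improved <- TRUE
        break
      }
      t_step <- t_step / 2
    }
    history <- c(history, obj$value)
    if (!improved) { converged <- TRUE; break }
  }
  list(kind = "linear", stages = NULL, weights = stats::setNames(w, colnames(X)),
       history = history, objective = obj,
       train_scores = as.numeric(X %*% w), converged = converged)
}

# Hessian of the objective in the weights of a linear score F(x) = w'x.
# Huber-hinge curvature is 1/(2h) inside the quadratic region, 0 outside;
# the repeated-measures term is an exact quadratic.
linear_hessian <- function(scores, cohort, sets, loss, X) {
  p <- ncol(X)
  H <- matrix(0, p, p)
  xbar_num <- rowsum(X, cohort$cell_idx, reorder = FALSE)
  xbar <- matrix(0, nrow(cohort$cells), p)
  xbar[as.integer(rownames(xbar_num)), ] <- xbar_num
  xbar <- xbar / cohort$rep_count
  cm <- cell_means(scores, cohort)

  bel <- sets$between$elem
  if (nrow(bel) && loss$lambda_B > 0) {
    n_pairs <- nrow(sets$between$pairs)
    d_size <- tabulate(bel$pair, nbins = n_pairs)
    w <- loss$lambda_B / (n_pairs * d_size[bel$pair])
    margin <- 1 - (cm[bel$cell_i] - cm[bel$cell_j])
    w2 <- w * huber_hinge_hess(margin, loss$h)
    if (any(w2 > 0)) {
      U <- xbar[bel$cell_i, , drop = FALSE] - xbar[bel$cell_j, , drop = FALSE]
      H <- H + crossprod(U, U * w2)
    }
  }
  wel <- sets$within$elem
  if (nrow(wel) && loss$lambda_W > 0) {
    n_used <- sum(sets$within$w_size > 0)
    w <- loss$lambda_W / (n_used * sets$within$w_size[wel$subject])
    margin <- 1 - (cm[wel$cell_hard] - cm[wel$cell_easy])
    w2 <- w * huber_hinge_hess(margin, loss$h)
    if (any(w2 > 0)) {
      U <- xbar[wel$cell_hard, , drop = FALSE] -
        xbar[wel$cell_easy, , drop = FALSE]
      H <- H + crossprod(U, U * w2)
    }
  }
  if (loss$lambda_R > 0) {
    Z <- X - xbar[cohort$cell_idx, , drop = FALSE]
    n_d <- tabulate(cohort$cells$subject, nbins = length(cohort$subjects))
    n_subj <- sum(n_d > 0)
    w_cell <- 1 / (n_subj * n_d[cohort$cells$subject])
    a <- 2 * loss$lambda_R * (w_cell / cohort$rep_count)[cohort$cell_idx]
    H <- H + crossprod(Z, Z * a)
  }
  H
}

#' Predict performance scores for a cohort
#'
#' Applies the fitted scoring function to every record of a cohort and
#' returns the per-record scores together with repetition-mean scores per
#' (subject, difficulty) cell.
#'
#' @param object a fitted [steps()] model.
#' @param cohort a [stress_cohort()] with the same feature layout as the
#'   training data.
#' @param type `"surface"` (default) for a [score_surface()], `"records"`
#'   for the raw per-record score vector.
#' @param ... unused.
#' @return A [score_surface()] or numeric vector.
#' @export
predict.steps_model <- function(object, cohort,
                                type = c("surface", "records"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(cohort, "stress_cohort"))
  if (ncol(cohort$features) != object$p)
    stop("cohort has ", ncol(cohort$features),
         " features but the model was trained with ", object$p)
  scores <- if (object$kind == "linear") {
    as.numeric(cohort$features %*% object$weights)
  } else {
    featdf <- as.data.frame(cohort$features)
    s <- numeric(nrow(featdf))
    for (stage in object$stages)
      s <- s + stage$rho * unname(stats::predict(stage$tree, featdf))
    s
  }
  if (type == "records") scores else score_surface(scores, cohort)
}

#' @export
print.steps_model <- function(x, ...) {
  cat("Stress-test performance scoring model (",
      if (x$kind == "linear") "linear, Newton-Raphson"
      else paste0("gradient-boosted trees, ", length(x$stages), " stage(s)"),
      ")\n", sep = "")
  cat("Objective:", format(utils::tail(x$history, 1L), digits = 6),
      "(from", format(x$history[1L], digits = 6), "at zero scores;",
      if (x$converged) "converged" else "iteration limit", ")\n")
  invisible(x)
}

#' @export
summary.steps_model <- function(object, ...) {
  out <- list(kind = object$kind,
              n_stages = length(object$stages),
              history = object$history,
              objective = object$objective,
              loss = object$loss,
              weights = object$weights,
              converged = object$converged)
  class(out) <- "summary.steps_model"
  out
}

#' @export
print.summary.steps_model <- function(x, ...) {
  cat("Stress-test performance scoring model\n")
  cat("  optimiser: ", if (x$kind == "linear") "Newton-Raphson (linear score)"
      else sprintf("gradient boosting, %d stage(s)", x$n_stages), "\n")
  cat(sprintf("  objective: %.6g -> %.6g over %d iteration(s)%s\n",
              x$history[1L], utils::tail(x$history, 1L),
              length(x$history) - 1L,
              if (x$converged) " (converged)" else ""))
  cat(sprintf("  final terms: between %.4g, within %.4g, repeated %.4g\n",
              x$objective$between, x$objective$within, x$objective$repeated))
  cat(sprintf("  loss: h = %g, lambda_B = %g, lambda_W = %g, lambda_R = %g\n",
              x$loss$h, x$loss$lambda_B, x$loss$lambda_W, x$loss$lambda_R))
  if (!is.null(x$weights)) {
    cat("  weights:\n")
    print(round(x$weights, 4))
  }
  invisible(x)
}

#' @export
coef.steps_model <- function(object, ...) {
  if (object$kind != "linear") {
    message("tree-ensemble model has no coefficient vector; returning NULL")
    return(invisible(NULL))
  }
  object$weights
}

#' Plot the training objective history
#'
#' @param x a fitted [steps()] model.
#' @param ... passed to [plot()].
#' @export
plot.steps_model <- function(x, ...) {
  plot(seq_along(x$history) - 1L, x$history, type = "b",
       xlab = "iteration", ylab = "objective C", ...)
  invisible(x)
}

#' Save / load a fitted scoring model
#'
#' Linear models are written as versioned JSON; tree ensembles are written
#' with R-native serialization (`saveRDS`).
#'
#' @param model a fitted [steps()] model.
#' @param path output file path.
#' @return `path` invisibly; `read_steps_model()` returns the model.
#' @export
write_steps_model <- function(model, path) {
  stopifnot(inherits(model, "steps_model"))
  if (model$kind == "linear") {
    obj <- list(schema = "stepscore-model/1", kind = "linear",
                weights = as.list(model$weights),
                feature_names = model$feature_names, p = model$p,
                loss = unclass(model$loss), history = model$history,
                converged = model$converged)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    saveRDS(model, path)
  }
  invisible(path)
}

#' @rdname write_steps_model
#' @export
read_steps_model <- function(path) {
  first <- readChar(path, 1L, useBytes = TRUE)
  if (identical(first, "{")) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$schema, "stepscore-model/1"))
      stop("unrecognised model schema")
    model <- list(kind = "linear", stages = NULL,
                  weights = stats::setNames(unlist(obj$weights),
                                            names(obj$weights)),
                  history = obj$history, feature_names = obj$feature_names,
                  p = obj$p, loss = do.call(loss_control, as.list(obj$loss)),
                  converged = obj$converged)
    class(model) <- "steps_model"
    model
  } else readRDS(path)
}
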