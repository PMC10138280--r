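#' Run the simulation study
#'
#' Repeats, for every combination of noise ratio and within-term weight:
#' simulate a cohort with [simulate_cohort()]; on the training subjects build
#' the between-subject set by the oracle rule (true severity) and by the
#' observed rule (SD-margin on the noisy clinical anchors); fit a scoring
#' model per arm; score the held-out test subjects; and evaluate (a)
#' concordance in reconstructing the between- and within-subject sets of the
#' test subjects, (b) the mean repetition SD, (c) Spearman correlation of
#' each aggregated reserve index with true severity, and (d) test AUC of each
#' index and of the raw clinical anchors for the median-split label.
#'
#' Test-set concordance is judged against ground-truth sets built from the
#' true severity for both arms by default, so the two arms are compared on
#' the same footing (`eval_sets = "own"` instead rebuilds each arm's own
#' observed/oracle sets on the test subjects).
#'
#' @param noise_ratio numeric vector of noise ratios (>= 1).
#' @param lambda_W numeric vector of within-term weights.
#' @param n_reps replications per condition.
#' @param n_subjects cohort size per replication (default 200).
#' @param arms any of `"steps"` (observed anchors) and `"oracle"`.
#' @param methods aggregation methods to evaluate.
#' @param loss_args list of [loss_control()] arguments other than `lambda_W`
#'   (defaults: `h` 0.5, `lambda_B` 1, `lambda_R` 1).
#' @param control a [boost_control()]; the default mirrors the package's
#'   reference settings (at most 50 stages, fixed unit step, tolerance 1e-4).
#' @param eval_sets `"truth"` or `"own"` (see above).
#' @param seed master seed; per-replication seeds are derived from it.
#' @param verbose print a line per replication.
#' @return A data frame of class `steps_study`, one row per condition x
#'   replication x arm x metric, with columns `noise_ratio`, `lambda_W`,
#'   `rep`, `arm`, `metric`, `value`. Replications whose observed
#'   between-set is empty are recorded as `NA` for that arm.
#' @seealso [summarize_study()]
#' @export
run_simulation_study <- function(noise_ratio = c(1, 2, 5, 10, 20, 50, 100),
                                 lambda_W = c(0.01, 0.5, 1),
                                 n_reps = 500L, n_subjects = 200L,
                                 arms = c("steps", "oracle"),
                                 methods = c("mean", "trimmed_mean",
                                             "positive_mean"),
                                 loss_args = list(h = 0.5, lambda_B = 1,
                                                  lambda_R = 1),
                                 control = boost_control(),
                                 eval_sets = c("truth", "own"),
                                 seed = 1L, verbose = FALSE) {
  eval_sets <- match.arg(eval_sets)
  arms <- match.arg(arms, c("steps", "oracle"), several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(noise_ratio) * n_reps),
                      nrow = n_reps)
  rows <- list()
  for (nr_i in seq_along(noise_ratio)) {
    nr <- noise_ratio[nr_i]
    for (r in seq_len(n_reps)) {
      sim <- simulate_cohort(n_subjects = n_subjects, noise_ratio = nr,
                             seed = rep_seeds[r, nr_i])
      prep <- study_prepare(sim)
      for (lw in lambda_W) {
        loss <- do.call(loss_control, c(loss_args, list(lambda_W = lw)))
        for (arm in arms) {
          met <- study_one_arm(prep, arm, loss, control, methods, eval_sets)
          rows[[length(rows) + 1L]] <-
            data.frame(noise_ratio = nr, lambda_W = lw, rep = r, arm = arm,
                       metric = names(met), value = unname(met),
                       stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(noise_ratio = nr, lambda_W = lw, rep = r,
                     arm = c("score1", "score1", "score2", "score2"),
                     metric = c("auc", "spearman", "auc", "spearman"),
                     value = c(prep$baseline["auc1"],
                               prep$baseline["spearman1"],
                               prep$baseline["auc2"],
                               prep$baseline["spearman2"]),
                     stringsAsFactors = FALSE)
      }
      if (verbose)
        message(sprintf("noise_ratio %g replication %d/%d done", nr, r,
                        n_reps))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("steps_study", "data.frame")
  out
}

# per-replication shared work: splits, truth lookups, baseline metrics,
# evaluation sets on the test subjects
study_prepare <- function(sim) {
  truth <- sim$truth
  train_cohort <- subset_cohort(sim$cohort, sim$train_ids)
  test_cohort <- subset_cohort(sim$cohort, sim$test_ids)
  sev <- stats::setNames(truth$S, truth$subject)
  lab <- stats::setNames(truth$label, truth$subject)
  test_sets <- order_sets(test_cohort, between = "oracle",
                          severity = sev[sim$test_ids])
  s_test <- truth[match(sim$test_ids, truth$subject), ]
  baseline <- c(
    auc1 = auc(s_test$score1, s_test$label),
    auc2 = auc(s_test$score2, s_test$label),
    spearman1 = stats::cor(s_test$score1, s_test$S, method = "spearman"),
    spearman2 = stats::cor(s_test$score2, s_test$S, method = "spearman"))
  healthy_train <- sim$train_ids[lab[sim$train_ids] == 0L]
  list(sim = sim, train_cohort = train_cohort, test_cohort = test_cohort,
       severity = sev, label = lab, test_sets = test_sets, s_test = s_test,
       baseline = baseline, healthy_train = healthy_train)
}

study_one_arm <- function(prep, arm, loss, control, methods, eval_sets) {
  sim <- prep$sim
  sets <- tryCatch(
    if (arm == "oracle")
      order_sets(prep$train_cohort, between = "oracle",
                 severity = prep$severity[sim$train_ids])
    else order_sets(prep$train_cohort, between = "observed"),
    error = function(e) NULL)
  metric_names <- c("concordance_B", "concordance_W", "repetition_sd",
                    paste0("spearman_", methods), paste0("auc_", methods),
                    "n_between_pairs", "n_stages")
  if (is.null(sets) || nrow(sets$between$pairs) == 0L)
    return(stats::setNames(rep(NA_real_, length(metric_names)),
                           metric_names))
  fit <- steps(prep$train_cohort, sets, method = "gbrt", loss = loss,
               control = control)
  test_surface <- predict(fit, prep$test_cohort)
  eval_on <- if (eval_sets == "truth") prep$test_sets else {
    if (arm == "oracle") prep$test_sets
    else order_sets(prep$test_cohort, between = "observed")
  }
  met <- c(
    concordance_B = if (nrow(eval_on$between$elem))
      concordance(test_surface, eval_on, "between") else NA_real_,
    concordance_W = concordance(test_surface, eval_on, "within"),
    repetition_sd = mean_repetition_sd(test_surface$record_scores,
                                       prep$test_cohort))
  train_surface <- score_surface(fit$train_scores, prep$train_cohort)
  ref <- build_reference(train_surface, prep$healthy_train)
  for (mth in methods) {
    idx <- aggregate_index(test_surface, ref, method = mth)
    idx <- idx[sim$test_ids]
    met[paste0("spearman_", mth)] <-
      stats::cor(idx, prep$s_test$S, method = "spearman")
    met[paste0("auc_", mth)] <- auc(idx, prep$s_test$label)
  }
  met["n_between_pairs"] <- nrow(sets$between$pairs)
  met["n_stages"] <- length(fit$stages)
  met
}

#' Summarise a simulation study
#'
#' Mean, SD and replication count of every metric per condition and arm
#' (`NA` replications, e.g. empty observed between-sets, are dropped with
#' their count reported).
#'
#' @param study a [run_simulation_study()] result.
#' @return A data frame with one row per (noise_ratio, lambda_W, arm,
#'   metric).
#' @export
summarize_study <- function(study) {
  stopifnot(is.data.frame(study))
  key <- list(noise_ratio = study$noise_ratio, lambda_W = study$lambda_W,
              arm = study$arm, metric = study$metric)
  agg <- stats::aggregate(study$value, by = key, FUN = function(v)
    c(mean = mean(v, na.rm = TRUE),
      sd = stats::sd(v, na.rm = TRUE),
      n = sum(!is.na(v)), n_missing = sum(is.na(v))))
  out <- cbind(agg[, 1:4], as.data.frame(agg$x))
  out[order(out$metric, out$arm, out$lambda_W, out$noise_ratio), ]
}
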