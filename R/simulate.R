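#' Observed severity under stress
#'
#' The noiseless signal feature of the simulated stress test: a logistic
#' transform of scaled latent severity whose midpoint drops as the combined
#' difficulty load rises. At low difficulty only the most severe subjects
#' show deficits; as the load increases, progressively milder subjects are
#' pushed past their tipping point.
#'
#' @param s_scaled scaled latent severity in (0, 1).
#' @param d1,d2 difficulty levels of the two domains (integers, 0-based).
#' @param k logistic growth rate (default 8).
#' @return `1 / (1 + exp(-k (s_scaled - a)))` with midpoint
#'   `a = 1 - 0.2 (d1 + d2)`.
#' @export
observed_severity <- function(s_scaled, d1, d2, k = 8) {
  a <- 1 - 0.2 * (d1 + d2)
  1 / (1 + exp(-k * (s_scaled - a)))
}

#' Simulate a stress-test cohort with known latent severity
#'
#' Generates the synthetic study design used throughout the package's
#' simulation experiments. Latent severity arises from two independent
#' components `s1, s2 ~ N(10, 1)` as `S = s1 * s2`; two noisy clinical
#' anchors `score1 = s1 + e`, `score2 = s2 + e` (`e ~ N(0, 1)`) stand for
#' existing domain knowledge. Each subject completes a difficulty grid
#' (default 3 x 3, levels 0..2) with repeated trials per cell. The feature
#' vector of each trial has the [observed_severity()] signal plus
#' `N(0, sigma^2)` noise in entry 1 and pure `N(0, sigma^2)` noise in the
#' remaining entries, with `sigma^2 = 1 / noise_ratio`: the noise ratio is
#' the clinical-anchor noise variance relative to the stress-test feature
#' noise variance, so larger values mean cleaner stress-test features.
#'
#' A subject is labelled positive when `S` exceeds the cohort median.
#' Subjects are split into train/test uniformly at random.
#'
#' @param n_subjects cohort size (default 200).
#' @param noise_ratio clinical-to-feature noise variance ratio, >= 1
#'   (default 1, i.e. feature noise variance 1).
#' @param levels difficulty levels per domain (default `c(3, 3)`).
#' @param reps repetitions per difficulty cell (default 2).
#' @param p feature-vector length (default 5; entry 1 carries the signal).
#' @param k growth rate of the logistic observed-severity transform
#'   (default 8).
#' @param train_frac fraction of subjects assigned to training (default 0.8).
#' @param seed integer seed; the full draw is a deterministic function of it.
#' @param scaling how latent severity is mapped into (0, 1): `"minmax"`
#'   (cohort min-max, clipped to the open interval) or `"rank"`
#'   (`rank / (n + 1)`).
#' @return A list of class `sim_cohort`: `cohort` (a [stress_cohort()] whose
#'   anchors are `score1`, `score2` and whose group labels are
#'   `"healthy"` / `"affected"`), `truth` (per-subject data frame with `s1`,
#'   `s2`, `S`, `S_scaled`, `label`, `score1`, `score2`), `train_ids`,
#'   `test_ids`, and the generator parameters.
#' @export
simulate_cohort <- function(n_subjects = 200L, noise_ratio = 1,
                            levels = c(3L, 3L), reps = 2L, p = 5L, k = 8,
                            train_frac = 0.8, seed = 1L,
                            scaling = c("minmax", "rank")) {
  scaling <- match.arg(scaling)
  stopifnot(noise_ratio >= 1, p >= 1L, n_subjects >= 2L)
  set.seed(seed)
  n <- as.integer(n_subjects)
  s1 <- stats::rnorm(n, 10, 1)
  s2 <- stats::rnorm(n, 10, 1)
  S <- s1 * s2
  score1 <- s1 + stats::rnorm(n)
  score2 <- s2 + stats::rnorm(n)
  s_scaled <- switch(scaling,
    minmax = pmin(pmax((S - min(S)) / (max(S) - min(S)), 1e-6), 1 - 1e-6),
    rank = rank(S) / (n + 1))
  label <- as.integer(S > stats::median(S))
  ids <- sprintf("S%04d", seq_len(n))

  sigma <- sqrt(1 / noise_ratio)
  grid <- expand.grid(rep = seq_len(reps),
                      d2 = seq_len(levels[2L]) - 1L,
                      d1 = seq_len(levels[1L]) - 1L,
                      subj = seq_len(n))
  m <- nrow(grid)
  features <- matrix(stats::rnorm(m * p, 0, sigma), m, p)
  features[, 1L] <- features[, 1L] +
    observed_severity(s_scaled[grid$subj], grid$d1, grid$d2, k)
  colnames(features) <- paste0("f", seq_len(p))

  n_train <- round(train_frac * n)
  train <- sort(sample.int(n, n_train))
  group <- ifelse(label == 1L, "affected", "healthy")
  anchors <- data.frame(subject = ids, score1 = score1, score2 = score2,
                        group = group, stringsAsFactors = FALSE)
  cohort <- stress_cohort(subject = ids[grid$subj],
                          difficulty = cbind(d1 = grid$d1, d2 = grid$d2),
                          repetition = grid$rep,
                          features = features,
                          anchors = anchors)
  truth <- data.frame(subject = ids, s1 = s1, s2 = s2, S = S,
                      S_scaled = s_scaled, label = label,
                      score1 = score1, score2 = score2,
                      stringsAsFactors = FALSE)
  structure(list(cohort = cohort, truth = truth,
                 train_ids = ids[train], test_ids = ids[-train],
                 params = list(n_subjects = n, noise_ratio = noise_ratio,
                               levels = levels, reps = reps, p = p, k = k,
                               train_frac = train_frac, seed = seed,
                               scaling = scaling)),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated stress-test cohort:", x$params$n_subjects, "subjects,",
      "noise ratio", x$params$noise_ratio,
      sprintf("(feature noise SD %.3f),", sqrt(1 / x$params$noise_ratio)),
      length(x$train_ids), "train /", length(x$test_ids), "test\n")
  invisible(x)
}
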