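# Small cohorts built in code for the unit tests.

# complete design: n_subj subjects x l1 x l2 grid x reps, deterministic
# features unless a filler function is given
toy_cohort <- function(n_subj = 2L, l1 = 3L, l2 = 3L, reps = 2L, p = 5L,
                       fill = function(m, p) matrix(seq_len(m * p) / (m * p),
                                                    m, p),
                       anchors = NULL) {
  grid <- expand.grid(rep = seq_len(reps), d2 = seq_len(l2) - 1L,
                      d1 = seq_len(l1) - 1L, subj = seq_len(n_subj))
  stress_cohort(subject = sprintf("S%02d", grid$subj),
                difficulty = cbind(d1 = grid$d1, d2 = grid$d2),
                repetition = grid$rep,
                features = fill(nrow(grid), p),
                anchors = anchors)
}

# noiseless, perfectly separable: the signal feature grows with both subject
# severity (subject index) and difficulty load, other features are zero
separable_cohort <- function(n_subj = 8L, l1 = 3L, l2 = 3L, reps = 2L,
                             p = 5L) {
  grid <- expand.grid(rep = seq_len(reps), d2 = seq_len(l2) - 1L,
                      d1 = seq_len(l1) - 1L, subj = seq_len(n_subj))
  f <- matrix(0, nrow(grid), p)
  f[, 1L] <- grid$subj + 0.3 * (grid$d1 + grid$d2)
  colnames(f) <- paste0("f", seq_len(p))
  stress_cohort(subject = sprintf("S%02d", grid$subj),
                difficulty = cbind(d1 = grid$d1, d2 = grid$d2),
                repetition = grid$rep, features = f)
}

# severity increasing with subject index (used for oracle sets on toys)
toy_severity <- function(cohort) {
  stats::setNames(seq_along(cohort$subjects), cohort$subjects)
}

# random small instance for property-style tests
fuzz_instance <- function(seed, n_subj = 5L, l1 = 2L, l2 = 2L, reps = 2L,
                          p = 3L) {
  set.seed(seed)
  grid <- expand.grid(rep = seq_len(reps), d2 = seq_len(l2) - 1L,
                      d1 = seq_len(l1) - 1L, subj = seq_len(n_subj))
  cohort <- stress_cohort(subject = sprintf("S%02d", grid$subj),
                          difficulty = cbind(d1 = grid$d1, d2 = grid$d2),
                          repetition = grid$rep,
                          features = matrix(rnorm(nrow(grid) * p),
                                            nrow(grid), p))
  sev <- stats::setNames(rnorm(n_subj), cohort$subjects)
  sets <- order_sets(cohort, between = "oracle", severity = sev)
  scores <- rnorm(length(cohort$subject))
  params <- loss_control(h = runif(1, 0.2, 1), lambda_B = runif(1, 0, 2),
                         lambda_W = runif(1, 0, 2), lambda_R = runif(1, 0, 2))
  list(cohort = cohort, sets = sets, scores = scores, params = params)
}

# a hand-held surface: record scores assigned per (subject, d1, d2, rep)
surface_from <- function(cohort, score_fun) {
  s <- score_fun(cohort$subj_idx, cohort$difficulty[, 1L],
                 if (ncol(cohort$difficulty) > 1L) cohort$difficulty[, 2L]
                 else 0L,
                 cohort$repetition)
  score_surface(s, cohort)
}
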