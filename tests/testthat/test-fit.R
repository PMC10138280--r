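test_that("degenerate fits predict zero everywhere (boosting starts at 0)", {
  co <- separable_cohort(n_subj = 4L)
  sets <- order_sets(co, between = "oracle", severity = toy_severity(co))
  fit <- steps(co, sets, loss = loss_control(lambda_B = 0, lambda_W = 0,
                                             lambda_R = 0))
  expect_equal(unname(predict(fit, co, type = "records")),
               rep(0, length(co$subject)))
  expect_equal(fit$history[1L], 0)
  expect_true(fit$converged)
})

test_that("boosting separates a noiseless separable cohort completely", {
  co <- separable_cohort(n_subj = 6L)
  sets <- order_sets(co, between = "oracle", severity = toy_severity(co))
  # leaf size scaled to the 108-record toy so trees can resolve single cells
  fit <- steps(co, sets, control = boost_control(minbucket = 2L))
  surf <- score_surface(fit$train_scores, co)
  expect_equal(concordance(surf, sets, "between"), 1.0)
  expect_equal(concordance(surf, sets, "within"), 1.0)
  expect_lt(tail(fit$history, 1L), fit$history[1L])
})

test_that("line-search keeps the objective history non-increasing", {
  sim <- simulate_cohort(n_subjects = 24, noise_ratio = 5, seed = 8)
  co <- subset_cohort(sim$cohort, sim$train_ids)
  sets <- order_sets(co, between = "observed")
  fit <- steps(co, sets,
               control = boost_control(n_iter = 15, step_mode = "line-search"))
  expect_true(all(diff(fit$history) <= 0))
})

test_that("fits are reproducible given identical seeds and inputs", {
  sim <- simulate_cohort(n_subjects = 20, noise_ratio = 10, seed = 4)
  co <- subset_cohort(sim$cohort, sim$train_ids)
  sets <- order_sets(co, between = "observed")
  f1 <- steps(co, sets, control = boost_control(n_iter = 8))
  f2 <- steps(co, sets, control = boost_control(n_iter = 8))
  expect_identical(f1$train_scores, f2$train_scores)
  expect_identical(f1$history, f2$history)
})

test_that("both optimisers beat the zero-score baseline on the separable cohort", {
  co <- separable_cohort(n_subj = 6L)
  sets <- order_sets(co, between = "oracle", severity = toy_severity(co))
  c0 <- steps_objective(numeric(length(co$subject)), co, sets)$value
  gb <- steps(co, sets, method = "gbrt")
  li <- steps(co, sets, method = "linear")
  expect_lt(tail(gb$history, 1L), c0)
  expect_lt(tail(li$history, 1L), c0)
})

test_that("Newton-Raphson converges to a small-gradient linear optimum", {
  sim <- simulate_cohort(n_subjects = 30, noise_ratio = 50, seed = 12)
  co <- subset_cohort(sim$cohort, sim$train_ids)
  sets <- order_sets(co, between = "observed")
  fit <- steps(co, sets, method = "linear",
               control = boost_control(tol = 1e-6))
  w <- coef(fit)
  expect_length(w, 5L)
  g_rec <- steps_gradient(as.numeric(co$features %*% w), co, sets,
                          loss_control())
  expect_lt(max(abs(crossprod(co$features, g_rec))), 1e-5)
  # the signal feature carries the largest weight
  expect_equal(which.max(abs(w)), 1L, ignore_attr = TRUE)
  expect_true(all(diff(fit$history) <= 0))
})

test_that("linear fit with an all-zero objective returns zero weights", {
  co <- separable_cohort(n_subj = 4L)
  sets <- order_sets(co, between = "oracle", severity = toy_severity(co))
  fit <- steps(co, sets, method = "linear",
               loss = loss_control(lambda_B = 0, lambda_W = 0, lambda_R = 0))
  expect_equal(unname(coef(fit)), rep(0, 5))
})

test_that("prediction is consistent with training and permutation equivariant", {
  sim <- simulate_cohort(n_subjects = 16, noise_ratio = 10, seed = 2)
  co <- subset_cohort(sim$cohort, sim$train_ids)
  sets <- order_sets(co, between = "observed")
  fit <- steps(co, sets, control = boost_control(n_iter = 6))
  expect_equal(unname(predict(fit, co, type = "records")), fit$train_scores)

  n <- length(co$subject)
  set.seed(1)
  perm <- sample(n)
  co_p <- stress_cohort(co$subject[perm], co$difficulty[perm, , drop = FALSE],
                        co$repetition[perm], co$features[perm, , drop = FALSE])
  expect_equal(predict(fit, co_p, type = "records"),
               predict(fit, co, type = "records")[perm],
               ignore_attr = TRUE)

  bad <- stress_cohort(co$subject, co$difficulty, co$repetition,
                       co$features[, 1:3])
  expect_error(predict(fit, bad), "features")
})

test_that("a one-stage unit-step ensemble equals its tree's raw prediction", {
  co <- separable_cohort(n_subj = 6L)
  sets <- order_sets(co, between = "oracle", severity = toy_severity(co))
  fit <- steps(co, sets, control = boost_control(n_iter = 1))
  expect_length(fit$stages, 1L)
  expect_equal(fit$stages[[1L]]$rho, 1)
  raw <- unname(predict(fit$stages[[1L]]$tree,
                        as.data.frame(co$features)))
  expect_equal(unname(predict(fit, co, type = "records")), raw)
})

test_that("models round-trip through serialization", {
  co <- separable_cohort(n_subj = 5L)
  sets <- order_sets(co, between = "oracle", severity = toy_severity(co))
  lin <- steps(co, sets, method = "linear")
  p1 <- withr::local_tempfile(fileext = ".json")
  write_steps_model(lin, p1)
  lin2 <- read_steps_model(p1)
  expect_equal(coef(lin2), coef(lin))
  expect_equal(predict(lin2, co, type = "records"),
               predict(lin, co, type = "records"))

  gb <- steps(co, sets, control = boost_control(n_iter = 4))
  p2 <- withr::local_tempfile(fileext = ".rds")
  write_steps_model(gb, p2)
  gb2 <- read_steps_model(p2)
  expect_equal(predict(gb2, co, type = "records"),
               predict(gb, co, type = "records"))
})
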