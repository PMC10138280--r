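test_that("Huber hinge matches its piecewise closed form", {
  expect_equal(huber_hinge(-0.6, 0.5), 0)
  expect_equal(huber_hinge(0, 0.5), 0.125)
  expect_equal(huber_hinge(2, 0.5), 2)
  expect_equal(huber_hinge(0.5, 0.5), 0.5)   # continuous at c = h
  expect_equal(huber_hinge(-0.5, 0.5), 0)    # continuous at c = -h
})

test_that("Huber hinge is continuous, monotone, and hinge-equal outside (-h, h)", {
  for (h in c(0.2, 0.5, 1.3)) {
    eps <- 1e-9
    expect_equal(huber_hinge(h - eps, h), huber_hinge(h + eps, h),
                 tolerance = 1e-6)
    expect_equal(huber_hinge(-h - eps, h), huber_hinge(-h + eps, h),
                 tolerance = 1e-6)
    expect_equal(huber_hinge_grad(h - eps, h), 1, tolerance = 1e-6)
    expect_equal(huber_hinge_grad(-h + eps, h), 0, tolerance = 1e-6)
    cs <- seq(-3, 3, by = 0.01)
    expect_true(all(diff(huber_hinge(cs, h)) >= 0))
    outside <- cs[abs(cs) >= h]
    expect_equal(huber_hinge(outside, h), pmax(0, outside))
  }
})

test_that("between term averages Huber penalties over pairs and cells", {
  co <- toy_cohort(n_subj = 2L, l1 = 1L, l2 = 1L, reps = 1L)
  b <- build_between_oracle(co, c(S01 = 1, S02 = 0))
  expect_equal(between_term(score_surface(c(2, 0), co), b), 0)
  expect_equal(between_term(score_surface(c(0, 0), co), b), 1)

  # two pairs with per-pair losses 1 and 0 average to 0.5
  co3 <- toy_cohort(n_subj = 3L, l1 = 1L, l2 = 1L, reps = 1L)
  b2 <- list(pairs = data.frame(i = c(1L, 2L), j = c(3L, 3L)),
             elem = data.frame(pair = c(1L, 2L), cell_i = c(1L, 2L),
                               cell_j = c(3L, 3L)))
  surf <- score_surface(c(0, 2, 0), co3)   # pair 1 loss hh(1)=1, pair 2 hh(-1)=0
  expect_equal(between_term(surf, b2), 0.5)
  expect_warning(
    val <- between_term(surf, list(pairs = data.frame(i = integer(),
                                                      j = integer()),
                                   elem = data.frame(pair = integer(),
                                                     cell_i = integer(),
                                                     cell_j = integer()))),
    "empty")
  expect_equal(val, 0)
})

test_that("within term averages within subjects then across subjects", {
  co <- toy_cohort(n_subj = 1L, l1 = 2L, l2 = 1L, reps = 1L)
  w <- build_within(co)
  hard_first <- co$cells$d1[1L] == 1L
  s <- if (hard_first) c(1.5, 0) else c(0, 1.5)
  expect_equal(within_term(score_surface(s, co), w), 0)  # margin at branch edge

  co2 <- toy_cohort(n_subj = 1L)
  expect_equal(within_term(score_surface(rep(0, 18), co2),
                           build_within(co2)), 1)

  # subject-level averages 1 and 0 give 0.5
  co3 <- toy_cohort(n_subj = 2L, l1 = 2L, l2 = 1L, reps = 1L)
  w3 <- build_within(co3)
  sc <- numeric(4)
  hard <- w3$elem$cell_hard[w3$elem$subject == 2L]
  easy <- w3$elem$cell_easy[w3$elem$subject == 2L]
  rec_of_cell <- match(seq_len(nrow(co3$cells)), co3$cell_idx)
  sc[rec_of_cell[hard]] <- 2
  sc[rec_of_cell[easy]] <- 0
  expect_equal(within_term(score_surface(sc, co3), w3), 0.5)
})

test_that("repeated term is the doubly-averaged population variance", {
  co <- toy_cohort(n_subj = 1L, l1 = 1L, l2 = 1L, reps = 2L)
  expect_equal(repeated_term(c(1, 3), co), 1)     # ((1-2)^2 + (3-2)^2) / 2
  co2 <- toy_cohort(n_subj = 2L, reps = 1L)
  expect_equal(repeated_term(rnorm(18), co2), 0)  # singleton cells
  co3 <- toy_cohort(n_subj = 2L)
  expect_equal(repeated_term(rep(3.7, 36), co3), 0)
})

test_that("objective composes the three weighted terms", {
  co <- toy_cohort(n_subj = 2L)
  sets <- order_sets(co, between = "oracle", severity = toy_severity(co))
  zero <- numeric(36)
  obj <- steps_objective(zero, co, sets, loss_control())
  expect_equal(obj$value, 2)        # L_B = L_W = 1, L_R = 0 at zero scores
  expect_equal(obj$between, 1)
  expect_equal(obj$within, 1)
  expect_equal(obj$repeated, 0)

  only_b <- steps_objective(zero, co, sets,
                            loss_control(lambda_W = 0, lambda_R = 0))
  expect_equal(only_b$value, only_b$between)
  none <- steps_objective(rnorm(36), co, sets,
                          loss_control(lambda_B = 0, lambda_W = 0,
                                       lambda_R = 0))
  expect_equal(none$value, 0)
})

test_that("hand-derived gradients for single-pair set-ups", {
  co <- toy_cohort(n_subj = 2L, l1 = 1L, l2 = 1L, reps = 1L)
  sets <- order_sets(co, between = "oracle",
                     severity = c(S01 = 1, S02 = 0))
  g <- steps_gradient(numeric(2), co, sets, loss_control())
  expect_equal(g, c(-1, 1))         # c = 1 > h: dL/dc = 1, chain rule signs

  co2 <- toy_cohort(n_subj = 2L, l1 = 1L, l2 = 1L, reps = 2L)
  sets2 <- order_sets(co2, between = "oracle",
                      severity = c(S01 = 1, S02 = 0))
  g2 <- steps_gradient(numeric(4), co2, sets2, loss_control())
  severe <- co2$subj_idx == 1L
  expect_equal(unique(g2[severe]), -0.5)   # spread by 1/|R_i^d|
  expect_equal(unique(g2[!severe]), 0.5)
})

test_that("analytic gradient matches central finite differences on fuzzed instances", {
  for (seed in 1:5) {
    inst <- fuzz_instance(seed)
    g <- steps_gradient(inst$scores, inst$cohort, inst$sets, inst$params)
    eps <- 1e-5
    for (i in seq_along(inst$scores)) {
      up <- dn <- inst$scores
      up[i] <- up[i] + eps
      dn[i] <- dn[i] - eps
      fd <- (steps_objective(up, inst$cohort, inst$sets, inst$params)$value -
             steps_objective(dn, inst$cohort, inst$sets,
                             inst$params)$value) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-6)
    }
  }
})

test_that("objective is convex in the record scores", {
  for (seed in 11:16) {
    inst <- fuzz_instance(seed)
    set.seed(seed + 100)
    a <- rnorm(length(inst$scores))
    b <- rnorm(length(inst$scores))
    t <- runif(1)
    f <- function(s) steps_objective(s, inst$cohort, inst$sets,
                                     inst$params)$value
    expect_lte(f(t * a + (1 - t) * b), t * f(a) + (1 - t) * f(b) + 1e-12)
  }
})

test_that("ordering terms are shift invariant; repeated term per-cell shift invariant", {
  inst <- fuzz_instance(21)
  co <- inst$cohort
  sets <- inst$sets
  s <- inst$scores
  surf <- score_surface(s, co)
  surf_c <- score_surface(s + 3.14, co)
  expect_equal(between_term(surf, sets$between), between_term(surf_c, sets$between))
  expect_equal(within_term(surf, sets$within), within_term(surf_c, sets$within))
  cell_shift <- rnorm(nrow(co$cells))[co$cell_idx]
  expect_equal(repeated_term(s + cell_shift, co), repeated_term(s, co))
})
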