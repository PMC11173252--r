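# Optimization behaviour: recovery of known potentials, determinism,
# orthogonality at the optimum, and entropy-production estimates.

test_that("single-EPR training recovers the quadratic well", {
  D <- 0.1
  sys <- rotational_toy_quadratic(c = 1, D = D)
  s <- analytic_samples(sys, 4000, D, seed = 1)
  cfg <- training_config(D = D, lambda1 = 1, lambda2 = 0, epochs = 400,
                         batch_size = 1024, lr = 2e-3, seed = 1)
  fit <- train_potential(sys, s, NULL, cfg)
  ref <- reference_from_potential(sys$potential, toy_domain, D,
                                  resolution = 81)
  expect_lt(rrmse(fit$model, ref, D = D), 0.15)
  # loss trace decreases overall
  tr <- fit$trace
  expect_lt(tr$epr[nrow(tr)], tr$epr[1])
})

test_that("training is deterministic given the configuration seed", {
  D <- 0.1
  sys <- rotational_toy_quadratic(c = 1, D = D)
  s <- analytic_samples(sys, 500, D, seed = 2)
  cfg <- training_config(D = D, lambda1 = 1, lambda2 = 0, epochs = 20,
                         seed = 7)
  f1 <- train_potential(sys, s, NULL, cfg)
  f2 <- train_potential(sys, s, NULL, cfg)
  expect_identical(f1$model$par, f2$model$par)
})

test_that("trained minimum value estimates the entropy production rate", {
  # closed form: e_p = 2 c^2 D for the rotational quadratic toy
  D <- 0.1
  sys <- rotational_toy_quadratic(c = 1, D = D)
  s <- analytic_samples(sys, 6000, D, seed = 3)
  cfg <- training_config(D = D, lambda1 = 1, lambda2 = 0, epochs = 500,
                         batch_size = 2048, lr = 2e-3, seed = 3)
  fit <- train_potential(sys, s, NULL, cfg)
  ep <- estimate_epr(fit$model, s, sys)
  expect_equal(ep, 2 * D, tolerance = 0.15)
  # and matches the quadrature oracle at the same accuracy
  expect_equal(ep, epr_quadrature_oracle(sys, D, resolution = 101),
               tolerance = 0.15)
})

test_that("estimated entropy production scales as c^2", {
  D <- 0.1
  s_for <- function(cc, seed) {
    sys <- rotational_toy_quadratic(c = cc, D = D)
    s <- analytic_samples(sys, 6000, D, seed = seed)
    cfg <- training_config(D = D, lambda1 = 1, lambda2 = 0, epochs = 500,
                           batch_size = 2048, lr = 2e-3, seed = seed)
    fit <- train_potential(sys, s, NULL, cfg)
    estimate_epr(fit$model, s, sys)
  }
  e1 <- s_for(1, 4)
  e2 <- s_for(2, 5)
  expect_gt(e2 / e1, 3.4)
  expect_lt(e2 / e1, 4.6)
})

test_that("residual force is orthogonal to gradients at the optimum", {
  # at the minimizer, E[(F + grad V) . grad W] = 0 for any test field W;
  # check with W = coordinate functions (grad W = e_k)
  D <- 0.1
  sys <- rotational_toy_quadratic(c = 1, D = D)
  s <- analytic_samples(sys, 6000, D, seed = 6)
  cfg <- training_config(D = D, lambda1 = 1, lambda2 = 0, epochs = 500,
                         batch_size = 2048, lr = 2e-3, seed = 6)
  fit <- train_potential(sys, s, NULL, cfg)
  X <- states_of(s)
  R <- sys_drift(sys, X) + potential_grad(fit$model, X)
  for (k in 1:2) {
    se <- stats::sd(R[, k]) / sqrt(nrow(X))
    expect_lt(abs(mean(R[, k])), 5 * se + 0.01)
  }
})

test_that("the objective is stable across loss-weight rescaling", {
  # lambda1 in {1, 10} should give comparable landscapes (convex objective)
  D <- 0.1
  sys <- rotational_toy_quadratic(c = 1, D = D)
  s <- analytic_samples(sys, 2000, D, seed = 7)
  ref <- reference_from_potential(sys$potential, toy_domain, D,
                                  resolution = 61)
  errs <- sapply(c(1, 10), function(l1) {
    cfg <- training_config(D = D, lambda1 = l1, lambda2 = 0, epochs = 300,
                           batch_size = 1024, lr = 1e-3, seed = 8)
    rrmse(train_potential(sys, s, NULL, cfg)$model, ref, D = D)
  })
  expect_lt(max(errs) / min(errs), 2.5)
})

test_that("training rejects inconsistent inputs with clear errors", {
  sys <- rotational_toy_quadratic(c = 1, D = 0.1)
  s3 <- sample_set(matrix(0, 5, 3), 0.1, "analytic")
  cfg <- training_config(D = 0.1, lambda1 = 1, lambda2 = 0, epochs = 1)
  expect_error(train_potential(sys, s3, NULL, cfg), "dimension")
  sysd <- dynamical_system(2L, drift = function(X) -X, diffusion = diag(2),
                           name = "iso")
  cfg2 <- training_config(D = 0.1, lambda1 = 10, lambda2 = 1, epochs = 1,
                          enhancement = list(type = "perturbation",
                                             sigma = 0.1))
  s2 <- sample_set(matrix(rnorm(20), 10, 2), 0.1, "analytic")
  expect_error(train_potential(sysd, s2, NULL, cfg2), "lambda2")
})
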