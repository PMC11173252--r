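# Evaluation machinery: metric identities, the finite-element reference and
# its convergence, barrier heights and force decomposition.

test_that("relative errors satisfy exact identities", {
  D <- 0.1
  sys <- rotational_toy_quadratic(c = 1, D = D)
  ref <- reference_from_potential(sys$potential, toy_domain, D,
                                  resolution = 61)
  # a perfect model scores zero
  expect_equal(rrmse(sys$potential, ref, D = D), 0, tolerance = 1e-12)
  expect_equal(rmae(sys$potential, ref, D = D), 0, tolerance = 1e-12)
  # scaling the candidate by (1 + a) scores exactly a (shared minimum at 0)
  scaled <- make_potential(
    value = function(x) 1.1 * potential_value(sys$potential, x), dim = 2L)
  expect_equal(rrmse(scaled, ref, D = D), 0.1, tolerance = 1e-9)
  expect_equal(rmae(scaled, ref, D = D), 0.1, tolerance = 1e-9)
  # metrics are invariant under constant offsets of the candidate
  shifted <- make_potential(
    value = function(x) potential_value(sys$potential, x) + 3, dim = 2L)
  expect_equal(rrmse(shifted, ref, D = D), 0, tolerance = 1e-12)
})

test_that("finite-element reference recovers the Boltzmann potential", {
  D <- 0.1
  sys <- rotational_toy_quadratic(c = 1, D = D)
  fem <- solve_fpe_reference_2d(sys, D, resolution = 101, domain = toy_domain)
  # compare with the analytic potential over the effective domain
  expect_lt(rrmse(sys$potential, fem, D = D), 0.02)
  # density is a proper probability: nonnegative (after floor) and normalized
  w <- eprnet:::trapezoid_weights(101, diff(toy_domain[1, ]) / 100)
  mass <- as.numeric(t(w) %*% fem$p %*% w)
  expect_equal(mass, 1, tolerance = 1e-6)
})

test_that("finite-element error decreases with grid refinement", {
  D <- 0.1
  sys <- rotational_toy_quadratic(c = 1, D = D)
  err <- sapply(c(31, 61, 121), function(res) {
    fem <- solve_fpe_reference_2d(sys, D, resolution = res,
                                  domain = toy_domain)
    rrmse(sys$potential, fem, D = D)
  })
  expect_true(all(diff(err) < 0))
  # roughly second-order elements: quartering the spacing cuts the error by
  # well over 2x per refinement
  expect_gt(err[1] / err[3], 4)
})

test_that("finite-element reference is exact-rotation invariant", {
  # the toy has the same steady state for every rotation strength c on the
  # full plane; on a finite box the circulating flux is not tangent to the
  # walls, so the domain must extend well beyond the evaluation mask for the
  # reflecting-boundary distortion to be negligible
  D <- 0.1
  wide <- rbind(c(-3, 3), c(-3, 3))
  f0 <- solve_fpe_reference_2d(rotational_toy_quadratic(c = 0, D = D), D,
                               resolution = 91, domain = wide)
  f2 <- solve_fpe_reference_2d(rotational_toy_quadratic(c = 2, D = D), D,
                               resolution = 91, domain = wide)
  mask <- (f0$U - min(f0$U)) <= 20 * D
  expect_lt(max(abs((f0$U - min(f0$U))[mask] - (f2$U - min(f2$U))[mask])),
            0.05)
})

test_that("barrier heights match the closed-form double well", {
  # 1D-style double well embedded in 2D: U = (x^2-1)^2 + y^2, barriers = 1
  U <- make_potential(
    value = function(x) (x[, 1]^2 - 1)^2 + x[, 2]^2,
    dim = 2L)
  bh <- barrier_heights_on_line(U, U, c(-1, 0), c(1, 0), n_points = 801)
  expect_equal(bh$model, c(1, 1), tolerance = 1e-4)
  expect_equal(bh$reference, c(1, 1), tolerance = 1e-4)
})

test_that("force decomposition reconstructs the drift exactly", {
  sys <- rotational_toy_quadratic(c = 1, D = 0.1)
  g <- as.matrix(expand.grid(seq(-1, 1, length.out = 5),
                             seq(-1, 1, length.out = 5)))
  dec <- force_decomposition(sys$potential, sys, g)
  expect_lt(max(abs(dec$grad_part + dec$nongrad_part - dec$force)),
            1e-10)
  # at the true potential the non-gradient part is the pure rotation
  # c J grad U0
  gU <- potential_grad(sys$potential, g)
  expect_lt(max(abs(dec$nongrad_part - cbind(-gU[, 2], gU[, 1]))), 1e-8)
})

test_that("conditional error map is exactly zero for the true potential", {
  sys <- gmm12_system(D = 0.02)
  cem <- conditional_error_map(sys$potential, sys,
                               seq(0.8, 2.0, length.out = 8),
                               seq(1.0, 2.2, length.out = 8),
                               n_cond = 32, seed = 1)
  expect_lt(max(cem$err, na.rm = TRUE), 1e-10)
  expect_true(any(is.finite(cem$err)))
})

test_that("marginalized potential of a product Gaussian is the 2D well", {
  # samples from N(0, diag(s2)); the marginal potential over (x1,x2) is
  # quadratic with curvatures D/s2
  D <- 0.1
  s2 <- c(0.5, 1, 0.7, 0.3)
  sys <- gmm_system(1, matrix(0, 1, 4), list(diag(s2)), D = D)
  s <- analytic_samples(sys, 6000, D, seed = 4)
  spec <- reduced_spec(c(1, 2), rbind(c(-1.2, 1.2), c(-1.7, 1.7)), grid = 41)
  ref <- marginalize_potential(sys$potential, s, spec, D)
  G <- as.matrix(expand.grid(ref$x1, ref$x2))
  truth <- D * (G[, 1]^2 / (2 * s2[1]) + G[, 2]^2 / (2 * s2[2]))
  est <- as.vector(ref$U)
  keep <- is.finite(est)
  err <- (est[keep] - mean(est[keep])) - (truth[keep] - mean(truth[keep]))
  expect_lt(sqrt(mean(err^2)) / diff(range(truth[keep])), 0.06)
})
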