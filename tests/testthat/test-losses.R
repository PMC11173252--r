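# Scientific properties of the training objectives.

test_that("force-projection loss reproduces a hand-computed value", {
  # V(x) = (x1^2 + x2^2)/2 so grad V = x; F = (1, 0) constant
  sys <- dynamical_system(2L, drift = function(X) cbind(rep(1, nrow(X)), 0),
                          name = "const")
  V <- quadratic_potential(2L, scale = 1)
  X <- rbind(c(0, 0), c(1, 1))
  # residuals (1,0)+(0,0) and (1,0)+(1,1): |.|^2 = 1 and 5; mean = 3
  expect_equal(epr_loss(V, X, sys), 3)
})

test_that("loss vanishes exactly at the true potential of gradient systems", {
  sys <- gmm_system(c(0.7, 0.3), rbind(c(0, 0), c(1.5, 1)), c(0.09, 0.04),
                    D = 0.05)
  X <- states_of(analytic_samples(sys, 300, 0.05, seed = 1))
  expect_lt(epr_loss(sys$potential, X, sys), 1e-20)
  expect_lt(hjb_loss(sys$potential, X, sys, 0.05), 1e-20)
})

test_that("excess loss is exactly quadratic in the perturbation amplitude", {
  # L(U0 + eps W) - L(U0) = eps^2 E|grad W|^2 for any direction W, so
  # doubling eps quadruples the excess loss (strict convexity in grad V)
  sys <- rotational_toy_quadratic(c = 1, D = 0.1)
  X <- states_of(analytic_samples(sys, 500, 0.1, seed = 2))
  W <- quadratic_potential(2L, scale = 0.3)
  perturbed <- function(eps) {
    make_potential(
      value = function(x) potential_value(sys$potential, x) +
        eps * potential_value(W, x),
      grad = function(x) potential_grad(sys$potential, x) +
        eps * potential_grad(W, x),
      dim = 2L)
  }
  l1 <- epr_loss(perturbed(0.1), X, sys)
  l2 <- epr_loss(perturbed(0.2), X, sys)
  l0 <- epr_loss(sys$potential, X, sys)
  expect_equal((l2 - l0) / (l1 - l0), 4, tolerance = 1e-8)
})

test_that("loss is strictly convex along random segments", {
  sys <- rotational_toy_quadratic(c = 2, D = 0.1)
  X <- states_of(analytic_samples(sys, 200, 0.1, seed = 3))
  set.seed(4)
  for (i in 1:100) {
    m1 <- mlp_potential(2L, hidden = c(6L, 6L))
    m2 <- m1
    m2$par <- m1$par + rnorm(length(m1$par), sd = 0.5)
    mid <- m1
    mid$par <- (m1$par + m2$par) / 2
    # convexity of the empirical loss in the *gradient field*; the
    # midpoint-parameter network is not the midpoint field, so test with the
    # mixed field directly
    Gmix <- (potential_grad(m1, X) + potential_grad(m2, X)) / 2
    Fm <- sys_drift(sys, X)
    lmix <- mean(rowSums((Fm + Gmix)^2))
    expect_lte(lmix,
               (epr_loss(m1, X, sys) + epr_loss(m2, X, sys)) / 2 + 1e-12)
  }
})

test_that("HJB residual of the zero potential is D times the drift divergence", {
  sys <- lorenz_system()
  zero <- make_potential(value = function(x) rep(0, nrow(x)),
                         grad = function(x) 0 * x,
                         laplacian = function(x) rep(0, nrow(x)),
                         dim = 3L)
  set.seed(5)
  X <- matrix(rnorm(30, sd = 5), 10, 3)
  expect_equal(hjb_residual(zero, X, sys, 1), rep(-41 / 3, 10))
})

test_that("orthogonality: minimum equals mean squared non-gradient force", {
  # for the rotational toy, F + grad U0 = c J grad U0, so the loss at U0 is
  # c^2 E|grad U0|^2, and with the Boltzmann law that is the entropy
  # production rate 2 c^2 D (closed form for the quadratic well)
  D <- 0.1
  for (cc in c(1, 2)) {
    sys <- rotational_toy_quadratic(c = cc, D = D)
    X <- states_of(analytic_samples(sys, 20000, D, seed = 6))
    lossU0 <- epr_loss(sys$potential, X, sys)
    expect_equal(lossU0, 2 * cc^2 * D, tolerance = 0.05)
  }
})

test_that("entropy production quadrature oracle matches the closed form", {
  D <- 0.1
  sys <- rotational_toy_quadratic(c = 1, D = D)
  ep <- epr_quadrature_oracle(sys, D, resolution = 101)
  expect_equal(ep, 2 * D, tolerance = 1e-6)
  # resolution-independent once resolved
  ep2 <- epr_quadrature_oracle(sys, D, resolution = 151)
  expect_equal(ep, ep2, tolerance = 1e-8)
})

test_that("weighted-norm loss with identity diffusion reduces to the plain loss", {
  drift <- function(X) cbind(-X[, 1] + X[, 2], -X[, 2])
  plain <- dynamical_system(2L, drift = drift, name = "plain")
  iso <- dynamical_system(2L, drift = drift, diffusion = diag(2),
                          name = "iso")
  m <- tiny_mlp(d = 2L)
  set.seed(7)
  X <- matrix(rnorm(40), 20, 2)
  expect_equal(vepr_loss(m, X, iso, 0.1), epr_loss(m, X, plain))
})

test_that("weighted-norm loss reproduces a one-dimensional hand example", {
  # d=1, sigma(x) = x (a = x^2, div a = 2x), F = -x, D = 0.5:
  # F^v = -x - 2*0.5*x = -2x; V with dV/dx = 1:
  # r = F^v + a V' = -2x + x^2; loss = E[r^2 / x^2]
  sigma_fun <- function(x) matrix(x[1], 1, 1)
  sys <- dynamical_system(1L, drift = function(X) -X,
                          diffusion = sigma_fun,
                          diffusion_div = function(x) 2 * x[1],
                          name = "mult1d")
  V <- make_potential(value = function(x) x[, 1],
                      grad = function(x) matrix(1, nrow(x), 1),
                      dim = 1L)
  X <- matrix(c(1, 2, 0.5), 3, 1)
  expected <- mean(((-2 * X + X^2)^2) / X^2)
  expect_equal(vepr_loss(V, X, sys, 0.5), expected, tolerance = 1e-12)
})

test_that("singular diffusion matrices raise an error naming the state", {
  sys <- dynamical_system(2L, drift = function(X) -X,
                          diffusion = function(x) diag(c(x[1], 1)),
                          name = "deg")
  X <- rbind(c(1, 1), c(0, 1))
  m <- tiny_mlp(d = 2L)
  expect_error(vepr_loss(m, X, sys, 0.1), "singular")
})

test_that("enhanced loss requires an enhanced set when lambda2 > 0", {
  sys <- rotational_toy_quadratic(c = 1, D = 0.1)
  X <- states_of(analytic_samples(sys, 50, 0.1, seed = 8))
  cfg <- training_config(D = 0.1, lambda1 = 10, lambda2 = 1, epochs = 1)
  m <- tiny_mlp(d = 2L)
  expect_error(enhanced_loss(m, X, NULL, sys, cfg), "enhanced")
  cfg0 <- training_config(D = 0.1, lambda1 = 1, lambda2 = 0, epochs = 1)
  expect_equal(enhanced_loss(m, X, NULL, sys, cfg0), epr_loss(m, X, sys))
})
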