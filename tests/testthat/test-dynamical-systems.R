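# Built-in model systems: hand-computed drift values, analytic divergences
# and exact steady-state identities.

test_that("Lorenz drift and constant divergence match hand values", {
  sys <- lorenz_system()
  x <- matrix(c(1, 1, 1), 1)
  # (beta1(y-x), x(beta2-z)-y, xy - beta3 z) at (1,1,1)
  expect_equal(drop(sys$drift(x)), c(0, 26, 1 - 8 / 3))
  expect_equal(drop(sys_drift_div(sys, x)), -10 - 1 - 8 / 3)
  # divergence is state-independent
  set.seed(1)
  X <- matrix(rnorm(30, sd = 10), 10, 3)
  expect_equal(sys_drift_div(sys, X), rep(-41 / 3, 10))
})

test_that("rotational toy drift rotates the gradient field", {
  sys <- rotational_toy_quadratic(c = 1, D = 0.1)
  # U0 = (x^2+y^2)/2: F = -grad U0 + c J grad U0; at (1,0): (-1, 1)
  expect_equal(drop(sys$drift(matrix(c(1, 0), 1))), c(-1, 1))
  # the curl part is divergence-free: div F = -Lap U0 = -2
  expect_equal(drop(sys_drift_div(sys, matrix(c(0.3, -0.7), 1))), -2)
})

test_that("rotational toy steady state is Boltzmann for every rotation c", {
  # p_ss ~ exp(-U0/D) independently of c: the analytic potential must satisfy
  # the HJB identity at scattered points for several c
  for (cc in c(0, 1, 4)) {
    sys <- rotational_toy_quadratic(c = cc, D = 0.1)
    set.seed(7)
    X <- matrix(rnorm(200, sd = 0.5), 100, 2)
    res <- hjb_residual(sys$potential, X, sys, 0.1)
    expect_lt(max(abs(res)), 1e-10)
  }
})

test_that("GMM system drift is D grad log p0 and potential solves HJB", {
  w <- c(0.6, 0.4)
  mu <- rbind(c(0, 0, 0), c(1, 1, 1))
  sys <- gmm_system(w, mu, c(0.04, 0.02), D = 0.05)
  set.seed(3)
  X <- states_of(analytic_samples(sys, 200, 0.05, seed = 3))
  # drift equals the numeric gradient of D log p0 computed from the potential
  gU <- potential_grad(sys$potential, X)
  expect_lt(max(abs(sys$drift(X) + gU)), 1e-8)
  # U0 = -D log p0 satisfies the HJB identity exactly for gradient systems
  res <- hjb_residual(sys$potential, X, sys, 0.05)
  expect_lt(max(abs(res)), 1e-10)
})

test_that("12D GMM fixture carries the benchmark parameters", {
  sys <- gmm12_system(D = 0.02)
  expect_identical(sys$dim, 12L)
  expect_equal(sys$meta$weights, c(0.6, 0.4))
  expect_equal(sys$meta$means[1, 1:3], c(1.2, 2.0, 0.6))
  expect_equal(sys$meta$means[2, 1:3], c(1.8, 1.4, 0.8))
  expect_equal(sys$meta$covs[[1]], diag(0.04, 12))
  expect_equal(sys$meta$covs[[2]], diag(0.02, 12))
})

test_that("gene network drift follows the Hill kinetics by hand", {
  sys <- toggle_network()
  # gene 1: -k x1 + a x1^n/(S^n+x1^n) + b S^n/(S^n+x2^n), a=0.37 b=0.5 k=1
  # S=0.5 n=3; at x = (0.5, 0.5): -0.5 + 0.37/2 + 0.5/2 = -0.065
  f <- drop(sys$drift(matrix(c(0.5, 0.5), 1)))
  expect_equal(f[1], -0.5 + 0.37 / 2 + 0.5 / 2, tolerance = 1e-12)
  expect_equal(f[2], f[1], tolerance = 1e-12) # symmetric wiring
})

test_that("analytic drift divergences agree with finite differences", {
  systems <- list(toggle_network(),
                  rotational_toy_quadratic(c = 2, D = 0.1),
                  gmm_system(c(0.5, 0.5), rbind(c(0, 0), c(1, 1)),
                             c(0.09, 0.04), D = 0.05))
  lo <- c(0.2, -1, -1); hi <- c(2.5, 1, 2)
  for (i in seq_along(systems)) {
    sys <- systems[[i]]
    set.seed(10 + i)
    X <- matrix(runif(20 * sys$dim, lo[i], hi[i]), 20, sys$dim)
    num <- vapply(seq_len(nrow(X)), function(r) {
      sum(diag(pracma::jacobian(function(x)

        drop(sys$drift(matrix(x, 1))), X[r, ])))
    }, numeric(1))
    ana <- sys_drift_div(sys, X)
    expect_lt(max(abs(ana - num) / pmax(abs(num), 1)), 1e-4)
  }
})

test_that("systems can be described, saved and rebuilt from config", {
  cfg <- list(type = "gene_network", activators = list(1, 2),
              repressors = list(2, 1), n = 3)
  sys <- system_from_config(cfg)
  expect_identical(sys$dim, 2L)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  sys2 <- system_from_config(path)
  X <- matrix(runif(10, 0, 3), 5, 2)
  expect_equal(sys2$drift(X), sys$drift(X))
})

test_that("custom drift expressions build a working system", {
  sys <- system_from_config(list(type = "custom", dim = 2,
                                 drift = c("-x1 + 0.5 * x2", "-x2"),
                                 divergence = "-2", name = "linear"))
  X <- matrix(c(1, 2, 0, 1), 2, 2)
  expect_equal(sys$drift(X), cbind(-X[, 1] + 0.5 * X[, 2], -X[, 2]))
  expect_equal(sys_drift_div(sys, X), c(-2, -2))
})
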