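# eprnet

Non-equilibrium potential landscapes for ergodic stochastic dynamics by
entropy-production-rate (EPR) loss minimization.

## What it computes

For an ergodic SDE

```
dX_t = F(X_t) dt + sqrt(2 D) dW_t
```

the *potential landscape* is `U(x) = -D log p_ss(x)`, with `p_ss` the steady
density. For gradient drifts `F = -grad U0` this is `U0` itself; for
non-equilibrium systems (limit cycles, chaotic attractors, gene circuits) no
closed form exists, and estimating `U` naively — kernel density plus a
logarithm — fails exactly where landscapes are interesting, on barriers and
saddles where samples are exponentially rare.

`eprnet` instead minimizes the convex, steady-state-weighted force-projection
loss

```
L_EPR(V) = (1/N) sum_i | F(x_i) + grad V(x_i) |^2 ,    x_i ~ p_ss ,
```

over a small `tanh` network `V(.; theta)`. The population minimizer is `U`
(up to a constant): `-grad U` is the orthogonal projection of `F` onto
gradient fields in the `p_ss`-weighted inner product. The minimal loss value
is the steady entropy production rate — zero exactly at equilibrium — which
the package exposes as `estimate_epr()`. Because samples never constrain `V`
on barrier tops, the loss is *enhanced* with the squared residual of the
viscous Hamilton–Jacobi–Bellman equation

```
-F . grad V + D Lap V - |grad V|^2 + D div F = 0
```

evaluated on a broader second sample set (`lambda1 * L_EPR + lambda2 *
L_HJB`, defaults 10 and 1). Three enhancement rules are built in: an ensemble
at larger noise `D' > D`, Gaussian-perturbed steady samples, and jittered
pair interpolations that cover inter-basin channels uniformly.

Also included:

- vectorized Euler–Maruyama ensemble simulation with reflecting boundaries
  and seeded determinism (`simulate_ensemble()`);
- built-in systems: rotational toy with closed-form EPR, Lorenz, arbitrary
  Gaussian-mixture gradient systems (including the 12-dimensional
  benchmark), and Hill-type gene regulatory networks
  (`rotational_toy_quadratic()`, `lorenz_system()`, `gmm_system()`,
  `gmm12_system()`, `gene_network_system()`);
- a bilinear finite-element steady Fokker–Planck reference solver in 2D with
  reflecting boundaries (`solve_fpe_reference_2d()`);
- landscape error metrics on the effective domain `{U0 - min U0 <= 20 D}`
  (`rrmse()`, `rmae()`), conditional-expectation error maps for mixture
  fixtures (`conditional_error_map()`), barrier heights along transition
  lines (`barrier_heights_on_line()`), force decomposition into gradient and
  flux parts (`force_decomposition()`), and an entropy-production quadrature
  oracle (`epr_quadrature_oracle()`);
- dimensionality reduction to two prescribed coordinates by two independent
  routes — projected-force training (`train_reduced_potential()`) and
  marginalization of a full potential (`marginalize_potential()`);
- a weighted-norm V-EPR loss for state-dependent diffusion (`vepr_loss()`);
- seeded end-to-end experiment drivers with YAML configs and deterministic
  artifacts (`run_landscape()`, `run_benchmark_table()`), plus a CLI at
  `inst/cli/eprnet.R`.

All derivatives (`grad_x V`, `Lap V`, and the parameter gradients of both
loss terms) are computed analytically in compiled code (RcppArmadillo) and
verified against finite differences in the test suite; no autodiff framework
is involved. Training is minibatch Adam, deterministic given the seed.

## Worked example

The rotational toy has drift `F = -grad U0 + c J grad U0` with
`U0 = (x^2 + y^2)/2` and rotation `J`: a non-equilibrium system whose
landscape and entropy production (`e_p = 2 c^2 D`) are known exactly.

```r
library(eprnet)

sys <- rotational_toy_quadratic(c = 1, D = 0.1)
s   <- simulate_ensemble(sys, D = 0.1, n_traj = 4000, t_final = 10,
                         dt = 0.01, seed = 1, init = "gaussian")
cfg <- training_config(D = 0.1, lambda1 = 10, lambda2 = 1,
                       enhancement = list(type = "larger_noise", D_prime = 0.2),
                       epochs = 1500, batch_size = 512, seed = 1)
fit <- train_potential(sys, s, config = cfg)
print(fit)
#> <eprnet_fit> enhanced EPR on rotational_toy(c=1) | final losses: epr 0.2063, hjb 0.00223

ref <- reference_from_potential(sys$potential,
                                rbind(c(-2.2, 2.2), c(-2.2, 2.2)), D = 0.1)
rrmse(fit$model, ref)
#> [1] 0.1356843

estimate_epr(fit$model, s, sys)   # exact value: 2 c^2 D = 0.2
#> [1] 0.1967405
```

The relative error is concentrated at the outer rim of the evaluation
domain, which extends to roughly six standard deviations of the steady
density; within the sampled region the landscape is accurate to a few
hundredths, and the entropy-production estimate lands within two percent of
the closed form.

The same interface scales to high dimension. The 12-dimensional bistable
Gaussian-mixture benchmark (`gmm12_system()`) trains in a few minutes on one
CPU; see `scripts/acceptance.R` for the full pipeline and
`vignettes/epr-landscapes.Rmd` for the method details and design decisions.

## Reproduction

Install and test (offline, one CPU):

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "eprnet",
                               load_package = "installed")'
```

Recompute the headline 12D benchmark quantities from scratch (simulation,
training, evaluation; roughly 10 minutes):

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

This writes `t1` (rRMSE over 10 000 mixture samples), `t2` (rMAE), `t3`
(maximum conditional-expectation error over an `(x1, x2)` grid) and `t4`
(larger barrier-height relative error in percent). All four are stochastic;
reference values and tolerances are discussed in the vignette.

An end-to-end experiment with artifacts (samples, checkpoint, loss trace,
metrics) can also be driven from a YAML config via the CLI:

```sh
Rscript inst/cli/eprnet.R run --config config.yaml --out results/
```
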