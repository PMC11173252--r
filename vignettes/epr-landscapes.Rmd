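---
title: "Constructing non-equilibrium potential landscapes with eprnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing non-equilibrium potential landscapes with eprnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
# The heavier examples are not evaluated at build time; they reproduce in a
# few minutes each on one CPU (see the README's reproduction section).
library(eprnet)
```

## The problem

Consider an ergodic stochastic differential equation on $\mathbb R^d$,

$$ \mathrm d X_t = F(X_t)\,\mathrm dt + \sqrt{2D}\,\mathrm dW_t , $$

with drift $F$ and scalar noise strength $D > 0$. Its stationary density
$p_{ss}$ defines the *potential landscape*

$$ U(x) = -D \ln p_{ss}(x). $$

For gradient systems ($F = -\nabla U_0$) the landscape is $U_0$ itself up to
an additive constant. For non-equilibrium systems — anything with a rotational
(curl) component, such as limit cycles, chaotic attractors or gene regulatory
circuits — $p_{ss}$ carries a non-vanishing probability flux and no closed
form exists; estimating $U$ from data is the computational problem this
package solves.

The direct route, estimating $p_{ss}$ by a histogram or kernel density and
taking $-D\ln(\cdot)$, degenerates quickly: the interesting parts of a
landscape (barriers, saddles) sit exactly where samples are exponentially
rare, and the logarithm amplifies the density estimator's relative error
there. `eprnet` instead fits $U$ *variationally*.

## The EPR loss

Write $\pi = p_{ss}$ and consider, over a parametric scalar field
$V(\cdot;\theta)$,

$$ L_{\mathrm{EPR}}[V] \;=\; \int \lvert F(x) + \nabla V(x)\rvert^2 \,
   \pi(x)\,\mathrm dx
   \;\approx\; \frac1N \sum_{i=1}^N \lvert F(x_i) + \nabla V(x_i)\rvert^2 , $$

with $x_i \sim \pi$ — in practice, late-time states of a simulated ensemble.
Three structural facts make this loss a sound estimator (each is asserted in
the package's test suite):

1. **The minimizer is the landscape.** $-\nabla U$ is the orthogonal
   projection of $F$ onto gradient fields in the $\pi$-weighted inner
   product, so the population loss is minimized exactly at $V = U$ (up to a
   constant). At the optimum the residual $F + \nabla U$ — the flux velocity
   — is $\pi$-orthogonal to every gradient field.
2. **The minimum is physical.** The minimal value equals the steady-state
   entropy production rate $e_p^{ss} = \int |J_{ss}|^2/p_{ss}\,\mathrm dx$;
   it is zero precisely for equilibrium (gradient) systems. The package
   exposes this via `estimate_epr()` and checks it against a quadrature
   oracle on a toy with the closed form $e_p = 2c^2 D$.
3. **The loss is convex** in the gradient field, so minimization is not
   plagued by spurious landscape-shaped local minima.

Only *samples* of $\pi$ and pointwise evaluations of $F$ are needed — no
density estimation, no normalizing constants, and the cost is dimension-robust
(the 12-dimensional benchmark below trains in minutes on one CPU).

## HJB enhancement

The empirical loss weights errors by $\pi$: in low-probability transition
regions (barrier tops) there are few or no samples and $V$ is unconstrained
exactly where one most wants accuracy. The landscape, however, satisfies the
viscous Hamilton–Jacobi–Bellman equation

$$ \mathcal N(V) = -F\cdot\nabla V + D\,\Delta V - |\nabla V|^2
   + D\,\nabla\!\cdot\!F = 0 , $$

pointwise. `eprnet` therefore minimizes the *enhanced* objective

$$ \lambda_1 \hat L_{\mathrm{EPR}}(\{x_i\}) +
   \lambda_2 \hat L_{\mathrm{HJB}}(\{x_i'\}), \qquad
   \hat L_{\mathrm{HJB}} = \frac1{N'}\sum_i \mathcal N(V)(x_i')^2 , $$

where the $x_i'$ are drawn from a *broader* distribution that does reach the
transition regions. Two enhancement rules are built in
(`training_config(enhancement = ...)`):

* `larger_noise`: simulate a second ensemble at $D' > D$ (its steady density
  $\propto p_{ss}^{D/D'}$ is flatter and covers barriers);
* `perturbation`: add isotropic Gaussian noise of scale $\sigma$ to the
  steady samples, thickening the sampled basins into the inter-basin region.

Defaults are $\lambda_1 = 10$, $\lambda_2 = 1$. The choice of rule matters in
high dimension: at $D' = 10D$ in 12 dimensions the enhanced density is
$\propto p_{ss}^{0.1}$, which spreads mass over a volume so large that the
saddle neighborhood is again sparsely covered, whereas a perturbation scale
$\sigma$ of roughly half the inter-basin distance divided by $\sqrt d$ places
enhanced samples directly on the barrier. The package's 12D default uses the
perturbation rule for this reason.

## Model, optimizer and numerical choices

The potential is a multilayer perceptron with `tanh` activations, by default
three hidden layers of 20 units — deliberately small, since landscapes are
smooth and the loss is convex in $\nabla V$. All derivative quantities are
computed *analytically* in compiled code (RcppArmadillo):

* $\nabla_x V$ by reverse-mode differentiation of the network;
* $\Delta V$ by $d$ second-order forward tangents, row-stacked so each layer
  costs one large matrix product rather than $d$ small ones;
* $\nabla_\theta$ of both loss terms by vector–Jacobian products through
  those recursions.

Every derivative path is tested against central finite differences at
tolerance $\sim 10^{-8}$. Training is minibatch Adam (learning rate $10^{-3}$,
batch 2048; the HJB term, whose per-sample cost scales with $d$, may use a
smaller `hjb_batch_size`), with an optional cosine learning-rate schedule
(`lr_schedule = "cosine"`) that removes the late-training gradient-noise
floor — useful when the HJB term must converge tightly in sparsely sampled
regions. Runs are deterministic given the seed. Double precision throughout.

Steady samples come from `simulate_ensemble()`, a vectorized Euler–Maruyama
integrator over the whole ensemble, with reflecting boundaries on bounded
domains (implemented by the exact tent-map folding of the reflected process)
and resampling of numerically diverged trajectories (more than 10% diverged
aborts with advice to reduce `dt`). For unbounded multistable systems, basins
must be seeded fairly: `init = "auto"` draws uniformly from the system's
domain or its declared `meta$init_box`; starting all mass in one basin is an
initialization artifact that no amount of training repairs, because the loss
only sees where the samples are.

## A worked example

```{r toy, eval = FALSE}
sys <- rotational_toy_quadratic(c = 1, D = 0.1)   # F = -grad U0 + c J grad U0
s   <- simulate_ensemble(sys, D = 0.1, n_traj = 2000, t_final = 10,
                         dt = 0.01, seed = 1, init = "gaussian")
cfg <- training_config(D = 0.1, lambda1 = 10, lambda2 = 1,
                       enhancement = list(type = "larger_noise", D_prime = 0.2),
                       epochs = 800, lr_schedule = "cosine", seed = 1)
fit <- train_potential(sys, s, config = cfg)

ref <- reference_from_potential(sys$potential, rbind(c(-2.2, 2.2), c(-2.2, 2.2)),
                                D = 0.1)
rrmse(fit$model, ref)          # relative L2 error on the effective domain
estimate_epr(fit$model, s, sys) # ~ 2 c^2 D = 0.2
```

Error metrics follow the reference definition: both potentials are restricted
to the effective domain $\{U_0 - \min U_0 \le 20D\}$, min-shifted there, and
compared by the relative norms `rrmse()` / `rmae()`. On two-dimensional
problems the reference can also be computed without the analytic potential by
the built-in finite-element Fokker–Planck solver
(`solve_fpe_reference_2d()`): bilinear Q1 elements on a tensor grid,
reflecting (zero-flux) boundaries, with the singular steady-state system
closed by a trapezoid-rule normalization row (the Q1 test functions partition
unity, so exactly one weak-form row is redundant).

## Dimensionality reduction

For $d \gg 2$ one wants a landscape over two prescribed coordinates
$z = (x_i, x_j)$; the right object is $\tilde U(z) = -D\ln \tilde p(z)$ with
$\tilde p$ the marginal steady density. Two routes are implemented:

* **Route 1** (`train_reduced_potential()`): first regress the *projected
  force* $\tilde F(z) = E_\pi[F_z \mid z]$ with a small two-output network
  (`fit_projected_force()`), then minimize the projected P-EPR + P-HJB
  losses, which take the same form as before with $F \to \tilde F$ and
  $d \to 2$.
* **Route 2** (`marginalize_potential()`): if a full-dimensional potential is
  already available, marginalize $\exp(-V/D)$ over the remaining coordinates
  by a weighted kernel estimate on the sample cloud (separable Gaussian
  product kernels, Silverman bandwidths); cells with insufficient sample
  coverage are masked `NA` rather than extrapolated.

The two routes are independent approximations of the same object; their
agreement on held-out grids is the package's consistency check
(`test-acceptance.R`).

## State-dependent diffusion

For $\mathrm dX = F\,\mathrm dt + \Sigma(X)\,\mathrm dW$ with
$A = \Sigma\Sigma^\top/2$, the landscape minimizes the weighted-norm V-EPR
loss built from the modified force
$F^v = F - D\,\nabla\!\cdot\!A$ and the $A^{-1}$-weighted residual norm
(`vepr_loss()`). When $\Sigma = \sqrt{2D} I$ this reduces — bit-compatibly, as
tested — to the plain EPR loss. The HJB enhancement assumes isotropic
diffusion and is disabled ($\lambda_2 = 0$) in this mode.

## The 12-dimensional benchmark

The package's headline validation (run by `scripts/acceptance.R`) is a
two-component Gaussian-mixture gradient system in $d = 12$
(`gmm12_system()`): weights $(0.6, 0.4)$, component covariances $0.04I$ and
$0.02I$, fixed means roughly $1.33$ apart, at $D = 0.02$ — at this noise the
two wells are separated by a barrier carrying essentially no steady samples.
Because the system is a gradient flow, $U = U_0$ analytically, so the learned
landscape can be scored exactly: relative errors over $10^4$ mixture samples,
a $32\times32$ map of conditional-expectation errors over the first two
coordinates, and the two barrier heights along the inter-mean line. Problem
sizes (ensemble of $10^4$ trajectories to $t = 20$, 2000 training epochs) are
package choices targeting a single-CPU run of under about ten minutes; the
original problem statement prints the benchmark but not its sampling or
optimization budget.

## Limitations

* The method estimates $U$ only where either sample set has support;
  landscapes are untrustworthy far outside the simulated ensemble, and the
  reduction routes mask (rather than extrapolate) uncovered cells.
* The HJB residual assumes isotropic constant diffusion; with a state-
  dependent $\Sigma$ only the plain V-EPR loss is available, so small-$D$
  transition regions are harder there.
* Ergodicity and stationarity of the sample set are assumptions the user
  controls via `t_final`; the package does not test for mixing.
* The FEM reference solver is two-dimensional by design; in higher dimension
  validation must rely on analytic fixtures or consistency checks.
* Barrier heights are read along a straight line between basin minima; for
  strongly curved transition paths this underestimates the saddle.
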