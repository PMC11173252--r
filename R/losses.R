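#' Force-projection (EPR) loss
#'
#' The empirical loss \eqn{(1/N)\sum_i |F(x_i) + \nabla V(x_i)|^2} over a
#' steady-state sample set. Its population version is the squared
#' \eqn{L^2_\pi} distance between the force and the nearest gradient field;
#' its minimizer is the potential \eqn{U = -D\ln p_{ss}} (up to a constant)
#' and its minimum value is the steady entropy production rate.
#'
#' @param model a potential-like object (see [potential_value()]).
#' @param samples an `eprnet_samples` object or a state matrix.
#' @param system the `eprnet_system` supplying the drift.
#' @param drift_values optional precomputed drift matrix at the samples.
#' @return scalar loss.
#' @export
epr_loss <- function(model, samples, system, drift_values = NULL) {
  X <- states_of(samples)
  if (ncol(X) != system$dim) stop("sample dimension does not match the system")
  Fm <- drift_values %||% sys_drift(system, X)
  G <- potential_grad(model, X)
  if (ncol(G) != ncol(X)) stop("model dimension does not match the system")
  mean(rowSums((Fm + G)^2))
}

#' Pointwise HJB residual
#'
#' The viscous HJB operator
#' \eqn{\mathcal{N}(V) = -F\cdot\nabla V + D\Delta V - |\nabla V|^2 +
#' D\,\nabla\cdot F}, which the true potential satisfies identically (for
#' constant isotropic diffusion).
#'
#' @inheritParams epr_loss
#' @param points states at which to evaluate the residual.
#' @param D noise strength.
#' @return vector of residuals, one per row of `points`.
#' @export
hjb_residual <- function(model, points, system, D) {
  if (!is.null(system$diffusion)) {
    stop("HJB residual assumes identity diffusion; use vepr_loss for ",
         "state-dependent diffusion matrices")
  }
  X <- states_of(points)
  Fm <- sys_drift(system, X)
  divF <- sys_drift_div(system, X)
  G <- potential_grad(model, X)
  lap <- potential_laplacian(model, X)
  -rowSums(Fm * G) + D * lap - rowSums(G^2) + D * divF
}

#' HJB loss over an enhanced sample set
#'
#' Mean squared HJB residual over samples from any enhancing distribution
#' (larger noise or Gaussian-perturbed states).
#'
#' @inheritParams hjb_residual
#' @param enhanced_samples sample set representing the enhancing distribution.
#' @export
hjb_loss <- function(model, enhanced_samples, system, D) {
  mean(hjb_residual(model, enhanced_samples, system, D)^2)
}

#' Enhanced loss
#'
#' \eqn{\lambda_1 L_{EPR} + \lambda_2 L_{HJB}}, the training objective for
#' small noise. With `lambda2 = 0` this is the plain ("single EPR") loss and
#' no enhanced set is needed.
#'
#' @inheritParams epr_loss
#' @param enhanced_samples enhanced sample set (required when `lambda2 > 0`).
#' @param config a [training_config()], or any list with `lambda1`, `lambda2`,
#'   `D`.
#' @export
enhanced_loss <- function(model, samples, enhanced_samples, system, config) {
  l1 <- config$lambda1; l2 <- config$lambda2
  out <- l1 * epr_loss(model, samples, system)
  if (l2 > 0) {
    if (is.null(enhanced_samples)) {
      stop("lambda2 > 0 requires an enhanced sample set")
    }
    out <- out + l2 * hjb_loss(model, enhanced_samples, system, config$D)
  }
  out
}

#' Weighted-norm EPR loss for state-dependent diffusion
#'
#' For the Ito SDE with diffusion matrix \eqn{\sigma(x)} and
#' \eqn{a = \sigma\sigma^T}, the potential minimizes
#' \eqn{E_\pi\,|F^v + a\nabla V|^2_{a^{-1}}} with
#' \eqn{F^v = F - D\,\nabla\cdot a} (row-wise divergence). With
#' \eqn{\sigma = I} this reduces exactly to [epr_loss()].
#'
#' @inheritParams epr_loss
#' @param D noise strength.
#' @export
vepr_loss <- function(model, samples, system, D) {
  X <- states_of(samples)
  G <- potential_grad(model, X)
  va <- vepr_arrays(system, X, D)
  r <- va$Fv + matrix(vapply(seq_len(nrow(X)),
                             function(i) drop(va$a[[i]] %*% G[i, ]),
                             numeric(ncol(X))),
                      nrow = nrow(X), ncol = ncol(X), byrow = TRUE)
  mean(vapply(seq_len(nrow(X)),
              function(i) drop(crossprod(r[i, ], va$ainv[[i]] %*% r[i, ])),
              numeric(1)))
}

# per-sample a, a^{-1} and F^v = F - D div(a); errors name the first state at
# which a fails to be positive definite
vepr_arrays <- function(system, X, D) {
  if (is.null(system$diffusion)) {
    stop("system has no diffusion matrix; vepr_loss needs one")
  }
  n <- nrow(X); d <- ncol(X)
  sigma_at <- if (is.matrix(system$diffusion)) {
    function(x) system$diffusion
  } else {
    system$diffusion
  }
  a <- vector("list", n); ainv <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sigma_at(X[i, ])
    ai <- s %*% t(s)
    ok <- tryCatch({ chol(ai); TRUE }, error = function(e) FALSE)
    if (!ok) {
      stop("diffusion matrix a(x) is singular at state (",
           paste(signif(X[i, ], 4), collapse = ", "), ")")
    }
    a[[i]] <- ai
    ainv[[i]] <- chol2inv(chol(ai))
  }
  diva <- if (is.matrix(system$diffusion)) {
    matrix(0, n, d) # constant a has zero divergence
  } else if (!is.null(system$diffusion_div)) {
    matrix(vapply(seq_len(n), function(i) system$diffusion_div(X[i, ]),
                  numeric(d)),
           nrow = n, ncol = d, byrow = TRUE)
  } else {
    numeric_a_divergence(sigma_at, X)
  }
  Fm <- sys_drift(system, X)
  list(a = a, ainv = ainv, Fv = Fm - D * diva)
}

# (div a)_i = sum_j d a_ij / d x_j by central differences, per sample
numeric_a_divergence <- function(sigma_at, X, eps = 1e-5) {
  n <- nrow(X); d <- ncol(X)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    x <- X[i, ]
    for (j in seq_len(d)) {
      h <- eps * (1 + abs(x[j]))
      xp <- x; xm <- x
      xp[j] <- x[j] + h; xm[j] <- x[j] - h
      ap <- sigma_at(xp) %*% t(sigma_at(xp))
      am <- sigma_at(xm) %*% t(sigma_at(xm))
      out[i, ] <- out[i, ] + (ap[, j] - am[, j]) / (2 * h)
    }
  }
  out
}

#' Steady entropy production rate estimate
#'
#' The EPR loss evaluated at a (trained) potential: at the minimizer it equals
#' the steady entropy production rate
#' \eqn{e_p^{ss} = \int |J_{ss}|^2 / p_{ss}\,dx}. Zero for gradient
#' (equilibrium) systems.
#'
#' @param model trained potential (an `eprnet_fit` or model object).
#' @inheritParams epr_loss
#' @export
estimate_epr <- function(model, samples, system) {
  epr_loss(model, samples, system)
}
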