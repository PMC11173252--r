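#' Define a dynamical system
#'
#' The container consumed by every other module: an SDE
#' \eqn{dx/dt = F(x) + \sqrt{2D}\,\dot w} on a domain that is either all of
#' R^d or a hyperrectangle with reflecting boundaries. Drift (and the optional
#' divergence, diffusion matrix, analytic potential and exact sampler) are
#' batched: they take an N x d state matrix and return N x d / length-N
#' results.
#'
#' When no analytic divergence is supplied, \eqn{\nabla\cdot F} is computed by
#' vectorized central finite differences; all built-in constructors provide
#' exact divergences because the HJB residual uses this quantity directly.
#'
#' @param dim state dimension.
#' @param drift function: N x d matrix -> N x d drift matrix.
#' @param drift_divergence optional function: N x d matrix -> length-N vector
#'   of \eqn{\nabla\cdot F}.
#' @param domain NULL (unbounded) or a d x 2 matrix of (low, high) bounds.
#' @param diffusion optional diffusion matrix \eqn{\sigma(x)}: either a
#'   constant d x m matrix or a function of a single state returning one.
#' @param diffusion_div optional analytic row divergence of
#'   \eqn{a = \sigma\sigma^T}: function of a single state returning the
#'   length-d vector with entries \eqn{\sum_j \partial_j a_{ij}}.
#' @param potential optional analytic ground-truth potential
#'   (`eprnet_potential`), on the same scale as \eqn{-D \ln p_{ss}}.
#' @param sampler optional exact steady-state sampler `function(n)` returning
#'   an n x d matrix.
#' @param name label used in reports.
#' @param meta free-form metadata list (used by fixtures).
#' @return object of class `eprnet_system`.
#' @export
dynamical_system <- function(dim, drift, drift_divergence = NULL, domain = NULL,
                             diffusion = NULL, diffusion_div = NULL,
                             potential = NULL, sampler = NULL,
                             name = "custom", meta = list()) {
  stopifnot(is.function(drift), dim >= 1)
  if (!is.null(domain)) {
    domain <- matrix(as.numeric(domain), ncol = 2L)
    if (nrow(domain) == 1L && dim > 1L) {
      domain <- matrix(rep(domain, each = dim), ncol = 2L)
    }
    stopifnot(nrow(domain) == dim)
    if (any(domain[, 1] >= domain[, 2])) {
      stop("domain bounds must satisfy low < high in every coordinate")
    }
  }
  sys <- structure(list(dim = as.integer(dim), drift = drift,
                        drift_divergence = drift_divergence, domain = domain,
                        diffusion = diffusion, diffusion_div = diffusion_div,
                        potential = potential, sampler = sampler, name = name,
                        meta = meta),
                   class = "eprnet_system")
  sys
}

#' @export
print.eprnet_system <- function(x, ...) {
  cat("<eprnet_system> ", x$name, " (d = ", x$dim, ", domain = ",
      if (is.null(x$domain)) "unbounded" else "hyperrectangle",
      if (!is.null(x$diffusion)) ", state-dependent diffusion" else "",
      ")\n", sep = "")
  invisible(x)
}

#' Evaluate drift and drift divergence
#'
#' @param system an `eprnet_system`.
#' @param x state matrix (rows) or single state vector.
#' @return `sys_drift`: drift matrix; `sys_drift_div`: vector of
#'   \eqn{\nabla \cdot F}.
#' @export
sys_drift <- function(system, x) {
  X <- as_states(x, system$dim)
  out <- system$drift(X)
  if (is.null(dim(x))) drop(out) else out
}

#' @rdname sys_drift
#' @export
sys_drift_div <- function(system, x) {
  X <- as_states(x, system$dim)
  if (!is.null(system$drift_divergence)) return(drop(system$drift_divergence(X)))
  numeric_divergence(system$drift, X)
}

# central-difference divergence of a batched vector field
numeric_divergence <- function(drift, X, eps = 1e-5) {
  d <- ncol(X)
  out <- numeric(nrow(X))
  for (j in seq_len(d)) {
    h <- eps * (1 + abs(X[, j]))
    Xp <- X; Xm <- X
    Xp[, j] <- X[, j] + h
    Xm[, j] <- X[, j] - h
    out <- out + (drift(Xp)[, j] - drift(Xm)[, j]) / (2 * h)
  }
  out
}

in_domain <- function(system, X, tol = 1e-9) {
  if (is.null(system$domain)) return(rep(TRUE, nrow(X)))
  lo <- system$domain[, 1]; hi <- system$domain[, 2]
  ok <- rep(TRUE, nrow(X))
  for (j in seq_len(ncol(X))) {
    ok <- ok & X[, j] >= lo[j] - tol & X[, j] <= hi[j] + tol
  }
  ok
}

# --- fixtures ----------------------------------------------------------------

#' Rotational toy system with exactly known steady state
#'
#' Builds the two-dimensional drift \eqn{F = -\nabla U_0 + c J \nabla U_0},
#' where J is the 90-degree rotation matrix. Because
#' \eqn{\nabla\cdot(J\nabla U_0\, e^{-U_0/D}) = 0} identically, the steady
#' density is exactly \eqn{\propto e^{-U_0/D}} for every noise strength D,
#' while the stationary flux (hence the entropy production rate) grows with
#' the rotation strength c. With the default quadratic well the steady EPR is
#' \eqn{2 c^2 D} in closed form, which makes this family the package's primary
#' non-equilibrium test fixture.
#'
#' @param u0 the confining potential: `"quadratic"` or an `eprnet_potential`
#'   with analytic gradient and Laplacian.
#' @param c rotation strength (c = 0 gives detailed balance).
#' @param scale curvature of the quadratic preset.
#' @export
make_rotational_toy <- function(u0 = "quadratic", c = 1, scale = 1) {
  if (identical(u0, "quadratic")) u0 <- quadratic_potential(dim = 2L, scale = scale)
  if (!inherits(u0, "eprnet_potential")) {
    stop("u0 must be \"quadratic\" or an eprnet_potential")
  }
  if (!isTRUE(u0$analytic_grad) || !isTRUE(u0$analytic_lap)) {
    stop("rotational toy needs a smooth confining potential with analytic ",
         "gradient and Laplacian; supply both to make_potential()")
  }
  drift <- function(X) {
    g <- u0$grad(X)
    cbind(-g[, 1] - c * g[, 2], -g[, 2] + c * g[, 1])
  }
  div <- function(X) -drop(u0$laplacian(X))
  sampler <- NULL
  is_quad <- !is.null(attr(u0, "quad_scale")) # set below for the preset
  make_sys <- function(sampler) {
    dynamical_system(2L, drift, drift_divergence = div, potential = u0,
                     sampler = sampler, name = sprintf("rotational_toy(c=%g)", c),
                     meta = list(type = "rotational_toy", c = c))
  }
  make_sys(sampler)
}

#' Rotational toy with quadratic well and its exact Gaussian sampler
#'
#' Convenience wrapper around [make_rotational_toy()] for the quadratic preset
#' that also attaches the exact steady-state sampler N(0, (D/scale) I).
#'
#' @inheritParams make_rotational_toy
#' @param D noise strength under which exact samples are drawn.
#' @export
rotational_toy_quadratic <- function(c = 1, D = 0.1, scale = 1) {
  sys <- make_rotational_toy("quadratic", c = c, scale = scale)
  sd <- sqrt(D / scale)
  sys$sampler <- function(n) matrix(stats::rnorm(2L * n, 0, sd), ncol = 2L)
  sys$meta$D <- D
  sys$meta$epr_exact <- 2 * c^2 * D # c^2 E|x|^2 under the Gaussian, scale-free
  sys
}

#' Lorenz system
#'
#' The classical chaotic drift \eqn{(\beta_1(y-x),\; x(\beta_2-z)-y,\;
#' xy-\beta_3 z)} with constant divergence \eqn{-\beta_1-1-\beta_3}.
#'
#' @param beta1,beta2,beta3 positive parameters; defaults 10, 28, 8/3.
#' @export
lorenz_system <- function(beta1 = 10, beta2 = 28, beta3 = 8 / 3) {
  stopifnot(beta1 > 0, beta2 > 0, beta3 > 0)
  drift <- function(X) {
    cbind(beta1 * (X[, 2] - X[, 1]),
          X[, 1] * (beta2 - X[, 3]) - X[, 2],
          X[, 1] * X[, 2] - beta3 * X[, 3])
  }
  div <- function(X) rep(-beta1 - 1 - beta3, nrow(X))
  dynamical_system(3L, drift, drift_divergence = div, name = "lorenz",
                   meta = list(type = "lorenz", beta = c(beta1, beta2, beta3)))
}

#' Gaussian-mixture gradient system
#'
#' Constructs the gradient system whose steady density at noise strength D is
#' exactly the mixture \eqn{p_0 = \sum_i w_i N(\mu_i, \Sigma_i)}: the ground
#' truth is \eqn{U_0 = -D \ln p_0} (normalization constants included) and the
#' drift is \eqn{F = -\nabla U_0 = D \nabla \ln p_0}. Supports isotropic
#' (scalar variance) and full covariance components; value, gradient and
#' Laplacian of \eqn{U_0} are analytic, and the exact sampler draws from the
#' mixture.
#'
#' @param weights mixture weights (must sum to 1).
#' @param means k x d matrix of component means (or a list of vectors).
#' @param covariances either a length-k numeric vector s_i (meaning
#'   \eqn{\Sigma_i = s_i I}) or a list of d x d positive-definite matrices.
#' @param D noise strength defining the potential scale.
#' @export
gmm_system <- function(weights, means, covariances, D) {
  if (is.list(means)) means <- do.call(rbind, means)
  means <- as.matrix(means)
  k <- length(weights); d <- ncol(means)
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (nrow(means) != k) stop("means/weights dimension mismatch")
  if (is.numeric(covariances) && !is.list(covariances)) {
    if (length(covariances) != k) stop("covariances/weights dimension mismatch")
    covs <- lapply(covariances, function(s) diag(s, d))
  } else {
    covs <- covariances
    if (length(covs) != k) stop("covariances/weights dimension mismatch")
    if (any(vapply(covs, function(S) nrow(S) != d || ncol(S) != d, logical(1)))) {
      stop("each covariance must be d x d")
    }
  }
  inv <- lapply(covs, solve)
  chol_u <- lapply(covs, chol)
  logdet <- vapply(covs, function(S) determinant(S, logarithm = TRUE)$modulus[1],
                   numeric(1))
  trinv <- vapply(inv, function(M) sum(diag(M)), numeric(1))
  lw <- log(weights)

  # log p0, grad log p0 and Delta log p0, batched
  mix_stats <- function(X) {
    n <- nrow(X)
    L <- matrix(0, n, k)      # log(w_i N_i)
    Svecs <- vector("list", k) # Sigma_i^{-1} (x - mu_i)
    for (i in seq_len(k)) {
      M <- sweep(X, 2L, means[i, ])
      Si <- M %*% inv[[i]]
      Svecs[[i]] <- Si
      quad <- rowSums(M * Si)
      L[, i] <- lw[i] - 0.5 * quad - 0.5 * (d * log(2 * pi) + logdet[i])
    }
    m <- apply(L, 1L, max)
    logp <- m + log(rowSums(exp(L - m)))
    R <- exp(L - logp) # responsibilities
    g <- matrix(0, n, d)
    dpp <- numeric(n) # Delta p / p
    for (i in seq_len(k)) {
      g <- g - R[, i] * Svecs[[i]]
      dpp <- dpp + R[, i] * (rowSums(Svecs[[i]]^2) - trinv[i])
    }
    list(logp = logp, g = g, dlogp = dpp - rowSums(g^2))
  }

  pot <- make_potential(
    value = function(X) -D * mix_stats(X)$logp,
    grad = function(X) -D * mix_stats(X)$g,
    laplacian = function(X) -D * mix_stats(X)$dlogp,
    dim = d
  )
  drift <- function(X) D * mix_stats(X)$g
  div <- function(X) D * mix_stats(X)$dlogp
  sampler <- function(n) {
    comp <- sample.int(k, n, replace = TRUE, prob = weights)
    Z <- matrix(stats::rnorm(n * d), n, d)
    X <- matrix(0, n, d)
    for (i in seq_len(k)) {
      idx <- comp == i
      if (any(idx)) {
        X[idx, ] <- sweep(Z[idx, , drop = FALSE] %*% chol_u[[i]], 2L,
                          means[i, ], "+")
      }
    }
    X
  }
  dynamical_system(d, drift, drift_divergence = div, potential = pot,
                   sampler = sampler, name = sprintf("gmm_%dd_%dcomp", d, k),
                   meta = list(type = "gmm", weights = weights, means = means,
                               covs = covs, D = D,
                               mix_stats = mix_stats,
                               # ensemble-initialization region spanning all
                               # components (basin-fair seeding at small D)
                               init_box = cbind(
                                 apply(means, 2L, min) - 4 * sqrt(max(vapply(
                                   covs, function(S) max(diag(S)), 1))),
                                 apply(means, 2L, max) + 4 * sqrt(max(vapply(
                                   covs, function(S) max(diag(S)), 1))))))
}

#' Twelve-dimensional two-component mixture fixture
#'
#' The built-in 12D bistable benchmark: a two-component Gaussian mixture with
#' weights 0.6/0.4, two fixed 12-dimensional means, and isotropic
#' covariances 0.04 I and 0.02 I. The gradient system constructed from it has
#' this mixture as its exact steady density at noise strength `D`.
#'
#' @param D noise strength (default 0.02).
#' @export
gmm12_system <- function(D = 0.02) {
  mu1 <- c(1.2, 2.0, 0.6, 1.5, 0.9, 1.5, 1.5, 0.9, 1.2, 1.2, 0.5, 1.8)
  mu2 <- c(1.8, 1.4, 0.8, 0.9, 0.9, 1.5, 2.0, 1.0, 1.6, 1.0, 0.7, 1.4)
  gmm_system(weights = c(0.6, 0.4), means = rbind(mu1, mu2),
             covariances = c(0.04, 0.02), D = D)
}

#' Hill-type gene regulatory network
#'
#' Builds the d-dimensional drift
#' \deqn{F_i(x) = -k x_i + \sum_{j \in A_i} \frac{a x_j^n}{S^n + x_j^n}
#'       + \sum_{j \in R_i} \frac{b S^n}{S^n + x_j^n},}
#' where \eqn{A_i} and \eqn{R_i} index the activators and repressors of node
#' i. The drift divergence is analytic (only self-loops contribute beyond the
#' degradation term). The default domain is the hyperrectangle [0, 3]^d with
#' reflecting boundaries.
#'
#' @param activators list of integer vectors, `activators[[i]]` = indices
#'   activating node i.
#' @param repressors list of integer vectors, same layout.
#' @param a,b,k,S positive rate constants; defaults a = 0.37, b = 0.5, k = 1,
#'   S = 0.5.
#' @param n Hill coefficient (>= 1); default 3.
#' @param domain per-coordinate bounds, default c(0, 3).
#' @export
gene_network_system <- function(activators, repressors, a = 0.37, b = 0.5,
                                k = 1, S = 0.5, n = 3, domain = c(0, 3)) {
  stopifnot(a > 0, b > 0, k > 0, S > 0, n >= 1)
  d <- length(activators)
  if (length(repressors) != d) stop("activators/repressors length mismatch")
  Amask <- matrix(0, d, d); Rmask <- matrix(0, d, d)
  for (i in seq_len(d)) {
    ai <- activators[[i]]; ri <- repressors[[i]]
    if (length(ai) && (any(ai < 1) || any(ai > d))) stop("invalid activator index")
    if (length(ri) && (any(ri < 1) || any(ri > d))) stop("invalid repressor index")
    Amask[i, ai] <- 1
    Rmask[i, ri] <- 1
  }
  Sn <- S^n
  check_states <- function(X) {
    if (n %% 1 != 0 && isTRUE(any(X < 0))) {
      stop("negative state with non-integer Hill coefficient: domain error")
    }
  }
  drift <- function(X) {
    check_states(X)
    xn <- X^n
    hact <- a * xn / (Sn + xn)      # activation input from each node
    hrep <- b * Sn / (Sn + xn)      # repression input from each node
    -k * X + hact %*% t(Amask) + hrep %*% t(Rmask)
  }
  div <- function(X) {
    check_states(X)
    xn <- X^n
    dh <- n * Sn * X^(n - 1) / (Sn + xn)^2 # d/dx of x^n/(S^n+x^n)
    self_act <- sweep(dh, 2L, diag(Amask), "*")
    self_rep <- sweep(dh, 2L, diag(Rmask), "*")
    -k * d + a * rowSums(self_act) - b * rowSums(self_rep)
  }
  dom <- matrix(rep(domain, each = d), ncol = 2L)
  dynamical_system(d, drift, drift_divergence = div, domain = dom,
                   name = sprintf("gene_network_%dd", d),
                   meta = list(type = "gene_network", a = a, b = b, k = k,
                               S = S, n = n, Amask = Amask, Rmask = Rmask))
}

# --- configuration loading ---------------------------------------------------

#' Build a system from a configuration list or YAML/JSON file
#'
#' Supported `type` values: `rotational_toy` (fields `c`, `scale`, optional
#' `D` for the exact sampler), `lorenz` (`beta1..beta3`), `gmm` (`weights`,
#' `means`, `covariances`, `D`), `gmm12` (`D`), `gene_network` (`activators`,
#' `repressors` as 1-based index lists, rate constants, `domain`), and
#' `custom` with `dim`, per-coordinate drift expressions in variables
#' `x1..xd` (divergence then computed by finite differences unless `divergence`
#' expressions are given), and optional `domain`.
#'
#' @param config a list, or a path to a YAML or JSON file containing one.
#' @export
system_from_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  type <- config$type %||% stop("system config needs a 'type' field")
  get <- function(f, default) config[[f]] %||% default
  sys <- switch(type,
    rotational_toy = {
      if (!is.null(config$D)) {
        rotational_toy_quadratic(c = get("c", 1), D = config$D,
                                 scale = get("scale", 1))
      } else {
        make_rotational_toy("quadratic", c = get("c", 1), scale = get("scale", 1))
      }
    },
    lorenz = lorenz_system(get("beta1", 10), get("beta2", 28), get("beta3", 8 / 3)),
    gmm = gmm_system(config$weights, do.call(rbind, lapply(config$means, unlist)),
                     if (is.list(config$covariances)) {
                       lapply(config$covariances, function(S) matrix(unlist(S), nrow = sqrt(length(unlist(S)))))
                     } else config$covariances,
                     config$D),
    gmm12 = gmm12_system(get("D", 0.02)),
    gene_network = gene_network_system(
      lapply(config$activators, as.integer),
      lapply(config$repressors, as.integer),
      a = get("a", 0.37), b = get("b", 0.5), k = get("k", 1),
      S = get("S", 0.5), n = get("n", 3), domain = unlist(get("domain", c(0, 3)))
    ),
    custom = custom_system_from_config(config),
    stop("unknown system type: ", type)
  )
  sys$meta$config <- config # keep the description for round-tripping
  sys
}

custom_system_from_config <- function(config) {
  d <- as.integer(config$dim)
  exprs <- lapply(config$drift, function(s) parse(text = s)[[1]])
  if (length(exprs) != d) stop("custom system needs one drift expression per coordinate")
  env_of <- function(X) {
    e <- new.env(parent = baseenv())
    for (j in seq_len(d)) assign(paste0("x", j), X[, j], envir = e)
    e
  }
  drift <- function(X) {
    e <- env_of(X)
    do.call(cbind, lapply(exprs, eval, envir = e))
  }
  div <- NULL
  if (!is.null(config$divergence)) {
    dexpr <- parse(text = config$divergence)[[1]]
    div <- function(X) {
      v <- eval(dexpr, envir = env_of(X))
      rep_len(v, nrow(X))
    }
  }
  dynamical_system(d, drift, drift_divergence = div,
                   domain = if (!is.null(config$domain)) {
                     matrix(unlist(config$domain), ncol = 2L, byrow = is.list(config$domain))
                   },
                   name = config$name %||% "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
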