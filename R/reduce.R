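#' Reduced-coordinate specification
#'
#' Names the two coordinates of interest \eqn{z = (x_i, x_j)}, the reduced
#' evaluation domain and the lattice resolution used for comparisons. Reduced
#' variables are always user-prescribed (typically from biophysical prior
#' knowledge, e.g. a pair of marker genes).
#'
#' @param z_indices two distinct coordinate indices.
#' @param reduced_domain optional 2 x 2 bounds matrix for z; defaults to the
#'   sample range when needed.
#' @param grid lattice resolution per axis (>= 32 for comparisons).
#' @export
reduced_spec <- function(z_indices, reduced_domain = NULL, grid = 64L) {
  z_indices <- as.integer(z_indices)
  if (length(z_indices) != 2L || z_indices[1] == z_indices[2]) {
    stop("z_indices must be two distinct coordinate indices")
  }
  if (grid < 32L) stop("grid resolution must be at least 32 per axis")
  if (!is.null(reduced_domain)) {
    reduced_domain <- matrix(as.numeric(reduced_domain), ncol = 2L)
  }
  structure(list(z_indices = z_indices, reduced_domain = reduced_domain,
                 grid = as.integer(grid)),
            class = "eprnet_reduced_spec")
}

check_spec_dim <- function(spec, system) {
  if (any(spec$z_indices > system$dim)) {
    stop("z_indices exceed the system dimension")
  }
}

#' Evaluate a projected force model
#'
#' @param model an `eprnet_force_model` from [fit_projected_force()].
#' @param z matrix of reduced states (rows).
#' @return `force_value`: n x 2 matrix of the learned projected force;
#'   `force_divergence`: length-n vector of \eqn{\nabla_z\cdot \tilde G}
#'   (exact, via forward tangents).
#' @export
force_value <- function(model, z) {
  cpp_mlp_value(model$par, model$dims, as_states(z, 2L))
}

#' @rdname force_value
#' @export
force_divergence <- function(model, z) {
  Z <- as_states(z, 2L)
  n <- nrow(Z)
  e1 <- matrix(rep(c(1, 0), each = n), n, 2L)
  e2 <- matrix(rep(c(0, 1), each = n), n, 2L)
  cpp_mlpk_jvp(model$par, model$dims, Z, e1)[, 1] +
    cpp_mlpk_jvp(model$par, model$dims, Z, e2)[, 2]
}

#' Learn the projected force by least-squares regression
#'
#' Trains a small network \eqn{\tilde G(z;\theta)} on
#' \eqn{(1/N)\sum_i |F_z(y_i, z_i) - \tilde G(z_i)|^2}; the population
#' minimizer is the conditional expectation
#' \eqn{\tilde F(z) = E_\pi[F_z \mid z]}. A warning is emitted when the
#' occupied region of z space is thinly covered.
#'
#' @param samples full-space steady samples.
#' @param system the dynamical system.
#' @param spec a [reduced_spec()].
#' @param epochs,batch_size,lr,hidden,seed optimizer settings.
#' @param min_per_bin coverage warning threshold (median samples per occupied
#'   16 x 16 bin).
#' @return an `eprnet_force_model`.
#' @export
fit_projected_force <- function(samples, system, spec, epochs = 1000L,
                                batch_size = 2048L, lr = 1e-3,
                                hidden = c(20L, 20L, 20L), seed = 1L,
                                min_per_bin = 5) {
  check_spec_dim(spec, system)
  X <- states_of(samples)
  Z <- X[, spec$z_indices, drop = FALSE]
  Fz <- sys_drift(system, X)[, spec$z_indices, drop = FALSE]
  cover <- table(cut(Z[, 1], 16L), cut(Z[, 2], 16L))
  if (stats::median(cover[cover > 0]) < min_per_bin) {
    warning("sparse coverage of the reduced plane: learned projected force ",
            "may be unreliable in thin regions")
  }
  set.seed(seed)
  dims <- as.integer(c(2L, hidden, 2L))
  model <- mlp_potential(2L, hidden = hidden, dim_out = 2L)
  par <- model$par
  opt <- adam_new(length(par))
  n <- nrow(Z); bs <- min(batch_size, n)
  steps <- max(1L, floor(n / bs))
  for (ep in seq_len(epochs)) {
    for (s in seq_len(steps)) {
      idx <- sample.int(n, bs)
      g <- cpp_mlpk_loss_grad(par, dims, Z[idx, , drop = FALSE],
                              Fz[idx, , drop = FALSE], TRUE)
      if (!is.finite(g$loss)) stop("non-finite regression loss at epoch ", ep)
      upd <- adam_step(opt, par, g$grad, lr)
      par <- upd$par; opt <- upd$state
    }
  }
  model$par <- par
  structure(list(dims = dims, par = par, z_indices = spec$z_indices),
            class = "eprnet_force_model")
}

#' Projected force-projection loss
#'
#' \eqn{(1/N)\sum_i |F_z(y_i, z_i) + \nabla_z \tilde V(z_i)|^2}; its
#' population minimizer is the reduced potential
#' \eqn{\tilde U = -D \ln \tilde p_{ss}} of the marginal steady density over
#' z. When z comprises all coordinates this coincides with [epr_loss()].
#'
#' @param reduced_model potential-like object over z (2D input).
#' @param samples full-space samples.
#' @param system the dynamical system.
#' @param spec a [reduced_spec()].
#' @export
p_epr_loss <- function(reduced_model, samples, system, spec) {
  check_spec_dim(spec, system)
  X <- states_of(samples)
  Z <- X[, spec$z_indices, drop = FALSE]
  Fz <- sys_drift(system, X)[, spec$z_indices, drop = FALSE]
  G <- potential_grad(reduced_model, Z)
  mean(rowSums((Fz + G)^2))
}

#' Projected HJB loss
#'
#' Mean squared projected-HJB residual
#' \eqn{-\tilde G\cdot\nabla_z\tilde V + D\Delta_z\tilde V -
#' |\nabla_z\tilde V|^2 + D\,\nabla_z\cdot\tilde G} over enhanced z samples,
#' with the projected force \eqn{\tilde G} learned beforehand
#' (two-stage procedure).
#'
#' @param reduced_model potential-like object over z.
#' @param reduced_force an `eprnet_force_model`.
#' @param z_points enhanced reduced states (matrix or sample set).
#' @param D noise strength.
#' @export
p_hjb_loss <- function(reduced_model, reduced_force, z_points, D) {
  Z <- states_of(z_points)[, 1:2, drop = FALSE]
  Gt <- force_value(reduced_force, Z)
  divG <- force_divergence(reduced_force, Z)
  g <- potential_grad(reduced_model, Z)
  lap <- potential_laplacian(reduced_model, Z)
  mean((-rowSums(Gt * g) + D * lap - rowSums(g^2) + D * divG)^2)
}

#' Train a reduced potential over two prescribed coordinates
#'
#' Two-stage procedure: learn the projected force \eqn{\tilde G} by
#' regression, then minimize
#' \eqn{\lambda_1 L_{P\mathrm{-}EPR} + \lambda_2 L_{P\mathrm{-}HJB}} where the
#' projection term uses the per-sample z-components of the full drift and the
#' HJB term uses \eqn{\tilde G} on enhanced z samples (Gaussian-perturbed
#' projections by default).
#'
#' @param system the dynamical system.
#' @param samples full-space steady samples.
#' @param spec a [reduced_spec()].
#' @param config a [training_config()]; its `enhancement` entry may be
#'   `list(type = "perturbation", sigma = ...)` (default sigma: half the
#'   per-axis sample standard deviation).
#' @param enhanced_z optional explicit matrix of enhanced z states.
#' @param force_epochs,force_seed stage-one settings.
#' @return list of class `eprnet_reduced_fit` with the reduced potential
#'   (`model`), the projected force (`force`) and the loss `trace`.
#' @export
train_reduced_potential <- function(system, samples, spec, config,
                                    enhanced_z = NULL, force_epochs = 1000L,
                                    force_seed = config$seed + 100L) {
  check_spec_dim(spec, system)
  X <- states_of(samples)
  Z <- X[, spec$z_indices, drop = FALSE]
  Fz <- sys_drift(system, X)[, spec$z_indices, drop = FALSE]
  force <- fit_projected_force(samples, system, spec, epochs = force_epochs,
                               batch_size = config$batch_size, lr = config$lr,
                               seed = force_seed)
  Xe <- NULL; Fe <- NULL; divFe <- NULL
  if (config$lambda2 > 0) {
    if (is.null(enhanced_z)) {
      enh <- config$enhancement
      sigma <- enh$sigma %||% (0.5 * mean(apply(Z, 2L, stats::sd)))
      set.seed(config$seed + 1L)
      Xe <- Z + matrix(stats::rnorm(length(Z), 0, sigma), nrow(Z), 2L)
    } else {
      Xe <- as_states(enhanced_z, 2L)
    }
    Fe <- force_value(force, Xe)
    divFe <- force_divergence(force, Xe)
  }
  dims <- as.integer(c(2L, config$hidden, 1L))
  out <- train_core(dims, Z, Fz, config$lambda1, config$lambda2, Xe, Fe, divFe,
                    config$D, config$epochs, config$batch_size, config$lr,
                    config$seed, config$trace_every)
  structure(list(model = out$model, force = force, trace = out$trace,
                 spec = spec, config = config),
            class = "eprnet_reduced_fit")
}

#' @export
potential_value.eprnet_reduced_fit <- function(model, x) {
  potential_value(model$model, x)
}

#' @export
potential_grad.eprnet_reduced_fit <- function(model, x) {
  potential_grad(model$model, x)
}

#' @export
potential_laplacian.eprnet_reduced_fit <- function(model, x) {
  potential_laplacian(model$model, x)
}

#' Marginalize a high-dimensional potential onto two coordinates
#'
#' Estimates the reduced steady density
#' \eqn{\tilde p(z) \propto \sum_i w(x_i) K_h(z - z_i)} on a lattice with a
#' product Gaussian kernel and returns \eqn{-D \ln \tilde p}. With identity
#' weights (the default) the samples are taken as already Boltzmann-distributed
#' and the estimator reduces to a kernel density estimate of the marginal;
#' with `weights = "boltzmann"` the samples are self-normalized-reweighted to
#' the model's own Boltzmann density \eqn{e^{-V/D}/\hat p}, where `phat`
#' estimates the sampling density. Thinly covered cells are masked (NA), not
#' extrapolated.
#'
#' @param model trained high-dimensional potential.
#' @param samples full-space samples covering the steady distribution.
#' @param spec a [reduced_spec()].
#' @param D noise strength.
#' @param bandwidth per-axis kernel bandwidths (default: Silverman plug-in).
#' @param weights `"identity"` or `"boltzmann"`.
#' @param phat optional sampling-density estimate, a function of the full
#'   state matrix (required only for `"boltzmann"` when the samples are not
#'   already steady-state).
#' @param min_count minimum effective sample count within 2 bandwidths for a
#'   cell to be reported.
#' @return an `eprnet_reference` with `source = "marginalized"` (masked cells
#'   NA).
#' @export
marginalize_potential <- function(model, samples, spec, D, bandwidth = NULL,
                                  weights = c("identity", "boltzmann"),
                                  phat = NULL, min_count = 5) {
  weights <- match.arg(weights)
  X <- states_of(samples)
  Z <- X[, spec$z_indices, drop = FALSE]
  n <- nrow(Z)
  w <- if (weights == "identity") {
    rep(1 / n, n)
  } else {
    logw <- -potential_value(model, X) / D
    if (!is.null(phat)) logw <- logw - log(pmax(phat(X), 1e-300))
    lw <- logw - max(logw)
    exp(lw) / sum(exp(lw))
  }
  dom <- spec$reduced_domain %||% rbind(range(Z[, 1]), range(Z[, 2]))
  g1 <- seq(dom[1, 1], dom[1, 2], length.out = spec$grid)
  g2 <- seq(dom[2, 1], dom[2, 2], length.out = spec$grid)
  h <- bandwidth %||% (1.06 * apply(Z, 2L, stats::sd) * n^(-1 / 6))
  K1 <- exp(-outer(g1, Z[, 1], "-")^2 / (2 * h[1]^2)) / (sqrt(2 * pi) * h[1])
  K2 <- exp(-outer(g2, Z[, 2], "-")^2 / (2 * h[2]^2)) / (sqrt(2 * pi) * h[2])
  ptilde <- K1 %*% (w * t(K2)) # grid1 x grid2
  # coverage: effective number of samples within 2 bandwidths of each node
  C1 <- (abs(outer(g1, Z[, 1], "-")) < 2 * h[1]) * 1
  C2 <- (abs(outer(g2, Z[, 2], "-")) < 2 * h[2]) * 1
  counts <- C1 %*% t(C2)
  U <- -D * log(pmax(ptilde, 1e-300))
  U[counts < min_count] <- NA_real_
  ref <- reference_solution(g1, g2, U, D, "marginalized")
  ref$counts <- counts
  ref
}

#' Export a gridded reduced potential or force field as tidy CSV
#'
#' @param obj an `eprnet_reference` (gridded potential) or
#'   `eprnet_force_model` with a prescribed grid.
#' @param path output CSV path.
#' @param spec needed to grid a force model.
#' @export
write_reduced_grid <- function(obj, path, spec = NULL) {
  if (inherits(obj, "eprnet_reference")) {
    df <- data.frame(z1 = rep(obj$x1, length(obj$x2)),
                     z2 = rep(obj$x2, each = length(obj$x1)),
                     value = as.vector(obj$U))
  } else if (inherits(obj, "eprnet_force_model")) {
    if (is.null(spec) || is.null(spec$reduced_domain)) {
      stop("gridding a force model needs a spec with a reduced_domain")
    }
    g1 <- seq(spec$reduced_domain[1, 1], spec$reduced_domain[1, 2],
              length.out = spec$grid)
    g2 <- seq(spec$reduced_domain[2, 1], spec$reduced_domain[2, 2],
              length.out = spec$grid)
    Z <- as.matrix(expand.grid(g1, g2))
    Fv <- force_value(obj, Z)
    df <- data.frame(z1 = Z[, 1], z2 = Z[, 2], f1 = Fv[, 1], f2 = Fv[, 2])
  } else {
    stop("unsupported object")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
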