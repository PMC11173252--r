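#' Steady-state sample sets
#'
#' A `eprnet_samples` object holds an N x d matrix of states approximating the
#' steady distribution (or an enhanced distribution), together with the noise
#' strength that generated it and provenance metadata.
#'
#' @param states N x d numeric matrix.
#' @param noise_strength the D (or D') under which the states were generated.
#' @param provenance one of `steady_ensemble`, `long_trajectory`,
#'   `larger_noise`, `gaussian_perturbed`, `analytic`.
#' @param seed,dt,t_final,burn_in_time simulation metadata (NA when not
#'   applicable).
#' @export
sample_set <- function(states, noise_strength, provenance = "steady_ensemble",
                       seed = NA_integer_, dt = NA_real_, t_final = NA_real_,
                       burn_in_time = NA_real_) {
  states <- as_states(states)
  if (nrow(states) < 1L) stop("sample set must contain at least one state")
  if (!all(is.finite(states))) stop("sample set contains non-finite states")
  provenance <- match.arg(provenance, c("steady_ensemble", "long_trajectory",
                                        "pair_interpolation",
                                        "larger_noise", "gaussian_perturbed",
                                        "analytic"))
  structure(list(states = states, noise_strength = noise_strength,
                 provenance = provenance, seed = seed, dt = dt,
                 t_final = t_final, burn_in_time = burn_in_time),
            class = "eprnet_samples")
}

#' @export
print.eprnet_samples <- function(x, ...) {
  cat("<eprnet_samples> N = ", nrow(x$states), ", d = ", ncol(x$states),
      ", D = ", format(x$noise_strength), ", provenance = ", x$provenance,
      "\n", sep = "")
  invisible(x)
}

#' Extract the state matrix from a sample set (or pass a matrix through)
#'
#' @param x an `eprnet_samples` object, matrix or numeric vector.
#' @return numeric matrix, one state per row.
#' @export
states_of <- function(x) {
  if (inherits(x, "eprnet_samples")) x$states else as_states(x)
}

# fold states back into a hyperrectangle (reflecting boundaries); exact for
# arbitrarily large excursions via the 2(hi-lo)-periodic tent map
reflect_into <- function(X, domain) {
  if (is.null(domain)) return(X)
  for (j in seq_len(ncol(X))) {
    lo <- domain[j, 1]; hi <- domain[j, 2]
    L <- hi - lo
    y <- (X[, j] - lo) %% (2 * L)
    X[, j] <- lo + ifelse(y > L, 2 * L - y, y)
  }
  X
}

#' Simulate a steady-state ensemble by Euler-Maruyama integration
#'
#' Integrates N independent trajectories of the SDE and returns their end
#' states (default), or thins a single long trajectory. Reflecting boundaries
#' are enforced by coordinate-wise folding at hyperrectangle faces. For
#' systems with a state-dependent diffusion matrix the Ito increment
#' \eqn{\sqrt{2D\,dt}\,\sigma(x)\xi} is used. Trajectories that reach a
#' non-finite state are resampled (with a diagnostic message); more than 10
#' percent resampled is treated as a sign that `dt` is too large and raises an
#' error.
#'
#' @param system an `eprnet_system`.
#' @param D noise strength (>= 0).
#' @param n_traj number of samples N.
#' @param t_final integration time; must be much longer than the system's
#'   relaxation time (per-fixture defaults are documented in the vignette).
#' @param dt time step.
#' @param init initialization rule: `"auto"` (uniform over a bounded domain,
#'   Gaussian around `init_center` otherwise), `"uniform"`, `"gaussian"`,
#'   `"analytic"` (exact sampler), or `"fixed"` (rows of `init_states`).
#' @param init_center,init_sd centre and scale of the Gaussian rule.
#' @param init_states matrix of starting states for `init = "fixed"`.
#' @param seed integer seed; the returned ensemble is deterministic given all
#'   arguments.
#' @param method `"endpoints"` (N independent trajectories) or `"trajectory"`
#'   (one long thinned trajectory).
#' @param burn_in_time,thin_time burn-in and spacing for the trajectory
#'   method.
#' @return an `eprnet_samples` object.
#' @export
simulate_ensemble <- function(system, D, n_traj = 10000L, t_final = 20,
                              dt = 0.01, init = c("auto", "uniform", "gaussian",
                                                  "analytic", "fixed"),
                              init_center = NULL, init_sd = 1,
                              init_states = NULL, seed = NULL,
                              method = c("endpoints", "trajectory"),
                              burn_in_time = t_final, thin_time = 10 * dt) {
  init <- match.arg(init)
  method <- match.arg(method)
  stopifnot(dt > 0, t_final > 0, D >= 0, n_traj >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- system$dim

  draw_init <- function(n) {
    if (init == "analytic") {
      if (is.null(system$sampler)) stop("system has no analytic sampler")
      return(system$sampler(n))
    }
    if (init == "fixed") {
      if (is.null(init_states)) stop("init = \"fixed\" needs init_states")
      S <- as_states(init_states, d)
      return(S[rep_len(seq_len(nrow(S)), n), , drop = FALSE])
    }
    # initialization region: the bounded domain, else a fixture-declared
    # init_box covering all metastable states (multistable systems must be
    # seeded across basins, not from a single point)
    box <- system$domain %||% system$meta$init_box
    use_uniform <- init == "uniform" || (init == "auto" && !is.null(box))
    if (use_uniform) {
      if (is.null(box)) stop("uniform initialization needs a bounded domain")
      lo <- box[, 1]; hi <- box[, 2]
      matrix(stats::runif(n * d, rep(lo, each = n), rep(hi, each = n)), n, d)
    } else {
      ctr <- init_center %||% rep(0, d)
      sweep(matrix(stats::rnorm(n * d, 0, init_sd), n, d), 2L, ctr, "+")
    }
  }

  integrate_em <- function(X, n_steps) {
    n <- nrow(X)
    amp <- sqrt(2 * D * dt)
    const_sigma <- is.matrix(system$diffusion)
    for (s in seq_len(n_steps)) {
      Fx <- system$drift(X)
      if (D > 0) {
        Z <- matrix(stats::rnorm(n * d), n, d)
        if (is.null(system$diffusion)) {
          X <- X + Fx * dt + amp * Z
        } else if (const_sigma) {
          X <- X + Fx * dt + amp * (Z %*% t(system$diffusion))
        } else {
          for (i in seq_len(n)) {
            X[i, ] <- X[i, ] + Fx[i, ] * dt +
              amp * drop(system$diffusion(X[i, ]) %*% Z[i, ])
          }
        }
      } else {
        X <- X + Fx * dt
      }
      X <- reflect_into(X, system$domain)
      # keep runaway trajectories from polluting arithmetic; they are
      # detected and resampled at the end
      X[!is.finite(X)] <- NA_real_
    }
    X
  }

  n_steps <- ceiling(t_final / dt)
  if (method == "endpoints") {
    X <- integrate_em(draw_init(n_traj), n_steps)
    bad <- !stats::complete.cases(X)
    n_resampled <- 0L
    tries <- 0L
    while (any(bad) && tries < 5L) {
      n_resampled <- n_resampled + sum(bad)
      if (n_resampled > 0.1 * n_traj) {
        stop("more than 10% of trajectories diverged; decrease dt")
      }
      X[bad, ] <- integrate_em(draw_init(sum(bad)), n_steps)
      bad <- !stats::complete.cases(X)
      tries <- tries + 1L
    }
    if (any(bad)) stop("trajectories kept diverging after resampling; decrease dt")
    if (n_resampled > 0) {
      message(n_resampled, " diverged trajectories were resampled")
    }
    sample_set(X, D, "steady_ensemble", seed = seed %||% NA_integer_, dt = dt,
               t_final = t_final)
  } else {
    thin_steps <- max(1L, round(thin_time / dt))
    X <- integrate_em(draw_init(1L), ceiling(burn_in_time / dt))
    out <- matrix(NA_real_, n_traj, d)
    for (i in seq_len(n_traj)) {
      X <- integrate_em(X, thin_steps)
      out[i, ] <- X
    }
    if (!all(is.finite(out))) stop("long trajectory diverged; decrease dt")
    sample_set(out, D, "long_trajectory", seed = seed %||% NA_integer_, dt = dt,
               t_final = burn_in_time + n_traj * thin_steps * dt,
               burn_in_time = burn_in_time)
  }
}

#' Enhanced samples from a larger noise strength
#'
#' Draws an independent ensemble from the same system at noise strength
#' `D_prime > D`; the broader distribution covers transition regions where the
#' HJB residual is otherwise unconstrained.
#'
#' @inheritParams simulate_ensemble
#' @param D_prime the larger noise strength D'.
#' @param ... passed to [simulate_ensemble()].
#' @export
enhance_by_larger_noise <- function(system, D, D_prime, ...) {
  stopifnot(D_prime > 0)
  if (D_prime <= D) {
    warning("D_prime <= D: enhanced samples will not be broader than the base ensemble")
  }
  out <- simulate_ensemble(system, D = D_prime, ...)
  out$provenance <- "larger_noise"
  out
}

#' Enhanced samples by Gaussian perturbation
#'
#' Adds i.i.d. centered Gaussian noise with per-coordinate standard deviation
#' `sigma` to each state; states are folded back into the domain when the
#' system is bounded.
#'
#' @param samples an `eprnet_samples` object.
#' @param sigma perturbation standard deviation (>= 0).
#' @param seed optional integer seed.
#' @param system optional system whose domain is used for re-reflection.
#' @export
enhance_by_perturbation <- function(samples, sigma, seed = NULL, system = NULL) {
  stopifnot(sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  X <- states_of(samples)
  if (sigma > 0) {
    X <- X + matrix(stats::rnorm(length(X), 0, sigma), nrow(X), ncol(X))
  }
  if (!is.null(system)) X <- reflect_into(X, system$domain)
  out <- sample_set(X, samples$noise_strength, "gaussian_perturbed",
                    seed = seed %||% NA_integer_, dt = samples$dt,
                    t_final = samples$t_final)
  out
}

#' Enhanced samples on transition paths between sampled states
#'
#' Draws `n` points as jittered convex combinations
#' \eqn{z = t x_i + (1 - t) x_j + \sigma \epsilon} of random pairs of steady
#' states, with \eqn{t \sim U(0, 1)}. For multistable systems the cross-basin
#' pairs trace the inter-basin channels *uniformly*, so the HJB residual stays
#' constrained on barrier tops where both the steady density and broadened
#' densities (larger noise, Gaussian perturbation) are exponentially thin.
#'
#' @param samples an `eprnet_samples` object.
#' @param n number of interpolated points (default: one per input state).
#' @param sigma standard deviation of the isotropic Gaussian jitter.
#' @param seed optional integer seed.
#' @param system optional system whose domain is used for re-reflection.
#' @export
enhance_by_interpolation <- function(samples, n = NULL, sigma = 0.05,
                                     seed = NULL, system = NULL) {
  stopifnot(sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  X <- states_of(samples)
  n <- as.integer(n %||% nrow(X))
  i <- sample.int(nrow(X), n, replace = TRUE)
  j <- sample.int(nrow(X), n, replace = TRUE)
  tt <- stats::runif(n)
  Z <- tt * X[i, , drop = FALSE] + (1 - tt) * X[j, , drop = FALSE]
  if (sigma > 0) {
    Z <- Z + matrix(stats::rnorm(length(Z), 0, sigma), nrow(Z), ncol(Z))
  }
  if (!is.null(system)) Z <- reflect_into(Z, system$domain)
  sample_set(Z, samples$noise_strength, "pair_interpolation",
             seed = seed %||% NA_integer_, dt = samples$dt,
             t_final = samples$t_final)
}

#' Read and write sample sets as headered CSV with a JSON sidecar
#'
#' @param samples an `eprnet_samples` object.
#' @param path CSV path; metadata is written to `<path>.json`.
#' @export
write_samples <- function(samples, path) {
  df <- as.data.frame(samples$states)
  names(df) <- paste0("x", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- samples[setdiff(names(samples), "states")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(noise_strength = NA_real_, provenance = "analytic")
  }
  sample_set(as.matrix(df), meta$noise_strength %||% NA_real_,
             meta$provenance %||% "analytic",
             seed = meta$seed %||% NA_integer_, dt = meta$dt %||% NA_real_,
             t_final = meta$t_final %||% NA_real_)
}

#' Exact steady-state samples from a system's analytic sampler
#'
#' @param system system with an `analytic_sampler`.
#' @param n number of draws.
#' @param D noise strength recorded in the metadata.
#' @param seed optional integer seed.
#' @export
analytic_samples <- function(system, n, D, seed = NULL) {
  if (is.null(system$sampler)) stop("system has no analytic sampler")
  if (!is.null(seed)) set.seed(seed)
  sample_set(system$sampler(n), D, "analytic", seed = seed %||% NA_integer_)
}
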