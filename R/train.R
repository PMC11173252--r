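#' Training configuration
#'
#' Collects the loss weights, noise strengths, enhancement rule, optimizer
#' hyperparameters and seed for [train_potential()]. Defaults follow the
#' method's standard settings: a 3 x 20 tanh network trained with Adam at
#' learning rate 1e-3 and batch size 2048.
#'
#' @param D noise strength of the target system.
#' @param lambda1,lambda2 nonnegative weights of the force-projection and HJB
#'   terms; `lambda2 = 0` gives the plain ("single EPR") objective.
#' @param enhancement how the HJB sample set is produced when it is not passed
#'   explicitly: `list(type = "none")`, `list(type = "larger_noise", D_prime =)`,
#'   `list(type = "perturbation", sigma =)` or
#'   `list(type = "interpolation", sigma =, n =)` (jittered convex
#'   combinations of sample pairs, covering inter-basin channels).
#' @param epochs number of passes over the sample set.
#' @param batch_size minibatch size (capped at N).
#' @param hjb_batch_size minibatch size of the HJB term (defaults to
#'   `batch_size`); the HJB term costs roughly `d` times more per sample than
#'   the force-projection term, so a smaller batch buys speed at the price of
#'   a noisier gradient for the regularizing term.
#' @param lr Adam learning rate.
#' @param lr_schedule `"constant"` or `"cosine"` (anneal from `lr` to
#'   `lr`/100 over the epochs; helps the HJB term converge in the
#'   low-density transition region).
#' @param hidden hidden-layer widths of the potential network.
#' @param seed integer seed controlling initialization and batching.
#' @param trace_every record the loss trace every this many epochs.
#' @export
training_config <- function(D, lambda1 = 10, lambda2 = 1,
                            enhancement = list(type = "none"),
                            epochs = 3000L, batch_size = 2048L,
                            hjb_batch_size = NULL, lr = 1e-3,
                            lr_schedule = c("constant", "cosine"),
                            hidden = c(20L, 20L, 20L), seed = 1L,
                            trace_every = 10L) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(lambda1 >= 0, lambda2 >= 0, D >= 0, epochs >= 1, batch_size >= 1,
            lr > 0)
  if (lambda1 + lambda2 <= 0) stop("lambda1 + lambda2 must be positive")
  structure(list(D = D, lambda1 = lambda1, lambda2 = lambda2,
                 enhancement = enhancement, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 hjb_batch_size = as.integer(hjb_batch_size %||% batch_size),
                 lr = lr, lr_schedule = lr_schedule,
                 hidden = as.integer(hidden), seed = as.integer(seed),
                 trace_every = as.integer(trace_every)),
            class = "eprnet_config")
}

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, par, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Shared minibatch Adam loop over (EPR term, optional HJB term) with all
# inputs precomputed as plain arrays; both terms draw their batches
# independently. Used by train_potential and train_reduced_potential.
train_core <- function(dims, X, Fm, lambda1, lambda2, Xe = NULL, Fe = NULL,
                       divFe = NULL, D = NA_real_, epochs, batch_size, lr,
                       seed, trace_every = 10L, vepr = NULL,
                       hjb_batch_size = batch_size,
                       lr_schedule = "constant") {
  set.seed(seed)
  model <- mlp_potential(dims[1], hidden = dims[-c(1, length(dims))],
                         dim_out = dims[length(dims)])
  par <- model$par
  opt <- adam_new(length(par))
  n <- nrow(X)
  bs <- min(batch_size, n)
  ne <- if (!is.null(Xe)) nrow(Xe) else 0L
  bse <- if (ne) min(hjb_batch_size, ne) else 0L
  steps_per_epoch <- max(1L, floor(n / bs))
  trace <- list()
  for (ep in seq_len(epochs)) {
    lr_ep <- if (identical(lr_schedule, "cosine")) {
      frac <- (ep - 1) / max(1L, epochs - 1L)
      lr / 100 + (lr - lr / 100) * 0.5 * (1 + cos(pi * frac))
    } else {
      lr
    }
    ep_epr <- 0; ep_hjb <- 0
    for (s in seq_len(steps_per_epoch)) {
      idx <- sample.int(n, bs)
      if (is.null(vepr)) {
        g1 <- cpp_epr_loss_grad(par, dims, X[idx, , drop = FALSE],
                                Fm[idx, , drop = FALSE], TRUE)
      } else {
        g1 <- vepr_batch_grad(par, dims, X, idx, vepr)
      }
      loss <- lambda1 * g1$loss
      grad <- lambda1 * g1$grad
      hl <- 0
      if (lambda2 > 0) {
        eidx <- sample.int(ne, bse)
        g2 <- cpp_hjb_loss_grad(par, dims, Xe[eidx, , drop = FALSE],
                                Fe[eidx, , drop = FALSE], divFe[eidx], D, TRUE)
        loss <- loss + lambda2 * g2$loss
        grad <- grad + lambda2 * g2$grad
        hl <- g2$loss
      }
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", ep, ", step ", s,
             "; first batch index ", idx[1])
      }
      upd <- adam_step(opt, par, grad, lr_ep)
      par <- upd$par
      opt <- upd$state
      ep_epr <- ep_epr + g1$loss
      ep_hjb <- ep_hjb + hl
    }
    if (ep %% trace_every == 0L || ep == epochs || ep == 1L) {
      trace[[length(trace) + 1L]] <- c(epoch = ep,
                                       epr = ep_epr / steps_per_epoch,
                                       hjb = ep_hjb / steps_per_epoch)
    }
  }
  model$par <- par
  tr <- as.data.frame(do.call(rbind, trace))
  tr$total <- lambda1 * tr$epr + lambda2 * tr$hjb
  list(model = model, trace = tr)
}

# V-EPR minibatch gradient: residual r = F^v + a grad V is the exact tangent
# of the weighted-norm loss, so the parameter gradient is a directional-
# gradient VJP with tangent r.
vepr_batch_grad <- function(par, dims, X, idx, vepr) {
  Xb <- X[idx, , drop = FALSE]
  G <- cpp_mlp_grad(par, dims, Xb)$grad
  nb <- length(idx)
  d <- ncol(Xb)
  r <- matrix(0, nb, d)
  loss <- 0
  for (i in seq_len(nb)) {
    ri <- vepr$Fv[idx[i], ] + drop(vepr$a[[idx[i]]] %*% G[i, ])
    r[i, ] <- ri
    loss <- loss + drop(crossprod(ri, vepr$ainv[[idx[i]]] %*% ri))
  }
  vjp <- cpp_dirgrad_vjp(par, dims, Xb, r)
  list(loss = loss / nb, grad = (2 / nb) * vjp$grad)
}

#' Train a potential landscape
#'
#' Minimizes the enhanced loss
#' \eqn{\lambda_1 \hat L_{EPR} + \lambda_2 \hat L_{HJB}} by minibatch Adam,
#' drawing the two batches independently from the steady and enhanced sample
#' sets. For systems with a diffusion matrix the force-projection term is the
#' weighted-norm (V-EPR) loss and `lambda2` must be 0. The run is
#' deterministic given the configuration seed.
#'
#' @param system an `eprnet_system`.
#' @param samples steady-state samples at the target D.
#' @param enhanced_samples samples of the enhancing distribution; if NULL and
#'   `config$lambda2 > 0`, they are generated according to
#'   `config$enhancement`.
#' @param config a [training_config()].
#' @return an `eprnet_fit`: list with the trained `model`, the per-epoch loss
#'   `trace` (columns epoch, epr, hjb, total) and the resolved `config`.
#' @export
train_potential <- function(system, samples, enhanced_samples = NULL, config) {
  X <- states_of(samples)
  if (nrow(X) < 1) stop("empty sample set")
  if (ncol(X) != system$dim) stop("sample dimension does not match the system")
  use_vepr <- !is.null(system$diffusion)
  if (use_vepr && config$lambda2 > 0) {
    stop("the HJB term assumes identity diffusion; set lambda2 = 0 for ",
         "systems with a diffusion matrix")
  }
  if (config$lambda2 > 0 && is.null(enhanced_samples)) {
    enh <- config$enhancement
    enhanced_samples <- switch(enh$type %||% "none",
      larger_noise = enhance_by_larger_noise(
        system, config$D, enh$D_prime, n_traj = nrow(X),
        t_final = enh$t_final %||% 20, dt = enh$dt %||% 0.01,
        seed = config$seed + 1L),
      perturbation = enhance_by_perturbation(samples, enh$sigma,
                                             seed = config$seed + 1L,
                                             system = system),
      interpolation = enhance_by_interpolation(samples, n = enh$n,
                                               sigma = enh$sigma %||% 0.05,
                                               seed = config$seed + 1L,
                                               system = system),
      stop("lambda2 > 0 requires an enhanced sample set or an enhancement rule")
    )
  }
  dims <- as.integer(c(system$dim, config$hidden, 1L))
  Fm <- sys_drift(system, X)
  Xe <- NULL; Fe <- NULL; divFe <- NULL
  if (config$lambda2 > 0) {
    Xe <- states_of(enhanced_samples)
    Fe <- sys_drift(system, Xe)
    divFe <- sys_drift_div(system, Xe)
  }
  vepr <- if (use_vepr) vepr_arrays(system, X, config$D) else NULL
  out <- train_core(dims, X, Fm, config$lambda1, config$lambda2, Xe, Fe, divFe,
                    config$D, config$epochs, config$batch_size, config$lr,
                    config$seed, config$trace_every, vepr = vepr,
                    hjb_batch_size = config$hjb_batch_size %||%
                      config$batch_size,
                    lr_schedule = config$lr_schedule %||% "constant")
  structure(list(model = out$model, trace = out$trace, config = config,
                 system_name = system$name,
                 method = if (config$lambda2 > 0) "enhanced EPR" else "single EPR"),
            class = "eprnet_fit")
}

#' @export
print.eprnet_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat("<eprnet_fit> ", x$method, " on ", x$system_name,
      sprintf(" | final losses: epr %.4g, hjb %.4g\n", last$epr, last$hjb),
      sep = "")
  invisible(x)
}
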