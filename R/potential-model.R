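#' Create a neural potential model
#'
#' Constructs a feed-forward scalar field \eqn{V(x;\theta)} used to represent
#' the potential landscape. The default architecture is three hidden layers of
#' 20 tanh units each with a linear readout. The model exposes exact
#' (analytically differentiated) evaluations of the value, the state gradient
#' \eqn{\nabla_x V} and the Laplacian \eqn{\Delta_x V}, all batched over rows
#' of a state matrix.
#'
#' @param dim_in input dimension (state-space dimension, or 2 for reduced
#'   potentials).
#' @param hidden integer vector of hidden-layer widths.
#' @param dim_out output dimension; 1 for potentials, 2 for projected force
#'   fields.
#' @param init_scale multiplier on the Glorot-uniform initialization range.
#' @return an object of class `eprnet_mlp` with elements `dims` (layer sizes)
#'   and `par` (flat parameter vector).
#' @export
mlp_potential <- function(dim_in, hidden = c(20L, 20L, 20L), dim_out = 1L,
                          init_scale = 1) {
  stopifnot(dim_in >= 1, length(hidden) >= 1, all(hidden >= 1), dim_out >= 1)
  dims <- as.integer(c(dim_in, hidden, dim_out))
  par <- numeric(0)
  for (l in seq_len(length(dims) - 1L)) {
    nin <- dims[l]; nout <- dims[l + 1L]
    r <- init_scale * sqrt(6 / (nin + nout))
    par <- c(par, stats::runif(nin * nout, -r, r), rep(0, nout))
  }
  structure(list(dims = dims, par = par), class = "eprnet_mlp")
}

#' @export
print.eprnet_mlp <- function(x, ...) {
  cat("<eprnet_mlp> ", paste(x$dims, collapse = "-"),
      " (", length(x$par), " parameters)\n", sep = "")
  invisible(x)
}

n_params <- function(model) length(model$par)

as_states <- function(x, dim = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(dim) && ncol(x) != dim) {
    stop("state matrix has ", ncol(x), " columns, expected ", dim)
  }
  x
}

#' Evaluate a potential object
#'
#' Generic accessors for anything that behaves as a scalar potential: neural
#' models (`eprnet_mlp`), analytic potentials (`eprnet_potential`), trained
#' fits (`eprnet_fit`), gridded references (`eprnet_reference`) and plain
#' functions. `potential_value` returns the values at the rows of `x`,
#' `potential_grad` the state gradients, and `potential_laplacian` the trace
#' of the state Hessian.
#'
#' @param model a potential-like object.
#' @param x numeric matrix of states (rows) or a single state vector.
#' @return numeric vector (`potential_value`, `potential_laplacian`) or matrix
#'   (`potential_grad`).
#' @export
potential_value <- function(model, x) UseMethod("potential_value")

#' @rdname potential_value
#' @export
potential_grad <- function(model, x) UseMethod("potential_grad")

#' @rdname potential_value
#' @export
potential_laplacian <- function(model, x) UseMethod("potential_laplacian")

#' @export
potential_value.eprnet_mlp <- function(model, x) {
  drop(cpp_mlp_value(model$par, model$dims, as_states(x, model$dims[1])))
}

#' @export
potential_grad.eprnet_mlp <- function(model, x) {
  cpp_mlp_grad(model$par, model$dims, as_states(x, model$dims[1]))$grad
}

#' @export
potential_laplacian.eprnet_mlp <- function(model, x) {
  drop(cpp_mlp_laplacian(model$par, model$dims, as_states(x, model$dims[1]))$lap)
}

#' @export
potential_value.eprnet_fit <- function(model, x) potential_value(model$model, x)

#' @export
potential_grad.eprnet_fit <- function(model, x) potential_grad(model$model, x)

#' @export
potential_laplacian.eprnet_fit <- function(model, x) potential_laplacian(model$model, x)

#' @export
potential_value.function <- function(model, x) {
  x <- as_states(x)
  apply(x, 1L, model)
}

#' @export
potential_grad.function <- function(model, x) num_grad_rows(model, as_states(x))

#' @export
potential_laplacian.function <- function(model, x) num_lap_rows(model, as_states(x))

# --- analytic potentials ----------------------------------------------------

#' Define an analytic potential
#'
#' Wraps closed-form value/gradient/Laplacian functions into the common
#' potential interface. All three functions must be vectorized over rows of a
#' state matrix; missing derivatives fall back to central finite differences
#' (flagged as non-analytic, which some constructors reject).
#'
#' @param value function: state matrix -> numeric vector.
#' @param grad function: state matrix -> gradient matrix, or NULL.
#' @param laplacian function: state matrix -> numeric vector, or NULL.
#' @param dim state dimension (optional, for validation).
#' @return object of class `eprnet_potential`.
#' @export
make_potential <- function(value, grad = NULL, laplacian = NULL, dim = NULL) {
  stopifnot(is.function(value))
  analytic_grad <- !is.null(grad)
  analytic_lap <- !is.null(laplacian)
  structure(list(value = value, grad = grad, laplacian = laplacian, dim = dim,
                 analytic_grad = analytic_grad, analytic_lap = analytic_lap),
            class = "eprnet_potential")
}

#' @export
potential_value.eprnet_potential <- function(model, x) {
  drop(model$value(as_states(x, model$dim)))
}

#' @export
potential_grad.eprnet_potential <- function(model, x) {
  x <- as_states(x, model$dim)
  if (model$analytic_grad) model$grad(x) else num_grad_rows(model$value, x)
}

#' @export
potential_laplacian.eprnet_potential <- function(model, x) {
  x <- as_states(x, model$dim)
  if (model$analytic_lap) drop(model$laplacian(x)) else num_lap_rows(model$value, x)
}

#' Quadratic confining potential
#'
#' The isotropic well \eqn{U(x) = s |x - x_0|^2 / 2}, the canonical
#' exactly-solvable confinement: under gradient dynamics with noise D its
#' steady density is Gaussian with variance D/s per coordinate.
#'
#' @param dim state dimension.
#' @param scale curvature s.
#' @param center well location.
#' @export
quadratic_potential <- function(dim = 2L, scale = 1, center = rep(0, dim)) {
  stopifnot(scale > 0, length(center) == dim)
  make_potential(
    value = function(x) 0.5 * scale * rowSums(sweep(x, 2L, center)^2),
    grad = function(x) scale * sweep(x, 2L, center),
    laplacian = function(x) rep(scale * dim, nrow(x)),
    dim = dim
  )
}

# central finite differences, rows of X, relative step
num_grad_rows <- function(value, X, eps = 1e-6) {
  d <- ncol(X)
  G <- matrix(0, nrow(X), d)
  for (j in seq_len(d)) {
    h <- eps * (1 + abs(X[, j]))
    Xp <- X; Xm <- X
    Xp[, j] <- X[, j] + h
    Xm[, j] <- X[, j] - h
    G[, j] <- (value(Xp) - value(Xm)) / (2 * h)
  }
  G
}

num_lap_rows <- function(value, X, eps = 1e-4) {
  d <- ncol(X)
  out <- numeric(nrow(X))
  f0 <- value(X)
  for (j in seq_len(d)) {
    h <- eps * (1 + abs(X[, j]))
    Xp <- X; Xm <- X
    Xp[, j] <- X[, j] + h
    Xm[, j] <- X[, j] - h
    out <- out + (value(Xp) - 2 * f0 + value(Xm)) / h^2
  }
  out
}

# --- persistence ------------------------------------------------------------

#' Save or load a neural potential checkpoint
#'
#' Checkpoints store the architecture and the flat parameter vector as JSON at
#' full precision.
#'
#' @param model an `eprnet_mlp`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "eprnet_mlp"))
  jsonlite::write_json(list(dims = model$dims, par = model$par), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(dims = as.integer(obj$dims), par = as.numeric(obj$par)),
            class = "eprnet_mlp")
}
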