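#' Construct a feedforward network for Levenberg-Marquardt training
#'
#' Fully connected layers; weight matrix `w_l` has one row per neuron of
#' layer `l` and one column per neuron of layer `l-1`, with a separate bias
#' vector per layer. Weights are initialized uniform(-0.5, 0.5) from a seeded
#' generator so runs are reproducible.
#'
#' @param layer_sizes Integer vector: input size, hidden sizes..., output
#'   size.
#' @param activations Activation per non-input layer: `"sigmoid"`, `"tanh"`
#'   or `"linear"`. A single value is recycled.
#' @param seed Integer seed for weight initialization (required).
#' @param bias Include bias vectors (default `TRUE`). `bias = FALSE` builds
#'   a pure weight model, useful for closed-form checks.
#' @return An `lmnet` object.
#' @examples
#' net <- lmnet(c(2, 4, 1), "sigmoid", seed = 1)
#' predict(net, matrix(c(0, 0), nrow = 1))
#' @export
lmnet <- function(layer_sizes, activations = "sigmoid", seed, bias = TRUE) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("layer_sizes needs >= 2 positive entries", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required for reproducible initialization", call. = FALSE)
  L <- length(layer_sizes) - 1L
  activations <- rep(match.arg(activations, c("sigmoid", "tanh", "linear"),
                               several.ok = TRUE), length.out = L)
  weights <- vector("list", L); biases <- vector("list", L)
  set.seed(as.integer(seed))
  for (l in seq_len(L)) {
    weights[[l]] <- matrix(stats::runif(layer_sizes[l + 1L] * layer_sizes[l], -0.5, 0.5),
                           nrow = layer_sizes[l + 1L])
    biases[[l]] <- if (bias) stats::runif(layer_sizes[l + 1L], -0.5, 0.5) else numeric(0)
  }
  structure(list(layer_sizes = layer_sizes, weights = weights,
                 biases = biases, activations = activations),
            class = "lmnet")
}

#' @export
print.lmnet <- function(x, ...) {
  cat(sprintf("<lmnet> %s | activations: %s | %d parameters\n",
              paste(x$layer_sizes, collapse = "-"),
              paste(x$activations, collapse = ","), n_params(x)))
  invisible(x)
}

act_fun <- function(name) switch(name,
  sigmoid = function(z) 1 / (1 + exp(-z)),
  tanh = tanh,
  linear = identity)

# derivative expressed through the activation value
act_deriv <- function(name) switch(name,
  sigmoid = function(a) a * (1 - a),
  tanh = function(a) 1 - a^2,
  linear = function(a) rep(1, length(a)))

n_params <- function(net) {
  sum(vapply(seq_along(net$weights),
             function(l) length(net$weights[[l]]) + length(net$biases[[l]]),
             numeric(1)))
}

# Flattening order (documented contract, used by the Jacobian and the model
# file): for each layer l = 1..L, the weights of w_l in row-major order
# (neuron j's incoming weights contiguous), then the biases b_l.
get_params <- function(net) {
  unlist(lapply(seq_along(net$weights), function(l) {
    c(as.vector(t(net$weights[[l]])), net$biases[[l]])
  }))
}

set_params <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$weights)) {
    w <- net$weights[[l]]
    nw <- length(w)
    net$weights[[l]] <- matrix(theta[pos + seq_len(nw)], nrow = nrow(w), byrow = TRUE)
    pos <- pos + nw
    nb <- length(net$biases[[l]])
    net$biases[[l]] <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  net
}

#' Forward pass through an `lmnet`
#'
#' @param net An `lmnet`.
#' @param x Input vector of length `layer_sizes[1]`.
#' @return List of activation vectors, one per layer (`a_0 = x`; the last is
#'   the prediction).
#' @export
nn_forward <- function(net, x) {
  if (length(x) != net$layer_sizes[1L]) stop("input length mismatch", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite input", call. = FALSE)
  acts <- forward_activations(net, matrix(x, nrow = 1L))
  lapply(acts, function(a) as.numeric(a[1L, ]))
}

# all-samples forward: returns list of n x size_l activation matrices
forward_activations <- function(net, X) {
  acts <- vector("list", length(net$weights) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(net$weights)) {
    z <- acts[[l]] %*% t(net$weights[[l]])
    if (length(net$biases[[l]]) > 0L) z <- sweep(z, 2, net$biases[[l]], "+")
    acts[[l + 1L]] <- act_fun(net$activations[l])(z)
  }
  acts
}

#' @export
predict.lmnet <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$layer_sizes[1L]) stop("input width mismatch", call. = FALSE)
  acts <- forward_activations(object, X)
  acts[[length(acts)]]
}

#' Residual vector and summed squared error of a network on a dataset
#'
#' Residuals are `prediction - target`, stacked sample-major, output-minor;
#' `f = e'e` is the quantity the Levenberg-Marquardt loop drives down.
#'
#' @param net An `lmnet`.
#' @param X Sample matrix (rows = samples).
#' @param targets Target matrix, rows paired with `X`.
#' @return List with `e` (residual vector) and `f` (sum of squares).
#' @export
nn_residuals <- function(net, X, targets) {
  X <- as.matrix(X); targets <- as.matrix(targets)
  if (nrow(X) == 0L) stop("empty dataset", call. = FALSE)
  if (nrow(X) != nrow(targets)) stop("X and targets row counts differ", call. = FALSE)
  Y <- predict(net, X)
  if (ncol(Y) != ncol(targets)) stop("target width mismatch", call. = FALSE)
  e <- as.vector(t(Y - targets))
  list(e = e, f = sum(e^2))
}

#' Analytic Jacobian of the residuals with respect to all parameters
#'
#' Row `(i-1)*n_outputs + o` holds the derivatives of residual `e_{i,o}` with
#' respect to every flattened parameter (per layer: row-major weights, then
#' biases), computed by per-output backpropagation.
#'
#' @inheritParams nn_residuals
#' @return Matrix of shape `(n_samples * n_outputs) x n_params`.
#' @seealso [fd_jacobian()] for the finite-difference oracle.
#' @export
nn_jacobian <- function(net, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty dataset", call. = FALSE)
  n <- nrow(X)
  L <- length(net$weights)
  K <- net$layer_sizes[length(net$layer_sizes)]
  P <- n_params(net)
  acts <- forward_activations(net, X)
  J <- matrix(0, n * K, P)

  # parameter column offsets per layer
  offsets <- integer(L)
  pos <- 0L
  for (l in seq_len(L)) {
    offsets[l] <- pos
    pos <- pos + length(net$weights[[l]]) + length(net$biases[[l]])
  }

  for (o in seq_len(K)) {
    aL <- acts[[L + 1L]]
    d <- matrix(0, n, K)
    d[, o] <- act_deriv(net$activations[L])(aL[, o])
    rows <- seq(o, by = K, length.out = n)
    l <- L
    while (l >= 1L) {
      a_prev <- acts[[l]]
      rows_l <- nrow(net$weights[[l]]); cols_l <- ncol(net$weights[[l]])
      # row-major weight block: param (j,k) -> column (j-1)*cols + k
      wblock <- d[, rep(seq_len(rows_l), each = cols_l), drop = FALSE] *
        a_prev[, rep(seq_len(cols_l), times = rows_l), drop = FALSE]
      J[rows, offsets[l] + seq_len(rows_l * cols_l)] <- wblock
      if (length(net$biases[[l]]) > 0L) {
        J[rows, offsets[l] + rows_l * cols_l + seq_len(rows_l)] <- d
      }
      if (l > 1L) {
        d <- (d %*% net$weights[[l]]) * act_deriv(net$activations[l - 1L])(a_prev)
      }
      l <- l - 1L
    }
  }
  J
}

#' Finite-difference Jacobian (verification oracle)
#'
#' Central differences on each flattened parameter; same shape and ordering
#' as [nn_jacobian()]. Used in tests to validate the analytic
#' backpropagation; quadratic in the parameter count, so keep it to small
#' networks.
#'
#' @inheritParams nn_residuals
#' @param h Step size (> 0).
#' @return Matrix of shape `(n_samples * n_outputs) x n_params`.
#' @export
fd_jacobian <- function(net, X, h = 1e-6) {
  if (h <= 0) stop("h must be positive", call. = FALSE)
  X <- as.matrix(X)
  theta <- get_params(net)
  K <- net$layer_sizes[length(net$layer_sizes)]
  res0 <- as.vector(t(predict(net, X)))
  J <- matrix(0, length(res0), length(theta))
  for (p in seq_along(theta)) {
    up <- theta; up[p] <- up[p] + h
    dn <- theta; dn[p] <- dn[p] - h
    rp <- as.vector(t(predict(set_params(net, up), X)))
    rm <- as.vector(t(predict(set_params(net, dn), X)))
    J[, p] <- (rp - rm) / (2 * h)
  }
  J
}

#' Initialize the damped training state
#'
#' @param mu Initial damping factor (default 0.01).
#' @param beta Damping decay rate in (0, 1) (default 0.1): accepted steps
#'   multiply `mu` by `beta`, rejected steps divide by it.
#' @return An `lm_train_state`.
#' @export
lm_train_state <- function(mu = 0.01, beta = 0.1) {
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)", call. = FALSE)
  structure(list(mu = mu, beta = beta, iteration = 0L,
                 f_history = numeric(0), status = "running"),
            class = "lm_train_state")
}

#' One Levenberg-Marquardt step
#'
#' Solves `(J'J + mu I) delta = J'e` and proposes `w - delta` (with
#' `e = prediction - target` this is the descent direction). If the proposal
#' lowers `F = e'e` it is accepted and `mu <- mu * beta`; otherwise the
#' weights are kept and `mu <- mu / beta`. The damped normal equations are
#' solved by Cholesky with a least-squares fallback when ill-conditioned.
#'
#' @param net An `lmnet`.
#' @param state An `lm_train_state`.
#' @inheritParams nn_residuals
#' @param mu_cap Abort threshold for `mu` (status `"mu_overflow"`).
#' @return List: `net`, `state`, `accepted`.
#' @export
lm_step <- function(net, state, X, targets, mu_cap = 1e10) {
  stopifnot(inherits(state, "lm_train_state"))
  r <- nn_residuals(net, X, targets)
  if (!is.finite(r$f)) stop("non-finite F(w)", call. = FALSE)
  J <- nn_jacobian(net, X)
  if (!all(is.finite(J))) stop("non-finite Jacobian", call. = FALSE)
  A <- crossprod(J)
  diag(A) <- diag(A) + state$mu
  g <- crossprod(J, r$e)
  delta <- tryCatch({
    R <- chol(A)
    backsolve(R, forwardsolve(t(R), g))
  }, error = function(e) qr.solve(A, g, tol = .Machine$double.eps))
  theta <- get_params(net)
  proposal <- set_params(net, theta - as.numeric(delta))
  f_new <- nn_residuals(proposal, X, targets)$f
  state$iteration <- state$iteration + 1L
  if (is.finite(f_new) && f_new < r$f) {
    net <- proposal
    state$mu <- state$mu * state$beta
    state$f_history <- c(state$f_history, f_new)
    accepted <- TRUE
  } else {
    state$mu <- state$mu / state$beta
    accepted <- FALSE
  }
  if (state$mu > mu_cap) state$status <- "mu_overflow"
  list(net = net, state = state, accepted = accepted)
}

#' Training loop control parameters
#'
#' @param max_iter Maximum LM iterations (accepted or rejected).
#' @param f_tol Stop when `F(w)` falls below this.
#' @param rel_tol Stop when the relative `F` improvement over the last 5
#'   accepted steps falls below this.
#' @param mu_cap Abort threshold for the damping factor.
#' @param mu,beta Initial damping and decay rate.
#' @return A list of class `lm_control`.
#' @export
lm_control <- function(max_iter = 200L, f_tol = 1e-6, rel_tol = 1e-9,
                       mu_cap = 1e10, mu = 0.01, beta = 0.1) {
  structure(list(max_iter = as.integer(max_iter), f_tol = f_tol,
                 rel_tol = rel_tol, mu_cap = mu_cap, mu = mu, beta = beta),
            class = "lm_control")
}

#' Train a network by damped least squares
#'
#' Iterates [lm_step()] until `F < f_tol` (converged), the relative
#' improvement over the last 5 accepted steps drops below `rel_tol`
#' (converged), `max_iter` is reached (stalled), or the damping factor
#' overflows `mu_cap`.
#'
#' @param net An initialized `lmnet`.
#' @inheritParams nn_residuals
#' @param control An [lm_control()] list.
#' @return An `lmnet_fit`: list with the trained `net` and the final
#'   `state` (including the accepted-step `F` history, which also records
#'   the initial `F`).
#' @export
lm_train <- function(net, X, targets, control = lm_control()) {
  state <- lm_train_state(mu = control$mu, beta = control$beta)
  f0 <- nn_residuals(net, X, targets)$f
  state$f_history <- f0
  while (state$iteration < control$max_iter) {
    step <- lm_step(net, state, X, targets, mu_cap = control$mu_cap)
    net <- step$net; state <- step$state
    if (state$status == "mu_overflow") break
    f_hist <- state$f_history
    if (f_hist[length(f_hist)] < control$f_tol) {
      state$status <- "converged"; break
    }
    n_acc <- length(f_hist)
    if (step$accepted && n_acc >= 6L) {
      recent <- f_hist[n_acc - 5L]
      rel <- (recent - f_hist[n_acc]) / max(recent, .Machine$double.eps)
      if (rel < control$rel_tol) { state$status <- "converged"; break }
    }
  }
  if (state$status == "running") state$status <- "stalled"
  structure(list(net = net, state = state, control = control),
            class = "lmnet_fit")
}

#' @export
print.lmnet_fit <- function(x, ...) {
  fh <- x$state$f_history
  cat(sprintf("<lmnet_fit> %s | %d iterations | F: %.4g -> %.4g | %s\n",
              paste(x$net$layer_sizes, collapse = "-"),
              x$state$iteration, fh[1L], fh[length(fh)], x$state$status))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameters of a trained network
#'
#' @param x An `lmnet` or `lmnet_fit`.
#' @param ... Unused.
#' @return Tibble with `layer`, `term` (`w[j,k]` or `b[j]`) and `estimate`.
#' @export
tidy.lmnet <- function(x, ...) {
  purrr::map_dfr(seq_along(x$weights), function(l) {
    w <- x$weights[[l]]
    dplyr::bind_rows(
      tibble::tibble(layer = l,
                     term = sprintf("w[%d,%d]",
                                    rep(seq_len(nrow(w)), each = ncol(w)),
                                    rep(seq_len(ncol(w)), times = nrow(w))),
                     estimate = as.vector(t(w))),
      tibble::tibble(layer = l,
                     term = sprintf("b[%d]", seq_along(x$biases[[l]])),
                     estimate = x$biases[[l]])
    )
  })
}

#' @export
tidy.lmnet_fit <- function(x, ...) tidy.lmnet(x$net, ...)

#' One-row summary of a training run
#'
#' @param x An `lmnet_fit`.
#' @param ... Unused.
#' @return Tibble: `iterations`, `accepted_steps`, `f_initial`, `f_final`,
#'   `mu_final`, `status`.
#' @export
glance.lmnet_fit <- function(x, ...) {
  fh <- x$state$f_history
  tibble::tibble(iterations = x$state$iteration,
                 accepted_steps = length(fh) - 1L,
                 f_initial = fh[1L], f_final = fh[length(fh)],
                 mu_final = x$state$mu, status = x$state$status)
}

#' Save / load a network as portable JSON
#'
#' The model file stores layer sizes, activation names, row-major weight
#' lists, bias lists and (for fits) the training control, at full double
#' precision so reloaded networks predict bit-identically.
#'
#' @param net An `lmnet` (or `lmnet_fit`, whose network is saved).
#' @param path File path.
#' @return `path` invisibly; `read_lmnet` returns the `lmnet`.
#' @export
write_lmnet <- function(net, path) {
  control <- NULL
  if (inherits(net, "lmnet_fit")) { control <- net$control; net <- net$net }
  payload <- list(
    layer_sizes = net$layer_sizes,
    activations = net$activations,
    weights = lapply(net$weights, function(w) as.vector(t(w))),
    biases = net$biases,
    control = control
  )
  # I(17) = 17 significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_lmnet
#' @export
read_lmnet <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  rebuild_lmnet(p)
}

# shared JSON -> lmnet reconstruction (no vector simplification, so layer
# shapes that happen to coincide cannot collapse into matrices)
rebuild_lmnet <- function(p) {
  sizes <- as.integer(unlist(p$layer_sizes))
  L <- length(sizes) - 1L
  weights <- lapply(seq_len(L), function(l) {
    matrix(as.numeric(unlist(p$weights[[l]])), nrow = sizes[l + 1L], byrow = TRUE)
  })
  structure(list(layer_sizes = sizes, weights = weights,
                 biases = lapply(p$biases, function(b) as.numeric(unlist(b))),
                 activations = as.character(unlist(p$activations))),
            class = "lmnet")
}
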