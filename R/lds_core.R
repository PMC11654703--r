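#' Simulate the latent trajectory of one condition in one context
#'
#' Runs the deterministic recursion `x(t) = A x(t-1) + B_m u_m(t) + B_c u_c(t)`
#' from `x(0) = x0[context]`, with the external inputs of the requested
#' condition. The first observed bin corresponds to `x(1)`; `x(0)` precedes
#' the observation window.
#'
#' @param params An [lds_params()] set.
#' @param grid The [make_task_grid()] the condition indices refer to.
#' @param condition Condition row index `k`.
#' @param context Context index (1 = motion context, 2 = color context).
#' @return `(T+1) x L` matrix of latent states, rows `t = 0..T`.
#' @export
simulate_latents <- function(params, grid, condition = 1L, context = 1L) {
  stopifnot(condition >= 1L, condition <= grid$n_conditions,
            context %in% c(1L, 2L))
  X <- sim_latents_all(params, grid, contexts = context)[[1L]]
  t(X[, , condition, drop = TRUE])
}

# Latents for all conditions at once; returns one [L, T+1, K] array per
# requested context (time index 1 corresponds to t = 0).
sim_latents_all <- function(params, grid, contexts = 1:2,
                            zero_inputs = NULL, zero_x0 = FALSE) {
  L <- params$class_spec$latent_dim
  Tn <- nrow(params$inputs$motion$course_in)
  K <- grid$n_conditions
  Um_series <- input_series(params$inputs, grid, "motion")
  Uc_series <- input_series(params$inputs, grid, "color")
  if ("motion" %in% zero_inputs) Um_series[] <- 0
  if ("color" %in% zero_inputs) Uc_series[] <- 0
  out <- vector("list", length(contexts))
  for (i in seq_along(contexts)) {
    cx <- contexts[i]
    A <- ctx_mat(params$A, cx)
    Bm <- ctx_mat(params$B_mot, cx)
    Bc <- ctx_mat(params$B_col, cx)
    X <- array(0, dim = c(L, Tn + 1L, K))
    X[, 1L, ] <- if (zero_x0) 0 else params$x0[, cx]
    for (t in seq_len(Tn)) {
      drive <- Bm %*% matrix(Um_series[, t, ], ncol = K) +
        Bc %*% matrix(Uc_series[, t, ], ncol = K)
      X[, t + 1L, ] <- A %*% matrix(X[, t, ], ncol = K) + drive
    }
    out[[i]] <- X
  }
  names(out) <- grid$contexts[contexts]
  out
}

#' Predicted response tensor of an LDS parameter set
#'
#' Maps the simulated latents of every condition and context through the
#' loading map and bias: `y[n,t,k,cx] = C x_{k,cx}(t) + d[n]`, on the raw
#' (pre-z-scoring) scale of the data the model was fitted to.
#'
#' @inheritParams simulate_latents
#' @return Array `[N, T, K, 2]`.
#' @export
reconstruct <- function(params, grid) {
  N <- n_neurons(params)
  Tn <- nrow(params$inputs$motion$course_in)
  K <- grid$n_conditions
  lat <- sim_latents_all(params, grid)
  out <- array(0, dim = c(N, Tn, K, 2L))
  for (cx in 1:2) {
    X <- lat[[cx]][, -1L, , drop = FALSE]          # drop x(0)
    Yhat <- params$C_load %*% matrix(X, nrow = dim(X)[1L]) + params$d
    out[, , , cx] <- array(Yhat, dim = c(N, Tn, K))
  }
  out
}

#' Mean squared reconstruction error
#'
#' `(1 / (N T K Cx)) * sum((y - yhat)^2)`. On per-neuron z-scored data this
#' equals the fraction of unexplained variance.
#'
#' @param data A `response_tensor` or a plain array.
#' @param pred A prediction of identical shape.
#' @return Scalar MSE.
#' @export
mse <- function(data, pred) {
  y <- if (inherits(data, "response_tensor")) data$Y else data
  yhat <- if (inherits(pred, "response_tensor")) pred$Y else pred
  if (!identical(dim(y), dim(yhat)) && length(y) != length(yhat)) {
    stop("shape mismatch between data and prediction")
  }
  mean((y - yhat)^2)
}

#' Training objective: MSE plus input-norm penalty
#'
#' `mse + lambda_inp * sum_{t,k,cx} ||B_cx u(t,k)||^2`, the objective
#' minimized by [fit_lds()]. The penalty discourages solutions that place
#' all structure in the external inputs; it uses the product `B u(t)` (the
#' input vector in latent space), never `u` alone, because of the
#' multiplicative degeneracy between `B` and `u`.
#'
#' @param params An [lds_params()] set.
#' @param data A `response_tensor`.
#' @param lambda_inp Non-negative penalty weight (default `1e-5`).
#' @param grid Task grid (defaults to the tensor's own).
#' @return Scalar cost; equals [mse()] when `lambda_inp = 0` or inputs vanish.
#' @export
lds_cost <- function(params, data, lambda_inp = 1e-5, grid = data$grid) {
  if (lambda_inp < 0) stop("lambda_inp must be non-negative")
  err <- mse(data, reconstruct(params, grid))
  pen <- 0
  if (lambda_inp > 0) {
    Um <- input_series(params$inputs, grid, "motion")
    Uc <- input_series(params$inputs, grid, "color")
    K <- grid$n_conditions
    for (cx in 1:2) {
      Bm <- ctx_mat(params$B_mot, cx)
      Bc <- ctx_mat(params$B_col, cx)
      for (t in seq_len(dim(Um)[2L])) {
        v <- Bm %*% matrix(Um[, t, ], ncol = K) + Bc %*% matrix(Uc[, t, ], ncol = K)
        pen <- pen + sum(v^2)
      }
    }
  }
  err + lambda_inp * pen
}

#' Orthonormalize the loading map by a similarity transformation
#'
#' With `C = U S V'` (thin SVD), transforms all latent-space parameters by
#' `Tm = S V'`: `A -> Tm A Tm^-1`, `B -> Tm B`, `x0 -> Tm x0`, and
#' `C -> C Tm^-1 = U`, which has orthonormal columns. The transformation is
#' a similarity, so predicted observations and the eigenvalue spectrum of
#' `A` are unchanged; it is idempotent up to a rotation fixed by the SVD.
#'
#' @param params An [lds_params()] set with full-column-rank loading map.
#' @return The transformed, observation-equivalent parameter set.
#' @export
orthonormalize <- function(params) {
  sv <- svd(params$C_load)
  if (min(sv$d) < max(sv$d) * 1e-10) {
    stop("degenerate loading map: C_load is (numerically) rank deficient")
  }
  Tm <- diag(sv$d, length(sv$d)) %*% t(sv$v)
  Tinv <- sv$v %*% diag(1 / sv$d, length(sv$d))
  map <- function(x, f) if (is.list(x)) lapply(x, f) else f(x)
  out <- params
  out$A <- map(params$A, function(A) Tm %*% A %*% Tinv)
  out$B_mot <- map(params$B_mot, function(B) Tm %*% B)
  out$B_col <- map(params$B_col, function(B) Tm %*% B)
  out$x0 <- Tm %*% params$x0
  out$C_load <- sv$u
  out
}
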