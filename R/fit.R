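#' Optimizer and objective settings for model fitting
#'
#' Defaults follow the settings used throughout: adaptive-moment (ADAM)
#' gradient descent with learning rate 0.009, input penalty weight
#' `lambda_inp = 1e-5`, random initialization from a zero-mean Gaussian
#' with SD 0.01, convergence when the cost changes by less than `1e-5`
#' between iterations after at least 5,000 iterations, and a cap of
#' 10,000 iterations.
#'
#' @param learning_rate ADAM step size.
#' @param lambda_inp Input-norm penalty weight (>= 0).
#' @param init_sd SD of the Gaussian parameter initialization.
#' @param convergence_dcost Cost-change threshold, checked every iteration.
#' @param max_iter,min_iter Iteration bounds.
#' @param n_restarts Default restart count for [multi_restart()].
#' @param seed Base seed for initialization.
#' @param lambda_dyn Optional normal-dynamics penalty weight on
#'   `||A A' - A' A||_F^2` (0 disables it).
#' @param freeze_C Optional `N x L` orthonormal loading map; when supplied
#'   the loading is fixed at this value and not updated (used with
#'   `lambda_dyn` so normality of the latent dynamics is preserved in the
#'   reconstructed responses).
#' @return A `fit_config` list.
#' @export
fit_config <- function(learning_rate = 0.009, lambda_inp = 1e-5,
                       init_sd = 0.01, convergence_dcost = 1e-5,
                       max_iter = 10000L, min_iter = 5000L,
                       n_restarts = 1L, seed = 1L,
                       lambda_dyn = 0, freeze_C = NULL) {
  if (lambda_inp < 0) stop("config error: lambda_inp must be non-negative")
  if (lambda_dyn < 0) stop("config error: lambda_dyn must be non-negative")
  stopifnot(learning_rate > 0, init_sd >= 0, max_iter >= 1,
            min_iter >= 0, convergence_dcost >= 0)
  structure(
    list(learning_rate = learning_rate, lambda_inp = lambda_inp,
         init_sd = init_sd, convergence_dcost = convergence_dcost,
         max_iter = as.integer(max_iter), min_iter = as.integer(min_iter),
         n_restarts = as.integer(n_restarts), seed = as.integer(seed),
         lambda_dyn = lambda_dyn, freeze_C = freeze_C),
    class = "fit_config"
  )
}

# Bias-corrected ADAM on a flat parameter vector. fn(theta) must return
# list(cost, grad). mask: indices whose gradient is zeroed (frozen).
adam_minimize <- function(theta, fn, lr, max_iter, min_iter, tol,
                          mask = NULL) {
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(max_iter)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r <- fn(theta)
    if (!is.finite(r$cost)) {
      stop("divergence: non-finite cost at iteration ", it)
    }
    trace[it] <- r$cost
    g <- r$grad
    if (any(!is.finite(g))) {
      stop("non-finite gradient at iteration ", it)
    }
    if (!is.null(mask)) g[mask] <- 0
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    theta <- theta - lr * (m / (1 - b1^it)) / (sqrt(v / (1 - b2^it)) + eps)
    if (it >= min_iter && abs(prev - r$cost) < tol) {
      converged <- TRUE
      break
    }
    prev <- r$cost
  }
  list(theta = theta, trace = trace[seq_len(it)], iterations = it,
       converged = converged)
}

# Condition metadata and data cube in the layout the C++ engine expects.
fit_problem <- function(data, grid = data$grid) {
  Y <- data$Y
  N <- dim(Y)[1L]; Tn <- dim(Y)[2L]; K <- dim(Y)[3L]
  cube <- aperm(Y, c(1L, 3L, 2L, 4L))
  dim(cube) <- c(N, K, 2L * Tn)
  cond <- grid$conditions
  list(cube = cube, N = N, Tn = Tn, K = K,
       mlev = as.integer(cond$motion_idx), mdir = as.integer(cond$motion_dir),
       clev = as.integer(cond$color_idx), cdir = as.integer(cond$color_dir),
       n_levels = grid$n_levels)
}

#' Fit a constrained LDS to a response tensor by gradient descent
#'
#' Minimizes the reconstruction MSE plus input-norm penalty jointly over
#' both contexts, with the parameter sharing pattern of the requested model
#' class, using ADAM with analytic gradients (backpropagation through the
#' latent recursion). All parameters are randomly initialized from
#' `N(0, init_sd^2)` under the config seed, so the fit is deterministic
#' given its seed. The returned loading map is orthonormalized post hoc.
#'
#' @param data A `response_tensor` (z-scored).
#' @param class_spec An [lds_class()] specification.
#' @param config A [fit_config()].
#' @param init Optional [lds_params()] to initialize from instead of random.
#' @return A `fit_result`: orthonormalized `params`, `train_mse`,
#'   `cost_trace`, `iterations`, `converged`, `seed`.
#' @export
fit_lds <- function(data, class_spec, config = fit_config(), init = NULL) {
  stopifnot(inherits(data, "response_tensor"), inherits(class_spec, "lds_class"))
  if (any(!is.finite(data$Y))) stop("data must be finite")
  prob <- fit_problem(data)
  lay <- theta_layout(class_spec, prob$N, prob$Tn, prob$n_levels)
  theta0 <- if (is.null(init)) {
    with_seed(config$seed, rnorm(lay$total, 0, config$init_sd))
  } else {
    pack_params(init)
  }
  mask <- NULL
  if (!is.null(config$freeze_C)) {
    idx <- lay$starts[["C"]]:lay$ends[["C"]]
    theta0[idx] <- as.numeric(config$freeze_C)
    mask <- idx
  }
  fn <- function(theta) {
    lds_cost_grad_cpp(theta, prob$cube, lay$L, lay$Um, lay$Uc,
                      class_spec$dynamics_cx, class_spec$inputs_cx,
                      class_spec$time_varying,
                      prob$mlev, prob$mdir, prob$clev, prob$cdir,
                      prob$n_levels, config$lambda_inp, config$lambda_dyn,
                      TRUE)
  }
  opt <- adam_minimize(theta0, fn, config$learning_rate, config$max_iter,
                       config$min_iter, config$convergence_dcost, mask)
  params <- unpack_params(opt$theta, class_spec, prob$N, prob$Tn,
                          prob$n_levels)
  params <- orthonormalize(params)
  final <- lds_cost_grad_cpp(opt$theta, prob$cube, lay$L, lay$Um, lay$Uc,
                             class_spec$dynamics_cx, class_spec$inputs_cx,
                             class_spec$time_varying,
                             prob$mlev, prob$mdir, prob$clev, prob$cdir,
                             prob$n_levels, config$lambda_inp,
                             config$lambda_dyn, FALSE)
  structure(
    list(params = params, class_spec = class_spec,
         train_mse = final$mse, cost_trace = opt$trace,
         iterations = opt$iterations, converged = opt$converged,
         seed = config$seed, config = config),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result %s: train MSE %.5f after %d iterations (%s)\n",
              x$class_spec$label, x$train_mse, x$iterations,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

#' Fit a model class from many random initializations
#'
#' Runs [fit_lds()] with independent seeds `config$seed + 0:(n-1)`. A
#' failing restart is recorded (with its error message) without aborting
#' the batch. Results are sorted by training MSE, best first.
#'
#' @inheritParams fit_lds
#' @param n_restarts Number of restarts (>= 1).
#' @return A `restart_set`: list of `fit_result`s plus a `failures` list;
#'   `summary()` gives mean/SD/SEM of the training MSE across models.
#' @export
multi_restart <- function(data, class_spec, config = fit_config(),
                          n_restarts = config$n_restarts) {
  stopifnot(n_restarts >= 1)
  fits <- list()
  failures <- list()
  for (i in seq_len(n_restarts)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    res <- tryCatch(fit_lds(data, class_spec, cfg_i),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(seed = cfg_i$seed, message = conditionMessage(res))
    } else {
      fits[[length(fits) + 1L]] <- res
    }
  }
  ord <- order(vapply(fits, function(f) f$train_mse, numeric(1L)))
  structure(list(fits = fits[ord], failures = failures,
                 class_spec = class_spec),
            class = "restart_set")
}

#' @export
summary.restart_set <- function(object, ...) {
  mses <- vapply(object$fits, function(f) f$train_mse, numeric(1L))
  out <- list(n = length(mses), n_failed = length(object$failures),
              mean_mse = mean(mses), sd_mse = stats::sd(mses),
              sem_mse = stats::sd(mses) / sqrt(length(mses)),
              best_mse = if (length(mses)) min(mses) else NA_real_,
              median_mse = stats::median(mses))
  class(out) <- "summary.restart_set"
  out
}

#' @export
print.summary.restart_set <- function(x, ...) {
  cat(sprintf("%d restarts (%d failed): train MSE %.5f +/- %.5f (SD), best %.5f\n",
              x$n, x$n_failed, x$mean_mse, x$sd_mse, x$best_mse))
  invisible(x)
}

#' Departure of a dynamics matrix from normality, as a penalty
#'
#' Squared Frobenius norm of the commutator `A A' - A' A`; zero if and only
#' if `A` is normal. Added to the fitting cost with weight `lambda_dyn`
#' when learning normal-dynamics variants.
#'
#' @param A Square matrix.
#' @return Scalar `||A A' - A' A||_F^2`.
#' @export
normal_penalty <- function(A) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  M <- A %*% t(A) - t(A) %*% A
  sum(M^2)
}
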