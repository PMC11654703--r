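# Flat parameter layout for TFR fitting:
# loading | core (context 1 then 2) | dir_courses | coh_scalars.
tfr_layout <- function(spec, n_neurons, n_bins) {
  l <- spec$latent_dim
  U <- sum(spec$input_dims)
  ncore <- if (spec$context_core) 2L else 1L
  sizes <- c(loading = n_neurons * l,
             core = ncore * l * n_bins * (U + 1L),
             dir = (2L * U + 1L) * n_bins,
             P = spec$n_levels * U + 1L)
  ends <- cumsum(sizes)
  list(sizes = sizes, starts = ends - sizes + 1L, ends = ends,
       total = sum(sizes), l = l, U = U, ncore = ncore)
}

tfr_unpack <- function(theta, spec, n_neurons, n_bins) {
  lay <- tfr_layout(spec, n_neurons, n_bins)
  take <- function(nm) theta[lay$starts[[nm]]:lay$ends[[nm]]]
  l <- lay$l; U <- lay$U; U1 <- U + 1L
  loading <- matrix(take("loading"), n_neurons, l)
  cr <- take("core")
  ncell <- l * n_bins * U1
  core <- if (spec$context_core) {
    list(array(cr[seq_len(ncell)], dim = c(l, n_bins, U1)),
         array(cr[ncell + seq_len(ncell)], dim = c(l, n_bins, U1)))
  } else {
    array(cr, dim = c(l, n_bins, U1))
  }
  dirc <- matrix(take("dir"), 2L * U + 1L, n_bins)
  tfr_params(spec, loading, core, dirc, take("P"))
}

tfr_pack <- function(params) {
  core <- if (is.list(params$core)) unlist(params$core) else as.numeric(params$core)
  c(as.numeric(params$loading), core, as.numeric(params$dir_courses),
    params$coh_scalars)
}

# Cost (plain reconstruction MSE) and analytic gradient of the TFR
# contraction with respect to every factor.
tfr_cost_grad <- function(theta, spec, prob, want_grad = TRUE) {
  N <- prob$N; Tn <- prob$Tn; K <- prob$K
  l <- spec$latent_dim
  U <- sum(spec$input_dims); U1 <- U + 1L
  lay <- tfr_layout(spec, N, Tn)
  params <- tfr_unpack(theta, spec, N, Tn)
  cidx <- prob$route$cidx; didx <- prob$route$didx
  P <- params$coh_scalars; R <- params$dir_courses
  # channel traces S[u, t', k]
  S <- array(0, dim = c(U1, Tn, K))
  for (u in seq_len(U1)) {
    for (k in seq_len(K)) S[u, , k] <- P[cidx[u, k]] * R[didx[u, k], ]
  }
  c1 <- 2 / (N * Tn * K * 2)
  sse <- 0
  gC <- matrix(0, N, l)
  gcore <- vector("list", lay$ncore)
  for (i in seq_len(lay$ncore)) gcore[[i]] <- array(0, dim = c(l, Tn, U1))
  gS <- array(0, dim = c(U1, Tn, K))
  for (cx in 1:2) {
    core <- ctx_mat(params$core, cx)
    X <- array(0, dim = c(l, Tn, K))
    for (j in seq_len(Tn)) {
      Cj <- matrix(core[, j, ], nrow = l)
      for (tp in seq_len(Tn - j + 1L)) {
        X[, tp + j - 1L, ] <- X[, tp + j - 1L, ] + Cj %*% matrix(S[, tp, ], ncol = K)
      }
    }
    Xmat <- matrix(X, nrow = l)
    Res <- params$loading %*% Xmat - matrix(prob$Y[, , , cx], nrow = N)
    sse <- sse + sum(Res^2)
    if (!want_grad) next
    GX <- array(c1 * (t(params$loading) %*% Res), dim = c(l, Tn, K))
    gC <- gC + c1 * (Res %*% t(Xmat))
    gi <- if (spec$context_core) cx else 1L
    for (j in seq_len(Tn)) {
      Cj <- matrix(core[, j, ], nrow = l)
      for (tp in seq_len(Tn - j + 1L)) {
        Gt <- matrix(GX[, tp + j - 1L, ], ncol = K)
        gcore[[gi]][, j, ] <- gcore[[gi]][, j, ] + Gt %*% t(matrix(S[, tp, ], ncol = K))
        gS[, tp, ] <- gS[, tp, ] + t(Cj) %*% Gt
      }
    }
  }
  msev <- sse / (N * Tn * K * 2)
  if (!want_grad) return(list(cost = msev, mse = msev, grad = NULL))
  gP <- numeric(length(P))
  gR <- matrix(0, nrow(R), Tn)
  for (u in seq_len(U1)) {
    for (k in seq_len(K)) {
      ci <- cidx[u, k]; di <- didx[u, k]
      gP[ci] <- gP[ci] + sum(gS[u, , k] * R[di, ])
      gR[di, ] <- gR[di, ] + P[ci] * gS[u, , k]
    }
  }
  grad <- c(as.numeric(gC), unlist(gcore), as.numeric(gR), gP)
  list(cost = msev, mse = msev, grad = grad)
}

tfr_problem <- function(data) {
  spec_dims <- dim(data$Y)
  list(Y = data$Y, N = spec_dims[1L], Tn = spec_dims[2L], K = spec_dims[3L])
}

#' Fit a TFR model by gradient descent
#'
#' Minimizes the reconstruction MSE over loading, per-context core tensor,
#' direction time courses, and coherence scalars with ADAM and analytic
#' gradients of the multilinear contraction — the same optimization route
#' as the LDS fit. The loading map is orthonormalized post hoc (absorbed
#' into the core).
#'
#' @param data A `response_tensor`.
#' @param class_spec A [tfr_class()].
#' @param config A [fit_config()]; `lambda_inp`/`lambda_dyn` do not apply
#'   to the TFR objective and are ignored.
#' @return A `fit_result` with `params` of class `tfr_params`.
#' @export
fit_tfr <- function(data, class_spec, config = fit_config()) {
  stopifnot(inherits(data, "response_tensor"), inherits(class_spec, "tfr_class"))
  if (data$grid$n_levels != class_spec$n_levels) {
    stop("grid has ", data$grid$n_levels, " levels but the TFR class expects ",
         class_spec$n_levels)
  }
  prob <- tfr_problem(data)
  prob$route <- tfr_routing(data$grid, class_spec$input_dims)
  lay <- tfr_layout(class_spec, prob$N, prob$Tn)
  theta0 <- with_seed(config$seed, rnorm(lay$total, 0, config$init_sd))
  fn <- function(theta) tfr_cost_grad(theta, class_spec, prob, TRUE)
  opt <- adam_minimize(theta0, fn, config$learning_rate, config$max_iter,
                       config$min_iter, config$convergence_dcost)
  params <- orthonormalize_tfr(tfr_unpack(opt$theta, class_spec, prob$N,
                                          prob$Tn))
  structure(
    list(params = params, class_spec = class_spec,
         train_mse = fn(opt$theta)$mse, cost_trace = opt$trace,
         iterations = opt$iterations, converged = opt$converged,
         seed = config$seed, config = config),
    class = "fit_result"
  )
}

#' Alternating estimation of a TFR model
#'
#' Alternates (i) a closed-form reduced-rank-regression update of the
#' loading map and core tensor given the current input traces (the loading
#' shared across contexts comes from the SVD of the stacked per-context
#' fitted values) with (ii) gradient refinement of the input factors
#' (direction courses and coherence scalars) holding loading and core
#' fixed. Provided as an independent solver for cross-checking the
#' gradient route on small problems.
#'
#' @inheritParams fit_tfr
#' @param n_outer Number of alternations.
#' @param inner_iter ADAM iterations per input-factor refinement.
#' @return A `fit_result` with `params` of class `tfr_params`.
#' @export
fit_tfr_als <- function(data, class_spec, config = fit_config(),
                        n_outer = 8L, inner_iter = 300L) {
  stopifnot(inherits(data, "response_tensor"), inherits(class_spec, "tfr_class"))
  prob <- tfr_problem(data)
  prob$route <- tfr_routing(data$grid, class_spec$input_dims)
  N <- prob$N; Tn <- prob$Tn; K <- prob$K
  l <- class_spec$latent_dim
  U <- sum(class_spec$input_dims); U1 <- U + 1L
  lay <- tfr_layout(class_spec, N, Tn)
  theta <- with_seed(config$seed, rnorm(lay$total, 0, 1))
  # start the input factors at smooth order-one values so the first
  # regression step is well conditioned
  theta[lay$starts[["dir"]]:lay$ends[["dir"]]] <- 1
  for (outer in seq_len(n_outer)) {
    params <- tfr_unpack(theta, class_spec, N, Tn)
    S <- tfr_input_traces(params, data$grid)
    # regressor matrix F[(t,k), (j,u)] = S[u, t-j+1, k]
    Fm <- matrix(0, Tn * K, Tn * U1)
    for (j in seq_len(Tn)) {
      for (u in seq_len(U1)) {
        col <- (u - 1L) * Tn + j
        for (tp in seq_len(Tn - j + 1L)) {
          Fm[(seq_len(K) - 1L) * Tn + tp + j - 1L, col] <- S[u, tp, ]
        }
      }
    }
    FtF <- crossprod(Fm) + 1e-8 * diag(ncol(Fm))
    Hs <- lapply(1:2, function(cx) {
      M <- matrix(prob$Y[, , , cx], nrow = N)  # N x (T*K), t fastest
      t(solve(FtF, t(M %*% Fm)))               # N x (T*U1)
    })
    fitted <- cbind(Hs[[1L]] %*% t(Fm), Hs[[2L]] %*% t(Fm))
    C <- svd(fitted, nu = l, nv = 0)$u
    core_from_H <- function(H) array(t(C) %*% H, dim = c(l, Tn, U1))
    theta[lay$starts[["loading"]]:lay$ends[["loading"]]] <- as.numeric(C)
    cores <- if (class_spec$context_core) {
      c(as.numeric(core_from_H(Hs[[1L]])), as.numeric(core_from_H(Hs[[2L]])))
    } else {
      as.numeric(core_from_H((Hs[[1L]] + Hs[[2L]]) / 2))
    }
    theta[lay$starts[["core"]]:lay$ends[["core"]]] <- cores
    # refine the input factors with loading and core frozen
    mask <- c(lay$starts[["loading"]]:lay$ends[["loading"]],
              lay$starts[["core"]]:lay$ends[["core"]])
    fn <- function(th) tfr_cost_grad(th, class_spec, prob, TRUE)
    opt <- adam_minimize(theta, fn, config$learning_rate, inner_iter, 0L,
                         config$convergence_dcost, mask)
    theta <- opt$theta
  }
  params <- orthonormalize_tfr(tfr_unpack(theta, class_spec, N, Tn))
  final <- tfr_cost_grad(theta, class_spec, prob, FALSE)
  structure(
    list(params = params, class_spec = class_spec, train_mse = final$mse,
         cost_trace = NULL, iterations = NA_integer_, converged = NA,
         seed = config$seed, config = config),
    class = "fit_result"
  )
}
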