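#' Define a tensor factor regression model class
#'
#' TFR factorizes the response tensor into an orthonormal loading map, a
#' per-context core tensor indexed by latent, lag, and input channel, and
#' low-rank input regressors (direction time courses and coherence
#' scalars) that are repeated across task conditions by fixed indicator
#' tensors. Channels are the real input dimensions (motion then color)
#' plus one baseline channel capturing condition-independent structure.
#'
#' @param latent_dim Rank of the factorization (columns of the loading map).
#' @param input_dims `c(motion, color)` real input channel counts.
#' @param context_core If `TRUE` the core tensor is learned per context.
#' @param n_levels Number of signed coherence levels of the task the model
#'   is built for (6 in the standard task).
#' @return A `tfr_class` specification.
#' @export
tfr_class <- function(latent_dim, input_dims = c(2L, 2L), context_core = TRUE,
                      n_levels = 6L) {
  if (length(input_dims) == 1L) input_dims <- rep(input_dims, 2L)
  structure(
    list(latent_dim = as.integer(latent_dim),
         input_dims = as.integer(input_dims),
         n_channels = sum(input_dims) + 1L,
         context_core = isTRUE(context_core),
         n_levels = as.integer(n_levels),
         label = if (context_core) "{ABcx}" else "{AB}"),
    class = "tfr_class"
  )
}

#' Exact learnable-parameter count of a TFR model
#'
#' Loading `N*l` + core `(2 if per-context else 1)*l*T*(U+1)` + direction
#' courses `(2U+1)*T` + coherence scalars `6U+1`, with `U` the number of
#' real input dimensions (the baseline channel has one course and one
#' scalar but no per-coherence structure).
#'
#' @param latent_dim Rank `l`.
#' @param input_dims `c(motion, color)` real input dimensions.
#' @param n_neurons,n_bins Data dimensions.
#' @param context_dependent_core Whether the core tensor is per-context.
#' @return Integer parameter count.
#' @examples
#' count_parameters_tfr(14, c(2, 2), n_neurons = 727, n_bins = 15)
#' @export
count_parameters_tfr <- function(latent_dim, input_dims, n_neurons, n_bins,
                                 context_dependent_core = TRUE) {
  if (length(input_dims) == 1L) input_dims <- rep(input_dims, 2L)
  U <- sum(input_dims)
  n_core <- if (context_dependent_core) 2L else 1L
  as.integer(
    n_neurons * latent_dim +
    n_core * latent_dim * n_bins * (U + 1L) +
    (2L * U + 1L) * n_bins +
    6L * U + 1L
  )
}

#' Fixed indicator tensors of the TFR factorization
#'
#' `T_ind[t, t', j]` is 1 iff `t - t' = j - 1` with `t >= t'` (the causal
#' convolution layout: lag index `j` is 1-based, lag `j - 1` bins).
#' `Q_ind` routes each condition to exactly one motion coherence cell, one
#' color coherence cell, and the shared baseline cell (columns: 6 motion
#' levels, 6 color levels, baseline). Both are data independent and are
#' rebuilt on demand, never stored.
#'
#' @param n_bins Number of time bins.
#' @param grid A [make_task_grid()].
#' @return List with `T_ind` (`[T, T, T]` 0/1 array) and `Q_ind`
#'   (`K x (2*n_levels + 1)` 0/1 matrix).
#' @export
build_indicators <- function(n_bins, grid) {
  T_ind <- array(0L, dim = c(n_bins, n_bins, n_bins))
  for (t in seq_len(n_bins)) {
    for (tp in seq_len(t)) {
      T_ind[t, tp, t - tp + 1L] <- 1L
    }
  }
  nl <- grid$n_levels
  K <- grid$n_conditions
  Q_ind <- matrix(0L, K, 2L * nl + 1L,
                  dimnames = list(NULL, c(paste0("mot", seq_len(nl)),
                                          paste0("col", seq_len(nl)),
                                          "baseline")))
  cond <- grid$conditions
  for (k in seq_len(K)) {
    Q_ind[k, cond$motion_idx[k]] <- 1L
    Q_ind[k, nl + cond$color_idx[k]] <- 1L
    Q_ind[k, 2L * nl + 1L] <- 1L
  }
  list(T_ind = T_ind, Q_ind = Q_ind)
}

# Per-channel routing of conditions into coherence-scalar and
# direction-course indices. Channel order: motion dims, color dims,
# baseline. For real channel u: scalar index c = 6(u-1) + level,
# course index d = 2(u-1) + direction; baseline uses c = 6U+1, d = 2U+1.
tfr_routing <- function(grid, input_dims) {
  U <- sum(input_dims)
  cond <- grid$conditions
  nl <- grid$n_levels
  K <- grid$n_conditions
  cidx <- matrix(0L, U + 1L, K)
  didx <- matrix(0L, U + 1L, K)
  for (u in seq_len(U)) {
    mod <- if (u <= input_dims[1L]) "motion" else "color"
    lev <- cond[[paste0(mod, "_idx")]]
    dir <- cond[[paste0(mod, "_dir")]]
    cidx[u, ] <- nl * (u - 1L) + lev
    didx[u, ] <- 2L * (u - 1L) + dir
  }
  cidx[U + 1L, ] <- nl * U + 1L
  didx[U + 1L, ] <- 2L * U + 1L
  list(cidx = cidx, didx = didx, U = U)
}

#' Parameter set of a tensor factor regression model
#'
#' @param class_spec A [tfr_class()].
#' @param loading `N x l` loading map.
#' @param core `[l, T, U+1]` core tensor (lags 0..T-1 along the second
#'   index), or a list of two such arrays when the core is per-context.
#' @param dir_courses `(2U+1) x T` direction time courses (two per real
#'   input dimension plus the baseline course).
#' @param coh_scalars Length `6U+1` coherence scalars (six per real input
#'   dimension plus the baseline scalar).
#' @param d Optional per-neuron bias carried over when a fitted LDS is
#'   embedded; the canonical TFR has none (defaults to zero, never counted
#'   or fitted).
#' @return A `tfr_params` object.
#' @export
tfr_params <- function(class_spec, loading, core, dir_courses, coh_scalars,
                       d = NULL) {
  stopifnot(inherits(class_spec, "tfr_class"))
  l <- class_spec$latent_dim
  U <- sum(class_spec$input_dims)
  loading <- as.matrix(loading)
  stopifnot(ncol(loading) == l)
  chk_core <- function(co) {
    stopifnot(length(dim(co)) == 3L, dim(co)[1L] == l, dim(co)[3L] == U + 1L)
    co
  }
  core <- if (class_spec$context_core) {
    stopifnot(is.list(core), length(core) == 2L)
    lapply(core, chk_core)
  } else {
    chk_core(core)
  }
  dir_courses <- as.matrix(dir_courses)
  stopifnot(nrow(dir_courses) == 2L * U + 1L)
  stopifnot(length(coh_scalars) == class_spec$n_levels * U + 1L)
  if (is.null(d)) d <- rep(0, nrow(loading))
  structure(
    list(class_spec = class_spec, loading = loading, core = core,
         dir_courses = dir_courses, coh_scalars = as.numeric(coh_scalars),
         d = as.numeric(d)),
    class = "tfr_params"
  )
}

# Channel input traces S[u, t', k] = P[c(u,k)] * R[d(u,k), t'].
tfr_input_traces <- function(params, grid) {
  route <- tfr_routing(grid, params$class_spec$input_dims)
  Tn <- ncol(params$dir_courses)
  K <- grid$n_conditions
  U1 <- route$U + 1L
  S <- array(0, dim = c(U1, Tn, K))
  for (u in seq_len(U1)) {
    for (k in seq_len(K)) {
      S[u, , k] <- params$coh_scalars[route$cidx[u, k]] *
        params$dir_courses[route$didx[u, k], ]
    }
  }
  S
}

#' Predict a response tensor from TFR parameters
#'
#' Contracts loading, core, indicator tensors, coherence scalars and
#' direction courses: the latent at time `t` is the causal convolution of
#' the core (over lags) with the per-channel input traces, mapped through
#' the loading map. Linear in every factor and fully deterministic.
#'
#' @param params A [tfr_params()] set.
#' @param grid A [make_task_grid()].
#' @return Array `[N, T, K, 2]` (the two contexts share the core unless the
#'   class is context-dependent).
#' @export
tfr_predict <- function(params, grid) {
  S <- tfr_input_traces(params, grid)
  Tn <- dim(S)[2L]
  K <- dim(S)[3L]
  N <- nrow(params$loading)
  l <- params$class_spec$latent_dim
  out <- array(0, dim = c(N, Tn, K, 2L))
  for (cx in 1:2) {
    core <- ctx_mat(params$core, cx)
    X <- array(0, dim = c(l, Tn, K))
    for (j in seq_len(Tn)) {            # lag j - 1
      Cj <- matrix(core[, j, ], nrow = l)
      for (tp in seq_len(Tn - j + 1L)) {
        X[, tp + j - 1L, ] <- X[, tp + j - 1L, ] +
          Cj %*% matrix(S[, tp, ], ncol = K)
      }
    }
    out[, , , cx] <- array(params$loading %*% matrix(X, nrow = l) + params$d,
                           dim = c(N, Tn, K))
  }
  out
}

#' Embed an LDS in the TFR core tensor
#'
#' The LDS is nested in TFR: with core `[l, lag j-1, u] = (A^(j-1) B)[l, u]`
#' for real channels and `A^j x0` on the baseline channel, the TFR
#' contraction reproduces the LDS forward simulation exactly, provided the
#' baseline direction course is an indicator on the first bin with unit
#' scalar (as [as_tfr()] sets up).
#'
#' @param A,B,x0 LDS dynamics matrix, combined input subspace `L x U`
#'   (motion columns then color), and initial condition for one context.
#' @param n_bins Number of time bins (lags 0..n_bins-1).
#' @return Core array `[L, n_bins, U+1]`.
#' @export
lds_to_core <- function(A, B, x0, n_bins) {
  L <- nrow(A)
  U <- ncol(B)
  core <- array(0, dim = c(L, n_bins, U + 1L))
  Apow <- diag(L)                        # A^(j-1)
  for (j in seq_len(n_bins)) {
    core[, j, seq_len(U)] <- Apow %*% B
    core[, j, U + 1L] <- (Apow %*% A) %*% x0   # A^j x0
    Apow <- Apow %*% A
  }
  core
}

#' Convert fitted LDS parameters to an equivalent TFR parameter set
#'
#' @param params An [lds_params()] set (time-varying or constant inputs).
#' @param grid A [make_task_grid()] with six signed levels.
#' @return A [tfr_params()] set whose [tfr_predict()] equals
#'   [reconstruct()] on every condition and context.
#' @export
as_tfr <- function(params, grid) {
  cs <- params$class_spec
  Tn <- nrow(params$inputs$motion$course_in)
  Um <- cs$input_dim_motion
  Uc <- cs$input_dim_color
  U <- Um + Uc
  nl <- grid$n_levels
  spec <- tfr_class(cs$latent_dim, c(Um, Uc), context_core = TRUE,
                    n_levels = nl)
  core <- lapply(1:2, function(cx) {
    lds_to_core(ctx_mat(params$A, cx),
                cbind(ctx_mat(params$B_mot, cx), ctx_mat(params$B_col, cx)),
                params$x0[, cx], Tn)
  })
  dir_courses <- matrix(0, 2L * U + 1L, Tn)
  coh_scalars <- numeric(nl * U + 1L)
  for (u in seq_len(U)) {
    mod <- if (u <= Um) params$inputs$motion else params$inputs$color
    jdim <- if (u <= Um) u else u - Um
    dir_courses[2L * (u - 1L) + 1L, ] <- mod$course_in[, jdim]
    dir_courses[2L * (u - 1L) + 2L, ] <- mod$course_out[, jdim]
    coh_scalars[nl * (u - 1L) + seq_len(nl)] <- mod$scalars[, jdim]
  }
  dir_courses[2L * U + 1L, 1L] <- 1      # baseline: first-bin indicator
  coh_scalars[nl * U + 1L] <- 1
  tfr_params(spec, params$C_load, core, dir_courses, coh_scalars,
             d = params$d)
}

#' Orthonormalize a TFR loading map
#'
#' Absorbs `S V'` of the loading's SVD into the core tensor so the loading
#' has orthonormal columns; predictions are unchanged.
#'
#' @param params A [tfr_params()] set.
#' @return Transformed parameter set.
#' @export
orthonormalize_tfr <- function(params) {
  sv <- svd(params$loading)
  if (min(sv$d) < max(sv$d) * 1e-10) stop("degenerate loading map")
  Tm <- diag(sv$d, length(sv$d)) %*% t(sv$v)
  apply_core <- function(co) {
    dims <- dim(co)
    array(Tm %*% matrix(co, nrow = dims[1L]), dim = dims)
  }
  out <- params
  out$core <- if (is.list(params$core)) lapply(params$core, apply_core)
              else apply_core(params$core)
  out$loading <- sv$u
  out
}
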