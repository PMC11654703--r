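#' Principal component dimensions of recorded activity in one context
#'
#' PCA of the context's population responses unfolded over times and
#' conditions — perturbation directions that require no model fitting.
#'
#' @param data A `response_tensor` (or `[N,T,K,cx]` array).
#' @param context Context index.
#' @return List with `dims` (`N x p` orthonormal, ordered by variance) and
#'   `variance` (per-PC variance).
#' @export
pca_dimensions <- function(data, context = 1L) {
  Y <- if (inherits(data, "response_tensor")) data$Y else data
  if (any(!is.finite(Y))) stop("data must be finite")
  N <- dim(Y)[1L]
  M <- matrix(Y[, , , context], nrow = N)       # N x (T*K)
  pr <- prcomp(t(M), center = TRUE, scale. = FALSE)
  list(dims = pr$rotation, variance = pr$sdev^2)
}

#' Specify a simulated causal perturbation
#'
#' State perturbations add a vector of fixed norm to the activity at a
#' single onset bin; input perturbations switch one modality's external
#' input off over a short window (as if the corresponding coherence were
#' transiently set to 0%).
#'
#' @param kind `"state"` or `"input"`.
#' @param direction Perturbation direction for state kind: a neuron-space
#'   vector (mapped into latent space through the orthonormal loading,
#'   which preserves its norm component in the model subspace) or a
#'   latent-space vector.
#' @param norm Perturbation norm (default 10).
#' @param onset Onset bin (default 1, the first analyzed bin).
#' @param window Switch-off window length in bins for input kind
#'   (default 2, i.e. 100 ms).
#' @param modality Modality to switch off for input kind.
#' @return A `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("state", "input"), direction = NULL,
                              norm = 10, onset = 1L, window = 2L,
                              modality = c("motion", "color")) {
  kind <- match.arg(kind)
  modality <- match.arg(modality)
  if (kind == "state" && is.null(direction)) {
    stop("state perturbations need a direction")
  }
  structure(list(kind = kind, direction = direction, norm = norm,
                 onset = as.integer(onset), window = as.integer(window),
                 modality = modality),
            class = "perturbation_spec")
}

#' Simulate a perturbation experiment on a fitted or ground-truth model
#'
#' Runs paired (perturbed / unperturbed) forward simulations and returns
#' the effect — their difference — in observation space. For a linear
#' model the effect of a state perturbation is identical across
#' conditions and scales linearly with the perturbation norm; the response
#' is classified as amplifying when the effect norm rises above its onset
#' value before decaying.
#'
#' @param params An [lds_params()] set (orthonormalized loading assumed for
#'   neuron-space directions).
#' @param grid Task grid.
#' @param spec A [perturbation_spec()].
#' @param context Context index.
#' @param conditions Conditions to probe (default all).
#' @param axes Optional named list/matrix of unit neuron-space axes to
#'   project the effect onto (e.g. a decision axis).
#' @return A `perturbation_result`: unperturbed and perturbed observation
#'   trajectories `[N, T, n_cond]`, the effect trajectories, the effect
#'   norm over time per condition, axis projections, and the `amplifying`
#'   flag.
#' @export
perturb <- function(params, grid, spec, context = 1L,
                    conditions = seq_len(grid$n_conditions), axes = NULL) {
  stopifnot(inherits(spec, "perturbation_spec"))
  Tn <- nrow(params$inputs$motion$course_in)
  if (spec$onset < 1L || spec$onset > Tn) {
    stop("perturbation onset outside the trial (1..", Tn, ")")
  }
  N <- n_neurons(params)
  L <- params$class_spec$latent_dim
  base_lat <- sim_latents_all(params, grid, contexts = context)[[1L]]
  obs_of <- function(X) {  # [L, T+1, K] -> [N, T, k-subset]
    Xs <- X[, -1L, conditions, drop = FALSE]
    array(params$C_load %*% matrix(Xs, nrow = L) + params$d,
          dim = c(N, Tn, length(conditions)))
  }
  unpert <- obs_of(base_lat)
  if (spec$kind == "state") {
    dir <- as.numeric(spec$direction)
    if (length(dir) == N) {
      dx <- as.numeric(t(params$C_load) %*% (spec$norm * dir))
    } else if (length(dir) == L) {
      dx <- spec$norm * dir / sqrt(sum(dir^2))
    } else {
      stop("direction must be neuron- or latent-space")
    }
    A <- ctx_mat(params$A, context)
    dX <- matrix(0, L, Tn)
    dX[, spec$onset] <- dx
    if (spec$onset < Tn) {
      for (t in (spec$onset + 1L):Tn) dX[, t] <- A %*% dX[, t - 1L]
    }
    dY <- params$C_load %*% dX                   # N x T, condition-independent
    effect <- array(dY, dim = c(N, Tn, length(conditions)))
    pert <- unpert + effect
  } else {
    pert_params <- params
    m <- pert_params$inputs[[spec$modality]]
    win <- spec$onset:min(Tn, spec$onset + spec$window - 1L)
    m$course_in[win, ] <- 0
    m$course_out[win, ] <- 0
    pert_params$inputs[[spec$modality]] <- m
    pert <- obs_of(sim_latents_all(pert_params, grid, contexts = context)[[1L]])
    effect <- pert - unpert
  }
  effect_norm <- apply(effect, c(2L, 3L), function(v) sqrt(sum(v^2)))
  onset_norm <- effect_norm[spec$onset, 1L]
  later <- if (spec$onset < Tn) {
    max(effect_norm[(spec$onset + 1L):Tn, 1L])
  } else {
    -Inf
  }
  amplifying <- is.finite(later) && later > onset_norm * (1 + 1e-9)
  projections <- NULL
  if (!is.null(axes)) {
    ax <- as.matrix(axes)
    projections <- array(t(ax) %*% matrix(effect[, , 1L], nrow = N),
                         dim = c(ncol(ax), Tn))
  }
  structure(
    list(unperturbed = unpert, perturbed = pert, effect = effect,
         effect_norm = effect_norm, projections = projections,
         amplifying = amplifying, spec = spec, context = context),
    class = "perturbation_result"
  )
}

#' Count transiently amplifying PC perturbations
#'
#' Applies state perturbations along the leading principal components of
#' the data and counts how many are transiently amplified — the
#' model-discriminating signature: strongly non-normal (dynamics-switching)
#' models amplify several PC perturbations, near-normal (input-switching)
#' models none.
#'
#' @param params Model parameters (orthonormalized loading).
#' @param data The `response_tensor` whose PCs define the directions.
#' @param n_pcs Number of leading PCs to probe.
#' @param context Context index.
#' @param norm Perturbation norm.
#' @return List with `n_amplifying`, per-PC logical `amplifying`, and the
#'   max effect-norm gain per PC.
#' @export
amplification_screen <- function(params, data, n_pcs = 10L, context = 1L,
                                 norm = 10) {
  pcs <- pca_dimensions(data, context)$dims
  n_pcs <- min(n_pcs, ncol(pcs))
  flags <- logical(n_pcs)
  gain <- numeric(n_pcs)
  for (i in seq_len(n_pcs)) {
    sp <- perturbation_spec("state", direction = pcs[, i], norm = norm)
    res <- perturb(params, data$grid, sp, context = context,
                   conditions = 1L)
    flags[i] <- res$amplifying
    onset <- res$effect_norm[sp$onset, 1L]
    gain[i] <- max(res$effect_norm[, 1L]) / onset
  }
  list(n_amplifying = sum(flags), amplifying = flags, gain = gain)
}

#' Project trajectories onto an ordered, orthogonalized set of task axes
#'
#' Orthogonalizes the ordered axes with a QR decomposition (the first axis
#' is unchanged up to sign), records the pairwise angles between the raw
#' axes, and projects per-condition trajectories onto the orthogonal
#' frame, optionally after subtracting the across-condition mean.
#'
#' @param data A `response_tensor` or `[N,T,K,cx]` array of trajectories.
#' @param axes `N x m` matrix of ordered unit axes (rank m).
#' @param subtract_condition_mean Remove the across-condition mean first.
#' @return List with `projections` (`[m, T, K, cx]`), the orthogonalized
#'   `axes_orth`, and `angles_deg` (pairwise angles before
#'   orthogonalization).
#' @export
task_subspace_projection <- function(data, axes,
                                     subtract_condition_mean = FALSE) {
  Y <- if (inherits(data, "response_tensor")) data$Y else data
  ax <- as.matrix(axes)
  qrd <- qr(ax)
  if (qrd$rank < ncol(ax)) {
    dep <- setdiff(seq_len(ncol(ax)), qrd$pivot[seq_len(qrd$rank)])
    stop("axis set is rank deficient; dependent axes: ",
         paste(dep, collapse = ", "))
  }
  Q <- qr.Q(qrd)
  # fix signs so each orthogonalized axis correlates positively with its input
  s <- sign(diag(qr.R(qrd)))
  Q <- sweep(Q, 2L, ifelse(s == 0, 1, s), "*")
  G <- crossprod(ax)
  cosang <- G / sqrt(outer(diag(G), diag(G)))
  angles <- acos(pmin(pmax(abs(cosang), 0), 1)) * 180 / pi
  diag(angles) <- 0
  dims <- dim(Y)
  if (subtract_condition_mean) {
    CI <- apply(Y, c(1L, 2L, 4L), mean)
    Y <- Y - aperm(array(CI, dim = dims[c(1L, 2L, 4L, 3L)]), c(1L, 2L, 4L, 3L))
  }
  proj <- array(t(Q) %*% matrix(Y, nrow = dims[1L]),
                dim = c(ncol(Q), dims[2L], dims[3L], dims[4L]))
  list(projections = proj, axes_orth = Q, angles_deg = angles)
}
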