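#' Specify a ground-truth LDS for synthetic-task generation
#'
#' Describes the generative system used to emulate the statistical shape of
#' condition-averaged population tensors from the contextual random-dots
#' task: a stable latent LDS with a planned eigenvalue spectrum, smooth
#' transient input courses whose amplitude scales with signed coherence, an
#' orthonormal loading map, and one of four context regimes.
#'
#' @param n_neurons,n_bins,latent_dim,input_dims Desk-scale defaults
#'   (60 neurons, 15 bins of 50 ms, 8 latents, 2+2 inputs) — large enough to
#'   exercise every downstream analysis while keeping fits at seconds scale.
#' @param eigen_plan Complex (or numeric) vector of target eigenvalues of
#'   the dynamics matrix; complex entries must appear with their conjugate
#'   partner. If shorter than `latent_dim` the remainder is filled with
#'   seeded fast real modes (norms in 0.2-0.6, never slow). The default plan
#'   contains a near-unity integration-like mode, slow real and rotational
#'   modes, and fast modes (slow-mode fraction 1/2).
#' @param non_normality Scalar >= 0 skewing the eigenbasis; 0 gives a normal
#'   dynamics matrix (Henrici index 0).
#' @param context_mode One of `"none"`, `"input-switching"`,
#'   `"dynamics-switching"`, `"both"`. Input switching scales the irrelevant
#'   modality's input subspace by `input_gain_irrelevant` in each context;
#'   dynamics switching re-aligns the eigenbasis per context (same
#'   spectrum).
#' @param input_gain_irrelevant Gain in `[0, 1]` applied to the irrelevant
#'   input subspace under input switching.
#' @param noise_sd SD of the i.i.d. Gaussian observation noise added on the
#'   rate scale before z-scoring.
#' @param seed Integer seed; identical specs give bit-identical outputs.
#' @return A `ground_truth_spec` object.
#' @export
ground_truth_spec <- function(n_neurons = 60L, n_bins = 15L, latent_dim = 8L,
                              input_dims = c(2L, 2L), eigen_plan = NULL,
                              non_normality = 0,
                              context_mode = c("none", "input-switching",
                                               "dynamics-switching", "both"),
                              input_gain_irrelevant = 0.6,
                              noise_sd = 0.1, seed = 1L) {
  context_mode <- match.arg(context_mode)
  if (is.null(eigen_plan)) {
    blocks <- list(0.97, 0.9,
                   complex(modulus = 0.85, argument = c(0.5, -0.5)),
                   0.6, 0.5,
                   complex(modulus = 0.4, argument = c(1, -1)))
    eigen_plan <- complex(0)
    for (b in blocks) {  # truncate by whole conjugate blocks
      if (length(eigen_plan) + length(b) > latent_dim) break
      eigen_plan <- c(eigen_plan, as.complex(b))
    }
  }
  eigen_plan <- as.complex(eigen_plan)
  if (length(eigen_plan) > latent_dim) {
    stop("dimension error: eigen_plan longer than latent_dim")
  }
  if (any(Mod(eigen_plan) <= 0) || any(Mod(eigen_plan) > 1.05)) {
    stop("eigen_plan norms must lie in (0, 1.05]")
  }
  if (non_normality < 0) stop("non_normality must be >= 0")
  if (input_gain_irrelevant < 0 || input_gain_irrelevant > 1) {
    stop("input_gain_irrelevant must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(input_dims) == 1L) input_dims <- rep(input_dims, 2L)
  stopifnot(latent_dim >= sum(input_dims) / 2)
  structure(
    list(n_neurons = as.integer(n_neurons), n_bins = as.integer(n_bins),
         latent_dim = as.integer(latent_dim),
         input_dims = as.integer(input_dims), eigen_plan = eigen_plan,
         non_normality = non_normality, context_mode = context_mode,
         input_gain_irrelevant = input_gain_irrelevant,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "ground_truth_spec"
  )
}

# Pair up the eigen plan into real 1x1 and conjugate 2x2 blocks; error on a
# complex value whose conjugate partner is missing.
eigenplan_blocks <- function(plan, tol = 1e-9) {
  blocks <- list()
  used <- rep(FALSE, length(plan))
  for (i in seq_along(plan)) {
    if (used[i]) next
    lam <- plan[i]
    if (abs(Im(lam)) < tol) {
      blocks[[length(blocks) + 1L]] <- matrix(Re(lam), 1L, 1L)
      used[i] <- TRUE
    } else {
      j <- which(!used & abs(plan - Conj(lam)) < tol &
                   seq_along(plan) != i)[1L]
      if (is.na(j)) {
        stop("plan error: complex eigenvalue ", format(lam),
             " has no conjugate partner")
      }
      re <- Re(lam); im <- abs(Im(lam))
      blocks[[length(blocks) + 1L]] <-
        matrix(c(re, im, -im, re), 2L, 2L)
      used[i] <- used[j] <- TRUE
    }
  }
  blocks
}

block_diag <- function(blocks) {
  n <- sum(vapply(blocks, nrow, integer(1L)))
  M <- matrix(0, n, n)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    M[idx, idx] <- b
    at <- at + nrow(b)
  }
  M
}

random_orthonormal <- function(nr, nc = nr) {
  q <- qr.Q(qr(matrix(rnorm(nr * max(nr, nc)), nr)))
  q[, seq_len(nc), drop = FALSE]
}

# Build A = R Lambda R^-1 where Lambda is the real block form of the plan
# and R blends an orthonormal basis toward a random skewed one.
build_dynamics <- function(plan, latent_dim, non_normality) {
  blocks <- eigenplan_blocks(plan)
  n_planned <- sum(vapply(blocks, nrow, integer(1L)))
  if (latent_dim > n_planned) {
    fill <- runif(latent_dim - n_planned, 0.2, 0.6)
    blocks <- c(blocks, lapply(fill, function(v) matrix(v, 1L, 1L)))
  }
  Lam <- block_diag(blocks)
  Q <- random_orthonormal(latent_dim)
  if (non_normality > 0) {
    S <- matrix(rnorm(latent_dim^2), latent_dim)
    S <- S / norm(S, "2")
    R <- Q + non_normality * S
    if (abs(det(R)) < 1e-8) R <- R + 0.1 * diag(latent_dim)
    A <- R %*% Lam %*% solve(R)
  } else {
    A <- Q %*% Lam %*% t(Q)
  }
  A
}

# Smooth transient course: rises to its peak (1) by bin 3, decays after,
# emulating inputs that are strong over the first third of the trial.
bump_course <- function(n_bins, t_peak = 3) {
  t <- seq_len(n_bins)
  (t / t_peak) * exp(1 - t / t_peak)
}

#' Draw a ground-truth LDS parameter set
#'
#' Realizes a [ground_truth_spec()]: the dynamics matrix has exactly the
#' planned eigenvalues by construction (real block form conjugated by a
#' basis skewed according to `non_normality`), the loading map is a random
#' orthonormal frame, input courses are smooth transient bumps and input
#' scalars equal the signed coherence levels, and the context regime
#' determines which parameters differ across contexts.
#'
#' @param spec A [ground_truth_spec()].
#' @param grid Task grid providing the signed coherence levels (default the
#'   standard 36-condition grid).
#' @return An [lds_params()] set in the generating model class.
#' @export
sample_ground_truth <- function(spec, grid = make_task_grid()) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  with_seed(spec$seed, {
    L <- spec$latent_dim
    dyn_cx <- spec$context_mode %in% c("dynamics-switching", "both")
    inp_cx <- spec$context_mode %in% c("input-switching", "both")
    cls <- lds_class(
      paste0(if (dyn_cx) "Acx" else "A", ",", if (inp_cx) "Bcx" else "B"),
      latent_dim = L, input_dims = spec$input_dims, time_varying = TRUE)

    if (dyn_cx) {
      A <- list(build_dynamics(spec$eigen_plan, L, spec$non_normality),
                build_dynamics(spec$eigen_plan, L, spec$non_normality))
    } else {
      A <- build_dynamics(spec$eigen_plan, L, spec$non_normality)
    }
    Bm0 <- random_orthonormal(L, spec$input_dims[1L])
    Bc0 <- random_orthonormal(L, spec$input_dims[2L])
    if (inp_cx) {
      g <- spec$input_gain_irrelevant
      # context 1 = motion context: color irrelevant; context 2: motion irrelevant
      B_mot <- list(Bm0, Bm0 * g)
      B_col <- list(Bc0 * g, Bc0)
    } else {
      B_mot <- Bm0
      B_col <- Bc0
    }
    # distinct roles per input dimension so the input subspace is truly
    # multidimensional: dim 1 scales with signed coherence, dim 2 with
    # coherence magnitude (the curved coh/|coh| structure of the task),
    # further dims get random smooth scalars; each dimension has its own
    # transient course (staggered peaks)
    mk_course <- function(U) {
      vapply(seq_len(U), function(j) bump_course(spec$n_bins, t_peak = 2 + j),
             numeric(spec$n_bins))
    }
    mk_scal <- function(U, levels) {
      s <- matrix(0, length(levels), U)
      if (U >= 1L) s[, 1L] <- levels
      if (U >= 2L) s[, 2L] <- abs(levels)
      if (U >= 3L) {
        s[, 3:U] <- matrix(rnorm(length(levels) * (U - 2L), 0, 0.2),
                           length(levels))
      }
      s
    }
    inputs <- input_model(
      mk_course(spec$input_dims[1L]), mk_course(spec$input_dims[1L]),
      mk_course(spec$input_dims[2L]), mk_course(spec$input_dims[2L]),
      scal_motion = mk_scal(spec$input_dims[1L], grid$motion_levels),
      scal_color = mk_scal(spec$input_dims[2L], grid$color_levels),
      time_varying = TRUE)
    x0 <- matrix(rnorm(L * 2L, 0, 0.3), L, 2L)
    if (spec$context_mode == "none") x0[, 2L] <- x0[, 1L]
    C_load <- random_orthonormal(spec$n_neurons, L)
    d <- rnorm(spec$n_neurons, 0, 0.2)
    lds_params(cls, A, B_mot, B_col, x0, C_load, d, inputs)
  })
}

#' Generate a synthetic condition-averaged response tensor
#'
#' Simulates every condition and context of the grid from a ground-truth
#' LDS, adds i.i.d. Gaussian noise on the rate scale, and z-scores each
#' neuron over all times, conditions, and contexts jointly (the z-scoring
#' window assumed throughout).
#'
#' @param gt Ground-truth [lds_params()].
#' @param grid A [make_task_grid()].
#' @param noise_sd Observation noise SD (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical tensors.
#' @param drop_degenerate Drop neurons with zero variance instead of
#'   erroring (a fitted/realistic neuron always varies; degeneracy can only
#'   arise in contrived noiseless settings).
#' @return A `response_tensor`: z-scored `Y[n,t,k,cx]`, the grid, the bin
#'   width, and the per-neuron z-scoring statistics.
#' @export
generate_observations <- function(gt, grid, noise_sd = 0.1, seed = 1L,
                                  drop_degenerate = FALSE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  raw <- reconstruct(gt, grid)
  if (any(!is.finite(raw))) {
    eigs <- unlist(lapply(if (is.list(gt$A)) gt$A else list(gt$A),
                          function(A) Mod(eigen(A, only.values = TRUE)$values)))
    stop(sprintf(
      "overflow: simulated rates are non-finite; largest |eigenvalue| = %.4f",
      max(eigs)))
  }
  with_seed(seed, {
    if (noise_sd > 0) {
      raw <- raw + array(rnorm(length(raw), 0, noise_sd), dim = dim(raw))
    }
  })
  as_response_tensor(raw, grid, drop_degenerate = drop_degenerate)
}

#' Assemble and z-score a response tensor
#'
#' @param Y Raw array `[N, T, K, n_contexts]` of condition-averaged rates.
#' @param grid Matching [make_task_grid()].
#' @param zscore Whether to z-score each neuron over all `(t, k, cx)`.
#' @param drop_degenerate Drop zero-variance neurons instead of erroring.
#' @return A `response_tensor`.
#' @export
as_response_tensor <- function(Y, grid, zscore = TRUE,
                               drop_degenerate = FALSE) {
  stopifnot(length(dim(Y)) == 4L, dim(Y)[3L] == grid$n_conditions)
  if (any(!is.finite(Y))) stop("response tensor contains missing or non-finite entries")
  N <- dim(Y)[1L]
  if (zscore) {
    flat <- matrix(Y, nrow = N)
    mu <- rowMeans(flat)
    sdv <- sqrt(rowMeans((flat - mu)^2))  # population SD over the pooled window
    degen <- sdv == 0
    if (any(degen)) {
      if (!drop_degenerate) {
        stop("degenerate z-scoring: neuron(s) ",
             paste(which(degen), collapse = ", "),
             " have zero variance (set drop_degenerate = TRUE to drop them)")
      }
      Y <- Y[!degen, , , , drop = FALSE]
      flat <- flat[!degen, , drop = FALSE]
      mu <- mu[!degen]; sdv <- sdv[!degen]
      N <- sum(!degen)
    }
    Yz <- array((flat - mu) / sdv, dim = dim(Y))
  } else {
    Yz <- Y
    mu <- rep(0, N); sdv <- rep(1, N)
  }
  structure(
    list(Y = Yz, grid = grid, bin_ms = 50,
         zscore_stats = list(mean = mu, sd = sdv)),
    class = "response_tensor"
  )
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x$Y)
  cat(sprintf("response_tensor: %d neurons x %d bins x %d conditions x %d contexts (z-scored)\n",
              d[1L], d[2L], d[3L], d[4L]))
  invisible(x)
}

#' Undo the per-neuron z-scoring of a response tensor
#'
#' @param data A `response_tensor`.
#' @return Array on the raw rate scale.
#' @export
unzscore <- function(data) {
  stopifnot(inherits(data, "response_tensor"))
  N <- dim(data$Y)[1L]
  flat <- matrix(data$Y, nrow = N)
  array(flat * data$zscore_stats$sd + data$zscore_stats$mean, dim = dim(data$Y))
}
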