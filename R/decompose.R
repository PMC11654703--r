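#' Condition-dependent / condition-independent decomposition
#'
#' Splits a response tensor into its condition-independent component (the
#' across-condition mean per neuron, time, and context — activity common to
#' all conditions, e.g. passage-of-time structure) and the
#' condition-dependent remainder (which late in the trial carries
#' choice-related activity). Also extracts, per time and context, the
#' leading singular vector of the CD neuron-by-condition slice and the
#' normalized CI vector.
#'
#' @param data A `response_tensor` (or plain `[N,T,K,cx]` array).
#' @return A `cdci_decomp`: `CD` (`[N,T,K,cx]`), `CI` (`[N,T,cx]`),
#'   `cd_lead` and `ci_dir` (`[N,T,cx]` unit vectors). `CD + CI`
#'   (broadcast) reconstructs the data exactly, and `CD` averages to zero
#'   across conditions everywhere.
#' @export
cd_ci_decompose <- function(data) {
  Y <- if (inherits(data, "response_tensor")) data$Y else data
  dims <- dim(Y)
  if (dims[3L] < 2L) stop("need at least 2 conditions")
  N <- dims[1L]; Tn <- dims[2L]; K <- dims[3L]; ncx <- dims[4L]
  CI <- apply(Y, c(1L, 2L, 4L), mean)
  CD <- Y - aperm(array(CI, dim = c(N, Tn, ncx, K)), c(1L, 2L, 4L, 3L))
  cd_lead <- array(0, dim = c(N, Tn, ncx))
  ci_dir <- array(0, dim = c(N, Tn, ncx))
  for (cx in seq_len(ncx)) {
    for (t in seq_len(Tn)) {
      slice <- matrix(CD[, t, , cx], N, K)
      cd_lead[, t, cx] <- svd(slice, nu = 1L, nv = 0L)$u[, 1L]
      v <- CI[, t, cx]
      nv <- sqrt(sum(v^2))
      ci_dir[, t, cx] <- if (nv > 0) v / nv else 0
    }
  }
  structure(list(CD = CD, CI = CI, cd_lead = cd_lead, ci_dir = ci_dir),
            class = "cdci_decomp")
}

#' Alignment of a direction with each eigenmode of the dynamics
#'
#' For a real mode the alignment is the absolute dot product with the unit
#' right eigenvector; for a complex-conjugate pair it is the cosine of the
#' minimum subspace angle between the vector and the plane spanned by the
#' real and imaginary parts of the eigenvector (shared by both members).
#' Alignments are reported non-negative, in `[0, 1]`.
#'
#' @param vector Unit direction; in neuron space if `C_load` is supplied
#'   (it is mapped to the latent basis via `C_load'`), otherwise already in
#'   the latent basis of the modes.
#' @param modes An [eigenmodes()] set (from orthonormalized parameters).
#' @param C_load Optional `N x L` orthonormal loading map.
#' @return Numeric vector of per-mode alignments.
#' @export
mode_alignment <- function(vector, modes, C_load = NULL) {
  stopifnot(inherits(modes, "eigenmode_set"))
  v <- as.numeric(vector)
  if (!is.null(C_load)) v <- as.numeric(t(C_load) %*% v)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero vector has no alignment")
  v <- v / nv
  out <- numeric(length(modes$values))
  for (pid in unique(modes$pair_id)) {
    members <- which(modes$pair_id == pid)
    r <- modes$R_eig[, members[1L]]
    if (length(members) == 1L) {
      rr <- Re(r)
      a <- abs(sum(v * rr)) / sqrt(sum(rr^2))
    } else {
      basis <- qr.Q(qr(cbind(Re(r), Im(r))))
      a <- sqrt(sum((t(basis) %*% v)^2))   # cos of min principal angle
    }
    out[members] <- min(a, 1)
  }
  out
}

#' Demixed coherence / coherence-magnitude input plane
#'
#' Regresses the per-coherence input vectors on the signed coherence, its
#' magnitude, and an intercept, then orthonormalizes the two coefficient
#' vectors (coherence direction first). Projections of the coherence inputs
#' onto this plane display the curved (signed + magnitude) layout of the
#' inferred input manifold. If the magnitude coefficient is (numerically)
#' contained in the coherence direction the plane collapses to 1D and is
#' flagged.
#'
#' @param input_vectors `L x n_levels` matrix, one input vector per signed
#'   coherence level (e.g. `B u` at a fixed time).
#' @param coherences Signed coherence values, one per column.
#' @param tol Relative tolerance for the collapse test.
#' @return List with `basis` (`L x 2`, or `L x 1` when collapsed),
#'   `collapsed` flag, raw regression `coefficients` (coh, |coh|,
#'   intercept), and `projections` of the inputs onto the basis.
#' @export
demix_input_plane <- function(input_vectors, coherences, tol = 1e-6) {
  V <- as.matrix(input_vectors)
  coherences <- as.numeric(coherences)
  stopifnot(ncol(V) == length(coherences))
  if (length(unique(coherences)) < 4L) {
    stop("degenerate plane: need at least 4 distinct coherence levels")
  }
  X <- rbind(coh = coherences, abs_coh = abs(coherences), intercept = 1)
  XXt <- X %*% t(X)
  if (rcond(XXt) < 1e-12) {
    stop("degenerate plane: coherence regressors are rank deficient (a single strength level?)")
  }
  W <- V %*% t(X) %*% solve(XXt)        # L x 3 coefficient vectors
  w_coh <- W[, 1L]; w_abs <- W[, 2L]
  n1 <- sqrt(sum(w_coh^2))
  if (n1 == 0) stop("degenerate plane: no coherence-dependent input component")
  q1 <- w_coh / n1
  resid <- w_abs - sum(w_abs * q1) * q1
  nr <- sqrt(sum(resid^2))
  collapsed <- nr <= tol * max(sqrt(sum(w_abs^2)), n1)
  basis <- if (collapsed) matrix(q1, ncol = 1L) else cbind(q1, resid / nr)
  colnames(basis) <- c("coh", "abs_coh")[seq_len(ncol(basis))]
  list(basis = basis, collapsed = collapsed, coefficients = W,
       projections = t(basis) %*% V)
}

#' Input-norm and output-norm traces per modality and context
#'
#' Input strength is `||B_cx u(t)||` per signed coherence level; output
#' strength is the latent norm `||x(t)||` simulated from each modality's
#' input alone (the other modality zeroed). With
#' `subtract_condition_mean = TRUE` (matching how coherence-specific
#' structure is isolated, since condition-independent activity can be
#' carried by either initial conditions or inputs) the across-level mean
#' trace is removed before taking norms.
#'
#' @param params An [lds_params()] set.
#' @param grid Task grid.
#' @param subtract_condition_mean Remove the across-level mean vector at
#'   each time before computing norms.
#' @return List of arrays `input` and `output`, each
#'   `[n_levels, T, modality, context]` with dimnames.
#' @export
summary_norms <- function(params, grid, subtract_condition_mean = TRUE) {
  Tn <- nrow(params$inputs$motion$course_in)
  nl <- grid$n_levels
  dims <- c(nl, Tn, 2L, 2L)
  dn <- list(level = format(grid$motion_levels), time = NULL,
             modality = c("motion", "color"), context = grid$contexts)
  inp <- array(0, dim = dims, dimnames = dn)
  outp <- array(0, dim = dims, dimnames = dn)
  L <- params$class_spec$latent_dim
  for (mi in 1:2) {
    modality <- c("motion", "color")[mi]
    for (cx in 1:2) {
      A <- ctx_mat(params$A, cx)
      bu <- array(0, dim = c(L, Tn, nl))
      for (lev in seq_len(nl)) {
        bu[, , lev] <- coherence_input_series(params, grid, modality, cx, lev)
      }
      x <- array(0, dim = c(L, Tn, nl))
      for (lev in seq_len(nl)) {
        xt <- params$x0[, cx]
        for (t in seq_len(Tn)) {
          xt <- A %*% xt + bu[, t, lev]
          x[, t, lev] <- xt
        }
      }
      if (subtract_condition_mean) {
        bu <- bu - as.numeric(apply(bu, c(1L, 2L), mean))
        x <- x - as.numeric(apply(x, c(1L, 2L), mean))
      }
      inp[, , mi, cx] <- t(sqrt(apply(bu^2, c(2L, 3L), sum)))
      outp[, , mi, cx] <- t(sqrt(apply(x^2, c(2L, 3L), sum)))
    }
  }
  list(input = inp, output = outp)
}

#' Two-sided rank-sum comparison of two model-summary samples
#'
#' Wilcoxon rank sum test of equal medians, as used to compare relevant
#' versus irrelevant input/output summaries across fitted models.
#'
#' @param a,b Numeric samples (e.g. one scalar summary per fitted model).
#' @return The p-value of the two-sided test.
#' @export
ranksum_compare <- function(a, b) {
  stats::wilcox.test(a, b, exact = FALSE)$p.value
}
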