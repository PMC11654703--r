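#' Observability Gramian and most-amplifying modes
#'
#' Solves the discrete-time Lyapunov equation `A' Q A - Q + C' C = 0` for a
#' stable dynamics matrix (spectral radius < 1) via the Kronecker
#' vectorization of `Q = A' Q A + C' C`. The eigenvectors of `Q` with the
#' largest eigenvalues are the most-amplifying state directions for the
#' readout.
#'
#' @param A Square dynamics matrix with spectral radius < 1.
#' @param C_load Observation/loading matrix (columns match `A`).
#' @return A `gramian_result`: symmetric positive-semidefinite `Q`, its
#'   eigenvalues and eigenvectors (most amplifying first), and the
#'   Frobenius residual of the Lyapunov equation.
#' @export
observability_gramian <- function(A, C_load) {
  A <- as.matrix(A)
  C_load <- as.matrix(C_load)
  L <- nrow(A)
  stopifnot(ncol(A) == L, ncol(C_load) == L)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1) {
    stop(sprintf("unstable dynamics: spectral radius %.6f >= 1; the observability Gramian is undefined", rho))
  }
  CtC <- crossprod(C_load)
  M <- diag(L^2) - kronecker(t(A), t(A))
  Q <- matrix(solve(M, as.numeric(CtC)), L, L)
  Q <- (Q + t(Q)) / 2
  resid <- norm(t(A) %*% Q %*% A - Q + CtC, "F")
  e <- eigen(Q, symmetric = TRUE)
  structure(
    list(Q = Q, eigenvalues = e$values, modes = e$vectors,
         residual = resid, spectral_radius = rho),
    class = "gramian_result"
  )
}

#' @export
print.gramian_result <- function(x, ...) {
  cat(sprintf("observability Gramian: top amplification %.3f, Lyapunov residual %.2e\n",
              x$eigenvalues[1L], x$residual))
  invisible(x)
}

#' Controllability of an input-driven linear system
#'
#' Rank of the controllability block matrix `[B, AB, ..., A^(L-1) B]`; the
#' system is fully controllable when the rank equals the latent dimension.
#'
#' @param A `L x L` dynamics matrix.
#' @param B `L x U` input matrix.
#' @return List with `rank`, `latent_dim`, and logical `controllable`.
#' @export
controllability_check <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  L <- nrow(A)
  blocks <- vector("list", L)
  blocks[[1L]] <- B
  for (i in seq_len(L - 1L)) blocks[[i + 1L]] <- A %*% blocks[[i]]
  ctrb <- do.call(cbind, blocks)
  r <- qr(ctrb)$rank
  list(rank = r, latent_dim = L, controllable = r == L)
}
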