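#' Decay time constant of a discrete-time eigenmode
#'
#' With 50-ms bins, a mode of norm `|lambda|` decays to `1/e` of its
#' initial amplitude after `tau = bin_ms / (-log|lambda|)` milliseconds.
#' A norm of exactly 1 is an integration mode (`tau = Inf`); norms above 1
#' give a negative value, the signed growth constant of an expanding mode.
#'
#' @param eig_norm Eigenvalue norm(s), > 0.
#' @param bin_ms Bin width in milliseconds.
#' @return Time constant(s) in ms (no rounding; round only for display).
#' @examples
#' time_constant(0.8)  # ~224 ms
#' @export
time_constant <- function(eig_norm, bin_ms = 50) {
  if (any(eig_norm <= 0)) stop("domain error: eigenvalue norm must be > 0")
  ifelse(eig_norm == 1, Inf, bin_ms / (-log(eig_norm)))
}

#' Rotation frequency of a discrete-time eigenmode
#'
#' The phase `omega = atan2(|Im lambda|, Re lambda)` of the
#' positive-imaginary member of a conjugate pair gives the per-bin rotation
#' angle; at `bin_hz` bins per second the frequency is
#' `f = bin_hz * omega / (2 pi)` Hz. Real positive eigenvalues rotate at 0
#' Hz; real negative eigenvalues alternate sign every bin, i.e. rotate at
#' the Nyquist frequency `bin_hz / 2`.
#'
#' @param lambda Complex (or numeric) eigenvalue(s), nonzero.
#' @param bin_hz Sampling rate in bins per second (20 for 50-ms bins).
#' @return Frequency(ies) in Hz.
#' @export
rotation_frequency <- function(lambda, bin_hz = 20) {
  lambda <- as.complex(lambda)
  if (any(lambda == 0)) stop("rotation frequency undefined for lambda = 0")
  omega <- atan2(abs(Im(lambda)), Re(lambda))
  bin_hz * omega / (2 * pi)
}

#' Henrici index of non-normality
#'
#' `sqrt(||A||_F^2 - sum |lambda_i|^2) / ||A||_F`, clipped to `[0, 1]`
#' against roundoff; 0 iff `A` is normal, 1 for maximally non-normal
#' matrices (e.g. nilpotent upper-triangular).
#'
#' @param A Nonzero square matrix.
#' @return Scalar in `[0, 1]`.
#' @export
henrici_index <- function(A) {
  A <- as.matrix(A)
  fro2 <- sum(A^2)
  if (fro2 == 0) stop("Henrici index undefined for the zero matrix")
  ev <- eigen(A, only.values = TRUE)$values
  h2 <- (fro2 - sum(Mod(ev)^2)) / fro2
  sqrt(min(max(h2, 0), 1))
}

#' Eigenmode decomposition of a dynamics matrix
#'
#' Computes paired eigenvalues with unit-norm right eigenvectors (columns
#' of `R_eig`) and left eigenvectors taken as the rows of `R_eig^-1` (not
#' independently normalized, so `L_eig %*% R_eig = I` and input loads are
#' non-normalized projections). Modes are ordered by descending eigenvalue
#' norm, ties broken by descending rotation frequency then by the sign of
#' the imaginary part (positive first); conjugate pairs are adjacent and
#' share decay time constant and rotation frequency. A mode is flagged slow
#' when `|lambda| > 0.8` (decay time constant above ~224 ms).
#'
#' @param A Square dynamics matrix, diagonalizable within tolerance.
#' @param bin_ms Bin width in ms (sets the time-constant scale).
#' @return An `eigenmode_set`: `values`, `norms`, `R_eig`, `L_eig`,
#'   `pair_id`, `tau_ms`, `freq_hz`, `slow`, `cond_R`.
#' @export
eigenmodes <- function(A, bin_ms = 50) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  e <- eigen(A)
  e$values <- as.complex(e$values)
  safe_freq <- function(v) {
    out <- rep(NA_real_, length(v))
    nz <- v != 0
    out[nz] <- rotation_frequency(v[nz], bin_hz = 1000 / bin_ms)
    out
  }
  freq <- safe_freq(e$values)
  # order: descending |lambda|, then descending frequency, then +Im first
  ord <- order(-Mod(e$values), -freq, -sign(Im(e$values)))
  values <- e$values[ord]
  R_eig <- e$vectors[, ord, drop = FALSE]
  sv <- svd(R_eig)$d
  cond_R <- max(sv) / min(sv)
  if (cond_R > 1e8) {
    stop(sprintf("near-defective dynamics matrix: eigenvector condition number %.3g", cond_R))
  }
  if (cond_R > 1e6) {
    warning(sprintf("dynamics matrix is close to non-diagonalizable (eigenvector condition number %.3g); mode analyses may be inaccurate", cond_R))
  }
  L_eig <- solve(R_eig)
  norms <- Mod(values)
  # conjugate-pair bookkeeping
  pair_id <- integer(length(values))
  pid <- 0L
  for (i in seq_along(values)) {
    if (pair_id[i] != 0L) next
    pid <- pid + 1L
    pair_id[i] <- pid
    if (abs(Im(values[i])) > 1e-12) {
      j <- which(pair_id == 0L & abs(values - Conj(values[i])) < 1e-8)[1L]
      if (!is.na(j)) pair_id[j] <- pid
    }
  }
  tau <- vapply(norms, function(n) {
    if (n == 0) NA_real_
    else if (abs(n - 1) < 1e-12) Inf
    else bin_ms / (-log(n))
  }, numeric(1L))
  structure(
    list(values = values, norms = norms, R_eig = R_eig, L_eig = L_eig,
         pair_id = pair_id, tau_ms = tau,
         freq_hz = safe_freq(values),
         slow = norms > 0.8, cond_R = cond_R, bin_ms = bin_ms, A = A),
    class = "eigenmode_set"
  )
}

#' @export
print.eigenmode_set <- function(x, ...) {
  cat(sprintf("eigenmode_set: %d modes, %d slow (|lambda| > 0.8), Henrici %.3f\n",
              length(x$values), sum(x$slow), henrici_index(x$A)))
  invisible(x)
}

#' Input loads onto the eigenmodes of the dynamics
#'
#' The load of an input vector `Bu(t)` onto a real mode is the magnitude of
#' its non-normalized projection onto the left eigenvector,
#' `|l_l' Bu(t)|`; a conjugate pair shares the single load
#' `2 ||Re(l') Bu Re(r) - Im(l') Bu Im(r)||`. Summing the per-mode (real)
#' and per-pair (complex) input contributions reconstructs `Bu(t)` exactly,
#' because the left eigenvectors are rows of `R_eig^-1`.
#'
#' @param modes An [eigenmodes()] set.
#' @param input_series `L x T` matrix of input vectors `B u(t)` expressed in
#'   the same latent basis as the dynamics matrix (use orthonormalized
#'   parameters throughout).
#' @return An `input_loads` object: `load_trace` (`n_modes x T`, pair
#'   members share a row value), `load_mean` (time average), and per-group
#'   contribution arrays whose sum equals the input series.
#' @export
input_loads <- function(modes, input_series) {
  stopifnot(inherits(modes, "eigenmode_set"))
  input_series <- as.matrix(input_series)
  L <- nrow(modes$R_eig)
  if (nrow(input_series) != L) {
    stop("basis error: input series dimension does not match the latent dimension of the modes")
  }
  Tn <- ncol(input_series)
  nm <- length(modes$values)
  alpha <- modes$L_eig %*% input_series          # n_modes x T, complex
  load_trace <- matrix(0, nm, Tn)
  groups <- list()
  for (pid in unique(modes$pair_id)) {
    members <- which(modes$pair_id == pid)
    l1 <- members[1L]
    r <- modes$R_eig[, l1]
    a <- alpha[l1, ]
    if (length(members) == 1L) {
      contrib <- outer(Re(r), Re(a))             # alpha real for real modes
      load <- abs(Re(a))
    } else {
      contrib <- 2 * (outer(Re(r), Re(a)) - outer(Im(r), Im(a)))
      load <- sqrt(colSums(contrib^2))           # norm of the pair vector
    }
    load_trace[members, ] <- matrix(load, length(members), Tn, byrow = TRUE)
    groups[[length(groups) + 1L]] <- list(members = members,
                                          contribution = contrib)
  }
  structure(
    list(load_trace = load_trace, load_mean = rowMeans(load_trace),
         groups = groups, modes = modes, input_series = input_series),
    class = "input_loads"
  )
}

#' Sum of per-mode input contributions
#'
#' @param loads An [input_loads()] object.
#' @return `L x T` matrix; equals the original input series to numerical
#'   precision (the load-reconstruction identity).
#' @export
load_reconstruction <- function(loads) {
  Reduce(`+`, lapply(loads$groups, function(g) g$contribution))
}

#' Input vector series of one coherence level in latent space
#'
#' Convenience for load analyses: `B_cx u(t)` for a single signed coherence
#' level of one modality (default the strongest positive coherence).
#'
#' @param params Orthonormalized [lds_params()].
#' @param grid Task grid.
#' @param modality `"motion"` or `"color"`.
#' @param context Context index.
#' @param level Signed level index (default the largest positive level).
#' @return `L x T` matrix of input vectors.
#' @export
coherence_input_series <- function(params, grid,
                                   modality = c("motion", "color"),
                                   context = 1L, level = grid$n_levels) {
  modality <- match.arg(modality)
  m <- params$inputs[[modality]]
  B <- ctx_mat(if (modality == "motion") params$B_mot else params$B_col,
               context)
  lev_val <- grid[[paste0(modality, "_levels")]][level]
  course <- if (lev_val > 0) m$course_in else m$course_out
  u <- t(course) * m$scalars[level, ]            # U x T
  B %*% u
}

#' Impulse response norms of a linear dynamics matrix
#'
#' Simulates `x(0) = v`, `x(t) = A x(t-1)` for each (unit-normalized)
#' direction and returns the state-norm traces `||x(t)||` — the signature
#' of transient amplification when a trace rises above 1 before decaying.
#'
#' @param A Square dynamics matrix.
#' @param directions `L x m` matrix of perturbation directions (normalized
#'   internally).
#' @param horizon Number of steps.
#' @return List with `norms` (`(horizon+1) x m`, row 1 is `t = 0`) and
#'   `mean` (average trace over directions).
#' @export
impulse_response <- function(A, directions, horizon = 15L) {
  A <- as.matrix(A)
  V <- as.matrix(directions)
  nrm <- sqrt(colSums(V^2))
  if (any(nrm == 0)) stop("zero perturbation direction")
  V <- sweep(V, 2L, nrm, "/")
  out <- matrix(0, horizon + 1L, ncol(V))
  out[1L, ] <- 1
  X <- V
  for (t in seq_len(horizon)) {
    X <- A %*% X
    out[t + 1L, ] <- sqrt(colSums(X^2))
  }
  list(norms = out, mean = rowMeans(out))
}

#' Random unit directions on the latent sphere
#'
#' @param latent_dim Dimension.
#' @param n Number of directions (default `latent_dim`, matching the count
#'   of left eigenvectors used for comparison traces).
#' @param seed Seed.
#' @return `latent_dim x n` matrix of unit columns.
#' @export
random_directions <- function(latent_dim, n = latent_dim, seed = 1L) {
  with_seed(seed, {
    V <- matrix(rnorm(latent_dim * n), latent_dim, n)
    sweep(V, 2L, sqrt(colSums(V^2)), "/")
  })
}

#' Normalized real parts of the left eigenvectors
#'
#' Perturbation directions aligned with how inputs couple into each mode.
#'
#' @param modes An [eigenmodes()] set.
#' @return `L x n_modes` matrix of unit columns.
#' @export
left_eigvec_directions <- function(modes) {
  V <- Re(t(modes$L_eig))
  sweep(V, 2L, sqrt(colSums(V^2)), "/")
}
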