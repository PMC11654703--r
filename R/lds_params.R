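#' Parameter set of a constrained linear dynamical system
#'
#' Bundles the full parameter set Theta = (A, B_mot, B_col, x0, C_load, d,
#' inputs) with the context tags of its model class. Parameters that the
#' class shares across contexts are stored once (a plain matrix); parameters
#' freed per context are stored as a two-element list ordered like the grid
#' contexts (motion context first).
#'
#' @param class_spec An [lds_class()] specification.
#' @param A Dynamics matrix `L x L`, or list of two when the class has
#'   context-dependent dynamics.
#' @param B_mot,B_col Input subspaces `L x U_m` / `L x U_c`, or lists of two
#'   when the class has context-dependent inputs.
#' @param x0 `L x 2` matrix of per-context initial conditions.
#' @param C_load `N x L` loading map (orthonormal columns after
#'   [orthonormalize()]).
#' @param d Length-`N` bias.
#' @param inputs An [input_model()].
#' @return An `lds_params` object.
#' @export
lds_params <- function(class_spec, A, B_mot, B_col, x0, C_load, d, inputs) {
  stopifnot(inherits(class_spec, "lds_class"), inherits(inputs, "input_model"))
  L <- class_spec$latent_dim
  x0 <- as.matrix(x0)
  C_load <- as.matrix(C_load)

  check_slot <- function(x, per_cx, nr, nc, name) {
    if (per_cx) {
      if (!is.list(x) || length(x) != 2L) {
        stop(name, " must be a list of two per-context matrices for class ",
             class_spec$label)
      }
      lapply(x, function(m) {
        m <- as.matrix(m)
        if (!all(dim(m) == c(nr, nc))) stop("dimension mismatch in ", name)
        m
      })
    } else {
      if (is.list(x)) stop(name, " is shared in class ", class_spec$label,
                           "; store it once, not per context")
      x <- as.matrix(x)
      if (!all(dim(x) == c(nr, nc))) stop("dimension mismatch in ", name)
      x
    }
  }
  A <- check_slot(A, class_spec$dynamics_cx, L, L, "A")
  B_mot <- check_slot(B_mot, class_spec$inputs_cx, L,
                      class_spec$input_dim_motion, "B_mot")
  B_col <- check_slot(B_col, class_spec$inputs_cx, L,
                      class_spec$input_dim_color, "B_col")
  if (!all(dim(x0) == c(L, 2L))) stop("x0 must be L x 2 (one column per context)")
  if (ncol(C_load) != L) stop("C_load must have L columns")
  if (length(d) != nrow(C_load)) stop("d must have one entry per neuron")
  if (ncol(inputs$motion$course_in) != class_spec$input_dim_motion ||
      ncol(inputs$color$course_in) != class_spec$input_dim_color) {
    stop("input model dimensionality does not match the class specification")
  }
  structure(
    list(class_spec = class_spec, A = A, B_mot = B_mot, B_col = B_col,
         x0 = x0, C_load = C_load, d = as.numeric(d), inputs = inputs),
    class = "lds_params"
  )
}

#' @export
print.lds_params <- function(x, ...) {
  cat(sprintf("lds_params %s: N=%d neurons, L=%d latents, inputs %d+%d\n",
              x$class_spec$label, nrow(x$C_load), x$class_spec$latent_dim,
              x$class_spec$input_dim_motion, x$class_spec$input_dim_color))
  invisible(x)
}

n_neurons <- function(params) nrow(params$C_load)

# ---- flat parameter vector layout (shared with the C++ gradient engine) ----
# Order: A | B_mot | B_col | x0 | C | d | courses (m_in, m_out, c_in, c_out,
# only when time-varying) | scal_m | scal_c. Matrices are column-major.
theta_layout <- function(class_spec, n_neurons, n_bins, n_levels = 6L) {
  L <- class_spec$latent_dim
  Um <- class_spec$input_dim_motion
  Uc <- class_spec$input_dim_color
  nA <- if (class_spec$dynamics_cx) 2L else 1L
  nB <- if (class_spec$inputs_cx) 2L else 1L
  sizes <- c(
    A = nA * L * L,
    B_mot = nB * L * Um,
    B_col = nB * L * Uc,
    x0 = 2L * L,
    C = n_neurons * L,
    d = n_neurons,
    courses = if (class_spec$time_varying) 2L * n_bins * (Um + Uc) else 0L,
    scal = n_levels * (Um + Uc)
  )
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  list(sizes = sizes, starts = starts, ends = ends, total = sum(sizes),
       L = L, Um = Um, Uc = Uc, nA = nA, nB = nB,
       n_neurons = n_neurons, n_bins = n_bins, n_levels = n_levels)
}

pack_params <- function(params, n_levels = nrow(params$inputs$motion$scalars)) {
  cs <- params$class_spec
  lay <- theta_layout(cs, n_neurons(params), nrow(params$inputs$motion$course_in),
                      n_levels)
  grab <- function(x) if (is.list(x)) unlist(lapply(x, as.numeric)) else as.numeric(x)
  courses <- if (cs$time_varying) {
    c(as.numeric(params$inputs$motion$course_in),
      as.numeric(params$inputs$motion$course_out),
      as.numeric(params$inputs$color$course_in),
      as.numeric(params$inputs$color$course_out))
  } else {
    numeric(0L)
  }
  theta <- c(grab(params$A), grab(params$B_mot), grab(params$B_col),
             as.numeric(params$x0), as.numeric(params$C_load), params$d,
             courses,
             as.numeric(params$inputs$motion$scalars),
             as.numeric(params$inputs$color$scalars))
  stopifnot(length(theta) == lay$total)
  theta
}

unpack_params <- function(theta, class_spec, n_neurons, n_bins, n_levels = 6L) {
  lay <- theta_layout(class_spec, n_neurons, n_bins, n_levels)
  stopifnot(length(theta) == lay$total)
  L <- lay$L; Um <- lay$Um; Uc <- lay$Uc
  take <- function(name) theta[lay$starts[[name]]:lay$ends[[name]]]
  split_cx <- function(v, nr, nc, per_cx) {
    if (per_cx) {
      n <- nr * nc
      list(matrix(v[seq_len(n)], nr, nc), matrix(v[n + seq_len(n)], nr, nc))
    } else {
      matrix(v, nr, nc)
    }
  }
  A <- split_cx(take("A"), L, L, class_spec$dynamics_cx)
  B_mot <- split_cx(take("B_mot"), L, Um, class_spec$inputs_cx)
  B_col <- split_cx(take("B_col"), L, Uc, class_spec$inputs_cx)
  x0 <- matrix(take("x0"), L, 2L)
  C_load <- matrix(take("C"), n_neurons, L)
  d <- take("d")
  if (class_spec$time_varying) {
    cr <- take("courses")
    nTm <- n_bins * Um; nTc <- n_bins * Uc
    cm_in <- matrix(cr[seq_len(nTm)], n_bins, Um)
    cm_out <- matrix(cr[nTm + seq_len(nTm)], n_bins, Um)
    cc_in <- matrix(cr[2L * nTm + seq_len(nTc)], n_bins, Uc)
    cc_out <- matrix(cr[2L * nTm + nTc + seq_len(nTc)], n_bins, Uc)
  } else {
    cm_in <- cm_out <- matrix(1, n_bins, Um)
    cc_in <- cc_out <- matrix(1, n_bins, Uc)
  }
  sc <- take("scal")
  scal_m <- matrix(sc[seq_len(n_levels * Um)], n_levels, Um)
  scal_c <- matrix(sc[n_levels * Um + seq_len(n_levels * Uc)], n_levels, Uc)
  inputs <- input_model(cm_in, cm_out, cc_in, cc_out, scal_m, scal_c,
                        time_varying = class_spec$time_varying)
  lds_params(class_spec, A, B_mot, B_col, x0, C_load, d, inputs)
}
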