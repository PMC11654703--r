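#' Define a constrained LDS model class
#'
#' The four model classes differ in which parameters may vary across the two
#' task contexts. In `{A,B}` everything but the initial condition is shared;
#' `{A,Bcx}` frees the motion/color input subspaces per context; `{Acx,B}`
#' frees the recurrent dynamics matrix; `{Acx,Bcx}` frees both. Initial
#' conditions `x0` are always learned per context, while the loading map,
#' bias, and external input time courses/scalars are always shared.
#'
#' @param label Class label, one of `"A,B"`, `"A,Bcx"`, `"Acx,B"`,
#'   `"Acx,Bcx"` (braces and whitespace are tolerated).
#' @param latent_dim Latent dimensionality L.
#' @param input_dims Integer vector `c(motion, color)` of input-subspace
#'   dimensionalities.
#' @param time_varying If `TRUE`, one free time course per input dimension
#'   and direction is learned; if `FALSE` the courses are fixed at 1 and the
#'   inputs are constant in time.
#'
#' @return An `lds_class` specification object.
#' @examples
#' lds_class("A,Bcx", latent_dim = 18, input_dims = c(3, 3))
#' @export
lds_class <- function(label, latent_dim, input_dims = c(3L, 3L),
                      time_varying = TRUE) {
  canon <- gsub("[{} ]", "", label)
  valid <- c("A,B", "A,Bcx", "Acx,B", "Acx,Bcx")
  if (!canon %in% valid) {
    stop("unknown model class label: ", label,
         " (expected one of ", paste(valid, collapse = ", "), ")")
  }
  if (length(input_dims) == 1L) input_dims <- rep(input_dims, 2L)
  stopifnot(latent_dim >= 1, all(input_dims >= 0), length(input_dims) == 2L)
  structure(
    list(
      label = paste0("{", canon, "}"),
      dynamics_cx = grepl("Acx", canon),
      inputs_cx = grepl("Bcx", canon),
      time_varying = isTRUE(time_varying),
      latent_dim = as.integer(latent_dim),
      input_dim_motion = as.integer(input_dims[1L]),
      input_dim_color = as.integer(input_dims[2L])
    ),
    class = "lds_class"
  )
}

#' @export
print.lds_class <- function(x, ...) {
  cat(sprintf("LDS class %s: latent %d, inputs %d+%d, %s inputs\n",
              x$label, x$latent_dim, x$input_dim_motion, x$input_dim_color,
              if (x$time_varying) "time-varying" else "time-constant"))
  invisible(x)
}

#' Exact learnable-parameter count of an LDS model class
#'
#' Counts every learnable slot: the dynamics matrix (L^2, doubled when
#' per-context), the input subspaces (L x U, doubled when per-context), the
#' shared loading map (N x L), the bias (N), the per-context initial
#' conditions (2L), and the external input parameters. Each input dimension
#' contributes two direction time courses of length T (when time-varying)
#' plus 6 coherence scalars, one per signed coherence level of the standard
#' six-level task.
#'
#' @param class_spec An [lds_class()] specification.
#' @param n_neurons Number of neurons N.
#' @param n_bins Number of time bins T.
#' @return Integer parameter count.
#' @examples
#' count_parameters(lds_class("A,Bcx", 18, c(3, 3)), n_neurons = 727, n_bins = 15)
#' @export
count_parameters <- function(class_spec, n_neurons, n_bins) {
  stopifnot(inherits(class_spec, "lds_class"))
  L <- class_spec$latent_dim
  U <- class_spec$input_dim_motion + class_spec$input_dim_color
  n_A <- if (class_spec$dynamics_cx) 2L else 1L
  n_B <- if (class_spec$inputs_cx) 2L else 1L
  per_dim_inputs <- (if (class_spec$time_varying) 2L * n_bins else 0L) + 6L
  as.integer(
    n_A * L^2 +             # recurrent dynamics
    n_B * L * U +           # input subspaces
    n_neurons * L +         # loading map
    n_neurons +             # bias
    2L * L +                # per-context initial conditions
    U * per_dim_inputs      # direction courses + coherence scalars
  )
}

#' Number of fitted data points in a condition-averaged response tensor
#'
#' @param n_neurons,n_bins,n_conditions,n_contexts Tensor dimensions.
#' @return Integer count `N * T * K * n_contexts`.
#' @export
count_data_points <- function(n_neurons, n_bins, n_conditions, n_contexts = 2L) {
  as.integer(n_neurons) * as.integer(n_bins) *
    as.integer(n_conditions) * as.integer(n_contexts)
}
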