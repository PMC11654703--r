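#' External input model shared across task conditions
#'
#' Each input dimension of a modality carries one learned time course per
#' evidence direction (positive/in-RF and negative/out-RF) and one scalar
#' per signed coherence level. The input of condition `k` along dimension
#' `j` at time `t` is `course[dir(k)][t, j] * scalars[level(k), j]`: a
#' single course is shared by all coherences of the same direction, and a
#' coherence level's input is shared by every condition containing that
#' level. With `time_varying = FALSE` all courses are identically 1 and the
#' inputs are constant over the trial.
#'
#' @param course_motion_in,course_motion_out `T x U_m` matrices of direction
#'   time courses for the motion modality.
#' @param course_color_in,course_color_out Same for the color modality.
#' @param scal_motion,scal_color `n_levels x U` matrices of coherence
#'   scalars; row i corresponds to the i-th signed level of the grid
#'   (ascending order).
#' @param time_varying Flag; when `FALSE` the courses must be all-ones.
#' @return An `input_model` object.
#' @export
input_model <- function(course_motion_in, course_motion_out,
                        course_color_in, course_color_out,
                        scal_motion, scal_color, time_varying = TRUE) {
  course_motion_in <- as.matrix(course_motion_in)
  course_motion_out <- as.matrix(course_motion_out)
  course_color_in <- as.matrix(course_color_in)
  course_color_out <- as.matrix(course_color_out)
  scal_motion <- as.matrix(scal_motion)
  scal_color <- as.matrix(scal_color)
  stopifnot(
    identical(dim(course_motion_in), dim(course_motion_out)),
    identical(dim(course_color_in), dim(course_color_out)),
    nrow(course_motion_in) == nrow(course_color_in),
    ncol(scal_motion) == ncol(course_motion_in),
    ncol(scal_color) == ncol(course_color_in),
    nrow(scal_motion) == nrow(scal_color)
  )
  if (!time_varying) {
    courses <- list(course_motion_in, course_motion_out,
                    course_color_in, course_color_out)
    if (!all(vapply(courses, function(m) all(m == 1), logical(1L)))) {
      stop("time_varying = FALSE requires all direction courses to equal 1")
    }
  }
  structure(
    list(
      motion = list(course_in = course_motion_in, course_out = course_motion_out,
                    scalars = scal_motion),
      color = list(course_in = course_color_in, course_out = course_color_out,
                   scalars = scal_color),
      time_varying = isTRUE(time_varying)
    ),
    class = "input_model"
  )
}

# Constant-in-time input model whose per-condition input equals the signed
# coherence level along every dimension scaled by `gain`.
constant_input_model <- function(n_bins, input_dims, levels, gain = 1) {
  ones_m <- matrix(1, n_bins, input_dims[1L])
  ones_c <- matrix(1, n_bins, input_dims[2L])
  input_model(ones_m, ones_m, ones_c, ones_c,
              scal_motion = matrix(levels * gain, length(levels), input_dims[1L]),
              scal_color = matrix(levels * gain, length(levels), input_dims[2L]),
              time_varying = FALSE)
}

#' Input coordinate series for every condition of a grid
#'
#' @param inputs An [input_model()].
#' @param grid A [make_task_grid()] grid.
#' @param modality `"motion"` or `"color"`.
#' @return Array `[U, T, K]` of input coordinates `u(t)` per condition.
#' @export
input_series <- function(inputs, grid, modality = c("motion", "color")) {
  modality <- match.arg(modality)
  m <- inputs[[modality]]
  Tn <- nrow(m$course_in)
  U <- ncol(m$course_in)
  if (nrow(m$scalars) != grid$n_levels) {
    stop("input model has ", nrow(m$scalars), " scalar rows but grid has ",
         grid$n_levels, " signed levels")
  }
  cond <- grid$conditions
  lev <- cond[[paste0(modality, "_idx")]]
  dir <- cond[[paste0(modality, "_dir")]]
  out <- array(0, dim = c(U, Tn, grid$n_conditions))
  for (k in seq_len(grid$n_conditions)) {
    course <- if (dir[k] == 1L) m$course_in else m$course_out
    # u_j(t) = course[t, j] * scalar[level, j]
    out[, , k] <- t(course) * m$scalars[lev[k], ]
  }
  out
}
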