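#' Build the coherence grid of a two-modality evidence task
#'
#' Constructs the task structure of a contextual random-dots experiment:
#' each trial presents a motion coherence and a color coherence drawn from
#' the same set of signed levels (three strengths by two directions in the
#' standard task), and every (motion, color) pairing defines one task
#' condition. The same conditions are presented under two contexts
#' ("attend motion" / "attend color").
#'
#' @param n_strengths Number of coherence strength levels per direction
#'   (3 in the standard task, giving 6 signed levels and 36 conditions).
#' @param strength_values Positive coherence values, one per strength level.
#'   Defaults to `c(0.05, 0.15, 0.5)` for the three-strength task, the
#'   typical range used in random-dots experiments.
#'
#' @return A `task_grid` object: signed coherence levels per modality
#'   (mirrored about zero, ascending), a `conditions` data frame with one
#'   row per condition (signed level, level index, direction index per
#'   modality), and the ordered context labels.
#'
#' @examples
#' grid <- make_task_grid()
#' grid$n_conditions  # 36
#' @export
make_task_grid <- function(n_strengths = 3, strength_values = NULL) {
  if (length(n_strengths) != 1L || n_strengths < 1) {
    stop("invalid grid: n_strengths must be a single value >= 1")
  }
  n_strengths <- as.integer(n_strengths)
  if (is.null(strength_values)) {
    strength_values <- if (n_strengths <= 3) {
      c(0.05, 0.15, 0.5)[seq_len(n_strengths)]
    } else {
      seq_len(n_strengths) / n_strengths
    }
  }
  if (length(strength_values) != n_strengths) {
    stop("invalid grid: need one strength value per strength level")
  }
  if (any(strength_values <= 0)) {
    stop("invalid grid: strength values must be positive (given for the positive direction)")
  }
  if (anyDuplicated(strength_values)) {
    stop("invalid grid: duplicate strength values")
  }
  levels <- sort(c(-strength_values, strength_values))
  conditions <- expand.grid(motion = levels, color = levels,
                            KEEP.OUT.ATTRS = FALSE)
  conditions <- conditions[order(conditions$motion, conditions$color), ]
  rownames(conditions) <- NULL
  conditions$k <- seq_len(nrow(conditions))
  conditions$motion_idx <- match(conditions$motion, levels)
  conditions$color_idx <- match(conditions$color, levels)
  # direction 1 = positive/in-RF evidence, 2 = negative/out-RF evidence
  conditions$motion_dir <- ifelse(conditions$motion > 0, 1L, 2L)
  conditions$color_dir <- ifelse(conditions$color > 0, 1L, 2L)
  conditions <- conditions[, c("k", "motion", "color", "motion_idx",
                               "color_idx", "motion_dir", "color_dir")]
  structure(
    list(
      motion_levels = levels,
      color_levels = levels,
      n_levels = length(levels),
      conditions = conditions,
      n_conditions = nrow(conditions),
      contexts = c("motion", "color"),
      n_contexts = 2L
    ),
    class = "task_grid"
  )
}

#' @export
print.task_grid <- function(x, ...) {
  cat(sprintf("task_grid: %d signed levels/modality, %d conditions, %d contexts\n",
              x$n_levels, x$n_conditions, x$n_contexts))
  cat("levels:", paste(format(x$motion_levels), collapse = " "), "\n")
  invisible(x)
}

# Keep a subset of conditions (for leave-one-condition-out folds). The
# signed level set is unchanged so level/direction indices stay valid.
subset_conditions <- function(grid, keep) {
  stopifnot(inherits(grid, "task_grid"))
  out <- grid
  out$conditions <- grid$conditions[keep, , drop = FALSE]
  rownames(out$conditions) <- NULL
  out$n_conditions <- nrow(out$conditions)
  out
}
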