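# Drop conditions from a response tensor without re-z-scoring (the
# z-scoring statistics of the full tensor are kept).
subset_response <- function(data, keep) {
  stopifnot(inherits(data, "response_tensor"))
  out <- data
  out$Y <- data$Y[, , keep, , drop = FALSE]
  out$grid <- subset_conditions(data$grid, keep)
  out
}

#' Leave-one-condition-out cross-validation
#'
#' One fold per task condition: the condition is removed from both contexts,
#' the model is refitted on the remaining conditions, and the held-out
#' condition is forward-generated from the refitted initial conditions and
#' the coherence inputs inferred from the other conditions (on the 6 x 6
#' grid, each coherence level of the held-out condition still appears in 5
#' other conditions, so its input parameters are identified). Generalization
#' is possible precisely because inputs are shared across conditions. The
#' held-out observations never enter any gradient step.
#'
#' A fold whose held-out condition carries a coherence level present in no
#' other condition has unidentifiable inputs and is skipped with a warning.
#'
#' @param data A `response_tensor`.
#' @param class_spec An [lds_class()] (or [tfr_class()]) specification;
#'   `dims_grid` rows override its dimensionalities.
#' @param dims_grid Optional data frame with columns `latent_dim` and
#'   `input_dim` (applied to both modalities) to sweep; `NULL` evaluates
#'   the spec as given.
#' @param config A [fit_config()]; the same seed initializes every fold.
#' @return A `loocv_report`: per-fold table (`latent_dim`, `input_dim`,
#'   `fold`, `held_mse`), per-grid-point summary with mean and SEM across
#'   folds, and the dims minimizing mean held-out MSE.
#' @export
loocv <- function(data, class_spec, dims_grid = NULL,
                  config = fit_config()) {
  stopifnot(inherits(data, "response_tensor"))
  grid <- data$grid
  K <- grid$n_conditions
  if (is.null(dims_grid)) {
    dims_grid <- data.frame(
      latent_dim = class_spec$latent_dim,
      input_dim = if (inherits(class_spec, "tfr_class")) {
        class_spec$input_dims[1L]
      } else {
        class_spec$input_dim_motion
      })
  }
  cond <- grid$conditions
  rows <- list()
  for (g in seq_len(nrow(dims_grid))) {
    spec_g <- respec_dims(class_spec, dims_grid$latent_dim[g],
                          dims_grid$input_dim[g])
    for (k in seq_len(K)) {
      others <- cond[-k, ]
      identifiable <-
        cond$motion_idx[k] %in% others$motion_idx &&
        cond$color_idx[k] %in% others$color_idx
      if (!identifiable) {
        warning("fold ", k, " skipped: a coherence level is unique to the ",
                "held-out condition, so its input is unidentifiable")
        next
      }
      train <- subset_response(data, setdiff(seq_len(K), k))
      pred <- if (inherits(spec_g, "tfr_class")) {
        ft <- fit_tfr(train, spec_g, config)
        tfr_predict(ft$params, grid)
      } else {
        ft <- fit_lds(train, spec_g, config)
        reconstruct(ft$params, grid)
      }
      held_mse <- mean((data$Y[, , k, ] - pred[, , k, ])^2)
      rows[[length(rows) + 1L]] <- data.frame(
        latent_dim = dims_grid$latent_dim[g],
        input_dim = dims_grid$input_dim[g],
        fold = k, held_mse = held_mse)
    }
  }
  folds <- do.call(rbind, rows)
  key <- interaction(folds$latent_dim, folds$input_dim, drop = TRUE)
  agg <- do.call(rbind, lapply(split(folds, key), function(df) {
    data.frame(latent_dim = df$latent_dim[1L], input_dim = df$input_dim[1L],
               n_folds = nrow(df), mean_mse = mean(df$held_mse),
               sem_mse = stats::sd(df$held_mse) / sqrt(nrow(df)))
  }))
  rownames(agg) <- NULL
  best <- agg[which.min(agg$mean_mse), , drop = FALSE]
  structure(list(fold_table = folds, summary = agg, best = best,
                 class_label = class_spec$label, n_conditions = K),
            class = "loocv_report")
}

# Rebuild a class specification with swept dimensionalities.
respec_dims <- function(class_spec, latent_dim, input_dim) {
  if (inherits(class_spec, "tfr_class")) {
    tfr_class(latent_dim, c(input_dim, input_dim),
              context_core = class_spec$context_core,
              n_levels = class_spec$n_levels)
  } else {
    lds_class(class_spec$label, latent_dim, c(input_dim, input_dim),
              time_varying = class_spec$time_varying)
  }
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("LOOCV %s: %d folds/grid point\n", x$class_label,
              x$summary$n_folds[1L]))
  print(x$summary)
  cat(sprintf("best: latent %d, inputs %d (mean held-out MSE %.5f)\n",
              x$best$latent_dim, x$best$input_dim, x$best$mean_mse))
  invisible(x)
}
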