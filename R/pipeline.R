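#' Run the full analysis pipeline from a configuration
#'
#' End-to-end driver: generate (or load) a response tensor, fit the
#' requested model classes with multiple restarts, optionally run LOOCV,
#' characterize the best fitted dynamics (eigenmodes, non-normality, slow
#' modes), screen PC perturbations for transient amplification, and write
#' a JSON summary plus TSV mode tables. Stages are isolated: a failing
#' stage is recorded in the error manifest and later stages that do not
#' depend on it still run. Deterministic given the configured seeds.
#'
#' @param config Path to a JSON configuration or an equivalent list.
#'   Fields: `seed`; `synth` (arguments of [ground_truth_spec()] plus
#'   `noise_sd`) or `data` (path of a serialized tensor); `classes` (list
#'   of `{label, latent_dim, input_dims}`); `fit` ([fit_config()]
#'   overrides); `n_restarts`; `loocv` (optional `{latent_dims,
#'   input_dims}` sweep); `analyses` (subset of `"dynamics"`,
#'   `"perturb"`).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the summary list (also written to
#'   `summary.json`).
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  analyses <- config$analyses %||% c("dynamics", "perturb")
  errors <- list()
  note_error <- function(stage, e) {
    errors[[length(errors) + 1L]] <<- list(stage = stage,
                                           message = conditionMessage(e))
  }
  summary <- list(seed = seed,
                  package_version = as.character(utils::packageVersion("ctxlds")))

  ## -- data -------------------------------------------------------------
  data <- tryCatch({
    if (!is.null(config$data)) {
      read_response_tensor(config$data)
    } else {
      sy <- config$synth %||% list()
      grid <- make_task_grid()
      gt_args <- sy[setdiff(names(sy), "noise_sd")]
      gt_args$seed <- gt_args$seed %||% seed
      spec <- do.call(ground_truth_spec, gt_args)
      gt <- sample_ground_truth(spec, grid)
      generate_observations(gt, grid, noise_sd = sy$noise_sd %||% spec$noise_sd,
                            seed = seed + 1L)
    }
  }, error = function(e) { note_error("data", e); NULL })

  ## -- fits -------------------------------------------------------------
  fits <- list()
  if (!is.null(data)) {
    cfg_args <- config$fit %||% list()
    cfg_args$seed <- cfg_args$seed %||% seed
    fcfg <- do.call(fit_config, cfg_args)
    n_restarts <- as.integer(config$n_restarts %||% 1L)
    for (cl in config$classes %||% list()) {
      label <- cl$label
      res <- tryCatch({
        spec <- lds_class(label, cl$latent_dim,
                          cl$input_dims %||% c(2L, 2L))
        multi_restart(data, spec, fcfg, n_restarts)
      }, error = function(e) { note_error(paste0("fit:", label), e); NULL })
      if (!is.null(res)) fits[[label]] <- res
    }
    summary$fits <- lapply(fits, function(rs) {
      s <- summary(rs)
      list(n_restarts = s$n, best_train_mse = s$best_mse,
           mean_train_mse = s$mean_mse, sd_train_mse = s$sd_mse)
    })
  }

  ## -- loocv ------------------------------------------------------------
  if (!is.null(data) && !is.null(config$loocv)) {
    dims_grid <- expand.grid(latent_dim = config$loocv$latent_dims,
                             input_dim = config$loocv$input_dims)
    for (label in names(fits)) {
      rep <- tryCatch({
        spec <- fits[[label]]$class_spec
        loocv(data, spec, dims_grid, do.call(fit_config, c(
          config$fit %||% list(), list(seed = seed))))
      }, error = function(e) { note_error(paste0("loocv:", label), e); NULL })
      if (!is.null(rep)) {
        write.table(rep$fold_table,
                    file.path(out_dir, paste0("loocv_", gsub("[{},]", "", label), ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        summary$loocv[[label]] <- list(best = as.list(rep$best))
      }
    }
  }

  ## -- dynamics ---------------------------------------------------------
  if ("dynamics" %in% analyses && length(fits)) {
    summary$dynamics <- list()
    for (label in names(fits)) {
      res <- tryCatch({
        best <- fits[[label]]$fits[[1L]]
        per_cx <- lapply(1:2, function(cx) {
          A <- ctx_mat(best$params$A, cx)
          m <- eigenmodes(A)
          tab <- mode_table(m, file.path(out_dir, sprintf(
            "modes_%s_cx%d.tsv", gsub("[{},]", "", label), cx)))
          list(henrici = henrici_index(A),
               slow_fraction = mean(m$slow),
               max_eig_norm = max(m$norms))
        })
        names(per_cx) <- c("motion_context", "color_context")
        per_cx
      }, error = function(e) { note_error(paste0("dynamics:", label), e); NULL })
      if (!is.null(res)) summary$dynamics[[label]] <- res
    }
  }

  ## -- perturbations ----------------------------------------------------
  if ("perturb" %in% analyses && length(fits) && !is.null(data)) {
    summary$perturb <- list()
    for (label in names(fits)) {
      res <- tryCatch({
        best <- fits[[label]]$fits[[1L]]
        scr <- amplification_screen(best$params, data,
                                    n_pcs = config$n_pcs %||% 10L)
        list(n_amplifying = scr$n_amplifying, max_gain = max(scr$gain))
      }, error = function(e) { note_error(paste0("perturb:", label), e); NULL })
      if (!is.null(res)) summary$perturb[[label]] <- res
    }
  }

  summary$errors <- errors
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
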