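# JSON/TSV serialization. Tensors and parameter sets are stored as JSON
# (shape + flattened column-major values); tables as TSV.

flat <- function(x) list(dim = dim(x), values = as.numeric(x))
unflat <- function(x) array(as.numeric(x$values), dim = as.integer(x$dim))

#' Write / read a response tensor
#'
#' @param data A `response_tensor`.
#' @param path Output path (JSON).
#' @return `read_response_tensor` returns the restored `response_tensor`
#'   (z-scoring is not reapplied; the stored statistics are kept).
#' @export
write_response_tensor <- function(data, path) {
  stopifnot(inherits(data, "response_tensor"))
  obj <- list(
    Y = flat(data$Y),
    bin_ms = data$bin_ms,
    zscore_mean = data$zscore_stats$mean,
    zscore_sd = data$zscore_stats$sd,
    grid = list(strengths = data$grid$motion_levels[data$grid$motion_levels > 0],
                conditions = data$grid$conditions)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_response_tensor
#' @export
read_response_tensor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- make_task_grid(length(obj$grid$strengths), obj$grid$strengths)
  out <- as_response_tensor(unflat(obj$Y), grid, zscore = FALSE)
  out$zscore_stats <- list(mean = obj$zscore_mean, sd = obj$zscore_sd)
  out$bin_ms <- obj$bin_ms
  out
}

#' Write / read LDS parameters
#'
#' Parameters are stored with their model-class header; the loader rebuilds
#' the object through the validating constructors.
#'
#' @param params An [lds_params()] set.
#' @param path Output path (JSON).
#' @export
write_lds_params <- function(params, path) {
  cs <- params$class_spec
  # per-context slots are written as named objects (never JSON arrays) so
  # the reader can tell them from a single shared matrix
  as_list <- function(x) {
    if (is.list(x)) stats::setNames(lapply(x, flat), c("ctx1", "ctx2"))
    else flat(x)
  }
  obj <- list(
    class_spec = list(label = cs$label, latent_dim = cs$latent_dim,
                      input_dims = c(cs$input_dim_motion, cs$input_dim_color),
                      time_varying = cs$time_varying),
    A = as_list(params$A), B_mot = as_list(params$B_mot),
    B_col = as_list(params$B_col),
    x0 = flat(params$x0), C_load = flat(params$C_load), d = params$d,
    inputs = list(
      course_motion_in = flat(params$inputs$motion$course_in),
      course_motion_out = flat(params$inputs$motion$course_out),
      course_color_in = flat(params$inputs$color$course_in),
      course_color_out = flat(params$inputs$color$course_out),
      scal_motion = flat(params$inputs$motion$scalars),
      scal_color = flat(params$inputs$color$scalars),
      time_varying = params$inputs$time_varying)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lds_params
#' @export
read_lds_params <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  cs <- lds_class(o$class_spec$label, o$class_spec$latent_dim,
                  o$class_spec$input_dims, o$class_spec$time_varying)
  un <- function(x) {
    if (!is.null(x$dim)) unflat(x) else unname(lapply(x, unflat))
  }
  inputs <- input_model(unflat(o$inputs$course_motion_in),
                        unflat(o$inputs$course_motion_out),
                        unflat(o$inputs$course_color_in),
                        unflat(o$inputs$course_color_out),
                        unflat(o$inputs$scal_motion),
                        unflat(o$inputs$scal_color),
                        o$inputs$time_varying)
  lds_params(cs, un(o$A), un(o$B_mot), un(o$B_col),
             unflat(o$x0), unflat(o$C_load), o$d, inputs)
}

#' Export a per-mode summary table
#'
#' One row per eigenmode: eigenvalue norm and components, decay time
#' constant, rotation frequency, slow flag, conjugate-pair id, and
#' optionally the time-averaged input loads.
#'
#' @param modes An [eigenmodes()] set.
#' @param path TSV output path.
#' @param loads Optional named list of [input_loads()] objects whose
#'   `load_mean` columns are appended.
#' @return The table, invisibly written to `path` if non-NULL.
#' @export
mode_table <- function(modes, path = NULL, loads = NULL) {
  df <- data.frame(
    mode = seq_along(modes$values),
    eig_norm = modes$norms,
    eig_re = Re(modes$values),
    eig_im = Im(modes$values),
    tau_ms = modes$tau_ms,
    freq_hz = modes$freq_hz,
    slow = modes$slow,
    pair_id = modes$pair_id
  )
  for (nm in names(loads)) df[[paste0("load_", nm)]] <- loads[[nm]]$load_mean
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
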