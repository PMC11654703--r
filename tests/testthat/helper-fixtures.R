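# Shared fixtures: everything is generated in code at test time.

grid36 <- make_task_grid()                       # the standard 6 x 6 task
grid16 <- make_task_grid(2, c(0.1, 0.5))         # 4 levels, 16 conditions
grid4 <- make_task_grid(1, 0.5)                  # 2 levels, 4 conditions

# Random LDS parameter set of a given class by drawing a flat parameter
# vector (exercises the same layout the optimizer uses).
rand_params <- function(class_spec, n_neurons, n_bins, grid, sd = 0.4,
                        seed = 1L) {
  lay <- ctxlds:::theta_layout(class_spec, n_neurons, n_bins, grid$n_levels)
  ctxlds:::with_seed(seed,
    ctxlds:::unpack_params(rnorm(lay$total, 0, sd), class_spec, n_neurons,
                           n_bins, grid$n_levels))
}

# Stable random LDS: like rand_params but with the dynamics rescaled to
# spectral radius `rho` so simulations stay bounded.
stable_params <- function(class_spec, n_neurons, n_bins, grid, rho = 0.85,
                          seed = 1L) {
  p <- rand_params(class_spec, n_neurons, n_bins, grid, seed = seed)
  shrink <- function(A) A * (rho / max(Mod(eigen(A, only.values = TRUE)$values)))
  p$A <- if (is.list(p$A)) lapply(p$A, shrink) else shrink(p$A)
  p
}

# Principal subspace angle (degrees) between the column spans of two bases.
subspace_angle <- function(Ba, Bb) {
  qa <- qr.Q(qr(as.matrix(Ba)))
  qb <- qr.Q(qr(as.matrix(Bb)))
  acos(min(c(svd(t(qa) %*% qb)$d, 1))) * 180 / pi
}

fast_config <- function(max_iter = 1000L, seed = 1L, ...) {
  fit_config(max_iter = max_iter, min_iter = 200L,
             convergence_dcost = 1e-8, seed = seed, ...)
}
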