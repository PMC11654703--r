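test_that("analytic gradients match central finite differences in every class", {
  set.seed(99)
  for (lbl in c("A,B", "A,Bcx", "Acx,B", "Acx,Bcx")) {
    tv <- lbl %in% c("A,B", "Acx,Bcx")   # cover both input modes across classes
    cs <- lds_class(lbl, 3, c(2, 1), time_varying = tv)
    gt <- stable_params(cs, 4, 4, grid16, seed = 5)
    data <- generate_observations(gt, grid16, noise_sd = 0.2, seed = 6)
    prob <- ctxlds:::fit_problem(data)
    lay <- ctxlds:::theta_layout(cs, 4, 4, grid16$n_levels)
    theta <- rnorm(lay$total, 0, 0.3)
    f <- function(th, wg = FALSE) {
      ctxlds:::lds_cost_grad_cpp(th, prob$cube, lay$L, lay$Um, lay$Uc,
                                 cs$dynamics_cx, cs$inputs_cx, cs$time_varying,
                                 prob$mlev, prob$mdir, prob$clev, prob$cdir,
                                 prob$n_levels, 1e-3, 0.2, wg)
    }
    g <- f(theta, TRUE)$grad
    idx <- sample(lay$total, min(20, lay$total))
    eps <- 1e-6
    num <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- tp[i] + eps
      tm <- theta; tm[i] <- tm[i] - eps
      (f(tp)$cost - f(tm)$cost) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - g[idx]) / pmax(1e-6, abs(num))), 1e-4)
  }
})

test_that("fitting the generating class to noiseless data drives the MSE down", {
  gt <- sample_ground_truth(
    ground_truth_spec(n_neurons = 20, latent_dim = 3, input_dims = c(1, 1),
                      eigen_plan = c(0.9, 0.7, 0.4), seed = 14), grid36)
  data <- generate_observations(gt, grid36, noise_sd = 0, seed = 1)
  ft <- fit_lds(data, gt$class_spec, fast_config(max_iter = 2500, seed = 3))
  expect_lt(ft$train_mse, 1e-3)
  expect_lt(max(abs(crossprod(ft$params$C_load) -
                      diag(gt$class_spec$latent_dim))), 1e-8)
  expect_equal(ft$train_mse, mse(data, reconstruct(ft$params, grid36)),
               tolerance = 1e-10)
})

test_that("stronger input penalties shrink the fitted input vectors", {
  gt <- sample_ground_truth(
    ground_truth_spec(n_neurons = 12, latent_dim = 2, input_dims = c(1, 1),
                      eigen_plan = c(0.8, 0.5), seed = 4), grid36)
  data <- generate_observations(gt, grid36, noise_sd = 0.1, seed = 5)
  bu_mass <- function(lam) {
    ft <- fit_lds(data, gt$class_spec,
                  fast_config(max_iter = 900, seed = 2, lambda_inp = lam))
    sn <- summary_norms(ft$params, grid36, subtract_condition_mean = FALSE)
    sum(sn$input^2)
  }
  path <- vapply(c(1e-5, 1e-1, 1e2), bu_mass, numeric(1))
  expect_true(all(diff(path) < 0))
})

test_that("restarts are deterministic, sorted, and propagate failures", {
  gt <- sample_ground_truth(
    ground_truth_spec(n_neurons = 10, latent_dim = 2, input_dims = c(1, 1),
                      eigen_plan = c(0.8, 0.5), seed = 8), grid36)
  data <- generate_observations(gt, grid36, noise_sd = 0.2, seed = 9)
  cfg <- fast_config(max_iter = 400, seed = 7)
  one <- multi_restart(data, gt$class_spec, cfg, n_restarts = 1)
  direct <- fit_lds(data, gt$class_spec, cfg)
  expect_equal(one$fits[[1]]$train_mse, direct$train_mse)
  expect_equal(one$fits[[1]]$params$A, direct$params$A)

  again <- multi_restart(data, gt$class_spec, cfg, n_restarts = 1)
  expect_identical(one$fits[[1]]$params$C_load, again$fits[[1]]$params$C_load)

  five <- multi_restart(data, gt$class_spec, cfg, n_restarts = 5)
  mses <- vapply(five$fits, function(f) f$train_mse, numeric(1))
  expect_identical(mses, sort(mses))
  s <- summary(five)
  expect_true(is.finite(s$sd_mse))
  expect_lte(s$best_mse, s$median_mse)
})

test_that("the normality penalty is the squared commutator norm", {
  S <- matrix(rnorm(9), 3); S <- S + t(S)
  expect_equal(normal_penalty(S), 0)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(normal_penalty(R), 0, tolerance = 1e-12)
  expect_equal(normal_penalty(matrix(c(0, 0, 1, 0), 2)), 2)
})

test_that("penalized fits with frozen loading learn near-normal dynamics", {
  gt <- sample_ground_truth(
    ground_truth_spec(n_neurons = 12, latent_dim = 2, input_dims = c(1, 1),
                      eigen_plan = c(0.8, 0.5), non_normality = 1.5, seed = 6),
    grid36)
  data <- generate_observations(gt, grid36, noise_sd = 0.1, seed = 7)
  base <- fit_lds(data, gt$class_spec, fast_config(max_iter = 800, seed = 1))
  h_base <- henrici_index(base$params$A)
  pen <- fit_lds(data, gt$class_spec,
                 fast_config(max_iter = 800, seed = 1, lambda_dyn = 1,
                             freeze_C = base$params$C_load))
  expect_lt(henrici_index(pen$params$A), max(0.05, h_base / 2))
  expect_equal(pen$params$C_load, base$params$C_load, tolerance = 1e-12)
})

test_that("LOOCV runs one fold per condition and never sees held-out data", {
  gt <- sample_ground_truth(
    ground_truth_spec(n_neurons = 8, latent_dim = 2, input_dims = c(1, 1),
                      eigen_plan = c(0.8, 0.5), seed = 10), grid16)
  data <- generate_observations(gt, grid16, noise_sd = 0.05, seed = 11)
  cfg <- fast_config(max_iter = 250, seed = 4)
  rep <- loocv(data, gt$class_spec, config = cfg)
  expect_equal(nrow(rep$fold_table), grid16$n_conditions)
  expect_equal(rep$summary$n_folds, grid16$n_conditions)
  expect_true(is.finite(rep$summary$sem_mse))

  # leakage: corrupting the held-out condition leaves the fold fit unchanged
  k <- 5L
  corrupted <- data
  corrupted$Y[, , k, ] <- 1e3
  keep <- setdiff(seq_len(grid16$n_conditions), k)
  f1 <- fit_lds(ctxlds:::subset_response(data, keep), gt$class_spec, cfg)
  f2 <- fit_lds(ctxlds:::subset_response(corrupted, keep), gt$class_spec, cfg)
  expect_identical(f1$params$A, f2$params$A)
  expect_identical(reconstruct(f1$params, grid16)[, , k, ],
                   reconstruct(f2$params, grid16)[, , k, ])
})

test_that("folds with unidentifiable held-out inputs are skipped with a warning", {
  gt <- sample_ground_truth(
    ground_truth_spec(n_neurons = 6, latent_dim = 2, input_dims = c(1, 1),
                      eigen_plan = c(0.8, 0.5), seed = 12), grid4)
  data <- generate_observations(gt, grid4, noise_sd = 0.05, seed = 13)
  # drop condition (+,+): in the remaining 3 conditions, positive motion
  # and positive color each appear exactly once, so holding those out
  # leaves their coherence inputs unidentifiable
  kpp <- which(grid4$conditions$motion > 0 & grid4$conditions$color > 0)
  sub <- ctxlds:::subset_response(data, setdiff(1:4, kpp))
  cfg <- fast_config(max_iter = 150, seed = 1)
  rep <- NULL
  w <- capture_warnings(rep <- loocv(sub, gt$class_spec, config = cfg))
  expect_true(any(grepl("skipped", w)))
  expect_lt(nrow(rep$fold_table), 3L)
})

test_that("configuration errors are caught", {
  expect_error(fit_config(lambda_inp = -1), "non-negative")
  expect_error(fit_config(learning_rate = 0))
})

test_that("a dimensionality sweep penalizes underfitting on clean data", {
  gt <- sample_ground_truth(
    ground_truth_spec(n_neurons = 10, latent_dim = 3, input_dims = c(1, 1),
                      eigen_plan = c(0.9, 0.75, 0.5), seed = 16), grid16)
  data <- generate_observations(gt, grid16, noise_sd = 0, seed = 17)
  cfg <- fast_config(max_iter = 500, seed = 3)
  sweep <- loocv(data, gt$class_spec,
                 dims_grid = data.frame(latent_dim = c(2, 3), input_dim = 1),
                 config = cfg)
  m2 <- sweep$summary$mean_mse[sweep$summary$latent_dim == 2]
  m3 <- sweep$summary$mean_mse[sweep$summary$latent_dim == 3]
  expect_lte(m3, m2)
  expect_equal(sweep$best$latent_dim, 3)
})

test_that("LOOCV dispatches to the TFR family", {
  gt <- sample_ground_truth(
    ground_truth_spec(n_neurons = 8, n_bins = 6, latent_dim = 2,
                      input_dims = c(1, 1), eigen_plan = c(0.85, 0.5),
                      seed = 18), grid16)
  data <- generate_observations(gt, grid16, noise_sd = 0.05, seed = 19)
  spec <- tfr_class(2, c(1, 1), n_levels = grid16$n_levels)
  rep <- loocv(data, spec, config = fast_config(max_iter = 250, seed = 5))
  expect_equal(nrow(rep$fold_table), 16L)
  expect_lt(rep$summary$mean_mse, 0.5)
})
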