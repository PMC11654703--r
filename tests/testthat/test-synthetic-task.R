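test_that("task grids enumerate the full coherence product", {
  expect_equal(grid36$n_conditions, 36L)
  expect_equal(length(grid36$motion_levels), 6L)
  expect_equal(grid4$n_conditions, 4L)

  # brute-force enumeration of the Cartesian product for 2 strengths
  levels <- sort(c(-c(0.1, 0.5), c(0.1, 0.5)))
  expect_equal(grid16$motion_levels, levels)
  brute <- expand.grid(m = levels, c = levels)
  expect_equal(grid16$n_conditions, nrow(brute))

  # mirrored about zero; each signed level appears in n_levels conditions
  expect_equal(grid36$motion_levels, -rev(grid36$motion_levels))
  counts <- table(grid36$conditions$motion_idx)
  expect_true(all(counts == grid36$n_levels))
  counts_c <- table(grid36$conditions$color_idx)
  expect_true(all(counts_c == grid36$n_levels))
})

test_that("invalid strength values are rejected", {
  expect_error(make_task_grid(2, c(0, 0.5)), "positive")
  expect_error(make_task_grid(2, c(0.5, 0.5)), "duplicate")
  expect_error(make_task_grid(0), "n_strengths")
  expect_error(make_task_grid(2, 0.5), "one strength value")
})

test_that("ground-truth dynamics realize the eigen plan by construction", {
  plan <- c(0.98, 0.8, 0.8, 0.5)
  spec <- ground_truth_spec(latent_dim = 4L, eigen_plan = plan,
                            non_normality = 0.8, seed = 3)
  gt <- sample_ground_truth(spec, grid36)
  got <- sort(Mod(eigen(gt$A)$values), decreasing = TRUE)
  expect_lt(max(abs(got - sort(plan, decreasing = TRUE))), 1e-10)

  # normal construction: Henrici index 0 for non_normality = 0, all real
  spec0 <- ground_truth_spec(latent_dim = 4L, eigen_plan = c(0.9, 0.7, 0.5, 0.3),
                             non_normality = 0, seed = 3)
  gt0 <- sample_ground_truth(spec0, grid36)
  # the index is a square root of a cancellation-limited difference, so
  # "zero" means zero at sqrt(machine precision); its square is at 1e-12
  expect_lt(henrici_index(gt0$A)^2, 1e-12)
  expect_lt(normal_penalty(gt0$A), 1e-12)

  # a complex target without its conjugate partner is a plan error
  expect_error(
    sample_ground_truth(ground_truth_spec(latent_dim = 4L,
                                          eigen_plan = c(0.9, 0.5 + 0.2i),
                                          seed = 1), grid36),
    "conjugate")
  expect_error(ground_truth_spec(latent_dim = 2L, eigen_plan = c(0.9, 0.8, 0.7)),
               "longer than latent_dim")
})

test_that("context_mode = none gives identical generative parameters", {
  gt <- sample_ground_truth(ground_truth_spec(context_mode = "none", seed = 5),
                            grid36)
  expect_false(is.list(gt$A))
  expect_false(is.list(gt$B_mot))
  expect_identical(gt$x0[, 1], gt$x0[, 2])
})

test_that("slow-mode fraction of a planned spectrum is exact", {
  plan <- c(0.95, 0.9, 0.85, 0.5)
  gt <- sample_ground_truth(
    ground_truth_spec(latent_dim = 8L, eigen_plan = plan, seed = 7), grid36)
  m <- eigenmodes(gt$A)
  # 3 planned slow modes; the automatic fill never exceeds norm 0.6
  expect_equal(sum(m$slow), 3L)
  expect_equal(mean(m$slow), 3 / 8)
})

test_that("generated tensors are z-scored, deterministic, and invert exactly", {
  spec <- ground_truth_spec(n_neurons = 40L, seed = 2)
  gt <- sample_ground_truth(spec, grid36)
  d1 <- generate_observations(gt, grid36, noise_sd = 0.5, seed = 11)
  d2 <- generate_observations(gt, grid36, noise_sd = 0.5, seed = 11)
  expect_identical(d1$Y, d2$Y)

  # brute-force per-neuron moments over the pooled (t, k, cx) window
  flat <- matrix(d1$Y, nrow = dim(d1$Y)[1])
  expect_lt(max(abs(rowMeans(flat))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(flat^2) - rowMeans(flat)^2) - 1)), 1e-9)

  # noiseless round trip: un-z-scored tensor equals the reconstruction
  d0 <- generate_observations(gt, grid36, noise_sd = 0, seed = 1)
  expect_lt(max(abs(unzscore(d0) - reconstruct(gt, grid36))), 1e-12)
})

test_that("degenerate zero-variance neurons error unless dropped", {
  cs <- lds_class("A,B", 2, c(1, 1))
  zero_inputs <- input_model(matrix(1, 15, 1), matrix(1, 15, 1),
                             matrix(1, 15, 1), matrix(1, 15, 1),
                             matrix(0, 6, 1), matrix(0, 6, 1),
                             time_varying = FALSE)
  dead <- lds_params(cs, A = matrix(0, 2, 2), B_mot = matrix(0, 2, 1),
                     B_col = matrix(0, 2, 1), x0 = matrix(0, 2, 2),
                     C_load = diag(2), d = c(0, 0), inputs = zero_inputs)
  expect_error(generate_observations(dead, grid36, noise_sd = 0, seed = 1),
               "degenerate")
  # one live neuron, one dead: dropping keeps the live one
  half <- dead
  half$d <- c(0, 1)
  half$x0 <- matrix(c(1, 0, 1, 0), 2, 2)  # drives neuron 1 only (C = I)
  half$A <- diag(c(0.5, 0))
  out <- generate_observations(half, grid36, noise_sd = 0, seed = 1,
                               drop_degenerate = TRUE)
  expect_equal(dim(out$Y)[1], 1L)
})

test_that("unstable ground truth overflows with an informative error", {
  cs <- lds_class("A,B", 1, c(1, 1))
  ones <- matrix(1, 15, 1)
  inputs <- input_model(ones, ones, ones, ones,
                        matrix(grid36$motion_levels, 6, 1),
                        matrix(grid36$color_levels, 6, 1))
  wild <- lds_params(cs, A = matrix(1e30, 1, 1), B_mot = matrix(1, 1, 1),
                     B_col = matrix(1, 1, 1), x0 = matrix(1, 1, 2),
                     C_load = matrix(1, 1, 1), d = 0, inputs = inputs)
  expect_error(generate_observations(wild, grid36, noise_sd = 0, seed = 1),
               "eigenvalue")
})

test_that("negating coherences and swapping direction courses is a symmetry", {
  spec <- ground_truth_spec(n_neurons = 20L, seed = 9)
  gt <- sample_ground_truth(spec, grid36)
  d1 <- generate_observations(gt, grid36, noise_sd = 0, seed = 1)

  # mirror the task: negate all signed levels (reversing the sorted order)
  # and compensate in the input model by swapping in/out courses and
  # reversing the scalar rows
  neg_grid <- grid36
  neg_grid$motion_levels <- -rev(grid36$motion_levels)
  neg_grid$color_levels <- -rev(grid36$color_levels)
  cond <- grid36$conditions
  cond$motion <- -cond$motion
  cond$color <- -cond$color
  cond$motion_idx <- 7L - cond$motion_idx
  cond$color_idx <- 7L - cond$color_idx
  cond$motion_dir <- 3L - cond$motion_dir
  cond$color_dir <- 3L - cond$color_dir
  neg_grid$conditions <- cond

  gt2 <- gt
  for (m in c("motion", "color")) {
    io <- gt$inputs[[m]]
    gt2$inputs[[m]]$course_in <- io$course_out
    gt2$inputs[[m]]$course_out <- io$course_in
    gt2$inputs[[m]]$scalars <- io$scalars[6:1, , drop = FALSE]
  }
  d2 <- generate_observations(gt2, neg_grid, noise_sd = 0, seed = 1)
  expect_equal(d1$Y, d2$Y, tolerance = 1e-12)
})
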