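test_that("eigenmode sets satisfy the defining identities", {
  m <- eigenmodes(diag(c(0.9, 0.5)))
  expect_equal(m$values, c(0.9 + 0i, 0.5 + 0i))
  expect_equal(abs(Re(m$R_eig)), diag(2), ignore_attr = TRUE)
  expect_equal(m$slow, c(TRUE, FALSE))

  # scaled rotation: one conjugate pair of norm 0.8
  th <- 0.6
  A <- 0.8 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mr <- eigenmodes(A)
  expect_equal(mr$norms, c(0.8, 0.8), tolerance = 1e-12)
  expect_equal(mr$pair_id, c(1L, 1L))
  expect_equal(mr$tau_ms[1], mr$tau_ms[2])
  expect_gt(Im(mr$values[1]), 0)        # positive-imaginary member first

  # random matrix: A = R Lambda L reconstruction, L R = I, eigen equations
  set.seed(20)
  A6 <- matrix(rnorm(36, 0, 0.4), 6)
  m6 <- eigenmodes(A6)
  recon <- m6$R_eig %*% diag(m6$values) %*% m6$L_eig
  expect_lt(max(Mod(recon - A6)), 1e-8)
  expect_lt(max(Mod(m6$L_eig %*% m6$R_eig - diag(6))), 1e-8)
  for (i in 1:6) {
    expect_lt(max(Mod(A6 %*% m6$R_eig[, i] - m6$values[i] * m6$R_eig[, i])), 1e-8)
    expect_lt(max(Mod(m6$L_eig[i, ] %*% A6 - m6$values[i] * m6$L_eig[i, ])), 1e-8)
  }
  expect_true(all(diff(m6$norms) <= 1e-12))  # descending norm order
})

test_that("time constants convert eigenvalue norms at 50-ms bins", {
  expect_equal(round(time_constant(0.7)), 140)
  expect_equal(round(time_constant(0.8)), 224)
  expect_equal(round(time_constant(0.9)), 475)
  expect_equal(signif(time_constant(0.98) / 1000, 2), 2.5)  # seconds
  expect_identical(time_constant(1), Inf)                   # integration mode
  expect_lt(time_constant(1.1), 0)                          # signed growth
  expect_error(time_constant(0), "domain")
  expect_error(time_constant(-0.5), "domain")
})

test_that("rotation frequencies cover real, complex, and Nyquist modes", {
  expect_equal(rotation_frequency(0.7), 0)
  expect_equal(rotation_frequency(0.8i), 5)        # quarter turn per bin
  expect_equal(rotation_frequency(-0.5), 10)       # Nyquist

  # brute force: a 1D signed sequence x(t) = (-0.5)^t alternates sign every
  # bin, i.e. completes a cycle every 2 bins: 20 bins/s / 2 = 10 Hz
  x <- (-0.5)^(0:10)
  flips <- sum(diff(sign(x)) != 0)
  period_bins <- 2 * 10 / flips
  expect_equal(20 / period_bins, rotation_frequency(-0.5))
  expect_error(rotation_frequency(0), "undefined")
})

test_that("Henrici index is 0 for normal, 1 for nilpotent, bounded otherwise", {
  S <- matrix(rnorm(16), 4); S <- S + t(S)
  expect_lt(henrici_index(S), 1e-10)
  for (c_val in c(0.1, 3)) {
    expect_equal(henrici_index(matrix(c(0, 0, c_val, 0), 2)), 1)
  }
  set.seed(4)
  for (i in 1:10) {
    h <- henrici_index(matrix(rnorm(25), 5))
    expect_gte(h, 0); expect_lte(h, 1)
  }
  expect_error(henrici_index(matrix(0, 2, 2)), "zero matrix")
})

test_that("input loads project onto left eigenvectors and reconstruct the input", {
  # diagonal dynamics, input along e1: full load on mode 1, none elsewhere
  m <- eigenmodes(diag(c(0.9, 0.5, 0.2)))
  bu <- matrix(c(1, 0, 0), 3, 4)
  ld <- input_loads(m, bu)
  expect_equal(ld$load_mean, c(1, 0, 0))
  # orthogonality: input in the left null direction of a mode loads zero
  expect_equal(ld$load_trace[2, ], rep(0, 4))

  # reconstruction identity on random systems with complex pairs
  for (L in c(5, 8, 10)) {
    set.seed(L)
    A <- matrix(rnorm(L^2, 0, 0.5), L)
    modes <- eigenmodes(A)
    expect_true(any(Im(modes$values) != 0))  # complex pairs present
    bu <- matrix(rnorm(L * 6), L)
    ld <- input_loads(modes, bu)
    expect_lt(max(abs(load_reconstruction(ld) - bu)), 1e-9)
    # pair members share one load value
    for (pid in unique(modes$pair_id)) {
      mem <- which(modes$pair_id == pid)
      if (length(mem) == 2) {
        expect_identical(ld$load_trace[mem[1], ], ld$load_trace[mem[2], ])
      }
    }
  }
  expect_error(input_loads(eigenmodes(diag(c(0.5, 0.2))), matrix(0, 3, 2)),
               "basis")
})

test_that("impulse responses expose transient amplification", {
  # normal dynamics: every trace decays within the eigenvalue bound
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  A <- Q %*% diag(c(0.9, 0.6, 0.4, 0.2)) %*% t(Q)
  ir <- impulse_response(A, random_directions(4, 6, seed = 2), horizon = 10)
  expect_true(all(diff(ir$norms) <= 1e-12))
  expect_true(all(ir$norms <= 0.9^(0:10) + 1e-12))

  # non-normal shear amplifies: ||x(1)|| = sqrt(25 + 0.81) > 1
  As <- matrix(c(0.9, 0, 5, 0.9), 2)
  irs <- impulse_response(As, matrix(c(0, 1), 2, 1), horizon = 3)
  expect_equal(irs$norms[2, 1], sqrt(25 + 0.81), tolerance = 1e-12)
  expect_gt(irs$norms[2, 1], 1)

  # along a real eigenvector the norm is exactly |lambda|^t
  m <- eigenmodes(matrix(c(0.8, 0.1, 0.2, 0.5), 2))
  v <- Re(m$R_eig[, 1])
  irv <- impulse_response(m$A, matrix(v), horizon = 6)
  expect_equal(irv$norms[, 1], m$norms[1]^(0:6), tolerance = 1e-10)
})

test_that("the observability Gramian solves the Lyapunov equation", {
  # A = 0: Q = C'C by direct substitution
  C <- matrix(rnorm(12), 4, 3)
  g0 <- observability_gramian(matrix(0, 3, 3), C)
  expect_equal(g0$Q, crossprod(C), tolerance = 1e-12)

  # scalar geometric series: a = 0.5, c = 1 -> sum 0.25^t = 4/3
  gs <- observability_gramian(matrix(0.5), matrix(1))
  expect_equal(gs$Q[1, 1], 4 / 3, tolerance = 1e-12)

  # random stable 5D: matches the truncated series oracle
  set.seed(8)
  A <- matrix(rnorm(25), 5); A <- A * (0.9 / max(Mod(eigen(A)$values)))
  C5 <- matrix(rnorm(20), 4, 5)
  g <- observability_gramian(A, C5)
  Qser <- matrix(0, 5, 5); At <- diag(5)
  for (t in 0:200) {
    Qser <- Qser + t(At) %*% crossprod(C5) %*% At
    At <- A %*% At
  }
  expect_lt(max(abs(g$Q - Qser)), 1e-6)
  expect_lt(g$residual, 1e-8)
  expect_true(all(g$eigenvalues > -1e-10))  # positive semidefinite

  expect_error(observability_gramian(diag(c(1.01, 0.5)), diag(2)), "unstable")
})

test_that("controllability rank follows the Krylov chain", {
  expect_false(controllability_check(diag(2), c(1, 0))$controllable)
  expect_equal(controllability_check(diag(2), c(1, 0))$rank, 1L)
  L <- 4
  shift <- matrix(0, L, L)
  shift[cbind(1:(L - 1), 2:L)] <- 1                # nilpotent shift chain
  eL <- diag(L)[, L]
  expect_true(controllability_check(shift, eL)$controllable)
  set.seed(3)
  expect_true(controllability_check(matrix(rnorm(16), 4),
                                    matrix(rnorm(8), 4))$controllable)
})

test_that("CD/CI decomposition is exact and mean-free", {
  gt <- sample_ground_truth(ground_truth_spec(n_neurons = 10, seed = 15), grid36)
  data <- generate_observations(gt, grid36, noise_sd = 0.2, seed = 16)
  dec <- cd_ci_decompose(data)
  # CD averages to zero across conditions everywhere
  expect_lt(max(abs(apply(dec$CD, c(1, 2, 4), mean))), 1e-12)
  # CD + broadcast CI reconstructs the data exactly
  recon <- dec$CD + aperm(array(dec$CI, dim = dim(data$Y)[c(1, 2, 4, 3)]),
                          c(1, 2, 4, 3))
  expect_equal(recon, data$Y, tolerance = 1e-12)
  # identical conditions have no CD component
  flatdata <- data
  for (k in seq_len(dim(data$Y)[3])) flatdata$Y[, , k, ] <- data$Y[, , 1, ]
  expect_lt(max(abs(cd_ci_decompose(flatdata)$CD)), 1e-12)
})

test_that("mode alignments match a brute-force search over the pair plane", {
  set.seed(23)
  A <- matrix(rnorm(25, 0, 0.5), 5)
  m <- eigenmodes(A)
  # a real eigenvector aligns perfectly with its own mode
  real_modes <- which(Im(m$values) == 0)
  i <- real_modes[1]
  a <- mode_alignment(Re(m$R_eig[, i]), m)
  expect_equal(a[i], 1, tolerance = 1e-9)

  # complex pair: compare to maximizing |cos| over the plane's unit circle
  pair <- which(table(m$pair_id)[m$pair_id] == 2)[1]
  r <- m$R_eig[, pair]
  basis <- qr.Q(qr(cbind(Re(r), Im(r))))
  v <- rnorm(5); v <- v / sqrt(sum(v^2))
  got <- mode_alignment(v, m)[pair]
  f <- function(th) abs(sum(v * (cos(th) * basis[, 1] + sin(th) * basis[, 2])))
  th_grid <- seq(0, pi, length.out = 20001)
  coarse <- th_grid[which.max(vapply(th_grid, f, numeric(1)))]
  brute <- stats::optimize(f, c(coarse - 1e-3, coarse + 1e-3),
                           maximum = TRUE)$objective
  expect_equal(got, brute, tolerance = 1e-9)

  # orthogonal to the pair plane: zero alignment
  vperp <- rnorm(5)
  vperp <- vperp - basis %*% crossprod(basis, vperp)
  expect_lt(mode_alignment(vperp, m)[pair], 1e-9)
  expect_error(mode_alignment(rep(0, 5), m), "zero vector")
})

test_that("demixing recovers constructed coherence planes", {
  coh <- grid36$motion_levels
  # purely linear inputs collapse to a 1D coherence axis
  v1 <- c(1, 0, 0, 0); v2 <- c(0, 1, 0, 0)
  lin <- outer(v1, coh)
  expect_true(demix_input_plane(lin, coh)$collapsed)

  # constructed coh + |coh| structure: plane recovered within 1 degree
  V <- outer(v1, coh) + outer(v2, abs(coh))
  dm <- demix_input_plane(V, coh)
  expect_false(dm$collapsed)
  expect_lt(subspace_angle(dm$basis, cbind(v1, v2)), 1)
  # coherence direction is recovered first
  expect_gt(abs(sum(dm$basis[, 1] * v1)), 0.999)

  expect_error(demix_input_plane(V[, 1:3], coh[1:3]), "4 distinct")

  # context-shared input model: identical planes across contexts
  gt <- sample_ground_truth(
    ground_truth_spec(context_mode = "dynamics-switching", seed = 2), grid36)
  planes <- lapply(1:2, function(cx) {
    bu <- vapply(1:6, function(lev) {
      coherence_input_series(gt, grid36, "motion", cx, lev)[, 5]
    }, numeric(gt$class_spec$latent_dim))
    demix_input_plane(bu, coh)$basis
  })
  expect_lt(subspace_angle(planes[[1]], planes[[2]]), 1e-8)
})

test_that("norm summaries vanish for zero inputs and tie shared-input contexts", {
  gt <- sample_ground_truth(
    ground_truth_spec(context_mode = "dynamics-switching", seed = 3), grid36)
  gt0 <- gt
  gt0$inputs$motion$scalars[] <- 0
  gt0$inputs$color$scalars[] <- 0
  sn0 <- summary_norms(gt0, grid36, subtract_condition_mean = TRUE)
  expect_lt(max(sn0$input), 1e-12)
  expect_lt(max(sn0$output), 1e-12)

  # inputs fixed across contexts: relevant and irrelevant input traces equal
  sn <- summary_norms(gt, grid36, subtract_condition_mean = FALSE)
  expect_equal(sn$input[, , 1, 1], sn$input[, , 1, 2], tolerance = 1e-12)
  expect_equal(sn$input[, , 2, 1], sn$input[, , 2, 2], tolerance = 1e-12)
})

test_that("scalar dynamics summaries are invariant to orthonormalization", {
  cs <- lds_class("A,B", 4, c(2, 2))
  p <- orthonormalize(stable_params(cs, 8, 5, grid16, seed = 9))
  p2 <- orthonormalize(p)   # loading already orthonormal: orthogonal transform
  for (f in list(function(A) sort(Mod(eigen(A)$values)),
                 henrici_index,
                 function(A) sort(Re(eigen(A)$values)))) {
    expect_equal(f(p$A), f(p2$A), tolerance = 1e-8)
  }
  g1 <- observability_gramian(p$A, p$C_load)
  g2 <- observability_gramian(p2$A, p2$C_load)
  expect_equal(g1$eigenvalues, g2$eigenvalues, tolerance = 1e-8)
  # total squared impulse energy over a full basis is rotation invariant
  ir1 <- impulse_response(p$A, diag(4), horizon = 8)
  ir2 <- impulse_response(p2$A, diag(4), horizon = 8)
  expect_equal(rowSums(ir1$norms^2), rowSums(ir2$norms^2), tolerance = 1e-8)
})
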