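test_that("grouping matrix has the topographic structure", {
  # 3x3 toroidal grid, 3x3 windows: every group has 9 members
  V <- build_grouping_matrix(3, 3, group_size = 3)
  expect_equal(dim(unclass(V)), c(9L, 9L))
  expect_true(all(rowSums(V) == 9))

  # singleton groups give the identity
  V1 <- build_grouping_matrix(4, 4, group_size = 1)
  expect_equal(unclass(V1), diag(16), ignore_attr = TRUE)

  # 4x4 torus, 3x3 windows: every atom sits in exactly 9 groups
  V2 <- build_grouping_matrix(4, 4, group_size = 3, wraparound = TRUE)
  expect_equal(nrow(V2), 16L)
  expect_true(all(colSums(V2) == 9))
  # enumerate group membership independently on the torus
  for (g in 1:16) {
    ar <- (g - 1) %/% 4 + 1
    ac <- (g - 1) %% 4 + 1
    members <- c()
    for (dr in 0:2) for (dc in 0:2) {
      r <- (ar + dr - 1) %% 4 + 1
      c <- (ac + dc - 1) %% 4 + 1
      members <- c(members, (r - 1) * 4 + c)
    }
    expect_equal(which(V2[g, ] == 1), sort(unique(members)))
  }

  # without wraparound only fitting windows survive
  V3 <- build_grouping_matrix(4, 5, group_size = 3, wraparound = FALSE)
  expect_equal(nrow(V3), 2L * 3L)
  expect_error(build_grouping_matrix(2, 4, group_size = 3), "group_size")
})

test_that("smoothed group penalty matches its closed forms and brute force", {
  # all-zero codes: G * N * sqrt(epsilon)
  V <- build_grouping_matrix(3, 3, 3)
  s0 <- matrix(0, 9, 5)
  expect_equal(smoothed_group_penalty(s0, V, 0.04), 9 * 5 * sqrt(0.04))

  # identity grouping, epsilon 0: entrywise L1 norm
  set.seed(41)
  s <- matrix(rnorm(9 * 4), 9, 4)
  V1 <- build_grouping_matrix(3, 3, 1)
  expect_equal(smoothed_group_penalty(s, V1, 0), sum(abs(s)))

  # brute-force triple loop on several shapes
  for (shape in list(c(3, 3, 3), c(4, 4, 3), c(2, 5, 2))) {
    Vx <- build_grouping_matrix(shape[1], shape[2], shape[3])
    sx <- matrix(rnorm(shape[1] * shape[2] * 6), shape[1] * shape[2], 6)
    expect_equal(smoothed_group_penalty(sx, Vx, 0.01),
                 brute_penalty(sx, Vx, 0.01), tolerance = 1e-12)
  }
  expect_error(smoothed_group_penalty(matrix(0, 8, 2), V, 0.01), "column count")
})

test_that("objective decomposes exactly and matches a brute-force oracle", {
  V <- build_grouping_matrix(3, 3, 3)
  cfg <- tsc_config(grid_rows = 3, grid_cols = 3)

  # zero data closed form
  A <- matrix(rnorm(6 * 9), 6, 9)
  ob0 <- tsc_objective(A, matrix(0, 9, 4), matrix(0, 6, 4), V, cfg)
  expect_equal(ob0$J, cfg$lambda * 9 * 4 * sqrt(cfg$epsilon) + cfg$gamma * sum(A^2))

  # perfect reconstruction with lambda = gamma = 0
  cfg0 <- tsc_config(lambda = 0, gamma = 0, grid_rows = 3, grid_cols = 3)
  s <- matrix(rnorm(9 * 4), 9, 4)
  expect_equal(tsc_objective(A, s, A %*% s, V, cfg0)$J, 0, tolerance = 1e-20)

  # random instance vs brute force; decomposition sums to J
  inst <- random_instance(6, 9, 4, seed = 7)
  ob <- tsc_objective(inst$A, inst$s, inst$x, V, cfg)
  expect_equal(ob$J, brute_objective(inst$A, inst$s, inst$x, V,
                                     cfg$lambda, cfg$gamma, cfg$epsilon),
               tolerance = 1e-12)
  expect_equal(sum(ob$terms), ob$J)
  expect_equal(ob$residual + inst$A %*% inst$s, inst$x)
  expect_error(tsc_objective(inst$A, inst$s, inst$x[1:3, ], V, cfg), "nrow")
})

test_that("analytic gradients match finite differences and their closed forms", {
  V <- build_grouping_matrix(3, 3, 3)
  cfg <- tsc_config(grid_rows = 3, grid_cols = 3)
  inst <- random_instance(6, 9, 4, seed = 13)

  # penalty gradient vanishes at the origin: grad = -2 A^T x
  g0 <- grad_codes(inst$A, matrix(0, 9, 4), inst$x, V, cfg)
  expect_equal(g0, -2 * crossprod(inst$A, inst$x))

  # lambda = 0 reduces to the least-squares gradient
  cfgl0 <- tsc_config(lambda = 0, grid_rows = 3, grid_cols = 3)
  expect_equal(grad_codes(inst$A, inst$s, inst$x, V, cfgl0),
               2 * crossprod(inst$A, inst$A %*% inst$s - inst$x))

  # finite differences
  expect_lt(rel_err(grad_codes(inst$A, inst$s, inst$x, V, cfg),
                    fd_grad_codes(inst$A, inst$s, inst$x, V, cfg)), 1e-4)
  expect_lt(rel_err(grad_dictionary(inst$A, inst$s, inst$x, cfg),
                    fd_grad_dictionary(inst$A, inst$s, inst$x, V, cfg)), 1e-4)

  # stationary dictionary: As = x and gamma = 0
  cfgg0 <- tsc_config(gamma = 0, grid_rows = 3, grid_cols = 3)
  expect_equal(grad_dictionary(inst$A, inst$s, inst$A %*% inst$s, cfgg0),
               matrix(0, 6, 9))
  # s = 0: decay-only gradient
  expect_equal(grad_dictionary(inst$A, matrix(0, 9, 4), inst$x * 0, cfg),
               2 * cfg$gamma * inst$A)

  # unsmoothed penalty is refused
  expect_error(grad_codes(inst$A, inst$s, inst$x, V,
                          tsc_config(epsilon = 0, grid_rows = 3, grid_cols = 3)),
               "epsilon")
})

test_that("code initialization follows the scaled correlation rule", {
  set.seed(5)
  A <- matrix(rnorm(6 * 4), 6, 4)
  x <- matrix(rnorm(6 * 3), 6, 3)

  # brute-force per-entry oracle
  expected <- matrix(0, 4, 3)
  for (r in 1:4) {
    for (n in 1:3) {
      expected[r, n] <- sum(A[, r] * x[, n]) / sqrt(sum(A[, r]^2))
    }
  }
  expect_equal(init_codes(A, x), expected, tolerance = 1e-12)

  # unit-norm dictionary: init is exactly A^T x
  Au <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  expect_equal(init_codes(Au, x), crossprod(Au, x))

  # orthonormal dictionary, x = 3rd atom: init is the 3rd basis vector
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(init_codes(Q, Q[, 3, drop = FALSE]),
               matrix(c(0, 0, 1, 0), 4, 1), tolerance = 1e-12)

  expect_error(init_codes(cbind(A, 0), x), "zero-norm")
})

test_that("encode descends monotonically, respects the constraint, and solves the convex subproblem", {
  set.seed(8)
  V <- build_grouping_matrix(3, 3, 3)
  cfg <- tsc_config(grid_rows = 3, grid_cols = 3, max_inner_iters = 300,
                    tol_rel = 1e-10)
  A <- qr.Q(qr(matrix(rnorm(81), 9, 9)))
  x <- matrix(rnorm(9 * 5), 9, 5)

  # least-squares limit: lambda = 0, constraint slack, orthonormal A
  cfg_ls <- tsc_config(lambda = 0, C = 1e6, grid_rows = 3, grid_cols = 3,
                       max_inner_iters = 300, tol_rel = 1e-12)
  enc_ls <- encode(A, x, V, cfg_ls)
  expect_equal(enc_ls$codes, crossprod(A, x), tolerance = 1e-8)

  # accepted-step objective sequence is non-increasing; terms sum to J
  enc <- encode(A, x, V, cfg)
  expect_true(all(diff(enc$trace$J) <= 1e-12))
  expect_equal(enc$trace$reconstruction + enc$trace$penalty + enc$trace$decay,
               enc$trace$J)

  # tight norm bound is enforced on every column
  cfg_tight <- tsc_config(C = 0.01, grid_rows = 3, grid_cols = 3)
  enc_t <- encode(A, x, V, cfg_tight)
  expect_true(all(colSums(enc_t$codes^2) <= 0.01 + 1e-12))

  # convexity: random restarts agree on the final objective
  finals <- replicate(5, {
    s0 <- matrix(rnorm(9 * 5), 9, 5)
    tail(encode(A, x, V, cfg, warm_start = s0)$trace$J, 1)
  })
  expect_lt(diff(range(finals)) / max(1, abs(mean(finals))), 1e-4)
})

test_that("smoothing limit: singleton-group penalty approaches the L1 norm", {
  V1 <- build_grouping_matrix(4, 2, 1)
  set.seed(20)
  for (i in 1:20) {
    s <- matrix(rnorm(8 * 3, sd = runif(1, 0.1, 3)), 8, 3)
    for (eps in c(1e-4, 1e-2, 0.25)) {
      gap <- abs(smoothed_group_penalty(s, V1, eps) - sum(abs(s)))
      expect_lte(gap, 8 * 3 * sqrt(eps))
    }
  }
})

test_that("learning descends in full-batch mode and is reproducible", {
  inst <- generate_tsc_instance(synth_tsc_config(d = 8, k = 9, N = 60,
                                                 atoms_active_per_sample = 2,
                                                 topographic = FALSE, seed = 3))
  cfg <- tsc_config(grid_rows = 3, grid_cols = 3, batch_size = 60,
                    max_outer_iters = 10, seed = 9)
  fit <- tsc_learn(inst$samples, cfg)
  expect_true(all(diff(fit$trace$J_full) <= 1e-10))
  expect_equal(sqrt(colSums(fit$dictionary^2)), rep(1, 9),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(colSums(fit$codes^2) <= cfg$C + 1e-12))
  expect_equal(fit$trace$reconstruction + fit$trace$penalty + fit$trace$decay,
               fit$trace$J_full)

  fit2 <- tsc_learn(inst$samples, cfg)
  expect_identical(fit$dictionary, fit2$dictionary)
  expect_identical(fit$codes, fit2$codes)
  expect_identical(fit$trace$J_full, fit2$trace$J_full)

  expect_error(tsc_learn(inst$samples,
                         tsc_config(grid_rows = 3, grid_cols = 3,
                                    batch_size = 61)), "batch_size")
})

test_that("tidy and glance summarize a fit consistently", {
  inst <- generate_tsc_instance(synth_tsc_config(d = 8, k = 9, N = 40,
                                                 atoms_active_per_sample = 2,
                                                 topographic = FALSE, seed = 2))
  fit <- tsc_learn(inst$samples,
                   tsc_config(grid_rows = 3, grid_cols = 3, batch_size = 40,
                              max_outer_iters = 5, seed = 4))
  td <- tidy(fit)
  expect_equal(nrow(td), 9L)
  expect_true(all(td$atom_norm - 1 < 1e-12))
  gl <- glance(fit)
  expect_equal(gl$objective, tail(fit$trace$J_full, 1))
  expect_s3_class(autoplot(fit), "ggplot")
})
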