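test_that("transform_response computes hellinger and presence-absence cells", {
  Y3 <- matrix(c(1, 0, 2, 3, 4, 2), 3, 2)  # rows (1,3), (0,4), (2,2)
  pre <- sqrt(sweep(Y3, 1, rowSums(Y3), "/"))
  expect_equal(unname(pre[1, ]), c(0.5, sqrt(3) / 2), tolerance = 1e-12)
  expect_equal(unname(pre[2, ]), c(0, 1), tolerance = 1e-12)
  h <- transform_response(Y3, "hellinger")
  expect_equal(unname(h)[, ], unname(sweep(pre, 2, colMeans(pre))),
               tolerance = 1e-12, ignore_attr = TRUE)

  pa_pre <- (Y3 > 0) * 1
  pa <- transform_response(Y3, "presence_absence")
  expect_equal(unname(pa)[, ], unname(sweep(pa_pre, 2, colMeans(pa_pre))),
               tolerance = 1e-14, ignore_attr = TRUE)

  # all modes return column-centered output
  for (m in c("hellinger", "presence_absence", "none")) {
    tr <- transform_response(tiny_community(3), m)
    expect_lt(max(abs(colSums(tr))), 1e-10 * nrow(tr))
    expect_equal(attr(tr, "transform_used"), m)
  }

  # mode none on an already centered matrix is the identity
  Z <- matrix(rnorm(20), 5, 4)
  Z <- sweep(Z, 2, colMeans(Z))
  expect_equal(unname(transform_response(Z, "none"))[, ], unname(Z),
               tolerance = 1e-14, ignore_attr = TRUE)

  # zero-total rows stay all-zero under hellinger, with a warning
  Y0 <- matrix(c(0, 1, 0, 2), 2, 2)
  pre0 <- rbind(c(0, 0), sqrt(c(1 / 3, 2 / 3)))
  expect_warning(h0 <- transform_response(Y0, "hellinger"), "zero total")
  expect_equal(unname(h0[1, ] + colMeans(pre0)), c(0, 0), tolerance = 1e-12)
})

test_that("rda_r2 matches a normal-equations oracle and handles edge cases", {
  # perfect fit: single response equal to the centered predictor
  x <- rnorm(20)
  Yt <- matrix(x - mean(x), 20, 1)
  expect_equal(rda_r2(Yt, matrix(x, 20, 1)), 1, tolerance = 1e-12)

  # empty predictor block is the null model
  expect_equal(rda_r2(Yt, NULL), 0)
  expect_equal(rda_r2(Yt, matrix(numeric(0), 20, 0)), 0)

  # random instances against the SVD oracle
  for (seed in 1:10) {
    inst <- random_instance(seed, n = 20, p = 3, mx = 2)
    expect_equal(rda_r2(inst$Yt, inst$X), oracle_r2(inst$Yt, inst$X),
                 tolerance = 1e-10)
  }

  # rank-deficient block: duplicated column changes nothing
  inst <- random_instance(11)
  expect_equal(rda_r2(inst$Yt, cbind(inst$X, inst$X[, 1])),
               rda_r2(inst$Yt, inst$X), tolerance = 1e-12)

  # saturated model is an error
  expect_error(rda_r2(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3)),
               "saturated")
})

test_that("adjusted_r2 matches the Ezekiel closed form", {
  expect_equal(adjusted_r2(0.5, 11, 1), 1 - 0.5 * 10 / 9, tolerance = 1e-15)
  expect_equal(adjusted_r2(1.0, 30, 7), 1)
  expect_equal(adjusted_r2(0.0, 20, 5), 1 - 19 / 14, tolerance = 1e-15)
  expect_equal(adjusted_r2(0.3, 50, 0), 0.3)  # m = 0 is a no-op
  expect_error(adjusted_r2(0.5, 5, 4), "n <= m")
})

test_that("varpart2 fractions match the residualization oracle", {
  for (seed in 1:10) {
    inst <- random_instance(seed, n = 30, p = 4, mx = 2, mw = 2)
    vp <- varpart2(inst$Yt, inst$X, inst$W)
    or <- oracle_varpart(inst$Yt, inst$X, inst$W)
    expect_equal(vp$frac_a, or[["frac_a"]], tolerance = 1e-8)
    expect_equal(vp$frac_b, or[["frac_b"]], tolerance = 1e-8)
    expect_equal(vp$frac_c, or[["frac_c"]], tolerance = 1e-8)
    expect_equal(vp$frac_d, or[["frac_d"]], tolerance = 1e-8)
  }
})

test_that("varpart2 obeys its structural invariants", {
  inst <- random_instance(5)
  vp <- varpart2(inst$Yt, inst$X, inst$W)
  # fractions sum to one
  expect_equal(vp$frac_a + vp$frac_b + vp$frac_c + vp$frac_d, 1,
               tolerance = 1e-10)
  expect_equal(vp$frac_d, 1 - vp$adj_r2_full, tolerance = 1e-12)
  expect_true(all(c(vp$r2_env, vp$r2_space, vp$r2_full) >= 0))
  expect_true(all(c(vp$r2_env, vp$r2_space, vp$r2_full) <= 1))

  # swapping the blocks swaps a and c, leaves b and d
  sw <- varpart2(inst$Yt, inst$W, inst$X)
  expect_equal(sw$frac_a, vp$frac_c, tolerance = 1e-12)
  expect_equal(sw$frac_c, vp$frac_a, tolerance = 1e-12)
  expect_equal(sw$frac_b, vp$frac_b, tolerance = 1e-12)
  expect_equal(sw$frac_d, vp$frac_d, tolerance = 1e-12)

  # duplicated block: no pure fractions
  dup <- varpart2(inst$Yt, inst$X, inst$X)
  expect_equal(dup$frac_a, 0, tolerance = 1e-14)
  expect_equal(dup$frac_c, 0, tolerance = 1e-14)

  # all-constant response is an error
  expect_error(varpart2(matrix(0, 20, 3), inst$X[1:20, ], inst$W[1:20, ]),
               "zero-variance")
})

test_that("a pure-noise predictor does not inflate the adjusted env fraction", {
  set.seed(202)
  diffs <- replicate(200, {
    n <- 40
    X <- matrix(rnorm(n * 2), n, 2)
    Y <- X %*% matrix(c(1, -0.5, 0.3, 0.8, 0, 0.4), 2, 3) +
      matrix(rnorm(n * 3), n, 3)
    Yt <- sweep(Y, 2, colMeans(Y), "-")
    W <- matrix(rnorm(n * 2), n, 2)
    base <- varpart2(Yt, X, W)$frac_a
    noisy <- varpart2(Yt, cbind(X, rnorm(n)), W)$frac_a
    noisy - base
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lte(mean(diffs), 0 + 2 * se)
})

test_that("noiseless env signal with noise space recovers the partition", {
  set.seed(77)
  n <- 100
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- X %*% matrix(rnorm(2 * 5), 2, 5)  # noiseless linear function of X
  Yt <- sweep(Y, 2, colMeans(Y), "-")
  W <- matrix(rnorm(n * 2), n, 2)
  vp <- varpart2(Yt, X, W)
  expect_equal(vp$frac_c, 0, tolerance = 0.02)
  expect_equal(vp$frac_a, vp$adj_r2_full, tolerance = 0.02)
  expect_equal(vp$r2_full, 1, tolerance = 1e-10)
})

test_that("varpart2 agrees with vegan on a shared instance", {
  skip_if_not_installed("vegan")
  inst <- random_instance(99, n = 40, p = 6, mx = 3, mw = 2)
  vp <- varpart2(inst$Yt, inst$X, inst$W)
  # vegan row order: [a] = X1|X2 (pure env), [b] = X2|X1 (pure space),
  # [c] shared, [d] residual
  vv <- vegan::varpart(inst$Yt, inst$X, inst$W)$part$indfract$Adj.R.square
  expect_equal(vp$frac_a, vv[1], tolerance = 1e-6)
  expect_equal(vp$frac_c, vv[2], tolerance = 1e-6)
  expect_equal(vp$frac_b, vv[3], tolerance = 1e-6)
  expect_equal(vp$frac_d, vv[4], tolerance = 1e-6)
})
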