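test_that("rank_species orders by abundance with deterministic tie-breaks", {
  Y <- matrix(c(1, 1, 1,   5, 5, 0,   0, 1, 0), 3, 3,
              dimnames = list(paste0("s", 1:3), c("sp1", "sp2", "sp3")))
  r <- rank_species(Y)  # totals 3, 10, 1
  expect_equal(r$species_ids, c("sp3", "sp1", "sp2"))

  # equal totals: lower occupancy ranks rarer
  Y2 <- matrix(c(6, 0, 0,   2, 2, 2), 3, 2,
               dimnames = list(paste0("s", 1:3), c("a", "b")))
  expect_equal(rank_species(Y2)$species_ids, c("a", "b"))
  expect_equal(length(rank_species(Y2)$ties), 1L)

  # equal totals and occupancy: label order
  Y3 <- matrix(c(1, 2, 2, 1), 2, 2,
               dimnames = list(paste0("s", 1:2), c("zz", "aa")))
  expect_equal(rank_species(Y3)$species_ids, c("aa", "zz"))

  # all-zero species is rarest of all
  Y4 <- cbind(Y, none = c(0, 0, 0))
  expect_equal(rank_species(Y4)$species_ids[1], "none")

  # occupancy criterion
  Y5 <- matrix(c(9, 0, 0,   1, 1, 1), 3, 2,
               dimnames = list(paste0("s", 1:3), c("dense", "sparse")))
  expect_equal(rank_species(Y5, "occupancy")$species_ids, c("dense", "sparse"))
})

test_that("run_cascade reproduces varpart2 step by step (slice oracle)", {
  Y <- tiny_community(13, n = 15, S = 12)
  set.seed(13)
  X <- matrix(rnorm(30), 15); W <- matrix(rnorm(30), 15)
  cfg <- run_config(transform = "none")
  tr <- run_cascade(Y, X, W, "remove_rare_first", cfg)

  # step 0 identical to varpart2 on the full community
  vp0 <- varpart2(transform_response(Y, "none"), X, W)
  expect_identical(tr$steps[[1]]$varpart$frac_a, vp0$frac_a)
  expect_identical(tr$steps[[1]]$varpart$r2_full, vp0$r2_full)

  # every step equals an independent slice + varpart2 call, bitwise
  rk <- rank_species(Y)
  for (s in 1:tr$max_steps) {
    drop <- rk$species_ids[seq_len(s)]
    Ys <- unclass(Y)[, setdiff(colnames(Y), drop), drop = FALSE]
    vps <- varpart2(transform_response(Ys, "none"), X, W)
    expect_identical(tr$steps[[s + 1]]$varpart$frac_d, vps$frac_d)
    expect_identical(tr$steps[[s + 1]]$varpart$r2_env, vps$r2_env)
  }

  # trace-shape invariants
  expect_equal(tr$max_steps, floor(0.5 * 12))
  expect_length(tr$steps, tr$max_steps + 1)
  expect_equal(vapply(tr$steps, function(s) length(s$removed), 1L),
               0:tr$max_steps)

  # common-first removes the reverse ranking
  tc <- run_cascade(Y, X, W, "remove_common_first", cfg)
  expect_equal(tc$steps[[2]]$removed,
               rk$species_ids[length(rk$species_ids)])
})

test_that("removing an all-zero species leaves unadjusted R2 unchanged", {
  Y <- tiny_community(5, n = 12, S = 6)
  Yz <- cbind(unclass(Y), aaa0 = 0)  # all-zero column ranked rarest
  set.seed(5)
  X <- matrix(rnorm(24), 12); W <- matrix(rnorm(24), 12)
  cfg <- run_config(transform = "none")
  tr <- run_cascade(Yz, X, W, "remove_rare_first", cfg)
  expect_equal(tr$steps[[1]]$removed, character(0))
  expect_equal(tr$steps[[2]]$removed, "aaa0")
  expect_equal(tr$steps[[2]]$varpart$r2_env, tr$steps[[1]]$varpart$r2_env,
               tolerance = 1e-12)
  expect_equal(tr$steps[[2]]$varpart$r2_full, tr$steps[[1]]$varpart$r2_full,
               tolerance = 1e-12)
})

test_that("hellinger cascades re-transform the reduced matrix at each step", {
  Y <- tiny_community(9, n = 15, S = 10)
  set.seed(9)
  X <- matrix(rnorm(30), 15); W <- matrix(rnorm(30), 15)
  tr <- run_cascade(Y, X, W, "remove_rare_first", run_config())
  s3 <- tr$steps[[4]]
  keep <- setdiff(colnames(Y), s3$removed)
  vp <- varpart2(transform_response(unclass(Y)[, keep], "hellinger"), X, W)
  expect_equal(s3$varpart$frac_a, vp$frac_a, tolerance = 1e-14)
})

test_that("delta_r2 subtracts final from reference with the right sign", {
  Y <- tiny_community(21, n = 14, S = 8)
  set.seed(21)
  X <- matrix(rnorm(28), 14); W <- matrix(rnorm(28), 14)
  tr <- run_cascade(Y, X, W, "remove_rare_first", run_config())
  first <- tr$steps[[1]]$varpart
  last <- tr$steps[[length(tr$steps)]]$varpart
  expect_equal(delta_r2(tr, "frac_d"), first$frac_d - last$frac_d)
  expect_equal(delta_r2(tr, "explained_total"),
               (first$frac_a + first$frac_b + first$frac_c) -
               (last$frac_a + last$frac_b + last$frac_c))
  # complement symmetry: explained_total delta = -frac_d delta
  expect_equal(delta_r2(tr, "explained_total"), -delta_r2(tr, "frac_d"),
               tolerance = 1e-12)
  expect_equal(delta_r2(tr, "frac_a"), first$frac_a - last$frac_a)

  broken <- tr; broken$steps <- broken$steps[1:2]
  expect_error(delta_r2(broken), "incomplete")
})

test_that("simpson_dominance matches hand-computed values", {
  Y <- matrix(c(5, 0, 0,  0, 5, 0), 3, 2)
  expect_equal(simpson_dominance(Y)$simpson, 0.5)
  Y1 <- matrix(c(2, 1, 4), 3, 1)
  expect_equal(simpson_dominance(Y1)$simpson, 1)
  Y4 <- matrix(1, 4, 4) / 4
  expect_equal(simpson_dominance(Y4)$simpson, 0.25)
  expect_equal(unname(simpson_dominance(Y)$rank_abundance), c(5, 5))
  expect_error(simpson_dominance(matrix(0, 3, 2)), "all-zero")
  # bounds: 1/S <= simpson <= 1
  Yr <- tiny_community(3, n = 8, S = 10)
  lam <- simpson_dominance(Yr)$simpson
  expect_gte(lam, 1 / 10)
  expect_lte(lam, 1)
})

test_that("exchangeable communities give direction-symmetric deltas", {
  # species i.i.d. with equal expected abundance: rarity order is noise, so
  # rare-first and common-first deltas should be statistically alike
  deltas <- vapply(1:60, function(seed) {
    sim <- simulate_metacommunity(n_sites = 30, n_species = 14, n_vars = 8,
                                  n_latent = 2, scenario = "exchangeable",
                                  seed = 1000 + seed)
    set.seed(seed)
    X <- matrix(rnorm(60), 30); W <- matrix(rnorm(60), 30)
    cfg <- run_config(seed = seed)
    c(delta_r2(run_cascade(sim$community, X, W, "remove_rare_first", cfg)),
      delta_r2(run_cascade(sim$community, X, W, "remove_common_first", cfg)))
  }, numeric(2))
  wt <- wilcox.test(deltas[1, ], deltas[2, ])
  expect_gt(wt$p.value, 0.01)
})
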