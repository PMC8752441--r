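test_that("reduce_block clips, orthogonalizes and matches the eigen oracle", {
  set.seed(1)
  X5 <- matrix(rnorm(200 * 5), 200, 5)
  rb <- reduce_block(X5, k = 20)
  expect_equal(ncol(rb$scores), 5)            # clipped to p
  expect_equal(rb$var_explained, 1, tolerance = 1e-12)
  cc <- cor(rb$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)

  # synthetic soil-like block: captured variance of 20 components equals the
  # top-20 eigenvalue share of the correlation matrix
  set.seed(2)
  F5 <- matrix(rnorm(220 * 5), 220, 5)
  X <- F5 %*% matrix(rnorm(5 * 107), 5, 107) + matrix(rnorm(220 * 107, sd = 0.4), 220, 107)
  rb20 <- reduce_block(X, k = 20)
  expect_equal(ncol(rb20$scores), 20)
  ev <- eigen(cor(X), symmetric = TRUE)$values
  expect_equal(rb20$var_explained, sum(ev[1:20]) / sum(ev), tolerance = 1e-8)

  expect_warning(reduce_block(cbind(X5, const = 1)), "constant")
})

test_that("cv_holdout_r2 at lambda 0 equals the OLS holdout oracle", {
  set.seed(3)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(40, sd = 0.8)
  fold <- rep(1:10, each = 4)
  spec <- ridge_spec(lambda_grid = 0, repetitions = 1, outer_folds = 10, seed = 1)
  out <- cv_holdout_r2(X, y, spec, outer_assignments = list(fold))
  expect_equal(out$mean, oracle_ols_holdout_r2(X, y, fold), tolerance = 1e-10)
})

test_that("cv_holdout_r2 behaves at the noiseless and null limits", {
  set.seed(4)
  X <- matrix(rnorm(200 * 2), 200, 2)
  y <- drop(X %*% c(2, -1))
  spec <- ridge_spec(repetitions = 2, n_lambda = 40, seed = 2)
  expect_gt(cv_holdout_r2(X, y, spec)$mean, 0.999)

  y0 <- rnorm(200)
  spec0 <- ridge_spec(repetitions = 10, n_lambda = 30, seed = 3)
  expect_lt(cv_holdout_r2(matrix(rnorm(200 * 5), 200, 5), y0, spec0)$mean, 0.05)

  # constant response: correlation undefined -> r2 = 0 with a flag
  outc <- cv_holdout_r2(X, rep(1, 200), ridge_spec(repetitions = 1, seed = 4))
  expect_equal(outc$mean, 0)
  expect_true(all(outc$flags))

  expect_error(cv_holdout_r2(X[1:10, ], y[1:10], spec), "n = 10")
})

test_that("partition_variance reproduces published decomposition rows exactly", {
  # seed-length row: r2 both 0.40, climate 0.41, soil 0.32
  p <- partition_variance(0.40, 0.41, 0.32)
  expect_equal(p$joint, 0.33, tolerance = 1e-12)
  expect_equal(p$independent_climate, 0.08, tolerance = 1e-12)
  expect_equal(p$independent_soil, -0.01, tolerance = 1e-12)
  # fully redundant blocks
  p2 <- partition_variance(0.5, 0.5, 0.5)
  expect_equal(unlist(p2), c(joint = 0.5, independent_climate = 0,
                             independent_soil = 0))
  # soil uninformative
  p3 <- partition_variance(0.37, 0.37, 0)
  expect_equal(unlist(p3), c(joint = 0, independent_climate = 0.37,
                             independent_soil = 0))
  # vectorized identities hold to 1e-12 on random triples
  set.seed(5)
  rb <- runif(50); rc <- runif(50); rs <- runif(50)
  pp <- partition_variance(rb, rc, rs)
  expect_equal(pp$independent_climate + pp$independent_soil + pp$joint, rb,
               tolerance = 1e-12)
  expect_equal(pp$independent_climate + pp$joint, rc, tolerance = 1e-12)
  expect_equal(pp$independent_soil + pp$joint, rs, tolerance = 1e-12)
})

test_that("display shares split the joint effect and hide negative effects", {
  d <- display_shares(0.47, 0.13, 0.03)
  expect_equal(d$display_climate, 0.365, tolerance = 1e-12)
  expect_equal(d$display_soil, 0.265, tolerance = 1e-12)
  expect_equal(d$display_climate + d$display_soil, 0.63, tolerance = 1e-12)
  # negative independent soil: its bar shows only the joint half
  dn <- display_shares(0.33, 0.08, -0.01)
  expect_equal(dn$display_soil, 0.165, tolerance = 1e-12)
  expect_equal(dn$display_climate, 0.245, tolerance = 1e-12)
})

test_that("partition_table keeps exact identities and recovers the driver ordering", {
  wd <- simulate_world(world_config(n_species = 400, n_ecoregions = 60,
                                    shared_latent_weight = 0, mean_occupancy = 5,
                                    seed = 17))
  a1 <- species_medians(wd$observations)
  tc <- attr(a1, "trait_cols")
  a2 <- ecoregion_medians(a1, wd$ecoregions, min_species = 3, min_fraction = 1e-4)$a2
  env <- aggregate_environment(wd$observations, wd$environment)
  env <- env[match(a2$ecoregion, env$ecoregion), ]
  keep <- c("height", "seed_mass", "SLA", "leaf_P")
  spec <- ridge_spec(repetitions = 3, n_lambda = 25, seed = 6)
  pt <- partition_table(as.matrix(a2[, keep]),
                        env[, attr(wd$environment, "climate_cols")],
                        env[, attr(wd$environment, "soil_cols")], spec)
  # identities exact per repetition
  for (tr in keep) {
    pr <- pt$per_rep[[tr]]
    dec <- partition_variance(pr$r2_both, pr$r2_climate, pr$r2_soil)
    expect_equal(dec$independent_climate + dec$independent_soil + dec$joint,
                 pr$r2_both, tolerance = 1e-12)
  }
  tab <- pt$table
  expect_equal(tab$independent_climate + tab$independent_soil + tab$joint,
               tab$r2_both, tolerance = 1e-12)
  expect_true(all(tab$r2_both_min <= tab$r2_both & tab$r2_both <= tab$r2_both_max))
  # size traits climate-led, economics traits soil-led at w = 0
  for (tr in c("height", "seed_mass")) {
    expect_gt(tab$independent_climate[tab$trait == tr],
              tab$independent_soil[tab$trait == tr])
  }
  for (tr in c("SLA", "leaf_P")) {
    expect_gt(tab$independent_soil[tab$trait == tr],
              tab$independent_climate[tab$trait == tr])
  }
})

test_that("climate-driven traits show independent climate effects across seeds", {
  # one size trait, shared_latent_weight 0: independent climate effect should
  # dominate and the joint effect stay small, across seeds
  wins <- 0L
  for (s in 1:10) {
    wd <- simulate_world(world_config(n_species = 400, n_ecoregions = 100,
                                      shared_latent_weight = 0, mean_occupancy = 5,
                                      seed = 200 + s))
    a1 <- species_medians(wd$observations)
    a2 <- ecoregion_medians(a1, wd$ecoregions, min_species = 2, min_fraction = 1e-4)$a2
    env <- aggregate_environment(wd$observations, wd$environment)
    env <- env[match(a2$ecoregion, env$ecoregion), ]
    spec <- ridge_spec(repetitions = 2, n_lambda = 20, seed = s)
    pt <- partition_table(as.matrix(a2[, "height", drop = FALSE]),
                          env[, attr(wd$environment, "climate_cols")],
                          env[, attr(wd$environment, "soil_cols")], spec)
    tb <- pt$table
    ok <- tb$independent_climate > tb$independent_soil &
      tb$joint < tb$independent_climate
    wins <- wins + as.integer(ok)
  }
  expect_equal(wins, 10L)
})
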