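test_that("world_config validates fields and names the offender", {
  expect_error(world_config(n_species = 0), "n_species")
  expect_error(world_config(shared_latent_weight = 2), "shared_latent_weight")
  expect_error(world_config(missing_rate = 1), "missing_rate")
  expect_error(world_config(trait_noise_sd = -1), "trait_noise_sd")
  expect_error(world_config(n_traits = 3, size_loadings = c(1, 0)), "size_loadings")
  cfg <- world_config()
  expect_s3_class(cfg, "world_config")
  expect_length(cfg$trait_names, 17)
  expect_identical(cfg$signed_trait, "leaf_d15N")
})

test_that("fixed seed gives bit-identical worlds", {
  cfg <- world_config(n_species = 60, n_ecoregions = 15, seed = 9,
                      missing_rate = 0.1)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1$observations, w2$observations)
  expect_identical(w1$environment, w2$environment)
  expect_identical(w1$ecoregions, w2$ecoregions)
  expect_identical(w1$truth$L, w2$truth$L)
})

test_that("noise-free single size trait reproduces the size score exactly", {
  cfg <- world_config(n_species = 100, n_ecoregions = 20, n_traits = 1,
                      trait_names = "t1", size_loadings = 1, econ_loadings = 0,
                      signed_trait = NA_character_,
                      trait_noise_sd = 0, taxonomy_sd = 0, seed = 3)
  w <- simulate_world(cfg)
  sc <- w$truth$size_score[match(w$observations$species, w$truth$species)]
  expect_equal(abs(cor(log(w$observations$t1), sc)), 1, tolerance = 1e-12)
})

test_that("shared_latent_weight = 1 with zero soil noise ties soil to L", {
  cfg <- world_config(n_species = 5, n_ecoregions = 200, shared_latent_weight = 1,
                      soil_noise_sd = 0, locations_per_ecoregion = 1, seed = 4)
  w <- simulate_world(cfg)
  env <- w$environment
  Lloc <- w$truth$L[match(env$ecoregion, w$truth$ecoregion)]
  for (j in attr(env, "soil_cols")[c(1, 50, 107)]) {
    expect_equal(abs(cor(env[[j]], Lloc)), 1, tolerance = 1e-10)
  }
})

test_that("cross-block correlation matches the closed form at w = 0.5", {
  # generator: climate_i = a_i L + e(sd s_c), soil_j = c_j (sqrt(w) L +
  # sqrt(1-w) F) + e(sd s_s) with L, F unit variance and orthogonal, so
  # corr(climate_i, soil_j) = a_i c_j sqrt(w) / sqrt((a_i^2+s_c^2)(c_j^2+s_s^2))
  sc <- 0.3; ss <- 0.3; w <- 0.5
  cfg <- world_config(n_species = 5, n_ecoregions = 2000, shared_latent_weight = w,
                      climate_noise_sd = sc, soil_noise_sd = ss,
                      locations_per_ecoregion = 1, seed = 8)
  wd <- simulate_world(cfg)
  env <- wd$environment
  a <- wd$truth$climate_loadings
  cc <- wd$truth$soil_loadings
  for (ij in list(c(1, 1), c(5, 30), c(12, 80))) {
    i <- ij[1]; j <- ij[2]
    expected <- a[i] * cc[j] * sqrt(w) /
      sqrt((a[i]^2 + sc^2) * (cc[j]^2 + ss^2))
    emp <- cor(env[[attr(env, "climate_cols")[i]]], env[[attr(env, "soil_cols")[j]]])
    expect_equal(emp, expected, tolerance = 0.07)
  }
})

test_that("cross-block correlation is monotone in shared_latent_weight", {
  mean_abs_cor <- function(w) {
    wd <- simulate_world(world_config(n_species = 5, n_ecoregions = 500,
                                      shared_latent_weight = w,
                                      locations_per_ecoregion = 1, seed = 21))
    env <- wd$environment
    cm <- cor(as.matrix(env[, attr(env, "climate_cols")[1:8]]),
              as.matrix(env[, attr(env, "soil_cols")[1:8]]))
    mean(abs(cm))
  }
  v <- vapply(c(0, 0.5, 1), mean_abs_cor, 0)
  expect_lt(v[1], v[2])
  expect_lt(v[2], v[3])
})

test_that("size scores track absolute latitude as noise vanishes", {
  r2_at <- function(noise) {
    wd <- simulate_world(world_config(n_species = 300, n_ecoregions = 40,
                                      score_noise_sd = noise, seed = 12))
    home_lat <- wd$truth$latitude[match(wd$truth$home_ecoregion, wd$truth$ecoregion)]
    summary(lm(wd$truth$size_score ~ abs(home_lat)))$r.squared
  }
  # noise 0 is an exact fit; summary.lm warns about it, which is the point
  expect_equal(suppressWarnings(r2_at(0)), 1, tolerance = 1e-10)
  expect_gt(r2_at(0.1), 0.95)
})

test_that("inject_missingness respects rate and the one-per-row/column floor", {
  set.seed(1)
  x <- matrix(exp(rnorm(1000 * 17)), 1000, 17,
              dimnames = list(NULL, sprintf("t%02d", 1:17)))
  df <- as_trait_df(x)
  expect_identical(inject_missingness(df, 0, seed = 1), df)
  expect_error(inject_missingness(df, 1, seed = 1), "rate")

  out <- inject_missingness(df, 0.2, seed = 7)
  m <- as.matrix(out[, attr(out, "trait_cols")])
  frac <- mean(is.na(m))
  se <- sqrt(0.2 * 0.8 / length(m))
  expect_lt(abs(frac - 0.2), 3 * se + 1 / length(m))
  expect_true(all(rowSums(!is.na(m)) >= 1))
  expect_true(all(colSums(!is.na(m)) >= 1))
  # deterministic under seed
  out2 <- inject_missingness(df, 0.2, seed = 7)
  expect_identical(out, out2)
})

test_that("truth_summary labels groups and expected drivers", {
  ts_at <- function(w) {
    truth_summary(simulate_world(world_config(n_species = 20, n_ecoregions = 5,
                                              shared_latent_weight = w,
                                              seed = 2))$truth)
  }
  ts0 <- ts_at(0)
  expect_identical(unique(ts0$expected_driver[ts0$group == "size"]), "climate")
  expect_identical(unique(ts0$expected_driver[ts0$group == "economics"]), "soil-independent")
  expect_identical(unique(ts0$expected_driver[ts0$group == "other"]), "none")
  expect_identical(unique(ts_at(1)$expected_driver[ts0$group == "economics"]), "joint")
  expect_identical(unique(ts_at(0.5)$expected_driver[ts0$group == "economics"]), "mixed")
})

test_that("topsoil flag marks exactly the depth-0 layer", {
  w <- simulate_world(world_config(n_species = 5, n_ecoregions = 5, seed = 1))
  env <- w$environment
  top <- attr(env, "topsoil_cols")
  expect_true(all(grepl("_d000$", top)))
  expect_identical(sort(top),
                   sort(grep("_d000$", attr(env, "soil_cols"), value = TRUE)))
})

test_that("world tables round-trip through delimited text", {
  w <- simulate_world(world_config(n_species = 30, n_ecoregions = 8, seed = 5,
                                   missing_rate = 0.1))
  dir <- tempfile("world")
  write_world(w, dir)
  back <- read_world(dir)
  expect_equal(back$observations$species, w$observations$species)
  m0 <- as.matrix(w$observations[, attr(w$observations, "trait_cols")])
  m1 <- as.matrix(back$observations[, attr(back$observations, "trait_cols")])
  expect_equal(unname(m1), unname(m0), tolerance = 1e-12)
  expect_identical(attr(back$environment, "topsoil_cols"),
                   attr(w$environment, "topsoil_cols"))
  expect_error(read_world(tempfile("nope")), "not found")
})
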