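test_that("correlation_matrix matches the direct Pearson formula", {
  set.seed(1)
  x <- matrix(exp(rnorm(15)), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  r <- correlation_matrix(x)
  expect_equal(unname(diag(r)), rep(1, 3))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(r[i, j], abs(oracle_pearson(log(x[, i]), log(x[, j]))),
                 tolerance = 1e-12)
  }
  # perfect anticorrelation on the log scale
  y <- cbind(a = exp(1:6), b = exp(-2 * (1:6)))
  expect_equal(correlation_matrix(y)["a", "b"], 1, tolerance = 1e-12)
  expect_error(correlation_matrix(cbind(a = exp(1:5), b = rep(2.7, 5))), "'b'")
})

test_that("complete-linkage clustering matches an exhaustive oracle", {
  # perfectly correlated pair: distance 0, same group
  r <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  cl <- cluster_traits(r)
  expect_equal(cl$heights, 0)
  expect_equal(unname(cl$groups), c(1, 1))
  # uncorrelated pair: distance 1, separate groups at cut 1.0
  r0 <- diag(2); dimnames(r0) <- list(c("a", "b"), c("a", "b"))
  cl0 <- cluster_traits(r0)
  expect_equal(cl0$heights, 1)
  expect_equal(length(unique(cl0$groups)), 2)

  # block structure: within-block |r| = 0.8/0.75, between blocks 0, so the
  # between-block merge sits exactly at height 1 and the strict cut splits it
  r4 <- diag(4)
  r4[1, 2] <- r4[2, 1] <- 0.8
  r4[3, 4] <- r4[4, 3] <- 0.75
  dimnames(r4) <- list(letters[1:4], letters[1:4])
  cl4 <- cluster_traits(r4)
  orc <- oracle_complete_linkage(1 - r4, cut = 1.0)
  expect_equal(sort(cl4$heights), sort(orc$heights), tolerance = 1e-12)
  expect_equal(length(unique(cl4$groups)), length(unique(orc$groups)))
  expect_equal(unname(cl4$groups[c("a", "b")][1]), unname(cl4$groups[c("a", "b")][2]))
  expect_false(cl4$groups[["a"]] == cl4$groups[["c"]])
  # invariant to trait input order
  perm <- c(3, 1, 4, 2)
  cl4p <- cluster_traits(r4[perm, perm])
  expect_equal(sort(cl4p$heights), sort(cl4$heights), tolerance = 1e-12)
  expect_equal(cl4p$groups[letters[1:4]][["a"]] == cl4p$groups[letters[1:4]][["b"]], TRUE)
})

test_that("pca_traits matches the eigen-decomposition oracle", {
  set.seed(2)
  x <- matrix(exp(matrix(rnorm(250), 50, 5) %*% diag(5) +
                    rnorm(250, sd = 0.1)), 50, 5,
              dimnames = list(NULL, paste0("t", 1:5)))
  pc <- pca_traits(x)
  ev <- eigen(cor(log(x)), symmetric = TRUE)$values
  expect_equal(unname(pc$var_fraction), ev / sum(ev), tolerance = 1e-10)
  # scores of distinct components are uncorrelated
  cc <- cor(pc$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(pc$loadings))) {
    v <- pc$loadings[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # rank-1 case: two perfectly correlated traits
  z <- exp(rnorm(30)); pc1 <- pca_traits(cbind(a = z, b = z^2))
  expect_equal(unname(pc1$var_fraction[1]), 1, tolerance = 1e-12)
  # isotropy: p independent traits -> fractions near 1/p
  set.seed(3)
  xi <- matrix(exp(rnorm(4 * 5000)), 5000, 4, dimnames = list(NULL, paste0("t", 1:4)))
  expect_equal(unname(pca_traits(xi)$var_fraction), rep(0.25, 4), tolerance = 0.05)
  expect_error(pca_traits(cbind(a = c(1, NA, 2))), "missing")
})

test_that("significant_axes finds constructed rank and rejects bad alpha", {
  expect_error(significant_axes(matrix(exp(rnorm(40)), 10, 4), alpha = 1.5), "alpha")
  set.seed(4)
  n <- 150
  f1 <- rnorm(n); f2 <- rnorm(n)
  load1 <- c(1, 1, 1, 0, 0, 0); load2 <- c(0, 0, 0, 1, 1, 1)
  x <- exp(outer(f1, load1) + outer(f2, load2) + matrix(rnorm(n * 6, sd = 0.05), n, 6))
  colnames(x) <- paste0("t", 1:6)
  expect_equal(significant_axes(x, n_perm = 199, alpha = 0.05, seed = 1), 2)
  # pure noise: no dominant structure
  for (s in 1:3) {
    set.seed(100 + s)
    xn <- matrix(exp(rnorm(80 * 6)), 80, 6, dimnames = list(NULL, paste0("t", 1:6)))
    expect_lte(significant_axes(xn, n_perm = 120, alpha = 0.05, seed = s), 1)
  }
  expect_warning(significant_axes(x, n_perm = 50, alpha = 0.05, seed = 1), "n_perm")
})

test_that("latitude_fit reproduces OLS at both levels", {
  lat <- runif(400, -65, 65)
  # exact linearity ("perfect fit" warnings from summary.lm are expected)
  f <- suppressWarnings(latitude_fit(2 * abs(lat), lat))
  expect_equal(f$species$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$binned$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$species$slope, 2, tolerance = 1e-12)
  # null case
  set.seed(5)
  f0 <- latitude_fit(rnorm(2000), runif(2000, -65, 65))
  expect_lt(f0$species$r_squared, 0.01)
  # noisy linear signal: binning averages noise out
  set.seed(6)
  sig <- abs(lat); y <- sig + rnorm(400, sd = 0.5 * sd(sig))
  fn <- latitude_fit(y, lat)
  expect_gt(fn$binned$r_squared, fn$species$r_squared)
  # direct least-squares oracle at both levels
  expect_equal(fn$species$r_squared, summary(lm(y ~ abs(lat)))$r.squared,
               tolerance = 1e-12)
  b <- floor(abs(lat))
  expect_equal(fn$binned$r_squared,
               summary(lm(tapply(y, b, mean) ~ tapply(abs(lat), b, mean)))$r.squared,
               tolerance = 1e-12)
  expect_error(latitude_fit(c(1, 2, 3), c(5, 5, 5)), "distinct")
})

test_that("size and economics axes separate along latitude in a synthetic world", {
  wd <- simulate_world(world_config(n_species = 800, n_ecoregions = 120,
                                    shared_latent_weight = 0, mean_occupancy = 5,
                                    seed = 31))
  a1 <- species_medians(wd$observations)
  tc <- attr(a1, "trait_cols")
  pca <- pca_traits(as.matrix(a1[, tc]), signed_traits = "leaf_d15N")
  ts <- truth_summary(wd$truth)
  cl <- sweep(pca$loadings, 2, pca$sdev, "*")
  szpc <- which.max(colSums(cl[ts$trait[ts$group == "size"], , drop = FALSE]^2))
  ecpc <- which.max(colSums(cl[ts$trait[ts$group == "economics"], , drop = FALSE]^2) *
                      (seq_along(pca$sdev) != szpc))
  lsz <- latitude_fit(pca$scores[, szpc], a1$latitude)
  lec <- latitude_fit(pca$scores[, ecpc], a1$latitude)
  expect_gt(lsz$binned$r_squared, 0.5)
  expect_lt(lec$binned$r_squared, 0.1)
})
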