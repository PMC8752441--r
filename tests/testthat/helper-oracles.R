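# Independent oracle implementations used to check the package's code paths.
# These are deliberately naive (direct formulas, exhaustive loops) and share
# no code with the package internals.

# Pearson correlation straight from the formula.
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Exhaustive complete-linkage agglomeration on a distance matrix.
# Returns merge heights in order and the final grouping when cutting strictly
# below `cut`.
oracle_complete_linkage <- function(d, cut = 1.0) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  cluster_dist <- function(a, b) max(d[a, b])
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- cluster_dist(clusters[[i]], clusters[[j]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  # regroup: repeat agglomeration but stop at merges >= cut
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- cluster_dist(clusters[[i]], clusters[[j]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    if (best_h >= cut) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  groups <- integer(n)
  for (g in seq_along(clusters)) groups[clusters[[g]]] <- g
  list(heights = heights, groups = groups)
}

# OLS-based holdout r-squared: per outer fold, ordinary lm on the training
# rows, predict the held-out rows, then square the correlation of the
# concatenated predictions with the observations.
oracle_ols_holdout_r2 <- function(X, y, fold) {
  pred <- numeric(length(y))
  df <- data.frame(y = y, X)
  for (f in sort(unique(fold))) {
    fit <- lm(y ~ ., data = df[fold != f, , drop = FALSE])
    pred[fold == f] <- predict(fit, newdata = df[fold == f, , drop = FALSE])
  }
  cor(pred, y)^2
}

# VIF by regressing each predictor on all the others with lm().
oracle_vif <- function(X) {
  X <- as.data.frame(X)
  vapply(seq_along(X), function(j) {
    r2 <- summary(lm(X[[j]] ~ ., data = X[-j]))$r.squared
    1 / (1 - r2)
  }, 0)
}

# Two-step RDA oracle: per-trait OLS fitted values, then eigen-decomposition
# of the fitted-value covariance matrix.
oracle_rda_eigenvalues <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = TRUE)
  fitted <- sapply(seq_len(ncol(Yc)), function(j) lm(Yc[, j] ~ Xc)$fitted.values)
  ev <- eigen(cov(fitted), symmetric = TRUE)$values
  ev[ev > max(ev) * 1e-10]
}

# Low-rank lognormal trait matrix with known log-scale truth.
make_rank_k <- function(n, p, k, scale = 0.6, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  U <- matrix(rnorm(n * k), n, k)
  V <- matrix(rnorm(p * k), p, k)
  lt <- U %*% t(V) * scale + matrix(rnorm(n * p, sd = noise_sd), n, p)
  x <- exp(lt)
  rownames(x) <- sprintf("sp%04d", seq_len(n))
  colnames(x) <- sprintf("t%02d", seq_len(p))
  list(x = x, log_truth = lt)
}

# Block taxonomy: species grouped into genera of size g, genera into
# families of size fg.
make_taxonomy <- function(n, g = 5, fg = 4) {
  genus <- sprintf("g%03d", ((seq_len(n) - 1) %/% g) + 1)
  n_gen <- length(unique(genus))
  fam_of_gen <- sprintf("f%03d", ((seq_len(n_gen) - 1) %/% fg) + 1)
  data.frame(species = sprintf("sp%04d", seq_len(n)),
             genus = genus,
             family = fam_of_gen[((seq_len(n) - 1) %/% g) + 1],
             stringsAsFactors = FALSE)
}

# Wrap a trait matrix as an observation-style data.frame for
# inject_missingness().
as_trait_df <- function(x) {
  df <- as.data.frame(x)
  attr(df, "trait_cols") <- colnames(x)
  df
}
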