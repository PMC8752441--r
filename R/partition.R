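# Climate/soil variance partitioning.
#
# Each trait (ecoregion level, natural-log scale) is regressed on three
# predictor sets - climate components only, soil components only, and both -
# with ridge regression; lambda is tuned by inner 10-fold cross-validation
# and the explained variance is the squared Pearson correlation of
# concatenated out-of-fold predictions versus observed values, repeated over
# re-randomized outer folds. With two predictor blocks, hierarchical
# partitioning reduces to inclusion-exclusion over the three fits:
#   joint               = r2_climate + r2_soil - r2_both
#   independent_climate = r2_both - r2_soil
#   independent_soil    = r2_both - r2_climate
# Independent effects can be negative (adding a block can reduce holdout
# explained variance).

#' Ridge regression and cross-validation settings
#'
#' @param lambda_grid explicit penalty grid, or `NULL` to derive a log-spaced
#'   grid of `n_lambda` values from the data (from `max |X'y|` on the
#'   standardized scale down by 4 decades). The penalty enters as
#'   `||y - Xb||^2 + lambda ||b||^2` with `X` standardized.
#' @param n_lambda grid size (default 100).
#' @param inner_folds folds for lambda selection (default 10).
#' @param outer_folds folds of the holdout loop (default 10).
#' @param repetitions number of repeats of the whole procedure (default 50).
#' @param block_size number of principal components each predictor block is
#'   reduced to (default 20).
#' @param seed integer seed.
#' @return a `ridge_spec` list.
#' @export
ridge_spec <- function(lambda_grid = NULL, n_lambda = 100L, inner_folds = 10L,
                       outer_folds = 10L, repetitions = 50L, block_size = 20L,
                       seed = 1L) {
  check_that(is.null(lambda_grid) || (is.numeric(lambda_grid) && all(lambda_grid >= 0)),
             "lambda_grid", "must be NULL or non-negative numeric")
  check_that(is_count(n_lambda), "n_lambda", "must be a count >= 1")
  check_that(is_count(inner_folds, min = 2L), "inner_folds", "must be >= 2")
  check_that(is_count(outer_folds, min = 2L), "outer_folds", "must be >= 2")
  check_that(is_count(repetitions), "repetitions", "must be >= 1")
  check_that(is_count(block_size), "block_size", "must be >= 1")
  check_that(is_count(seed, min = 0L), "seed", "must be a non-negative integer")
  structure(list(lambda_grid = lambda_grid, n_lambda = as.integer(n_lambda),
                 inner_folds = as.integer(inner_folds),
                 outer_folds = as.integer(outer_folds),
                 repetitions = as.integer(repetitions),
                 block_size = as.integer(block_size), seed = as.integer(seed)),
            class = "ridge_spec")
}

#' Reduce a predictor block to its leading principal components
#'
#' Standardizes the block internally (constant columns are dropped with a
#' warning) and returns the first `min(k, p, n-1)` component scores together
#' with the reduction map for reuse on new data.
#'
#' @param X predictor block (matrix or data.frame, >= 2 rows).
#' @param k target component count (default 20).
#' @return list: `scores` (n x k'), `map` (center, scale, rotation, kept
#'   columns), `var_explained` (fraction of block variance captured).
#' @export
reduce_block <- function(X, k = 20L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, ncol(X) >= 1)
  s <- apply(X, 2, sd)
  if (any(s == 0)) {
    warning(sprintf("dropping %d constant column(s) before PCA", sum(s == 0)))
    X <- X[, s > 0, drop = FALSE]
    if (!ncol(X)) stop("all columns constant", call. = FALSE)
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  kk <- min(k, ncol(X), nrow(X) - 1L)
  list(scores = pc$x[, seq_len(kk), drop = FALSE],
       map = list(center = pc$center, scale = pc$scale,
                  rotation = pc$rotation[, seq_len(kk), drop = FALSE],
                  kept = colnames(X)),
       var_explained = sum(pc$sdev[seq_len(kk)]^2) / sum(pc$sdev^2))
}

# Standardize training predictors; returns function to apply to new data.
.std_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}
.std_apply <- function(X, f) sweep(sweep(X, 2, f$center, "-"), 2, f$scale, "/")

# Ridge path via SVD of the standardized training matrix. Returns a
# prediction matrix (rows of Xte x lambdas). At lambda = 0 this is exactly
# the (min-norm) OLS prediction.
.ridge_predict <- function(Xtr, ytr, Xte, lambdas) {
  f <- .std_fit(Xtr)
  Xs <- .std_apply(Xtr, f)
  yb <- mean(ytr)
  yc <- ytr - yb
  sv <- svd(Xs)
  uy <- crossprod(sv$u, yc)          # d-length
  d <- sv$d
  keep <- d > max(d) * 1e-12
  Zte <- .std_apply(Xte, f) %*% sv$v  # n_te x d
  pred <- matrix(0, nrow(Xte), length(lambdas))
  for (li in seq_along(lambdas)) {
    w <- ifelse(keep | lambdas[li] > 0, d / (d^2 + lambdas[li]), 0)
    w[!keep & lambdas[li] == 0] <- 0
    pred[, li] <- Zte %*% (w * uy) + yb
  }
  pred
}

.default_lambda_grid <- function(X, y, n_lambda) {
  f <- .std_fit(X)
  Xs <- .std_apply(X, f)
  lmax <- max(abs(crossprod(Xs, y - mean(y))))
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = n_lambda))
}

.make_folds <- function(n, k) sample(rep(seq_len(k), length.out = n))

#' Cross-validated holdout r-squared of a ridge model
#'
#' Per repetition: the rows are split into `outer_folds`; within each
#' training set, lambda is chosen by `inner_folds`-fold cross-validation
#' (minimum mean squared error); the held-out 1/outer_folds of rows is
#' predicted; and out-of-fold predictions, concatenated over all outer folds,
#' are scored as `r^2 = cor(predicted, observed)^2`. Mean, minimum and
#' maximum over repetitions are reported. If the concatenated predictions are
#' constant (e.g. lambda driven to infinity), r-squared is reported as 0 and
#' flagged.
#'
#' @param X predictor matrix (component scores).
#' @param y response vector (natural-log trait values).
#' @param spec a [ridge_spec()].
#' @param outer_assignments optional list (length `repetitions`) of integer
#'   fold vectors, to share fold splits across models.
#' @return list: `mean`, `min`, `max`, `per_rep`, `flags` (constant
#'   predictions), `lambda` (chosen per repetition x outer fold).
#' @export
cv_holdout_r2 <- function(X, y, spec = ridge_spec(), outer_assignments = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y", call. = FALSE)
  if (n < 30) stop(sprintf("n = %d too small; need >= 30 (or reduce outer_folds below %d)",
                           n, spec$outer_folds), call. = FALSE)
  if (n < 2 * spec$outer_folds) {
    stop(sprintf("n = %d too small for %d outer folds; reduce outer_folds",
                 n, spec$outer_folds), call. = FALSE)
  }
  grid <- spec$lambda_grid
  if (is.null(grid)) grid <- .default_lambda_grid(X, y, spec$n_lambda)
  grid <- sort(grid, decreasing = TRUE)

  set.seed(spec$seed)
  if (is.null(outer_assignments)) {
    outer_assignments <- lapply(seq_len(spec$repetitions), function(r) .make_folds(n, spec$outer_folds))
  }
  stopifnot(length(outer_assignments) >= spec$repetitions)

  per_rep <- numeric(spec$repetitions)
  flags <- logical(spec$repetitions)
  lambda_chosen <- matrix(NA_real_, spec$repetitions, spec$outer_folds)
  for (r in seq_len(spec$repetitions)) {
    fold <- outer_assignments[[r]]
    pred <- numeric(n)
    for (f in sort(unique(fold))) {
      tr <- which(fold != f); te <- which(fold == f)
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      if (length(grid) > 1) {
        inner <- .make_folds(length(tr), spec$inner_folds)
        mse <- matrix(NA_real_, spec$inner_folds, length(grid))
        for (g in seq_len(spec$inner_folds)) {
          itr <- which(inner != g); ite <- which(inner == g)
          p <- .ridge_predict(Xtr[itr, , drop = FALSE], ytr[itr],
                              Xtr[ite, , drop = FALSE], grid)
          mse[g, ] <- colMeans((p - ytr[ite])^2)
        }
        lam <- grid[which.min(colMeans(mse))]
      } else {
        lam <- grid[1]
      }
      lambda_chosen[r, f] <- lam
      pred[te] <- .ridge_predict(Xtr, ytr, X[te, , drop = FALSE], lam)[, 1]
    }
    if (sd(pred) == 0 || sd(y) == 0) {
      per_rep[r] <- 0; flags[r] <- TRUE
    } else {
      per_rep[r] <- cor(pred, y)^2
    }
  }
  list(mean = mean(per_rep), min = min(per_rep), max = max(per_rep),
       per_rep = per_rep, flags = flags, lambda = lambda_chosen)
}

#' Hierarchical partition of explained variance over two predictor blocks
#'
#' Inclusion-exclusion decomposition of the three model r-squared values
#' into a joint effect and two independent effects. With exactly two
#' predictor groups the averaged-orderings formulation of hierarchical
#' partitioning collapses to these formulas, and the identities
#' `independent_climate + joint = r2_climate`,
#' `independent_soil + joint = r2_soil` and
#' `independent_climate + independent_soil + joint = r2_both` hold exactly.
#' Negative independent effects are legal (a block can reduce holdout
#' explained variance).
#'
#' @param r2_both,r2_climate,r2_soil r-squared of the combined and
#'   single-block models (vectors allowed; matched elementwise).
#' @return data.frame with `joint`, `independent_climate`, `independent_soil`.
#' @export
partition_variance <- function(r2_both, r2_climate, r2_soil) {
  data.frame(joint = r2_climate + r2_soil - r2_both,
             independent_climate = r2_both - r2_soil,
             independent_soil = r2_both - r2_climate)
}

#' Display shares of climate and soil (equal split of the joint effect)
#'
#' The joint effect is split equally among climate and soil; a negative
#' independent effect is not drawn, so the corresponding bar shows only its
#' joint half.
#'
#' @param joint,independent_climate,independent_soil partition components.
#' @return data.frame with `display_climate`, `display_soil`.
#' @export
display_shares <- function(joint, independent_climate, independent_soil) {
  data.frame(display_climate = pmax(independent_climate, 0) + joint / 2,
             display_soil = pmax(independent_soil, 0) + joint / 2)
}

#' Per-trait climate/soil partition table
#'
#' Reduces the climate and soil blocks to `block_size` principal components
#' each, then for every trait fits the climate-only, soil-only and combined
#' ridge models with shared outer-fold assignments per repetition (so the
#' decomposition identities are exact per repetition), and tabulates the
#' partition.
#'
#' @param traits ecoregion-level trait matrix (original scale; log applied
#'   internally except `signed_traits`).
#' @param climate,soil predictor blocks (rows matching `traits`).
#' @param spec a [ridge_spec()].
#' @param groups optional named character vector of trait group labels.
#' @param signed_traits traits exempt from the log transform.
#' @return list: `table` (one row per trait: r2 of the three models with
#'   mean/min/max, partition components, display shares), `per_rep` (raw
#'   per-repetition r2 triples per trait).
#' @export
partition_table <- function(traits, climate, soil, spec = ridge_spec(),
                            groups = NULL, signed_traits = character(0)) {
  traits <- as.matrix(traits)
  if (anyNA(traits)) stop("trait matrix has missing values", call. = FALSE)
  ly <- log_trait_matrix(traits, signed_traits = signed_traits)
  red_c <- reduce_block(climate, spec$block_size)
  red_s <- reduce_block(soil, spec$block_size)
  Sc <- red_c$scores; Ss <- red_s$scores
  Sb <- cbind(Sc, Ss)
  n <- nrow(traits)
  set.seed(spec$seed)
  assignments <- lapply(seq_len(spec$repetitions), function(r) .make_folds(n, spec$outer_folds))
  seeds <- spawn_seeds(spec$seed, 3L * ncol(traits))

  rows <- vector("list", ncol(traits))
  per_rep <- vector("list", ncol(traits))
  names(per_rep) <- colnames(traits)
  for (j in seq_len(ncol(traits))) {
    y <- ly[, j]
    sp <- function(k) { s <- spec; s$seed <- seeds[3L * (j - 1L) + k]; s }
    fit_c <- cv_holdout_r2(Sc, y, sp(1L), outer_assignments = assignments)
    fit_s <- cv_holdout_r2(Ss, y, sp(2L), outer_assignments = assignments)
    fit_b <- cv_holdout_r2(Sb, y, sp(3L), outer_assignments = assignments)
    part <- partition_variance(fit_b$per_rep, fit_c$per_rep, fit_s$per_rep)
    pm <- colMeans(part)
    disp <- display_shares(pm["joint"], pm["independent_climate"], pm["independent_soil"])
    rows[[j]] <- data.frame(
      trait = colnames(traits)[j],
      group = if (is.null(groups)) NA_character_ else unname(groups[colnames(traits)[j]]),
      r2_both = fit_b$mean, r2_both_min = fit_b$min, r2_both_max = fit_b$max,
      r2_climate = fit_c$mean, r2_climate_min = fit_c$min, r2_climate_max = fit_c$max,
      r2_soil = fit_s$mean, r2_soil_min = fit_s$min, r2_soil_max = fit_s$max,
      independent_soil = pm[["independent_soil"]],
      independent_climate = pm[["independent_climate"]],
      joint = pm[["joint"]],
      display_climate = disp$display_climate, display_soil = disp$display_soil,
      stringsAsFactors = FALSE
    )
    per_rep[[j]] <- data.frame(rep = seq_len(spec$repetitions),
                               r2_both = fit_b$per_rep, r2_climate = fit_c$per_rep,
                               r2_soil = fit_s$per_rep)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, per_rep = per_rep,
       reduction = list(climate = red_c, soil = red_s))
}
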