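# Quality control and gap-filling.
#
# Missing trait values are imputed by a hierarchical probabilistic matrix
# factorization: the species-by-trait matrix (zlog scale) is modelled as
# X[s,t] ~ N(u_s' v_t, 1/tau), with species latent vectors shrunk towards
# their genus mean, genus towards family, family towards a global mean
# (conjugate Gaussian chain, fixed hyper-variances). A Gibbs sampler yields
# posterior draws; imputations are the mean of thinned post-burn-in draws and
# the per-cell draw standard deviation is the prediction confidence.

#' zlog transform of trait values
#'
#' Standardizes each trait column: `z = (x - mean) / sd`, computed over
#' non-missing entries. Input is expected on the natural-log scale for
#' lognormal traits (use [log_trait_matrix()] upstream); the fitted transform
#' is stored so it can be inverted after imputation.
#'
#' @param x numeric matrix (rows = observations or species, columns = traits).
#' @return list with `z` (the standardized matrix) and `transform` (a
#'   `zlog_transform`: per-trait mean and sd).
#' @export
zlog <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("trait%02d", seq_len(ncol(x)))
  mu <- colMeans(x, na.rm = TRUE)
  s <- apply(x, 2, sd, na.rm = TRUE)
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 2)) {
    stop(sprintf("trait '%s' has fewer than 2 non-missing values",
                 colnames(x)[which(n_obs < 2)[1]]), call. = FALSE)
  }
  if (any(!is.finite(s)) || any(s == 0)) {
    bad <- colnames(x)[which(!is.finite(s) | s == 0)[1]]
    stop(sprintf("trait '%s' is constant (sd = 0); zlog undefined", bad), call. = FALSE)
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, s, "/")
  transform <- structure(list(mean = mu, sd = s), class = "zlog_transform")
  list(z = z, transform = transform)
}

#' Invert a zlog transform
#'
#' @param z standardized matrix (columns matching the transform).
#' @param transform a `zlog_transform` from [zlog()].
#' @return matrix on the pre-standardization (natural-log) scale.
#' @export
zlog_inverse <- function(z, transform) {
  stopifnot(inherits(transform, "zlog_transform"))
  z <- as.matrix(z)
  sweep(sweep(z, 2, transform$sd, "*"), 2, transform$mean, "+")
}

#' Z-score quality-control filter
#'
#' Cells with `|z| > 4` are set to missing and counted as excluded; cells
#' with `3 < |z| <= 4` are retained but flagged for plausibility checking.
#' The boundary is strict: `|z| = 4` exactly is retained.
#'
#' @param z standardized trait matrix (from [zlog()]).
#' @return list with `z` (filtered matrix), `report` (per-trait counts of
#'   excluded and flagged cells), and `flagged` (row/trait index of flagged
#'   cells).
#' @export
qc_filter <- function(z) {
  z <- as.matrix(z)
  az <- abs(z)
  excl <- !is.na(az) & az > 4
  flag <- !is.na(az) & az > 3 & az <= 4
  out <- z
  out[excl] <- NA
  report <- data.frame(
    trait = colnames(z),
    n_excluded = colSums(excl),
    n_flagged = colSums(flag),
    row.names = NULL, stringsAsFactors = FALSE
  )
  fl <- which(flag, arr.ind = TRUE)
  flagged <- data.frame(row = fl[, 1],
                        trait = colnames(z)[fl[, 2]],
                        z = z[flag], stringsAsFactors = FALSE)
  list(z = out, report = report, flagged = flagged)
}

#' Hierarchical matrix-factorization model settings
#'
#' @param rank latent dimension K (default 10).
#' @param noise_precision fixed observation-noise precision tau (default 4,
#'   i.e. residual variance 0.25 on the zlog scale).
#' @param prior_var fixed hyper-variance of each level of the latent
#'   hierarchy (species around genus, genus around family, family around the
#'   global mean, and of trait vectors), default 1.
#' @param max_iter maximum Gibbs iterations (default 1000).
#' @param burn_in discarded initial iterations (default 200).
#' @param thin retain every `thin`-th post-burn-in iteration (default 20).
#' @param patience consecutive iterations with stable validation RMSE that
#'   trigger early stopping (default 5).
#' @param stable_tol RMSE change below which an iteration counts as stable
#'   (default 1e-4). Set to 0 to disable early stopping.
#' @param split train/test/validation fractions of observed cells, summing
#'   to 1 (default 0.8/0.1/0.1). The test split is monitored and logged only;
#'   the validation split drives early stopping.
#' @param seed integer seed.
#' @return an `hpmf_model` list.
#' @export
hpmf_model <- function(rank = 10L, noise_precision = 4, prior_var = 1,
                       max_iter = 1000L, burn_in = 200L, thin = 20L,
                       patience = 5L, stable_tol = 1e-4,
                       split = c(train = 0.8, test = 0.1, validation = 0.1),
                       seed = 1L) {
  check_that(is_count(rank), "rank", "must be a count >= 1")
  check_that(is_real(noise_precision) && noise_precision > 0, "noise_precision", "must be > 0")
  check_that(is_real(prior_var) && prior_var > 0, "prior_var", "must be > 0")
  check_that(is_count(max_iter), "max_iter", "must be a count >= 1")
  check_that(is_count(burn_in, min = 0L) && burn_in < max_iter, "burn_in",
             "must be a count < max_iter")
  check_that(is_count(thin), "thin", "must be a count >= 1")
  check_that(is_count(patience), "patience", "must be a count >= 1")
  check_that(is_real(stable_tol, 0), "stable_tol", "must be >= 0")
  check_that(length(split) == 3 && all(split >= 0) && abs(sum(split) - 1) < 1e-8,
             "split", "must be three non-negative fractions summing to 1")
  check_that(is_count(seed, min = 0L), "seed", "must be a non-negative integer")
  structure(list(rank = as.integer(rank), noise_precision = noise_precision,
                 prior_var = prior_var, max_iter = as.integer(max_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 patience = as.integer(patience), stable_tol = stable_tol,
                 split = split, seed = as.integer(seed)),
            class = "hpmf_model")
}

# Gibbs update for one hierarchy of group means: children (n_child x K) are
# N(group mean, v I), group means are N(parent, v I). Returns sampled means.
.sample_group_means <- function(children, group_of, parent_of_group, n_groups,
                                v, K) {
  sums <- rowsum(children, group_of, reorder = TRUE)
  counts <- as.integer(table(factor(group_of, levels = seq_len(n_groups))))
  # rowsum drops empty groups; rebuild full matrix
  full <- matrix(0, n_groups, K)
  full[as.integer(rownames(sums)), ] <- sums
  prec <- counts + 1            # (n_child + 1)/v, v cancels in mean
  mean_ <- (full + parent_of_group) / prec
  mean_ + matrix(rnorm(n_groups * K, sd = sqrt(v / prec)), n_groups, K)
}

#' Gap-fill a trait matrix by hierarchical probabilistic matrix factorization
#'
#' Imputes missing cells of a species-by-trait (or observation-by-trait)
#' matrix using taxonomic structure: latent vectors of species are shrunk
#' towards genus means, genus towards family, family towards a global mean.
#' Values are zlog-standardized internally (natural-log first for lognormal
#' traits), sampled by Gibbs, and imputations are back-transformed to the
#' original scale. Observed cells pass through unchanged.
#'
#' @param x numeric matrix, rows named by species (or carrying `rownames`
#'   matching `taxonomy$species`); columns = traits; `NA` = missing. Values
#'   on the original (positive) scale unless listed in `signed_traits`.
#' @param taxonomy data.frame with columns `species`, `genus`, `family`
#'   (optionally `higher`, unused: the family level is already shrunk to a
#'   global mean). Must cover every row of `x`.
#' @param model an [hpmf_model()].
#' @param signed_traits trait names exempt from the natural-log transform.
#' @return list with `completed` (original scale, observed cells unchanged),
#'   `sd` (per-cell posterior draw sd on the zlog scale; `NA` where observed),
#'   and `report` (validation/test RMSE trajectories, retained draw count,
#'   early-stop flag, iterations run).
#' @export
gapfill <- function(x, taxonomy, model = hpmf_model(), signed_traits = character(0)) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("trait%02d", seq_len(ncol(x)))
  if (is.null(rownames(x))) stop("x must have rownames identifying species", call. = FALSE)
  if (any(!is.finite(x[!is.na(x)]))) stop("non-finite values in input", call. = FALSE)
  if (any(rowSums(!is.na(x)) == 0)) {
    stop("every row (species) needs at least one observed value", call. = FALSE)
  }
  if (any(colSums(!is.na(x)) == 0)) {
    stop("every column (trait) needs at least one observed value", call. = FALSE)
  }
  miss <- is.na(x)
  if (!any(miss)) {
    return(list(completed = x, sd = matrix(NA_real_, nrow(x), ncol(x),
                                           dimnames = dimnames(x)),
                report = list(n_draws = 0L, stopped_early = FALSE,
                              iterations = 0L, rmse_validation = numeric(0),
                              rmse_test = numeric(0))))
  }
  tx <- taxonomy[match(rownames(x), taxonomy$species), , drop = FALSE]
  if (anyNA(tx$species)) {
    stop("taxonomy does not cover all species in x", call. = FALSE)
  }

  lx <- log_trait_matrix(x, signed_traits = signed_traits)
  zl <- zlog(lx)
  z <- zl$z

  n <- nrow(z); p <- ncol(z); K <- model$rank
  v <- model$prior_var; tau <- model$noise_precision
  set.seed(model$seed)

  genus <- as.integer(factor(tx$genus))
  family_of_genus <- as.integer(factor(tx$family))[match(seq_len(max(genus)), genus)]
  n_gen <- max(genus); n_fam <- max(family_of_genus)

  obs_idx <- which(!miss)
  split_lab <- sample(c("train", "test", "validation"), length(obs_idx),
                      replace = TRUE, prob = model$split)
  train_idx <- obs_idx[split_lab == "train"]
  test_idx <- obs_idx[split_lab == "test"]
  val_idx <- obs_idx[split_lab == "validation"]
  if (!length(train_idx)) stop("no training cells after split", call. = FALSE)
  train_mask <- matrix(FALSE, n, p); train_mask[train_idx] <- TRUE

  # per-row / per-column observed (training) index lists
  row_obs <- lapply(seq_len(n), function(i) which(train_mask[i, ]))
  col_obs <- lapply(seq_len(p), function(j) which(train_mask[, j]))

  U <- matrix(rnorm(n * K, sd = 0.1), n, K)
  V <- matrix(rnorm(p * K, sd = 0.1), p, K)
  gen_mean <- matrix(0, n_gen, K)
  fam_mean <- matrix(0, n_fam, K)
  global_mean <- rep(0, K)
  Ik <- diag(K)

  rmse_at <- function(idx) {
    if (!length(idx)) return(NA_real_)
    pred <- rowSums(U[((idx - 1L) %% n) + 1L, , drop = FALSE] *
                      V[((idx - 1L) %/% n) + 1L, , drop = FALSE])
    sqrt(mean((z[idx] - pred)^2))
  }

  draw_sum <- matrix(0, n, p)
  draw_sumsq <- matrix(0, n, p)
  n_draws <- 0L
  rmse_val <- numeric(0); rmse_test <- numeric(0)
  stable_run <- 0L; stopped_early <- FALSE
  iter_done <- 0L

  for (iter in seq_len(model$max_iter)) {
    # species latents
    for (i in seq_len(n)) {
      jt <- row_obs[[i]]
      prior_mu <- gen_mean[genus[i], ]
      if (length(jt)) {
        Vj <- V[jt, , drop = FALSE]
        prec <- tau * crossprod(Vj) + Ik / v
        b <- tau * crossprod(Vj, z[i, jt]) + prior_mu / v
      } else {
        prec <- Ik / v
        b <- prior_mu / v
      }
      ch <- chol(prec)
      mu <- backsolve(ch, forwardsolve(t(ch), b))
      U[i, ] <- mu + backsolve(ch, rnorm(K))
    }
    # trait latents
    for (j in seq_len(p)) {
      it <- col_obs[[j]]
      if (length(it)) {
        Ui <- U[it, , drop = FALSE]
        prec <- tau * crossprod(Ui) + Ik / v
        b <- tau * crossprod(Ui, z[it, j])
      } else {
        prec <- Ik / v
        b <- rep(0, K)
      }
      ch <- chol(prec)
      mu <- backsolve(ch, forwardsolve(t(ch), b))
      V[j, ] <- mu + backsolve(ch, rnorm(K))
    }
    # hierarchy: genus <- species, family <- genus, global <- family
    gen_mean <- .sample_group_means(U, genus, fam_mean[family_of_genus, , drop = FALSE],
                                    n_gen, v, K)
    fam_mean <- .sample_group_means(gen_mean, family_of_genus,
                                    matrix(global_mean, n_fam, K, byrow = TRUE),
                                    n_fam, v, K)
    gm_prec <- n_fam + 1
    gm_mu <- colSums(fam_mean) / gm_prec
    global_mean <- gm_mu + rnorm(K, sd = sqrt(v / gm_prec))

    rv <- rmse_at(val_idx)
    rmse_val <- c(rmse_val, rv)
    rmse_test <- c(rmse_test, rmse_at(test_idx))
    iter_done <- iter

    if (iter > model$burn_in && (iter - model$burn_in) %% model$thin == 0L) {
      pred <- U %*% t(V)
      draw_sum <- draw_sum + pred
      draw_sumsq <- draw_sumsq + pred^2
      n_draws <- n_draws + 1L
    }

    if (model$stable_tol > 0 && length(rmse_val) >= 2 && !is.na(rv)) {
      d <- abs(rv - rmse_val[length(rmse_val) - 1L])
      stable_run <- if (!is.na(d) && d < model$stable_tol) stable_run + 1L else 0L
      if (stable_run >= model$patience && n_draws >= 1L) {
        stopped_early <- TRUE
        break
      }
    }
  }

  if (n_draws == 0L) {
    # schedule exhausted before a retained draw (burn_in close to max_iter):
    # fall back to the final state as a single draw
    pred <- U %*% t(V)
    draw_sum <- pred; draw_sumsq <- pred^2; n_draws <- 1L
  }
  post_mean <- draw_sum / n_draws
  post_var <- pmax(0, draw_sumsq / n_draws - post_mean^2)
  post_sd <- sqrt(post_var * ifelse(n_draws > 1, n_draws / (n_draws - 1), NA_real_))

  z_complete <- z
  z_complete[miss] <- post_mean[miss]
  lx_complete <- zlog_inverse(z_complete, zl$transform)
  completed <- lx_complete
  for (j in colnames(x)) {
    if (!(j %in% signed_traits)) completed[, j] <- exp(lx_complete[, j])
  }
  completed[!miss] <- x[!miss]
  sd_out <- matrix(NA_real_, n, p, dimnames = dimnames(x))
  sd_out[miss] <- post_sd[miss]

  list(completed = completed, sd = sd_out,
       report = list(n_draws = n_draws, stopped_early = stopped_early,
                     iterations = iter_done,
                     rmse_validation = rmse_val, rmse_test = rmse_test,
                     transform = zl$transform))
}
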