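# Trait covariation structure: absolute Pearson correlation matrix,
# complete-linkage clustering on the 1 - |r| distance, correlation-matrix
# PCA of the natural-log traits, a permutation test for the number of
# significant axes, and latitudinal-gradient regressions of component scores
# (species-level and binned at 1 degree absolute latitude).

#' Absolute pairwise Pearson correlation matrix of traits
#'
#' Pairwise-complete absolute Pearson correlations. Positive traits are
#' natural-log-transformed first (default); traits listed in `signed_traits`
#' stay on their raw scale (they can be negative).
#'
#' @param traits numeric matrix or data.frame of trait values (rows =
#'   species-by-ecoregion entries).
#' @param log_scale log-transform positive traits first (default TRUE).
#' @param signed_traits traits exempt from the log transform.
#' @param min_pairs minimum complete pairs per trait pair (default 3).
#' @return symmetric matrix with unit diagonal, entries in `[0, 1]`.
#' @export
correlation_matrix <- function(traits, log_scale = TRUE,
                               signed_traits = character(0), min_pairs = 3L) {
  x <- as.matrix(traits)
  if (log_scale) x <- log_trait_matrix(x, signed_traits = signed_traits)
  v <- apply(x, 2, sd, na.rm = TRUE)
  if (any(!is.finite(v) | v == 0)) {
    stop(sprintf("trait '%s' has zero variance", colnames(x)[which(!is.finite(v) | v == 0)[1]]),
         call. = FALSE)
  }
  ok <- !is.na(x)
  pairs <- crossprod(ok)
  if (any(pairs < min_pairs)) {
    stop(sprintf("fewer than %d complete pairs for some trait pair", min_pairs), call. = FALSE)
  }
  r <- abs(cor(x, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Complete-linkage clustering of traits on the 1 - |r| distance
#'
#' Builds the complete-linkage dendrogram on `d = 1 - |r|` and assigns trait
#' groups by cutting strictly below `cut`: traits merging at height >= `cut`
#' end up in different groups (default cut 1.0, i.e. only traits with some
#' absolute correlation cluster together).
#'
#' @param corr absolute correlation matrix (from [correlation_matrix()]).
#' @param cut cut height on the distance scale (default 1.0).
#' @return `trait_cluster` list: `tree` (hclust), `heights`, `groups`
#'   (named integer vector), `cut`.
#' @export
cluster_traits <- function(corr, cut = 1.0) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  d <- as.dist(1 - abs(corr))
  tree <- hclust(d, method = "complete")
  groups <- cutree(tree, h = cut - 1e-9)
  structure(list(tree = tree, heights = tree$height, groups = groups, cut = cut),
            class = "trait_cluster")
}

#' Correlation-matrix PCA of the trait table
#'
#' PCA of the column-standardized natural-log trait matrix (signed traits
#' z-standardized on the raw scale). Each component is oriented so that its
#' largest-magnitude loading is positive.
#'
#' @param traits complete numeric trait matrix (no missing values; gap-fill
#'   first).
#' @param log_scale,signed_traits as in [correlation_matrix()].
#' @return `pca_result` list: `loadings` (trait x component), `scores`
#'   (row x component), `var_fraction`, `sdev`.
#' @export
pca_traits <- function(traits, log_scale = TRUE, signed_traits = character(0)) {
  x <- as.matrix(traits)
  if (anyNA(x)) stop("trait matrix has missing values; run gapfill first", call. = FALSE)
  if (log_scale) x <- log_trait_matrix(x, signed_traits = signed_traits)
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, "*")
  sco <- sweep(pc$x, 2, flip, "*")
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = rot, scores = sco, var_fraction = varfrac,
                 sdev = pc$sdev), class = "pca_result")
}

#' Number of significant principal components by permutation
#'
#' Replaces the sequential-Bonferroni dimension test by a permutation test:
#' each component's variance fraction is compared with its null distribution
#' obtained by independently permuting every trait column; axes are tested
#' in order with a Holm step-down threshold (`alpha / (K - k + 1)`) and
#' counting stops at the first non-significant axis.
#'
#' @param traits complete trait matrix.
#' @param n_perm number of permutations (default 199; < 100 warns).
#' @param alpha significance level in (0, 1).
#' @param seed integer seed.
#' @param log_scale,signed_traits as in [pca_traits()].
#' @return number of retained components.
#' @export
significant_axes <- function(traits, n_perm = 199L, alpha = 0.05, seed = 1L,
                             log_scale = TRUE, signed_traits = character(0)) {
  if (!is_real(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null distribution")
  x <- as.matrix(traits)
  if (anyNA(x)) stop("trait matrix has missing values; run gapfill first", call. = FALSE)
  if (log_scale) x <- log_trait_matrix(x, signed_traits = signed_traits)
  x <- scale(x)
  obs <- prcomp(x, center = FALSE, scale. = FALSE)$sdev^2
  obs <- obs / sum(obs)
  K <- length(obs)
  set.seed(as.integer(seed))
  exceed <- integer(K)
  for (b in seq_len(n_perm)) {
    xp <- apply(x, 2, sample)
    vp <- prcomp(xp, center = FALSE, scale. = FALSE)$sdev^2
    vp <- vp / sum(vp)
    if (length(vp) < K) vp <- c(vp, rep(0, K - length(vp)))
    exceed <- exceed + (vp >= obs)
  }
  pvals <- (1 + exceed) / (n_perm + 1)
  retained <- 0L
  for (k in seq_len(K)) {
    if (pvals[k] <= alpha / (K - k + 1)) retained <- k else break
  }
  retained
}

#' Latitudinal-gradient fit of component scores
#'
#' Ordinary least squares of a score on absolute latitude, at two levels:
#' over all rows (species-by-ecoregion level) and over means within integer
#' 1-degree bins of absolute latitude (`bin = floor(|lat|)`, regressing bin
#' mean score on bin mean absolute latitude).
#'
#' @param scores numeric vector (e.g. one PCA score column).
#' @param latitudes latitude (degrees) per score entry.
#' @return list of two `latitude_fit` entries, `species` and `binned`, each
#'   with slope, intercept and r-squared.
#' @export
latitude_fit <- function(scores, latitudes) {
  stopifnot(length(scores) == length(latitudes))
  al <- abs(latitudes)
  if (length(unique(al)) < 3) stop("need at least 3 distinct latitudes", call. = FALSE)
  fit1 <- lm(scores ~ al)
  bins <- floor(al)
  bs <- tapply(scores, bins, mean)
  bl <- tapply(al, bins, mean)
  if (length(bs) < 3) stop("need at least 3 distinct latitude bins", call. = FALSE)
  fit2 <- lm(bs ~ bl)
  mk <- function(fit, level) {
    structure(list(level = level,
                   slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                   r_squared = summary(fit)$r.squared), class = "latitude_fit")
  }
  list(species = mk(fit1, "species"), binned = mk(fit2, "binned_1deg"))
}
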