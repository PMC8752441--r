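# Redundancy analysis: constrained ordination of the ecoregion-level trait
# matrix on climate + topsoil predictors, preceded by iterative pruning of
# collinear predictors via the variance inflation factor.

#' Variance inflation factors
#'
#' `vif_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor j on
#' all other predictors.
#'
#' @param X predictor matrix (n > p).
#' @return named numeric vector of VIFs (>= 1; `Inf` for perfectly collinear
#'   predictors).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p == 1L) return(setNames(1, colnames(X)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  names(out) <- colnames(X)
  out
}

#' Iterative VIF pruning of a predictor set
#'
#' Repeatedly removes the highest-VIF predictor while any VIF exceeds
#' `exclude_above` (default 20), and reports whether the final model reached
#' `target_max` (default 10).
#'
#' @param X standardized predictor matrix.
#' @param exclude_above removal threshold (default 20).
#' @param target_max target maximum VIF to report against (default 10).
#' @return list: `X` (pruned matrix), `report` (data.frame of predictor,
#'   final or at-removal VIF, excluded flag), `max_vif`, `target_met`.
#' @export
vif_prune <- function(X, exclude_above = 20, target_max = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%03d", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X)) {
    stop(sprintf("n = %d <= p = %d; VIF requires more rows than predictors",
                 nrow(X), ncol(X)), call. = FALSE)
  }
  removed <- data.frame(predictor = character(0), vif = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    v <- vif(X)
    if (max(v) <= exclude_above || ncol(X) == 1L) break
    worst <- which.max(v)
    removed <- rbind(removed, data.frame(predictor = colnames(X)[worst],
                                         vif = v[worst], stringsAsFactors = FALSE))
    X <- X[, -worst, drop = FALSE]
  }
  v <- vif(X)
  report <- rbind(
    data.frame(predictor = names(v), vif = unname(v), excluded = FALSE,
               stringsAsFactors = FALSE),
    if (nrow(removed)) data.frame(predictor = removed$predictor, vif = removed$vif,
                                  excluded = TRUE, stringsAsFactors = FALSE)
  )
  rownames(report) <- NULL
  list(X = X, report = report, max_vif = max(v), target_met = max(v) < target_max)
}

#' Redundancy analysis (constrained ordination)
#'
#' Multivariate least squares of the response matrix on the predictors,
#' followed by an eigen-decomposition of the fitted-value covariance.
#' Responses are centred (and by default scaled) per trait; predictors are
#' standardized. Variance fractions per constrained axis are reported both
#' relative to the total response variance and relative to the constrained
#' (fitted) variance, since published axis percentages do not always state
#' their denominator. Each axis is oriented so its largest-magnitude
#' predictor score is positive.
#'
#' @param Y response matrix (ecoregion x trait; natural-log traits).
#' @param X predictor matrix (VIF-pruned; topsoil-filtered upstream).
#' @param scale_y scale responses to unit variance (default TRUE).
#' @return `rda_result` list: `eigenvalues`, `frac_total`, `frac_constrained`,
#'   `trait_scores` (raw eigenvectors and sqrt-eigenvalue-scaled),
#'   `site_scores`, `predictor_scores` (correlation of predictors with site
#'   scores), `total_variance`, `constrained_variance`.
#' @export
fit_rda <- function(Y, X, scale_y = TRUE) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = scale_y)
  Xc <- scale(X, center = TRUE, scale = TRUE)
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    stop("predictor matrix is rank-deficient; prune collinear predictors with vif_prune()",
         call. = FALSE)
  }
  fitted <- qr.fitted(qrx, Yc)
  sv <- svd(fitted / sqrt(n - 1))
  ev <- sv$d^2
  keep <- ev > max(ev) * 1e-12
  ev <- ev[keep]
  axes <- paste0("RDA", seq_along(ev))
  W <- sv$v[, keep, drop = FALSE]                     # trait eigenvectors
  site <- (Yc %*% W)                                  # site scores (response space)
  site_lc <- (fitted %*% W)                           # linear-constraint scores
  pred_cor <- cor(Xc, site_lc)
  # sign convention: largest-magnitude predictor score positive per axis
  flip <- apply(pred_cor, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  W <- sweep(W, 2, flip, "*")
  site <- sweep(site, 2, flip, "*")
  site_lc <- sweep(site_lc, 2, flip, "*")
  pred_cor <- sweep(pred_cor, 2, flip, "*")
  dimnames(W) <- list(colnames(Y), axes)
  colnames(site) <- colnames(site_lc) <- axes
  colnames(pred_cor) <- axes
  total_var <- sum(apply(Yc, 2, var))
  constrained_var <- sum(apply(fitted, 2, var))
  structure(list(
    eigenvalues = setNames(ev, axes),
    frac_total = setNames(ev / total_var, axes),
    frac_constrained = setNames(ev / sum(ev), axes),
    trait_scores = list(raw = W, scaled = sweep(W, 2, sqrt(ev), "*")),
    site_scores = site, site_scores_lc = site_lc,
    predictor_scores = pred_cor,
    total_variance = total_var, constrained_variance = constrained_var
  ), class = "rda_result")
}
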