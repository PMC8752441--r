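#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor lm lm.fit median prcomp predict quantile rnorm rpois
#'   runif sd var coef as.dist cutree hclust rlnorm setNames rbinom
#' @importFrom utils head tail modifyList read.delim write.table
NULL

# required so data.table's `[` dispatch works inside this package
.datatable.aware <- TRUE

# Validation helper: stops with a message naming the offending field.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

is_real <- function(x, lo = -Inf, hi = Inf) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= lo && x <= hi
}

#' Spawn per-stage seeds from one master seed
#'
#' Deterministically derives a vector of independent 31-bit seeds from a
#' single master seed, so that one knob reproduces a full pipeline run.
#'
#' @param master_seed integer master seed.
#' @param n number of seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
spawn_seeds <- function(master_seed, n) {
  check_that(is_count(master_seed, min = 0L), "master_seed", "must be a non-negative integer")
  check_that(is_count(n), "n", "must be a positive integer")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Natural-log transform of a trait matrix, leaving designated signed traits
# (e.g. a delta-15N analogue that can be negative) on their raw scale.
log_trait_matrix <- function(x, signed_traits = character(0)) {
  x <- as.matrix(x)
  out <- x
  for (j in colnames(x)) {
    if (j %in% signed_traits) next
    v <- x[, j]
    if (any(v <= 0, na.rm = TRUE)) {
      stop(sprintf("trait '%s' has non-positive values and is not declared signed; cannot log-transform", j),
           call. = FALSE)
    }
    out[, j] <- log(v)
  }
  out
}

# r-squared of an OLS fit of y on x (single predictor), plain formula.
ols_r2 <- function(x, y) {
  fit <- lm(y ~ x)
  summary(fit)$r.squared
}
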