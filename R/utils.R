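#' @importFrom rlang abort warn inform %||%
#' @importFrom stats rnorm qnorm pnorm cor sd var optimize median pchisq
#'   qchisq rbinom runif setNames phyper p.adjust quantile
#' @importFrom utils head
NULL

# Center columns and scale to unit sample variance; zero-variance columns
# are left centered (all-zero) rather than producing NaN.
standardize_columns <- function(x) {
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  x
}

# Shrink a sample correlation matrix toward the identity. Applied wherever
# the LD matrix is inverted; the stored LD itself stays a plain correlation.
shrink_ld <- function(R, lambda = 0.1) {
  stopifnot(lambda >= 0, lambda < 1)
  Rs <- (1 - lambda) * R + lambda * diag(nrow(R))
  dimnames(Rs) <- dimnames(R)
  Rs
}

# Draw m vectors from MVN(0, R) given an upper Cholesky factor; returns an
# m x p matrix.
rmvn_chol <- function(m, chol_R) {
  p <- ncol(chol_R)
  matrix(rnorm(m * p), m, p) %*% chol_R
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x >= 0
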