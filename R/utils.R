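#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov optim pchisq pnorm pt qchisq qnorm quantile
#'   rbinom rnorm runif sd setNames uniroot var
#' @importFrom utils read.csv write.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop2(name, " must be a single number")
  if (x < lower || x > upper)
    stop2(name, " must be in [", lower, ", ", upper, "], got ", x)
  invisible(x)
}

zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop2("cannot standardize a constant vector")
  (v - mean(v)) / s
}

#' Ordinary least squares with family-clustered (sandwich) standard errors
#'
#' Fits y = X beta by least squares and computes CR1 cluster-robust standard
#' errors (Stata-style small-sample correction \eqn{G/(G-1) \cdot (N-1)/(N-k)}),
#' with p-values on \eqn{G - 1} degrees of freedom, where G is the number of
#' clusters (families).
#'
#' @param y numeric response vector.
#' @param X design matrix (including an intercept column if wanted).
#' @param cluster vector of cluster (family) identifiers, same length as `y`.
#' @return list with `coef`, `se`, `t`, `p`, `vcov`, `residuals`, `n`,
#'   `n_clusters`.
#' @keywords internal
lm_cluster <- function(y, X, cluster) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || length(cluster) != n)
    stop2("y, X and cluster must have matching lengths")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop2("design matrix is rank deficient")
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  k <- ncol(X)
  XtXinv <- chol2inv(qr.R(qr_x))
  cl <- as.character(cluster)
  G <- length(unique(cl))
  Xe <- X * as.numeric(res)
  meat_half <- rowsum(Xe, cl)
  meat <- crossprod(meat_half)
  adj <- (G / (G - 1)) * ((n - 1) / (n - k))
  V <- adj * XtXinv %*% meat %*% XtXinv
  se <- sqrt(diag(V))
  tval <- as.numeric(beta) / se
  p <- 2 * stats::pt(-abs(tval), df = G - 1)
  list(coef = setNames(as.numeric(beta), colnames(X)),
       se = setNames(se, colnames(X)),
       t = setNames(tval, colnames(X)),
       p = setNames(p, colnames(X)),
       vcov = V, residuals = as.numeric(res), n = n, n_clusters = G)
}

## symmetric square root of a PSD matrix (handles the exactly singular
## MZ Kronecker covariance where chol() fails)
mat_sqrt <- function(S) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8) stop2("covariance matrix is not PSD")
  eg$vectors %*% (t(eg$vectors) * sqrt(pmax(eg$values, 0)))
}

## correlated standard-normal pair columns: cor(z1, z2') = r
rnorm_pair <- function(n, r) {
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  cbind(z1, z2)
}

## draws sex codes (1 = male, 2 = female) for n pairs, shared within pair
draw_pair_sex <- function(n, p_female = 0.56) {
  1L + rbinom(n, 1L, p_female)
}
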