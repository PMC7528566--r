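## Eating-behavior pattern derivation: correlation-matrix PCA, the
## eigenvalue > 1 retention rule, varimax rotation (classic Kaiser pairwise
## algorithm with row normalization), loading-based labeling, and
## regression-method component scores.

#' Correlation-matrix principal component analysis
#'
#' Eigendecomposition of the sample correlation matrix; loadings are the
#' eigenvectors scaled by the square root of their eigenvalues, so squared
#' loadings sum (over variables) to the eigenvalue and eigenvalues sum to
#' the number of variables.
#'
#' @param items n x p table of numeric item responses (no missing values,
#'   no constant column).
#' @return object of class `pca_solution` with `eigenvalues`, `loadings`
#'   (unrotated, sign-oriented), `pct_var` (percentage of total variance per
#'   component), and the sample correlation matrix `R`.
#' @export
pca_correlation <- function(items) {
  X <- as.matrix(items)
  if (ncol(X) < 2) stop2("need at least 2 item columns")
  if (anyNA(X)) stop2("items contain missing values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop2("constant column(s): ",
          paste(colnames(X)[sds == 0], collapse = ", "))
  R <- cor(X)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  L <- eig$vectors %*% diag(sqrt(pmax(ev, 0)), ncol(X))
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  structure(list(eigenvalues = ev,
                 loadings = orient_loadings(L),
                 pct_var = 100 * ev / ncol(X),
                 R = R, n = nrow(X)),
            class = "pca_solution")
}

#' Component retention by the eigenvalue-greater-than-1 rule
#'
#' @param eigenvalues non-increasing eigenvalue vector.
#' @param cutoff retention threshold (strict inequality), default 1.
#' @return list with `n_retained` and a `scree` data.frame
#'   (rank vs eigenvalue) for plotting.
#' @export
retain_components <- function(eigenvalues, cutoff = 1) {
  if (length(eigenvalues) == 0) stop2("empty eigenvalue vector")
  if (is.unsorted(rev(eigenvalues), strictly = FALSE))
    stop2("eigenvalues must be in descending order")
  list(n_retained = sum(eigenvalues > cutoff),
       scree = data.frame(rank = seq_along(eigenvalues),
                          eigenvalue = eigenvalues))
}

#' Varimax criterion of a loading matrix
#'
#' Sum over components of the variance of the squared loadings
#' (raw criterion, computed on row-normalized loadings when
#' `normalize = TRUE`).
#'
#' @param loadings variables x components matrix.
#' @param normalize apply Kaiser row normalization first?
#' @return scalar criterion value.
#' @export
varimax_criterion <- function(loadings, normalize = TRUE) {
  L <- as.matrix(loadings)
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  p <- nrow(L)
  sum(colSums(L^4) - colSums(L^2)^2 / p)
}

#' Varimax rotation (Kaiser pairwise planar rotations)
#'
#' Orthogonal rotation maximizing the varimax criterion, using repeated
#' sweeps of optimal Givens rotations over all component pairs, with Kaiser
#' row normalization (each variable's loadings scaled to unit communality
#' before rotation and scaled back afterwards). Converges when a full sweep
#' improves the criterion by less than `eps`. Communalities are preserved
#' exactly because the rotation is orthonormal.
#'
#' @param loadings variables x k loading matrix (k >= 1).
#' @param normalize Kaiser row normalization (default TRUE).
#' @param eps convergence tolerance on the criterion.
#' @param max_iter maximum number of sweeps.
#' @return list with `loadings` (rotated, sign-oriented), `rotmat`
#'   (orthonormal k x k rotation), `iterations`, `criterion`.
#' @export
varimax_rotate <- function(loadings, normalize = TRUE, eps = 1e-8,
                           max_iter = 1000) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k < 1) stop2("need at least one component")
  rot <- diag(k)
  if (k == 1) {
    return(list(loadings = orient_loadings(L), rotmat = rot,
                iterations = 0L, criterion = varimax_criterion(L, normalize)))
  }
  h <- rep(1, nrow(L))
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
  }
  W <- L / h
  p <- nrow(W)
  crit <- varimax_criterion(W, normalize = FALSE)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      x <- W[, i]; y <- W[, j]
      u <- x^2 - y^2; v <- 2 * x * y
      A <- sum(u); B <- sum(v)
      num <- sum(2 * u * v) - 2 * A * B / p
      den <- sum(u^2 - v^2) - (A^2 - B^2) / p
      phi <- atan2(num, den) / 4
      if (abs(phi) > 1e-12) {
        G <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
        W[, c(i, j)] <- W[, c(i, j)] %*% G
        rot[, c(i, j)] <- rot[, c(i, j)] %*% G
      }
    }
    new_crit <- varimax_criterion(W, normalize = FALSE)
    if (new_crit - crit < eps) break
    crit <- new_crit
    if (iter >= max_iter)
      stop2("varimax failed to converge after ", iter, " sweeps")
  }
  Lr <- W * h
  dimnames(Lr) <- dimnames(L)
  colnames(rot) <- colnames(L)
  list(loadings = orient_loadings(Lr), rotmat = rot, iterations = iter,
       criterion = varimax_criterion(Lr, normalize = normalize))
}

#' Orient loading signs deterministically
#'
#' Flips each component so that its largest-absolute loading is positive;
#' makes labeling and downstream scoring reproducible.
#'
#' @param loadings variables x k matrix.
#' @return sign-oriented matrix.
#' @export
orient_loadings <- function(loadings) {
  L <- as.matrix(loadings)
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Contributing variables per component
#'
#' Variables whose absolute rotated loading meets the threshold, per
#' component, sorted by decreasing absolute loading.
#'
#' @param loadings rotated loading matrix (rownames = variable names).
#' @param threshold absolute-loading cutoff (default 0.30).
#' @return named list of data.frames (`variable`, `loading`).
#' @export
label_loadings <- function(loadings, threshold = 0.30) {
  L <- as.matrix(loadings)
  vars <- rownames(L) %||% paste0("var", seq_len(nrow(L)))
  out <- lapply(seq_len(ncol(L)), function(j) {
    sel <- which(abs(L[, j]) >= threshold)
    sel <- sel[order(-abs(L[sel, j]))]
    data.frame(variable = vars[sel], loading = L[sel, j],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(out) <- colnames(L) %||% paste0("PC", seq_len(ncol(L)))
  out
}

#' Component scores
#'
#' Regression-method scores: standardized items times the weight matrix
#' \eqn{R^{-1} \Lambda}; scores are re-standardized to unit variance. A
#' simple sum-score alternative (sign-weighted sum of items meeting the
#' loading threshold) is available for sensitivity analyses.
#'
#' @param items n x p item table (standardized internally).
#' @param loadings rotated loading matrix.
#' @param method `"regression"` (default) or `"sum"`.
#' @param threshold loading cutoff used by the sum method.
#' @return n x k matrix of standardized component scores.
#' @export
component_scores <- function(items, loadings, method = c("regression", "sum"),
                             threshold = 0.30) {
  method <- match.arg(method)
  X <- as.matrix(items)
  if (anyNA(X)) stop2("items contain missing values")
  Z <- scale(X)
  L <- as.matrix(loadings)
  if (method == "regression") {
    R <- cor(X)
    W <- tryCatch(solve(R, L), error = function(e)
      stop2("item correlation matrix is singular: ", conditionMessage(e)))
  } else {
    W <- sign(L) * (abs(L) >= threshold)
    if (all(W == 0)) stop2("no loading meets the threshold; no sum score")
  }
  S <- Z %*% W
  S <- scale(S)
  attr(S, "scaled:center") <- NULL
  attr(S, "scaled:scale") <- NULL
  colnames(S) <- colnames(L)
  S
}

#' Derive eating-behavior patterns from item responses
#'
#' Full pattern workflow: correlation-matrix PCA, eigenvalue > `cutoff`
#' retention, varimax rotation of the retained loadings, sign orientation,
#' loading-based labeling, and standardized component scores.
#'
#' @param items n x p item table.
#' @param eigen_cutoff retention threshold (default 1.0).
#' @param loading_cutoff labeling threshold (default 0.30).
#' @param score_method `"regression"` or `"sum"`.
#' @return `pca_solution` augmented with `n_retained`, `rotated`, `rotmat`,
#'   `rotation_meta` (records Kaiser normalization), `pct_var_rotated`,
#'   `labels`, `scores`, `scree`.
#' @examples
#' items <- simulate_items(default_item_design(), n = 400, seed = 1)
#' sol <- derive_patterns(items)
#' sol$n_retained
#' @export
derive_patterns <- function(items, eigen_cutoff = 1, loading_cutoff = 0.30,
                            score_method = "regression") {
  sol <- pca_correlation(items)
  ret <- retain_components(sol$eigenvalues, cutoff = eigen_cutoff)
  k <- ret$n_retained
  sol$n_retained <- k
  sol$scree <- ret$scree
  if (k == 0) {
    sol$rotated <- NULL
    return(sol)
  }
  vr <- varimax_rotate(sol$loadings[, seq_len(k), drop = FALSE])
  sol$rotated <- vr$loadings
  sol$rotmat <- vr$rotmat
  sol$rotation_meta <- list(method = "varimax", kaiser_normalization = TRUE,
                            iterations = vr$iterations,
                            criterion = vr$criterion)
  ## post-rotation redistribution of explained variance across components
  sol$pct_var_rotated <- 100 * colSums(vr$loadings^2) / nrow(vr$loadings)
  sol$labels <- label_loadings(vr$loadings, threshold = loading_cutoff)
  sol$scores <- component_scores(items, vr$loadings, method = score_method,
                                 threshold = loading_cutoff)
  sol
}

#' @export
print.pca_solution <- function(x, ...) {
  cat("correlation-matrix PCA:", length(x$eigenvalues), "variables, n =",
      x$n, "\n")
  cat("eigenvalues:", paste(sprintf("%.2f", x$eigenvalues), collapse = " "),
      "\n")
  if (!is.null(x$n_retained)) {
    cat("retained components (eigenvalue > 1):", x$n_retained, "\n")
    if (x$n_retained > 0)
      cat("variance explained by retained components:",
          sprintf("%.1f%%", sum(x$pct_var_rotated)), "\n")
  }
  invisible(x)
}
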