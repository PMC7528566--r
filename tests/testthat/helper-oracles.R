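## Independent oracles used by the test suite. These deliberately avoid the
## code paths they are checking: the AE likelihood is re-derived from the
## closed-form 2x2 normal density over an exhaustive (a, e) lattice, and the
## varimax oracle is a brute-force search over Givens rotation angles.

## exhaustive grid-search ML for the AE model (mu held at the supplied value,
## typically the ML mean); returns the h2 on the lattice with maximal loglik
grid_search_ae_h2 <- function(Ymz, Ydz, mu, step = 0.001, path_max = 1.3) {
  a <- seq(step, path_max, by = step)
  e <- seq(step, path_max, by = step)
  a2 <- a^2
  e2 <- e^2
  suff <- function(Y) {
    Yc <- Y - mu
    list(n = nrow(Y), t11 = sum(Yc[, 1]^2), t22 = sum(Yc[, 2]^2),
         t12 = sum(Yc[, 1] * Yc[, 2]))
  }
  smz <- suff(Ymz); sdz <- suff(Ydz)
  V <- outer(a2, e2, `+`)                 # total variance, grid a x e
  n2ll <- matrix(0, length(a), length(e))
  for (g in list(list(s = smz, cov = a2), list(s = sdz, cov = 0.5 * a2))) {
    CV <- matrix(g$cov, length(a), length(e))
    DET <- V^2 - CV^2
    bad <- DET <= 0
    DET[bad] <- NA
    n2ll <- n2ll + g$s$n * (2 * log(2 * pi) + log(DET)) +
      (V * (g$s$t11 + g$s$t22) - 2 * CV * g$s$t12) / DET
  }
  ix <- arrayInd(which.min(n2ll), dim(n2ll))
  a2[ix[1]] / (a2[ix[1]] + e2[ix[2]])
}

## brute-force varimax: repeated sweeps over component pairs, grid search of
## the Givens angle on each pair (with Kaiser row normalization, matching the
## implementation), refined to step ~1e-5 rad
oracle_varimax_givens <- function(L, tol = 1e-10, max_sweeps = 200) {
  h <- sqrt(rowSums(L^2)); h[h == 0] <- 1
  W <- L / h
  crit <- function(M) varimax_criterion(M, normalize = FALSE)
  k <- ncol(W)
  best <- crit(W)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      pair <- W[, c(i, j)]
      eval_angle <- function(phi) {
        G <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
        Wp <- W
        Wp[, c(i, j)] <- pair %*% G
        crit(Wp)
      }
      angles <- seq(-pi / 4, pi / 4, length.out = 181)
      vals <- vapply(angles, eval_angle, numeric(1))
      phi <- angles[which.max(vals)]
      for (width in c(pi / 180, pi / 18000)) {  # two refinement passes
        fine <- seq(phi - width, phi + width, length.out = 41)
        vals <- vapply(fine, eval_angle, numeric(1))
        phi <- fine[which.max(vals)]
      }
      if (eval_angle(phi) > crit(W) + 1e-14) {
        G <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
        W[, c(i, j)] <- pair %*% G
        improved <- TRUE
      }
    }
    new <- crit(W)
    if (!improved || new - best < tol) break
    best <- new
  }
  list(loadings = W * h, criterion = crit(W))
}

## data with an exact sample correlation r between two columns
exact_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); y <- rnorm(n)
  x <- zscore_(x)
  y <- zscore_(residuals(lm(y ~ x)))
  cbind(x = x, y = r * x + sqrt(1 - r^2) * y)
}

zscore_ <- function(v) (v - mean(v)) / stats::sd(v)

## columns with exactly identity sample correlation (whitened)
exact_whitened <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  Xc <- scale(X, scale = FALSE)
  Z <- Xc %*% solve(chol(stats::cov(Xc)))
  colnames(Z) <- paste0("v", seq_len(p))
  Z
}

## paired matrices straight from a generated cohort (pools nothing)
paired_from <- function(d, traits) pair_wide(d, traits)
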