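## Classical-twin quantitative genetics by maximum likelihood: intraclass
## correlations, univariate ACE/ADE/AE/E fits with profile-likelihood CIs,
## nested-model comparison, and the bivariate AE Cholesky decomposition.
##
## Expected pair covariance for a standardized trait:
##   var    = a^2 + c^2 + d^2 + e^2
##   cov_MZ = a^2 + c^2 + d^2
##   cov_DZ = 0.5 a^2 + c^2 + 0.25 d^2
## Optimization runs over unconstrained real path coefficients (squared in
## the covariance), the standard Cholesky trick that removes boundary
## constraints on variances.

TWIN_MODELS <- list(
  E   = character(0),
  AE  = c("a"),
  ACE = c("a", "c"),
  ADE = c("a", "d")
)

## sufficient statistics of an (n x 2) pair matrix
pair_suff <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 3) stop2("need at least 3 pairs per zygosity group")
  m <- colMeans(Y)
  S <- crossprod(sweep(Y, 2, m))  # scatter about the mean
  list(n = nrow(Y), m = m, S = S,
       fingerprint = c(n = nrow(Y), sum = sum(Y), ss = sum(Y^2),
                       cp = sum(Y[, 1] * Y[, 2])))
}

## -2 log-likelihood contribution of one zygosity group, Sigma 2x2 exchangeable
nll_group2 <- function(suff, v, cv, mu) {
  det_s <- v^2 - cv^2
  if (det_s <= 0 || v <= 0) return(Inf)
  dm <- suff$m - mu
  Tm <- suff$S + suff$n * tcrossprod(dm)
  tr <- (v * (Tm[1, 1] + Tm[2, 2]) - 2 * cv * Tm[1, 2]) / det_s
  suff$n * (2 * log(2 * pi) + log(det_s)) + tr
}

## expected (v, cov_mz, cov_dz) from squared paths
twin_cov <- function(a2 = 0, c2 = 0, d2 = 0, e2 = 0) {
  list(v = a2 + c2 + d2 + e2,
       mz = a2 + c2 + d2,
       dz = 0.5 * a2 + c2 + 0.25 * d2)
}

nll_univariate <- function(par, model, suff_mz, suff_dz) {
  mu <- par[1]
  paths <- par[-1]
  comp <- setNames(rep(0, 3), c("a", "c", "d"))
  comp[TWIN_MODELS[[model]]] <- paths[seq_along(TWIN_MODELS[[model]])]
  e <- paths[length(paths)]
  cv <- twin_cov(a2 = comp["a"]^2, c2 = comp["c"]^2, d2 = comp["d"]^2,
                 e2 = e^2)
  nll_group2(suff_mz, cv$v, cv$mz, mu) + nll_group2(suff_dz, cv$v, cv$dz, mu)
}

## double-entry Pearson correlation of a pair matrix
double_entry_cor <- function(Y) {
  Y <- as.matrix(Y)
  if (stats::sd(as.numeric(Y)) == 0) stop2("zero variance in pair matrix")
  cor(c(Y[, 1], Y[, 2]), c(Y[, 2], Y[, 1]))
}

#' Intraclass correlations per zygosity group
#'
#' Double-entry Pearson correlation (each pair entered in both orders) with
#' a family-level bootstrap confidence interval.
#'
#' @param paired a `paired_set` from [pair_wide()], or a single
#'   `paired_matrix`.
#' @param trait trait name if the paired matrices hold several traits.
#' @param boot number of bootstrap draws for the CI (0 to skip).
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap.
#' @return `data.frame` with one row per zygosity group: `zygosity`,
#'   `n_pairs`, `icc`, `lower`, `upper`.
#' @export
intraclass_correlation <- function(paired, trait = NULL, boot = 1000,
                                   conf = 0.95, seed = NULL) {
  if (inherits(paired, "paired_matrix"))
    paired <- setNames(list(paired), attr(paired, "zygosity") %||% "all")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(paired), function(z) {
    Y <- pm_trait(paired[[z]], trait)
    if (nrow(Y) < 3) stop2("need at least 3 pairs in group ", z)
    icc <- double_entry_cor(Y)
    lo <- hi <- NA_real_
    if (boot > 0) {
      bs <- vapply(seq_len(boot), function(i) {
        double_entry_cor(Y[sample.int(nrow(Y), replace = TRUE), ,
                           drop = FALSE])
      }, numeric(1))
      qs <- quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    }
    data.frame(zygosity = z, n_pairs = nrow(Y), icc = icc,
               lower = lo, upper = hi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## pooled DZ pair matrix from a paired_set (SS-DZ and OS-DZ share r = 0.5)
pool_dz <- function(paired, trait) {
  dz_names <- intersect(c("DZSS", "DZOS", "DZ"), names(paired))
  if (length(dz_names) == 0) stop2("no DZ group present")
  do.call(rbind, lapply(dz_names, function(z) pm_trait(paired[[z]], trait)))
}

#' Univariate twin variance-component fit by maximum likelihood
#'
#' Fits the bivariate-normal twin likelihood under the expected covariance
#' structure of the chosen model, over unconstrained path coefficients plus
#' a common mean. Standardized variance shares are the squared paths divided
#' by the total variance; 95% CIs by profile likelihood.
#'
#' @param paired a `paired_set` from [pair_wide()] (SS-DZ and OS-DZ pooled
#'   as DZ), or a list with elements `MZ` and `DZ` of pair matrices.
#' @param model one of `"ACE"`, `"ADE"`, `"AE"`, `"E"`.
#' @param trait trait name if the paired matrices hold several traits.
#' @param ci `"profile"` (default) or `"none"`.
#' @param conf confidence level for the profile CIs.
#' @return object of class `twin_fit`: `model`, `paths`, `shares` (named
#'   a2/c2/d2/e2 as applicable), `ci` (matrix of lower/upper per share),
#'   `loglik`, `n_pairs`, `mu`, `convergence`, `boundary` flag.
#' @examples
#' d <- simulate_univariate_twins(uni_arch(a2 = 0.6, e2 = 0.4),
#'                                500, 500, seed = 2)
#' pw <- pair_wide(d, "bmi")
#' fit_univariate(pw, model = "AE", ci = "none")
#' @export
fit_univariate <- function(paired, model = c("AE", "ACE", "ADE", "E"),
                           trait = NULL, ci = c("profile", "none"),
                           conf = 0.95) {
  model <- match.arg(model)
  ci <- match.arg(ci)
  Ymz <- if (!is.null(paired$MZ)) pm_trait(paired$MZ, trait) else
    stop2("MZ group missing")
  Ydz <- pool_dz(paired, trait)
  suff_mz <- pair_suff(Ymz)
  suff_dz <- pair_suff(Ydz)

  rmz <- double_entry_cor(Ymz)
  rdz <- double_entry_cor(Ydz)
  v0 <- (var(as.numeric(Ymz)) * suff_mz$n + var(as.numeric(Ydz)) * suff_dz$n) /
    (suff_mz$n + suff_dz$n)
  mu0 <- (sum(Ymz) + sum(Ydz)) / (2 * (suff_mz$n + suff_dz$n))
  clamp <- function(x) max(0.02, min(0.95, x))
  start_share <- switch(model,
    E   = c(),
    AE  = c(a = clamp(rmz)),
    ACE = c(a = clamp(2 * (rmz - rdz)), c = clamp(2 * rdz - rmz)),
    ADE = c(a = clamp(4 * rdz - rmz), d = clamp(2 * rmz - 4 * rdz)))
  e_share <- max(0.02, 1 - sum(start_share))
  par0 <- c(mu0, sqrt(c(start_share, e = e_share) * v0))

  opt <- optim(par0, nll_univariate, model = model, suff_mz = suff_mz,
               suff_dz = suff_dz, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  ## polish from the Nelder-Mead solution
  opt2 <- optim(opt$par, nll_univariate, model = model, suff_mz = suff_mz,
                suff_dz = suff_dz, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-12))
  if (opt2$value <= opt$value) opt <- opt2
  if (!is.finite(opt$value))
    stop2("twin model optimization failed to converge; trace: ",
          paste(format(opt$par, digits = 4), collapse = ", "))

  comp_names <- c(TWIN_MODELS[[model]], "e")
  paths <- setNames(abs(opt$par[-1]), comp_names)
  v <- sum(paths^2)
  shares <- setNames(paths^2 / v, paste0(comp_names, "2"))
  boundary <- any(shares < 1e-4)

  fit <- structure(list(
    model = model, trait = trait %||% attr(paired$MZ, "traits")[1],
    mu = opt$par[1], paths = paths, total_variance = v, shares = shares,
    loglik = -opt$value / 2, n_pairs = c(MZ = suff_mz$n, DZ = suff_dz$n),
    convergence = opt$convergence == 0, boundary = boundary,
    fingerprint = list(mz = suff_mz$fingerprint, dz = suff_dz$fingerprint),
    suff = list(mz = suff_mz, dz = suff_dz),
    icc = c(MZ = rmz, DZ = rdz)
  ), class = "twin_fit")

  if (ci == "profile" && model != "E") {
    fit$ci <- t(vapply(seq_along(shares), function(i) {
      profile_ci_share(fit, comp = i, conf = conf)
    }, numeric(2)))
    dimnames(fit$ci) <- list(names(shares), c("lower", "upper"))
    fit$conf <- conf
  }
  fit
}

## profile -2 loglik with the share of component `comp` fixed at s.
## Free parameters: mu, log total variance, and (for 3-component models) a
## logit mixing how the remaining 1-s splits between the other components.
profile_nll_share <- function(s, comp, fit) {
  model <- fit$model
  comp_names <- c(TWIN_MODELS[[model]], "e")
  k <- length(comp_names)
  others <- setdiff(seq_len(k), comp)
  obj <- function(free) {
    mu <- free[1]; v <- exp(free[2])
    rest <- 1 - s
    if (k == 2) {
      sh <- numeric(2); sh[comp] <- s; sh[others] <- rest
    } else {
      w <- stats::plogis(free[3])
      sh <- numeric(3); sh[comp] <- s
      sh[others] <- rest * c(w, 1 - w)
    }
    paths2 <- setNames(sh * v, comp_names)
    args <- list(a2 = 0, c2 = 0, d2 = 0,
                 e2 = paths2[["e"]])
    for (nm in setdiff(comp_names, "e")) args[[paste0(nm, "2")]] <- paths2[[nm]]
    cv <- do.call(twin_cov, args)
    nll_group2(fit$suff$mz, cv$v, cv$mz, mu) +
      nll_group2(fit$suff$dz, cv$v, cv$dz, mu)
  }
  free0 <- c(fit$mu, log(fit$total_variance))
  if (k == 3) {
    sh_hat <- fit$shares[others]
    w0 <- sh_hat[1] / max(sum(sh_hat), 1e-8)
    free0 <- c(free0, stats::qlogis(min(max(w0, 1e-6), 1 - 1e-6)))
  }
  optim(free0, obj, method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-11))$value
}

## profile-likelihood CI for one standardized share (component index `comp`)
profile_ci_share <- function(fit, comp, conf = 0.95) {
  crit <- qchisq(conf, df = 1)
  n2ll_hat <- -2 * fit$loglik
  s_hat <- unname(fit$shares[comp])
  g <- function(s) (profile_nll_share(s, comp, fit) - n2ll_hat) - crit
  eps <- 1e-6
  lower <- if (s_hat <= eps || g(eps) < 0) 0 else
    uniroot(g, c(eps, s_hat), tol = 1e-5)$root
  upper <- if (s_hat >= 1 - eps || g(1 - eps) < 0) 1 else
    uniroot(g, c(s_hat, 1 - eps), tol = 1e-5)$root
  c(lower, upper)
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("%s twin model, trait '%s': logLik = %.2f, pairs MZ/DZ = %d/%d\n",
              x$model, x$trait, x$loglik, x$n_pairs["MZ"], x$n_pairs["DZ"]))
  for (i in seq_along(x$shares)) {
    ci_txt <- if (!is.null(x$ci))
      sprintf(" (%.0f%% CI %.3f, %.3f)", 100 * (x$conf %||% 0.95),
              x$ci[i, 1], x$ci[i, 2]) else ""
    cat(sprintf("  %s = %.3f%s\n", names(x$shares)[i], x$shares[i], ci_txt))
  }
  if (x$boundary) cat("  note: boundary solution (a share pinned near 0)\n")
  invisible(x)
}

#' Likelihood-ratio comparison of nested twin models
#'
#' @param parent the richer model fit (e.g. ACE or ADE).
#' @param submodel the nested fit (e.g. AE), fitted to the same data.
#' @return list with `lr`, `df`, `p.value`, `aic_diff`
#'   (AIC(parent) - AIC(submodel)), and a `boundary_note` recording that the
#'   chi-square reference is conservative when the tested share sits on the
#'   boundary of its parameter space.
#' @export
compare_models <- function(parent, submodel) {
  if (!inherits(parent, "twin_fit") || !inherits(submodel, "twin_fit"))
    stop2("compare_models expects twin_fit objects")
  nested <- list(AE = c("ACE", "ADE"), E = c("AE", "ACE", "ADE"))
  same_model <- identical(parent$model, submodel$model)
  if (!same_model &&
      (!submodel$model %in% names(nested) ||
       !parent$model %in% nested[[submodel$model]]))
    stop2(submodel$model, " is not nested in ", parent$model)
  same <- isTRUE(all.equal(parent$fingerprint, submodel$fingerprint,
                           tolerance = 1e-12))
  if (!same) stop2("fits were computed on different data")
  df <- length(parent$paths) - length(submodel$paths)
  lr <- 2 * (parent$loglik - submodel$loglik)
  if (lr < -1e-6)
    warning("negative LR statistic (", format(lr),
            "): parent fit did not reach its optimum")
  lr <- max(lr, 0)
  k_par <- length(parent$paths) + 1L   # + mean
  k_sub <- length(submodel$paths) + 1L
  p <- if (df == 0) 1 else pchisq(lr, df, lower.tail = FALSE)
  list(parent = parent$model, submodel = submodel$model,
       lr = lr, df = df, p.value = p,
       aic_diff = (2 * k_par - 2 * parent$loglik) -
         (2 * k_sub - 2 * submodel$loglik),
       boundary_note = paste("variance shares are tested on the boundary;",
                             "the chi-square p-value is conservative"))
}

## ---- bivariate AE Cholesky ------------------------------------------------

## sufficient statistics for (n x 4) matrices ordered
## (twin1 trait1, twin1 trait2, twin2 trait1, twin2 trait2)
quad_suff <- function(Y) {
  Y <- as.matrix(Y)
  m <- colMeans(Y)
  list(n = nrow(Y), m = m, S = crossprod(sweep(Y, 2, m)))
}

nll_group4 <- function(suff, Sigma, mu) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdet <- 2 * sum(log(diag(ch)))
  dm <- suff$m - mu
  Tm <- suff$S + suff$n * tcrossprod(dm)
  Sinv <- chol2inv(ch)
  suff$n * (4 * log(2 * pi) + logdet) + sum(Sinv * Tm)
}

biv_sigma <- function(pa, r_g) {
  La <- matrix(c(pa["a11"], pa["a21"], 0, pa["a22"]), 2)
  Le <- matrix(c(pa["e11"], pa["e21"], 0, pa["e22"]), 2)
  Ga <- tcrossprod(La)
  Ee <- tcrossprod(Le)
  Sw <- Ga + Ee
  rbind(cbind(Sw, r_g * Ga), cbind(r_g * Ga, Sw))
}

nll_bivariate <- function(par, suff_mz, suff_dz) {
  mu <- rep(par[1:2], 2)
  pa <- setNames(par[3:8], c("a11", "a21", "a22", "e11", "e21", "e22"))
  nll_group4(suff_mz, biv_sigma(pa, 1), mu) +
    nll_group4(suff_dz, biv_sigma(pa, 0.5), mu)
}

## moment-based starting values for the Cholesky paths
biv_start <- function(Ymz, Ydz) {
  per_twin <- function(Y) rbind(Y[, 1:2], Y[, 3:4])
  Cw <- (cov(per_twin(Ymz)) * nrow(Ymz) + cov(per_twin(Ydz)) * nrow(Ydz)) /
    (nrow(Ymz) + nrow(Ydz))
  cross <- function(Y) {
    Cx <- cov(Y)[1:2, 3:4]
    (Cx + t(Cx)) / 2
  }
  G0 <- 2 * (cross(Ymz) - cross(Ydz))
  floor_pd <- function(M, lo = 0.05) {
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    eg$vectors %*% diag(pmax(eg$values, lo)) %*% t(eg$vectors)
  }
  G0 <- floor_pd(G0)
  E0 <- floor_pd(Cw - G0)
  c(t(chol(G0))[c(1, 2, 4)], t(chol(E0))[c(1, 2, 4)])
}

#' Bivariate AE Cholesky decomposition
#'
#' Maximizes the 4-variate normal twin likelihood with lower-triangular
#' genetic (`a11`, `a21`, `a22`) and nonshared-environment (`e11`, `e21`,
#' `e22`) paths; the cross-twin cross-trait covariance is the genetic
#' covariance scaled by the zygosity genetic correlation (1 MZ, 0.5 DZ).
#' Derived quantities: genetic correlation `ra`, environmental correlation
#' `re`, per-trait heritabilities, and the genetic share of the phenotypic
#' covariance `a11*a21 / (a11*a21 + e11*e21)`. Confidence intervals by
#' family-level bootstrap (resampling pairs within zygosity groups).
#'
#' @param paired a `paired_set` holding exactly two traits (SS-DZ and OS-DZ
#'   pooled as DZ).
#' @param traits optional two trait names (default: the traits of `paired`).
#' @param ci `"none"` (default) or `"bootstrap"`.
#' @param draws bootstrap draws (default 1000).
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap.
#' @return object of class `cholesky_fit` with `paths`, `ra`, `re`,
#'   `genetic_share`, `h2` (per trait), `rp_implied`, `loglik`, `n_pairs`,
#'   `heywood` flag, and optional `ci`.
#' @export
fit_bivariate_cholesky <- function(paired, traits = NULL,
                                   ci = c("none", "bootstrap"),
                                   draws = 1000, conf = 0.95, seed = NULL) {
  ci <- match.arg(ci)
  traits <- traits %||% attr(paired$MZ, "traits")
  if (length(traits) != 2) stop2("exactly two traits are required")
  quad <- function(pm) cbind(pm_trait(pm, traits[1])[, 1],
                             pm_trait(pm, traits[2])[, 1],
                             pm_trait(pm, traits[1])[, 2],
                             pm_trait(pm, traits[2])[, 2])
  Ymz <- quad(paired$MZ)
  dz_names <- intersect(c("DZSS", "DZOS", "DZ"), names(paired))
  Ydz <- do.call(rbind, lapply(paired[dz_names], quad))

  fit_once <- function(Ymz, Ydz, par0 = NULL) {
    suff_mz <- quad_suff(Ymz)
    suff_dz <- quad_suff(Ydz)
    if (is.null(par0)) {
      cm <- colMeans(rbind(Ymz, Ydz))
      par0 <- c((cm[1:2] + cm[3:4]) / 2, biv_start(Ymz, Ydz))
    }
    opt <- optim(par0, nll_bivariate, suff_mz = suff_mz, suff_dz = suff_dz,
                 method = "Nelder-Mead",
                 control = list(maxit = 10000, reltol = 1e-12))
    opt2 <- optim(opt$par, nll_bivariate, suff_mz = suff_mz,
                  suff_dz = suff_dz, method = "BFGS",
                  control = list(maxit = 1000, reltol = 1e-12))
    if (opt2$value <= opt$value) opt <- opt2
    opt
  }
  opt <- fit_once(Ymz, Ydz)
  if (!is.finite(opt$value)) stop2("bivariate Cholesky failed to converge")
  derive <- function(par) {
    pa <- setNames(par[3:8], c("a11", "a21", "a22", "e11", "e21", "e22"))
    ## sign normalization: flipping a whole column of the Cholesky factor
    ## leaves the covariance unchanged
    if (pa["a11"] < 0) pa[c("a11", "a21")] <- -pa[c("a11", "a21")]
    pa["a22"] <- abs(pa["a22"])
    if (pa["e11"] < 0) pa[c("e11", "e21")] <- -pa[c("e11", "e21")]
    pa["e22"] <- abs(pa["e22"])
    g_cov <- pa["a11"] * pa["a21"]
    e_cov <- pa["e11"] * pa["e21"]
    v1 <- pa["a11"]^2 + pa["e11"]^2
    v2 <- pa["a21"]^2 + pa["a22"]^2 + pa["e21"]^2 + pa["e22"]^2
    c(pa,
      ra = unname(pa["a21"] / sqrt(pa["a21"]^2 + pa["a22"]^2)),
      re = unname(pa["e21"] / sqrt(pa["e21"]^2 + pa["e22"]^2)),
      genetic_share = unname(g_cov / (g_cov + e_cov)),
      h2_1 = unname(pa["a11"]^2 / v1),
      h2_2 = unname((pa["a21"]^2 + pa["a22"]^2) / v2),
      rp_implied = unname((g_cov + e_cov) / sqrt(v1 * v2)))
  }
  dv <- derive(opt$par)
  fit <- structure(list(
    traits = traits,
    mu = opt$par[1:2],
    paths = dv[1:6],
    ra = dv[["ra"]], re = dv[["re"]],
    genetic_share = dv[["genetic_share"]],
    h2 = setNames(c(dv[["h2_1"]], dv[["h2_2"]]), traits),
    rp_implied = dv[["rp_implied"]],
    loglik = -opt$value / 2,
    n_pairs = c(MZ = nrow(Ymz), DZ = nrow(Ydz)),
    convergence = opt$convergence == 0,
    heywood = dv[["genetic_share"]] < 0 || dv[["genetic_share"]] > 1
  ), class = "cholesky_fit")

  if (ci == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    stat <- matrix(NA_real_, draws, 3,
                   dimnames = list(NULL, c("ra", "re", "genetic_share")))
    for (b in seq_len(draws)) {
      bz <- fit_once(Ymz[sample.int(nrow(Ymz), replace = TRUE), ],
                     Ydz[sample.int(nrow(Ydz), replace = TRUE), ],
                     par0 = opt$par)
      dvb <- derive(bz$par)
      stat[b, ] <- dvb[c("ra", "re", "genetic_share")]
    }
    al <- (1 - conf) / 2
    fit$ci <- apply(stat, 2, quantile, probs = c(al, 1 - al))
    fit$draws <- draws
  }
  fit
}

#' @export
print.cholesky_fit <- function(x, ...) {
  cat(sprintf("bivariate AE Cholesky (%s, %s): logLik = %.2f, pairs MZ/DZ = %d/%d\n",
              x$traits[1], x$traits[2], x$loglik,
              x$n_pairs["MZ"], x$n_pairs["DZ"]))
  cat(sprintf("  ra = %.3f, re = %.3f\n", x$ra, x$re))
  cat(sprintf("  genetic share of covariance = %.1f%%\n",
              100 * x$genetic_share))
  cat(sprintf("  h2: %s = %.2f, %s = %.2f; implied rp = %.3f\n",
              x$traits[1], x$h2[1], x$traits[2], x$h2[2], x$rp_implied))
  if (x$heywood) cat("  warning: Heywood-like solution (share outside [0,1])\n")
  invisible(x)
}
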