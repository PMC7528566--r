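## Single-mediator structural models (product of coefficients) with
## family-clustered sandwich errors and bias-corrected bootstrap CIs.
## For a saturated linear path model the two-regression estimates coincide
## with a joint SEM fit: a from m ~ x, (b, c) from y ~ m + x, and the
## total effect c + a*b equals the slope of y ~ x on the same sample.

## standardized path coefficients from the correlation matrix of (x, m, y);
## used by the bootstrap for speed
paths_from_cor <- function(r_xm, r_xy, r_my) {
  den <- 1 - r_xm^2
  b <- (r_my - r_xy * r_xm) / den
  cc <- (r_xy - r_my * r_xm) / den
  c(a = r_xm, b = b, c = cc, total = r_xy, indirect = r_xm * b)
}

#' Fit a single-mediator linear path model
#'
#' Estimates the exposure-to-mediator path `a` (from `m ~ x`), the
#' mediator-to-outcome path `b` and direct effect `c` (from `y ~ m + x`),
#' and the total effect (from `y ~ x`; equal to `c + a*b` exactly on the
#' same sample). Inputs are expected to be pre-residualized on age, sex and
#' genetic principal components; variables are z-scored so coefficients are
#' standardized betas. Standard errors are family-clustered (CR1 sandwich,
#' p-values on G-1 df).
#'
#' @param x,m,y exposure, mediator, outcome vectors.
#' @param families family (cluster) identifiers.
#' @param standardize z-score the inputs (default TRUE).
#' @param draws if > 0, also compute [bc_bootstrap()] CIs with this many
#'   draws.
#' @param seed seed for the bootstrap.
#' @param conf confidence level for bootstrap CIs.
#' @return object of class `mediation_fit`: `paths` (a, b, c with `se` and
#'   `p`), `effects` (total, direct, indirect), `percentage_mediation`,
#'   `n`, `n_families`, and optionally `ci`/`draws`.
#' @examples
#' d <- simulate_prs_mediation(
#'   mediation_model(0.15, 0.38, 0.23, n_individuals = 949), seed = 7)
#' fit_mediation(d$prs_bmi, d$pattern, d$bmi, d$family_id)
#' @export
fit_mediation <- function(x, m, y, families, standardize = TRUE,
                          draws = 0, seed = NULL, conf = 0.95) {
  n <- length(x)
  if (length(m) != n || length(y) != n || length(families) != n)
    stop2("x, m, y and families must have equal length")
  if (anyNA(x) || anyNA(m) || anyNA(y))
    stop2("inputs contain missing values; residualize on complete cases")
  G <- length(unique(families))
  if (G < 30)
    warning("only ", G, " families: clustered inference may be unreliable")
  if (abs(cor(m, x)) > 0.99)
    stop2("mediator and exposure are collinear (|r| > 0.99)")
  if (standardize) {
    x <- zscore(x); m <- zscore(m); y <- zscore(y)
  }
  Xa <- cbind(`(intercept)` = 1, x = x)
  Xbc <- cbind(`(intercept)` = 1, m = m, x = x)
  fa <- lm_cluster(m, Xa, families)
  fbc <- lm_cluster(y, Xbc, families)
  ftot <- lm_cluster(y, Xa, families)
  a <- unname(fa$coef["x"]); b <- unname(fbc$coef["m"])
  cc <- unname(fbc$coef["x"]); total <- unname(ftot$coef["x"])
  indirect <- a * b
  stopifnot(abs(total - (cc + indirect)) < 1e-10)  # linear-model identity
  pm <- if (sign(indirect) == sign(total) && total != 0)
    100 * indirect / total else NA_real_
  fit <- structure(list(
    paths = data.frame(
      path = c("a", "b", "c"),
      estimate = c(a, b, cc),
      se = unname(c(fa$se["x"], fbc$se["m"], fbc$se["x"])),
      p = unname(c(fa$p["x"], fbc$p["m"], fbc$p["x"])),
      row.names = NULL),
    effects = c(total = total, direct = cc, indirect = indirect),
    total_se = unname(ftot$se["x"]), total_p = unname(ftot$p["x"]),
    percentage_mediation = pm,
    n = n, n_families = G
  ), class = "mediation_fit")
  if (draws > 0) {
    bb <- bc_bootstrap(x, m, y, families, draws = draws, seed = seed,
                       conf = conf, standardize = FALSE)
    fit$ci <- bb$ci
    fit$draws <- draws
    fit$z0 <- bb$z0
  }
  fit
}

#' Bias-corrected cluster bootstrap for mediation effects
#'
#' Resamples whole families with replacement (co-twins stay together, so
#' the within-family dependence is preserved), recomputes standardized
#' total/direct/indirect effects on each draw, and forms bias-corrected
#' percentile intervals: the correction \eqn{z_0} is the normal quantile of
#' the fraction of bootstrap estimates below the point estimate; no
#' acceleration term.
#'
#' @inheritParams fit_mediation
#' @param draws number of bootstrap draws (>= 200).
#' @return list with `ci` (3 x 2 matrix for total/direct/indirect), `z0`,
#'   `draws`, and the bootstrap `replicates` matrix.
#' @export
bc_bootstrap <- function(x, m, y, families, draws = 1000, seed = NULL,
                         conf = 0.95, standardize = TRUE) {
  check_number(draws, "draws", lower = 200)
  if (standardize) {
    x <- zscore(x); m <- zscore(m); y <- zscore(y)
  }
  if (!is.null(seed)) set.seed(seed)
  R <- cor(cbind(x, m, y))
  est <- paths_from_cor(R[1, 2], R[1, 3], R[2, 3])[c("total", "c", "indirect")]
  names(est) <- c("total", "direct", "indirect")

  idx_by_fam <- split(seq_along(x), families)
  G <- length(idx_by_fam)
  reps <- matrix(NA_real_, draws, 3,
                 dimnames = list(NULL, c("total", "direct", "indirect")))
  for (bz in seq_len(draws)) {
    idx <- unlist(idx_by_fam[sample.int(G, replace = TRUE)],
                  use.names = FALSE)
    Rb <- cor(cbind(x[idx], m[idx], y[idx]))
    pb <- paths_from_cor(Rb[1, 2], Rb[1, 3], Rb[2, 3])
    reps[bz, ] <- pb[c("total", "c", "indirect")]
  }
  al <- (1 - conf) / 2
  z_al <- qnorm(c(al, 1 - al))
  ci <- matrix(NA_real_, 3, 2,
               dimnames = list(c("total", "direct", "indirect"),
                               c("lower", "upper")))
  z0 <- numeric(3)
  for (i in 1:3) {
    bdist <- reps[, i]
    if (max(bdist) - min(bdist) < 1e-12)
      stop2("degenerate bootstrap distribution for the ",
            colnames(reps)[i], " effect")
    frac <- mean(bdist < est[i])
    frac <- min(max(frac, 1 / (draws + 1)), draws / (draws + 1))
    z0[i] <- qnorm(frac)
    probs <- pnorm(2 * z0[i] + z_al)
    ci[i, ] <- quantile(bdist, probs, names = FALSE)
  }
  list(ci = ci, z0 = setNames(z0, c("total", "direct", "indirect")),
       draws = draws, replicates = reps)
}

#' Percentage mediation
#'
#' `100 * indirect / total`, computed from the unrounded estimates by
#' default. `rounded = TRUE` reproduces the display convention of rounding
#' the two effects to `digits` decimals before taking the ratio (e.g.
#' 0.06 / 0.29 = 20.7%). Suppressed (NA, with a message) when the indirect
#' and total effects have opposite signs: the ratio is not interpretable
#' under inconsistent mediation.
#'
#' @param fit a `mediation_fit`.
#' @param rounded use the rounded-display convention?
#' @param digits decimals for the rounded convention.
#' @return percentage (scalar), or NA for inconsistent mediation.
#' @export
percentage_mediation <- function(fit, rounded = FALSE, digits = 2) {
  eff <- fit$effects
  if (eff["total"] == 0) stop2("total effect is zero")
  if (sign(eff["indirect"]) != sign(eff["total"])) {
    message("inconsistent mediation (indirect and total effects have ",
            "opposite signs); percentage suppressed")
    return(NA_real_)
  }
  if (rounded) {
    unname(100 * round(eff["indirect"], digits) / round(eff["total"], digits))
  } else {
    unname(100 * eff["indirect"] / eff["total"])
  }
}

#' Test whether mediation paths differ by sex
#'
#' Adds `x:sex` to the mediator equation and `x:sex`, `m:sex` to the
#' outcome equation, with family-clustered Wald p-values. Inputs should be
#' residualized on age and genetic PCs but not on sex. If any interaction
#' is significant at `alpha`, sex-stratified mediation fits are returned as
#' well.
#'
#' @inheritParams fit_mediation
#' @param sex binary sex vector (any two values; e.g. 1 = male, 2 = female).
#' @param alpha significance level for reporting stratified fits.
#' @return list with `coefficients` (term, estimate, se, p for the
#'   interaction terms), `any_significant`, and `stratified` (named list of
#'   `mediation_fit`s, present when any interaction p < alpha).
#' @export
sex_interaction_test <- function(x, m, y, sex, families, alpha = 0.05) {
  lv <- sort(unique(sex))
  if (length(lv) < 2) stop2("sex is constant; need both sexes")
  if (length(lv) > 2) stop2("sex must be binary")
  s <- as.numeric(sex == lv[2])
  x <- zscore(x); m <- zscore(m); y <- zscore(y)
  Xm <- cbind(`(intercept)` = 1, x = x, sex = s, `x:sex` = x * s)
  Xy <- cbind(`(intercept)` = 1, m = m, x = x, sex = s,
              `x:sex` = x * s, `m:sex` = m * s)
  fm <- lm_cluster(m, Xm, families)
  fy <- lm_cluster(y, Xy, families)
  coefs <- data.frame(
    equation = c("mediator", "outcome", "outcome"),
    term = c("x:sex", "x:sex", "m:sex"),
    estimate = unname(c(fm$coef["x:sex"], fy$coef["x:sex"], fy$coef["m:sex"])),
    se = unname(c(fm$se["x:sex"], fy$se["x:sex"], fy$se["m:sex"])),
    p = unname(c(fm$p["x:sex"], fy$p["x:sex"], fy$p["m:sex"])),
    row.names = NULL)
  any_sig <- any(coefs$p < alpha)
  out <- list(coefficients = coefs, any_significant = any_sig)
  if (any_sig) {
    out$stratified <- lapply(setNames(lv, paste0("sex_", lv)), function(l) {
      sel <- sex == l
      fit_mediation(x[sel], m[sel], y[sel], families[sel])
    })
  }
  out
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("mediation fit: n = %d individuals, %d families\n",
              x$n, x$n_families))
  cat(sprintf("  a = %.3f (p = %.2g), b = %.3f (p = %.2g), c = %.3f (p = %.2g)\n",
              x$paths$estimate[1], x$paths$p[1],
              x$paths$estimate[2], x$paths$p[2],
              x$paths$estimate[3], x$paths$p[3]))
  cat(sprintf("  total = %.3f, direct = %.3f, indirect = %.3f\n",
              x$effects["total"], x$effects["direct"], x$effects["indirect"]))
  if (!is.null(x$ci)) {
    cat(sprintf("  BC bootstrap (%d draws) 95%% CI, indirect: (%.3f, %.3f)\n",
                x$draws, x$ci["indirect", 1], x$ci["indirect", 2]))
  }
  if (!is.na(x$percentage_mediation))
    cat(sprintf("  percentage mediation = %.1f%%\n", x$percentage_mediation))
  invisible(x)
}
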