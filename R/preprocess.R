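## Covariate residualization, derived obesity measures, and pairing of the
## long cohort table into per-zygosity wide matrices.

#' Residualize a variable on covariates
#'
#' Least-squares residuals of `values` on an intercept plus the covariate
#' columns. Residuals are exactly orthogonal (to machine precision) to the
#' intercept and every covariate column, which is what downstream twin and
#' mediation models assume of their inputs.
#'
#' @param values numeric vector without missing entries.
#' @param covariates numeric matrix / data.frame of covariates (may be
#'   `NULL`, in which case only the mean is removed).
#' @return residual vector, same length as `values`.
#' @examples
#' age <- runif(100, 31, 37)
#' y <- 0.5 * age + rnorm(100)
#' r <- residualize(y, cbind(age = age))
#' max(abs(crossprod(cbind(1, age), r)))  # ~ 0
#' @export
residualize <- function(values, covariates = NULL) {
  values <- as.numeric(values)
  if (anyNA(values)) stop2("values contain missing entries")
  X <- matrix(1, length(values), 1, dimnames = list(NULL, "(intercept)"))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (anyNA(C)) stop2("covariates contain missing entries")
    if (nrow(C) != length(values))
      stop2("covariates must have one row per observation")
    if (is.null(colnames(C))) colnames(C) <- paste0("cov", seq_len(ncol(C)))
    X <- cbind(X, C)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop2("covariate matrix is rank deficient; collinear column(s): ",
          paste(bad, collapse = ", "))
  }
  as.numeric(qr.resid(qr_x, values))
}

#' Waist circumference adjusted for BMI
#'
#' Residualizes waist circumference on BMI (plus intercept), giving an index
#' of abdominal fat distribution independent of overall adiposity.
#'
#' @param wc waist circumference (cm).
#' @param bmi body mass index (kg/m^2).
#' @return adjusted-WC vector, orthogonal to BMI.
#' @export
adjust_wc_for_bmi <- function(wc, bmi) {
  residualize(wc, cbind(bmi = as.numeric(bmi)))
}

#' Pair a long cohort table into per-zygosity wide matrices
#'
#' Retains only complete twin pairs (both co-twins present, no missing value
#' in any requested trait) and arranges them one pair per row with columns
#' `<trait>_t1`, `<trait>_t2`. Twin-order assignment is taken from the input
#' as given; no re-sorting within pairs.
#'
#' @param data cohort `data.frame` with `family_id`, `twin_order`,
#'   `zygosity` columns.
#' @param traits character vector of trait column names to carry.
#' @return named list (one element per zygosity present) of `paired_matrix`
#'   data.frames (`family_id` plus `_t1`/`_t2` trait columns); attribute
#'   `"counts"` reports pairs retained and individuals dropped per group.
#' @export
pair_wide <- function(data, traits) {
  if (length(traits) == 0) stop2("traits must name at least one column")
  missing_cols <- setdiff(c("family_id", "twin_order", "zygosity", traits),
                          names(data))
  if (length(missing_cols))
    stop2("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(data$twin_order %in% 1:2)) stop2("twin_order must be 1 or 2")
  key <- paste(data$family_id, data$twin_order)
  if (anyDuplicated(key))
    stop2("duplicate (family_id, twin_order) row(s): ",
          paste(unique(key[duplicated(key)]), collapse = "; "))

  complete_row <- stats::complete.cases(data[traits])
  d <- data[complete_row, , drop = FALSE]
  tab <- table(d$family_id)
  keep_fam <- names(tab)[tab == 2L]
  d <- d[as.character(d$family_id) %in% keep_fam, , drop = FALSE]
  d <- d[order(match(as.character(d$family_id), keep_fam), d$twin_order), ,
         drop = FALSE]

  out <- list()
  counts <- list()
  for (z in unique(d$zygosity)) {
    dz <- d[d$zygosity == z, , drop = FALSE]
    t1 <- dz[dz$twin_order == 1L, , drop = FALSE]
    t2 <- dz[dz$twin_order == 2L, , drop = FALSE]
    stopifnot(identical(t1$family_id, t2$family_id))
    w <- data.frame(family_id = t1$family_id)
    for (tr in traits) {
      w[[paste0(tr, "_t1")]] <- t1[[tr]]
      w[[paste0(tr, "_t2")]] <- t2[[tr]]
    }
    class(w) <- c("paired_matrix", "data.frame")
    attr(w, "zygosity") <- z
    attr(w, "traits") <- traits
    out[[z]] <- w
    counts[[z]] <- nrow(w)
  }
  attr(out, "counts") <- list(
    pairs = counts,
    individuals_in = nrow(data),
    individuals_retained = 2L * sum(unlist(counts)),
    dropped_incomplete = nrow(data) - 2L * sum(unlist(counts))
  )
  class(out) <- c("paired_set", "list")
  out
}

#' Undo [pair_wide()] for one zygosity group
#'
#' @param paired a `paired_matrix`.
#' @return long `data.frame` with `family_id`, `twin_order` and trait columns.
#' @export
unpair_wide <- function(paired) {
  traits <- attr(paired, "traits")
  long <- do.call(rbind, lapply(1:2, function(tw) {
    d <- data.frame(family_id = paired$family_id, twin_order = tw)
    for (tr in traits) d[[tr]] <- paired[[paste0(tr, "_", c("t1", "t2")[tw])]]
    d
  }))
  long[order(match(long$family_id, paired$family_id), long$twin_order), ,
       drop = FALSE]
}

## extract the (n x 2) twin-pair matrix for one trait from a paired_matrix
pm_trait <- function(paired, trait = NULL) {
  traits <- attr(paired, "traits")
  if (is.null(trait)) {
    if (length(traits) != 1L)
      stop2("paired matrix holds ", length(traits),
            " traits; specify `trait`")
    trait <- traits
  }
  cols <- paste0(trait, c("_t1", "_t2"))
  if (!all(cols %in% names(paired))) stop2("trait ", trait, " not present")
  as.matrix(paired[cols])
}

#' Pearson partial correlation with family-clustered p-value
#'
#' Correlation of two covariate-residualized vectors; the p-value comes from
#' regressing one standardized residual on the other with family-clustered
#' sandwich standard errors (robust to co-twin non-independence).
#'
#' @param x,y numeric vectors of common length.
#' @param covariates covariate matrix (or `NULL` for a plain correlation).
#' @param families cluster (family) identifiers.
#' @return list with `estimate`, `p.value`, `n`, `n_families`.
#' @export
partial_correlation <- function(x, y, covariates = NULL, families) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  if (length(families) != length(x))
    stop2("families must match the data length")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    stop2("zero variance after residualization")
  zx <- zscore(rx); zy <- zscore(ry)
  r <- cor(zx, zy)
  fit <- lm_cluster(zy, cbind(`(intercept)` = 1, x = zx), families)
  list(estimate = r, p.value = unname(fit$p["x"]), n = length(x),
       n_families = fit$n_clusters)
}
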