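## Canonical cohort table I/O and a full synthetic cohort combining the
## pattern-factor, twin-variance and polygenic-score structures, used by the
## end-to-end pipeline.

COHORT_ID_COLS <- c("family_id", "twin_order", "zygosity", "sex", "age")

#' Write a cohort table as CSV
#'
#' Canonical schema: `family_id, twin_order (1/2), zygosity (MZ/DZSS/DZOS),
#' sex (1/2), age, bmi, wc, item_01..item_15, dqs, prs_bmi, prs_whr,
#' gpc_1..gpc_10`; optional columns may be absent.
#'
#' @param data cohort `data.frame`.
#' @param path output file.
#' @export
write_cohort <- function(data, path) {
  miss <- setdiff(COHORT_ID_COLS, names(data))
  if (length(miss))
    stop2("cohort table lacks required column(s): ",
          paste(miss, collapse = ", "))
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV and validate the schema
#'
#' @param path input CSV.
#' @return cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop2("schema error: input is empty")
  miss <- setdiff(COHORT_ID_COLS, names(d))
  if (length(miss))
    stop2("schema error: missing column(s): ", paste(miss, collapse = ", "))
  if (!all(d$zygosity %in% c("MZ", "DZSS", "DZOS")))
    stop2("schema error: zygosity must be MZ, DZSS or DZOS")
  d
}

#' Simulate a complete synthetic twin cohort
#'
#' A demonstration-grade cohort for end-to-end pipeline runs: four latent
#' eating-behavior pattern phenotypes and two obesity phenotypes (BMI, WC)
#' with AE twin structure and a chosen genetic correlation matrix; 16
#' questionnaire variables (15 items + a diet-quality score) loading the
#' pattern phenotypes with simple structure; and a polygenic-score column
#' built from the BMI additive factor so that its squared correlation with
#' BMI is `prs_r2`. Ten pure-noise genetic principal components are included
#' so the residualization stage has realistic inputs.
#'
#' Defaults mirror a cohort of 527 MZ, 470 same-sex DZ and 503 opposite-sex
#' DZ pairs with pattern heritabilities 0.36-0.48, BMI/WC heritabilities
#' 0.76/0.62, and a snacking-BMI phenotypic correlation of 0.35 of which
#' 75% is genetic.
#'
#' @param n_mz,n_dzss,n_dzos pair counts per zygosity group.
#' @param h2_patterns heritabilities of the 4 pattern phenotypes.
#' @param h2_bmi,h2_wc obesity-trait heritabilities.
#' @param prs_r2 squared PRS-BMI correlation.
#' @param item_loading loading of each questionnaire variable on its pattern.
#' @param seed integer seed.
#' @return long cohort `data.frame` in the canonical schema, with the
#'   generating pattern phenotypes attached as attribute `"patterns"`.
#' @export
simulate_cohort <- function(n_mz = 527, n_dzss = 470, n_dzos = 503,
                            h2_patterns = c(0.48, 0.40, 0.36, 0.44),
                            h2_bmi = 0.76, h2_wc = 0.62,
                            prs_r2 = 0.083, item_loading = 0.55,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(h2_patterns) == 4)
  h2 <- c(h2_patterns, bmi = h2_bmi, wc = h2_wc)
  k <- length(h2)

  ## genetic / environmental cross-trait correlations (traits: P1..P4, bmi, wc)
  Ra <- diag(k); Re <- diag(k)
  set_pair <- function(R, i, j, val) { R[i, j] <- R[j, i] <- val; R }
  ## snacking (P1) and emotional/external (P4) correlate with obesity;
  ## targets: rp 0.35/0.32 (P1) and 0.26/0.23 (P4), ~75% genetic
  tgt <- list(c(1, 5, 0.35, 0.75), c(1, 6, 0.32, 0.71),
              c(4, 5, 0.26, 0.75), c(4, 6, 0.23, 0.64))
  for (tg in tgt) {
    i <- tg[1]; j <- tg[2]; rp <- tg[3]; gs <- tg[4]
    Ra <- set_pair(Ra, i, j, gs * rp / sqrt(h2[i] * h2[j]))
    Re <- set_pair(Re, i, j, (1 - gs) * rp / sqrt((1 - h2[i]) * (1 - h2[j])))
  }
  Ra <- set_pair(Ra, 5, 6, 0.80)  # bmi-wc genetic overlap
  Re <- set_pair(Re, 5, 6, 0.60)
  Sa <- diag(sqrt(h2)) %*% Ra %*% diag(sqrt(h2))
  Se <- diag(sqrt(1 - h2)) %*% Re %*% diag(sqrt(1 - h2))
  if (min(eigen(Sa, symmetric = TRUE)$values) < 1e-8 ||
      min(eigen(Se, symmetric = TRUE)$values) < 1e-8)
    stop2("cross-trait correlation targets imply a non-PD covariance")

  zygosity <- c(rep("MZ", n_mz), rep("DZSS", n_dzss), rep("DZOS", n_dzos))
  out <- cohort_frame(zygosity)
  n_fam <- length(zygosity)
  Y <- matrix(0, 2 * n_fam, k)
  A_bmi <- numeric(2 * n_fam)
  for (grp in list(c("MZ", 1), c("DZSS", 0.5), c("DZOS", 0.5))) {
    idx_fam <- which(zygosity == grp[1])
    n <- length(idx_fam)
    if (n == 0) next
    rg <- as.numeric(grp[2])
    A <- matrix(rnorm(2 * k * n), n) %*%
      mat_sqrt(kronecker(matrix(c(1, rg, rg, 1), 2), Sa))
    E <- matrix(rnorm(2 * k * n), n) %*% mat_sqrt(kronecker(diag(2), Se))
    P <- A + E  # n x 2k, ordered (twin1 traits, twin2 traits)
    Y[2L * idx_fam - 1L, ] <- P[, 1:k, drop = FALSE]          # twin 1 rows
    Y[2L * idx_fam, ] <- P[, k + 1:k, drop = FALSE]           # twin 2 rows
    A_bmi[2L * idx_fam - 1L] <- A[, 5]
    A_bmi[2L * idx_fam] <- A[, k + 5]
  }

  ## questionnaire variables: var j loads its pattern phenotype at
  ## `item_loading`; variables 1-4 -> P1, 5-7 + dqs -> P2, 8-11 -> P3,
  ## 12-15 -> P4
  assignment <- c(rep(1, 4), rep(2, 3), rep(3, 4), rep(4, 4), 2)
  lam <- item_loading
  V <- sapply(assignment, function(f)
    lam * Y[, f] + sqrt(1 - lam^2) * rnorm(2 * n_fam))
  colnames(V) <- c(sprintf("item_%02d", 1:15), "dqs")

  ## PRS proxy: scaled BMI additive factor plus noise, corr(X, bmi)^2 = prs_r2
  w <- sqrt(prs_r2 / h2_bmi)
  prs <- w * A_bmi / sqrt(h2_bmi) + sqrt(1 - w^2) * rnorm(2 * n_fam)

  out$bmi <- Y[, 5]
  out$wc <- Y[, 6]
  out <- cbind(out, as.data.frame(V))
  out$prs_bmi <- prs
  out$prs_whr <- rnorm(2 * n_fam)  # null score: no pathway to simulate
  for (g in 1:10) out[[paste0("gpc_", g)]] <- rnorm(2 * n_fam)
  attr(out, "patterns") <- Y[, 1:4]
  out
}
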