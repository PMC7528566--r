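## Synthetic twin-cohort generators with known variance-component, factor,
## polygenic-score and mediation structure. Latent A/C/D/E factors are drawn
## as standard normals with the classical within-pair correlations (A: 1 MZ /
## 0.5 DZ; D: 1 / 0.25; C: 1 / 1; E: 0 / 0) and phenotypes composed as
## a*A + c*C + d*D + e*E, so expected covariance matrices are exact by
## construction.

#' Univariate generating architecture (A/C/D/E variance shares)
#'
#' Standardized variance shares of a single phenotype. Shares must be
#' non-negative and sum to 1; shared environment (C) and dominance (D)
#' cannot both be positive because twins reared together cannot identify
#' them simultaneously.
#'
#' @param a2 additive-genetic share.
#' @param c2 shared-environment share.
#' @param d2 dominance share.
#' @param e2 nonshared-environment share.
#' @return object of class `uni_arch`.
#' @examples
#' uni_arch(a2 = 0.76, e2 = 0.24)
#' @export
uni_arch <- function(a2 = 0, c2 = 0, d2 = 0, e2 = 0) {
  shares <- c(a2 = a2, c2 = c2, d2 = d2, e2 = e2)
  if (any(!is.finite(shares)) || any(shares < 0))
    stop2("variance shares must be finite and non-negative")
  if (abs(sum(shares) - 1) > 1e-12)
    stop2("variance shares must sum to 1, got ", format(sum(shares), digits = 15))
  if (shares["c2"] > 0 && shares["d2"] > 0)
    stop2("c2 and d2 cannot both be positive: C and D are not jointly ",
          "identifiable in a design with twins reared together")
  structure(as.list(shares), class = "uni_arch")
}

#' @export
print.uni_arch <- function(x, ...) {
  cat(sprintf("generating architecture: a2=%.3f c2=%.3f d2=%.3f e2=%.3f\n",
              x$a2, x$c2, x$d2, x$e2))
  invisible(x)
}

## within-pair correlations of the latent factors by zygosity
zyg_factor_cor <- function(zygosity) {
  list(A = ifelse(zygosity == "MZ", 1, 0.5),
       D = ifelse(zygosity == "MZ", 1, 0.25))
}

## assemble the shared id / covariate columns of a long cohort table;
## one row per individual, twin 1 before twin 2 within each family
cohort_frame <- function(zygosity, p_female = 0.56, age_range = c(31, 37)) {
  n_fam <- length(zygosity)
  age <- runif(n_fam, age_range[1], age_range[2])
  sex1 <- draw_pair_sex(n_fam, p_female)
  sex2 <- sex1
  os <- zygosity == "DZOS"
  if (any(os)) sex2[os] <- 3L - sex1[os]  # opposite-sex pairs discordant
  data.frame(
    family_id = rep(seq_len(n_fam), each = 2L),
    twin_order = rep(1:2, n_fam),
    zygosity = rep(zygosity, each = 2L),
    sex = as.integer(rbind(sex1, sex2)),
    age = rep(age, each = 2L),
    stringsAsFactors = FALSE
  )
}

#' Simulate a univariate twin cohort
#'
#' Generates complete twin pairs whose phenotype is composed from latent
#' A/C/D/E factors with the classical within-pair correlations, so that the
#' phenotype has mean 0 and variance 1 in expectation, MZ covariance
#' `a2 + c2 + d2` and DZ covariance `0.5 a2 + c2 + 0.25 d2`.
#'
#' @param arch a [uni_arch()] generating architecture.
#' @param n_mz,n_dz number of MZ and DZ pairs (> 0).
#' @param seed optional integer seed.
#' @param os_dz_fraction fraction of DZ pairs that are opposite-sex.
#' @param trait name of the phenotype column in the returned table.
#' @return long-format cohort `data.frame`: one row per individual with
#'   `family_id`, `twin_order`, `zygosity` (MZ/DZSS/DZOS), `sex` (1 = male,
#'   2 = female; OS-DZ pairs are sex-discordant), `age` (uniform on 31-37,
#'   shared within pair) and the phenotype column.
#' @examples
#' d <- simulate_univariate_twins(uni_arch(a2 = 0.76, e2 = 0.24),
#'                                n_mz = 200, n_dz = 200, seed = 1)
#' head(d)
#' @export
simulate_univariate_twins <- function(arch, n_mz, n_dz, seed = NULL,
                                      os_dz_fraction = 0.5, trait = "bmi") {
  if (!inherits(arch, "uni_arch")) arch <- do.call(uni_arch, as.list(arch))
  check_number(n_mz, "n_mz", lower = 1)
  check_number(n_dz, "n_dz", lower = 1)
  check_number(os_dz_fraction, "os_dz_fraction", 0, 1)
  if (!is.null(seed)) set.seed(seed)

  n_os <- round(n_dz * os_dz_fraction)
  zygosity <- c(rep("MZ", n_mz), rep("DZSS", n_dz - n_os), rep("DZOS", n_os))
  n_fam <- length(zygosity)
  rr <- zyg_factor_cor(zygosity)

  a <- sqrt(arch$a2); cc <- sqrt(arch$c2); d <- sqrt(arch$d2); e <- sqrt(arch$e2)
  A <- matrix(0, n_fam, 2); D <- matrix(0, n_fam, 2)
  if (a > 0) {
    z <- rnorm(n_fam); z2 <- rnorm(n_fam)
    A <- cbind(z, rr$A * z + sqrt(1 - rr$A^2) * z2)
  }
  if (d > 0) {
    z <- rnorm(n_fam); z2 <- rnorm(n_fam)
    D <- cbind(z, rr$D * z + sqrt(1 - rr$D^2) * z2)
  }
  C <- if (cc > 0) rnorm(n_fam) else numeric(n_fam)
  E <- if (e > 0) matrix(rnorm(2 * n_fam), n_fam, 2) else matrix(0, n_fam, 2)

  y <- a * A + cc * C + d * D + e * E  # n_fam x 2
  out <- cohort_frame(zygosity)
  out[[trait]] <- as.numeric(t(y))
  attr(out, "arch") <- arch
  out
}

#' Bivariate generating architecture
#'
#' Two univariate architectures plus the additive-genetic (`ra`) and
#' nonshared-environment (`re`) cross-trait correlations. The implied
#' phenotypic correlation \eqn{r_p = \sqrt{a^2_1 a^2_2}\, r_a +
#' \sqrt{e^2_1 e^2_2}\, r_e} must lie in `[-1, 1]`.
#'
#' @param trait1,trait2 [uni_arch()] objects.
#' @param ra,re cross-trait correlations in `[-1, 1]`.
#' @return object of class `biv_arch` (fields `trait1`, `trait2`, `ra`,
#'   `re`, implied `rp` and implied `genetic_share` of the covariance).
#' @export
biv_arch <- function(trait1, trait2, ra, re) {
  check_number(ra, "ra", -1, 1)
  check_number(re, "re", -1, 1)
  if (!inherits(trait1, "uni_arch") || !inherits(trait2, "uni_arch"))
    stop2("trait1 and trait2 must be uni_arch objects")
  gcov <- sqrt(trait1$a2 * trait2$a2) * ra
  ecov <- sqrt(trait1$e2 * trait2$e2) * re
  rp <- gcov + ecov
  if (abs(rp) > 1)
    stop2("implied phenotypic correlation ", format(rp), " is infeasible")
  structure(list(trait1 = trait1, trait2 = trait2, ra = ra, re = re,
                 rp = rp,
                 genetic_share = if (rp != 0) gcov / rp else NA_real_),
            class = "biv_arch")
}

#' Bivariate architecture from phenotypic targets
#'
#' Convenience constructor: given two AE heritabilities, a target phenotypic
#' correlation and the genetic share of the cross-trait covariance, solves
#' for the `ra` and `re` that produce them.
#'
#' @param h2_1,h2_2 trait heritabilities (AE model, so `e2 = 1 - h2`).
#' @param rp target phenotypic correlation.
#' @param genetic_share target fraction of the covariance due to genes.
#' @return a [biv_arch()].
#' @examples
#' biv_arch_from_targets(0.48, 0.76, rp = 0.35, genetic_share = 0.75)
#' @export
biv_arch_from_targets <- function(h2_1, h2_2, rp, genetic_share) {
  check_number(h2_1, "h2_1", 0, 1); check_number(h2_2, "h2_2", 0, 1)
  check_number(rp, "rp", -1, 1)
  check_number(genetic_share, "genetic_share", 0, 1)
  ra <- genetic_share * rp / sqrt(h2_1 * h2_2)
  re <- (1 - genetic_share) * rp / sqrt((1 - h2_1) * (1 - h2_2))
  biv_arch(uni_arch(a2 = h2_1, e2 = 1 - h2_1),
           uni_arch(a2 = h2_2, e2 = 1 - h2_2), ra = ra, re = re)
}

#' Simulate a bivariate twin cohort
#'
#' Two phenotypes per individual with AE cross-trait structure: the additive
#' factors of the two traits correlate `ra` within an individual and
#' `r_zyg * ra` across co-twins (r_zyg = 1 MZ, 0.5 DZ); nonshared factors
#' correlate `re` within an individual and 0 across co-twins. Within-trait
#' C/D components, if present, are independent across traits.
#'
#' @inheritParams simulate_univariate_twins
#' @param arch a [biv_arch()].
#' @param traits names for the two phenotype columns.
#' @return long cohort `data.frame` with both trait columns.
#' @export
simulate_bivariate_twins <- function(arch, n_mz, n_dz, seed = NULL,
                                     os_dz_fraction = 0.5,
                                     traits = c("bmi", "wc")) {
  if (!inherits(arch, "biv_arch")) stop2("arch must be a biv_arch object")
  if (length(traits) != 2L) stop2("exactly two trait names are required")
  check_number(n_mz, "n_mz", lower = 1)
  check_number(n_dz, "n_dz", lower = 1)
  check_number(os_dz_fraction, "os_dz_fraction", 0, 1)
  if (!is.null(seed)) set.seed(seed)

  n_os <- round(n_dz * os_dz_fraction)
  zygosity <- c(rep("MZ", n_mz), rep("DZSS", n_dz - n_os), rep("DZOS", n_os))
  n_fam <- length(zygosity)
  out <- cohort_frame(zygosity)

  Rtr_a <- matrix(c(1, arch$ra, arch$ra, 1), 2)
  Rtr_e <- matrix(c(1, arch$re, arch$re, 1), 2)
  y <- matrix(0, 2L * n_fam, 2L)  # rows follow the long table, cols = traits
  archs <- list(arch$trait1, arch$trait2)
  paths <- lapply(archs, function(u)
    list(a = sqrt(u$a2), c = sqrt(u$c2), d = sqrt(u$d2), e = sqrt(u$e2)))

  for (rz in list(c("MZ", 1, 1), c("DZSS", 0.5, 0.25), c("DZOS", 0.5, 0.25))) {
    idx_fam <- which(zygosity == rz[1])
    n <- length(idx_fam)
    if (n == 0) next
    r_a <- as.numeric(rz[2]); r_d <- as.numeric(rz[3])
    ## latent vectors ordered (twin1 trait1, twin1 trait2, twin2 t1, twin2 t2)
    Sa <- kronecker(matrix(c(1, r_a, r_a, 1), 2), Rtr_a)
    A <- matrix(rnorm(4 * n), n) %*% mat_sqrt(Sa)
    E <- matrix(rnorm(4 * n), n) %*% mat_sqrt(kronecker(diag(2), Rtr_e))
    yz <- matrix(0, n, 4)
    for (j in 1:2) {
      p <- paths[[j]]
      Cj <- if (p$c > 0) rnorm(n) else numeric(n)
      Dj <- if (p$d > 0) rnorm_pair(n, r_d) else matrix(0, n, 2)
      for (tw in 1:2) {
        col <- (tw - 1L) * 2L + j
        yz[, col] <- p$a * A[, col] + p$e * E[, col] +
          p$c * Cj + p$d * Dj[, tw]
      }
    }
    rows <- as.vector(rbind(2L * idx_fam - 1L, 2L * idx_fam))
    y[rows, 1] <- as.numeric(t(yz[, c(1, 3), drop = FALSE]))
    y[rows, 2] <- as.numeric(t(yz[, c(2, 4), drop = FALSE]))
  }
  out[[traits[1]]] <- y[, 1]
  out[[traits[2]]] <- y[, 2]
  attr(out, "arch") <- arch
  out
}

#' Item factor design for the eating-style questionnaire generator
#'
#' @param loading_matrix items x factors matrix of loadings in `[-1, 1]`.
#' @param uniqueness optional per-item residual variances; defaults to
#'   `1 - communality` so items have unit variance.
#' @return object of class `item_design`.
#' @export
item_design <- function(loading_matrix, uniqueness = NULL) {
  L <- as.matrix(loading_matrix)
  if (any(abs(L) > 1)) stop2("loadings must lie in [-1, 1]")
  comm <- rowSums(L^2)
  if (any(comm > 1 + 1e-12))
    stop2("item communality exceeds 1 for item(s) ",
          paste(which(comm > 1 + 1e-12), collapse = ", "))
  if (is.null(uniqueness)) uniqueness <- 1 - comm
  if (any(abs(comm + uniqueness - 1) > 1e-12))
    stop2("communality + uniqueness must equal 1 per item")
  if (any(uniqueness < 0)) stop2("uniqueness must be non-negative")
  structure(list(loading_matrix = L, uniqueness = as.numeric(uniqueness),
                 n_items = nrow(L), n_factors = ncol(L)),
            class = "item_design")
}

#' Default 16-variable, 4-factor item design
#'
#' A simple-structure template with `items_per_factor` items loading each of
#' `n_factors` orthogonal factors at `loading` (remaining variance unique),
#' emulating a 15-eating-style-items + diet-quality-score questionnaire.
#'
#' @param n_items,n_factors,items_per_factor,loading design parameters.
#' @return an [item_design()].
#' @export
default_item_design <- function(n_items = 16, n_factors = 4,
                                items_per_factor = 4, loading = 0.5) {
  if (n_factors * items_per_factor > n_items)
    stop2("design needs n_items >= n_factors * items_per_factor")
  L <- matrix(0, n_items, n_factors)
  for (f in seq_len(n_factors))
    L[(f - 1) * items_per_factor + seq_len(items_per_factor), f] <- loading
  item_design(L)
}

#' Population correlation matrix implied by an item design
#'
#' @param design an [item_design()].
#' @return the items x items matrix \eqn{\Lambda \Lambda^T + \Psi}.
#' @export
population_item_correlation <- function(design) {
  L <- design$loading_matrix
  R <- L %*% t(L) + diag(design$uniqueness)
  dimnames(R) <- NULL
  R
}

#' Simulate questionnaire item responses with planted factor structure
#'
#' Items are linear combinations of independent standard-normal factors plus
#' unique noise, so the population correlation matrix is exactly
#' \eqn{\Lambda \Lambda^T + \Psi}. Optionally discretized to 4 ordinal
#' categories by quartile thresholds (usually/often/sometimes/seldom); the
#' default is continuous scores.
#'
#' @param design an [item_design()].
#' @param n number of individuals; must be at least `10 * n_items`.
#' @param seed optional integer seed.
#' @param ordinal discretize each item to integer categories 1-4?
#' @return `data.frame` of item columns (`item_01`, ...); the generating
#'   factor scores are attached as attribute `"factors"`.
#' @export
simulate_items <- function(design, n, seed = NULL, ordinal = FALSE) {
  if (!inherits(design, "item_design")) stop2("design must be an item_design")
  check_number(n, "n", lower = 10 * design$n_items)
  if (!is.null(seed)) set.seed(seed)
  Fmat <- matrix(rnorm(n * design$n_factors), n)
  X <- Fmat %*% t(design$loading_matrix) +
    matrix(rnorm(n * design$n_items), n) %*% diag(sqrt(design$uniqueness))
  if (ordinal) {
    X <- apply(X, 2, function(col) {
      findInterval(col, quantile(col, c(0.25, 0.5, 0.75))) + 1L
    })
  }
  out <- as.data.frame(X)
  names(out) <- sprintf("item_%02d", seq_len(design$n_items))
  attr(out, "factors") <- Fmat
  out
}

#' Mediation generating model (polygenic score -> mediator -> outcome)
#'
#' Standardized single-mediator chain: exposure X (polygenic-score proxy),
#' mediator \eqn{M = a X + u_m}, outcome \eqn{Y = b M + c X + u_y}, all with
#' unit variance. The implied squared exposure-outcome correlation is
#' \eqn{(c + ab)^2}. If `c_path` is omitted it is solved from `prs_r2` as
#' \eqn{c = \sqrt{prs\_r2} - ab}; if both are given they must agree.
#'
#' @param a_path,b_path,c_path standardized path coefficients.
#' @param n_families number of families (>= 10), or use `n_individuals`.
#' @param pair_fraction fraction of families contributing both co-twins.
#' @param prs_r2 target squared exposure-outcome correlation in `[0, 1)`.
#' @param n_individuals alternative sizing: total individuals; converted to
#'   `n_families = round(n / (1 + pair_fraction))`.
#' @param seed default RNG seed carried by the model.
#' @return object of class `mediation_model`.
#' @examples
#' mediation_model(0.15, 0.38, 0.23, n_individuals = 949)
#' @export
mediation_model <- function(a_path, b_path, c_path = NULL,
                            n_families = NULL, pair_fraction = 0.5,
                            prs_r2 = NULL, n_individuals = NULL,
                            seed = NULL) {
  check_number(a_path, "a_path", -1, 1)
  check_number(b_path, "b_path", -1, 1)
  check_number(pair_fraction, "pair_fraction", 0, 1)
  if (is.null(c_path)) {
    if (is.null(prs_r2))
      stop2("supply c_path or prs_r2")
    check_number(prs_r2, "prs_r2", 0, 1 - 1e-12)
    c_path <- sqrt(prs_r2) - a_path * b_path
  } else if (!is.null(prs_r2)) {
    if (abs((c_path + a_path * b_path)^2 - prs_r2) > 1e-8)
      stop2("prs_r2 is inconsistent with the path coefficients: (c + ab)^2 = ",
            format((c_path + a_path * b_path)^2))
  }
  if (is.null(n_families)) {
    if (is.null(n_individuals)) stop2("supply n_families or n_individuals")
    n_families <- round(n_individuals / (1 + pair_fraction))
  }
  check_number(n_families, "n_families", lower = 10)
  var_um <- 1 - a_path^2
  var_uy <- 1 - b_path^2 - c_path^2 - 2 * a_path * b_path * c_path
  if (var_um < 0 || var_uy < 0)
    stop2("path coefficients imply negative residual variance ",
          "(mediator: ", format(var_um), ", outcome: ", format(var_uy), ")")
  structure(list(a_path = a_path, b_path = b_path, c_path = c_path,
                 n_families = as.integer(n_families),
                 pair_fraction = pair_fraction,
                 var_um = var_um, var_uy = var_uy, seed = seed),
            class = "mediation_model")
}

#' Simulate a clustered polygenic-score mediation cohort
#'
#' Families contribute one or two members; co-twin clustering is induced by
#' within-pair correlation of the exposure (1 for MZ, 0.5 for DZ, as for a
#' genetic score) and of the mediator/outcome residuals (0.4 MZ / 0.2 DZ).
#' One third of pair families are MZ. Point estimates of the paths are
#' unaffected by the clustering; it matters for standard errors.
#'
#' @param model a [mediation_model()].
#' @param prs_r2 optional; validated against `(c + ab)^2` if supplied.
#' @param seed optional integer seed (overrides `model$seed`).
#' @return long cohort `data.frame` with `family_id`, `twin_order`,
#'   `zygosity`, `sex`, `age`, `prs_bmi` (X), `pattern` (M), `bmi` (Y).
#' @export
simulate_prs_mediation <- function(model, prs_r2 = NULL, seed = NULL) {
  if (!inherits(model, "mediation_model"))
    stop2("model must be a mediation_model")
  if (!is.null(prs_r2)) {
    tot <- model$c_path + model$a_path * model$b_path
    if (abs(tot^2 - prs_r2) > 1e-8)
      stop2("prs_r2 inconsistent with model paths: (c + ab)^2 = ",
            format(tot^2))
  }
  seed <- seed %||% model$seed
  if (!is.null(seed)) set.seed(seed)

  n_fam <- model$n_families
  n_pairs <- round(model$pair_fraction * n_fam)
  n_single <- n_fam - n_pairs
  zyg_pair <- ifelse(runif(n_pairs) < 1 / 3, "MZ", "DZSS")
  r_x <- ifelse(zyg_pair == "MZ", 1, 0.5)
  r_u <- ifelse(zyg_pair == "MZ", 0.4, 0.2)

  gen_col <- function(r_pair) {
    zp <- rnorm(n_pairs); zp2 <- rnorm(n_pairs)
    pair <- cbind(zp, r_pair * zp + sqrt(1 - r_pair^2) * zp2)
    c(as.numeric(t(pair)), rnorm(n_single))
  }
  X <- gen_col(r_x)
  Um <- gen_col(r_u)
  Uy <- gen_col(r_u)
  M <- model$a_path * X + sqrt(model$var_um) * Um
  Y <- model$b_path * M + model$c_path * X + sqrt(model$var_uy) * Uy

  fam_pair <- rep(seq_len(n_pairs), each = 2L)
  fam_single <- n_pairs + seq_len(n_single)
  out <- data.frame(
    family_id = c(fam_pair, fam_single),
    twin_order = c(rep(1:2, n_pairs), rep(1L, n_single)),
    zygosity = c(rep(zyg_pair, each = 2L),
                 ifelse(runif(n_single) < 1 / 3, "MZ", "DZSS")),
    stringsAsFactors = FALSE
  )
  sex_pair <- draw_pair_sex(n_pairs)  # MZ/DZSS pairs are same-sex
  out$sex <- c(rep(sex_pair, each = 2L), draw_pair_sex(n_single))
  out$age <- c(rep(runif(n_pairs, 31, 37), each = 2L), runif(n_single, 31, 37))
  out$prs_bmi <- X
  out$pattern <- M
  out$bmi <- Y
  attr(out, "model") <- model
  out
}
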