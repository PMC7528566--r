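test_that("uni_arch validates its invariants", {
  expect_error(uni_arch(a2 = -0.1, e2 = 1.1), "non-negative")
  expect_error(uni_arch(a2 = 0.5, e2 = 0.4), "sum to 1")
  expect_error(uni_arch(a2 = 0.4, c2 = 0.2, d2 = 0.1, e2 = 0.3),
               "not jointly identifiable")
  a <- uni_arch(a2 = 0.76, e2 = 0.24)
  expect_s3_class(a, "uni_arch")
  expect_equal(a$a2 + a$c2 + a$d2 + a$e2, 1, tolerance = 1e-12)
})

test_that("simulate_univariate_twins rejects bad inputs and is deterministic", {
  arch <- uni_arch(a2 = 0.5, e2 = 0.5)
  expect_error(simulate_univariate_twins(arch, 0, 10), "n_mz")
  expect_error(simulate_univariate_twins(arch, 10, 10, os_dz_fraction = 1.5),
               "os_dz_fraction")
  d1 <- simulate_univariate_twins(arch, 50, 50, seed = 99)
  d2 <- simulate_univariate_twins(arch, 50, 50, seed = 99)
  expect_identical(d1, d2)
})

test_that("zygosity bookkeeping: MZ same-sex, OS-DZ sex-discordant", {
  d <- simulate_univariate_twins(uni_arch(a2 = 0.5, e2 = 0.5),
                                 200, 200, seed = 3, os_dz_fraction = 0.5)
  sex1 <- d$sex[d$twin_order == 1]
  sex2 <- d$sex[d$twin_order == 2]
  zyg <- d$zygosity[d$twin_order == 1]
  expect_true(all(sex1[zyg == "MZ"] == sex2[zyg == "MZ"]))
  expect_true(all(sex1[zyg == "DZSS"] == sex2[zyg == "DZSS"]))
  expect_true(all(sex1[zyg == "DZOS"] != sex2[zyg == "DZOS"]))
  expect_true(all(d$age >= 31 & d$age <= 37))
  ## age shared within pair
  expect_identical(d$age[d$twin_order == 1], d$age[d$twin_order == 2])
})

test_that("degenerate architectures give the expected ICCs", {
  ## pure A: phenotype equals the additive factor, so ICC_MZ = 1 exactly
  d <- simulate_univariate_twins(uni_arch(a2 = 1), 800, 800, seed = 5)
  pw <- pair_wide(d, "bmi")
  icc <- intraclass_correlation(pw, boot = 0)
  expect_equal(icc$icc[icc$zygosity == "MZ"], 1, tolerance = 1e-12)
  dz <- icc$icc[icc$zygosity %in% c("DZSS", "DZOS")]
  expect_true(all(abs(dz - 0.5) < 0.08))
  ## pure E: no familial resemblance
  d0 <- simulate_univariate_twins(uni_arch(e2 = 1), 800, 800, seed = 6)
  icc0 <- intraclass_correlation(pair_wide(d0, "bmi"), boot = 0)
  expect_true(all(abs(icc0$icc) < 0.08))
})

test_that("moment matching at n = 1e5 pairs within 3 Monte-Carlo SEs", {
  ## ACE and ADE architectures; ICC expectations from the path model
  cases <- list(
    list(arch = uni_arch(a2 = 0.5, c2 = 0.2, e2 = 0.3),
         mz = 0.7, dz = 0.45),
    list(arch = uni_arch(a2 = 0.4, d2 = 0.2, e2 = 0.4),
         mz = 0.6, dz = 0.25)
  )
  for (cs in cases) {
    d <- simulate_univariate_twins(cs$arch, 1e5, 1e5, seed = 42)
    expect_lt(abs(mean(d$bmi)), 3 / sqrt(nrow(d)))
    expect_lt(abs(var(d$bmi) - 1), 3 * sqrt(2 / nrow(d)))
    icc <- intraclass_correlation(pair_wide(d, "bmi"), boot = 0)
    se_r <- function(r, n) (1 - r^2) / sqrt(n)
    expect_lt(abs(icc$icc[icc$zygosity == "MZ"] - cs$mz),
              3 * se_r(cs$mz, 1e5))
    dz <- icc[icc$zygosity %in% c("DZSS", "DZOS"), ]
    pooled_dz <- sum(dz$icc * dz$n_pairs) / sum(dz$n_pairs)
    expect_lt(abs(pooled_dz - cs$dz), 3 * se_r(cs$dz, 1e5))
  }
})

test_that("biv_arch enforces feasibility and computes implied quantities", {
  t1 <- uni_arch(a2 = 0.5, e2 = 0.5)
  expect_error(biv_arch(t1, t1, ra = 1.2, re = 0), "ra")
  expect_error(biv_arch(t1, t1, ra = 1, re = 1.01), "re")
  ## symmetric case: genetic covariance share equals a2
  sym <- biv_arch(t1, t1, ra = 0.6, re = 0.6)
  expect_equal(sym$genetic_share, 0.5, tolerance = 1e-12)
  expect_equal(sym$rp, 0.6, tolerance = 1e-12)
  tgt <- biv_arch_from_targets(0.48, 0.76, rp = 0.35, genetic_share = 0.75)
  expect_equal(tgt$rp, 0.35, tolerance = 1e-12)
  expect_equal(tgt$genetic_share, 0.75, tolerance = 1e-12)
})

test_that("bivariate generator reproduces the implied cross-trait structure", {
  arch <- biv_arch_from_targets(0.48, 0.76, rp = 0.35, genetic_share = 0.75)
  d <- simulate_bivariate_twins(arch, 2e4, 2e4, seed = 8)
  r_obs <- cor(d$bmi, d$wc)
  expect_lt(abs(r_obs - 0.35), 3 * (1 - 0.35^2) / sqrt(nrow(d)))
  ## null environmental overlap: all covariance genetic
  arch0 <- biv_arch(uni_arch(a2 = 0.6, e2 = 0.4),
                    uni_arch(a2 = 0.6, e2 = 0.4), ra = 0.5, re = 0)
  d0 <- simulate_bivariate_twins(arch0, 800, 800, seed = 9)
  covs <- as.matrix(d0[c("age", "sex")])
  for (tr in c("bmi", "wc"))
    d0[[tr]] <- residualize(d0[[tr]], covs) / sd(d0[[tr]])
  fit <- fit_bivariate_cholesky(pair_wide(d0, c("bmi", "wc")))
  expect_lt(abs(fit$re), 0.12)
  expect_gt(fit$genetic_share, 0.85)
})

test_that("item designs and the item generator honor the factor model", {
  expect_error(item_design(matrix(0.8, 4, 2)), "communality")
  des <- default_item_design()
  expect_equal(des$n_items, 16)
  R <- population_item_correlation(des)
  expect_equal(R, des$loading_matrix %*% t(des$loading_matrix) +
                 diag(des$uniqueness))
  ## with 4 items per factor at 0.5, population eigenvalues are 1.75 (x4)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1), 4)
  ## zero loadings -> identity population correlation, nothing above 1
  des0 <- item_design(matrix(0, 8, 2))
  ev0 <- eigen(population_item_correlation(des0), only.values = TRUE)$values
  expect_true(all(abs(ev0 - 1) < 1e-12))
  expect_error(simulate_items(des, n = 50), "n must be")
})

test_that("sample eigenvalues approach population eigenvalues (2 factors, n = 1e5)", {
  L <- matrix(0, 8, 2)
  L[1:4, 1] <- c(0.7, 0.6, 0.65, 0.55)
  L[5:8, 2] <- c(0.6, 0.5, 0.7, 0.45)
  des <- item_design(L)
  pop_ev <- eigen(population_item_correlation(des), only.values = TRUE)$values
  items <- simulate_items(des, n = 1e5, seed = 13)
  samp_ev <- eigen(cor(as.matrix(items)), only.values = TRUE)$values
  expect_true(all(abs(samp_ev - pop_ev) < 0.02))
})

test_that("items can be discretized to 4 ordinal categories", {
  items <- simulate_items(default_item_design(), n = 400, seed = 2,
                          ordinal = TRUE)
  expect_true(all(unlist(items) %in% 1:4))
})

test_that("mediation model validates paths, sizes and prs_r2 consistency", {
  expect_error(mediation_model(0.8, 0.8, 0.7, n_families = 100),
               "negative residual variance")
  expect_error(mediation_model(0.15, 0.38, n_families = 100),
               "supply c_path or prs_r2")
  expect_error(mediation_model(0.15, 0.38, 0.23, n_families = 100,
                               prs_r2 = 0.5), "inconsistent")
  expect_error(mediation_model(0.1, 0.1, 0.1, n_families = 5), "n_families")
  ## c solved from prs_r2
  mm <- mediation_model(0.15, 0.38, prs_r2 = 0.083, n_families = 633)
  expect_equal((mm$c_path + 0.15 * 0.38)^2, 0.083, tolerance = 1e-12)
  ## n_individuals sizing used for the n = 949 analysis sample
  mm9 <- mediation_model(0.15, 0.38, 0.23, n_individuals = 949)
  d <- simulate_prs_mediation(mm9, seed = 1)
  expect_equal(nrow(d), 949)
})

test_that("mediation generator: determinism, clustering, implied R2", {
  mm <- mediation_model(0.15, 0.38, 0.23, n_families = 2e4,
                        pair_fraction = 0.5)
  d <- simulate_prs_mediation(mm, seed = 21)
  expect_identical(d, simulate_prs_mediation(mm, seed = 21))
  ## squared X-Y correlation converges to (c + ab)^2
  expect_lt(abs(cor(d$prs_bmi, d$bmi)^2 - (0.23 + 0.15 * 0.38)^2), 0.01)
  ## all unit variance in expectation
  expect_lt(abs(var(d$pattern) - 1), 0.03)
  expect_lt(abs(var(d$bmi) - 1), 0.03)
  ## co-twins exist and MZ pairs share the polygenic score exactly
  pairs <- d[d$family_id %in% d$family_id[duplicated(d$family_id)], ]
  mzp <- pairs[pairs$zygosity == "MZ", ]
  x1 <- mzp$prs_bmi[mzp$twin_order == 1]
  x2 <- mzp$prs_bmi[mzp$twin_order == 2]
  expect_equal(x1, x2, tolerance = 1e-12)
  expect_error(simulate_prs_mediation(mm, prs_r2 = 0.5), "inconsistent")
})
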