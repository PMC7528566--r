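make_paired <- function(a2, n_mz, n_dz, seed, model_trait = "bmi") {
  d <- simulate_univariate_twins(uni_arch(a2 = a2, e2 = 1 - a2),
                                 n_mz, n_dz, seed = seed)
  pair_wide(d, model_trait)
}

test_that("intraclass correlation: exact and simulated cases", {
  ## identical values within every pair -> ICC = 1
  pm <- structure(data.frame(family_id = 1:10,
                             bmi_t1 = rnorm(10), bmi_t2 = NA),
                  class = c("paired_matrix", "data.frame"))
  pm$bmi_t2 <- pm$bmi_t1
  attr(pm, "traits") <- "bmi"; attr(pm, "zygosity") <- "MZ"
  icc <- intraclass_correlation(pm, boot = 0)
  expect_equal(icc$icc, 1, tolerance = 1e-12)
  ## a2 = 0.76: expected ICC_MZ = 0.76, ICC_DZ = 0.38
  pw <- make_paired(0.76, 2000, 2000, seed = 31)
  icc <- intraclass_correlation(pw, boot = 0)
  expect_lt(abs(icc$icc[icc$zygosity == "MZ"] - 0.76), 0.04)
  dz <- icc[icc$zygosity != "MZ", ]
  expect_lt(abs(sum(dz$icc * dz$n_pairs) / sum(dz$n_pairs) - 0.38), 0.05)
  ## bootstrap CI brackets the estimate
  icc_ci <- intraclass_correlation(pw$MZ, boot = 200, seed = 1)
  expect_true(icc_ci$lower < icc_ci$icc && icc_ci$icc < icc_ci$upper)
  expect_error(intraclass_correlation(pm[1:2, ]), "at least 3")
})

test_that("AE maximum likelihood matches the exhaustive grid-search oracle", {
  ## small instances where the lattice is informative (0.001 step in paths)
  for (seed in c(101, 202, 303)) {
    pw <- make_paired(0.6, 25, 25, seed = seed)
    fit <- fit_univariate(pw, model = "AE", ci = "none")
    h2_oracle <- grid_search_ae_h2(pm_mz <- as.matrix(pw$MZ[c("bmi_t1", "bmi_t2")]),
                                   do.call(rbind, lapply(pw[setdiff(names(pw), "MZ")],
                                     function(p) as.matrix(p[c("bmi_t1", "bmi_t2")]))),
                                   mu = fit$mu)
    expect_lt(abs(unname(fit$shares["a2"]) - h2_oracle), 0.005)
  }
})

test_that("univariate fits recover ACE and ADE structures", {
  d <- simulate_univariate_twins(uni_arch(a2 = 0.4, c2 = 0.3, e2 = 0.3),
                                 4000, 4000, seed = 32)
  fit <- fit_univariate(pair_wide(d, "bmi"), model = "ACE", ci = "none")
  expect_lt(abs(fit$shares["a2"] - 0.4), 0.06)
  expect_lt(abs(fit$shares["c2"] - 0.3), 0.06)
  expect_equal(sum(fit$shares), 1, tolerance = 1e-8)
  d2 <- simulate_univariate_twins(uni_arch(a2 = 0.4, d2 = 0.2, e2 = 0.4),
                                  4000, 4000, seed = 33)
  fit2 <- fit_univariate(pair_wide(d2, "bmi"), model = "ADE", ci = "none")
  expect_lt(abs(fit2$shares["a2"] - 0.4), 0.08)
  expect_lt(abs(fit2$shares["d2"] - 0.2), 0.10)
  ## nested log-likelihood ordering: parent >= submodel
  ae2 <- fit_univariate(pair_wide(d2, "bmi"), model = "AE", ci = "none")
  expect_gte(fit2$loglik, ae2$loglik - 1e-6)
})

test_that("profile CIs bracket the estimate and respect bounds", {
  pw <- make_paired(0.48, 500, 500, seed = 34)
  fit <- fit_univariate(pw, model = "AE", ci = "profile")
  expect_true(fit$ci["a2", "lower"] < fit$shares["a2"])
  expect_true(fit$ci["a2", "upper"] > fit$shares["a2"])
  expect_true(all(fit$ci >= 0 & fit$ci <= 1))
})

test_that("compare_models: identity, calibration and power", {
  pw <- make_paired(0.5, 400, 400, seed = 35)
  ae <- fit_univariate(pw, model = "AE", ci = "none")
  ace <- fit_univariate(pw, model = "ACE", ci = "none")
  ## identical models -> LR = 0, p = 1
  cmp0 <- compare_models(ae, ae)
  expect_equal(cmp0$lr, 0)
  expect_equal(cmp0$p.value, 1)
  cmp <- compare_models(ace, ae)
  expect_gte(cmp$lr, -1e-6)
  expect_equal(cmp$df, 1)
  ## mismatched data rejected
  pw2 <- make_paired(0.5, 400, 400, seed = 36)
  ae2 <- fit_univariate(pw2, model = "AE", ci = "none")
  expect_error(compare_models(ace, ae2), "different data")
  ## non-nested rejected
  ade <- fit_univariate(pw, model = "ADE", ci = "none")
  expect_error(compare_models(ade, ace), "not nested")
})

test_that("ACE vs AE test is conservative under c2 = 0 and powerful under c2 = 0.3", {
  ## calibration, 120 reps at 400+400 pairs (scaled for runtime); boundary
  ## testing makes the nominal 5% level conservative
  set.seed(37)
  rej <- vapply(seq_len(120), function(i) {
    pw <- make_paired(0.5, 400, 400, seed = 5000 + i)
    cmp <- compare_models(fit_univariate(pw, "ACE", ci = "none"),
                          fit_univariate(pw, "AE", ci = "none"))
    cmp$p.value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.08)
  ## power at c2 = 0.3, large n
  det <- vapply(seq_len(15), function(i) {
    d <- simulate_univariate_twins(uni_arch(a2 = 0.3, c2 = 0.3, e2 = 0.4),
                                   2000, 2000, seed = 6000 + i)
    pw <- pair_wide(d, "bmi")
    cmp <- compare_models(fit_univariate(pw, "ACE", ci = "none"),
                          fit_univariate(pw, "AE", ci = "none"))
    cmp$p.value < 0.05
  }, logical(1))
  expect_gte(mean(det), 0.95)
})

test_that("mean estimated h2 is monotone in the generating a2", {
  set.seed(38)
  grid <- seq(0.1, 0.9, by = 0.1)
  mean_h2 <- vapply(grid, function(a2) {
    mean(vapply(1:8, function(i) {
      pw <- make_paired(a2, 500, 500, seed = round(1e4 * a2) + i)
      unname(fit_univariate(pw, "AE", ci = "none")$shares["a2"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_h2) > 0))
})

test_that("bivariate Cholesky satisfies its algebraic identity and null case", {
  arch <- biv_arch_from_targets(0.48, 0.76, rp = 0.35, genetic_share = 0.75)
  d <- simulate_bivariate_twins(arch, 527, 973, seed = 39)
  covs <- as.matrix(d[c("age", "sex")])
  for (tr in c("bmi", "wc"))
    d[[tr]] <- residualize(d[[tr]], covs) / sd(d[[tr]])
  fit <- fit_bivariate_cholesky(pair_wide(d, c("bmi", "wc")))
  expect_true(fit$convergence)
  ## identity: sqrt(h2_1 h2_2) ra + sqrt(e2_1 e2_2) re = implied rp
  lhs <- sqrt(fit$h2[1] * fit$h2[2]) * fit$ra +
    sqrt((1 - fit$h2[1]) * (1 - fit$h2[2])) * fit$re
  expect_equal(unname(lhs), fit$rp_implied, tolerance = 1e-6)
  ## genetic covariance share definition
  pa <- fit$paths
  expect_equal(fit$genetic_share,
               unname(pa["a11"] * pa["a21"] /
                        (pa["a11"] * pa["a21"] + pa["e11"] * pa["e21"])),
               tolerance = 1e-12)
  expect_lt(abs(fit$genetic_share - 0.75), 0.12)
})

test_that("bivariate bootstrap CI covers a null re", {
  arch0 <- biv_arch(uni_arch(a2 = 0.6, e2 = 0.4),
                    uni_arch(a2 = 0.6, e2 = 0.4), ra = 0.5, re = 0)
  d <- simulate_bivariate_twins(arch0, 400, 400, seed = 40)
  fit <- fit_bivariate_cholesky(pair_wide(d, c("bmi", "wc")),
                                ci = "bootstrap", draws = 200, seed = 2)
  expect_true(fit$ci["2.5%", "re"] <= 0 && fit$ci["97.5%", "re"] >= 0)
  expect_equal(fit$draws, 200)
})

test_that("Falconer consistency: 2(rMZ - rDZ) agrees with ML at 1e5 pairs", {
  pw <- make_paired(0.6, 1e5, 1e5, seed = 41)
  fit <- fit_univariate(pw, "AE", ci = "none")
  icc <- intraclass_correlation(pw, boot = 0)
  rmz <- icc$icc[icc$zygosity == "MZ"]
  dz <- icc[icc$zygosity != "MZ", ]
  rdz <- sum(dz$icc * dz$n_pairs) / sum(dz$n_pairs)
  expect_lt(abs(unname(fit$shares["a2"]) - 2 * (rmz - rdz)), 0.01)
})
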