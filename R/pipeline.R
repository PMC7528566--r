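## End-to-end orchestration: preprocess -> patterns -> twin models ->
## partial correlations -> bivariate Cholesky -> mediation, with stage-level
## logging of retained/excluded counts and a JSON + text report.

#' Pipeline configuration
#'
#' @param input path to a cohort CSV in the canonical schema.
#' @param items item column names used for the PCA.
#' @param obesity_traits obesity measure columns.
#' @param exposure polygenic-score column (set `NULL` to skip mediation).
#' @param covariates covariate columns for residualization.
#' @param gpc_covariates genetic-PC columns added for the mediation stage
#'   (used when present in the input).
#' @param eigen_cutoff,loading_cutoff,alpha analysis thresholds.
#' @param bivariate_top number of strongest pattern-obesity correlations to
#'   decompose with the bivariate Cholesky.
#' @param draws bootstrap draws for mediation CIs.
#' @param seed RNG seed recorded in every output artifact.
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input,
                            items = c(sprintf("item_%02d", 1:15), "dqs"),
                            obesity_traits = c("bmi", "wc"),
                            exposure = "prs_bmi",
                            covariates = c("age", "sex"),
                            gpc_covariates = paste0("gpc_", 1:10),
                            eigen_cutoff = 1.0, loading_cutoff = 0.30,
                            alpha = 0.05, bivariate_top = 2,
                            draws = 1000, seed = 1, out_dir = NULL) {
  check_number(eigen_cutoff, "eigen_cutoff", lower = 1e-12)
  check_number(loading_cutoff, "loading_cutoff", lower = 1e-12)
  check_number(alpha, "alpha", 1e-12, 1)
  check_number(draws, "draws", lower = 200)
  structure(list(input = input, items = items,
                 obesity_traits = obesity_traits, exposure = exposure,
                 covariates = covariates, gpc_covariates = gpc_covariates,
                 eigen_cutoff = eigen_cutoff,
                 loading_cutoff = loading_cutoff, alpha = alpha,
                 bivariate_top = bivariate_top, draws = draws,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) read and validate the cohort; (2) derive eating-behavior
#' patterns by PCA + varimax; (3) residualize pattern scores and obesity
#' traits on the covariates and standardize; (4) intraclass correlations
#' and univariate AE fits (with ACE/ADE comparisons) per trait; (5) partial
#' correlations between patterns and obesity traits; (6) bivariate Cholesky
#' for the strongest pattern-obesity correlations; (7) mediation of
#' exposure -> pattern -> obesity with BC bootstrap CIs. Every stage logs
#' retained/excluded counts; any failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return report list (also written as JSON and text summary when
#'   `config$out_dir` is set).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop2("need a pipeline_config")
  stage <- "input"
  report <- list(config = config[setdiff(names(config), "out_dir")],
                 seed = config$seed)
  result <- tryCatch({
    set.seed(config$seed)
    d <- read_cohort(config$input)
    need <- c(config$items, config$obesity_traits, config$covariates)
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop2("schema error: missing column(s): ", paste(miss, collapse = ", "))
    pipeline_log(stage, nrow(d), " individuals read")

    stage <- "preprocess"
    keep <- stats::complete.cases(d[c(config$items, config$obesity_traits,
                                      config$covariates)])
    d <- d[keep, , drop = FALSE]
    pipeline_log(stage, sum(!keep), " individuals excluded (missing data), ",
                 nrow(d), " retained")
    report$counts <- list(individuals = nrow(d), excluded = sum(!keep))

    stage <- "patterns"
    sol <- derive_patterns(d[config$items],
                           eigen_cutoff = config$eigen_cutoff,
                           loading_cutoff = config$loading_cutoff)
    k <- sol$n_retained
    if (k == 0) stop2("no component exceeded the eigenvalue cutoff")
    pattern_cols <- paste0("pattern_", seq_len(k))
    scores <- sol$scores
    colnames(scores) <- pattern_cols
    d[pattern_cols] <- as.data.frame(scores)
    pipeline_log(stage, k, " components retained; variance explained ",
                 sprintf("%.1f%%", sum(sol$pct_var_rotated)))
    report$patterns <- list(
      n_retained = k,
      eigenvalues = sol$eigenvalues,
      pct_var_rotated = unname(sol$pct_var_rotated),
      rotation = sol$rotation_meta,
      loadings = apply(sol$rotated, 2, round, 4),
      labels = lapply(sol$labels, function(l) l$variable))

    stage <- "residualize"
    covs <- as.matrix(d[config$covariates])
    traits <- c(pattern_cols, config$obesity_traits)
    for (tr in traits) d[[tr]] <- zscore(residualize(d[[tr]], covs))

    stage <- "twin_model"
    pw <- pair_wide(d, traits)
    report$counts$pairs <- attr(pw, "counts")$pairs
    pipeline_log(stage, "pairs per zygosity: ",
                 paste(names(report$counts$pairs),
                       unlist(report$counts$pairs), collapse = ", "))
    report$twin <- lapply(setNames(traits, traits), function(tr) {
      ae <- fit_univariate(pw, model = "AE", trait = tr)
      ace <- fit_univariate(pw, model = "ACE", trait = tr, ci = "none")
      ade <- fit_univariate(pw, model = "ADE", trait = tr, ci = "none")
      icc <- intraclass_correlation(pw, trait = tr, boot = 200)
      list(icc = icc,
           h2 = unname(ae$shares["a2"]), h2_ci = unname(ae$ci["a2", ]),
           e2 = unname(ae$shares["e2"]),
           ace_vs_ae = compare_models(ace, ae)[c("lr", "df", "p.value")],
           ade_vs_ae = compare_models(ade, ae)[c("lr", "df", "p.value")])
    })

    stage <- "partial_correlation"
    pc <- list()
    for (pat in pattern_cols) for (ob in config$obesity_traits) {
      r <- partial_correlation(d[[pat]], d[[ob]], covariates = NULL,
                               families = d$family_id)
      pc[[paste(pat, ob, sep = "_x_")]] <-
        list(r = r$estimate, p = r$p.value)
    }
    report$partial_correlations <- pc

    stage <- "bivariate"
    ord <- order(-abs(vapply(pc, `[[`, numeric(1), "r")))
    top <- names(pc)[ord][seq_len(min(config$bivariate_top, length(pc)))]
    report$bivariate <- lapply(setNames(top, top), function(nm) {
      parts <- strsplit(nm, "_x_", fixed = TRUE)[[1]]
      fit <- fit_bivariate_cholesky(pw, traits = parts)
      list(ra = fit$ra, re = fit$re, genetic_share = fit$genetic_share,
           h2 = as.list(fit$h2), rp_implied = fit$rp_implied,
           heywood = fit$heywood)
    })
    pipeline_log(stage, length(top), " trait pairs decomposed")

    stage <- "mediation"
    report$mediation <- list()
    if (!is.null(config$exposure) && config$exposure %in% names(d) &&
        !all(is.na(d[[config$exposure]]))) {
      gpc <- intersect(config$gpc_covariates, names(d))
      med_covs <- as.matrix(d[c(config$covariates, gpc)])
      x <- residualize(d[[config$exposure]], med_covs)
      for (pat in pattern_cols) for (ob in config$obesity_traits) {
        m <- residualize(d[[pat]], med_covs)
        y <- residualize(d[[ob]], med_covs)
        fit <- fit_mediation(x, m, y, d$family_id,
                             draws = config$draws)
        report$mediation[[paste(pat, ob, sep = "_to_")]] <- list(
          a = fit$paths$estimate[1], b = fit$paths$estimate[2],
          c = fit$paths$estimate[3],
          total = unname(fit$effects["total"]),
          direct = unname(fit$effects["direct"]),
          indirect = unname(fit$effects["indirect"]),
          indirect_ci = unname(fit$ci["indirect", ]),
          percentage_mediation = fit$percentage_mediation,
          percentage_mediation_rounded_display =
            tryCatch(percentage_mediation(fit, rounded = TRUE),
                     error = function(e) NA_real_))
      }
      pipeline_log(stage, length(report$mediation), " mediation fits")
    } else {
      pipeline_log(stage, "skipped (no exposure column)")
    }
    report
  }, error = function(e) {
    stop2("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(result,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(pipeline_summary(result),
               file.path(config$out_dir, "summary.txt"))
  }
  invisible(result)
}

pipeline_summary <- function(report) {
  lines <- c(
    sprintf("twinpath pipeline report (seed %d)", report$seed),
    sprintf("individuals analyzed: %d (excluded: %d)",
            report$counts$individuals, report$counts$excluded),
    sprintf("patterns retained: %d (eigenvalues > cutoff)",
            report$patterns$n_retained),
    sprintf("variance explained by retained components: %.1f%%",
            sum(report$patterns$pct_var_rotated)),
    "heritability (AE model):",
    vapply(names(report$twin), function(tr)
      sprintf("  %s: h2 = %.2f (%.2f, %.2f)", tr, report$twin[[tr]]$h2,
              report$twin[[tr]]$h2_ci[1], report$twin[[tr]]$h2_ci[2]),
      character(1)),
    "bivariate decompositions:",
    vapply(names(report$bivariate), function(nm)
      sprintf("  %s: genetic share = %.0f%% (ra = %.2f, re = %.2f)", nm,
              100 * report$bivariate[[nm]]$genetic_share,
              report$bivariate[[nm]]$ra, report$bivariate[[nm]]$re),
      character(1)))
  if (length(report$mediation)) {
    lines <- c(lines, "mediation (exposure -> pattern -> obesity):",
      vapply(names(report$mediation), function(nm) {
        md <- report$mediation[[nm]]
        sprintf("  %s: total = %.2f, direct = %.2f, indirect = %.2f (CI %.2f, %.2f)",
                nm, md$total, md$direct, md$indirect,
                md$indirect_ci[1], md$indirect_ci[2])
      }, character(1)))
  }
  lines
}
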