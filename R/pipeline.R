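#' Run the full risk-score comparison on a cohort bundle
#'
#' End-to-end driver: computes the six RVIs and the thresholded PRS matrix,
#' fits every score-phenotype association (logistic for the lifetime
#' diagnosis with site as a fixed covariate; random-intercept linear mixed
#' models for the continuous symptom scores), applies Benjamini-Hochberg FDR
#' within each score family, builds the five-model AIC ladder for every
#' (outcome, RVI) pair with the selected PRS threshold, and, when a second
#' wave is present, runs the residualized-change analysis. Associations with
#' PRS predictors additionally adjust for the genetic principal components
#' and genotyping plate.
#'
#' @param bundle A `cohort_bundle` (from [simulate_cohort()] or
#'   [read_bundle()]).
#' @param outdir Optional directory: results are written as TSVs plus a YAML
#'   run log carrying the seed and config hash.
#' @param prs_threshold Which PRS column to carry into the association,
#'   ladder and change analyses (reported alongside all thresholds in the
#'   score table; the driver never auto-selects the best-performing
#'   threshold).
#' @param base_covariates Covariates for all association models; site enters
#'   as a fixed covariate for the binary outcome and as a random intercept
#'   for continuous ones.
#' @param thresholds PRS p-value thresholds.
#' @param force Overwrite non-empty `outdir`.
#' @return List with `rvi`, `prs`, `data` (merged subject table),
#'   `associations` (data frame), `ladders` (data frame of stacked ladder
#'   tables), `ladder_contrasts`, and `change` (data frame or `NULL`).
#' @export
run_full_analysis <- function(bundle, outdir = NULL, prs_threshold = "pT_0.1",
                              base_covariates = c("age", "age2", "sex",
                                                  "education", "income"),
                              thresholds = default_thresholds(),
                              force = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  cov <- bundle$covariates
  rvi <- rvi_pipeline(bundle$metrics, cov, bundle$panels,
                      terms = c(base_covariates, "site"))
  stats_tab <- parse_sumstats(bundle$sumstats)
  prs <- prs_pipeline(stats_tab, bundle$genotypes, thresholds = thresholds)
  data <- merge(merge(cov, rvi, by = "subject_id"), prs, by = "subject_id")

  rvi_cols <- c("rvi_sub", "rvi_corth", "rvi_corsa", "rvi_md", "rvi_fa",
                "rvi_multi")
  if (!prs_threshold %in% names(prs))
    stop("prs_threshold '", prs_threshold, "' not among computed columns: ",
         paste(setdiff(names(prs), "subject_id"), collapse = ", "))
  predictors <- c(rvi_cols, prs_threshold)
  pc_cols <- grep("^pc[0-9]+$", names(cov), value = TRUE)
  prs_extra <- c(pc_cols, intersect("plate", names(cov)))

  outcomes <- list(list(name = "lifetime_mdd", kind = "binary"))
  if ("symptom_w1" %in% names(cov))
    outcomes <- c(outcomes, list(list(name = "symptom_w1",
                                      kind = "continuous")))
  if ("symptom_w2" %in% names(cov))
    outcomes <- c(outcomes, list(list(name = "symptom_w2",
                                      kind = "continuous")))

  results <- list()
  for (oc in outcomes) {
    for (pr in predictors) {
      extra <- if (pr == prs_threshold) prs_extra else character()
      if (oc$kind == "binary") {
        spec <- model_spec(oc$name, "binary", pr,
                           covariates = c(base_covariates, "site", extra))
      } else {
        spec <- model_spec(oc$name, "continuous", pr,
                           covariates = c(base_covariates, extra),
                           random_intercept = "site")
      }
      results[[length(results) + 1L]] <- fit_association(spec, data)
    }
  }
  results <- adjust_fdr(results)
  assoc <- association_table(results)

  ladders <- list(); contrasts <- list()
  for (oc in outcomes) {
    ri <- if (oc$kind == "binary") NULL else "site"
    covs <- if (oc$kind == "binary") c(base_covariates, "site")
            else base_covariates
    for (rv in rvi_cols) {
      lad <- aic_ladder(data, oc$name, oc$kind, rvi = rv,
                        prs = prs_threshold, covariates = covs,
                        prs_covariates = prs_extra, random_intercept = ri)
      tag <- data.frame(outcome = oc$name, rvi = rv,
                        stringsAsFactors = FALSE)
      ladders[[length(ladders) + 1L]] <- cbind(tag, as.data.frame(lad))
      contrasts[[length(contrasts) + 1L]] <- cbind(tag, attr(lad, "deltas"))
    }
  }
  ladders <- do.call(rbind, ladders)
  contrasts <- do.call(rbind, contrasts)

  change <- NULL
  if (all(c("symptom_w1", "symptom_w2", "age_diff") %in% names(cov))) {
    ch <- residualized_change(
      data, baseline = "symptom_w1", followup = "symptom_w2",
      covariates = c("sex", "age_diff", "education", "income", "site"),
      predictors = predictors)
    ch <- adjust_fdr(ch)
    change <- association_table(ch)
    change$outcome <- "symptom_change"
  } else {
    message("single-wave bundle: residualized-change stage skipped")
  }

  out <- list(rvi = rvi, prs = prs, data = data, associations = assoc,
              ladders = ladders, ladder_contrasts = contrasts,
              change = change)
  if (!is.null(outdir)) write_results(out, bundle, outdir, force)
  out
}

write_results <- function(out, bundle, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory is not empty (use force = TRUE): ", outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(out$rvi, file.path(outdir, "rvi_scores.tsv"))
  write_tsv(out$prs, file.path(outdir, "prs_scores.tsv"))
  write_tsv(attr(out$prs, "variant_counts"),
            file.path(outdir, "prs_variant_counts.tsv"))
  write_tsv(out$associations, file.path(outdir, "associations.tsv"))
  write_tsv(out$ladders, file.path(outdir, "model_ladders.tsv"))
  write_tsv(out$ladder_contrasts, file.path(outdir, "ladder_contrasts.tsv"))
  if (!is.null(out$change))
    write_tsv(out$change, file.path(outdir, "residualized_change.tsv"))
  log <- list(seed = if (!is.null(bundle$config)) bundle$config$seed,
              config_hash = if (!is.null(bundle$config))
                config_hash(bundle$config)
              else bundle$manifest$config_hash,
              n_subjects = nrow(out$data),
              dropped_variants = list(
                qc = nrow(attr(out$prs, "exclusions") %||% data.frame()),
                alignment = nrow(attr(out$prs, "dropped") %||% data.frame())),
              clumped_variants = length(attr(out$prs, "clumped")))
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
  invisible(outdir)
}
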