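#' Specify one association model
#'
#' One spec pairs a depressive phenotype with a single risk score (an RVI or
#' a PRS column) and the covariate set, and says how to fit it: ordinary
#' least squares for continuous outcomes, maximum-likelihood logistic
#' regression for binary ones, and a random-intercept linear mixed model when
#' a grouping factor (study site) is supplied with a continuous outcome.
#'
#' @param outcome Outcome column name.
#' @param kind `"continuous"` or `"binary"`.
#' @param predictor Score column name (z-scored before fitting).
#' @param covariates Character vector of covariate column names (must not
#'   contain the predictor).
#' @param random_intercept Optional grouping-factor column for a mixed model
#'   (continuous outcomes only).
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome, kind = c("continuous", "binary"), predictor,
                       covariates = character(), random_intercept = NULL) {
  kind <- match.arg(kind)
  if (predictor %in% covariates)
    stop("predictor '", predictor, "' must not appear among the covariates")
  if (!is.null(random_intercept) && kind == "binary")
    stop("random intercepts are supported for continuous outcomes only")
  structure(list(outcome = outcome, kind = kind, predictor = predictor,
                 covariates = covariates, random_intercept = random_intercept),
            class = "model_spec")
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) stop("cannot z-score a zero-variance column")
  (x - mean(x)) / s
}

# Shared fitter: returns the fitted model object on prepared data.
fit_model <- function(outcome, kind, rhs, random_intercept, data) {
  if (kind == "binary") {
    f <- stats::reformulate(rhs, response = outcome)
    fit <- stats::glm(f, data = data, family = stats::binomial())
    if (!fit$converged)
      stop("logistic fit did not converge (", fit$iter, " IWLS iterations)")
    return(fit)
  }
  if (!is.null(random_intercept))
    data[[random_intercept]] <- factor(data[[random_intercept]])
  if (!is.null(random_intercept) &&
      nlevels(data[[random_intercept]]) > 1L) {
    f <- stats::as.formula(paste(
      outcome, "~", paste(rhs, collapse = " + "),
      "+ (1 |", random_intercept, ")"))
    fit <- lme4::lmer(f, data = data, REML = FALSE)
    conv <- fit@optinfo$conv$opt
    if (!is.null(conv) && conv != 0)
      stop("mixed-model optimizer reported non-convergence (code ", conv, ")")
    return(fit)
  }
  # single-level grouping degenerates to OLS (random-intercept variance is
  # not identifiable with one group)
  stats::lm(stats::reformulate(rhs, response = outcome), data = data)
}

#' Fit one association model
#'
#' Complete-case rows are selected over every column the spec names; the
#' predictor is z-scored and continuous outcomes are z-scored (binary
#' outcomes are left on their natural scale), so the reported coefficient is
#' a standardized effect size. Mixed models are fit by maximum likelihood,
#' not REML, so their log-likelihoods and AICs are comparable across
#' fixed-effect specifications. The predictor p-value is a Wald test (normal
#' reference for logistic and mixed fits, t for OLS).
#'
#' @param spec A [model_spec()].
#' @param data Merged subject-level data frame (scores + phenotypes +
#'   covariates).
#' @return An `assoc_result`: list with `spec`, `beta`, `se`, `p`, `n`,
#'   `loglik`, `k` (parameter count), and the underlying `fit`.
#' @export
fit_association <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- c(spec$outcome, spec$predictor, spec$covariates,
            spec$random_intercept)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("column(s) not in data: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  if (!nrow(d)) stop("no complete-case rows for this model")
  d[[spec$predictor]] <- zscore(d[[spec$predictor]])
  if (spec$kind == "continuous") d[[spec$outcome]] <- zscore(d[[spec$outcome]])
  rhs <- c(spec$predictor, spec$covariates)
  fit <- fit_model(spec$outcome, spec$kind, rhs, spec$random_intercept, d)
  extract_result(fit, spec, nrow(d))
}

extract_result <- function(fit, spec, n) {
  if (inherits(fit, "lmerMod")) {
    co <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    beta <- co[[spec$predictor]]
    sei <- se[[which(names(co) == spec$predictor)]]
    p <- 2 * stats::pnorm(-abs(beta / sei))
  } else {
    sm <- summary(fit)$coefficients
    beta <- sm[spec$predictor, 1L]
    sei <- sm[spec$predictor, 2L]
    p <- sm[spec$predictor, 4L]
  }
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  if (n <= k) stop("model has as many parameters as observations")
  structure(list(spec = spec, beta = unname(beta), se = unname(sei),
                 p = unname(p), n = n, loglik = as.numeric(ll), k = k,
                 fit = fit),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: beta = %.4f (se %.4f), p = %.3g, n = %d\n",
              x$spec$outcome, x$spec$predictor, x$beta, x$se, x$p, x$n))
  invisible(x)
}

#' Collect association results into a table
#'
#' @param results List of `assoc_result` objects.
#' @return Data frame with columns `outcome, predictor, beta, se, p, n,
#'   loglik, k` (and `q` if [adjust_fdr()] has run).
#' @export
association_table <- function(results) {
  rows <- lapply(results, function(r) {
    data.frame(outcome = r$spec$outcome, predictor = r$spec$predictor,
               beta = r$beta, se = r$se, p = r$p,
               q = if (is.null(r$q)) NA_real_ else r$q,
               n = r$n, loglik = r$loglik, k = r$k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg FDR within score families
#'
#' Corrects the association p-values within families, by default one family
#' per score column (each RVI type, and each selected PRS threshold, is its
#' own family spanning the outcomes it was tested against).
#'
#' @param results List of `assoc_result` objects.
#' @param family Either `NULL` (family = predictor name) or a vector of
#'   family keys, one per result.
#' @return The list with a `q` element added to every result.
#' @export
adjust_fdr <- function(results, family = NULL) {
  if (is.null(family))
    family <- vapply(results, function(r) r$spec$predictor, "")
  stopifnot(length(family) == length(results))
  p <- vapply(results, `[[`, 0, "p")
  for (f in unique(family)) {
    i <- which(family == f)
    q <- stats::p.adjust(p[i], method = "BH")
    for (k in seq_along(i)) results[[i[k]]]$q <- q[k]
  }
  results
}

#' Residualized-change analysis for two-wave symptom scores
#'
#' Stage 1 regresses the follow-up score on the baseline score plus the
#' change covariates (sex, age difference, parent education, family income,
#' site by default) by OLS. Stage 2 regresses the stage-1 residuals,
#' z-scored, on each z-scored baseline predictor with no further covariates
#' (they were already removed in stage 1). If stage-1 residuals are all zero
#' (follow-up fully determined by baseline), every stage-2 coefficient is 0.
#'
#' @param data Subject-level data frame with both waves.
#' @param baseline,followup Baseline and follow-up outcome column names.
#' @param covariates Stage-1 covariate column names (besides the baseline
#'   score).
#' @param predictors Character vector of baseline score columns to test.
#' @return List of `assoc_result` objects, one per predictor (the `fit` of
#'   each is the stage-2 OLS).
#' @export
residualized_change <- function(data, baseline, followup, covariates,
                                predictors) {
  cols <- c(baseline, followup, covariates)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), , drop = FALSE]
  if (!nrow(d)) stop("no subjects present at both waves with complete data")
  f1 <- stats::reformulate(c(baseline, covariates), response = followup)
  stage1 <- stats::lm(f1, data = d)
  d$.change_resid <- stats::resid(stage1)
  # a follow-up fully determined by stage 1 leaves residuals that are pure
  # floating-point noise; treat them as identically zero
  tol <- max(1e-12, 1e-10 * stats::sd(d[[followup]]))
  degenerate <- stats::sd(d$.change_resid) < tol
  lapply(predictors, function(pr) {
    dd <- d[!is.na(d[[pr]]), , drop = FALSE]
    if (degenerate || stats::sd(dd$.change_resid) < tol) {
      spec <- model_spec(".change_resid", "continuous", pr)
      return(structure(list(spec = spec, beta = 0, se = 0, p = 1,
                            n = nrow(dd), loglik = NA_real_, k = 2L,
                            fit = NULL),
                       class = "assoc_result"))
    }
    fit_association(model_spec(".change_resid", "continuous", pr), dd)
  })
}
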