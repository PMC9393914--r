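#' McFadden pseudo-R-squared
#'
#' `1 - loglik / loglik0`, where `loglik0` is the intercept-only model's
#' log-likelihood on the same rows. For a fitted binomial GLM the
#' intercept-only log-likelihood is recovered from the stored null deviance.
#'
#' @param fit A binomial `glm` fit, or a numeric log-likelihood (then
#'   `loglik0` is required).
#' @param loglik0 Intercept-only log-likelihood (ignored when `fit` is a
#'   `glm`).
#' @return The pseudo-R-squared (proportion, not percent).
#' @export
mcfadden_r2 <- function(fit, loglik0 = NULL) {
  if (inherits(fit, "glm")) {
    ll <- as.numeric(stats::logLik(fit))
    loglik0 <- ll + (fit$deviance - fit$null.deviance) / 2
  } else {
    ll <- as.numeric(fit)
    if (is.null(loglik0)) stop("loglik0 required when fit is a bare log-likelihood")
  }
  1 - ll / loglik0
}

#' Nakagawa-Schielzeth marginal R-squared from variance components
#'
#' `var_fixed / (var_fixed + var_random + var_residual)`: the share of
#' outcome variance attributable to the fixed effects alone.
#'
#' @param var_fixed Variance of the fixed-effect predictions.
#' @param var_random Summed random-intercept variances.
#' @param var_residual Residual variance.
#' @return The marginal R-squared (proportion).
#' @export
nakagawa_marginal <- function(var_fixed, var_random, var_residual) {
  var_fixed / (var_fixed + var_random + var_residual)
}

#' Marginal R-squared of a mixed (or linear) model
#'
#' Fixed-effects variance share in the Nakagawa-Schielzeth sense:
#' `var(X beta) / (var(X beta) + sum of random-intercept variances +
#' residual variance)`, with sample variances of the fixed-effect
#' predictions. For an ordinary `lm` (no random terms) this reduces exactly
#' to the coefficient of determination.
#'
#' @param fit A `lmerMod` or `lm` fit.
#' @return The marginal R-squared (proportion).
#' @export
marginal_r2 <- function(fit) {
  if (inherits(fit, "lmerMod")) {
    fixed <- as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit))
    vf <- stats::var(fixed)
    vc <- as.data.frame(lme4::VarCorr(fit))
    vre <- sum(vc$vcov[vc$grp != "Residual"])
    vres <- vc$vcov[vc$grp == "Residual"]
    return(nakagawa_marginal(vf, vre, vres))
  }
  if (inherits(fit, "lm")) {
    vf <- stats::var(stats::fitted(fit))
    return(nakagawa_marginal(vf, 0, stats::var(stats::resid(fit))))
  }
  stop("marginal_r2 expects an lm or lmerMod fit")
}

model_vars <- function(fit) {
  f <- stats::formula(fit)
  all.vars(f[[3L]])
}

#' Change in explanatory power between nested fits
#'
#' Quantifies what a risk score adds over the covariate-only null, in
#' percentage points: the difference in coefficient of determination for
#' OLS, in McFadden pseudo-R-squared for logistic models (both models scored
#' against the shared intercept-only log-likelihood, so the difference is
#' the score's contribution relative to the null), and in Nakagawa marginal
#' R-squared for mixed models. Both fits must be maximum-likelihood fits of
#' nested specifications on identical rows.
#'
#' @param null_fit,full_fit Nested fitted models (full adds predictors).
#' @param kind `"ols"`, `"mcfadden"` or `"marginal"`.
#' @return Change in R-squared, in percentage points.
#' @export
delta_r2 <- function(null_fit, full_fit, kind = c("ols", "mcfadden",
                                                  "marginal")) {
  kind <- match.arg(kind)
  n0 <- stats::nobs(null_fit); n1 <- stats::nobs(full_fit)
  if (n0 != n1)
    stop("fits use different row sets (", n0, " vs ", n1, " rows)")
  extra <- setdiff(model_vars(null_fit), model_vars(full_fit))
  if (length(extra))
    stop("fits are not nested; null has term(s) absent from full: ",
         paste(extra, collapse = ", "))
  val <- switch(kind,
    ols = summary(full_fit)$r.squared - summary(null_fit)$r.squared,
    mcfadden = mcfadden_r2(full_fit) - mcfadden_r2(null_fit),
    marginal = marginal_r2(full_fit) - marginal_r2(null_fit))
  100 * val
}

#' AIC model ladder: covariates, brain score, genetic score, both
#'
#' Fits the five-model comparison on one outcome, all by maximum likelihood
#' on the identical complete-case row set:
#' \describe{
#'   \item{M1}{base covariates only (the covariate set used with brain
#'     scores, i.e. without genetic principal components or plate)}
#'   \item{M2}{M1 + the RVI column}
#'   \item{M3}{PRS covariates (base + genetic PCs + genotype plate)}
#'   \item{M4}{M3 + the PRS column}
#'   \item{M5}{M4 + the RVI column}
#' }
#' Scores and continuous outcomes are z-scored. AIC is `2k - 2 loglik`
#' exactly from the stored parameter count and log-likelihood. Contrasts of
#' interest (M2-M1, M4-M3, M5-M4, M5-M3) are flagged when they clear the
#' conventional 2-AIC-unit margin.
#'
#' @param data Subject-level data frame.
#' @param outcome Outcome column name.
#' @param kind `"continuous"` or `"binary"`.
#' @param rvi,prs RVI and PRS column names.
#' @param covariates Base covariate columns (for models with brain scores).
#' @param prs_covariates Additional covariate columns for any model that
#'   carries the PRS covariate set (genetic PCs, plate).
#' @param random_intercept Optional grouping factor (continuous outcomes).
#' @return A `model_comparison` data frame: `model, predictors, k, loglik,
#'   aic, r2` (R-squared variant, in percent), with attribute `"deltas"`
#'   (contrast, delta_aic, meaningful) and `"r2_kind"`.
#' @export
aic_ladder <- function(data, outcome, kind = c("continuous", "binary"),
                       rvi, prs, covariates = character(),
                       prs_covariates = character(),
                       random_intercept = NULL) {
  kind <- match.arg(kind)
  cols <- unique(c(outcome, rvi, prs, covariates, prs_covariates,
                   random_intercept))
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("column(s) not in data: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  if (!nrow(d)) stop("no complete-case rows across the five models")
  d[[rvi]] <- zscore(d[[rvi]])
  d[[prs]] <- zscore(d[[prs]])
  if (kind == "continuous") d[[outcome]] <- zscore(d[[outcome]])

  base <- covariates
  full_cov <- c(covariates, prs_covariates)
  rhs_list <- list(M1 = base, M2 = c(base, rvi), M3 = full_cov,
                   M4 = c(full_cov, prs), M5 = c(full_cov, prs, rvi))
  preds <- c(M1 = "covariates", M2 = "covariates + RVI",
             M3 = "covariates(PRS)", M4 = "covariates(PRS) + PRS",
             M5 = "covariates(PRS) + PRS + RVI")
  r2_kind <- if (kind == "binary") "mcfadden"
             else if (!is.null(random_intercept) &&
                      length(unique(d[[random_intercept]])) > 1L) "marginal"
             else "ols"
  fits <- lapply(rhs_list, function(rhs) {
    rhs <- if (length(rhs)) rhs else "1"
    fit_model(outcome, kind, rhs, random_intercept, d)
  })
  rows <- lapply(names(fits), function(m) {
    fit <- fits[[m]]
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    r2 <- switch(r2_kind, mcfadden = mcfadden_r2(fit),
                 marginal = marginal_r2(fit),
                 ols = summary(fit)$r.squared)
    data.frame(model = m, predictors = preds[[m]], k = k,
               loglik = as.numeric(ll), aic = 2 * k - 2 * as.numeric(ll),
               r2 = 100 * r2, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  contrasts <- data.frame(
    contrast = c("M2-M1", "M4-M3", "M5-M4", "M5-M3"),
    delta_aic = c(tab$aic[2] - tab$aic[1], tab$aic[4] - tab$aic[3],
                  tab$aic[5] - tab$aic[4], tab$aic[5] - tab$aic[3]),
    stringsAsFactors = FALSE)
  contrasts$meaningful <- contrasts$delta_aic <= -2
  attr(tab, "deltas") <- contrasts
  attr(tab, "r2_kind") <- r2_kind
  attr(tab, "n") <- nrow(d)
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model ladder (", attr(x, "r2_kind"), " R2, n = ", attr(x, "n"),
      "):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 6)
  cat("\nAIC contrasts:\n")
  print.data.frame(attr(x, "deltas"), row.names = FALSE, digits = 6)
  invisible(x)
}
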