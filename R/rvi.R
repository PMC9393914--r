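#' Residualize regional brain metrics on covariates
#'
#' Removes covariate effects from every metric column by ordinary least
#' squares before z-normalization: for each region the metric is regressed on
#' an intercept plus the requested covariate terms (categorical covariates
#' such as sex and site expand to indicator contrasts), and the residuals are
#' returned. The regression is fit over all subjects with complete data for
#' that region; the z-normalization step, not this one, is what anchors
#' scores to the healthy reference.
#'
#' @param metrics Data frame: `subject_id` plus one numeric column per
#'   region/tract.
#' @param covariates Data frame keyed by `subject_id` containing the
#'   covariate columns.
#' @param terms Character vector of covariate column names to regress out,
#'   e.g. `c("age", "age2", "sex", "site", "education", "income")`.
#' @return A data frame of the same shape as `metrics` (same `subject_id`
#'   order) holding residuals; entries missing in the input stay `NA`.
#' @export
residualize_metrics <- function(metrics, covariates, terms) {
  stopifnot("subject_id" %in% names(metrics),
            "subject_id" %in% names(covariates))
  idx <- match(metrics$subject_id, covariates$subject_id)
  if (anyNA(idx))
    stop("subject(s) in metric table missing from covariate table: ",
         paste(utils::head(metrics$subject_id[is.na(idx)], 5), collapse = ", "))
  cov <- covariates[idx, , drop = FALSE]
  missing_terms <- setdiff(terms, names(cov))
  if (length(missing_terms))
    stop("covariate column(s) not found: ", paste(missing_terms, collapse = ", "))
  X <- if (length(terms))
    stats::model.matrix(stats::reformulate(terms),
                        data = cov[, terms, drop = FALSE])
  else matrix(1, nrow(cov), 1L, dimnames = list(NULL, "(Intercept)"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  region_cols <- setdiff(names(metrics), "subject_id")
  out <- metrics
  Y <- as.matrix(metrics[, region_cols, drop = FALSE])
  complete_all <- !apply(is.na(Y), 1L, any)
  for (j in seq_along(region_cols)) {
    y <- Y[, j]
    ok <- !is.na(y)
    r <- rep(NA_real_, length(y))
    if (all(ok)) {
      r <- qr.resid(qrX, y)
    } else {
      qi <- qr(X[ok, , drop = FALSE])
      if (qi$rank < ncol(X))
        stop("covariate design rank-deficient on complete cases for region ",
             region_cols[j])
      r[ok] <- qr.resid(qi, y[ok])
    }
    out[[region_cols[j]]] <- r
  }
  out
}

#' Healthy-reference normalization statistics
#'
#' Computes, for every region, the mean and sample standard deviation
#' (n - 1 denominator) of the covariate residuals over the healthy subset
#' only. "Healthy" means no self-reported psychiatric diagnosis and no
#' antidepressant use; the flag is supplied by the caller. These statistics
#' anchor everyone's z-scores to the healthy brain.
#'
#' @param residuals Residual table from [residualize_metrics()].
#' @param healthy Logical vector (one per row of `residuals`) marking the
#'   healthy reference subset.
#' @return A `normalization_reference`: list with `stats` (data frame
#'   `region`, `mean`, `sd`, `n`) and `healthy_n`.
#' @export
compute_reference_stats <- function(residuals, healthy) {
  stopifnot(length(healthy) == nrow(residuals))
  healthy <- healthy & !is.na(healthy)
  region_cols <- setdiff(names(residuals), "subject_id")
  if (sum(healthy) < 2)
    stop("need at least 2 healthy subjects to define the reference; got ",
         sum(healthy))
  st <- lapply(region_cols, function(rc) {
    v <- residuals[[rc]][healthy]
    v <- v[!is.na(v)]
    if (length(v) < 2)
      stop("fewer than 2 healthy subjects with data for region ", rc)
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  st <- as.data.frame(do.call(rbind, st))
  st <- cbind(region = region_cols, st, stringsAsFactors = FALSE)
  degenerate <- st$region[st$sd == 0]
  if (length(degenerate))
    stop("zero healthy-reference SD for region(s): ",
         paste(degenerate, collapse = ", "))
  structure(list(stats = st, healthy_n = sum(healthy)),
            class = "normalization_reference")
}

#' Z-normalize residuals against the healthy reference
#'
#' Applies `z = (residual - mean) / sd` per region, to all subjects (healthy
#' and otherwise), using the healthy-derived statistics. By construction the
#' healthy subset then has per-region mean 0 and sample SD 1.
#'
#' @param residuals Residual table from [residualize_metrics()].
#' @param reference A `normalization_reference` covering every region column.
#' @return A data frame of z-scores, same shape as `residuals`.
#' @export
z_normalize <- function(residuals, reference) {
  stopifnot(inherits(reference, "normalization_reference"))
  region_cols <- setdiff(names(residuals), "subject_id")
  missing <- setdiff(region_cols, reference$stats$region)
  if (length(missing))
    stop("region(s) missing from normalization reference: ",
         paste(missing, collapse = ", "))
  out <- residuals
  i <- match(region_cols, reference$stats$region)
  for (k in seq_along(region_cols)) {
    rc <- region_cols[k]
    out[[rc]] <- (residuals[[rc]] - reference$stats$mean[i[k]]) /
      reference$stats$sd[i[k]]
  }
  out
}

#' Compute the Regional Vulnerability Index for one modality
#'
#' The RVI of a subject is the single Pearson correlation coefficient between
#' the subject's vector of region-wise z-scores and the corresponding
#' meta-analytic effect sizes: how closely the individual brain expresses the
#' expected case-control pattern. Subjects with any missing region are not
#' scored for the modality (the correlation is never computed over a shifting
#' region subset), and a subject whose z-vector has zero variance gets `NA`
#' with a warning rather than aborting the cohort.
#'
#' @param z Z-score table from [z_normalize()] (columns `subject_id` + one
#'   per region) or a numeric matrix with subject row names, columns in the
#'   same region order as `effects`.
#' @param effects Numeric effect-size vector aligned to the z columns
#'   (length >= 3, non-constant).
#' @return Named numeric vector of per-subject scores in `[-1, 1]`.
#' @export
compute_rvi <- function(z, effects) {
  if (is.data.frame(z)) {
    ids <- z$subject_id
    zm <- as.matrix(z[, setdiff(names(z), "subject_id"), drop = FALSE])
    rownames(zm) <- ids
  } else {
    zm <- as.matrix(z)
  }
  if (ncol(zm) != length(effects))
    stop("z columns (", ncol(zm), ") and effect vector (", length(effects),
         ") are not aligned")
  if (length(effects) < 3)
    stop("at least 3 regions are required")
  if (stats::sd(effects) == 0)
    stop("effect vector has zero variance; panel cannot support a correlation")
  d <- effects - mean(effects)
  dn <- sqrt(sum(d^2))
  scores <- apply(zm, 1L, function(v) {
    if (anyNA(v)) return(NA_real_)
    vc <- v - mean(v)
    vn <- sqrt(sum(vc^2))
    if (vn == 0) return(NaN)                       # flagged below
    sum(vc * d) / (vn * dn)
  })
  flat <- is.nan(scores)
  if (any(flat)) {
    warning(sum(flat), " subject(s) with zero-variance z-profile scored as NA")
    scores[flat] <- NA_real_
  }
  scores
}

#' Multimodal RVI
#'
#' The multimodal index is the arithmetic mean of the five per-modality
#' scores. Under the default `"complete"` rule a subject must have all
#' modalities to receive a multimodal score; `"available"` averages whatever
#' is present.
#'
#' @param scores Data frame or matrix of per-modality score columns (one row
#'   per subject).
#' @param rule `"complete"` (default) or `"available"`.
#' @return Numeric vector of multimodal scores (`NA` where the rule is not
#'   met).
#' @export
compute_multimodal_rvi <- function(scores, rule = c("complete", "available")) {
  rule <- match.arg(rule)
  m <- as.matrix(as.data.frame(scores))
  if (rule == "complete") {
    out <- rowMeans(m)
  } else {
    out <- rowMeans(m, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
  }
  out
}

#' Full RVI pipeline over all modalities
#'
#' Runs residualization, healthy-reference z-normalization and Pearson
#' scoring for each modality, then averages into the multimodal index.
#' Residualization is fit on all subjects; only the z-normalization uses the
#' healthy subset.
#'
#' @param metrics Named list of metric tables, one per modality (names from
#'   the modality vocabulary), each `subject_id` + region columns.
#' @param covariates Covariate table keyed by `subject_id`, with a logical
#'   `healthy` column.
#' @param panels Named list of `effect_size_panel` objects (same names).
#' @param terms Covariate names to residualize on.
#' @param mappings Optional named list of harmonization maps (see
#'   [harmonize_panel()]); `NULL` entries mean identity.
#' @param drop Optional named list of per-modality region drop-lists.
#' @param multi_rule Completeness rule for the multimodal score.
#' @return Data frame: `subject_id`, `rvi_sub`, `rvi_corth`, `rvi_corsa`,
#'   `rvi_md`, `rvi_fa`, `rvi_multi`.
#' @export
rvi_pipeline <- function(metrics, covariates, panels,
                         terms = c("age", "age2", "sex", "site",
                                   "education", "income"),
                         mappings = NULL, drop = NULL,
                         multi_rule = "complete") {
  stopifnot(is.list(metrics), is.list(panels),
            all(names(metrics) %in% MODALITIES),
            "healthy" %in% names(covariates))
  short <- c(subcortical_volume = "rvi_sub", cortical_thickness = "rvi_corth",
             cortical_surface_area = "rvi_corsa", mean_diffusivity = "rvi_md",
             fractional_anisotropy = "rvi_fa")
  ids <- metrics[[1L]]$subject_id
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (mod in names(metrics)) {
    tab <- metrics[[mod]]
    if (!identical(tab$subject_id, ids))
      stop("metric tables must share an identical subject_id order")
    harmonized <- harmonize_panel(
      panels[[mod]], setdiff(names(tab), "subject_id"),
      mapping = mappings[[mod]], drop = drop[[mod]] %||% character())
    resolved <- resolve_metrics(harmonized, tab)
    resolved_df <- data.frame(subject_id = ids, resolved,
                              check.names = FALSE, stringsAsFactors = FALSE)
    res <- residualize_metrics(resolved_df, covariates, terms)
    healthy <- covariates$healthy[match(ids, covariates$subject_id)]
    ref <- compute_reference_stats(res, healthy)
    zt <- z_normalize(res, ref)
    out[[short[[mod]]]] <- compute_rvi(zt, harmonized$d)
  }
  mod_cols <- intersect(unname(short), names(out))
  out$rvi_multi <- compute_multimodal_rvi(out[, mod_cols, drop = FALSE],
                                          rule = multi_rule)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
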