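#' @keywords internal
"_PACKAGE"

MODALITIES <- c("subcortical_volume", "cortical_thickness",
                "cortical_surface_area", "mean_diffusivity",
                "fractional_anisotropy")

#' Read a reference effect-size panel
#'
#' A panel holds the meta-analytic case-control pattern for one brain
#' modality: one Cohen's d per region or tract, with cases minus controls as
#' the sign convention (a positive RVI then means "more case-like"). Panels
#' are tab-separated files with a header and columns `region`, `d` and an
#' optional `se`; standard errors are stored but unused by the score, which
#' weights all regions equally.
#'
#' @param path Path to a TSV file with columns `region`, `d` (optional `se`).
#' @param modality One of `"subcortical_volume"`, `"cortical_thickness"`,
#'   `"cortical_surface_area"`, `"mean_diffusivity"`,
#'   `"fractional_anisotropy"`.
#' @param negate If `TRUE`, flip the sign of every effect size (for panels
#'   distributed with a controls-minus-cases convention).
#' @return An object of class `effect_size_panel`: a list with `modality` and
#'   a data frame `entries` (columns `region`, `d`, optionally `se`),
#'   preserving the input row order.
#' @export
read_effect_size_panel <- function(path, modality, negate = FALSE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("region", "d") %in% names(tab)))
    stop("panel file must have header columns 'region' and 'd': ", path)
  if (!is.numeric(tab$d)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$d))))
    stop("non-numeric effect size in panel '", path, "' at data line(s): ",
         paste(bad, collapse = ", "))
  }
  entries <- data.frame(region = as.character(tab$region), d = tab$d,
                        stringsAsFactors = FALSE)
  if ("se" %in% names(tab)) entries$se <- tab$se
  if (negate) entries$d <- -entries$d
  new_effect_size_panel(entries, modality)
}

new_effect_size_panel <- function(entries, modality) {
  modality <- match.arg(modality, MODALITIES)
  dup <- unique(entries$region[duplicated(entries$region)])
  if (length(dup))
    stop("duplicate region label(s) in panel: ", paste(dup, collapse = ", "))
  if (nrow(entries) < 3)
    stop("panel has ", nrow(entries),
         " regions; at least 3 are required for a Pearson correlation")
  if (!all(is.finite(entries$d)))
    stop("non-finite effect size(s) in panel for region(s): ",
         paste(entries$region[!is.finite(entries$d)], collapse = ", "))
  structure(list(modality = modality, entries = entries),
            class = "effect_size_panel")
}

#' Write an effect-size panel back to TSV
#'
#' Inverse of [read_effect_size_panel()]: the numeric content round-trips
#' bit-for-bit through the 17-significant-digit decimal representation.
#'
#' @param panel An `effect_size_panel`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_effect_size_panel <- function(panel, path) {
  stopifnot(inherits(panel, "effect_size_panel"))
  e <- panel$entries
  cols <- c("region", "d", if ("se" %in% names(e)) "se")
  lines <- c(paste(cols, collapse = "\t"),
             vapply(seq_len(nrow(e)), function(i) {
               vals <- vapply(cols[-1], function(cn)
                 format(e[[cn]][i], digits = 17, scientific = FALSE,
                        trim = TRUE), "")
               paste(c(e$region[i], vals), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.effect_size_panel <- function(x, ...) {
  cat("Effect-size panel (", x$modality, "): ", nrow(x$entries),
      " regions, d in [", sprintf("%.3f", min(x$entries$d)), ", ",
      sprintf("%.3f", max(x$entries$d)), "]\n", sep = "")
  invisible(x)
}

#' Read a region harmonization map from YAML
#'
#' The map resolves panel region labels to metric column names in the cohort
#' table: a single column, or two hemisphere columns to be averaged
#' (bilateral mean). YAML keys are panel labels, values a scalar or a list of
#' column names.
#'
#' @param path Path to a YAML file.
#' @return A named list of character vectors (class `region_map`).
#' @export
read_region_map <- function(path) {
  m <- yaml::read_yaml(path)
  m <- lapply(m, as.character)
  structure(m, class = "region_map")
}

#' Harmonize a panel against cohort metric columns
#'
#' Resolves every panel region to the metric column(s) carrying it, in panel
#' order. Mapping a region to two columns requests their bilateral mean.
#' Regions on `drop` are removed symmetrically from the effect vector and the
#' column resolution; any other unmapped or missing region is an error, since
#' silently shrinking the correlation's support would change the score's
#' meaning. Cohort columns absent from the panel are ignored: the panel
#' defines the score's support.
#'
#' @param panel An `effect_size_panel`.
#' @param metric_columns Character vector of available metric column names.
#' @param mapping Named list (panel region -> 1 or 2 metric columns), e.g.
#'   from [read_region_map()]. `NULL` means identity (region label == column
#'   name).
#' @param drop Character vector of panel regions to exclude.
#' @return A data frame with one row per retained panel region, in panel
#'   order: `region`, `d`, `columns` (list column of metric column names) and
#'   `rule` (`"single"` or `"bilateral_mean"`).
#' @export
harmonize_panel <- function(panel, metric_columns, mapping = NULL,
                            drop = character()) {
  stopifnot(inherits(panel, "effect_size_panel"))
  e <- panel$entries
  keep <- !(e$region %in% drop)
  e <- e[keep, , drop = FALSE]
  if (nrow(e) < 3)
    stop("fewer than 3 panel regions remain after dropping")
  if (is.null(mapping))
    mapping <- stats::setNames(as.list(e$region), e$region)
  unmapped <- setdiff(e$region, names(mapping))
  if (length(unmapped))
    stop("panel region(s) not in harmonization map and not dropped: ",
         paste(unmapped, collapse = ", "))
  cols <- lapply(e$region, function(r) as.character(mapping[[r]]))
  missing_cols <- setdiff(unlist(cols), metric_columns)
  if (length(missing_cols))
    stop("mapped metric column(s) absent from cohort table: ",
         paste(missing_cols, collapse = ", "))
  nres <- lengths(cols)
  if (any(nres < 1 | nres > 2))
    stop("each panel region must resolve to 1 or 2 metric columns")
  flat <- unlist(cols)
  dup <- unique(flat[duplicated(flat)])
  if (length(dup))
    stop("metric column(s) mapped to more than one panel region: ",
         paste(dup, collapse = ", "))
  out <- data.frame(region = e$region, d = e$d, stringsAsFactors = FALSE)
  out$columns <- cols
  out$rule <- ifelse(nres == 2, "bilateral_mean", "single")
  out
}

#' Resolve harmonized metric values for each subject
#'
#' Applies the column resolution from [harmonize_panel()] to a wide metric
#' table, averaging hemisphere pairs where the rule is `bilateral_mean`.
#'
#' @param harmonized Output of [harmonize_panel()].
#' @param metrics Data frame with a `subject_id` column and metric columns.
#' @return A numeric matrix, subjects x harmonized regions (panel order),
#'   with `subject_id` as row names.
#' @export
resolve_metrics <- function(harmonized, metrics) {
  stopifnot("subject_id" %in% names(metrics))
  m <- vapply(seq_len(nrow(harmonized)), function(i) {
    cols <- harmonized$columns[[i]]
    if (length(cols) == 1L) as.numeric(metrics[[cols]])
    else rowMeans(cbind(as.numeric(metrics[[cols[1]]]),
                        as.numeric(metrics[[cols[2]]])))
  }, numeric(nrow(metrics)))
  m <- matrix(m, nrow = nrow(metrics))
  dimnames(m) <- list(metrics$subject_id, harmonized$region)
  m
}
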