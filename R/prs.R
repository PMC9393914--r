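#' Read GWAS summary statistics
#'
#' Expects a TSV with header `SNP, CHR, BP, A1, A2, BETA, P` and optional
#' `INFO`, `FRQ`. `A1` is the effect allele and `BETA` its additive-scale
#' per-allele effect (log-odds for a binary discovery trait); odds ratios
#' must be log-transformed upstream.
#'
#' @param path TSV path.
#' @return Data frame with columns `id, chrom, pos, a1, a2, beta, p`
#'   (+ `info`, `frq` when present), validated.
#' @export
read_sumstats <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  parse_sumstats(tab)
}

#' Validate an in-memory summary-statistics table
#'
#' Same contract as [read_sumstats()] but starting from a data frame with
#' the external-format column names.
#'
#' @param tab Data frame with columns `SNP, CHR, BP, A1, A2, BETA, P`
#'   (optional `INFO`, `FRQ`).
#' @return Validated internal-format data frame.
#' @export
parse_sumstats <- function(tab) {
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("summary statistics missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(id = as.character(tab$SNP), chrom = as.character(tab$CHR),
                    pos = as.integer(tab$BP), a1 = toupper(tab$A1),
                    a2 = toupper(tab$A2), beta = as.numeric(tab$BETA),
                    p = as.numeric(tab$P), stringsAsFactors = FALSE)
  if ("INFO" %in% names(tab)) out$info <- as.numeric(tab$INFO)
  if ("FRQ" %in% names(tab)) out$frq <- as.numeric(tab$FRQ)
  validate_sumstats(out)
}

validate_sumstats <- function(s) {
  dup <- unique(s$id[duplicated(s$id)])
  if (length(dup))
    stop("duplicate variant id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  if (any(!is.finite(s$p) | s$p <= 0 | s$p > 1))
    stop("p-values must lie in (0, 1]")
  if (any(s$a1 == s$a2)) stop("effect allele equals other allele for some variants")
  ok <- c("A", "C", "G", "T")
  if (!all(s$a1 %in% ok & s$a2 %in% ok))
    stop("alleles must be single bases A/C/G/T")
  s
}

#' Construct a genotype matrix container
#'
#' @param dosage Numeric matrix, subjects x variants, entries in `[0, 2]`
#'   counting copies of each variant's counted allele (`NA` allowed).
#'   Row names are subject ids, column names variant ids.
#' @param variants Data frame with columns `id, chrom, pos, counted, other`
#'   (counted = the allele the dosage counts).
#' @return A `genotype_matrix` (list with `dosage`, `variants`).
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage),
            all(c("id", "chrom", "pos", "counted", "other") %in% names(variants)),
            ncol(dosage) == nrow(variants))
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$id
  if (!identical(colnames(dosage), as.character(variants$id)))
    stop("dosage column names must equal variants$id, in order")
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' Read genotypes from a dosage TSV + variant sidecar
#'
#' Dosage file: first column `subject_id`, one column per variant id.
#' Sidecar: TSV with columns `id, chrom, pos, counted, other`.
#'
#' @param dosage_path,variants_path File paths.
#' @return A `genotype_matrix`.
#' @export
read_dosage <- function(dosage_path, variants_path) {
  d <- utils::read.delim(dosage_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  v <- utils::read.delim(variants_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  v$id <- as.character(v$id); v$chrom <- as.character(v$chrom)
  v$pos <- as.integer(v$pos)
  v$counted <- toupper(v$counted); v$other <- toupper(v$other)
  m <- as.matrix(d[, setdiff(names(d), "subject_id"), drop = FALSE])
  rownames(m) <- d$subject_id
  m <- m[, v$id, drop = FALSE]
  genotype_matrix(m, v)
}

#' Read genotypes from a VCF
#'
#' Uses the `DS` (dosage) FORMAT field when present, otherwise counts ALT
#' alleles in hard `GT` calls. The ALT allele is the counted allele.
#' Multi-allelic records are dropped with a warning.
#'
#' @param path VCF path (plain or bgzipped).
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "ID", "REF", "ALT"),
                             drop = FALSE],
                       stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) dropped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  has_ds <- any(grepl("DS", v@gt[, 1], fixed = TRUE))
  if (has_ds) {
    m <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    m <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L,
                                   dimnames = list(NULL, names(m)))
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(id) | id == "."]
  variants <- data.frame(id = id, chrom = fix$CHROM, pos = as.integer(fix$POS),
                         counted = toupper(fix$ALT), other = toupper(fix$REF),
                         stringsAsFactors = FALSE)
  m <- t(m)                                  # vcfR is variants x subjects
  colnames(m) <- variants$id
  genotype_matrix(m, variants)
}

#' QC-filter summary-statistic variants against cohort genotypes
#'
#' Keeps variants present in both inputs with imputation `INFO >= info_min`
#' (skipped when the column is absent) and cohort minor allele frequency
#' `>= maf_min`, where MAF is `min(f, 1 - f)` with `f` the mean dosage / 2.
#'
#' @param stats Summary statistics (from [read_sumstats()]).
#' @param genotypes A `genotype_matrix`.
#' @param info_min,maf_min QC thresholds (defaults 0.8 and 0.005).
#' @return The filtered summary statistics, with the per-variant exclusion
#'   log attached as attribute `"exclusions"` (data frame `id`, `reason`).
#' @export
qc_filter_variants <- function(stats, genotypes, info_min = 0.8,
                               maf_min = 0.005) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  reason <- rep(NA_character_, nrow(stats))
  in_geno <- stats$id %in% genotypes$variants$id
  reason[!in_geno] <- "absent_from_genotypes"
  f <- colMeans(genotypes$dosage, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  m <- maf[match(stats$id, names(maf))]
  low_maf <- in_geno & !is.na(m) & m < maf_min
  reason[low_maf & is.na(reason)] <- "maf_below_threshold"
  if ("info" %in% names(stats)) {
    low_info <- !is.na(stats$info) & stats$info < info_min
    reason[low_info & is.na(reason)] <- "info_below_threshold"
  }
  keep <- is.na(reason)
  if (!any(keep))
    stop("no variants remain after QC / id intersection")
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- data.frame(id = stats$id[!keep],
                                        reason = reason[!keep],
                                        stringsAsFactors = FALSE)
  out
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Align summary-statistic effects to the genotype's counted allele
#'
#' Matches variants by id and orients each effect onto the allele the dosage
#' counts: same orientation keeps `beta`, swapped alleles negate it, and a
#' strand flip (complementary alleles) is attempted before giving up.
#' Strand-ambiguous variants (A/T, C/G) are dropped, as are allele pairs that
#' do not match after flipping; drops are logged, never fatal.
#'
#' @param stats (Filtered) summary statistics.
#' @param genotypes A `genotype_matrix`.
#' @return Data frame `id`, `effect`, `p` for aligned variants, with dropped
#'   variants in attribute `"dropped"` (data frame `id`, `reason`).
#' @export
align_alleles <- function(stats, genotypes) {
  v <- genotypes$variants
  i <- match(stats$id, v$id)
  present <- !is.na(i)
  s <- stats[present, , drop = FALSE]
  vv <- v[i[present], , drop = FALSE]
  ambiguous <- s$a2 == COMPLEMENT[s$a1]
  effect <- rep(NA_real_, nrow(s))
  reason <- rep(NA_character_, nrow(s))
  same <- s$a1 == vv$counted & s$a2 == vv$other
  swap <- s$a1 == vv$other & s$a2 == vv$counted
  fa1 <- unname(COMPLEMENT[s$a1]); fa2 <- unname(COMPLEMENT[s$a2])
  fsame <- fa1 == vv$counted & fa2 == vv$other
  fswap <- fa1 == vv$other & fa2 == vv$counted
  effect[same | (!same & !swap & fsame)] <- s$beta[same | (!same & !swap & fsame)]
  effect[swap | (!same & !swap & fswap)] <- -s$beta[swap | (!same & !swap & fswap)]
  reason[ambiguous] <- "strand_ambiguous"
  effect[ambiguous] <- NA_real_
  reason[is.na(effect) & is.na(reason)] <- "allele_mismatch"
  keep <- is.na(reason)
  out <- data.frame(id = s$id[keep], effect = effect[keep], p = s$p[keep],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- data.frame(id = s$id[!keep], reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Plink-style clumping: variants are visited in order of ascending p-value
#' (ties broken by ascending position, then id); each visited variant that
#' has not been removed becomes an index, and every other not-yet-removed
#' variant on the same chromosome within `window_kb` kilobases whose squared
#' dosage correlation with the index reaches `r2_max` is removed. Variants
#' with `p > p_max` are never indexed or retained. LD is computed on the
#' analysis sample's dosages (`ld_genotypes` lets a dedicated reference panel
#' stand in). A monomorphic variant has undefined r2; it is treated as
#' r2 = 0 with a warning.
#'
#' @param stats Summary statistics restricted to variants present in the
#'   genotypes.
#' @param genotypes A `genotype_matrix` (the scoring sample).
#' @param r2_max Squared-correlation threshold (default 0.25).
#' @param window_kb Window half-width in kb (default 250).
#' @param p_max Clump p-value ceiling (default 1).
#' @param ld_genotypes Optional `genotype_matrix` to compute LD from instead.
#' @return Character vector of retained (index) variant ids.
#' @export
ld_clump <- function(stats, genotypes, r2_max = 0.25, window_kb = 250,
                     p_max = 1, ld_genotypes = NULL) {
  ld <- if (is.null(ld_genotypes)) genotypes else ld_genotypes
  s <- stats[stats$id %in% colnames(ld$dosage), , drop = FALSE]
  s <- s[s$p <= p_max, , drop = FALSE]
  if (!nrow(s)) return(character())
  ord <- order(s$p, s$pos, s$id)
  s <- s[ord, , drop = FALSE]
  D <- ld$dosage[, s$id, drop = FALSE]
  sds <- apply(D, 2L, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("monomorphic variant(s) in LD computation; r2 treated as 0: ",
            paste(utils::head(s$id[sds == 0], 5), collapse = ", "))
  removed <- rep(FALSE, nrow(s))
  kept <- rep(FALSE, nrow(s))
  win <- window_kb * 1000
  for (k in seq_len(nrow(s))) {
    if (removed[k]) next
    kept[k] <- TRUE
    cand <- which(!removed & !kept & s$chrom == s$chrom[k] &
                    abs(s$pos - s$pos[k]) <= win)
    if (!length(cand)) next
    if (sds[k] == 0 || is.na(sds[k])) next        # index monomorphic: removes nothing
    r <- suppressWarnings(
      stats::cor(D[, k], D[, cand, drop = FALSE],
                 use = "pairwise.complete.obs"))
    r2 <- as.numeric(r)^2
    r2[!is.finite(r2)] <- 0
    removed[cand[r2 >= r2_max]] <- TRUE
  }
  s$id[kept]
}

#' Default p-value threshold set
#' @return The six standard thresholds `(0.001, 0.01, 0.05, 0.1, 0.5, 1)`.
#' @export
default_thresholds <- function() c(0.001, 0.01, 0.05, 0.1, 0.5, 1)

#' Compute polygenic risk scores at each p-value threshold
#'
#' The score at threshold T is the weighted allele sum
#' `sum over clumped variants with p <= T of dosage x aligned effect`
#' (a raw sum, not a per-variant average; scores are standardized by the
#' association models downstream). Missing dosages contribute the variant's
#' mean dosage so scores stay comparable across subjects.
#'
#' @param genotypes A `genotype_matrix`.
#' @param aligned Output of [align_alleles()] (`id`, `effect`, `p`).
#' @param clumped Character vector of retained variant ids from [ld_clump()].
#' @param thresholds Strictly increasing p-value thresholds in `(0, 1]`.
#' @return Data frame `subject_id` + one `pT_<t>` column per threshold, with
#'   per-threshold variant counts in attribute `"variant_counts"`.
#' @export
compute_prs <- function(genotypes, aligned, clumped,
                        thresholds = default_thresholds()) {
  if (!length(thresholds)) stop("threshold set must not be empty")
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must be strictly increasing and in (0, 1]")
  a <- aligned[aligned$id %in% clumped, , drop = FALSE]
  D <- genotypes$dosage[, a$id, drop = FALSE]
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    for (j in seq_len(ncol(D))) D[is.na(D[, j]), j] <- mu[j]
  }
  out <- data.frame(subject_id = rownames(genotypes$dosage),
                    stringsAsFactors = FALSE)
  counts <- integer(length(thresholds))
  for (t in seq_along(thresholds)) {
    inc <- a$p <= thresholds[t]
    counts[t] <- sum(inc)
    sc <- if (any(inc)) as.numeric(D[, inc, drop = FALSE] %*% a$effect[inc])
          else rep(0, nrow(D))
    out[[paste0("pT_", format(thresholds[t], trim = TRUE))]] <- sc
  }
  attr(out, "variant_counts") <-
    data.frame(threshold = thresholds, n_variants = counts)
  out
}

#' End-to-end PRS pipeline
#'
#' QC filter, allele alignment, LD clumping and thresholded scoring in one
#' call, with the intermediate logs attached.
#'
#' @inheritParams qc_filter_variants
#' @inheritParams ld_clump
#' @inheritParams compute_prs
#' @return The PRS table from [compute_prs()], with attributes
#'   `"variant_counts"`, `"exclusions"`, `"dropped"` and `"clumped"`.
#' @export
prs_pipeline <- function(stats, genotypes, info_min = 0.8, maf_min = 0.005,
                         r2_max = 0.25, window_kb = 250, p_max = 1,
                         thresholds = default_thresholds(),
                         ld_genotypes = NULL) {
  filtered <- qc_filter_variants(stats, genotypes, info_min, maf_min)
  aligned <- align_alleles(filtered, genotypes)
  keep <- filtered[filtered$id %in% aligned$id, , drop = FALSE]
  clumped <- ld_clump(keep, genotypes, r2_max, window_kb, p_max, ld_genotypes)
  prs <- compute_prs(genotypes, aligned, clumped, thresholds)
  attr(prs, "exclusions") <- attr(filtered, "exclusions")
  attr(prs, "dropped") <- attr(aligned, "dropped")
  attr(prs, "clumped") <- clumped
  prs
}
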