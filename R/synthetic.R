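#' Simulation configuration for a synthetic cohort
#'
#' Bundles every knob of the generator with defaults emulating a
#' community-based adult imaging-genetics sample: site-nested sampling,
#' covariate confounding of the regional metrics, LD-block genotypes with a
#' discovery-scale summary-statistics panel, a liability-threshold diagnosis,
#' negative-binomial symptom counts at up to two waves, and regional
#' deviations that express the reference case-control pattern in proportion
#' to each subject's modality loading.
#'
#' @param n_subjects Cohort size.
#' @param case_fraction Fraction of subjects above the liability threshold
#'   (lifetime diagnosis); default 0.3, a community lifetime prevalence.
#' @param n_sites Number of study sites; `site_sd` is the SD of the site
#'   random intercepts on the liability scale.
#' @param regions Named integer vector: regions/tracts per modality.
#' @param rvi_loading Named non-negative loadings: how strongly each
#'   modality's pattern expression enters the liability. Defaults place the
#'   signal in white matter (MD, FA) only.
#' @param prs_loading Non-negative loading of the true genetic score on the
#'   liability.
#' @param n_variants,n_causal,ld_block_size,ld_rho Genotype panel: number of
#'   variants, causal subset size, variants per exchangeable LD block, and
#'   the latent (haplotype-level) within-block correlation.
#' @param maf_range Uniform range for per-variant minor allele frequencies.
#' @param beta_sd SD of causal per-allele effects.
#' @param discovery_n Discovery-study sample size used to give the emitted
#'   summary statistics realistic standard errors and p-values.
#' @param ambiguous_fraction Fraction of variants given strand-ambiguous
#'   (A/T, C/G) allele pairs, to exercise alignment drops.
#' @param flip_fraction Fraction of summary-statistic rows emitted with
#'   swapped allele orientation (and negated beta), to exercise alignment.
#' @param panel_mean,panel_sd Distribution of reference panel effect sizes
#'   (small negative Cohen's d values, as in case-control meta-analyses).
#' @param covariate_effects Named list of per-unit covariate effects on the
#'   raw regional metrics (confounding removed by residualization).
#' @param site_metric_sd SD of per-site, per-region metric offsets.
#' @param region_noise_sd Residual SD of a regional metric around its
#'   structural part; the pattern signal `E * d` is small against it, so
#'   per-subject profile correlations stay in a realistic range.
#' @param site_sd SD of liability site intercepts.
#' @param symptom_dispersion Negative-binomial size parameter of the symptom
#'   counts.
#' @param symptom_mean,symptom_mean_followup Target mean symptom counts at
#'   baseline and follow-up (defaults 1.3 and 1.6, a mildly increasing
#'   subclinical scale).
#' @param symptom_slope Log-scale slope of the symptom mean on standardized
#'   liability.
#' @param waves 1 or 2 assessment waves.
#' @param followup_fraction Fraction of subjects retained at wave 2.
#' @param change_loading Extra loading of the liability drivers on the wave-2
#'   latent score (0 = symptom change is pure noise).
#' @param change_noise_sd SD of the wave-2 latent innovation.
#' @param n_pcs Number of (null) genetic principal-component columns.
#' @param n_plates Number of genotyping plates (null factor).
#' @param med_fraction Fraction of subjects flagged as taking
#'   antidepressants, which excludes them from the healthy reference.
#' @param seed Integer seed; every output is a pure function of
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 2000, case_fraction = 0.3, n_sites = 4,
                       regions = c(subcortical_volume = 14,
                                   cortical_thickness = 34,
                                   cortical_surface_area = 34,
                                   mean_diffusivity = 22,
                                   fractional_anisotropy = 22),
                       rvi_loading = c(subcortical_volume = 0,
                                       cortical_thickness = 0,
                                       cortical_surface_area = 0,
                                       mean_diffusivity = 0.5,
                                       fractional_anisotropy = 0.5),
                       prs_loading = 0.3,
                       n_variants = 200, n_causal = 50, ld_block_size = 5,
                       ld_rho = 0.9, maf_range = c(0.05, 0.5),
                       beta_sd = 0.1, discovery_n = 1e5,
                       ambiguous_fraction = 0.05, flip_fraction = 0.3,
                       panel_mean = -0.05, panel_sd = 0.1,
                       covariate_effects = list(age = -0.01, age2 = -2e-4,
                                                sex = 0.1, education = 0.02,
                                                income = 0.02),
                       site_metric_sd = 0.1, region_noise_sd = 1,
                       site_sd = 0.2,
                       symptom_dispersion = 1.2, symptom_mean = 1.3,
                       symptom_mean_followup = 1.6, symptom_slope = 0.5,
                       waves = 2, followup_fraction = 0.55,
                       change_loading = 0.2, change_noise_sd = 0.5,
                       n_pcs = 5, n_plates = 4, med_fraction = 0.1,
                       seed = 1L) {
  stopifnot(n_subjects > 0, case_fraction >= 0, case_fraction <= 1,
            n_sites >= 1, all(regions >= 3), all(rvi_loading >= 0),
            prs_loading >= 0, n_variants >= 1, n_causal <= n_variants,
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            waves %in% c(1, 2), followup_fraction > 0,
            followup_fraction <= 1, is.numeric(seed))
  if (!setequal(names(regions), MODALITIES) ||
      !setequal(names(rvi_loading), MODALITIES))
    stop("regions and rvi_loading must be named by the five modalities")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

region_names <- function(modality, k) {
  prefix <- c(subcortical_volume = "sv", cortical_thickness = "ct",
              cortical_surface_area = "sa", mean_diffusivity = "md",
              fractional_anisotropy = "fa")[[modality]]
  sprintf("%s_region_%02d", prefix, seq_len(k))
}

#' Simulate a reference effect-size panel
#'
#' Draws one Cohen's d per region from `N(panel_mean, panel_sd)`, emulating
#' the small case-control effects of a meta-analytic reference. A
#' zero-variance configuration is rejected: a constant effect vector cannot
#' support the Pearson correlation that defines the score. Deterministic
#' given `(config, modality)`: the panel draw uses a seed offset fixed by the
#' modality, so the standalone call and the full cohort simulation agree.
#'
#' @param config A [sim_config()].
#' @param modality One of the five modality tags.
#' @return An `effect_size_panel`.
#' @export
simulate_reference_panel <- function(config, modality) {
  stopifnot(inherits(config, "sim_config"))
  modality <- match.arg(modality, MODALITIES)
  if (config$panel_sd <= 0)
    stop("panel_sd must be positive: a zero-variance panel cannot define ",
         "a correlation-based score")
  k <- config$regions[[modality]]
  set.seed(config$seed * 10L + match(modality, MODALITIES))
  d <- stats::rnorm(k, config$panel_mean, config$panel_sd)
  new_effect_size_panel(
    data.frame(region = region_names(modality, k), d = d,
               stringsAsFactors = FALSE),
    modality)
}

zscale <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

simulate_genotypes <- function(cfg, ids) {
  n <- cfg$n_subjects
  nv <- cfg$n_variants
  maf <- stats::runif(nv, cfg$maf_range[1], cfg$maf_range[2])
  block <- rep(seq_len(ceiling(nv / cfg$ld_block_size)),
               each = cfg$ld_block_size)[seq_len(nv)]
  nb <- max(block)
  thr <- stats::qnorm(maf)
  dosage <- matrix(0, n, nv)
  for (h in 1:2) {
    u <- matrix(stats::rnorm(n * nb), n, nb)
    lat <- sqrt(cfg$ld_rho) * u[, block, drop = FALSE] +
      sqrt(1 - cfg$ld_rho) * matrix(stats::rnorm(n * nv), n, nv)
    dosage <- dosage + (lat < matrix(thr, n, nv, byrow = TRUE))
  }
  # allele pairs; a slice of variants is strand-ambiguous on purpose
  bases <- c("A", "C", "G", "T")
  counted <- sample(bases, nv, replace = TRUE)
  ambiguous <- stats::runif(nv) < cfg$ambiguous_fraction
  other <- vapply(seq_len(nv), function(j) {
    if (ambiguous[j]) COMPLEMENT[[counted[j]]]
    else sample(setdiff(bases, c(counted[j], COMPLEMENT[[counted[j]]])), 1L)
  }, "")
  variants <- data.frame(
    id = sprintf("rs%05d", seq_len(nv)), chrom = "1",
    pos = seq_len(nv) * 50000L, counted = counted, other = other,
    stringsAsFactors = FALSE)
  rownames(dosage) <- ids
  colnames(dosage) <- variants$id
  list(geno = genotype_matrix(dosage, variants), maf = maf, block = block)
}

simulate_sumstats <- function(cfg, gm, maf, beta_full) {
  v <- gm$variants
  se <- 1 / sqrt(2 * maf * (1 - maf) * cfg$discovery_n)
  beta_hat <- beta_full + stats::rnorm(length(se), 0, se)
  p <- 2 * stats::pnorm(-abs(beta_hat / se))
  p[p < 1e-300] <- 1e-300
  flip <- stats::runif(nrow(v)) < cfg$flip_fraction
  a1 <- ifelse(flip, v$other, v$counted)
  a2 <- ifelse(flip, v$counted, v$other)
  frq <- ifelse(flip, 1 - maf, maf)
  data.frame(SNP = v$id, CHR = v$chrom, BP = v$pos, A1 = a1, A2 = a2,
             BETA = ifelse(flip, -beta_hat, beta_hat), P = p,
             INFO = stats::runif(nrow(v), 0.7, 1),
             FRQ = frq, stringsAsFactors = FALSE)
}

nbinom_counts <- function(target_mean, slope, liability_z, dispersion) {
  mu0 <- target_mean * exp(-slope^2 / 2)
  mu <- mu0 * exp(slope * liability_z)
  stats::rnbinom(length(mu), size = dispersion, mu = mu)
}

#' Simulate a complete synthetic cohort bundle
#'
#' Generates, deterministically from the config seed, everything the
#' pipeline consumes: the five reference panels, per-modality regional
#' metric tables, a covariate/phenotype table (site-nested, with a healthy
#' flag, a liability-threshold lifetime diagnosis, and negative-binomial
#' symptom counts at one or two waves), LD-block genotypes, discovery-style
#' summary statistics, and the ground truth needed to audit every stage.
#'
#' The generative chain: per-subject pattern expressions `E_m ~ N(0,1)` and
#' a true genetic score `G` (dosage-weighted causal effects) drive a latent
#' liability `gamma z(G) + sum_m lambda_m z(E_m) + site + N(0,1)`; the top
#' `case_fraction` of liability is the lifetime diagnosis; each regional
#' metric is covariate effects + `E_m * d_region` + noise, so high-liability
#' subjects express the reference pattern in proportion to the configured
#' loadings.
#'
#' @param config A [sim_config()].
#' @return A `cohort_bundle` list: `config`, `panels`, `metrics` (list of
#'   data frames), `covariates` (with phenotypes), `genotypes`
#'   (`genotype_matrix`), `sumstats`, `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_subjects
  if (cfg$case_fraction * n < 10)
    warning("fewer than 10 expected cases; downstream logistic fits will be ",
            "unstable")
  panels <- lapply(MODALITIES, function(m) simulate_reference_panel(cfg, m))
  names(panels) <- MODALITIES

  set.seed(cfg$seed)
  ids <- sprintf("S%05d", seq_len(n))

  # covariates, sites, genetic nuisance columns
  site <- paste0("site", sample.int(cfg$n_sites, n, replace = TRUE))
  age <- round(stats::rnorm(n, 59, 10), 1)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  education <- round(stats::rnorm(n, 14, 3))
  income <- sample.int(5L, n, replace = TRUE)
  pcs <- matrix(stats::rnorm(n * cfg$n_pcs), n, cfg$n_pcs,
                dimnames = list(NULL, paste0("pc", seq_len(cfg$n_pcs))))
  plate <- paste0("plate", sample.int(cfg$n_plates, n, replace = TRUE))

  g <- simulate_genotypes(cfg, ids)
  beta_full <- rep(0, cfg$n_variants)
  if (cfg$n_causal > 0) {
    causal <- sample.int(cfg$n_variants, cfg$n_causal)
    beta_full[causal] <- stats::rnorm(cfg$n_causal, 0, cfg$beta_sd)
  }
  G <- as.numeric(g$geno$dosage %*% beta_full)
  sumstats <- simulate_sumstats(cfg, g$geno, g$maf, beta_full)

  E <- matrix(stats::rnorm(n * 5), n, 5, dimnames = list(NULL, MODALITIES))
  site_int <- stats::rnorm(cfg$n_sites, 0, cfg$site_sd)
  names(site_int) <- paste0("site", seq_len(cfg$n_sites))
  lambda <- cfg$rvi_loading[MODALITIES]
  drivers <- cfg$prs_loading * zscale(G) +
    as.numeric(E %*% lambda)
  liability <- drivers + site_int[site] + stats::rnorm(n)

  case <- as.integer(liability > stats::quantile(liability,
                                                 1 - cfg$case_fraction))
  med <- stats::rbinom(n, 1L, cfg$med_fraction)
  healthy <- case == 0L & med == 0L

  lz <- zscale(liability)
  symptom_w1 <- nbinom_counts(cfg$symptom_mean, cfg$symptom_slope, lz,
                              cfg$symptom_dispersion)
  # quadratic age on a centred, rescaled basis (same span as raw age^2, but
  # commensurate with the other model columns)
  age2 <- ((age - 60) / 10)^2
  covtab <- data.frame(subject_id = ids, age = age, age2 = age2, sex = sex,
                       site = site, education = education, income = income,
                       pcs, plate = plate, med = med, healthy = healthy,
                       lifetime_mdd = case, symptom_w1 = symptom_w1,
                       stringsAsFactors = FALSE)
  if (cfg$waves == 2) {
    followed <- stats::runif(n) < cfg$followup_fraction
    liab2 <- liability + cfg$change_loading * drivers +
      stats::rnorm(n, 0, cfg$change_noise_sd)
    symptom_w2 <- nbinom_counts(cfg$symptom_mean_followup, cfg$symptom_slope,
                                zscale(liab2), cfg$symptom_dispersion)
    covtab$symptom_w2 <- ifelse(followed, symptom_w2, NA_integer_)
    covtab$age_diff <- ifelse(followed, round(2 + stats::rnorm(n, 0, 0.1), 2),
                              NA_real_)
  }

  ce <- cfg$covariate_effects
  sexM <- as.numeric(sex == "M")
  base_structural <- ce$age * age + ce$age2 * age^2 + ce$sex * sexM +
    ce$education * education + ce$income * income
  metrics <- lapply(MODALITIES, function(m) {
    k <- cfg$regions[[m]]
    d <- panels[[m]]$entries$d
    site_off <- matrix(stats::rnorm(cfg$n_sites * k, 0, cfg$site_metric_sd),
                       cfg$n_sites, k)
    rownames(site_off) <- paste0("site", seq_len(cfg$n_sites))
    vals <- outer(base_structural, rep(1, k)) +
      site_off[site, , drop = FALSE] +
      outer(E[, m], d) +
      matrix(stats::rnorm(n * k, 0, cfg$region_noise_sd), n, k)
    out <- data.frame(subject_id = ids, vals, stringsAsFactors = FALSE)
    names(out) <- c("subject_id", region_names(m, k))
    out
  })
  names(metrics) <- MODALITIES

  truth <- list(liability = liability, E = E, G = G, beta = beta_full,
                site_intercepts = site_int, drivers = drivers,
                maf = g$maf, ld_block = g$block)
  structure(list(config = cfg, panels = panels, metrics = metrics,
                 covariates = covtab, genotypes = g$geno,
                 sumstats = sumstats, truth = truth),
            class = "cohort_bundle")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a cohort bundle to disk
#'
#' Emits every file in the plain-text formats the consuming stages read
#' (panel TSVs, wide metric TSVs, a covariate/phenotype TSV, dosage +
#' variant-sidecar genotype TSVs, a summary-statistics TSV and ground-truth
#' TSVs), plus a YAML manifest recording the seed, a hash of the
#' configuration, and an md5 per file. Re-running with the same config and
#' seed reproduces byte-identical files. An existing non-empty directory is
#' refused unless `force = TRUE`.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param outdir Output directory (created if missing).
#' @param force Overwrite a non-empty directory.
#' @return The manifest, invisibly.
#' @export
write_bundle <- function(bundle, outdir, force = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory is not empty (use force = TRUE to overwrite): ",
         outdir)
  if (dir.exists(outdir) && length(dir(outdir)) && force)
    message("overwriting non-empty directory: ", outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (m in MODALITIES) {
    files <- c(files,
               write_effect_size_panel(bundle$panels[[m]],
                                       file.path(outdir, paste0("panel_", m, ".tsv"))),
               write_tsv(bundle$metrics[[m]],
                         file.path(outdir, paste0("metrics_", m, ".tsv"))))
  }
  files <- c(files,
             write_tsv(bundle$covariates, file.path(outdir, "covariates.tsv")),
             write_tsv(data.frame(subject_id = rownames(bundle$genotypes$dosage),
                                  bundle$genotypes$dosage,
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE),
                       file.path(outdir, "genotypes_dosage.tsv")),
             write_tsv(bundle$genotypes$variants,
                       file.path(outdir, "genotypes_variants.tsv")),
             write_tsv(bundle$sumstats, file.path(outdir, "sumstats.tsv")),
             write_tsv(data.frame(subject_id = bundle$covariates$subject_id,
                                  liability = bundle$truth$liability,
                                  genetic_score = bundle$truth$G,
                                  drivers = bundle$truth$drivers,
                                  bundle$truth$E, check.names = FALSE),
                       file.path(outdir, "groundtruth_subjects.tsv")),
             write_tsv(data.frame(id = bundle$genotypes$variants$id,
                                  causal_beta = bundle$truth$beta,
                                  maf = bundle$truth$maf,
                                  ld_block = bundle$truth$ld_block),
                       file.path(outdir, "groundtruth_variants.tsv")))
  manifest <- list(seed = bundle$config$seed,
                   config_hash = config_hash(bundle$config),
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a cohort bundle from disk
#'
#' Inverse of [write_bundle()] for the analysis-facing files (panels,
#' metrics, covariates, genotypes, summary statistics; ground truth is
#' loaded when present).
#'
#' @param dir Bundle directory.
#' @return A `cohort_bundle` (without the original `config`; the manifest is
#'   attached as `manifest`).
#' @export
read_bundle <- function(dir) {
  panels <- lapply(MODALITIES, function(m)
    read_effect_size_panel(file.path(dir, paste0("panel_", m, ".tsv")), m))
  names(panels) <- MODALITIES
  metrics <- lapply(MODALITIES, function(m)
    utils::read.delim(file.path(dir, paste0("metrics_", m, ".tsv")),
                      stringsAsFactors = FALSE, check.names = FALSE))
  names(metrics) <- MODALITIES
  covariates <- utils::read.delim(file.path(dir, "covariates.tsv"),
                                  stringsAsFactors = FALSE)
  genotypes <- read_dosage(file.path(dir, "genotypes_dosage.tsv"),
                           file.path(dir, "genotypes_variants.tsv"))
  sumstats_raw <- file.path(dir, "sumstats.tsv")
  sumstats <- utils::read.delim(sumstats_raw, stringsAsFactors = FALSE)
  truth <- NULL
  gt <- file.path(dir, "groundtruth_subjects.tsv")
  if (file.exists(gt))
    truth <- list(subjects = utils::read.delim(gt, stringsAsFactors = FALSE),
                  variants = utils::read.delim(
                    file.path(dir, "groundtruth_variants.tsv"),
                    stringsAsFactors = FALSE))
  manifest <- NULL
  mf <- file.path(dir, "manifest.yaml")
  if (file.exists(mf)) manifest <- yaml::read_yaml(mf)
  structure(list(config = NULL, panels = panels, metrics = metrics,
                 covariates = covariates, genotypes = genotypes,
                 sumstats = sumstats, truth = truth, manifest = manifest),
            class = "cohort_bundle")
}
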