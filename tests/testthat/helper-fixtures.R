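# Small programmatic fixtures shared across test files.

tiny_panel_file <- function(rows = c("hippocampus\t-0.14", "amygdala\t-0.05",
                                     "thalamus\t0.02"),
                            header = "region\td") {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(header, rows), f)
  f
}

tiny_genotypes <- function(dosage, chrom = NULL, pos = NULL, counted = NULL,
                           other = NULL) {
  nv <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("v", seq_len(nv))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  genotype_matrix(dosage, data.frame(
    id = colnames(dosage),
    chrom = chrom %||% rep("1", nv),
    pos = pos %||% (seq_len(nv) * 1000L),
    counted = counted %||% rep("A", nv),
    other = other %||% rep("G", nv),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Score + covariate table with genuine signal for ladder checks.
make_acc_ladder_data <- function(n = 2000, seed = 808) {
  set.seed(seed)
  rvi <- rnorm(n); prs <- rnorm(n); age <- rnorm(n, 50, 10)
  eta <- 0.4 * rvi + 0.3 * prs - 0.01 * (age - 50)
  data.frame(y = rbinom(n, 1, stats::plogis(eta)), ycont = eta + rnorm(n),
             rvi = rvi, prs = prs, age = age, pc1 = rnorm(n),
             stringsAsFactors = FALSE)
}

# A fast low-footprint config for replicate-heavy simulations.
small_config <- function(...) {
  args <- list(n_subjects = 500, n_variants = 48, n_causal = 12,
               ld_block_size = 4, waves = 1)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
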