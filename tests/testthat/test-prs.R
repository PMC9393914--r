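sumstats_df <- function(id, chrom = "1", pos = seq_along(id) * 1000L,
                        a1 = "A", a2 = "G", beta = 0.1, p = 0.5, ...) {
  data.frame(id = id, chrom = chrom, pos = as.integer(pos), a1 = a1, a2 = a2,
             beta = beta, p = p, ..., stringsAsFactors = FALSE)
}

test_that("QC keeps variants passing both INFO and cohort-MAF thresholds", {
  # cohort MAFs by construction: mean dosage / 2
  dos <- cbind(v1 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0.2),  # maf 0.01
               v2 = c(rep(1, 4), rep(0, 6)),             # maf 0.2
               v3 = c(rep(0, 9), 0.02),                  # maf 0.001
               v4 = rep(2, 10))                          # maf 0
  g <- tiny_genotypes(dos)
  s <- sumstats_df(c("v1", "v2", "v3", "v4"),
                   info = c(0.9, 0.7, 0.95, 0.99))
  out <- qc_filter_variants(s, g)
  expect_identical(out$id, "v1")
  excl <- attr(out, "exclusions")
  expect_setequal(excl$id, c("v2", "v3", "v4"))
  expect_identical(excl$reason[excl$id == "v2"], "info_below_threshold")
  expect_identical(excl$reason[excl$id == "v4"], "maf_below_threshold")

  s2 <- sumstats_df(c("v1", "v2", "v3", "v4"))       # no INFO column
  out2 <- qc_filter_variants(s2, g)
  expect_setequal(out2$id, c("v1", "v2"))            # nothing excluded on info
})

test_that("variants absent from the genotypes are logged; empty result errors", {
  g <- tiny_genotypes(cbind(v1 = c(0, 1, 2, 1)))
  s <- sumstats_df(c("v1", "vX"))
  out <- qc_filter_variants(s, g)
  expect_identical(attr(out, "exclusions")$reason, "absent_from_genotypes")
  expect_error(qc_filter_variants(sumstats_df("vY"), g), "no variants")
})

test_that("allele alignment orients effects onto the counted allele", {
  g <- tiny_genotypes(cbind(v1 = 0:2, v2 = 0:2, v3 = 0:2, v4 = 0:2),
                      counted = c("A", "G", "A", "T"),
                      other = c("G", "A", "T", "C"))
  s <- sumstats_df(c("v1", "v2", "v3", "v4"), beta = 0.2,
                   a1 = c("A", "A", "A", "A"), a2 = c("G", "G", "T", "G"))
  out <- align_alleles(s, g)
  expect_equal(out$effect[out$id == "v1"], 0.2)     # identical orientation
  expect_equal(out$effect[out$id == "v2"], -0.2)    # swapped alleles
  dropped <- attr(out, "dropped")
  expect_identical(dropped$reason[dropped$id == "v3"], "strand_ambiguous")
  # v4: counted T / other C vs A/G resolves by strand flip (A->T, G->C)
  expect_equal(out$effect[out$id == "v4"], 0.2)
})

test_that("unresolvable allele pairs are dropped with a reason", {
  g <- tiny_genotypes(cbind(v1 = 0:2), counted = "A", other = "C")
  s <- sumstats_df("v1", a1 = "A", a2 = "G")
  out <- align_alleles(s, g)
  expect_identical(nrow(out), 0L)
  expect_identical(attr(out, "dropped")$reason, "allele_mismatch")
})

test_that("greedy clumping follows the hand-traced example", {
  set.seed(10)
  x <- rnorm(200)
  s2 <- 0.7 * x + sqrt(1 - 0.49) * rnorm(200)      # r2 ~ 0.5 with x
  s3 <- 0.97 * x + sqrt(1 - 0.97^2) * rnorm(200)   # r2 ~ 0.9 with x
  clip <- function(v) pmin(pmax(v + 1, 0), 2)
  dos <- cbind(S1 = clip(x), S2 = clip(s2), S3 = clip(s3))
  stopifnot(cor(dos[, "S1"], dos[, "S2"])^2 > 0.25,
            cor(dos[, "S1"], dos[, "S3"])^2 > 0.25)
  g <- tiny_genotypes(dos, pos = c(100000L, 200000L, 600000L))
  s <- sumstats_df(c("S1", "S2", "S3"), pos = c(100000L, 200000L, 600000L),
                   p = c(1e-6, 1e-4, 1e-3))
  kept <- ld_clump(s, g)
  # S2 is inside S1's 250 kb window and in LD -> removed; S3 is 500 kb away
  # from S1, so it survives despite high r2.
  expect_setequal(kept, c("S1", "S3"))
})

test_that("clumping keeps everything under zero LD and dedupes twins", {
  set.seed(2)
  dos <- matrix(sample(0:2, 300, TRUE), 100, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  g <- tiny_genotypes(dos, pos = c(1000L, 2000L, 3000L))
  s <- sumstats_df(c("a", "b", "c"), pos = c(1000L, 2000L, 3000L),
                   p = c(0.01, 0.02, 0.03))
  if (max(cor(dos)[upper.tri(diag(3))]^2) < 0.25)
    expect_setequal(ld_clump(s, g), c("a", "b", "c"))

  twin <- cbind(t1 = dos[, 1], t2 = dos[, 1])
  g2 <- tiny_genotypes(twin, pos = c(1000L, 2000L))
  s2 <- sumstats_df(c("t1", "t2"), pos = c(1000L, 2000L), p = c(0.5, 0.2))
  expect_identical(ld_clump(s2, g2), "t2")         # lower p wins
})

test_that("clumping matches a naive full-matrix reference on random instances", {
  set.seed(31)
  for (rep in 1:30) {
    nv <- sample(5:20, 1)
    n <- 60
    base <- matrix(rnorm(n * nv), n, nv)
    # induce LD by mixing neighbours
    for (j in 2:nv) base[, j] <- 0.8 * base[, j - 1] + 0.6 * base[, j]
    dos <- pmin(pmax(round(base + 1), 0), 2)
    colnames(dos) <- sprintf("v%02d", seq_len(nv))
    pos <- as.integer(cumsum(sample(c(50000L, 400000L), nv, TRUE,
                                    prob = c(0.8, 0.2))))
    g <- tiny_genotypes(dos, pos = pos)
    s <- sumstats_df(colnames(dos), pos = pos, p = runif(nv))
    kept <- ld_clump(s, g, p_max = 0.9)
    expect_setequal(kept, clump_oracle(s, dos, p_max = 0.9))
    expect_true(clump_recheck(s, dos, kept, p_max = 0.9))
  }
})

test_that("monomorphic variants clump as if uncorrelated, with a warning", {
  dos <- cbind(m = rep(1, 50), x = sample(0:2, 50, TRUE))
  g <- tiny_genotypes(dos, pos = c(1000L, 2000L))
  s <- sumstats_df(c("m", "x"), pos = c(1000L, 2000L), p = c(0.1, 0.2))
  expect_warning(kept <- ld_clump(s, g), "monomorphic")
  expect_setequal(kept, c("m", "x"))
})

test_that("PRS is the dosage-weighted effect sum, nested across thresholds", {
  dos <- rbind(s1 = c(0, 1, 2))
  colnames(dos) <- c("a", "b", "c")
  g <- tiny_genotypes(dos)
  aligned <- data.frame(id = c("a", "b", "c"), effect = c(0.1, -0.2, 0.3),
                        p = c(0.0005, 0.04, 0.2))
  prs <- compute_prs(g, aligned, clumped = c("a", "b", "c"))
  expect_equal(prs$pT_1, 0 * 0.1 + 1 * (-0.2) + 2 * 0.3)    # 0.4
  expect_equal(prs$pT_0.001, 0)
  expect_equal(prs$pT_0.05, -0.2)
  counts <- attr(prs, "variant_counts")$n_variants
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts, c(1L, 1L, 2L, 2L, 3L, 3L))

  aligned0 <- aligned; aligned0$effect <- 0
  prs0 <- compute_prs(g, aligned0, c("a", "b", "c"))
  expect_true(all(as.matrix(prs0[-1]) == 0))
  expect_error(compute_prs(g, aligned, c("a"), thresholds = numeric()),
               "empty")
})

test_that("missing dosages contribute the variant's mean dosage", {
  dos <- cbind(v = c(0, 2, NA, 2))
  g <- tiny_genotypes(dos)
  aligned <- data.frame(id = "v", effect = 0.5, p = 0.01)
  prs <- compute_prs(g, aligned, "v", thresholds = 1)
  expect_equal(prs$pT_1, c(0, 1, mean(c(0, 2, 2)) * 0.5, 1))
})

test_that("scaling every beta scales every score linearly", {
  set.seed(4)
  dos <- matrix(sample(0:2, 200, TRUE), 20, 10,
                dimnames = list(NULL, paste0("v", 1:10)))
  g <- tiny_genotypes(dos)
  aligned <- data.frame(id = paste0("v", 1:10), effect = rnorm(10),
                        p = runif(10))
  p1 <- compute_prs(g, aligned, aligned$id)
  aligned2 <- aligned; aligned2$effect <- 3 * aligned2$effect
  p2 <- compute_prs(g, aligned2, aligned$id)
  for (cl in setdiff(names(p1), "subject_id"))
    expect_equal(p2[[cl]], 3 * p1[[cl]], tolerance = 1e-15)
})

test_that("score at a larger threshold is the smaller one plus the new band", {
  set.seed(13)
  dos <- matrix(sample(0:2, 500, TRUE), 50, 10,
                dimnames = list(NULL, paste0("v", 1:10)))
  g <- tiny_genotypes(dos)
  aligned <- data.frame(id = paste0("v", 1:10), effect = rnorm(10),
                        p = runif(10))
  prs <- compute_prs(g, aligned, aligned$id, thresholds = c(0.3, 1))
  band <- aligned$p > 0.3 & aligned$p <= 1
  contrib <- as.numeric(dos[, band, drop = FALSE] %*% aligned$effect[band])
  expect_equal(prs$pT_1, prs$pT_0.3 + contrib, tolerance = 1e-12)
})

test_that("dosage TSV + sidecar round-trips through the reader", {
  set.seed(3)
  dos <- matrix(round(runif(20, 0, 2), 3), 5, 4,
                dimnames = list(paste0("s", 1:5), paste0("v", 1:4)))
  g <- tiny_genotypes(dos)
  fd <- tempfile(fileext = ".tsv"); fv <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(subject_id = rownames(dos), dos,
                                check.names = FALSE),
                     fd, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$variants, fv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g2 <- read_dosage(fd, fv)
  expect_equal(g2$dosage, g$dosage)
  expect_identical(g2$variants$counted, g$variants$counted)
})

test_that("VCF genotypes load via GT hard calls and DS dosages", {
  skip_if_not_installed("vcfR")
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t1000\trs1\tG\tA\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "1\t2000\trs2\tC\tT\t.\t.\t.\tGT\t0|1\t1|1\t0|0"), f)
  g <- read_genotypes_vcf(f)
  expect_equal(unname(g$dosage[, "rs1"]), c(0, 1, 2))
  expect_equal(unname(g$dosage[, "rs2"]), c(1, 2, 0))
  expect_identical(g$variants$counted, c("A", "T"))   # ALT is counted

  f2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t1000\trs1\tG\tA\t.\t.\t.\tGT:DS\t0/0:0.12\t0/1:0.98"), f2)
  g2 <- read_genotypes_vcf(f2)
  expect_equal(unname(g2$dosage[, "rs1"]), c(0.12, 0.98))
})
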