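# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths.

# Pearson correlation from the raw definition.
pearson_oracle <- function(x, y) {
  xc <- x - sum(x) / length(x)
  yc <- y - sum(y) / length(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Benjamini-Hochberg step-up by definition: q(i) = min_{j >= i} p(j) * m / j
# over the sorted p-values, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Naive greedy clumping re-implementation with a full precomputed r2 matrix.
clump_oracle <- function(stats, dosage, r2_max = 0.25, window_kb = 250,
                         p_max = 1) {
  s <- stats[stats$p <= p_max, , drop = FALSE]
  s <- s[order(s$p, s$pos, s$id), , drop = FALSE]
  if (!nrow(s)) return(character())
  r2 <- suppressWarnings(stats::cor(dosage[, s$id, drop = FALSE]))^2
  r2[!is.finite(r2)] <- 0
  status <- rep("free", nrow(s))
  for (i in seq_len(nrow(s))) {
    if (status[i] != "free") next
    status[i] <- "kept"
    for (j in seq_len(nrow(s))) {
      if (status[j] == "free" && s$chrom[j] == s$chrom[i] &&
          abs(s$pos[j] - s$pos[i]) <= window_kb * 1000 &&
          r2[i, j] >= r2_max)
        status[j] <- "removed"
    }
  }
  s$id[status == "kept"]
}

# Exhaustive pairwise re-check of a clumping result: no retained pair in
# LD within the window, and every excluded variant justified by a retained
# index that precedes it in (p, pos, id) order.
clump_recheck <- function(stats, dosage, retained, r2_max = 0.25,
                          window_kb = 250, p_max = 1) {
  s <- stats[stats$p <= p_max, , drop = FALSE]
  r2 <- suppressWarnings(stats::cor(dosage[, s$id, drop = FALSE]))^2
  r2[!is.finite(r2)] <- 0
  rownames(r2) <- colnames(r2) <- s$id
  win <- window_kb * 1000
  keyrank <- order(order(s$p, s$pos, s$id))
  names(keyrank) <- s$id
  for (a in retained) for (b in retained) {
    if (a == b) next
    ia <- match(a, s$id); ib <- match(b, s$id)
    if (s$chrom[ia] == s$chrom[ib] && abs(s$pos[ia] - s$pos[ib]) <= win &&
        r2[a, b] >= r2_max)
      return(FALSE)
  }
  for (v in setdiff(s$id, retained)) {
    iv <- match(v, s$id)
    justified <- any(vapply(retained, function(a) {
      ia <- match(a, s$id)
      s$chrom[ia] == s$chrom[iv] && abs(s$pos[ia] - s$pos[iv]) <= win &&
        r2[a, v] >= r2_max && keyrank[a] < keyrank[v]
    }, logical(1)))
    if (!justified) return(FALSE)
  }
  TRUE
}

# OLS residuals by explicit normal equations.
resid_oracle <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}
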