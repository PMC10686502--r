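# Shared fixture builders. All randomness is seeded at the call site.

# A minimal well-formed summary data.frame.
make_records <- function(n = 3, beta = NULL, se = NULL, pval = NULL,
                         eaf = NULL, chrom = NULL, pos = NULL) {
  data.frame(
    variant_id = sprintf("rs%03d", seq_len(n)),
    chrom = if (is.null(chrom)) rep("1", n) else chrom,
    pos = if (is.null(pos)) 1e6 * seq_len(n) else pos,
    effect_allele = rep("A", n), other_allele = rep("G", n),
    eaf = if (is.null(eaf)) seq(0.1, 0.4, length.out = n) else eaf,
    beta = if (is.null(beta)) seq(0.02, 0.05, length.out = n) else beta,
    se = if (is.null(se)) rep(0.003, n) else se,
    pval = if (is.null(pval)) rep(1e-10, n) else pval,
    n = rep(400000, n), stringsAsFactors = FALSE)
}

# Random harmonized pairs around a true slope.
make_pairs <- function(J = 20, theta = 0.3, seed = 1, noise = 0) {
  set.seed(seed)
  x <- runif(J, 0.02, 0.1)
  sx <- runif(J, 0.002, 0.005)
  sy <- runif(J, 0.01, 0.03)
  y <- theta * x + rnorm(J, 0, noise) + rnorm(J, 0, sy)
  harmonized_set(x, sx, y, sy)
}

# Independent greedy-clumping reference: straightforward re-implementation
# with explicit loops, used as the oracle for ld_clump.
clump_oracle <- function(rec, r2, r2_threshold, window_kb) {
  ord <- order(rec$pval, rec$chrom, rec$pos)
  alive <- rep(TRUE, nrow(rec))
  keep <- character()
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, rec$variant_id[i])
    alive[i] <- FALSE
    for (j in seq_len(nrow(rec))) {
      if (!alive[j]) next
      if (rec$chrom[j] == rec$chrom[i] &&
          abs(rec$pos[j] - rec$pos[i]) <= window_kb * 1000 &&
          r2[rec$variant_id[j], rec$variant_id[i]] >= r2_threshold)
        alive[j] <- FALSE
    }
  }
  keep
}

# Dense two-stage grid search for the weighted-median balance point.
weighted_median_oracle <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  f <- stats::approxfun(r, s, rule = 2, ties = "ordered")
  scan <- function(lo, hi, n) {
    g <- seq(lo, hi, length.out = n)
    g[which.min(abs(f(g) - 0.5))]
  }
  b <- scan(min(r), max(r), 20001)
  step <- (max(r) - min(r)) / 20000
  scan(b - step, b + step, 20001)
}

# Weighted least-squares oracle with the same overdispersion convention as
# the package (scale floored at 1), via lm().
wls_oracle <- function(y, X, w, df) {
  fit <- stats::lm(y ~ 0 + X, weights = w)
  s <- summary(fit)
  scale <- max(1, s$sigma) / s$sigma
  list(coef = unname(coef(fit)), se = unname(s$coefficients[, 2] * scale))
}
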