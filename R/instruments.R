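#' Select genome-wide-significant variants
#'
#' Retains records with `pval` strictly below the threshold (the conventional
#' genome-wide significance level 5e-8 by default).
#'
#' @param ds a [trait_dataset()].
#' @param p_threshold significance threshold; strict inequality is applied.
#' @return a `trait_dataset` with only the significant records. An empty
#'   result is permitted and raises a warning.
#' @export
select_significant <- function(ds, p_threshold = 5e-8) {
  stopifnot(inherits(ds, "trait_dataset"), p_threshold > 0, p_threshold <= 1)
  keep <- ds$records$pval < p_threshold
  if (!any(keep))
    warning("no variant reaches p < ", format(p_threshold), " for '",
            ds$trait, "'")
  .subset_dataset(ds, keep)
}

#' Construct an LD matrix
#'
#' Pairwise squared-correlation (r2) matrix over a set of variants. Must be
#' symmetric with unit diagonal and entries in [0, 1].
#'
#' @param r2 square numeric matrix of r2 values.
#' @param ids variant ids, one per row/column (defaults to dimnames).
#' @return object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(ids)) stop("variant ids required")
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(ids))
    stop("r2 must be square with one row per variant id")
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1))
    stop("r2 values must lie in [0, 1]")
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1")
  dimnames(r2) <- list(ids, ids)
  structure(list(ids = as.character(ids), r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from a pair list
#'
#' Reads a 3-column tab-delimited file (`id_a`, `id_b`, `r2`), symmetrizes,
#' and fills the diagonal with 1. Unlisted pairs get r2 = 0.
#'
#' @param path file path to the pair list (header row required).
#' @return an [ld_matrix()].
#' @export
read_ld_pairs <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("pair list needs columns id_a, id_b, r2")
  names(tab)[1:3] <- c("id_a", "id_b", "r2")
  ids <- sort(unique(c(tab$id_a, tab$id_b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(tab$id_a, tab$id_b)] <- tab$r2
  m <- pmax(m, t(m))
  diag(m) <- 1
  ld_matrix(m, ids)
}

#' Greedy LD clumping
#'
#' Prunes a set of variants to an LD-independent subset: repeatedly take the
#' remaining variant with the smallest p-value as an index variant and remove
#' every remaining variant on the same chromosome within `window_kb`
#' kilobases whose r2 with the index is at or above `r2_threshold`. Ties in
#' p-value are broken by (chrom, pos) order for determinism. Defaults match
#' the conventional stringent setting r2 < 0.001 in a 10,000 kb window.
#'
#' Variants absent from `ld` are treated as independent of everything, with
#' a warning. With `ld = NULL` all variants are assumed independent.
#'
#' @param ds a [trait_dataset()] (typically after [select_significant()]).
#' @param ld an [ld_matrix()] or NULL.
#' @param r2_threshold r2 at or above which a variant is pruned.
#' @param window_kb clumping window in kilobases.
#' @return a `trait_dataset` containing the index variants, in original
#'   record order.
#' @export
ld_clump <- function(ds, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(ds, "trait_dataset"))
  rec <- ds$records
  if (nrow(rec) <= 1L) return(ds)
  if (is.null(ld)) {
    warning("no LD matrix supplied; variants assumed independent")
    return(ds)
  }
  stopifnot(inherits(ld, "ld_matrix"))
  unknown <- setdiff(rec$variant_id, ld$ids)
  if (length(unknown) > 0L)
    warning(length(unknown),
            " variant(s) absent from LD matrix; treated as independent")

  ord <- order(rec$pval, rec$chrom, rec$pos)
  alive <- rep(TRUE, nrow(rec))
  keep <- logical(nrow(rec))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive)
    if (length(cand) == 0L) break
    same_chr <- !is.na(rec$chrom[cand]) & !is.na(rec$chrom[i]) &
      rec$chrom[cand] == rec$chrom[i]
    in_window <- same_chr & !is.na(rec$pos[cand]) & !is.na(rec$pos[i]) &
      abs(rec$pos[cand] - rec$pos[i]) <= window_kb * 1000
    if (!any(in_window)) next
    cand <- cand[in_window]
    r2 <- rep(0, length(cand))
    known <- rec$variant_id[cand] %in% ld$ids
    if (rec$variant_id[i] %in% ld$ids && any(known))
      r2[known] <- ld$r2[rec$variant_id[cand][known], rec$variant_id[i]]
    alive[cand[r2 >= r2_threshold]] <- FALSE
  }
  .subset_dataset(ds, keep)
}

#' Per-variant instrument strength
#'
#' Variance in the exposure explained by one variant and its F statistic,
#' under the standardized-trait approximation:
#' `r2_j = 2 * beta^2 * eaf * (1 - eaf)` and `f_j = beta^2 / se^2`.
#'
#' @param beta per-allele effect on the (standardized) exposure.
#' @param se its standard error.
#' @param eaf effect-allele frequency, or NA (then `r2_j` is NA).
#' @return named list with `r2_j` and `f_j`. Vectorized over its arguments.
#' @export
snp_strength <- function(beta, se, eaf = NA_real_) {
  stopifnot(all(is.na(se) | se > 0))
  list(r2_j = 2 * beta^2 * eaf * (1 - eaf),
       f_j = beta^2 / se^2)
}

#' Aggregate instrument strength
#'
#' Total variance explained and the overall F statistic for a set of k
#' independent instruments in a GWAS of n individuals:
#' `R2 = sum(r2_j)` and `F = ((n - k - 1) / k) * R2 / (1 - R2)`.
#' F <= 10 conventionally signals weak instruments. The mean per-variant F
#' is reported alongside, as both conventions appear in applied work.
#'
#' @param ds a [trait_dataset()] of instruments, or NULL when `r2_total`
#'   is supplied directly.
#' @param n exposure GWAS sample size.
#' @param r2_total optionally, the total variance explained (overrides the
#'   per-variant computation; `k` must then be given too).
#' @param k optionally, the instrument count.
#' @return named list: `r2_total`, `f_overall`, `f_mean` (NA when computed
#'   from `r2_total` alone), `k`, `weak_instrument` flag (`f_overall <= 10`).
#' @export
overall_strength <- function(ds = NULL, n, r2_total = NULL, k = NULL) {
  f_mean <- NA_real_
  if (is.null(r2_total)) {
    stopifnot(inherits(ds, "trait_dataset"))
    rec <- ds$records
    k <- nrow(rec)
    if (k < 1L) stop("at least one instrument required")
    s <- snp_strength(rec$beta, rec$se, rec$eaf)
    r2_total <- sum(s$r2_j)
    f_mean <- mean(s$f_j)
  } else stopifnot(!is.null(k), k >= 1L)
  if (is.na(r2_total)) stop("r2_total is NA (missing eaf?)")
  if (n <= k + 1) stop("sample size must exceed k + 1")
  f_overall <- ((n - k - 1) / k) * r2_total / (1 - r2_total)
  list(r2_total = r2_total, f_overall = f_overall, f_mean = f_mean, k = k,
       weak_instrument = f_overall <= 10)
}
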