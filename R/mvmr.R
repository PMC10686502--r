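#' Multivariable MR by weighted least squares
#'
#' Joint estimation of the direct effect of each exposure on the outcome,
#' conditional on the others: weighted regression of the outcome effects on
#' all exposure effect columns without intercept, weights `1 / se_y^2`.
#' Standard errors carry a multiplicative overdispersion scale
#' `max(1, sqrt(RSS_w / (J - m)))` (never below the homoscedastic
#' weighted-fit SE); p-values are two-sided t with `J - m` degrees of
#' freedom; per-exposure OR and 95% CI by exponentiation.
#'
#' @param table multi-exposure harmonized table from [harmonize_multi()]
#'   (columns `beta_x1`, `se_x1`, ..., `beta_y`, `se_y`), or any data.frame
#'   with those columns.
#' @param exposures exposure labels (defaults to the table's `exposures`
#'   attribute, else `x1`, `x2`, ...).
#' @return object of class `mvmr_result`: data.frame with one row per
#'   exposure (`exposure`, `theta`, `se`, `pval`, `or`, `ci_low`,
#'   `ci_high`) plus attributes `n_snp` and `df`.
#' @export
mvmr_ivw <- function(table, exposures = NULL) {
  bx_cols <- grep("^beta_x[0-9]+$", names(table), value = TRUE)
  bx_cols <- bx_cols[order(as.integer(sub("beta_x", "", bx_cols)))]
  m <- length(bx_cols)
  if (m < 1L) stop("no exposure effect columns (beta_x1, beta_x2, ...)")
  if (is.null(exposures)) exposures <- attr(table, "exposures")
  if (is.null(exposures)) exposures <- paste0("x", seq_len(m))
  stopifnot(length(exposures) == m)
  X <- as.matrix(table[, bx_cols, drop = FALSE])
  y <- table$beta_y
  w <- 1 / table$se_y^2
  J <- nrow(X)
  if (J < m + 1L) stop("need more instruments than exposures")
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < m) {
    dep <- exposures[qrX$pivot[(qrX$rank + 1L):m]]
    stop("collinear exposure effects: ", paste(dep, collapse = ", "))
  }
  fit <- stats::lm.wfit(X, y, w)
  rss <- sum(w * fit$residuals^2)
  scale <- max(1, sqrt(rss / (J - m)))
  xtwx_inv <- chol2inv(fit$qr$qr[seq_len(m), seq_len(m), drop = FALSE])
  se <- sqrt(diag(xtwx_inv)) * scale
  theta <- unname(fit$coefficients)
  pval <- 2 * stats::pt(-abs(theta / se), df = J - m)
  z <- stats::qnorm(0.975)
  out <- data.frame(exposure = exposures, theta = theta, se = se,
                    pval = pval, or = exp(theta),
                    ci_low = exp(theta - z * se),
                    ci_high = exp(theta + z * se),
                    stringsAsFactors = FALSE)
  attr(out, "n_snp") <- J
  attr(out, "df") <- J - m
  class(out) <- c("mvmr_result", class(out))
  out
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("Multivariable MR (", attr(x, "n_snp"), " instruments, ",
      nrow(x), " exposures)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Assemble the joint instrument set for multivariable MR
#'
#' Takes the union of each exposure's genome-wide-significant variants and
#' jointly clumps it, ranking every variant by its smallest p-value across
#' the exposures, so that one LD-independent instrument list serves the
#' joint model.
#'
#' @param exposures list of two or more [trait_dataset()] objects.
#' @param ld an [ld_matrix()] or NULL (independence assumed, with warning).
#' @param p_threshold per-exposure significance threshold.
#' @param r2_threshold,window_kb clumping parameters, as [ld_clump()].
#' @return a `trait_dataset` holding the clumped union; `beta`/`se`/`pval`
#'   columns come from the exposure in which each variant is most
#'   significant (used only for ranking — effect columns for the joint fit
#'   come from [harmonize_multi()]).
#' @export
mvmr_instrument_union <- function(exposures, ld = NULL, p_threshold = 5e-8,
                                  r2_threshold = 0.001, window_kb = 10000) {
  if (!is.list(exposures) || length(exposures) < 2L)
    stop("at least two exposures required")
  sig <- lapply(exposures, function(ds)
    suppressWarnings(select_significant(ds, p_threshold))$records)
  merged <- do.call(rbind, sig)
  if (nrow(merged) == 0L) stop("no variant is significant in any exposure")
  # Keep, per variant, the row with the smallest p across exposures.
  merged <- merged[order(merged$pval), , drop = FALSE]
  merged <- merged[!duplicated(merged$variant_id), , drop = FALSE]
  union_ds <- trait_dataset(merged,
                            trait = paste(vapply(exposures,
                                                 function(d) d$trait, ""),
                                          collapse = "+"))
  ld_clump(union_ds, ld, r2_threshold, window_kb)
}
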