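# Internal: pull the numeric vectors an estimator needs from a harmonized set
# (or accept a plain data.frame with the same columns).
.mr_data <- function(pairs) {
  if (inherits(pairs, "harmonized_set")) pairs <- retained_pairs(pairs)
  stopifnot(is.data.frame(pairs),
            all(c("beta_x", "se_x", "beta_y", "se_y") %in% names(pairs)))
  list(id = if ("variant_id" %in% names(pairs)) pairs$variant_id else
         paste0("snp", seq_len(nrow(pairs))),
       x = pairs$beta_x, sx = pairs$se_x,
       y = pairs$beta_y, sy = pairs$se_y)
}

.mr_estimate <- function(method, theta, se, pval, n_snp) {
  est <- list(method = method, theta = theta, se = se, pval = pval,
              n_snp = n_snp)
  class(est) <- "mr_estimate"
  to_or(est)
}

#' Convert a causal estimate to the odds-ratio scale
#'
#' Populates `or`, `ci_low`, `ci_high` from a log-odds effect and its
#' standard error: `OR = exp(theta)`, 95% CI `exp(theta -/+ 1.96 se)`. The
#' CI is symmetric on the log scale, so `sqrt(ci_low * ci_high) == or`.
#'
#' @param est an `mr_estimate` (or any list with `theta` and `se`).
#' @return the estimate with OR fields populated.
#' @export
to_or <- function(est) {
  z <- stats::qnorm(0.975)
  est$or <- exp(est$theta)
  est$ci_low <- exp(est$theta - z * est$se)
  est$ci_high <- exp(est$theta + z * est$se)
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: theta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g, nSNP = %d\n",
              x$method, x$theta, x$se, x$or, x$ci_low, x$ci_high, x$pval,
              x$n_snp))
  invisible(x)
}

#' Wald ratio estimate from a single instrument
#'
#' Per-variant causal estimate: outcome effect divided by exposure effect,
#' with the first-order delta-method standard error `se_y / |beta_x|`
#' (exposure-side uncertainty ignored, the usual two-sample simplification).
#'
#' @param pairs a one-row harmonized pair (data.frame or `harmonized_set`
#'   with a single retained pair).
#' @return an `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(pairs) {
  d <- .mr_data(pairs)
  if (length(d$x) != 1L) stop("wald_ratio takes exactly one pair")
  if (d$x == 0) stop("exposure effect is zero; Wald ratio undefined")
  theta <- d$y / d$x
  se <- d$sy / abs(d$x)
  .mr_estimate("wald", theta, se, 2 * stats::pnorm(-abs(theta / se)), 1L)
}

#' Inverse-variance weighted estimate
#'
#' Precision-weighted pooling of per-variant Wald ratios with weights
#' `w_j = beta_x_j^2 / se_y_j^2`, algebraically identical to weighted
#' least-squares regression of `beta_y` on `beta_x` through the origin with
#' weights `1 / se_y^2`. The `"fixed"` standard error is `(sum w)^(-1/2)`;
#' `"multiplicative_random"` (the default, and the primary estimate the
#' pipeline reports) inflates it by `sqrt(max(1, Q / (J - 1)))`, where Q is
#' Cochran's heterogeneity statistic — overdispersion widens the interval
#' but underdispersion never narrows it. P-values are two-sided normal.
#'
#' A single pair falls back to [wald_ratio()] (method reported as `"wald"`).
#'
#' @param pairs a `harmonized_set` or pairs data.frame.
#' @param mode `"multiplicative_random"` or `"fixed"`.
#' @return an `mr_estimate` with method `"ivw_mre"` or `"ivw_fixed"`.
#' @export
mr_ivw <- function(pairs, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  d <- .mr_data(pairs)
  J <- length(d$x)
  if (J == 0L) stop("no instruments")
  if (J == 1L) return(wald_ratio(pairs))
  w <- d$x^2 / d$sy^2
  r <- d$y / d$x
  theta <- sum(w * r) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (r - theta)^2)
  se <- if (mode == "fixed") se_fixed else
    se_fixed * sqrt(max(1, q / (J - 1)))
  .mr_estimate(if (mode == "fixed") "ivw_fixed" else "ivw_mre",
               theta, se, 2 * stats::pnorm(-abs(theta / se)), J)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' unconstrained intercept, weights `1 / se_y^2`. The slope is a causal
#' estimate robust to directional pleiotropy under the InSIDE assumption;
#' the intercept estimates the average direct (pleiotropic) effect. Pairs
#' are re-signed so every `beta_x >= 0` before fitting, the conventional
#' orientation that makes the intercept interpretable. Standard errors use
#' a multiplicative overdispersion scale `max(1, sqrt(RSS_w / (J - 2)))`;
#' p-values are two-sided t with `J - 2` degrees of freedom.
#'
#' @param pairs a `harmonized_set` or pairs data.frame with at least 3 pairs.
#' @return list with elements `slope` and `intercept`, both `mr_estimate`
#'   objects (methods `"egger_slope"`, `"egger_intercept"`; the intercept's
#'   OR fields refer to `exp(intercept)` and are rarely of interest).
#' @export
mr_egger <- function(pairs) {
  d <- .mr_data(pairs)
  J <- length(d$x)
  if (J < 3L) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(d$x)
  flip[flip == 0] <- 1
  x <- d$x * flip
  y <- d$y * flip
  w <- 1 / d$sy^2
  fit <- stats::lm.wfit(cbind(intercept = 1, slope = x), y, w)
  rss <- sum(w * fit$residuals^2)
  scale <- max(1, sqrt(rss / (J - 2)))
  xtwx_inv <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
  se <- sqrt(diag(xtwx_inv)) * scale
  est <- fit$coefficients
  pv <- 2 * stats::pt(-abs(est / se), df = J - 2)
  list(slope = .mr_estimate("egger_slope", est[["slope"]], se[[2]],
                            pv[[2]], J),
       intercept = .mr_estimate("egger_intercept", est[["intercept"]],
                                se[[1]], pv[[1]], J))
}

# Weighted-median point estimate: order the ratios, accumulate normalized
# weights, and interpolate linearly to the 50% weight point.
.weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  J <- length(r)
  if (0.5 >= s[J]) return(r[J])
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted median estimate
#'
#' The causal estimate consistent when instruments carrying at least half of
#' the total weight are valid. Wald ratios are ordered and the estimate
#' interpolates the ratio at which the cumulative normalized weight (each
#' ratio contributing half its weight at its own position) crosses 50%.
#' Weights are `beta_x^2 / se_y^2`. The standard error comes from a seeded
#' parametric bootstrap: effect pairs are redrawn from normal distributions
#' centred on the observations with their reported standard errors, and the
#' estimator's spread across resamples is reported.
#'
#' @param pairs a `harmonized_set` or pairs data.frame with at least 3 pairs.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = 1L) {
  d <- .mr_data(pairs)
  J <- length(d$x)
  if (J < 3L) stop("weighted median requires at least 3 instruments")
  w <- d$x^2 / d$sy^2
  theta <- .weighted_median_point(d$y / d$x, w)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      xb <- stats::rnorm(J, d$x, d$sx)
      yb <- stats::rnorm(J, d$y, d$sy)
      ok <- xb != 0
      .weighted_median_point(yb[ok] / xb[ok], xb[ok]^2 / d$sy[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  .mr_estimate("weighted_median", theta, se,
               2 * stats::pnorm(-abs(theta / se)), J)
}

# Evaluate a block with a local, restorable RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Fit the standard two-sample MR estimator suite
#'
#' The main fitting function: takes a harmonized instrument-outcome set and
#' returns the inverse-variance weighted estimate (the primary analysis),
#' MR-Egger slope and intercept, and the weighted median, plus Cochran's Q.
#' Methods needing more instruments than available are omitted with a
#' reason recorded in `$skipped`. With a single instrument only the Wald
#' ratio is returned.
#'
#' @param pairs a [harmonized_set()] (or data.frame with columns `beta_x`,
#'   `se_x`, `beta_y`, `se_y`).
#' @param methods subset of `c("ivw", "egger", "weighted_median")`.
#' @param ivw_mode passed to [mr_ivw()].
#' @param n_boot,seed bootstrap controls for [mr_weighted_median()].
#' @return object of class `mr_fit`: list with `estimates` (list of
#'   `mr_estimate`), `heterogeneity` (from [cochran_q()], when J >= 2),
#'   `exposure`, `outcome`, `n_snp`, `skipped`.
#' @seealso [mr_sensitivity()] for the pleiotropy diagnostics and outlier
#'   workflow; [summary.mr_fit()] for a result table.
#' @export
mr_fit <- function(pairs, methods = c("ivw", "egger", "weighted_median"),
                   ivw_mode = "multiplicative_random",
                   n_boot = 1000, seed = 1L) {
  methods <- match.arg(methods, c("ivw", "egger", "weighted_median"),
                       several.ok = TRUE)
  d <- .mr_data(pairs)
  J <- length(d$x)
  if (J == 0L) stop("no retained instruments")
  est <- list()
  skipped <- character()
  if (J == 1L) {
    est$wald <- wald_ratio(pairs)
    msgs <- c(ivw = "single instrument: Wald ratio reported",
              egger = "needs >= 3 instruments",
              weighted_median = "needs >= 3 instruments")
    skipped <- msgs[intersect(names(msgs), methods)]
  } else {
    if ("ivw" %in% methods) est$ivw <- mr_ivw(pairs, ivw_mode)
    if ("egger" %in% methods) {
      if (J >= 3L) {
        eg <- mr_egger(pairs)
        est$egger <- eg$slope
        est$egger_intercept <- eg$intercept
      } else skipped <- c(skipped, egger = "needs >= 3 instruments")
    }
    if ("weighted_median" %in% methods) {
      if (J >= 3L)
        est$weighted_median <- mr_weighted_median(pairs, n_boot, seed)
      else skipped <- c(skipped, weighted_median = "needs >= 3 instruments")
    }
  }
  het <- if (J >= 2L) cochran_q(pairs) else NULL
  structure(list(estimates = est, heterogeneity = het,
                 exposure = if (inherits(pairs, "harmonized_set"))
                   pairs$exposure else "exposure",
                 outcome = if (inherits(pairs, "harmonized_set"))
                   pairs$outcome else "outcome",
                 n_snp = J, skipped = skipped),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Two-sample MR: ", x$exposure, " -> ", x$outcome,
      " (", x$n_snp, " instruments)\n", sep = "")
  for (e in x$estimates) print(e)
  if (!is.null(x$heterogeneity))
    cat(sprintf("Cochran's Q = %.3f (df %d), p = %.3g\n",
                x$heterogeneity$q_stat, x$heterogeneity$q_df,
                x$heterogeneity$q_pval))
  if (length(x$skipped))
    cat("skipped:", paste(names(x$skipped), x$skipped, sep = ": ",
                          collapse = "; "), "\n")
  invisible(x)
}

#' Summarize an MR fit as a result table
#'
#' @param object an `mr_fit`.
#' @param ... unused.
#' @return data.frame with one row per estimate: exposure, outcome, method,
#'   n_snp, theta, se, pval, or, ci_low, ci_high.
#' @export
summary.mr_fit <- function(object, ...) {
  rows <- lapply(object$estimates, function(e)
    data.frame(exposure = object$exposure, outcome = object$outcome,
               method = e$method, n_snp = e$n_snp, theta = e$theta,
               se = e$se, pval = e$pval, or = e$or, ci_low = e$ci_low,
               ci_high = e$ci_high, stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$theta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  th <- coef(object)
  se <- vapply(object$estimates, function(e) e$se, numeric(1))
  out <- cbind(th - z * se, th + z * se)
  colnames(out) <- paste0(format(100 * c((1 - level) / 2,
                                         1 - (1 - level) / 2), 3), " %")
  out
}
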