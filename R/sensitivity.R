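#' Cochran's Q heterogeneity test
#'
#' Weighted heterogeneity of the per-variant Wald ratios around the
#' fixed-effect IVW estimate: `Q = sum w_j (r_j - theta_ivw)^2` with
#' `w_j = beta_x_j^2 / se_y_j^2`. Under homogeneity Q is chi-square with
#' `J - 1` degrees of freedom; a small p-value signals heterogeneity,
#' often a symptom of horizontal pleiotropy.
#'
#' @param pairs a `harmonized_set` or pairs data.frame with J >= 2.
#' @return list: `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(pairs) {
  d <- .mr_data(pairs)
  J <- length(d$x)
  if (J < 2L) stop("Cochran's Q requires at least 2 instruments")
  w <- d$x^2 / d$sy^2
  r <- d$y / d$x
  theta <- sum(w * r) / sum(w)
  q <- sum(w * (r - theta)^2)
  list(q_stat = q, q_df = J - 1L,
       q_pval = stats::pchisq(q, df = J - 1L, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression estimates the average direct
#' effect of the instruments on the outcome; an intercept significantly
#' different from zero (two-sided t, p < alpha) indicates directional
#' horizontal pleiotropy.
#'
#' @param pairs a `harmonized_set` or pairs data.frame with J >= 3.
#' @param alpha flag threshold (default 0.05).
#' @return list: `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`, `pleiotropy` flag.
#' @export
egger_intercept_test <- function(pairs, alpha = 0.05) {
  ic <- mr_egger(pairs)$intercept
  list(egger_intercept = ic$theta, egger_intercept_se = ic$se,
       egger_intercept_pval = ic$pval, pleiotropy = ic$pval < alpha)
}

# Leave-one-out through-origin WLS slopes for each variant, given
# A = sum(x*y/sy^2), B = sum(x^2/sy^2).
.loo_slopes <- function(x, y, sy2) {
  a <- x * y / sy2
  b <- x^2 / sy2
  (sum(a) - a) / (sum(b) - b)
}

#' Simulation-based pleiotropy residual test with outlier and distortion
#' analysis
#'
#' A three-part diagnostic for horizontal pleiotropy built on the weighted
#' residual sum of squares (RSS) of the through-origin IVW fit, each
#' variant's residual taken against the leave-one-out slope so an outlier
#' cannot mask itself:
#'
#' * **Global test** — the observed RSS is compared with its null
#'   distribution from `n_sim` parametric simulations that redraw every
#'   outcome effect from `Normal(theta_(-j) * beta_x_j, se_y_j)` (and, when
#'   `exposure_noise = TRUE`, every exposure effect from
#'   `Normal(beta_x_j, se_x_j)`); `p = (1 + #\{RSS_sim >= RSS_obs\}) /
#'   (n_sim + 1)`, so p is never below `1 / (n_sim + 1)`.
#' * **Outlier test** — each variant's observed weighted squared residual is
#'   compared with its own simulated distribution; per-variant p-values are
#'   Bonferroni-corrected across the J variants and variants with corrected
#'   p below `outlier_alpha` are flagged.
#' * **Distortion test** — when outliers are flagged, the shift in the IVW
#'   estimate after their removal is compared with the distribution of
#'   shifts from removing `n_dist` random subsets of the same size.
#'
#' When outliers are found the IVW analysis is re-run once on the
#' outlier-free set (`estimate_after_removal`); the procedure is not
#' iterated.
#'
#' @param pairs a `harmonized_set` or pairs data.frame with J >= 4.
#' @param n_sim simulated datasets for the global/outlier tests.
#' @param outlier_alpha threshold on Bonferroni-corrected per-variant
#'   p-values.
#' @param n_dist random subsets for the distortion test.
#' @param exposure_noise redraw exposure effects in the simulations
#'   (default TRUE).
#' @param seed RNG seed.
#' @return list: `global_rss`, `global_pval`, `outliers` (variant ids),
#'   `outlier_pvals` (Bonferroni-corrected, named), `distortion_pval` (NA
#'   when no outliers), `estimate_after_removal` (an `mr_estimate`, NULL
#'   when no outliers), `n_snp`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, outlier_alpha = 0.05,
                      n_dist = 1000, exposure_noise = TRUE, seed = 1L) {
  d <- .mr_data(pairs)
  J <- length(d$x)
  if (J < 4L) {
    warning("outlier test requires at least 4 instruments; returning NAs")
    return(list(global_rss = NA_real_, global_pval = NA_real_,
                outliers = character(), outlier_pvals = numeric(),
                distortion_pval = NA_real_, estimate_after_removal = NULL,
                n_snp = J))
  }
  x <- d$x; y <- d$y; sx <- d$sx; sy <- d$sy
  sy2 <- sy^2
  loo <- .loo_slopes(x, y, sy2)
  res_obs <- (y - loo * x)^2 / sy2
  rss_obs <- sum(res_obs)

  withr_seed(seed, {
    # Simulated datasets: rows = simulations, columns = variants.
    xs <- if (exposure_noise)
      matrix(stats::rnorm(n_sim * J, rep(x, each = n_sim),
                          rep(sx, each = n_sim)), n_sim, J)
    else matrix(x, n_sim, J, byrow = TRUE)
    ys <- matrix(stats::rnorm(n_sim * J, rep(loo * x, each = n_sim),
                              rep(sy, each = n_sim)), n_sim, J)
    sy2m <- matrix(sy2, n_sim, J, byrow = TRUE)
    a <- xs * ys / sy2m
    b <- xs^2 / sy2m
    loo_sim <- (rowSums(a) - a) / (rowSums(b) - b)
    res_sim <- (ys - loo_sim * xs)^2 / sy2m
    rss_sim <- rowSums(res_sim)

    global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    p_snp <- (1 + colSums(res_sim >= rep(res_obs, each = n_sim))) /
      (n_sim + 1)
    p_corr <- pmin(1, p_snp * J)
    names(p_corr) <- d$id
    out_idx <- which(p_corr < outlier_alpha)

    distortion_pval <- NA_real_
    est_after <- NULL
    if (length(out_idx) > 0L && length(out_idx) < J - 1L) {
      ivw_slope <- function(keep)
        sum(x[keep] * y[keep] / sy2[keep]) / sum(x[keep]^2 / sy2[keep])
      theta_all <- ivw_slope(seq_len(J))
      theta_after <- ivw_slope(setdiff(seq_len(J), out_idx))
      d_obs <- theta_after - theta_all
      d_null <- vapply(seq_len(n_dist), function(b) {
        drop <- sample.int(J, length(out_idx))
        ivw_slope(setdiff(seq_len(J), drop)) - theta_all
      }, numeric(1))
      distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_dist + 1)
      keep_pairs <- if (inherits(pairs, "harmonized_set"))
        retained_pairs(pairs)[-out_idx, , drop = FALSE]
      else pairs[-out_idx, , drop = FALSE]
      est_after <- mr_ivw(keep_pairs)
    }
    list(global_rss = rss_obs, global_pval = global_pval,
         outliers = d$id[out_idx], outlier_pvals = p_corr,
         distortion_pval = distortion_pval,
         estimate_after_removal = est_after, n_snp = J)
  })
}

#' Run the full sensitivity workflow on a harmonized set
#'
#' Applies the reporting discipline of a standard two-sample MR analysis:
#' Cochran's Q and the Egger intercept test always run; when the intercept
#' test signals pleiotropy (p < alpha) the simulation-based outlier
#' procedure ([mr_presso()]) runs, and when outliers are found the IVW
#' analysis is repeated once without them.
#'
#' @param pairs a `harmonized_set` or pairs data.frame.
#' @param alpha significance level for the pleiotropy flag.
#' @param n_sim,outlier_alpha,exposure_noise,seed passed to [mr_presso()].
#' @param always_presso run the outlier procedure regardless of the
#'   intercept test (default FALSE).
#' @return object of class `mr_sensitivity`: merged fields of
#'   [cochran_q()], [egger_intercept_test()] and (when run) [mr_presso()].
#' @export
mr_sensitivity <- function(pairs, alpha = 0.05, n_sim = 1000,
                           outlier_alpha = 0.05, exposure_noise = TRUE,
                           seed = 1L, always_presso = FALSE) {
  d <- .mr_data(pairs)
  J <- length(d$x)
  out <- list(n_snp = J, q_stat = NA_real_, q_df = NA_integer_,
              q_pval = NA_real_, egger_intercept = NA_real_,
              egger_intercept_pval = NA_real_, pleiotropy = NA,
              presso_global_pval = NA_real_, presso_outliers = character(),
              presso_distortion_pval = NA_real_,
              estimate_after_removal = NULL)
  if (J >= 2L) out[names(cochran_q(pairs))] <- cochran_q(pairs)
  if (J >= 3L) {
    it <- egger_intercept_test(pairs, alpha)
    out$egger_intercept <- it$egger_intercept
    out$egger_intercept_pval <- it$egger_intercept_pval
    out$pleiotropy <- it$pleiotropy
  }
  if ((isTRUE(out$pleiotropy) || always_presso) && J >= 4L) {
    pr <- mr_presso(pairs, n_sim = n_sim, outlier_alpha = outlier_alpha,
                    exposure_noise = exposure_noise, seed = seed)
    out$presso_global_pval <- pr$global_pval
    out$presso_outliers <- pr$outliers
    out$presso_distortion_pval <- pr$distortion_pval
    out$estimate_after_removal <- pr$estimate_after_removal
  }
  class(out) <- "mr_sensitivity"
  out
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("Sensitivity diagnostics (", x$n_snp, " instruments)\n", sep = "")
  if (!is.na(x$q_stat))
    cat(sprintf("  Cochran's Q = %.3f (df %d), p = %.3g\n",
                x$q_stat, x$q_df, x$q_pval))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4f, p = %.3g%s\n",
                x$egger_intercept, x$egger_intercept_pval,
                if (isTRUE(x$pleiotropy)) "  [pleiotropy flagged]" else ""))
  if (!is.na(x$presso_global_pval)) {
    cat(sprintf("  Global outlier test p = %.3g; %d outlier(s)\n",
                x$presso_global_pval, length(x$presso_outliers)))
    if (length(x$presso_outliers))
      cat("    outliers:", paste(x$presso_outliers, collapse = ", "),
          sprintf("; distortion p = %.3g\n", x$presso_distortion_pval))
  }
  invisible(x)
}
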