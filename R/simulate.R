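#' Ground truth for a synthetic two-sample MR dataset
#'
#' Fixes every generating parameter of a paired exposure/outcome
#' summary-statistics dataset: the true causal effect, per-variant
#' instrument effects, the horizontal-pleiotropy regime, allele
#' frequencies, and the two GWAS sample sizes. Defaults mimic a large
#' biobank exposure GWAS (~450,000 individuals) paired with a large
#' case-control outcome GWAS (~300,000 individuals) and instrument counts
#' in the tens, the scale at which published dietary-exposure MR analyses
#' operate.
#'
#' Pleiotropy regimes parameterize violations of the instrumental-variable
#' assumptions: `"none"` sets every direct effect to zero; `"balanced"`
#' draws direct effects with mean zero (InSIDE holds, no directional bias);
#' `"directional"` adds a common non-zero mean `alpha_mean`;
#' `"inside_violated"` makes the direct effects proportional to instrument
#' strength, breaking the InSIDE assumption MR-Egger relies on.
#'
#' @param theta true causal effect (log-odds per exposure unit).
#' @param n_snp number of instruments.
#' @param gamma true instrument effects on the exposure; default drawn
#'   uniformly on [0.015, 0.04] (comfortably genome-wide significant at the
#'   default sample size, per-variant F far above 10).
#' @param pleiotropy_mode one of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violated"`.
#' @param alpha_sd spread of the direct effects in the balanced/directional
#'   regimes (log-odds; default 0.002, comparable to the per-variant
#'   outcome sampling error so pleiotropy is material but not dominant).
#' @param alpha_mean mean direct effect in the directional regime.
#' @param alpha explicit direct-effect vector (overrides the regime draw).
#' @param n_exp,n_out exposure/outcome GWAS sample sizes.
#' @param maf minor-allele frequencies, recycled to `n_snp`; default drawn
#'   uniformly on [0.05, 0.5].
#' @param seed RNG seed; fixes gamma, maf, alpha and the dataset noise.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(theta = 0, n_snp = 50, gamma = NULL,
                      pleiotropy_mode = c("none", "balanced", "directional",
                                          "inside_violated"),
                      alpha_sd = 0.002, alpha_mean = 0.003, alpha = NULL,
                      n_exp = 450000, n_out = 300000, maf = NULL,
                      seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snp >= 1L, n_exp > 1, n_out > 1)
  par_seed <- seed
  drawn <- withr_seed(par_seed, {
    g <- if (is.null(gamma)) stats::runif(n_snp, 0.015, 0.04) else
      rep_len(gamma, n_snp)
    m <- if (is.null(maf)) stats::runif(n_snp, 0.05, 0.5) else
      rep_len(maf, n_snp)
    a <- if (!is.null(alpha)) rep_len(alpha, n_snp) else switch(
      pleiotropy_mode,
      none = rep(0, n_snp),
      balanced = stats::rnorm(n_snp, 0, alpha_sd),
      directional = stats::rnorm(n_snp, alpha_mean, alpha_sd),
      inside_violated = g * stats::rnorm(n_snp, 0.15, 0.05))
    list(g = g, m = m, a = a)
  })
  stopifnot(all(drawn$m > 0), all(drawn$m < 1))
  structure(list(theta = theta, n_snp = as.integer(n_snp),
                 gamma = drawn$g, alpha = drawn$a,
                 pleiotropy_mode = pleiotropy_mode,
                 outlier_ids = character(),
                 n_exp = n_exp, n_out = n_out, maf = drawn$m,
                 seed = seed),
            class = "sim_truth")
}

# Analytic standard error of a per-allele GWAS effect for a (standardized)
# trait: se = 1 / sqrt(2 N p (1 - p)).
.sim_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# Two-sided normal p, floored at the smallest positive double so that
# extreme associations stay inside the record model's (0, 1] range.
.two_sided_p <- function(beta, se)
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)

#' Simulate a paired exposure/outcome summary-statistics dataset
#'
#' Draws, for each variant j, an observed exposure effect
#' `beta_x_j ~ Normal(gamma_j, se_x_j)` and an observed outcome effect
#' `beta_y_j ~ Normal(theta * gamma_j + alpha_j, se_y_j)`, with analytic
#' standard errors `se = 1 / sqrt(2 N p (1 - p))` from the respective
#' sample sizes — the standard summary-statistics approximation in which a
#' binary outcome's log-odds effects are treated as Gaussian. P-values are
#' two-sided normal. Deterministic given `truth$seed`.
#'
#' @param truth a [sim_truth()].
#' @return list: `exposure` and `outcome` ([trait_dataset()] objects) and
#'   `truth`.
#' @export
simulate_pair <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  J <- truth$n_snp
  se_x <- .sim_se(truth$n_exp, truth$maf)
  se_y <- .sim_se(truth$n_out, truth$maf)
  dat <- withr_seed(truth$seed + 1L, {
    bx <- stats::rnorm(J, truth$gamma, se_x)
    by <- stats::rnorm(J, truth$theta * truth$gamma + truth$alpha, se_y)
    list(bx = bx, by = by)
  })
  mk <- function(beta, se, n, label, binary) {
    trait_dataset(data.frame(
      variant_id = sprintf("rs%05d", seq_len(J)),
      chrom = as.character(1L + (seq_len(J) - 1L) %% 22L),
      pos = 1e6 * seq_len(J),
      effect_allele = "A", other_allele = "G",
      eaf = truth$maf, beta = beta, se = se,
      pval = .two_sided_p(beta, se), n = n,
      stringsAsFactors = FALSE),
      trait = label, is_binary = binary)
  }
  list(exposure = mk(dat$bx, se_x, truth$n_exp, "sim_exposure", FALSE),
       outcome = mk(dat$by, se_y, truth$n_out, "sim_outcome", TRUE),
       truth = truth)
}

#' Simulate two exposures and one outcome for multivariable MR
#'
#' Two instrument blocks (sizes `n_snp_a`, `n_snp_b`, plus an optional
#' shared block) act on exposures A and B; A additionally acts on B with
#' cross-effect `cross_ab` (so A's instruments reach B at
#' `cross_ab * gamma_A`). Outcome effects are
#' `d1 * (effect on A) + d2 * (effect on B) + noise`. The mediation
#' scenario of interest sets `d1 = 0, cross_ab > 0, d2 > 0`: A then
#' associates with the outcome entirely through B, so univariable MR of A
#' finds an effect `d2 * cross_ab` while the multivariable direct effect of
#' A is zero.
#'
#' @param n_snp_a,n_snp_b instruments specific to A and to B.
#' @param d1,d2 direct effects of A and B on the outcome (log-odds).
#' @param cross_ab effect of A on B per unit of A.
#' @param overlap_frac fraction of A's instruments also given an
#'   independent effect on B (0 = disjoint blocks; 1 with identical gammas
#'   produces a deliberately collinear design).
#' @param identical_gammas give overlapping variants the same effect on A
#'   and B (collinearity stress case).
#' @param n_exp,n_out,maf,seed as [sim_truth()].
#' @return list: `exposure_a`, `exposure_b`, `outcome`
#'   ([trait_dataset()]s) and `truth` (list of generating parameters).
#' @export
simulate_mvmr <- function(n_snp_a = 25, n_snp_b = 25, d1 = 0, d2 = 0.3,
                          cross_ab = 0.5, overlap_frac = 0,
                          identical_gammas = FALSE,
                          n_exp = 450000, n_out = 300000, maf = NULL,
                          seed = 1L) {
  J <- n_snp_a + n_snp_b
  par <- withr_seed(seed, {
    list(gamma_a = stats::runif(n_snp_a, 0.015, 0.04),
         gamma_b = stats::runif(n_snp_b, 0.015, 0.04),
         maf = if (is.null(maf)) stats::runif(J, 0.05, 0.5) else
           rep_len(maf, J))
  })
  # True per-variant effects on each trait over the union of instruments.
  g_on_a <- c(par$gamma_a, rep(0, n_snp_b))
  g_on_b <- c(cross_ab * par$gamma_a, par$gamma_b)
  n_ovl <- round(overlap_frac * n_snp_a)
  if (n_ovl > 0) {
    idx <- seq_len(n_ovl)
    g_on_b[idx] <- if (identical_gammas) g_on_a[idx] else
      g_on_b[idx] + withr_seed(seed + 2L, stats::runif(n_ovl, 0.015, 0.04))
  }
  g_on_y <- d1 * g_on_a + d2 * g_on_b
  se_x <- .sim_se(n_exp, par$maf)
  se_y <- .sim_se(n_out, par$maf)
  dat <- withr_seed(seed + 1L, {
    list(ba = stats::rnorm(J, g_on_a, se_x),
         bb = stats::rnorm(J, g_on_b, se_x),
         by = stats::rnorm(J, g_on_y, se_y))
  })
  if (n_ovl > 0 && identical_gammas)
    # Collinearity stress case: overlapping variants report the very same
    # observed effect on both exposures.
    dat$bb[seq_len(n_ovl)] <- dat$ba[seq_len(n_ovl)]
  mk <- function(beta, se, n, label, binary = FALSE) {
    trait_dataset(data.frame(
      variant_id = sprintf("rs%05d", seq_len(J)),
      chrom = as.character(1L + (seq_len(J) - 1L) %% 22L),
      pos = 1e6 * seq_len(J),
      effect_allele = "A", other_allele = "G",
      eaf = par$maf, beta = beta, se = se,
      pval = .two_sided_p(beta, se), n = n,
      stringsAsFactors = FALSE),
      trait = label, is_binary = binary)
  }
  list(exposure_a = mk(dat$ba, se_x, n_exp, "sim_exposure_a"),
       exposure_b = mk(dat$bb, se_x, n_exp, "sim_exposure_b"),
       outcome = mk(dat$by, se_y, n_out, "sim_outcome", TRUE),
       truth = list(d1 = d1, d2 = d2, cross_ab = cross_ab,
                    gamma_on_a = g_on_a, gamma_on_b = g_on_b,
                    maf = par$maf, n_exp = n_exp, n_out = n_out,
                    seed = seed))
}

#' Inject pleiotropic outliers into a simulated outcome dataset
#'
#' Shifts the outcome effect of the listed variants by
#' `magnitude * se_y` — a controlled exclusion-restriction violation used
#' to exercise outlier detection.
#'
#' @param sim output of [simulate_pair()].
#' @param ids variant ids to perturb (must exist in the outcome dataset).
#' @param magnitude shift in units of each variant's outcome standard
#'   error.
#' @return `sim` with the outcome betas/p-values updated and
#'   `truth$outlier_ids` recording the perturbed variants.
#' @export
inject_outliers <- function(sim, ids, magnitude) {
  rec <- sim$outcome$records
  idx <- match(ids, rec$variant_id)
  if (anyNA(idx)) stop("unknown variant id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  rec$beta[idx] <- rec$beta[idx] + magnitude * rec$se[idx]
  rec$pval[idx] <- .two_sided_p(rec$beta[idx], rec$se[idx])
  sim$outcome$records <- rec
  sim$truth$outlier_ids <- union(sim$truth$outlier_ids, ids)
  sim
}

#' Harmonized view of a simulated pair
#'
#' The generator emits exposure and outcome effects already on a common
#' effect-allele frame, so simulation studies can skip string-level
#' harmonization and zip the two datasets directly into a
#' [harmonized_set()]. (Running [harmonize()] instead gives the identical
#' set; this is the fast path for replicate loops.)
#'
#' @param sim output of [simulate_pair()].
#' @return a `harmonized_set` of all simulated variants.
#' @export
sim_harmonized <- function(sim) {
  ex <- sim$exposure$records
  ou <- sim$outcome$records
  stopifnot(identical(ex$variant_id, ou$variant_id))
  harmonized_set(ex$beta, ex$se, ou$beta, ou$se,
                 variant_id = ex$variant_id,
                 exposure = sim$exposure$trait, outcome = sim$outcome$trait)
}
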