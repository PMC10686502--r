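#' Build an analysis configuration
#'
#' Collects everything one full analysis grid needs: exposure and outcome
#' summary-statistics files (or in-memory datasets), thresholds, methods,
#' multivariable adjustment pairs, simulation budgets and the master seed.
#'
#' @param exposures named list: label -> file path, or label ->
#'   `trait_dataset`.
#' @param outcomes named list, same convention.
#' @param ld an [ld_matrix()], a pair-list file path, or NULL.
#' @param p_select instrument significance threshold.
#' @param clump_r2,clump_kb clumping parameters.
#' @param alpha two-sided significance level for the result flags.
#' @param suggestive_band p-value band reported as suggestive (near-miss)
#'   evidence; default `[0.05, 0.10)`.
#' @param methods estimation methods for [mr_fit()].
#' @param ivw_mode `"multiplicative_random"` (default) or `"fixed"`.
#' @param mvmr_pairs list of `c(exposure, adjusted_for, outcome)` label
#'   triples for the multivariable follow-ups.
#' @param mvmr_snp_set `"union"` (jointly clumped union of both exposures'
#'   instruments, default) or `"primary"` (the first exposure's set only).
#' @param p_adjust multiplicity correction across the grid's primary
#'   p-values: `"none"` (default), `"bonferroni"` or `"fdr"`.
#' @param n_boot,n_sim bootstrap/simulation budgets.
#' @param seed master seed; every stochastic step derives its stream from
#'   it.
#' @param column_maps optional named list of per-file column maps for
#'   [read_summary_table()].
#' @return object of class `mr_config`.
#' @export
mr_config <- function(exposures, outcomes, ld = NULL, p_select = 5e-8,
                      clump_r2 = 0.001, clump_kb = 10000, alpha = 0.05,
                      suggestive_band = c(0.05, 0.10),
                      methods = c("ivw", "egger", "weighted_median"),
                      ivw_mode = "multiplicative_random",
                      mvmr_pairs = list(), mvmr_snp_set = "union",
                      p_adjust = "none",
                      n_boot = 1000, n_sim = 1000, seed = 1L,
                      column_maps = list()) {
  stopifnot(length(exposures) >= 1L, length(outcomes) >= 1L,
            !is.null(names(exposures)), !is.null(names(outcomes)),
            p_select > 0, p_select <= 1, clump_r2 >= 0, clump_r2 <= 1,
            clump_kb > 0, alpha > 0, alpha < 1)
  p_adjust <- match.arg(p_adjust, c("none", "bonferroni", "fdr"))
  mvmr_snp_set <- match.arg(mvmr_snp_set, c("union", "primary"))
  for (f in c(exposures, outcomes))
    if (is.character(f) && !file.exists(f)) stop("file not found: ", f)
  if (is.character(ld)) ld <- read_ld_pairs(ld)
  structure(list(exposures = exposures, outcomes = outcomes, ld = ld,
                 p_select = p_select, clump_r2 = clump_r2,
                 clump_kb = clump_kb, alpha = alpha,
                 suggestive_band = suggestive_band, methods = methods,
                 ivw_mode = ivw_mode, mvmr_pairs = mvmr_pairs,
                 mvmr_snp_set = mvmr_snp_set, p_adjust = p_adjust,
                 n_boot = n_boot, n_sim = n_sim, seed = as.integer(seed),
                 column_maps = column_maps),
            class = "mr_config")
}

#' Read an analysis configuration from a YAML file
#'
#' The YAML mirrors the arguments of [mr_config()]; `exposures` and
#' `outcomes` are label-to-path maps, `mvmr_pairs` a list of
#' `[exposure, adjusted_for, outcome]` triples.
#'
#' @param path YAML file path.
#' @return an `mr_config`.
#' @export
read_mr_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(mr_config)))]
  if (!is.null(args$mvmr_pairs))
    args$mvmr_pairs <- lapply(args$mvmr_pairs, unlist)
  do.call(mr_config, args)
}

.load_trait <- function(x, label, config, is_binary = FALSE) {
  if (inherits(x, "trait_dataset")) {
    x$trait <- label  # result rows carry the config's labels
    return(x)
  }
  read_summary_table(x, column_map = config$column_maps[[label]],
                     trait = label, is_binary = is_binary)
}

# A stable small seed derived from the master seed and a pair label.
# Double arithmetic keeps the product exact and below 2^31 after reduction.
.derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 1000003 +
                sum(utf8ToInt(label)) * 7919) %% 2147483629)
}

#' Run the univariable analysis grid
#'
#' For every exposure-outcome pair: select significant instruments, clump,
#' harmonize, discard outcome-associated instruments, estimate (IVW
#' primary plus the configured complements), and run the sensitivity
#' workflow — with the outlier procedure triggered by a significant Egger
#' intercept and a single re-estimation when outliers are found. A failing
#' pair is logged and skipped, never fatal. Deterministic given the
#' config's seed.
#'
#' @param config an [mr_config()].
#' @return object of class `mr_study`: list with `results` (data.frame,
#'   one row per exposure x outcome x method, with sensitivity columns,
#'   significance and suggestive flags), `audits` (per-pair harmonization
#'   audits), `log` (character), and `config`.
#' @export
run_univariable_grid <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  rows <- list()
  audits <- list()
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))
  for (ex_label in names(config$exposures)) {
    exposure <- .load_trait(config$exposures[[ex_label]], ex_label, config)
    iv <- suppressWarnings(select_significant(exposure, config$p_select))
    if (n_variants(iv) == 0L) {
      say("SKIP ", ex_label, ": no genome-wide-significant instrument")
      next
    }
    iv <- suppressWarnings(ld_clump(iv, config$ld, config$clump_r2,
                                    config$clump_kb))
    for (out_label in names(config$outcomes)) {
      pair_label <- paste(ex_label, out_label, sep = " -> ")
      res <- tryCatch({
        outcome <- .load_trait(config$outcomes[[out_label]], out_label,
                               config, is_binary = TRUE)
        hset <- harmonize(iv, outcome)
        op <- stats::setNames(outcome$records$pval,
                              outcome$records$variant_id)
        hset <- drop_outcome_associated(hset, op, config$p_select)
        audits[[pair_label]] <- hset$audit
        pairs <- retained_pairs(hset)
        if (nrow(pairs) == 0L) stop("no instruments survive harmonization")
        pair_seed <- .derive_seed(config$seed, pair_label)
        fit <- mr_fit(hset, methods = config$methods,
                      ivw_mode = config$ivw_mode,
                      n_boot = config$n_boot, seed = pair_seed)
        sens <- mr_sensitivity(hset, alpha = config$alpha,
                               n_sim = config$n_sim,
                               seed = pair_seed + 1L)
        tab <- summary(fit)
        tab$q_stat <- sens$q_stat
        tab$q_pval <- sens$q_pval
        tab$egger_intercept <- sens$egger_intercept
        tab$egger_intercept_pval <- sens$egger_intercept_pval
        tab$presso_global_pval <- sens$presso_global_pval
        tab$n_outliers <- length(sens$presso_outliers)
        tab$presso_distortion_pval <- sens$presso_distortion_pval
        if (!is.null(sens$estimate_after_removal)) {
          e2 <- sens$estimate_after_removal
          tab$theta_after_outlier_removal <- e2$theta
          tab$pval_after_outlier_removal <- e2$pval
          say("OUTLIERS ", pair_label, ": ",
              paste(sens$presso_outliers, collapse = ","),
              "; IVW re-estimated")
        } else {
          tab$theta_after_outlier_removal <- NA_real_
          tab$pval_after_outlier_removal <- NA_real_
        }
        for (nm in names(fit$skipped))
          say("NOTE ", pair_label, " [", nm, "]: ", fit$skipped[[nm]])
        tab
      }, error = function(e) {
        say("FAIL ", pair_label, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[pair_label]] <- res
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(results) <- NULL
  if (nrow(results)) {
    padj <- switch(config$p_adjust,
                   none = results$pval,
                   bonferroni = stats::p.adjust(results$pval, "bonferroni"),
                   fdr = stats::p.adjust(results$pval, "fdr"))
    results$significant <- padj < config$alpha
    results$suggestive <- !results$significant &
      padj >= config$suggestive_band[1] & padj < config$suggestive_band[2]
  }
  structure(list(results = results, audits = audits, log = log,
                 config = config),
            class = "mr_study")
}

#' @export
print.mr_study <- function(x, ...) {
  cat("MR study grid: ", length(x$config$exposures), " exposure(s) x ",
      length(x$config$outcomes), " outcome(s); ", nrow(x$results),
      " result rows\n", sep = "")
  if (nrow(x$results)) {
    sig <- x$results[x$results$significant & !is.na(x$results$significant), ]
    cat("  significant rows: ", nrow(sig), "\n", sep = "")
  }
  invisible(x)
}

#' Run multivariable MR follow-ups
#'
#' For each configured `(exposure, adjusted_for, outcome)` triple, builds
#' the joint instrument set ([mvmr_instrument_union()] or the primary
#' exposure's set, per config), harmonizes all three traits onto one frame
#' and fits [mvmr_ivw()], reporting the primary exposure's direct effect
#' with an `adjusted_for` column.
#'
#' @param config an [mr_config()] with non-empty `mvmr_pairs`.
#' @param univariable optionally, the univariable [run_univariable_grid()]
#'   result; when supplied, triples whose exposure-outcome IVW row is
#'   absent are still run, but a note is logged.
#' @return data.frame in the analysis-table schema plus `adjusted_for`
#'   (empty with no configured pairs).
#' @export
run_mvmr_followups <- function(config, univariable = NULL) {
  stopifnot(inherits(config, "mr_config"))
  out <- list()
  for (trip in config$mvmr_pairs) {
    stopifnot(length(trip) == 3L)
    ex1 <- .load_trait(config$exposures[[trip[1]]], trip[1], config)
    ex2 <- .load_trait(config$exposures[[trip[2]]], trip[2], config)
    outcome <- .load_trait(config$outcomes[[trip[3]]], trip[3], config,
                           is_binary = TRUE)
    ivset <- if (config$mvmr_snp_set == "union")
      mvmr_instrument_union(list(ex1, ex2), config$ld, config$p_select,
                            config$clump_r2, config$clump_kb)
    else suppressWarnings(ld_clump(select_significant(ex1, config$p_select),
                                   config$ld, config$clump_r2,
                                   config$clump_kb))
    keep <- function(ds) .subset_dataset(
      ds, ds$records$variant_id %in% ivset$records$variant_id)
    tab <- harmonize_multi(list(keep(ex1), keep(ex2)), keep(outcome))
    fit <- mvmr_ivw(tab, exposures = c(trip[1], trip[2]))
    row <- fit[fit$exposure == trip[1], , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      exposure = trip[1], adjusted_for = trip[2], outcome = trip[3],
      method = "mvmr_ivw", n_snp = attr(fit, "n_snp"),
      theta = row$theta, se = row$se, pval = row$pval, or = row$or,
      ci_low = row$ci_low, ci_high = row$ci_high,
      significant = row$pval < config$alpha, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame()
  rownames(res) <- NULL
  res
}

#' Write the result tables of a study to a directory
#'
#' Emits the analysis table (`univariable.tsv`), optional multivariable
#' table (`mvmr.tsv`), per-pair harmonization audits
#' (`harmonization_audit.tsv`) and the run log (`run.log`).
#'
#' @param study an `mr_study` from [run_univariable_grid()].
#' @param dir output directory (created if needed).
#' @param mvmr optional data.frame from [run_mvmr_followups()].
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, mvmr = NULL) {
  stopifnot(inherits(study, "mr_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(study$results, file.path(dir, "univariable.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(mvmr) && nrow(mvmr))
    utils::write.table(mvmr, file.path(dir, "mvmr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (length(study$audits)) {
    aud <- do.call(rbind, lapply(names(study$audits), function(nm)
      data.frame(pair = nm, t(study$audits[[nm]]),
                 stringsAsFactors = FALSE)))
    utils::write.table(aud, file.path(dir, "harmonization_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(study$log, file.path(dir, "run.log"))
  invisible(dir)
}
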