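.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.complement_allele <- function(a) {
  paste(rev(.COMPLEMENT[strsplit(a, "")[[1]]]), collapse = "")
}

.is_palindromic <- function(a1, a2) {
  nchar(a1) == 1L && nchar(a2) == 1L && .COMPLEMENT[a1] == a2
}

#' Harmonize one exposure/outcome record pair onto a common effect allele
#'
#' Places the outcome effect on the exposure's effect-allele frame:
#' matching alleles are kept as-is (`aligned`); swapped alleles negate the
#' outcome beta and complement its frequency (`flipped`); strand
#' complementing is attempted only when direct and swapped matching both
#' fail. Palindromic variants (A/T, C/G) carry no strand information in
#' their alleles, so they are resolved by allele-frequency concordance when
#' both frequencies are informative, and dropped (`dropped_palindromic`)
#' when either frequency is missing or falls in the ambiguous window
#' `(palindrome_eaf_window, 1 - palindrome_eaf_window)`. Allele sets that
#' cannot be reconciled give `dropped_incompatible`.
#'
#' @param exp_rec,out_rec single-row data.frames (or lists) with fields
#'   `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`.
#' @param palindrome_eaf_window lower edge of the ambiguous frequency
#'   window; default 0.42 (ambiguous when the frequency is in (0.42, 0.58)).
#' @return one-row data.frame: `variant_id`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`, `eaf_x`, `eaf_y`, `status`.
#' @export
harmonize_pair <- function(exp_rec, out_rec, palindrome_eaf_window = 0.42) {
  if (exp_rec$variant_id != out_rec$variant_id)
    stop("records refer to different variants")
  ex_ea <- exp_rec$effect_allele; ex_oa <- exp_rec$other_allele
  ou_ea <- out_rec$effect_allele; ou_oa <- out_rec$other_allele
  beta_y <- out_rec$beta; eaf_y <- out_rec$eaf

  res <- function(status, by = beta_y, ey = eaf_y)
    data.frame(variant_id = exp_rec$variant_id,
               beta_x = exp_rec$beta, se_x = exp_rec$se,
               beta_y = by, se_y = out_rec$se,
               eaf_x = exp_rec$eaf, eaf_y = ey,
               status = status, stringsAsFactors = FALSE)

  if (.is_palindromic(ex_ea, ex_oa)) {
    # Strand is unknowable from alleles; use frequency concordance.
    if (!(ou_ea == ex_ea && ou_oa == ex_oa) &&
        !(ou_ea == ex_oa && ou_oa == ex_ea))
      return(res("dropped_incompatible"))
    if (ou_ea == ex_oa) { beta_y <- -beta_y; eaf_y <- 1 - eaf_y }
    w <- palindrome_eaf_window
    ambiguous <- function(f) is.na(f) || (f > w && f < 1 - w)
    if (ambiguous(exp_rec$eaf) || ambiguous(eaf_y))
      return(res("dropped_palindromic", by = beta_y, ey = eaf_y))
    if ((exp_rec$eaf < 0.5) != (eaf_y < 0.5)) {
      # Outcome reported on the opposite strand: flip to the exposure frame.
      beta_y <- -beta_y; eaf_y <- 1 - eaf_y
      return(res("flipped", by = beta_y, ey = eaf_y))
    }
    return(res("aligned", by = beta_y, ey = eaf_y))
  }

  if (ou_ea == ex_ea && ou_oa == ex_oa) return(res("aligned"))
  if (ou_ea == ex_oa && ou_oa == ex_ea)
    return(res("flipped", by = -beta_y,
               ey = if (is.na(eaf_y)) NA_real_ else 1 - eaf_y))
  # Last resort: the outcome GWAS may report the opposite strand.
  ou_ea_c <- .complement_allele(ou_ea); ou_oa_c <- .complement_allele(ou_oa)
  if (ou_ea_c == ex_ea && ou_oa_c == ex_oa) return(res("aligned"))
  if (ou_ea_c == ex_oa && ou_oa_c == ex_ea)
    return(res("flipped", by = -beta_y,
               ey = if (is.na(eaf_y)) NA_real_ else 1 - eaf_y))
  res("dropped_incompatible")
}

#' Harmonize an exposure dataset with an outcome dataset
#'
#' Matches variants by id, harmonizes each pair with [harmonize_pair()],
#' and returns the analysis-ready set together with an audit of what
#' happened to every matched variant. Instruments absent from the outcome
#' GWAS are dropped and counted (`missing_outcome`); no proxy lookup is
#' attempted.
#'
#' @param exposure,outcome [trait_dataset()] objects.
#' @inheritParams harmonize_pair
#' @return object of class `harmonized_set`: list with `exposure`,
#'   `outcome` (labels), `pairs` (data.frame of retained and dropped pairs
#'   with their `status`), and `audit` (named counts by status, including
#'   `missing_outcome`).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.42) {
  stopifnot(inherits(exposure, "trait_dataset"),
            inherits(outcome, "trait_dataset"))
  ex <- exposure$records
  ou <- outcome$records
  common <- intersect(ex$variant_id, ou$variant_id)
  n_missing <- nrow(ex) - length(common)
  rows <- lapply(common, function(v)
    harmonize_pair(ex[ex$variant_id == v, ], ou[ou$variant_id == v, ],
                   palindrome_eaf_window))
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), beta_x = numeric(),
               se_x = numeric(), beta_y = numeric(), se_y = numeric(),
               eaf_x = numeric(), eaf_y = numeric(), status = character(),
               stringsAsFactors = FALSE)
  audit <- c(table(factor(pairs$status,
                          levels = c("aligned", "flipped",
                                     "dropped_palindromic",
                                     "dropped_incompatible",
                                     "dropped_outcome_associated"))))
  audit <- c(audit, missing_outcome = n_missing)
  structure(list(exposure = exposure$trait, outcome = outcome$trait,
                 pairs = pairs, audit = audit),
            class = "harmonized_set")
}

#' Build a harmonized set directly from effect vectors
#'
#' Convenience constructor for analysis and simulation code that already
#' holds frame-consistent effects.
#'
#' @param beta_x,se_x exposure effects and standard errors.
#' @param beta_y,se_y outcome effects and standard errors on the same
#'   effect-allele frame.
#' @param variant_id variant ids (generated when omitted).
#' @param exposure,outcome trait labels.
#' @return a `harmonized_set` with all pairs `aligned`.
#' @export
harmonized_set <- function(beta_x, se_x, beta_y, se_y,
                           variant_id = paste0("snp", seq_along(beta_x)),
                           exposure = "exposure", outcome = "outcome") {
  stopifnot(length(beta_x) == length(se_x),
            length(beta_x) == length(beta_y),
            length(beta_x) == length(se_y),
            all(se_x > 0), all(se_y > 0))
  pairs <- data.frame(variant_id = as.character(variant_id),
                      beta_x = beta_x, se_x = se_x,
                      beta_y = beta_y, se_y = se_y,
                      eaf_x = NA_real_, eaf_y = NA_real_,
                      status = "aligned", stringsAsFactors = FALSE)
  audit <- c(aligned = nrow(pairs), flipped = 0L, dropped_palindromic = 0L,
             dropped_incompatible = 0L, dropped_outcome_associated = 0L,
             missing_outcome = 0L)
  structure(list(exposure = exposure, outcome = outcome, pairs = pairs,
                 audit = audit),
            class = "harmonized_set")
}

#' Retained exposure/outcome pairs of a harmonized set
#' @param hset a `harmonized_set`.
#' @return data.frame of pairs with status `aligned` or `flipped`.
#' @export
retained_pairs <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  p <- hset$pairs[hset$pairs$status %in% c("aligned", "flipped"), ,
                  drop = FALSE]
  rownames(p) <- NULL
  p
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set: ", x$exposure, " -> ", x$outcome, "\n", sep = "")
  cat("  retained: ", sum(x$pairs$status %in% c("aligned", "flipped")),
      " of ", nrow(x$pairs) + x$audit[["missing_outcome"]],
      " matched instruments\n", sep = "")
  nz <- x$audit[x$audit > 0]
  if (length(nz))
    cat("  audit: ", paste(names(nz), nz, sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Discard instruments associated with the outcome
#'
#' Instruments whose outcome-GWAS p-value reaches genome-wide significance
#' plausibly act on the outcome directly, violating the exclusion
#' restriction; they are flagged `dropped_outcome_associated`.
#'
#' @param hset a `harmonized_set`.
#' @param outcome_pvals named numeric vector of outcome p-values keyed by
#'   variant id, covering every retained pair.
#' @param p_threshold exclusion threshold (default 5e-8, strict inequality).
#' @return the `harmonized_set` with statuses and audit updated.
#' @export
drop_outcome_associated <- function(hset, outcome_pvals, p_threshold = 5e-8) {
  stopifnot(inherits(hset, "harmonized_set"))
  retained <- hset$pairs$status %in% c("aligned", "flipped")
  ids <- hset$pairs$variant_id[retained]
  if (!all(ids %in% names(outcome_pvals)))
    stop("outcome p-values missing for some retained pairs")
  drop <- retained & hset$pairs$variant_id %in%
    names(outcome_pvals)[outcome_pvals < p_threshold]
  hset$pairs$status[drop] <- "dropped_outcome_associated"
  hset$audit[["dropped_outcome_associated"]] <-
    hset$audit[["dropped_outcome_associated"]] + sum(drop)
  hset$audit[["aligned"]] <- sum(hset$pairs$status == "aligned")
  hset$audit[["flipped"]] <- sum(hset$pairs$status == "flipped")
  hset
}

#' Harmonize several exposures and one outcome onto a single frame
#'
#' Builds the design table multivariable MR consumes: one row per variant
#' with frame-consistent effects for every exposure and the outcome. Each
#' trait is harmonized pairwise to the first exposure's effect-allele frame;
#' variants missing from any trait, or failing any pairwise harmonization,
#' are dropped.
#'
#' @param exposures list of two or more [trait_dataset()] objects.
#' @param outcome a [trait_dataset()].
#' @inheritParams harmonize_pair
#' @return data.frame with columns `variant_id`, `beta_x1`, `se_x1`, ...,
#'   `beta_y`, `se_y`; attribute `exposures` holds the labels.
#' @export
harmonize_multi <- function(exposures, outcome, palindrome_eaf_window = 0.42) {
  if (!is.list(exposures) || length(exposures) < 2L)
    stop("at least two exposures required")
  ref <- exposures[[1L]]$records
  ids <- ref$variant_id
  for (ds in exposures[-1L]) ids <- intersect(ids, ds$records$variant_id)
  ids <- intersect(ids, outcome$records$variant_id)

  harmonize_to_ref <- function(ds, v) {
    harmonize_pair(ref[ref$variant_id == v, ],
                   ds$records[ds$records$variant_id == v, ],
                   palindrome_eaf_window)
  }
  rows <- lapply(ids, function(v) {
    out <- list(variant_id = v,
                beta_x1 = ref$beta[ref$variant_id == v],
                se_x1 = ref$se[ref$variant_id == v])
    for (j in seq_along(exposures)[-1L]) {
      h <- harmonize_to_ref(exposures[[j]], v)
      if (!h$status %in% c("aligned", "flipped")) return(NULL)
      out[[paste0("beta_x", j)]] <- h$beta_y
      out[[paste0("se_x", j)]] <- h$se_y
    }
    h <- harmonize_to_ref(outcome, v)
    if (!h$status %in% c("aligned", "flipped")) return(NULL)
    out$beta_y <- h$beta_y
    out$se_y <- h$se_y
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    tab <- data.frame(variant_id = character(), stringsAsFactors = FALSE)
  } else tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "exposures") <- vapply(exposures, function(d) d$trait, "")
  tab
}
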