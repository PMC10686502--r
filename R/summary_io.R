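#' @keywords internal
"_PACKAGE"

# Canonical column layout shared by every table this package reads or writes.
.SUMMARY_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")
.MANDATORY_COLS <- c("variant_id", "effect_allele", "other_allele",
                     "beta", "se", "pval")

#' Construct a GWAS summary-statistics dataset
#'
#' A `trait_dataset` bundles one trait's per-variant association statistics
#' (effect allele, other allele, effect-allele frequency, beta, standard
#' error, p-value, sample size) with a trait label. Betas are on the scale of
#' the source GWAS: log-odds for binary traits, trait units otherwise.
#'
#' Rows violating the record invariants (non-positive SE, p-value outside
#' (0, 1], allele strings not over A/C/G/T, effect allele equal to other
#' allele, frequency outside [0, 1], duplicated variant id) are dropped with
#' a message giving the count. Allele strings are upper-cased on ingest;
#' alleles longer than one base (indels) are kept but flagged in the
#' validation report, since downstream harmonization assumes SNPs.
#'
#' @param records data.frame with (at least) columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`; optionally
#'   `chrom`, `pos`, `eaf`, `n`. Missing optional columns are filled with NA.
#' @param trait trait label.
#' @param accession source accession string (e.g. an IEU OpenGWAS id), or "".
#' @param is_binary logical; TRUE when betas are log-odds.
#' @param drop_invalid drop rows failing the invariants (default TRUE);
#'   if FALSE, offending rows cause an error.
#' @return object of class `trait_dataset`: a list with elements `trait`,
#'   `accession`, `is_binary` and `records` (a data.frame in canonical
#'   column order).
#' @export
trait_dataset <- function(records, trait = "trait", accession = "",
                          is_binary = FALSE, drop_invalid = TRUE) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.MANDATORY_COLS, names(records))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (col in setdiff(.SUMMARY_COLS, names(records))) records[[col]] <- NA
  records <- records[, .SUMMARY_COLS]

  records$variant_id    <- as.character(records$variant_id)
  records$chrom         <- as.character(records$chrom)
  records$pos           <- suppressWarnings(as.numeric(records$pos))
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele  <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))

  bad <- .invalid_record_mask(records)
  if (any(bad)) {
    if (!drop_invalid)
      stop(sum(bad), " record(s) violate summary-statistic invariants")
    message("trait_dataset: dropped ", sum(bad), " invalid record(s) for '",
            trait, "'")
    records <- records[!bad, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(list(trait = trait, accession = accession,
                 is_binary = isTRUE(is_binary), records = records,
                 n_dropped = sum(bad)),
            class = "trait_dataset")
}

# Per-row invariant violations (uniqueness handled at dataset level).
.invalid_record_mask <- function(records) {
  allele_ok <- function(a) !is.na(a) & grepl("^[ACGT]+$", a)
  bad <- is.na(records$variant_id) | records$variant_id == "" |
    !allele_ok(records$effect_allele) | !allele_ok(records$other_allele) |
    records$effect_allele == records$other_allele |
    is.na(records$beta) |
    is.na(records$se) | records$se <= 0 |
    is.na(records$pval) | records$pval <= 0 | records$pval > 1 |
    (!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1)) |
    (!is.na(records$pos) & records$pos < 1)
  bad | duplicated(records$variant_id)
}

#' @export
print.trait_dataset <- function(x, ...) {
  cat("GWAS summary dataset: ", x$trait,
      if (nzchar(x$accession)) paste0(" [", x$accession, "]"), "\n", sep = "")
  cat("  ", nrow(x$records), " variants; scale: ",
      if (x$is_binary) "log-odds" else "trait units", "\n", sep = "")
  invisible(x)
}

#' Number of variants in a dataset
#' @param ds a `trait_dataset`.
#' @return integer count of records.
#' @export
n_variants <- function(ds) nrow(ds$records)

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited table with a header row into a
#' [trait_dataset()]. Non-canonical headers are renamed through `column_map`.
#' `"NA"`, `""` and `"."` are read as missing. Rows violating the record
#' invariants are dropped and counted (reported via a message).
#'
#' @param path file path.
#' @param column_map named character vector mapping file headers to canonical
#'   field names, e.g. `c(SNP = "variant_id", A1 = "effect_allele")`. Columns
#'   already canonically named need no entry.
#' @inheritParams trait_dataset
#' @return a `trait_dataset`.
#' @export
read_summary_table <- function(path, column_map = NULL, trait = NULL,
                               accession = "", is_binary = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", "", "."),
                           comment.char = "", quote = "\"",
                           check.names = FALSE)
  if (nrow(tab) == 0L) stop("no data rows in: ", path)
  if (!is.null(column_map)) {
    hit <- names(tab) %in% names(column_map)
    names(tab)[hit] <- unname(column_map[names(tab)[hit]])
  }
  missing_cols <- setdiff(.MANDATORY_COLS, names(tab))
  if (length(missing_cols) > 0L)
    stop("unmapped mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(trait)) trait <- sub("\\.[^.]*$", "", basename(path))
  trait_dataset(tab, trait = trait, accession = accession,
                is_binary = is_binary)
}

#' Write a dataset as a canonical tab-delimited summary table
#'
#' Output uses the fixed canonical header
#' `variant_id chrom pos effect_allele other_allele eaf beta se pval n`,
#' missing values encoded as `NA`, full numeric precision (up to 17
#' significant digits), so that [read_summary_table()] inverts it exactly.
#'
#' @param ds a `trait_dataset` with at least one record.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(ds, path) {
  stopifnot(inherits(ds, "trait_dataset"))
  if (nrow(ds$records) == 0L) stop("refusing to write an empty dataset")
  rec <- ds$records
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- vapply(x, function(v)
        if (is.na(v)) "NA" else format(v, digits = 17, scientific = NA,
                                       trim = TRUE), "")
      out
    } else ifelse(is.na(x), "NA", as.character(x))
  }
  out <- vapply(rec, fmt, character(nrow(rec)))
  if (nrow(rec) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(NULL, names(rec)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(.SUMMARY_COLS, collapse = "\t"), con)
  writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Validate a dataset against the summary-record invariants
#'
#' Checks every rule the record model imposes and returns per-rule violation
#' counts. A dataset built by [trait_dataset()] with `drop_invalid = TRUE`
#' always reports zero violations except possibly `indel_allele`, which is a
#' flag rather than an error (alleles longer than one base are legal but
#' unusual for instruments).
#'
#' @param ds a `trait_dataset`.
#' @return object of class `mr_validation`: named integer vector of violation
#'   counts with attribute `n_records`.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "trait_dataset"))
  r <- ds$records
  allele_ok <- function(a) !is.na(a) & grepl("^[ACGT]+$", a)
  counts <- c(
    missing_id        = sum(is.na(r$variant_id) | r$variant_id == ""),
    duplicate_id      = sum(duplicated(r$variant_id)),
    bad_allele        = sum(!allele_ok(r$effect_allele) |
                              !allele_ok(r$other_allele)),
    same_alleles      = sum(!is.na(r$effect_allele) & !is.na(r$other_allele) &
                              r$effect_allele == r$other_allele),
    nonpositive_se    = sum(is.na(r$se) | r$se <= 0),
    pval_out_of_range = sum(is.na(r$pval) | r$pval <= 0 | r$pval > 1),
    eaf_out_of_range  = sum(!is.na(r$eaf) & (r$eaf < 0 | r$eaf > 1)),
    bad_position      = sum(!is.na(r$pos) & r$pos < 1),
    missing_beta      = sum(is.na(r$beta)),
    indel_allele      = sum(nchar(r$effect_allele) > 1L |
                              nchar(r$other_allele) > 1L, na.rm = TRUE)
  )
  structure(counts, n_records = nrow(r), class = c("mr_validation", class(counts)))
}

#' @export
print.mr_validation <- function(x, ...) {
  cat("Validation of", attr(x, "n_records"), "records\n")
  hard <- x[names(x) != "indel_allele"]
  if (sum(hard) == 0L) cat("  no invariant violations\n")
  for (nm in names(x)[x > 0L]) cat("  ", nm, ": ", x[[nm]], "\n", sep = "")
  invisible(x)
}

#' Total hard violations in a validation report
#' @param report an `mr_validation` object.
#' @return integer; indel flags are informational and excluded.
#' @export
n_violations <- function(report) {
  sum(report[names(report) != "indel_allele"])
}

# Subset a trait_dataset by a logical/integer index on records.
.subset_dataset <- function(ds, idx) {
  ds$records <- ds$records[idx, , drop = FALSE]
  rownames(ds$records) <- NULL
  ds
}
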