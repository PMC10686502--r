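rec <- function(id = "rs1", ea = "A", oa = "G", eaf = 0.2, beta = 0.1,
                se = 0.01, pval = 1e-9) {
  data.frame(variant_id = id, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, pval = pval,
             stringsAsFactors = FALSE)
}

test_that("swapped outcome alleles flip the outcome beta and frequency", {
  h <- harmonize_pair(rec(ea = "A", oa = "G", beta = 0.10),
                      rec(ea = "G", oa = "A", beta = -0.05, eaf = 0.8))
  expect_equal(h$status, "flipped")
  expect_equal(h$beta_y, 0.05)
  expect_equal(h$eaf_y, 0.2)
  expect_equal(h$beta_x, 0.10)
})

test_that("matching alleles pass through unchanged", {
  h <- harmonize_pair(rec(), rec(beta = -0.05))
  expect_equal(h$status, "aligned")
  expect_equal(h$beta_y, -0.05)
})

test_that("ambiguous palindromic variants are dropped", {
  h <- harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.50),
                      rec(ea = "A", oa = "T", eaf = 0.50))
  expect_equal(h$status, "dropped_palindromic")
  h2 <- harmonize_pair(rec(ea = "C", oa = "G", eaf = NA),
                       rec(ea = "C", oa = "G", eaf = 0.1))
  expect_equal(h2$status, "dropped_palindromic")
})

test_that("informative palindromic variants are resolved by frequency", {
  # concordant frequencies: same strand, keep as-is
  h <- harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.1, beta = 0.1),
                      rec(ea = "A", oa = "T", eaf = 0.15, beta = 0.05))
  expect_equal(h$status, "aligned")
  expect_equal(h$beta_y, 0.05)
  # discordant frequencies: outcome reported on the other strand
  h2 <- harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.1, beta = 0.1),
                       rec(ea = "A", oa = "T", eaf = 0.85, beta = 0.05))
  expect_equal(h2$status, "flipped")
  expect_equal(h2$beta_y, -0.05)
  expect_equal(h2$eaf_y, 0.15)
})

test_that("irreconcilable allele sets are dropped", {
  h <- harmonize_pair(rec(ea = "A", oa = "G"), rec(ea = "A", oa = "C"))
  expect_equal(h$status, "dropped_incompatible")
})

test_that("strand complements are tried only after direct matching fails", {
  # outcome on the opposite strand: A/G vs T/C
  h <- harmonize_pair(rec(ea = "A", oa = "G", beta = 0.1),
                      rec(ea = "T", oa = "C", beta = 0.05))
  expect_equal(h$status, "aligned")
  expect_equal(h$beta_y, 0.05)
  # opposite strand and swapped: A/G vs C/T
  h2 <- harmonize_pair(rec(ea = "A", oa = "G", beta = 0.1),
                       rec(ea = "C", oa = "T", beta = 0.05, eaf = 0.8))
  expect_equal(h2$status, "flipped")
  expect_equal(h2$beta_y, -0.05)
})

test_that("harmonization is idempotent and sign-consistent", {
  out <- rec(ea = "G", oa = "A", beta = -0.05, eaf = 0.8)
  h1 <- harmonize_pair(rec(), out)
  # re-harmonize the already-aligned pair: nothing changes
  out_aligned <- rec(ea = "A", oa = "G", beta = h1$beta_y, eaf = h1$eaf_y)
  h2 <- harmonize_pair(rec(), out_aligned)
  expect_equal(h2$beta_y, h1$beta_y)
  expect_equal(h2$status, "aligned")
  # flipping both alleles and the beta sign of the outcome yields the
  # identical retained pair
  out_flipped <- rec(ea = "A", oa = "G", beta = 0.05, eaf = 0.2)
  h3 <- harmonize_pair(rec(), out_flipped)
  expect_equal(h3$beta_y, h1$beta_y)
  expect_equal(h3$eaf_y, h1$eaf_y)
})

test_that("set-level harmonization audits every matched variant", {
  ex <- trait_dataset(data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    chrom = "1", pos = 1:5 * 1e6,
    effect_allele = c("A", "A", "A", "C", "A"),
    other_allele = c("G", "G", "T", "G", "G"),
    eaf = c(0.2, 0.2, 0.5, 0.3, 0.2), beta = 0.1, se = 0.01,
    pval = 1e-9, n = 1e5, stringsAsFactors = FALSE), trait = "exp")
  ou <- trait_dataset(data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "1", pos = 1:4 * 1e6,
    effect_allele = c("A", "G", "A", "A"),
    other_allele = c("G", "A", "T", "C"),
    eaf = c(0.2, 0.8, 0.5, 0.3), beta = c(0.05, -0.05, 0.02, 0.01),
    se = 0.01, pval = 0.5, n = 1e5, stringsAsFactors = FALSE),
    trait = "out")
  h <- harmonize(ex, ou)
  expect_equal(unname(h$audit[["aligned"]]), 1L)
  expect_equal(unname(h$audit[["flipped"]]), 1L)
  expect_equal(unname(h$audit[["dropped_palindromic"]]), 1L)
  expect_equal(unname(h$audit[["dropped_incompatible"]]), 1L)
  expect_equal(unname(h$audit[["missing_outcome"]]), 1L)
  # audit counts sum to the number of exposure instruments
  expect_equal(sum(h$audit), n_variants(ex))
  expect_equal(nrow(retained_pairs(h)), 2L)
})

test_that("outcome-associated instruments are discarded", {
  h <- harmonized_set(rep(0.1, 10), rep(0.01, 10),
                      rnorm(10, 0, 0.01), rep(0.01, 10))
  pv <- setNames(c(1e-9, 0.5, rep(0.3, 7), 4.9e-8), h$pairs$variant_id)
  h2 <- drop_outcome_associated(h, pv)
  expect_equal(sum(h2$pairs$status == "dropped_outcome_associated"), 2L)
  expect_equal(nrow(retained_pairs(h2)), 8L)
  expect_equal(unname(h2$audit[["dropped_outcome_associated"]]), 2L)
  # p exactly at threshold is retained (strict inequality)
  h3 <- drop_outcome_associated(h, setNames(rep(5e-8, 10),
                                            h$pairs$variant_id))
  expect_equal(nrow(retained_pairs(h3)), 10L)
  expect_error(drop_outcome_associated(h, pv[1:3]), "missing")
})

test_that("multi-exposure harmonization equals row-wise pairwise calls", {
  set.seed(5)
  base <- make_records(6, beta = runif(6, 0.02, 0.05))
  mk <- function(beta, ea = NULL, oa = NULL, eaf = NULL, drop = NULL) {
    df <- base
    if (!is.null(drop)) df <- df[-drop, ]
    df$beta <- beta
    if (!is.null(ea)) df$effect_allele <- ea
    if (!is.null(oa)) df$other_allele <- oa
    if (!is.null(eaf)) df$eaf <- eaf
    trait_dataset(df)
  }
  ex1 <- mk(runif(6, 0.02, 0.05))
  # second exposure with swapped alleles: must be flipped onto ex1's frame
  ex2 <- mk(runif(6, -0.05, 0.05), ea = "G", oa = "A",
            eaf = 1 - base$eaf)
  ou <- mk(runif(6, -0.02, 0.02))
  tab <- harmonize_multi(list(ex1, ex2), ou)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$beta_x2, -ex2$records$beta)  # flipped sign
  expect_equal(tab$beta_y, ou$records$beta)
  # a variant missing from one exposure drops its row
  tab2 <- harmonize_multi(list(ex1, mk(runif(5, 0.01, 0.02), drop = 3)), ou)
  expect_equal(nrow(tab2), 5L)
  expect_false("rs003" %in% tab2$variant_id)
  expect_error(harmonize_multi(list(ex1), ou), "two exposures")
})
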