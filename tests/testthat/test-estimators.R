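test_that("the Wald ratio follows the delta-method formulas", {
  p <- harmonized_set(0.5, 0.01, 0.15, 0.05)
  e <- wald_ratio(p)
  expect_equal(e$theta, 0.3)
  expect_equal(e$se, 0.1)
  p0 <- harmonized_set(0.5, 0.01, 0, 0.05)
  e0 <- wald_ratio(p0)
  expect_equal(e0$theta, 0)
  expect_equal(e0$pval, 1)
  expect_error(wald_ratio(harmonized_set(0, 0.01, 0.1, 0.05)), "zero")
})

test_that("the Wald SE approximates the Monte-Carlo ratio spread for strong instruments", {
  # second-order / sampling oracle: simulate the ratio distribution
  set.seed(42)
  bx <- 0.5; sx <- 0.02; by <- 0.15; sy <- 0.05  # se_x/|beta_x| = 0.04 < 0.1
  r <- rnorm(2e5, by, sy) / rnorm(2e5, bx, sx)
  e <- wald_ratio(harmonized_set(bx, sx, by, sy))
  expect_lt(abs(e$se / sd(r) - 1), 0.10)
})

test_that("IVW reduces to the Wald ratio and to equal-weight means", {
  p1 <- harmonized_set(0.5, 0.01, 0.15, 0.05)
  expect_equal(mr_ivw(p1)$theta, wald_ratio(p1)$theta)
  expect_equal(mr_ivw(p1)$method, "wald")
  p2 <- harmonized_set(c(1, 1), c(0.01, 0.01), c(0.2, 0.4), c(0.1, 0.1))
  expect_equal(mr_ivw(p2)$theta, 0.3)
})

test_that("IVW-fixed equals weighted regression through the origin", {
  for (seed in 1:5) {
    h <- make_pairs(J = 30, seed = seed, noise = 0.01)
    p <- retained_pairs(h)
    oracle <- lm(beta_y ~ 0 + beta_x, data = p, weights = 1 / p$se_y^2)
    e <- mr_ivw(h, "fixed")
    expect_equal(e$theta, unname(coef(oracle)[1]), tolerance = 1e-10)
    # closed-form fixed SE
    expect_equal(e$se, 1 / sqrt(sum(p$beta_x^2 / p$se_y^2)),
                 tolerance = 1e-12)
  }
})

test_that("random-effects IVW never narrows below the fixed SE", {
  h_hom <- make_pairs(J = 25, seed = 2, noise = 0)     # underdispersed
  h_het <- make_pairs(J = 25, seed = 2, noise = 0.05)  # overdispersed
  expect_gte(mr_ivw(h_hom)$se, mr_ivw(h_hom, "fixed")$se - 1e-15)
  expect_gt(mr_ivw(h_het)$se, mr_ivw(h_het, "fixed")$se)
})

test_that("MR-Egger recovers exact lines and matches the WLS oracle", {
  x <- c(0.02, 0.05, 0.08, 0.03)
  h0 <- harmonized_set(x, rep(0.003, 4), 0.4 * x, rep(0.01, 4))
  eg0 <- mr_egger(h0)
  expect_equal(eg0$slope$theta, 0.4, tolerance = 1e-12)
  expect_equal(eg0$intercept$theta, 0, tolerance = 1e-12)
  h1 <- harmonized_set(x, rep(0.003, 4), 0.1 + 0.4 * x, rep(0.01, 4))
  eg1 <- mr_egger(h1)
  expect_equal(eg1$slope$theta, 0.4, tolerance = 1e-12)
  expect_equal(eg1$intercept$theta, 0.1, tolerance = 1e-12)
  expect_error(mr_egger(harmonized_set(x[1:2], rep(1, 2), x[1:2],
                                       rep(1, 2))), "at least 3")
  for (seed in 1:5) {
    h <- make_pairs(J = 30, seed = seed, noise = 0.02)
    p <- retained_pairs(h)
    fit <- lm(beta_y ~ beta_x, data = p, weights = 1 / p$se_y^2)
    s <- summary(fit)
    scale <- max(1, s$sigma) / s$sigma
    eg <- mr_egger(h)
    expect_equal(eg$slope$theta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(eg$intercept$theta, unname(coef(fit)[1]),
                 tolerance = 1e-10)
    expect_equal(eg$slope$se, unname(s$coefficients[2, 2] * scale),
                 tolerance = 1e-10)
    expect_equal(eg$intercept$se, unname(s$coefficients[1, 2] * scale),
                 tolerance = 1e-10)
    expect_equal(eg$slope$pval,
                 2 * pt(-abs(eg$slope$theta / eg$slope$se), df = 28),
                 tolerance = 1e-12)
  }
})

test_that("the Egger fit is invariant to re-orientation of any subset", {
  h <- make_pairs(J = 20, seed = 9, noise = 0.02)
  base <- mr_egger(h)
  for (seed in 1:5) {
    set.seed(seed)
    flip <- sample(c(-1, 1), 20, replace = TRUE)
    p <- retained_pairs(h)
    h2 <- harmonized_set(p$beta_x * flip, p$se_x, p$beta_y * flip, p$se_y)
    eg2 <- mr_egger(h2)
    expect_equal(eg2$slope$theta, base$slope$theta, tolerance = 1e-12)
    expect_equal(eg2$intercept$theta, base$intercept$theta,
                 tolerance = 1e-12)
  }
})

test_that("the weighted median interpolates the 50% weight point", {
  # equal weights: plain median of the ratios
  h <- harmonized_set(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.2, 0.3),
                      rep(0.1, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50)$theta, 0.2)
  # equal weights, even count: midpoint of central ratios
  h4 <- harmonized_set(rep(1, 4), rep(0.01, 4), c(0.1, 0.2, 0.4, 0.5),
                       rep(0.1, 4))
  expect_equal(mr_weighted_median(h4, n_boot = 50)$theta, 0.3)
  # a ratio carrying 90% of the weight dominates
  w_target <- c(0.9, 0.05, 0.05)
  x <- sqrt(w_target)  # se_y = 1 so w = x^2
  hd <- harmonized_set(x, rep(0.01, 3), x * c(0.25, 0.1, 0.4), rep(1, 3))
  est <- mr_weighted_median(hd, n_boot = 50)$theta
  expect_lt(abs(est - 0.25), 0.02)
})

test_that("the weighted median matches a dense grid search", {
  for (seed in 1:5) {
    h <- make_pairs(J = 25, seed = seed, noise = 0.03)
    p <- retained_pairs(h)
    r <- p$beta_y / p$beta_x
    w <- p$beta_x^2 / p$se_y^2
    expect_equal(mr_weighted_median(h, n_boot = 10)$theta,
                 weighted_median_oracle(r, w), tolerance = 1e-6)
  }
})

test_that("the bootstrap SE is seeded and reproducible", {
  h <- make_pairs(J = 15, seed = 4, noise = 0.02)
  e1 <- mr_weighted_median(h, n_boot = 200, seed = 7)
  e2 <- mr_weighted_median(h, n_boot = 200, seed = 7)
  e3 <- mr_weighted_median(h, n_boot = 200, seed = 8)
  expect_identical(e1$se, e2$se)
  expect_false(identical(e1$se, e3$se))
})

test_that("odds-ratio conversion is the exact log transform", {
  e0 <- to_or(list(theta = 0, se = 0.1))
  expect_equal(e0$or, 1)
  expect_equal(e0$ci_low * e0$ci_high, 1, tolerance = 1e-12)
  # log-transform of a published OR/CI: OR 0.478 (0.271, 0.841)
  e <- to_or(list(theta = log(0.478), se = 0.289))
  expect_equal(e$or, 0.478)
  expect_equal(e$ci_low, 0.271, tolerance = 0.002)
  expect_equal(e$ci_high, 0.842, tolerance = 0.002)
  # log-scale CI width is 2 * 1.96 * se
  expect_equal(log(e$ci_high) - log(e$ci_low),
               2 * qnorm(0.975) * 0.289, tolerance = 1e-12)
  expect_equal(sqrt(e$ci_low * e$ci_high), e$or, tolerance = 1e-12)
})

test_that("all estimators are scale-equivariant in the exposure", {
  h <- make_pairs(J = 20, seed = 6, noise = 0.02)
  p <- retained_pairs(h)
  cc <- 2.5
  h_scaled <- harmonized_set(p$beta_x * cc, p$se_x * cc, p$beta_y, p$se_y)
  expect_equal(mr_ivw(h_scaled)$theta, mr_ivw(h)$theta / cc,
               tolerance = 1e-12)
  expect_equal(mr_egger(h_scaled)$slope$theta,
               mr_egger(h)$slope$theta / cc, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h_scaled, n_boot = 10)$theta,
               mr_weighted_median(h, n_boot = 10)$theta / cc,
               tolerance = 1e-10)
})

test_that("the fitting front-end assembles estimates and skip reasons", {
  h <- make_pairs(J = 10, seed = 3, noise = 0.01)
  fit <- mr_fit(h, n_boot = 50, seed = 2)
  expect_s3_class(fit, "mr_fit")
  tab <- summary(fit)
  expect_setequal(tab$method, c("ivw_mre", "egger_slope",
                                "egger_intercept", "weighted_median"))
  expect_true(all(tab$ci_low < tab$or & tab$or < tab$ci_high))
  expect_equal(unname(coef(fit)["ivw"]), mr_ivw(h)$theta)
  # two instruments: Egger and weighted median are skipped with reasons
  h2 <- harmonized_set(c(0.05, 0.08), c(0.003, 0.003), c(0.01, 0.02),
                       c(0.01, 0.01))
  fit2 <- mr_fit(h2, n_boot = 10)
  expect_setequal(summary(fit2)$method, "ivw_mre")
  expect_setequal(names(fit2$skipped), c("egger", "weighted_median"))
  # one instrument: Wald fallback
  fit1 <- mr_fit(harmonized_set(0.05, 0.003, 0.01, 0.01))
  expect_equal(summary(fit1)$method, "wald")
})

test_that("IVW under the balanced-pleiotropy null rejects at the nominal rate", {
  rej <- 0
  n_rep <- 2000
  for (i in seq_len(n_rep)) {
    sim <- simulate_pair(sim_truth(theta = 0, pleiotropy_mode = "balanced",
                                   seed = 50000 + i))
    if (mr_ivw(sim_harmonized(sim))$pval < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})
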