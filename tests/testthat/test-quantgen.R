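test_that("REML components match the balanced one-way ANOVA closed form", {
  ph <- generate_phenotypes(genetic_design(120, 4, 0.5, 1,
                                           scenario_effect = 0, seed = 11))
  fit <- fit_mixed(ph, fixed = ~ 1)
  s <- summary(aov(value ~ genotype, data = ph))[[1]]
  msb <- s[["Mean Sq"]][1]
  msw <- s[["Mean Sq"]][2]
  expect_equal(fit$sigma_g2, (msb - msw) / 4, tolerance = 1e-6)
  expect_equal(fit$sigma_r2, msw, tolerance = 1e-6)
  expect_equal(fit$n_rep, 4)
})

test_that("BLUPs shrink genotype means toward zero", {
  ph <- generate_phenotypes(genetic_design(60, 4, 0.3, 1,
                                           scenario_effect = 0, seed = 13))
  fit <- fit_mixed(ph, fixed = ~ 1)
  raw_dev <- tapply(ph$value, ph$genotype, mean) - mean(ph$value)
  blups <- fit$blups[names(raw_dev)]
  expect_true(all(abs(blups) < abs(raw_dev) + 1e-10))
  # same ordering: shrinkage is monotone
  expect_equal(order(blups), order(raw_dev))
})

test_that("mixed-model inputs are validated", {
  ph <- generate_phenotypes(genetic_design(10, 4, 1, 1, seed = 1))
  expect_error(fit_mixed(ph, fixed = ~ nonexistent), "not in records")
  expect_error(fit_mixed(ph[, c("genotype", "scenario")], ~ scenario),
               "columns")
  expect_error(fit_mixed(ph[1:2, ], ~ 1), ">= 2 genotypes")
})

test_that("a null genetic variance is estimated at the boundary", {
  hits <- vapply(1:60, function(r) {
    ph <- generate_phenotypes(genetic_design(240, 4, 0, 1,
                                             scenario_effect = 0,
                                             seed = 4000 + r))
    f <- suppressWarnings(fit_mixed(ph, ~ 1))
    f$sigma_g2 <= 0.05 * f$sigma_r2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("BIC selection identifies the generating fixed structure", {
  # a real scenario effect: the scenario model wins in >= 90% of replicates
  wins <- vapply(1:100, function(r) {
    ph <- generate_phenotypes(genetic_design(60, 4, 0.25, 1,
                                             scenario_effect = -1,
                                             seed = 3000 + r))
    select_model(ph, candidates = list(~ 1, ~ scenario))$best_index == 2
  }, logical(1))
  expect_gte(mean(wins), 0.9)
  # no scenario effect: the intercept-only fixed part wins on average
  wins0 <- vapply(1:100, function(r) {
    ph <- generate_phenotypes(genetic_design(60, 4, 0.25, 1,
                                             scenario_effect = 0,
                                             seed = 6000 + r))
    select_model(ph, candidates = list(~ 1, ~ scenario))$best_index == 1
  }, logical(1))
  expect_gt(mean(wins0), 0.5)
  # single candidate returns that candidate; bic table is complete
  sel <- select_model(generate_phenotypes(genetic_design(20, 4, 1, 1,
                                                         seed = 2)),
                      candidates = list(~ scenario))
  expect_identical(sel$best_index, 1L)
  expect_identical(nrow(sel$bic_table), 1L)
})

test_that("heritability follows its closed form and monotonicities", {
  expect_equal(heritability(1, 1, 4), 0.8)
  expect_equal(heritability(1, 1, 2), 2 / 3)
  expect_equal(heritability(0, 1, 4), 0)
  expect_equal(heritability(2, 1, 1e9), 1, tolerance = 1e-8)
  expect_error(heritability(0, 0, 4), "undefined")
  # strictly increasing in n and in sigma_g2
  ns <- c(1, 2, 4, 8, 16)
  expect_true(all(diff(vapply(ns, function(n) heritability(0.5, 1, n),
                              numeric(1))) > 0))
  sg <- c(0.1, 0.5, 1, 2)
  expect_true(all(diff(vapply(sg, function(s) heritability(s, 1, 4),
                              numeric(1))) > 0))
})

test_that("BLUP accuracy reaches the theoretical sqrt(H2) bound", {
  for (h2 in c(0.5, 0.8)) {
    sg <- h2 / (4 * (1 - h2))
    ph <- generate_phenotypes(genetic_design(240, 4, sg, 1,
                                             scenario_effect = -0.5,
                                             seed = round(1000 * h2)))
    fit <- fit_mixed(ph, ~ scenario)
    truth <- attr(ph, "truth")$genotype_effects
    acc <- cor(fit$blups[names(truth)], truth)
    expect_gte(acc, sqrt(h2) - 0.05)
  }
})

test_that("genotypic CV is the sample SD over the mean", {
  expect_equal(genotypic_cv(c(8, 12)), sd(c(8, 12)) / 10) # ~0.2828
  expect_equal(genotypic_cv(rep(5, 10)), 0)
  x <- withr::with_seed(1, rnorm(50, mean = 10))
  expect_equal(genotypic_cv(3 * x), genotypic_cv(x), tolerance = 1e-12)
  expect_error(genotypic_cv(c(-1, 1)), "zero mean")
})

test_that("genotypic correlations of BLUPs recover the planted genetic correlation", {
  rho <- 0.7
  withr::with_seed(31, {
    g <- 240
    z1 <- rnorm(g)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(g)
    geno <- sprintf("G%04d", seq_len(g))
    mk <- function(eff) {
      df <- expand.grid(genotype = geno, replicate = 1:4,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      df$scenario <- ifelse(df$replicate %% 2 == 1, "WW", "WD")
      # high-precision traits (H2 ~ 0.94) so BLUP shrinkage attenuates the
      # between-trait correlation by well under the 0.1 tolerance
      df$value <- eff[match(df$genotype, geno)] +
        ifelse(df$scenario == "WD", -0.5, 0) + rnorm(nrow(df), sd = 0.5)
      df
    }
    f1 <- fit_mixed(mk(z1), ~ scenario)
    f2 <- fit_mixed(mk(z2), ~ scenario)
  })
  est <- cor(f1$blups[geno], f2$blups[geno])
  expect_lt(abs(est - rho), 0.1)
})
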