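test_that("balanced ANOVA matches brute-force sums of squares on a toy table", {
  # the classic additive toy: genotype and block explain everything (MSe = 0)
  trial <- toy_trial()
  av <- rcbd_anova(trial)
  y <- trial$y
  grand <- mean(y)
  g_means <- tapply(y, trial$genotype, mean)
  b_means <- tapply(y, trial$block, mean)
  ss_g <- 2 * sum((g_means - grand)^2)
  ss_b <- 3 * sum((b_means - grand)^2)
  expect_equal(av$df_genotype, 2)
  expect_equal(av$df_block, 1)
  expect_equal(av$df_residual, 2)
  expect_equal(av$ms_genotype, ss_g / 2)
  expect_equal(av$ms_block, ss_b / 1)
  expect_equal(av$ms_residual, 0, tolerance = 1e-12)

  # a perturbed toy with genuine residual: every statistic by hand
  dat <- data.frame(genotype = rep(c("g1", "g2", "g3"), each = 2),
                    block = rep(c("b1", "b2"), 3),
                    y = c(1, 2, 3, 5, 5, 6))
  av2 <- rcbd_anova(trial_table(dat, trait_spec_list_public("y")))
  y <- dat$y
  grand <- mean(y)
  g_means <- tapply(y, dat$genotype, mean)
  b_means <- tapply(y, dat$block, mean)
  ss_g <- 2 * sum((g_means - grand)^2)
  ss_b <- 3 * sum((b_means - grand)^2)
  ss_e <- sum((y - grand)^2) - ss_g - ss_b
  expect_equal(av2$ms_genotype, ss_g / 2)
  expect_equal(av2$ms_block, ss_b / 1)
  expect_equal(av2$ms_residual, ss_e / 2)
  expect_equal(av2$f_genotype, (ss_g / 2) / (ss_e / 2))
  expect_equal(av2$p_genotype,
               pf((ss_g / 2) / (ss_e / 2), 2, 2, lower.tail = FALSE))
})

test_that("sums of squares partition the total on random balanced data", {
  for (seed in 1:5) {
    trial <- simulate_trial(diag_config(n_genotypes = 15, k = 2, seed = seed))
    av <- rcbd_anova(trial)
    for (i in seq_len(nrow(av))) {
      y <- trial[[av$trait[i]]]
      ss_tot <- sum((y - mean(y))^2)
      ss_model <- av$ms_block[i] * av$df_block[i] +
        av$ms_genotype[i] * av$df_genotype[i] +
        av$ms_residual[i] * av$df_residual[i]
      expect_equal(ss_model, ss_tot, tolerance = 1e-9)
    }
  }
})

test_that("a constant response is reported as ns with p = 1", {
  dat <- data.frame(genotype = rep(c("g1", "g2", "g3"), 2),
                    block = rep(c("b1", "b2"), each = 3), y = 5)
  av <- rcbd_anova(trial_table(dat, trait_spec_list_public("y")))
  expect_equal(av$ms_genotype, 0)
  expect_equal(av$p_genotype, 1)
  expect_equal(av$sig_genotype, "ns")
})

test_that("F-test p-value agrees with a within-block permutation test", {
  cfg <- diag_config(n_genotypes = 12, n_blocks = 3, s2g = 0.6, s2e = 1,
                     k = 1, seed = 8, block_sd = 1)
  trial <- simulate_trial(cfg)
  av <- rcbd_anova(trial)
  f_obs <- av$f_genotype
  set.seed(101)
  n_perm <- 4000
  d <- data.frame(y = trial$T1, genotype = factor(trial$genotype),
                  block = factor(trial$block))
  f_perm <- replicate(n_perm, {
    yp <- unlist(tapply(d$y, d$block, sample), use.names = FALSE)
    dd <- d[order(d$block), ]
    dd$y <- yp
    at <- anova(lm(y ~ block + genotype, data = dd))
    at$`F value`[2]
  })
  p_perm <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  expect_lt(abs(p_perm - av$p_genotype), 0.03)
})

test_that("missing plots trigger the singleton warning and adjust df", {
  trial <- simulate_trial(diag_config(n_genotypes = 10, n_blocks = 2, k = 1, seed = 3))
  trial$T1[trial$genotype == "G01" & trial$block == "B2"] <- NA
  expect_warning(av <- rcbd_anova(trial), "fewer than 2 blocks")
  expect_equal(av$df_residual, (10 - 1) * (2 - 1) - 1)
})

test_that("EMS components follow the closed form, with truncation at zero", {
  vc <- variance_components(0.62, 0.07, 3)
  expect_equal(unname(vc["sigma2_g"]), (0.62 - 0.07) / 3)
  expect_equal(round(unname(vc["sigma2_g"]), 2), 0.18)
  expect_equal(unname(vc["sigma2_p"]), unname(vc["sigma2_g"]) + 0.07)
  vc2 <- variance_components(4554.42, 0.06, 3)
  expect_equal(unname(vc2["sigma2_g"]), 1518.12)
  expect_equal(unname(variance_components(0.5, 0.5, 3)["sigma2_g"]), 0)
  expect_warning(variance_components(0.1, 0.5, 3), "truncated")
  expect_error(variance_components(1, 0.5, 1), "n_blocks")
})

test_that("heritability is clamped, handles degenerate input, and is monotone", {
  expect_equal(round(heritability(1.18, 7.16, 42), 2), 0.87)
  expect_equal(round(heritability(42.76, 419.21, 42), 2), 0.81)
  expect_equal(heritability(0, 5, 42), 0)
  expect_warning(h <- heritability(0, 0, 42), "undefined")
  expect_true(is.na(h))
  # monotone in sigma2_g with the gap sigma2_p - sigma2_g fixed
  gap <- 3
  h_seq <- vapply(c(0.5, 1, 2, 4), function(s) heritability(s, s + gap, 10), numeric(1))
  expect_true(all(diff(h_seq) > 0))
  # monotone in the divisor
  expect_gt(heritability(1, 4, 20), heritability(1, 4, 5))
})

test_that("coefficients of variation follow sqrt(variance)/mean", {
  expect_equal(round(coefficient_of_variation(0.1, 1.37), 2), 0.23)
  expect_equal(round(coefficient_of_variation(9.28, 19.46, percent = TRUE), 2), 15.65)
  expect_equal(coefficient_of_variation(0, 5), 0)
  expect_error(coefficient_of_variation(1, 0), "positive")
})

test_that("variability classification respects the published cut points", {
  expect_equal(classify_variability(c(0, 9.99), "gcv_pcv"), c("low", "low"))
  expect_equal(classify_variability(c(10, 19.99), "gcv_pcv"), rep("intermediate", 2))
  expect_equal(classify_variability(c(20, 29), "gcv_pcv"), rep("high", 2))
  expect_equal(classify_variability(c(29, 30, 60), "heritability"),
               c("low", "intermediate", "intermediate"))
  expect_equal(classify_variability(c(61, 98), "heritability"), rep("high", 2))
  expect_error(classify_variability(-1, "gcv_pcv"), "non-negative")
})

test_that("GCV never exceeds PCV in the variance summary", {
  for (seed in 1:5) {
    trial <- simulate_trial(diag_config(n_genotypes = 20, k = 3, seed = seed))
    vs <- variance_summary(trial)
    expect_true(all(vs$gcv <= vs$pcv + 1e-12))
    expect_true(all(vs$sigma2_p >= vs$sigma2_g))
    expect_true(all(vs$h2 >= 0 & vs$h2 <= 1))
  }
})
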