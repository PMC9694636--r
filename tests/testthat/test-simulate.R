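test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(n_cases = 10, n_controls = 40, n_snps = 5,
                             n_ld_blocks = 2), "sim_config")
  expect_error(sim_config(n_ld_blocks = 1000, n_snps = 10))
  expect_error(sim_config(allele_freq_range = c(0, 0.5)))
  expect_error(sim_config(allele_freq_range = c(0.5, 0.1)))
  expect_error(sim_config(prevalence = 0))
  expect_error(sim_config(within_block_r2 = 1))
})

test_that("simulate_cohort is a pure function of (config, seed)", {
  cfg <- sim_config(n_cases = 50, n_controls = 200, n_snps = 20,
                    n_ld_blocks = 5, missing_rate = 0.02, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$true_weights, b$true_weights)
  # different seed changes the draw
  cfg2 <- sim_config(n_cases = 50, n_controls = 200, n_snps = 20,
                     n_ld_blocks = 5, missing_rate = 0.02, seed = 8)
  expect_false(identical(simulate_cohort(cfg2)$genotypes$dosages,
                         a$genotypes$dosages))
})

test_that("dosages are valid, counts honoured, missingness injected", {
  cfg <- sim_config(n_cases = 60, n_controls = 240, n_snps = 15,
                    n_ld_blocks = 3, missing_rate = 0.05, seed = 3)
  sim <- simulate_cohort(cfg)
  d <- sim$genotypes$dosages
  expect_equal(dim(d), c(300L, 15L))
  expect_true(all(d[!is.na(d)] %in% 0:2))
  expect_gt(mean(is.na(d)), 0.02)
  expect_equal(as.integer(table(sim$cohort$status)[c("case", "control")]),
               c(60L, 240L))
  expect_true(all(is.na(sim$cohort$bmi) | sim$cohort$bmi >= 18.5))
})

test_that("unattainable case counts fail with the bound named", {
  cfg <- sim_config(n_cases = 5000, n_controls = 10, n_snps = 5,
                    n_ld_blocks = 1, prevalence = 0.01, seed = 1)
  expect_error(simulate_cohort(cfg, max_batches = 2L),
               class = "ghdpgs_unattainable_counts")
})

test_that("allele frequencies and LD structure match the configuration", {
  # null model so case-control sampling cannot distort genotype frequencies
  cfg <- sim_config(n_cases = 1000, n_controls = 9000, n_snps = 24,
                    n_ld_blocks = 6, within_block_r2 = 0.5,
                    allele_freq_range = c(0.2, 0.4),
                    causal_fraction = 0, seed = 11)
  sim <- simulate_cohort(cfg)
  d <- sim$genotypes$dosages
  n <- nrow(d)
  f_hat <- colMeans(d) / 2
  # 3 binomial SEs around the configured band (per-SNP target is hidden in
  # the draw, so check against the band edges)
  se <- sqrt(0.4 * 0.6 / (2 * n)) * 3
  expect_true(all(f_hat > 0.2 - se & f_hat < 0.4 + se))
  blocks <- rep(1:6, each = 4)
  r2 <- suppressWarnings(cor(d))^2
  same <- outer(blocks, blocks, "==") & upper.tri(r2)
  diff <- outer(blocks, blocks, "!=") & upper.tri(r2)
  expect_lt(abs(mean(r2[same]) - 0.5), 0.1)
  expect_lt(abs(mean(r2[diff])), 0.05)
})

test_that("liability gradient separates deciles when effects exist", {
  cfg <- sim_config(n_cases = 3000, n_controls = 17000, n_snps = 50,
                    n_ld_blocks = 50, causal_fraction = 0.2,
                    effect_sd = 0.3, prevalence = 0.15, seed = 5)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  qs <- quantile(co$true_liability, c(0.1, 0.9))
  top <- mean(co$status[co$true_liability >= qs[2]] == "case")
  bot <- mean(co$status[co$true_liability <= qs[1]] == "case")
  expect_gt(top, bot)
  # single-SNP refits recover the generative weights (parameter-recovery
  # oracle: marginal log-odds on an LD-free panel)
  ss <- simulate_gwas_summary(sim$genotypes, co)
  expect_gt(cor(ss$beta, sim$true_weights), 0.8)
})

test_that("simulate_gwas_summary flags monomorphic SNPs and needs 2+ per group", {
  d <- cbind(rep(1, 20), rbinom(20, 2, 0.5))
  geno <- tiny_genotypes(d)
  co <- tiny_cohort(rep(list(character()), 20),
                    status = rep(c("case", "control"), 10))
  ss <- simulate_gwas_summary(geno, co)
  expect_true(ss$monomorphic[1])
  expect_true(is.na(ss$beta[1]))
  expect_equal(ss$p[1], 1)
  co1 <- tiny_cohort(rep(list(character()), 20),
                     status = c("case", rep("control", 19)))
  expect_error(simulate_gwas_summary(geno, co1),
               class = "ghdpgs_insufficient_groups")
})

test_that("single-SNP effect estimates are consistent with the truth", {
  # direct generative check on one SNP with true log-odds 0.5
  set.seed(21)
  n <- 50000
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-1.5 + 0.5 * g))
  geno <- tiny_genotypes(cbind(g = g, junk = rbinom(n, 2, 0.4)))
  co <- ghd_cohort(rownames(geno$dosages), ifelse(y == 1, "case", "control"))
  ss <- simulate_gwas_summary(geno, co)
  expect_lt(abs(ss$beta[1] - 0.5), 2 * ss$se[1])
})

test_that("simulate_mr_instruments honours the noiseless limit and seed", {
  iv <- simulate_mr_instruments(10, causal_beta = 0.4, pleiotropy_mean = 0,
                                seed = 3, noise_sd = 0)
  expect_equal(iv$beta_outcome / iv$beta_exposure, rep(0.4, 10))
  iv2 <- simulate_mr_instruments(10, 0.4, 0, seed = 3, noise_sd = 0)
  expect_identical(iv, iv2)
  expect_error(simulate_mr_instruments(1, 0.4))
})
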