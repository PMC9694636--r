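make_cohort <- function(n_cases, n_controls) {
  ghd_cohort(sprintf("S%05d", seq_len(n_cases + n_controls)),
             rep(c("case", "control"), c(n_cases, n_controls)))
}

test_that("balance_controls draws the stated subset sizes, reproducibly", {
  co <- make_cohort(100, 450)
  subs <- balance_controls(co, resample_scheme(10, 4, seed = 3))
  expect_length(subs, 10)
  for (s in subs) {
    expect_length(s$case_idx, 100)
    expect_length(s$control_idx, 400)
    expect_false(anyDuplicated(s$control_idx) > 0)
    expect_true(all(co$status[s$control_idx] == "control"))
  }
  expect_identical(subs, balance_controls(co, resample_scheme(10, 4, seed = 3)))
  expect_false(identical(subs[[1]]$control_idx, subs[[2]]$control_idx))
  # pool exactly 4x cases: the whole pool is used
  co2 <- make_cohort(50, 200)
  sub1 <- balance_controls(co2, resample_scheme(1, 4, seed = 1))
  expect_equal(sub1[[1]]$control_idx, which(co2$status == "control"))
  expect_error(balance_controls(make_cohort(100, 300), resample_scheme(1, 4)),
               class = "ghdpgs_insufficient_controls")
})

test_that("collinearity screen keeps independent SNPs and prunes dependencies", {
  set.seed(14)
  X <- sapply(1:5, function(i) rbinom(400, 2, 0.4))
  colnames(X) <- paste0("s", 1:5)
  res <- collinearity_screen(X, 10)
  expect_equal(res$retained, colnames(X))
  expect_true(all(res$vif < 1.2))
  # duplicated column: exactly one of the pair dropped
  X2 <- cbind(X, dup = X[, 1])
  res2 <- collinearity_screen(X2, 10)
  expect_length(res2$dropped, 1)
  expect_true(res2$dropped %in% c("s1", "dup"))
  expect_true(all(res2$vif < 10))
  # exact linear dependence: one dropped, remaining VIF under threshold
  X3 <- cbind(X[, 1:3], sum12 = X[, 1] + X[, 2])
  res3 <- collinearity_screen(X3, 10)
  expect_length(res3$dropped, 1)
  expect_true(all(res3$vif < 10))
})

test_that("train_pgs with one subset equals the single direct fit", {
  cfg <- sim_config(n_cases = 200, n_controls = 800, n_snps = 12,
                    n_ld_blocks = 12, causal_fraction = 0.5,
                    effect_sd = 0.4, prevalence = 0.2, seed = 17)
  sim <- simulate_cohort(cfg)
  scheme <- resample_scheme(1, 4, seed = 5)
  model <- train_pgs(sim$cohort, sim$genotypes, sim$genotypes$snp_ids,
                     scheme, n_folds = 5, n_repeats = 2)
  idx <- c(balance_controls(sim$cohort, scheme)[[1]]$case_idx,
           balance_controls(sim$cohort, scheme)[[1]]$control_idx)
  direct <- fit_logistic(sim$genotypes$dosages[idx, model$snp_ids],
                         sim$cohort$status[idx])
  expect_equal(unname(model$weights), unname(direct$weights))
  expect_equal(model$intercept, direct$intercept)
  # same scheme + seed reproduces the identical model
  model2 <- train_pgs(sim$cohort, sim$genotypes, sim$genotypes$snp_ids,
                      scheme, n_folds = 5, n_repeats = 2)
  expect_identical(model$weights, model2$weights)
  expect_identical(model$training_auc, model2$training_auc)
})

test_that("the selected subset maximises mean CV AUC by construction", {
  cfg <- sim_config(n_cases = 150, n_controls = 700, n_snps = 10,
                    n_ld_blocks = 10, causal_fraction = 0.4,
                    effect_sd = 0.4, prevalence = 0.2, seed = 19)
  sim <- simulate_cohort(cfg)
  model <- train_pgs(sim$cohort, sim$genotypes, sim$genotypes$snp_ids,
                     resample_scheme(4, 4, seed = 2), n_folds = 5,
                     n_repeats = 2)
  aucs <- model$provenance$subset_aucs
  expect_equal(model$training_auc, max(aucs))
  expect_equal(model$provenance$selected_subset, which.max(aucs))
})

test_that("forward AIC selection finds a strong signal and resists pure noise", {
  set.seed(23)
  n <- 10000
  g_causal <- rbinom(n, 2, 0.3)
  noise <- sapply(1:6, function(i) rbinom(n, 2, 0.3))
  X <- cbind(causal = g_causal, noise)
  colnames(X) <- c("causal", paste0("n", 1:6))
  y <- rbinom(n, 1, plogis(-1 + 0.5 * g_causal))
  model <- stepwise_aic(X, y)
  expect_equal(model$snp_ids[1], "causal")
  path <- model$provenance$aic_path
  expect_true(all(diff(path) < 0))     # AIC non-increasing along the path
  # all-noise candidates: few or no admissions
  y0 <- rbinom(n, 1, 0.2)
  m0 <- stepwise_aic(X, y0)
  expect_lte(length(m0$snp_ids), 2)
  # size-1 candidate set with real signal
  m1 <- stepwise_aic(X[, "causal", drop = FALSE], y)
  expect_equal(m1$snp_ids, "causal")
})

test_that("stepwise model is no larger than the full model, similar CV AUC", {
  cfg <- sim_config(n_cases = 500, n_controls = 2000, n_snps = 30,
                    n_ld_blocks = 30, causal_fraction = 0.2,
                    effect_sd = 0.35, prevalence = 0.15, seed = 29)
  sim <- simulate_cohort(cfg)
  d <- sim$genotypes$dosages
  y <- sim$cohort$status
  full_cv <- cross_validated_auc(d, y, n_folds = 5, n_repeats = 2, seed = 1)
  sw <- stepwise_aic(d, y)
  expect_lte(length(sw$snp_ids), ncol(d))
  sw_cv <- cross_validated_auc(d[, sw$snp_ids, drop = FALSE], y,
                               n_folds = 5, n_repeats = 2, seed = 1)
  expect_lt(abs(sw_cv$mean_auc - full_cv$mean_auc), 0.05)
})
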