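test_that("Wald odds ratios match closed-form arithmetic", {
  est <- odds_ratio_wald(contingency_table(10, 10, 10, 10))
  expect_equal(est$odds_ratio, 1)
  expect_equal(est$ci_low * est$ci_high, 1, tolerance = 1e-12)
  est2 <- odds_ratio_wald(contingency_table(20, 10, 10, 20), alpha = 0.05)
  expect_equal(est2$odds_ratio, 4)
  expect_equal(est2$se_log, sqrt(0.3))
  z <- qnorm(0.975)
  expect_equal(est2$ci_low, exp(log(4) - z * sqrt(0.3)))
  expect_equal(est2$ci_low, 1.367, tolerance = 1e-3)
  expect_equal(est2$ci_high, 11.70, tolerance = 1e-3)
  expect_false(est2$corrected)
})

test_that("zero cells trigger the flagged Haldane-Anscombe correction", {
  est <- odds_ratio_wald(contingency_table(5, 0, 3, 10))
  expect_true(est$corrected)
  expect_equal(est$odds_ratio, (5.5 * 10.5) / (0.5 * 3.5))
  expect_error(odds_ratio_wald(contingency_table(0, 0, 3, 10)),
               class = "ghdpgs_inestimable")
})

test_that("Wald interval properties hold on random tables", {
  set.seed(41)
  for (i in 1:25) {
    cells <- rpois(4, 20) + 1
    est <- odds_ratio_wald(contingency_table(cells[1], cells[2],
                                             cells[3], cells[4]))
    expect_lt(abs(sqrt(est$ci_low * est$ci_high) - est$odds_ratio), 1e-9)
    expect_lte(est$ci_low, est$odds_ratio)
    expect_lte(est$odds_ratio, est$ci_high)
    # inverse symmetry
    inv <- odds_ratio_wald(contingency_table(cells[3], cells[4],
                                             cells[1], cells[2]))
    expect_equal(est$odds_ratio * inv$odds_ratio, 1, tolerance = 1e-12)
    # scaling all cells narrows the CI around the same OR
    big <- odds_ratio_wald(contingency_table(cells[1] * 5, cells[2] * 5,
                                             cells[3] * 5, cells[4] * 5))
    expect_equal(big$odds_ratio, est$odds_ratio)
    expect_lt(big$ci_high / big$ci_low, est$ci_high / est$ci_low)
  }
})

test_that("top-vs-bottom OR evaluates the stated 2x2 directly", {
  # 100 distinct scores; top 25 hold 10 cases / 15 controls, bottom 50 hold
  # 5 cases / 45 controls -> OR = (10/15)/(5/45) = 6
  scores <- data.frame(sample_id = sprintf("S%03d", 1:100), pgs = 1:100,
                       percentile = percentile_rank(1:100))
  class(scores) <- c("score_vector", "data.frame")
  y <- integer(100)
  y[76:85] <- 1L          # 10 cases in the top 25
  y[1:5] <- 1L            # 5 cases in the bottom 50
  res <- top_vs_bottom_or(scores, y, top_fraction = 0.25)
  expect_equal(res$estimate$odds_ratio, 6)
  expect_equal(res$stratum_label, "top 25% vs bottom 50%")
  expect_error(top_vs_bottom_or(scores, y, 0.25, 0.8))
})

test_that("null scores give near-unity top-quartile ORs", {
  set.seed(43)
  ors <- replicate(20, {
    n <- 10000
    sc <- data.frame(sample_id = seq_len(n), pgs = rnorm(n),
                     percentile = percentile_rank(rnorm(n)))
    class(sc) <- c("score_vector", "data.frame")
    top_vs_bottom_or(sc, rbinom(n, 1, 0.15), 0.25)$estimate$odds_ratio
  })
  expect_true(all(ors > 0.6 & ors < 1.6))
})

test_that("septile assignment follows the mid-rank band edges", {
  sc <- data.frame(pgs = 1:14, percentile = percentile_rank(1:14))
  expect_equal(assign_septiles(sc), rep(1:7, each = 2))
  # rank exactly 0.50 falls in septile 4 (the 42.9-57.1% reference band)
  sc2 <- data.frame(pgs = 1:21, percentile = percentile_rank(1:21))
  expect_equal(assign_septiles(sc2)[11], 4L)
  # all-tied scores collapse into the middle septile
  expect_equal(unique(assign_septiles(rep(1, 10))), 4L)
  expect_error(assign_septiles(1:3))
})

test_that("BMI bands use the standard cutpoints", {
  expect_equal(assign_bmi_band(c(24, 27.5, 30, 18.5, 29.999)),
               c("low", "medium", "high", "low", "medium"))
  expect_error(assign_bmi_band(17), class = "ghdpgs_bmi_range")
  expect_error(assign_bmi_band(NA_real_), class = "ghdpgs_bmi_range")
})

test_that("the 21-cell grid uses the medium-BMI/median-PGS reference", {
  set.seed(44)
  n <- 4200
  co <- ghd_cohort(sprintf("S%05d", 1:n),
                   ifelse(rbinom(n, 1, 0.2) == 1, "case", "control"),
                   bmi = pmax(18.5, rnorm(n, 27, 4.5)))
  sc <- data.frame(sample_id = co$sample_id, pgs = rnorm(n),
                   percentile = percentile_rank(rnorm(n)))
  class(sc) <- c("score_vector", "data.frame")
  grid <- bmi_pgs_grid(co, sc)
  expect_equal(nrow(grid), 21)
  ref <- grid[grid$reference, ]
  expect_equal(nrow(ref), 1)
  expect_equal(ref$bmi_band, "medium")
  expect_equal(ref$septile, 4L)
  expect_equal(ref$or, 1)
  expect_false(any(duplicated(grid[, c("bmi_band", "septile")])))
  # empty cell is named in the failure
  co2 <- co[co$bmi >= 25, ]
  class(co2) <- c("ghd_cohort", "data.frame")
  sc2 <- sc[co$bmi >= 25, ]
  sc2$percentile <- percentile_rank(sc2$pgs)
  expect_error(bmi_pgs_grid(co2, sc2), "low",
               class = "ghdpgs_empty_stratum")
})
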