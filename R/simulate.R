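#' Simulation configuration for a synthetic case-control cohort
#'
#' Describes the full generative model: LD-structured genotypes, a sparse
#' logistic disease model calibrated to a marginal prevalence, a BMI covariate
#' partially correlated with the true genetic score, and ICD-10-style
#' diagnosis codes. The defaults emulate the real cohort the pipeline was
#' designed around: ~2,787 cases and ~13,400 controls genotyped at a candidate
#' panel of ~375 SNPs organised in LD blocks.
#'
#' @param n_cases,n_controls requested case/control counts (> 0).
#' @param n_snps number of SNPs in the candidate panel.
#' @param n_ld_blocks number of equicorrelated LD blocks (<= n_snps).
#' @param within_block_r2 target squared dosage correlation within a block,
#'   in \[0, 1). The latent Gaussian correlation is calibrated analytically so
#'   the *dosage* r-squared matches this value.
#' @param allele_freq_range ordered pair of effect-allele frequencies strictly
#'   inside (0, 1); per-SNP frequencies are drawn uniformly from this range.
#' @param causal_fraction fraction of SNPs with a nonzero true effect.
#' @param effect_sd SD (log-odds scale) of the nonzero true effects.
#' @param prevalence marginal disease probability the intercept is solved for.
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2).
#' @param bmi_genetic_corr correlation in \[-1, 1\] between BMI and the
#'   standardized true genetic score.
#' @param bmi_case_shift additive BMI shift (kg/m^2) for cases, so BMI can act
#'   as an environmental risk marker; 0 disables it.
#' @param missing_rate fraction of dosage entries and BMI values set missing.
#' @param seed integer global seed; all stages derive child seeds from it via
#'   [child_seed()].
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cases = 2787, n_controls = 13400,
                       n_snps = 375, n_ld_blocks = 75,
                       within_block_r2 = 0.5,
                       allele_freq_range = c(0.05, 0.5),
                       causal_fraction = 0.2, effect_sd = 0.15,
                       prevalence = 0.08,
                       bmi_mean = 27, bmi_sd = 4.5,
                       bmi_genetic_corr = 0.1,
                       bmi_case_shift = 0,
                       missing_rate = 0, seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_snps = as.integer(n_snps), n_ld_blocks = as.integer(n_ld_blocks),
    within_block_r2 = within_block_r2,
    allele_freq_range = as.numeric(allele_freq_range),
    causal_fraction = causal_fraction, effect_sd = effect_sd,
    prevalence = prevalence, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    bmi_genetic_corr = bmi_genetic_corr, bmi_case_shift = bmi_case_shift,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_cases > 0, n_controls > 0, n_snps > 0, n_ld_blocks > 0,
      n_ld_blocks <= n_snps,
      within_block_r2 >= 0, within_block_r2 < 1,
      length(allele_freq_range) == 2,
      allele_freq_range[1] > 0, allele_freq_range[2] < 1,
      allele_freq_range[1] <= allele_freq_range[2],
      causal_fraction >= 0, causal_fraction <= 1,
      effect_sd >= 0, prevalence > 0, prevalence < 1,
      bmi_sd > 0, bmi_genetic_corr >= -1, bmi_genetic_corr <= 1,
      missing_rate >= 0, missing_rate < 1
    )
  })
  structure(cfg, class = "sim_config")
}

#' Construct a genotype matrix of effect-allele dosages
#'
#' @param dosages numeric matrix, samples x SNPs; every non-missing entry must
#'   be exactly 0, 1 or 2.
#' @param sample_ids,snp_ids row/column identifiers (snp_ids unique).
#' @param map data.frame with one row per SNP: `snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` (bim-style, 1-based positions).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            snp_ids = colnames(dosages), map = NULL) {
  dosages <- as.matrix(dosages)
  stopifnot(!is.null(sample_ids), !is.null(snp_ids),
            nrow(dosages) == length(sample_ids),
            ncol(dosages) == length(snp_ids),
            !anyDuplicated(snp_ids))
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    abort_ghd("dosages must be 0, 1, 2 or missing", "ghdpgs_invalid_dosage")
  if (is.null(map)) {
    map <- data.frame(snp = snp_ids, chrom = "1",
                      pos = seq_along(snp_ids) * 10000L,
                      effect_allele = "A", other_allele = "G",
                      stringsAsFactors = FALSE)
  }
  stopifnot(identical(map$snp, as.character(snp_ids)), all(map$pos >= 1))
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(list(dosages = dosages, sample_ids = as.character(sample_ids),
                 snp_ids = as.character(snp_ids), map = map,
                 effect_alleles = map$effect_allele),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs, %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Construct a cohort table
#'
#' @param sample_ids character identifiers.
#' @param status "case"/"control" (or "excluded") per sample.
#' @param bmi numeric kg/m^2 or NA.
#' @param diagnosis_codes list of character vectors of ICD-10-style codes.
#' @param true_liability optional latent log-odds (synthetic cohorts only).
#' @return a data.frame of class `ghd_cohort` with a `diagnosis_codes`
#'   list-column.
#' @export
ghd_cohort <- function(sample_ids, status, bmi = NA_real_,
                       diagnosis_codes = NULL, true_liability = NA_real_) {
  n <- length(sample_ids)
  stopifnot(length(status) == n, !anyNA(status))
  if (is.null(diagnosis_codes)) diagnosis_codes <- rep(list(character()), n)
  stopifnot(length(diagnosis_codes) == n)
  bmi <- rep_len(as.numeric(bmi), n)
  if (any(!is.na(bmi) & bmi <= 0))
    abort_ghd("bmi must be positive when present", "ghdpgs_invalid_bmi")
  out <- data.frame(sample_id = as.character(sample_ids),
                    status = as.character(status),
                    bmi = bmi,
                    true_liability = rep_len(as.numeric(true_liability), n),
                    stringsAsFactors = FALSE)
  out$diagnosis_codes <- diagnosis_codes
  class(out) <- c("ghd_cohort", "data.frame")
  out
}

# --- latent-Gaussian LD calibration ------------------------------------------

# P(Z1 > s, Z2 > t) for standard bivariate normal with correlation r,
# by 1-D Gaussian quadrature over the conditional tail.
bvn_upper <- function(s, t, r) {
  if (abs(r) < 1e-12)
    return(stats::pnorm(s, lower.tail = FALSE) * stats::pnorm(t, lower.tail = FALSE))
  sd <- sqrt(1 - r^2)
  stats::integrate(function(z)
    stats::dnorm(z) * stats::pnorm((t - r * z) / sd, lower.tail = FALSE),
    lower = s, upper = Inf, rel.tol = 1e-10)$value
}

# Dosage correlation between two SNPs of allele frequency f whose latent
# Gaussians have correlation r, under HWE double-thresholding.
dosage_corr_given_latent <- function(r, f) {
  a <- stats::qnorm((1 - f)^2)    # above: at least one effect allele
  b <- stats::qnorm(1 - f^2)      # above: two effect alleles
  th <- c(a, b)
  cov <- 0
  for (s in th) for (t in th)
    cov <- cov + bvn_upper(s, t, r) -
      stats::pnorm(s, lower.tail = FALSE) * stats::pnorm(t, lower.tail = FALSE)
  cov / (2 * f * (1 - f))
}

# Latent correlation that yields the target dosage correlation at frequency f.
calibrate_latent_corr <- function(target_dosage_corr, f) {
  if (target_dosage_corr <= 0) return(0)
  stats::uniroot(function(r) dosage_corr_given_latent(r, f) - target_dosage_corr,
                 lower = 0, upper = 0.99999, tol = 1e-8)$root
}

# --- cohort simulation -------------------------------------------------------

draw_block_dosages <- function(n, freqs, latent_r) {
  k <- length(freqs)
  z <- matrix(stats::rnorm(n * k), n, k)
  if (latent_r > 0) {
    shared <- stats::rnorm(n)
    z <- sqrt(latent_r) * shared + sqrt(1 - latent_r) * z
  }
  d <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    a <- stats::qnorm((1 - freqs[j])^2)
    b <- stats::qnorm(1 - freqs[j]^2)
    d[, j] <- (z[, j] > a) + (z[, j] > b)
  }
  d
}

sim_snp_map <- function(cfg, blocks) {
  n <- cfg$n_snps
  ids <- sprintf("rs%07d", seq_len(n) * 13L + 1000000L)
  chrom <- character(n); pos <- integer(n)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    chrom[idx] <- as.character(((b - 1L) %% 22L) + 1L)
    # blocks on the same chromosome are spaced 10 Mb apart; SNPs within a
    # block sit 5 kb apart so a 250 kb clumping window always covers a block
    base <- 1e6 + 1e7 * ((b - 1L) %/% 22L)
    pos[idx] <- as.integer(base + 5000L * (seq_along(idx) - 1L))
  }
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n, replace = TRUE)
  oa <- vapply(ea, function(x) sample(setdiff(alleles, x), 1L), "")
  data.frame(snp = ids, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = unname(oa),
             stringsAsFactors = FALSE)
}

#' Simulate a case-control cohort with LD-structured genotypes
#'
#' Genotypes are drawn per LD block from an equicorrelated latent Gaussian,
#' double-thresholded to dosages \{0,1,2\} at Hardy-Weinberg genotype
#' frequencies; the latent correlation is calibrated so the dosage r-squared
#' matches `config$within_block_r2`. Disease status follows a logistic model
#' on the centered dosage-weighted sum whose intercept is solved numerically
#' so the marginal prevalence matches `config$prevalence`; individuals are
#' drawn until the requested case and control counts are filled. BMI is a
#' Gaussian blend of the standardized true genetic score and independent
#' noise (values below 18.5 are re-drawn), and diagnosis codes are assigned
#' from case/control code menus so cohort-definition filters have work to do.
#'
#' @param config a [sim_config()].
#' @param max_batches bound on the number of sampling batches before the
#'   requested case count is declared unattainable.
#' @return list with `genotypes` ([genotype_matrix()]), `cohort`
#'   ([ghd_cohort()]), and `true_weights` (named per-SNP log-odds vector).
#' @export
simulate_cohort <- function(config, max_batches = 20L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config

  set.seed(child_seed(cfg$seed, 0L))
  blocks <- sort(rep_len(seq_len(cfg$n_ld_blocks), cfg$n_snps))
  freqs <- stats::runif(cfg$n_snps, cfg$allele_freq_range[1], cfg$allele_freq_range[2])
  map <- sim_snp_map(cfg, blocks)

  # true sparse effects
  n_causal <- round(cfg$causal_fraction * cfg$n_snps)
  w <- numeric(cfg$n_snps)
  if (n_causal > 0)
    w[sample(cfg$n_snps, n_causal)] <- stats::rnorm(n_causal, 0, cfg$effect_sd)
  names(w) <- map$snp

  # per-block latent correlation calibrated to the dosage r2 target
  target_r <- sqrt(cfg$within_block_r2)
  latent_r <- vapply(unique(blocks), function(b) {
    f <- mean(freqs[blocks == b])
    calibrate_latent_corr(target_r, f)
  }, numeric(1))

  draw_batch <- function(n) {
    d <- matrix(0L, n, cfg$n_snps)
    for (b in unique(blocks)) {
      idx <- which(blocks == b)
      d[, idx] <- draw_block_dosages(n, freqs[idx], latent_r[b])
    }
    d
  }

  # solve the intercept on a calibration pool so that the marginal
  # prevalence matches the configured value
  set.seed(child_seed(cfg$seed, 1L))
  pool <- draw_batch(5000L)
  g_score <- function(d) drop(d %*% w) - sum(2 * freqs * w)
  s_pool <- g_score(pool)
  intercept <- stats::uniroot(
    function(c0) mean(stats::plogis(c0 + s_pool)) - cfg$prevalence,
    lower = -30, upper = 30, tol = 1e-10)$root

  # rejection-sample cases and controls to the requested counts
  set.seed(child_seed(cfg$seed, 2L))
  need_draws <- ceiling(1.5 * max(cfg$n_cases / cfg$prevalence,
                                  cfg$n_controls / (1 - cfg$prevalence)))
  batch_n <- ceiling(need_draws / 4)
  case_d <- list(); ctrl_d <- list(); case_s <- list(); ctrl_s <- list()
  n_case <- 0L; n_ctrl <- 0L; batches <- 0L
  while ((n_case < cfg$n_cases || n_ctrl < cfg$n_controls) && batches < max_batches) {
    batches <- batches + 1L
    d <- draw_batch(batch_n)
    s <- g_score(d)
    y <- stats::rbinom(batch_n, 1L, stats::plogis(intercept + s)) == 1L
    if (n_case < cfg$n_cases) {
      take <- which(y)[seq_len(min(sum(y), cfg$n_cases - n_case))]
      case_d[[batches]] <- d[take, , drop = FALSE]
      case_s[[batches]] <- s[take]
      n_case <- n_case + length(take)
    }
    if (n_ctrl < cfg$n_controls) {
      take <- which(!y)[seq_len(min(sum(!y), cfg$n_controls - n_ctrl))]
      ctrl_d[[batches]] <- d[take, , drop = FALSE]
      ctrl_s[[batches]] <- s[take]
      n_ctrl <- n_ctrl + length(take)
    }
  }
  if (n_case < cfg$n_cases || n_ctrl < cfg$n_controls)
    abort_ghd(sprintf(
      "could not draw %d cases and %d controls at prevalence %.3g within %d batches of %d draws",
      cfg$n_cases, cfg$n_controls, cfg$prevalence, max_batches, batch_n),
      "ghdpgs_unattainable_counts")

  dos <- rbind(do.call(rbind, case_d), do.call(rbind, ctrl_d))
  liab <- intercept + c(unlist(case_s), unlist(ctrl_s))
  status <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  n <- nrow(dos)
  ids <- sprintf("S%06d", seq_len(n))

  # BMI: blend of standardized genetic score and noise, optional case shift
  set.seed(child_seed(cfg$seed, 3L))
  gsc <- liab - intercept
  zg <- if (stats::sd(gsc) > 0) as.numeric(scale(gsc)) else numeric(n)
  rho <- cfg$bmi_genetic_corr
  bmi <- cfg$bmi_mean + cfg$bmi_sd * (rho * zg + sqrt(1 - rho^2) * stats::rnorm(n)) +
    cfg$bmi_case_shift * (status == "case")
  for (i in 1:100) {
    low <- which(bmi < 18.5)
    if (!length(low)) break
    bmi[low] <- cfg$bmi_mean + cfg$bmi_sd * (rho * zg[low] +
      sqrt(1 - rho^2) * stats::rnorm(length(low))) +
      cfg$bmi_case_shift * (status[low] == "case")
  }
  bmi[bmi < 18.5] <- 18.5

  codes <- assign_sim_codes(status, child_seed(cfg$seed, 4L))

  # missingness injection (dosages and BMI)
  if (cfg$missing_rate > 0) {
    set.seed(child_seed(cfg$seed, 5L))
    dos[stats::runif(length(dos)) < cfg$missing_rate] <- NA_integer_
    bmi[stats::runif(n) < cfg$missing_rate] <- NA_real_
  }

  geno <- genotype_matrix(dos, sample_ids = ids, snp_ids = map$snp, map = map)
  cohort <- ghd_cohort(ids, status, bmi = bmi, diagnosis_codes = codes,
                       true_liability = liab)
  list(genotypes = geno, cohort = cohort, true_weights = w)
}

# Diagnosis-code menus: cases are a mix of self-report (pseudo-code SR1073),
# preeclampsia codes (O14.x) and gestational hypertension without proteinuria
# (O13); controls carry a live-birth code; a small control fraction also gets
# a gestational-diabetes code (O24.x) so exclusion rules are exercised.
assign_sim_codes <- function(status, seed) {
  set.seed(seed)
  n <- length(status)
  codes <- vector("list", n)
  case_menu <- list("SR1073", "O14.0", "O14.1", "O14.9", "O13", "O15.0")
  case_p <- c(0.55, 0.12, 0.08, 0.05, 0.17, 0.03)
  live_menu <- c("Z34.8", "Z37.0", "Z37.2", "Z37.3", "Z37.5", "Z37.6",
                 "Z38.1", "Z38.3", "Z38.6", "Z39")
  is_case <- status == "case"
  pick <- sample(seq_along(case_menu), sum(is_case), replace = TRUE, prob = case_p)
  codes[is_case] <- lapply(pick, function(k)
    unique(c(case_menu[[k]], sample(live_menu, 1L))))
  ctrl_idx <- which(!is_case)
  excl <- stats::runif(length(ctrl_idx)) < 0.03
  codes[ctrl_idx] <- lapply(seq_along(ctrl_idx), function(i) {
    base <- sample(live_menu, 1L)
    if (excl[i]) c(base, sample(c("O24.0", "O24.9", "E10"), 1L)) else base
  })
  codes
}

#' Per-SNP univariate logistic GWAS on a cohort
#'
#' Fits one univariate logistic regression per SNP of case/control status on
#' the (mean-imputed) dosage and reports the Wald effect, SE and two-sided
#' p-value — a stand-in for externally supplied GWAS summary statistics.
#' Monomorphic SNPs are flagged: beta and SE are `NA` and p is 1 by
#' convention.
#'
#' @param genotypes a [genotype_matrix()].
#' @param cohort a [ghd_cohort()] with both statuses present (>= 2 each).
#' @return data.frame with columns `snp, chrom, pos, effect_allele,
#'   other_allele, beta, se, p, monomorphic`.
#' @export
simulate_gwas_summary <- function(genotypes, cohort) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(cohort, "ghd_cohort"))
  y <- as.integer(cohort$status == "case")
  if (sum(y) < 2 || sum(1 - y) < 2)
    abort_ghd("need at least 2 samples in each status group", "ghdpgs_insufficient_groups")
  d <- impute_mean_dosage(genotypes$dosages)
  m <- ncol(d)
  beta <- se <- rep(NA_real_, m); p <- rep(1, m)
  mono <- apply(d, 2, function(x) stats::var(x) == 0)
  for (j in which(!mono)) {
    fit <- stats::glm.fit(cbind(1, d[, j]), y, family = stats::binomial())
    cf <- fit$coefficients[2]
    # SE from the inverse observed information
    X <- cbind(1, d[, j])
    wgt <- fit$weights
    vc <- tryCatch(solve(crossprod(X, X * wgt)), error = function(e) NULL)
    if (is.null(vc) || !is.finite(vc[2, 2])) { mono[j] <- TRUE; next }
    beta[j] <- cf
    se[j] <- sqrt(vc[2, 2])
    p[j] <- 2 * stats::pnorm(abs(cf / se[j]), lower.tail = FALSE)
  }
  out <- genotypes$map
  out$beta <- beta; out$se <- se; out$p <- p; out$monomorphic <- mono
  out
}

# per-column mean imputation of missing dosages (kept on the dosage scale,
# i.e. 2 x allele frequency)
impute_mean_dosage <- function(d) {
  if (!anyNA(d)) return(d)
  mns <- colMeans(d, na.rm = TRUE)
  mns[is.nan(mns)] <- 0
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mns[idx[, 2]]
  d
}

#' Construct a Mendelian-randomization instrument set
#'
#' @param snp_ids unique identifiers.
#' @param beta_exposure,se_exposure per-SNP exposure effect and SE (> 0).
#' @param beta_outcome,se_outcome per-SNP outcome effect and SE (> 0).
#' @param p_exposure per-SNP exposure p-value.
#' @return object of class `mr_instruments`.
#' @export
mr_instruments <- function(snp_ids, beta_exposure, se_exposure,
                           beta_outcome, se_outcome, p_exposure = NULL) {
  n <- length(snp_ids)
  stopifnot(!anyDuplicated(snp_ids),
            length(beta_exposure) == n, length(se_exposure) == n,
            length(beta_outcome) == n, length(se_outcome) == n,
            all(se_exposure > 0), all(se_outcome > 0))
  if (is.null(p_exposure))
    p_exposure <- 2 * stats::pnorm(abs(beta_exposure / se_exposure), lower.tail = FALSE)
  structure(list(snp_ids = as.character(snp_ids),
                 beta_exposure = as.numeric(beta_exposure),
                 se_exposure = as.numeric(se_exposure),
                 beta_outcome = as.numeric(beta_outcome),
                 se_outcome = as.numeric(se_outcome),
                 p_exposure = as.numeric(p_exposure)),
            class = "mr_instruments")
}

#' Simulate two-sample MR instruments with known causal effect
#'
#' Exposure effects are drawn from N(`exposure_beta_mean`,
#' `exposure_beta_sd`^2); outcome effects are
#' `causal_beta * beta_exposure + pleiotropy_mean + e`, with
#' `e ~ N(0, (noise_sd * se_outcome)^2)` per SNP, so `noise_sd = 0` gives the
#' noiseless limit where every per-instrument ratio equals `causal_beta`
#' (when `pleiotropy_mean = 0`).
#'
#' @param n_instruments number of instruments (>= 2).
#' @param causal_beta true causal effect of exposure on outcome.
#' @param pleiotropy_mean average directional pleiotropy added to every
#'   outcome effect (the MR-Egger intercept recovers it).
#' @param seed integer seed.
#' @param exposure_beta_mean,exposure_beta_sd exposure effect distribution.
#' @param se_exposure_range,se_outcome_range uniform ranges for per-SNP SEs.
#' @param noise_sd multiplier on `se_outcome` for the outcome noise.
#' @return an [mr_instruments()] object.
#' @export
simulate_mr_instruments <- function(n_instruments, causal_beta,
                                    pleiotropy_mean = 0, seed = 1L,
                                    exposure_beta_mean = 0.15,
                                    exposure_beta_sd = 0.05,
                                    se_exposure_range = c(0.01, 0.02),
                                    se_outcome_range = c(0.02, 0.05),
                                    noise_sd = 1) {
  stopifnot(n_instruments >= 2)
  set.seed(as.integer(seed))
  bx <- stats::rnorm(n_instruments, exposure_beta_mean, exposure_beta_sd)
  sx <- stats::runif(n_instruments, se_exposure_range[1], se_exposure_range[2])
  sy <- stats::runif(n_instruments, se_outcome_range[1], se_outcome_range[2])
  by <- causal_beta * bx + pleiotropy_mean +
    stats::rnorm(n_instruments, 0, noise_sd * sy)
  mr_instruments(sprintf("iv%04d", seq_len(n_instruments)),
                 bx, sx, by, sy)
}
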