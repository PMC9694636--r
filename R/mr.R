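#' Select and harmonize genetic instruments
#'
#' Keeps rows with exposure p-value strictly below the genome-wide
#' significance threshold (default 5e-8) and harmonizes signs so every
#' exposure effect is positive, flipping the matching outcome effect in
#' tandem. Fewer than 2 retained instruments is allowed here but the IVW and
#' Egger estimators will refuse such a set.
#'
#' @param instruments an [mr_instruments()] object (or data.frame with the
#'   same fields).
#' @param threshold exposure p-value threshold (default 5e-8).
#' @return an [mr_instruments()] with the retained, harmonized rows.
#' @export
select_instruments <- function(instruments, threshold = 5e-8) {
  x <- instruments
  keep <- x$p_exposure < threshold
  flip <- x$beta_exposure < 0
  bx <- ifelse(flip, -x$beta_exposure, x$beta_exposure)
  by <- ifelse(flip, -x$beta_outcome, x$beta_outcome)
  mr_instruments(x$snp_ids[keep], bx[keep], x$se_exposure[keep],
                 by[keep], x$se_outcome[keep], x$p_exposure[keep])
}

mr_result <- function(method, beta, se, alpha = 0.05,
                      egger_intercept = NA_real_, intercept_se = NA_real_,
                      intercept_p = NA_real_, n_instruments = NA_integer_) {
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(method = method, beta = beta, se = se, or = exp(beta),
                 ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                 alpha = alpha, egger_intercept = egger_intercept,
                 intercept_se = intercept_se, intercept_p = intercept_p,
                 pleiotropy_flag = isTRUE(intercept_p < 0.05),
                 n_instruments = n_instruments),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result:%s> beta %.4f (se %.4f), OR %.3f [%.3f-%.3f], k=%d\n",
              x$method, x$beta, x$se, x$or, x$ci_low, x$ci_high,
              x$n_instruments))
  if (x$method == "Egger")
    cat(sprintf("  intercept %.4f (p = %.3g)%s\n", x$egger_intercept,
                x$intercept_p,
                if (x$pleiotropy_flag) " [pleiotropy flagged]" else ""))
  invisible(x)
}

#' Single-instrument ratio (Wald ratio) estimate
#'
#' `beta = beta_outcome / beta_exposure` with the first-order SE
#' `se_outcome / |beta_exposure|`.
#'
#' @param beta_exposure,beta_outcome,se_outcome scalars.
#' @param alpha significance level.
#' @return an `mr_result` with method `"ratio"`.
#' @export
mr_ratio <- function(beta_exposure, beta_outcome, se_outcome, alpha = 0.05) {
  stopifnot(beta_exposure != 0, se_outcome > 0)
  mr_result("ratio", beta_outcome / beta_exposure,
            se_outcome / abs(beta_exposure), alpha, n_instruments = 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect IVW:
#' `beta = sum(bx * by / sy^2) / sum(bx^2 / sy^2)` and
#' `se = sqrt(1 / sum(bx^2 / sy^2))` — equivalently the weighted
#' through-the-origin regression of outcome on exposure effects. With
#' `random_effects = TRUE`, the SE is inflated by
#' `max(1, sqrt(Q / (k - 1)))` (multiplicative random-effects model).
#'
#' @param instruments an [mr_instruments()] with >= 2 rows.
#' @param alpha significance level (default 0.05).
#' @param random_effects inflate the SE by the residual overdispersion.
#' @return an `mr_result` with method `"IVW"`.
#' @export
ivw_estimate <- function(instruments, alpha = 0.05, random_effects = FALSE) {
  x <- instruments
  k <- length(x$snp_ids)
  if (k < 2)
    abort_ghd("IVW needs at least 2 instruments", "ghdpgs_too_few_instruments")
  if (any(x$se_outcome == 0))
    abort_ghd("outcome SEs must be positive", "ghdpgs_zero_se")
  w <- 1 / x$se_outcome^2
  denom <- sum(x$beta_exposure^2 * w)
  beta <- sum(x$beta_exposure * x$beta_outcome * w) / denom
  se <- sqrt(1 / denom)
  if (random_effects) {
    q <- sum(w * (x$beta_outcome - beta * x$beta_exposure)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  mr_result("IVW", beta, se, alpha, n_instruments = k)
}

#' MR-Egger regression with pleiotropy intercept test
#'
#' Weighted least squares of outcome effects on exposure effects with
#' weights `1/se_outcome^2` and a free intercept. The slope is the causal
#' estimate; the intercept estimates average directional pleiotropy and is
#' tested two-sided against 0 using the t distribution with k-2 degrees of
#' freedom; `intercept_p < 0.05` raises the pleiotropy flag.
#'
#' @param instruments an [mr_instruments()] with >= 3 rows (harmonized so
#'   exposure effects vary).
#' @param alpha significance level for the slope CI (default 0.05).
#' @return an `mr_result` with method `"Egger"`.
#' @export
egger_estimate <- function(instruments, alpha = 0.05) {
  x <- instruments
  k <- length(x$snp_ids)
  if (k < 3)
    abort_ghd("MR-Egger needs at least 3 instruments",
              "ghdpgs_too_few_instruments")
  if (stats::var(x$beta_exposure) == 0)
    abort_ghd("degenerate design: all exposure effects equal",
              "ghdpgs_degenerate_design")
  fit <- stats::lm(x$beta_outcome ~ x$beta_exposure,
                   weights = 1 / x$se_outcome^2)
  sm <- summary(fit)$coefficients
  mr_result("Egger", beta = sm[2, 1], se = sm[2, 2], alpha,
            egger_intercept = sm[1, 1], intercept_se = sm[1, 2],
            intercept_p = 2 * stats::pt(abs(sm[1, 3]), df = k - 2,
                                        lower.tail = FALSE),
            n_instruments = k)
}

#' Filter MR results by odds-ratio effect size
#'
#' Keeps results whose OR changes the odds by at least 10%: `or >= 1.1` or
#' `or <= 0.9` (both boundaries inclusive); dropped results are reported via
#' `message()`.
#'
#' @param results list of `mr_result` objects.
#' @return the retained sublist.
#' @export
reporting_filter <- function(results) {
  keep <- vapply(results, function(r) r$or >= 1.1 || r$or <= 0.9, logical(1))
  for (r in results[!keep])
    message(sprintf("dropped %s result with OR %.3f (inside (0.9, 1.1))",
                    r$method, r$or))
  results[keep]
}
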