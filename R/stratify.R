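#' 2x2 contingency table for odds-ratio estimation
#'
#' @param a,b exposed cases / exposed controls.
#' @param c,d reference cases / reference controls.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0))
  if (a + b == 0 || c + d == 0)
    abort_ghd("inestimable: a+b and c+d must both be positive",
              "ghdpgs_inestimable")
  structure(as.list(cells), class = "contingency_table")
}

#' Wald odds ratio with confidence interval
#'
#' `OR = ad / bc`, `SE_log = sqrt(1/a + 1/b + 1/c + 1/d)`,
#' `CI = exp(log OR +/- z * SE_log)` with the exact normal quantile
#' (1.959964 at alpha 0.05, not 1.96). If any cell is zero, the
#' Haldane-Anscombe 0.5 correction is added to all four cells and flagged.
#' The interval is geometrically symmetric: `sqrt(ci_low * ci_high)` equals
#' the point estimate to machine precision.
#'
#' @param table a [contingency_table()] (or anything coercible via `a,b,c,d`
#'   fields).
#' @param alpha two-sided significance level (default 0.05).
#' @return object of class `or_estimate`: list with `odds_ratio`, `ci_low`,
#'   `ci_high`, `se_log`, `alpha`, `corrected`, `cells`.
#' @export
odds_ratio_wald <- function(table, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (!inherits(table, "contingency_table"))
    table <- contingency_table(table$a, table$b, table$c, table$d)
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se_log <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(odds_ratio = or,
                 ci_low = exp(log(or) - z * se_log),
                 ci_high = exp(log(or) + z * se_log),
                 se_log = se_log, alpha = alpha, corrected = corrected,
                 cells = table),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %.3f (%d%% CI %.3f-%.3f)%s\n", x$odds_ratio,
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              if (x$corrected) " [0.5-corrected]" else ""))
  invisible(x)
}

#' Odds ratio of a top score percentile versus the bottom half
#'
#' The exposed group is samples with percentile rank `>= 1 - top_fraction`;
#' the reference group is percentile rank `< bottom_fraction`.
#'
#' @param scores a `score_vector` from [compute_pgs()] (needs `percentile`).
#' @param labels case/control labels aligned with `scores` rows.
#' @param top_fraction exposed tail size, e.g. 0.01 for the top 1%.
#' @param bottom_fraction reference group size from the bottom (default 0.5).
#' @param alpha significance level (default 0.05).
#' @return list of class `stratum_result` with `stratum_label` and `estimate`
#'   (an [odds_ratio_wald()] result).
#' @export
top_vs_bottom_or <- function(scores, labels, top_fraction,
                             bottom_fraction = 0.5, alpha = 0.05) {
  stopifnot(top_fraction > 0, bottom_fraction > 0,
            top_fraction + bottom_fraction <= 1)
  y <- as_case01(labels)
  p <- scores$percentile
  exposed <- p >= 1 - top_fraction
  reference <- p < bottom_fraction
  if (!any(exposed) || !any(reference))
    abort_ghd("empty exposed or reference group after thresholding",
              "ghdpgs_empty_group")
  est <- odds_ratio_wald(contingency_table(
    a = sum(y[exposed]), b = sum(!y[exposed]),
    c = sum(y[reference]), d = sum(!y[reference])), alpha)
  structure(list(stratum_label = sprintf("top %g%% vs bottom %g%%",
                                         100 * top_fraction,
                                         100 * bottom_fraction),
                 estimate = est),
            class = "stratum_result")
}

#' Assign PGS septiles
#'
#' Septile k holds samples with mid-rank percentile in `[(k-1)/7, k/7)` (the
#' last interval closed), so septile 4 spans ranks ~42.9-57.1% — the
#' medium-PGS reference band. With all scores tied, mid-ranking puts every
#' sample in one septile (degenerate, but well defined).
#'
#' @param scores a `score_vector` (or numeric vector of raw scores).
#' @return integer vector of septiles in 1..7.
#' @export
assign_septiles <- function(scores) {
  p <- if (is.data.frame(scores)) scores$percentile else percentile_rank(scores)
  stopifnot(length(p) >= 7)
  pmin(floor(p * 7) + 1L, 7L)
}

#' Assign BMI bands
#'
#' low = \[18.5, 25), medium = \[25, 30), high = \[30, Inf). Values below
#' 18.5 must have been filtered out upstream ([filter_bmi()]) and are an
#' error here.
#'
#' @param bmi numeric BMI values (kg/m^2), no missing values.
#' @return character vector in `c("low", "medium", "high")`.
#' @export
assign_bmi_band <- function(bmi) {
  if (anyNA(bmi) || any(bmi < 18.5))
    abort_ghd("BMI below 18.5 or missing: run filter_bmi() first",
              "ghdpgs_bmi_range")
  c("low", "medium", "high")[findInterval(bmi, c(18.5, 25, 30))]
}

#' BMI-band by PGS-septile odds-ratio grid
#'
#' Samples are cross-classified into 3 BMI bands x 7 PGS septiles; each of
#' the 21 strata is compared with the reference stratum (medium BMI, septile
#' 4) via [odds_ratio_wald()]. The reference stratum is reported with OR 1.
#'
#' @param cohort a [ghd_cohort()] with non-missing BMI >= 18.5 and a `status`
#'   column.
#' @param scores a `score_vector` aligned with the cohort rows.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per stratum: `bmi_band`, `septile`, `a`,
#'   `b` (stratum cases/controls), `or`, `ci_low`, `ci_high`, `corrected`,
#'   `reference`.
#' @export
bmi_pgs_grid <- function(cohort, scores, alpha = 0.05) {
  stopifnot(inherits(cohort, "ghd_cohort"), nrow(cohort) == nrow(scores))
  band <- assign_bmi_band(cohort$bmi)
  sept <- assign_septiles(scores)
  y <- as_case01(cohort$status)
  strata <- expand.grid(bmi_band = c("low", "medium", "high"), septile = 1:7,
                        stringsAsFactors = FALSE)
  in_stratum <- function(bd, sp) band == bd & sept == sp
  ref <- in_stratum("medium", 4L)
  rc <- sum(y[ref]); rd <- sum(!y[ref])
  if (rc < 1 || rd < 1)
    abort_ghd("reference stratum (medium BMI, septile 4) needs >=1 case and >=1 control",
              "ghdpgs_bad_reference")
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- in_stratum(strata$bmi_band[i], strata$septile[i])
    if (!any(sel))
      abort_ghd(sprintf("empty stratum (%s BMI, septile %d)",
                        strata$bmi_band[i], strata$septile[i]),
                "ghdpgs_empty_stratum")
    a <- sum(y[sel]); b <- sum(!y[sel])
    is_ref <- strata$bmi_band[i] == "medium" && strata$septile[i] == 4L
    if (is_ref) {
      data.frame(bmi_band = strata$bmi_band[i], septile = strata$septile[i],
                 a = a, b = b, or = 1, ci_low = 1, ci_high = 1,
                 corrected = FALSE, reference = TRUE)
    } else {
      est <- odds_ratio_wald(contingency_table(a, b, rc, rd), alpha)
      data.frame(bmi_band = strata$bmi_band[i], septile = strata$septile[i],
                 a = a, b = b, or = est$odds_ratio, ci_low = est$ci_low,
                 ci_high = est$ci_high, corrected = est$corrected,
                 reference = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$bmi_band, out$septile), ]
}
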