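#' Maximum-likelihood logistic regression on a dosage matrix
#'
#' Unpenalized fit by iteratively reweighted least squares (via
#' `stats::glm.fit`, epsilon 1e-8, at most 100 iterations), standard errors
#' from the inverse observed information, two-sided normal p-values. Perfect
#' or quasi-perfect separation (diverging coefficients or fitted
#' probabilities pinned at 0/1) is an error: a penalized fit would not match
#' the analysis model.
#'
#' @param dosages numeric matrix (samples x predictors), no missing values.
#' @param labels case/control labels (`"case"`/`"control"`, logical, or 0/1
#'   with 1 = case); both classes must be present.
#' @param on_separation `"error"` (default, the analysis-model contract) or
#'   `"allow"`: keep the last IRLS iterate, flagging `separation = TRUE`.
#'   The tolerant mode exists for cross-validation, where a separated
#'   training fold still yields a valid *ranking* of held-out samples.
#' @return list with `weights` (named), `intercept`, `se`, `z`, `p` (all
#'   including the intercept as first element of `se`/`z`/`p`), `loglik`,
#'   `aic`, `converged`, `separation`, `n`.
#' @export
fit_logistic <- function(dosages, labels,
                         on_separation = c("error", "allow")) {
  on_separation <- match.arg(on_separation)
  y <- as_case01(labels)
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == length(y))
  if (anyNA(dosages))
    abort_ghd("missing dosages: impute upstream", "ghdpgs_missing_dosage")
  if (length(unique(y)) < 2)
    abort_ghd("both classes must be present", "ghdpgs_one_class")
  X <- cbind(`(Intercept)` = 1, dosages)
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  cf <- fit$coefficients
  mu <- fit$fitted.values
  separated <- any(!is.finite(cf)) || any(abs(cf[-1]) > 15) ||
    (any(mu > 1 - 1e-10 | mu < 1e-10) && all((mu > 0.5) == (y == 1)))
  if (separated && on_separation == "error") {
    abort_ghd(paste0("(quasi-)separation detected: max |coef| = ",
                     format(max(abs(cf[-1])), digits = 3)),
              "ghdpgs_separation")
  }
  info <- crossprod(X, X * fit$weights)
  vc <- tryCatch(solve(info), error = function(e)
    abort_ghd("singular information matrix (collinear predictors?)",
              "ghdpgs_singular_fit"))
  se <- sqrt(diag(vc))
  z <- cf / se
  ll <- -fit$deviance / 2
  list(weights = cf[-1], intercept = unname(cf[1]),
       se = se, z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       loglik = ll, aic = 2 * length(cf) - 2 * ll,
       converged = fit$converged, separation = separated, n = length(y))
}

as_case01 <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("case", "control")))
    as.integer(labels == "case")
  } else {
    y <- as.integer(labels)
    stopifnot(all(y %in% c(0L, 1L)))
    y
  }
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random case scores above a random control, with
#' ties counted 1/2 — computed from mid-ranks, never from a fitted curve.
#'
#' @param scores numeric risk scores.
#' @param labels case/control labels (see [fit_logistic()]).
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  y <- as_case01(labels)
  n1 <- sum(y); n0 <- sum(1 - y)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: each class is split round-robin after a
# within-class shuffle, so every fold holds both classes
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validated AUC of a logistic model
#'
#' For each repeat, samples are split into stratified folds; a logistic model
#' is fit on the training folds and out-of-fold linear scores are pooled into
#' one vector per repeat, whose AUC is computed by [auc_mann_whitney()]. The
#' mean over repeats is the headline number.
#'
#' @param dosages predictor matrix (no missing values).
#' @param labels case/control labels.
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats (default 10).
#' @param seed integer seed for the fold shuffles.
#' @return list with `mean_auc`, `repeat_aucs`, `n_folds`, `n_repeats`,
#'   `seed`.
#' @export
cross_validated_auc <- function(dosages, labels, n_folds = 10, n_repeats = 10,
                                seed = 1L) {
  y <- as_case01(labels)
  dosages <- as.matrix(dosages)
  if (min(sum(y), sum(1 - y)) < n_folds)
    abort_ghd(sprintf(
      "smallest class has %d samples; stratified %d-fold CV needs at least %d",
      min(sum(y), sum(1 - y)), n_folds, n_folds), "ghdpgs_class_too_small")
  set.seed(as.integer(seed))
  repeat_aucs <- vapply(seq_len(n_repeats), function(r) {
    fold <- stratified_folds(y, n_folds)
    oof <- numeric(length(y))
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      fit <- suppressWarnings(
        fit_logistic(dosages[tr, , drop = FALSE], y[tr],
                     on_separation = "allow"))
      oof[!tr] <- dosages[!tr, , drop = FALSE] %*% fit$weights + fit$intercept
    }
    auc_mann_whitney(oof, y)
  }, numeric(1))
  list(mean_auc = mean(repeat_aucs), repeat_aucs = repeat_aucs,
       n_folds = n_folds, n_repeats = n_repeats, seed = as.integer(seed))
}
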