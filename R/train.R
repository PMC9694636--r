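#' Balanced control-resampling scheme
#'
#' The training procedure balances a case-control cohort by drawing several
#' control subsets, each `control_ratio` times the case count, and trains one
#' candidate model per subset.
#'
#' @param n_subsets number of balanced subsets (default 10).
#' @param control_ratio controls per case within a subset (default 4).
#' @param seed integer seed for the control draws.
#' @return object of class `resample_scheme`.
#' @export
resample_scheme <- function(n_subsets = 10, control_ratio = 4, seed = 1L) {
  stopifnot(n_subsets >= 1, control_ratio >= 1)
  structure(list(n_subsets = as.integer(n_subsets),
                 control_ratio = as.integer(control_ratio),
                 seed = as.integer(seed)),
            class = "resample_scheme")
}

#' Draw balanced case/control index subsets
#'
#' Each subset contains every case plus `control_ratio * n_cases` controls
#' sampled without replacement (independently across subsets).
#'
#' @param cohort a [ghd_cohort()] with a `status` column.
#' @param scheme a [resample_scheme()].
#' @return list of length `n_subsets`; each element a list with integer row
#'   indexes `case_idx` and `control_idx` into `cohort`.
#' @export
balance_controls <- function(cohort, scheme = resample_scheme()) {
  stopifnot(inherits(cohort, "ghd_cohort"), inherits(scheme, "resample_scheme"))
  case_idx <- which(cohort$status == "case")
  ctrl_idx <- which(cohort$status == "control")
  need <- scheme$control_ratio * length(case_idx)
  if (length(ctrl_idx) < need)
    abort_ghd(sprintf("need %d controls (%d cases x ratio %d) but only %d available",
                      need, length(case_idx), scheme$control_ratio,
                      length(ctrl_idx)),
              "ghdpgs_insufficient_controls")
  set.seed(child_seed(scheme$seed, 10L))
  lapply(seq_len(scheme$n_subsets), function(i)
    list(case_idx = case_idx,
         control_idx = sort(sample(ctrl_idx, need))))
}

#' Iterative variance-inflation-factor screen
#'
#' VIF of predictor j is `1 / (1 - R2_j)` where `R2_j` is from the linear
#' regression of column j on the remaining columns (computed via the inverse
#' correlation matrix). The SNP with the largest VIF is dropped until all
#' VIFs fall below `vif_threshold`; exactly collinear columns (singular
#' correlation matrix) are removed first by QR rank detection, reported with
#' infinite VIF.
#'
#' @param dosages numeric matrix (samples x SNPs) or [genotype_matrix()];
#'   missing entries mean-imputed.
#' @param vif_threshold drop threshold (> 1), default 10.
#' @return list with `retained` (ids), `dropped` (ids), `vif` (named vector
#'   for the retained set).
#' @export
collinearity_screen <- function(dosages, vif_threshold = 10) {
  stopifnot(vif_threshold > 1)
  if (inherits(dosages, "genotype_matrix")) dosages <- dosages$dosages
  d <- impute_mean_dosage(as.matrix(dosages))
  stopifnot(ncol(d) >= 2)
  ids <- colnames(d) %||% paste0("snp", seq_len(ncol(d)))
  colnames(d) <- ids
  v <- apply(d, 2, stats::var)
  if (any(v == 0))
    abort_ghd(paste0("zero-variance SNP(s): ",
                     paste(ids[v == 0], collapse = ", ")),
              "ghdpgs_zero_variance")
  dropped <- character()
  # remove exact linear dependencies first (QR with pivoting)
  repeat {
    qrd <- qr(scale(d, center = TRUE, scale = FALSE))
    if (qrd$rank == ncol(d)) break
    gone <- colnames(d)[qrd$pivot[(qrd$rank + 1):ncol(d)]][1]
    dropped <- c(dropped, gone)
    d <- d[, colnames(d) != gone, drop = FALSE]
    if (ncol(d) < 2) break
  }
  vifs <- function(m) {
    if (ncol(m) < 2) return(stats::setNames(rep(1, ncol(m)), colnames(m)))
    diag(solve(stats::cor(m)))
  }
  vf <- vifs(d)
  while (max(vf) >= vif_threshold && ncol(d) > 1) {
    gone <- colnames(d)[which.max(vf)]
    dropped <- c(dropped, gone)
    d <- d[, colnames(d) != gone, drop = FALSE]
    vf <- vifs(d)
  }
  list(retained = colnames(d), dropped = dropped,
       vif = stats::setNames(as.numeric(vf), colnames(d)))
}

#' A trained polygenic risk score model
#'
#' @param snp_ids ordered unique SNP ids.
#' @param weights finite per-SNP log-odds weights.
#' @param intercept fitted intercept (not used for ranking).
#' @param effect_alleles per-SNP effect allele labels.
#' @param training_auc mean cross-validated AUC of the selected model.
#' @param provenance list of config + seed metadata.
#' @return object of class `pgs_model`.
#' @export
pgs_model <- function(snp_ids, weights, intercept = 0,
                      effect_alleles = rep("A", length(snp_ids)),
                      training_auc = NA_real_, provenance = list()) {
  stopifnot(length(weights) == length(snp_ids), !anyDuplicated(snp_ids),
            all(is.finite(weights)),
            is.na(training_auc) || (training_auc >= 0 && training_auc <= 1))
  structure(list(snp_ids = as.character(snp_ids),
                 weights = stats::setNames(as.numeric(weights), snp_ids),
                 intercept = as.numeric(intercept),
                 effect_alleles = as.character(effect_alleles),
                 training_auc = training_auc, provenance = provenance),
            class = "pgs_model")
}

#' @export
print.pgs_model <- function(x, ...) {
  cat(sprintf("<pgs_model> %d SNPs, training AUC %.3f\n",
              length(x$snp_ids), x$training_auc))
  invisible(x)
}

#' Train a PGS by balanced resampling with CV-AUC model selection
#'
#' For each balanced subset: collinearity screen, unpenalized logistic fit,
#' and repeated stratified cross-validated AUC. The subset whose model has
#' the highest mean CV AUC becomes the returned [pgs_model()]; ties are
#' broken by fewer SNPs, then by lower subset index.
#'
#' @param cohort a [ghd_cohort()].
#' @param genotypes a [genotype_matrix()] covering `snp_panel`.
#' @param snp_panel character vector of (clumped) candidate SNP ids.
#' @param scheme a [resample_scheme()].
#' @param n_folds,n_repeats CV configuration (defaults 10 x 10).
#' @param vif_threshold collinearity screen threshold (default 10).
#' @return a [pgs_model()]; `provenance$subset_aucs` holds every candidate's
#'   mean CV AUC and `provenance$selected_subset` the winner's index.
#' @export
train_pgs <- function(cohort, genotypes, snp_panel, scheme = resample_scheme(),
                      n_folds = 10, n_repeats = 10, vif_threshold = 10) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  missing <- setdiff(snp_panel, genotypes$snp_ids)
  if (length(missing))
    abort_ghd(paste0("panel SNPs absent from genotypes: ",
                     paste(missing, collapse = ", ")), "ghdpgs_missing_snp")
  subsets <- balance_controls(cohort, scheme)
  d_all <- impute_mean_dosage(genotypes$dosages[, snp_panel, drop = FALSE])
  candidates <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    idx <- c(subsets[[i]]$case_idx, subsets[[i]]$control_idx)
    y <- as.integer(cohort$status[idx] == "case")
    d <- d_all[idx, , drop = FALSE]
    scr <- collinearity_screen(d, vif_threshold)
    d <- d[, scr$retained, drop = FALSE]
    fit <- fit_logistic(d, y)
    cv <- cross_validated_auc(d, y, n_folds, n_repeats,
                              seed = child_seed(scheme$seed, 20L + i %% 80L))
    candidates[[i]] <- list(fit = fit, cv = cv, snps = scr$retained,
                            dropped = scr$dropped, idx = idx)
  }
  aucs <- vapply(candidates, function(cnd) cnd$cv$mean_auc, numeric(1))
  nsnp <- vapply(candidates, function(cnd) length(cnd$snps), integer(1))
  best <- order(-aucs, nsnp, seq_along(candidates))[1]
  cnd <- candidates[[best]]
  ea <- genotypes$map$effect_allele[match(cnd$snps, genotypes$map$snp)]
  pgs_model(cnd$snps, cnd$fit$weights, cnd$fit$intercept,
            effect_alleles = ea, training_auc = cnd$cv$mean_auc,
            provenance = list(
              scheme = unclass(scheme), n_folds = n_folds,
              n_repeats = n_repeats, vif_threshold = vif_threshold,
              subset_aucs = aucs, selected_subset = best,
              dropped_collinear = cnd$dropped,
              subset_rows = cnd$idx))
}

#' Forward stepwise logistic selection by AIC
#'
#' Starting from the intercept-only model, repeatedly add the candidate SNP
#' whose addition minimizes AIC (`2k - 2 logLik`); stop when no addition
#' lowers the AIC. Weights are from the final refit.
#'
#' @param dosages predictor matrix (missing entries mean-imputed).
#' @param labels case/control labels.
#' @param candidates candidate SNP ids (columns of `dosages`); default all.
#' @return a [pgs_model()] on the selected SNPs; `provenance$aic_path` holds
#'   the AIC after each accepted step (intercept-only first).
#' @export
stepwise_aic <- function(dosages, labels, candidates = colnames(dosages)) {
  if (inherits(dosages, "genotype_matrix")) dosages <- dosages$dosages
  d <- impute_mean_dosage(as.matrix(dosages))
  y <- as_case01(labels)
  stopifnot(length(candidates) >= 1, all(candidates %in% colnames(d)))
  null_ll <- {
    p1 <- mean(y)
    sum(y) * log(p1) + sum(1 - y) * log(1 - p1)
  }
  current <- character()
  aic_path <- 2 * 1 - 2 * null_ll
  best_fit <- NULL
  repeat {
    pool <- setdiff(candidates, current)
    if (!length(pool)) break
    trial <- vapply(pool, function(s) {
      fit <- tryCatch(fit_logistic(d[, c(current, s), drop = FALSE], y),
                      ghdpgs_error = function(e) NULL)
      if (is.null(fit)) Inf else fit$aic
    }, numeric(1))
    if (min(trial) >= aic_path[length(aic_path)] - 1e-10) break
    add <- pool[which.min(trial)]
    current <- c(current, add)
    best_fit <- fit_logistic(d[, current, drop = FALSE], y)
    aic_path <- c(aic_path, best_fit$aic)
  }
  if (!length(current))
    return(pgs_model(character(), numeric(), intercept = stats::qlogis(mean(y)),
                     effect_alleles = character(),
                     provenance = list(aic_path = aic_path)))
  pgs_model(current, best_fit$weights, best_fit$intercept,
            provenance = list(aic_path = aic_path))
}
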