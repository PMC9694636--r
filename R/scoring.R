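#' Mid-rank percentile ranks
#'
#' Fraction of the cohort scoring strictly lower plus half the tied fraction;
#' equal scores share a rank, and ranks lie strictly inside (0, 1).
#'
#' @param x numeric scores.
#' @return numeric vector of percentile ranks.
#' @export
percentile_rank <- function(x) {
  (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Score a cohort with a PGS model
#'
#' `score_s = sum_i w_i g_{s,i}` over the model SNPs, with missing dosages
#' mean-imputed per SNP. Every model SNP must be present in the genotypes;
#' when a model SNP's effect allele matches the genotype file's *other*
#' allele, the dosage is flipped (`2 - g`) before scoring. Percentile ranks
#' are computed against the scored cohort itself (mid-rank convention), so
#' per-sample scores are independent of cohort composition but ranks are not.
#'
#' @param model a [pgs_model()].
#' @param genotypes a [genotype_matrix()].
#' @param include_intercept add the model intercept to every score (does not
#'   affect ranks); default `FALSE`.
#' @return data.frame of class `score_vector` with columns `sample_id`,
#'   `pgs`, `percentile`.
#' @export
compute_pgs <- function(model, genotypes, include_intercept = FALSE) {
  stopifnot(inherits(model, "pgs_model"), inherits(genotypes, "genotype_matrix"))
  missing <- setdiff(model$snp_ids, genotypes$snp_ids)
  if (length(missing))
    abort_ghd(paste0("model SNPs absent from genotypes: ",
                     paste(missing, collapse = ", ")), "ghdpgs_missing_snp")
  d <- impute_mean_dosage(genotypes$dosages[, model$snp_ids, drop = FALSE])
  geno_ea <- genotypes$map$effect_allele[match(model$snp_ids, genotypes$map$snp)]
  geno_oa <- genotypes$map$other_allele[match(model$snp_ids, genotypes$map$snp)]
  flip <- model$effect_alleles != geno_ea
  if (any(flip)) {
    bad <- flip & model$effect_alleles != geno_oa
    if (any(bad))
      abort_ghd(paste0("effect allele mismatch (not flippable) for: ",
                       paste(model$snp_ids[bad], collapse = ", ")),
                "ghdpgs_allele_conflict")
    d[, flip] <- 2 - d[, flip]
  }
  scores <- drop(d %*% model$weights)
  if (include_intercept) scores <- scores + model$intercept
  out <- data.frame(sample_id = genotypes$sample_ids,
                    pgs = as.numeric(scores),
                    percentile = percentile_rank(scores),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  out
}
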