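#' Build a SNP record table
#'
#' The working unit of variant selection: one row per SNP with genomic
#' coordinates, alleles, association p-value and a provenance tag.
#'
#' @param snp,chrom,pos,effect_allele,other_allele,p,source per-SNP columns;
#'   `pos` 1-based, `p` in (0, 1].
#' @return data.frame of class `snp_records`.
#' @export
snp_records <- function(snp, chrom, pos, effect_allele, other_allele, p,
                        source = "unknown") {
  stopifnot(all(pos >= 1), all(p > 0), all(p <= 1))
  out <- data.frame(snp = as.character(snp), chrom = as.character(chrom),
                    pos = as.integer(pos),
                    effect_allele = as.character(effect_allele),
                    other_allele = as.character(other_allele),
                    p = as.numeric(p),
                    source = rep_len(as.character(source), length(snp)),
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_records", "data.frame")
  out
}

as_snp_records <- function(df, source = "unknown") {
  snp_records(df$snp, df$chrom, df$pos, df$effect_allele, df$other_allele,
              df$p, df$source %||% source)
}

#' Select SNPs below a p-value cutoff
#'
#' Strict inequality: a record with `p` exactly equal to the cutoff is
#' excluded. Input order is preserved.
#'
#' @param records a [snp_records()] table.
#' @param cutoff p-value cutoff in (0, 1); default the conventional
#'   suggestive-association threshold 1e-5.
#' @return the selected subset, same class.
#' @export
select_by_pvalue <- function(records, cutoff = 1e-5) {
  stopifnot(cutoff > 0, cutoff < 1)
  out <- records[records$p < cutoff, , drop = FALSE]
  class(out) <- class(records)
  out
}

#' Merge SNP lists from several sources
#'
#' Deduplicates by SNP id with first-seen-wins, recording every source that
#' contributed each id; ids listed in `known_missing` (e.g. variants absent
#' from the genotyped panel) are dropped and reported. Conflicting effect
#' alleles for one id across sources are an error.
#'
#' @param lists list of [snp_records()] tables, each with a `source` tag.
#' @param known_missing SNP ids to drop.
#' @return list with `records` (deduplicated [snp_records()] plus a `sources`
#'   column), and `report` (per-source counts, distinct count, dropped ids).
#' @export
merge_snp_sources <- function(lists, known_missing = character()) {
  stopifnot(is.list(lists), length(lists) > 0)
  all_rec <- do.call(rbind, lapply(lists, function(x) as.data.frame(x)))
  per_source <- table(all_rec$source)
  # effect-allele consistency across sources
  ea <- tapply(all_rec$effect_allele, all_rec$snp, unique)
  bad <- names(ea)[vapply(ea, length, integer(1)) > 1]
  if (length(bad))
    abort_ghd(paste0("conflicting effect alleles for: ",
                     paste(bad, collapse = ", ")), "ghdpgs_allele_conflict")
  sources <- tapply(all_rec$source, all_rec$snp, function(s)
    paste(unique(s), collapse = ";"))
  keep <- !duplicated(all_rec$snp)
  rec <- all_rec[keep, , drop = FALSE]
  rec$sources <- unname(sources[rec$snp])
  dropped <- intersect(rec$snp, known_missing)
  rec <- rec[!rec$snp %in% known_missing, , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("snp_records", "data.frame")
  list(records = rec,
       report = list(per_source = per_source,
                     distinct = nrow(rec),
                     dropped_missing = dropped))
}

#' LD matrix of squared dosage correlations
#'
#' @param snp_ids identifiers.
#' @param r2 symmetric matrix in \[0,1\] with unit diagonal.
#' @return object of class `ld_matrix`.
#' @export
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == nrow(r2), nrow(r2) == ncol(r2),
            all(r2 >= -1e-12), all(r2 <= 1 + 1e-12),
            max(abs(r2 - t(r2))) < 1e-12,
            all(abs(diag(r2) - 1) < 1e-12))
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2),
            class = "ld_matrix")
}

#' Estimate pairwise LD (r-squared) from dosages
#'
#' r2 is the squared Pearson correlation of dosage vectors after per-SNP
#' mean imputation of missing entries. Zero-variance (monomorphic) SNPs
#' cannot be correlated and are excluded, with their ids reported.
#'
#' @param genotypes a [genotype_matrix()] with >= 2 samples.
#' @return list with `ld` ([ld_matrix()]) and `excluded` (zero-variance ids).
#' @export
estimate_ld <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            nrow(genotypes$dosages) >= 2)
  d <- impute_mean_dosage(genotypes$dosages)
  v <- apply(d, 2, stats::var)
  excluded <- colnames(d)[v == 0]
  d <- d[, v > 0, drop = FALSE]
  r2 <- stats::cor(d)^2
  r2 <- (r2 + t(r2)) / 2   # symmetrize away float noise
  diag(r2) <- 1
  list(ld = ld_matrix(colnames(d), r2), excluded = excluded)
}

#' Greedy LD clumping
#'
#' PLINK-style: repeatedly take the lowest-p unclaimed SNP as an index and
#' claim all unclaimed SNPs on the same chromosome within `window_bp` whose
#' r2 with the index is `>= r2_threshold`; the retained set is the index
#' SNPs. Ties in p are broken by lexicographic SNP id, so the result does not
#' depend on input order.
#'
#' @param records a [snp_records()] table with chromosome and position set.
#' @param ld an [ld_matrix()] covering every record.
#' @param r2_threshold clumping r2 threshold in (0, 1\]; default 0.1.
#' @param window_bp clumping window in base pairs; default 250,000.
#' @return the retained records, in the order they were claimed as indexes.
#' @export
ld_clump <- function(records, ld, r2_threshold = 0.1, window_bp = 250000) {
  stopifnot(inherits(ld, "ld_matrix"), r2_threshold > 0, r2_threshold <= 1,
            window_bp >= 0)
  missing <- setdiff(records$snp, ld$snp_ids)
  if (length(missing))
    abort_ghd(paste0("records missing from LD matrix: ",
                     paste(missing, collapse = ", ")), "ghdpgs_missing_ld")
  ord <- order(records$p, records$snp)
  rec <- records[ord, , drop = FALSE]
  unclaimed <- rep(TRUE, nrow(rec))
  retained <- integer()
  while (any(unclaimed)) {
    i <- which(unclaimed)[1]
    retained <- c(retained, i)
    near <- which(unclaimed & rec$chrom == rec$chrom[i] &
                    abs(rec$pos - rec$pos[i]) <= window_bp)
    r2i <- ld$r2[rec$snp[i], rec$snp[near]]
    unclaimed[near[r2i >= r2_threshold]] <- FALSE
    unclaimed[i] <- FALSE
  }
  out <- rec[retained, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_records", "data.frame")
  out
}
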