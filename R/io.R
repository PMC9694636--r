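# TSV is the interchange format everywhere: one documented header row,
# tab-separated, no quoting surprises, readable by the paired reader.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Write / read a dosage matrix as TSV
#'
#' Samples x SNPs; first column `sample_id`, remaining columns one per SNP
#' (header row of SNP ids); missing dosages written as `NA`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path file path.
#' @return `path` invisibly (writer); a [genotype_matrix()] (reader — the
#'   SNP map is written alongside as `<path>.map.tsv` and read back).
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  df <- data.frame(sample_id = genotypes$sample_ids,
                   genotypes$dosages, check.names = FALSE)
  write_tsv(df, path)
  write_tsv(genotypes$map, paste0(path, ".map.tsv"))
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(d) <- "integer"
  map_path <- paste0(path, ".map.tsv")
  map <- if (file.exists(map_path)) read_tsv(map_path) else NULL
  if (!is.null(map)) map$chrom <- as.character(map$chrom)
  genotype_matrix(d, sample_ids = df$sample_id, snp_ids = colnames(d),
                  map = map)
}

#' Write / read a cohort table as TSV
#'
#' Columns `sample_id`, `status`, `bmi`, `codes` (semicolon-joined diagnosis
#' codes), `true_liability` (NA for real cohorts), and `label` when present.
#'
#' @param cohort a [ghd_cohort()].
#' @param path file path.
#' @return `path` invisibly (writer); a [ghd_cohort()] (reader).
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "ghd_cohort"))
  df <- data.frame(sample_id = cohort$sample_id, status = cohort$status,
                   bmi = cohort$bmi,
                   codes = vapply(cohort$diagnosis_codes, paste,
                                  character(1), collapse = ";"),
                   true_liability = cohort$true_liability)
  if (!is.null(cohort$label)) df$label <- cohort$label
  write_tsv(df, path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- read_tsv(path)
  codes <- strsplit(ifelse(is.na(df$codes), "", df$codes), ";", fixed = TRUE)
  out <- ghd_cohort(df$sample_id, df$status, bmi = df$bmi,
                    diagnosis_codes = codes,
                    true_liability = df$true_liability)
  if (!is.null(df$label)) out$label <- df$label
  out
}

#' Write / read GWAS summary statistics as TSV
#'
#' Columns `snp, chrom, pos, effect_allele, other_allele, beta, se, p`;
#' extra columns are preserved.
#'
#' @param sumstats data.frame with at least the listed columns.
#' @param path file path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_sumstats_tsv <- function(sumstats, path) {
  stopifnot(all(sumstat_cols %in% names(sumstats)))
  extra <- setdiff(names(sumstats), sumstat_cols)
  write_tsv(sumstats[, c(sumstat_cols, extra)], path)
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(sumstat_cols %in% names(df)))
  df$chrom <- as.character(df$chrom)
  df
}

#' Write / read a PGS scoring file
#'
#' PGS-Catalog-style TSV with columns `rsID, chr_name, chr_position,
#' effect_allele, other_allele, effect_weight`; training provenance
#' (resampling scheme, CV configuration, seeds, AUC) goes into a JSON
#' sidecar at `<path>.json`.
#'
#' @param model a [pgs_model()].
#' @param path file path for the TSV.
#' @param map optional bim-style data.frame supplying `chr_name` and
#'   `chr_position` per SNP (defaults to 0 when unknown).
#' @return `path` invisibly (writer); a [pgs_model()] (reader).
#' @export
write_scoring_file <- function(model, path, map = NULL) {
  stopifnot(inherits(model, "pgs_model"))
  idx <- if (!is.null(map)) match(model$snp_ids, map$snp) else
    rep(NA_integer_, length(model$snp_ids))
  other <- if (!is.null(map)) map$other_allele[idx] else
    rep("N", length(model$snp_ids))
  df <- data.frame(rsID = model$snp_ids,
                   chr_name = if (!is.null(map)) map$chrom[idx] else "0",
                   chr_position = if (!is.null(map)) map$pos[idx] else 0L,
                   effect_allele = model$effect_alleles,
                   other_allele = other,
                   effect_weight = unname(model$weights))
  write_tsv(df, path)
  jsonlite::write_json(
    list(intercept = model$intercept, training_auc = model$training_auc,
         provenance = model$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scoring_file
#' @export
read_scoring_file <- function(path) {
  df <- read_tsv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
    else list(intercept = 0, training_auc = NA_real_, provenance = list())
  pgs_model(df$rsID, df$effect_weight,
            intercept = meta$intercept %||% 0,
            effect_alleles = df$effect_allele,
            training_auc = meta$training_auc %||% NA_real_,
            provenance = meta$provenance %||% list())
}

#' Write per-sample scores as TSV
#'
#' Columns `sample_id`, `pgs`, `percentile`.
#' @param scores a `score_vector` from [compute_pgs()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) write_tsv(scores, path)

# --- PLINK 1 binary (bed/bim/fam) -------------------------------------------

# 2-bit codes, SNP-major: 00 = hom effect allele (dosage 2), 01 = missing,
# 10 = het, 11 = hom other allele (dosage 0). A1 in the .bim is the effect
# allele.
dosage_to_code <- function(g) {
  code <- integer(length(g))
  code[is.na(g)] <- 1L
  code[!is.na(g) & g == 2] <- 0L
  code[!is.na(g) & g == 1] <- 2L
  code[!is.na(g) & g == 0] <- 3L
  code
}

code_to_dosage <- c(2L, NA_integer_, 1L, 0L)  # indexed by code + 1

#' Write / read genotypes as PLINK 1 .bed/.bim/.fam
#'
#' SNP-major .bed with the standard magic bytes; `.bim` columns are
#' chromosome, SNP id, 0 cM, 1-based position, A1 = effect allele, A2 =
#' other allele; `.fam` carries sample ids with phenotype 2 for cases and 1
#' for controls when a cohort is supplied (0 = unknown otherwise).
#'
#' @param genotypes a [genotype_matrix()].
#' @param prefix path prefix (files `<prefix>.bed/.bim/.fam` are written).
#' @param cohort optional [ghd_cohort()] supplying case/control phenotypes.
#' @return `prefix` invisibly (writer); a list with `genotypes` and
#'   `phenotype` (reader).
#' @export
write_plink <- function(genotypes, prefix, cohort = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosages
  n <- nrow(d); m <- ncol(d)
  fam <- data.frame(fid = genotypes$sample_ids, iid = genotypes$sample_ids,
                    pat = 0L, mat = 0L, sex = 2L, phe = 0L)
  if (!is.null(cohort)) {
    st <- cohort$status[match(genotypes$sample_ids, cohort$sample_id)]
    fam$phe <- ifelse(is.na(st), 0L, ifelse(st == "case", 2L, 1L))
  }
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = genotypes$map$chrom, snp = genotypes$map$snp,
                    cm = 0L, pos = genotypes$map$pos,
                    a1 = genotypes$map$effect_allele,
                    a2 = genotypes$map$other_allele)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  npad <- 4L * ceiling(n / 4L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    code <- c(dosage_to_code(d[, j]), rep(3L, npad - n))
    cm <- matrix(code, nrow = 4L)
    bytes <- cm[1, ] + 4L * cm[2, ] + 16L * cm[3, ] + 64L * cm[4, ]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "snp", "cm", "pos", "a1", "a2")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + m * ceiling(n / 4))
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    abort_ghd("not a SNP-major PLINK .bed file", "ghdpgs_bad_bed")
  body <- as.integer(raw[-(1:3)])
  bps <- ceiling(n / 4)  # bytes per SNP
  # expand each byte into its four 2-bit codes
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  d <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    col_codes <- codes[, ((j - 1) * bps + 1):(j * bps)]
    d[, j] <- code_to_dosage[as.vector(col_codes)[seq_len(n)] + 1L]
  }
  map <- data.frame(snp = bim$snp, chrom = as.character(bim$chrom),
                    pos = bim$pos, effect_allele = bim$a1,
                    other_allele = bim$a2, stringsAsFactors = FALSE)
  geno <- genotype_matrix(d, sample_ids = fam$V2, snp_ids = bim$snp, map = map)
  phe <- ifelse(fam$V6 == 2L, "case", ifelse(fam$V6 == 1L, "control", NA))
  list(genotypes = geno, phenotype = phe)
}

#' Write / read MR instrument sets as TSV
#'
#' Columns `snp, beta_exposure, se_exposure, p_exposure, beta_outcome,
#' se_outcome`.
#'
#' @param instruments an [mr_instruments()].
#' @param path file path.
#' @return `path` invisibly (writer); an [mr_instruments()] (reader).
#' @export
write_instruments_tsv <- function(instruments, path) {
  x <- instruments
  write_tsv(data.frame(snp = x$snp_ids, beta_exposure = x$beta_exposure,
                       se_exposure = x$se_exposure, p_exposure = x$p_exposure,
                       beta_outcome = x$beta_outcome,
                       se_outcome = x$se_outcome), path)
}

#' @rdname write_instruments_tsv
#' @export
read_instruments_tsv <- function(path) {
  df <- read_tsv(path)
  mr_instruments(df$snp, df$beta_exposure, df$se_exposure,
                 df$beta_outcome, df$se_outcome, df$p_exposure)
}

#' Write MR results as TSV
#' @param results list of `mr_result` objects.
#' @param path file path.
#' @param labels optional per-result labels (e.g. exposure names).
#' @return `path`, invisibly.
#' @export
write_mr_results_tsv <- function(results, path, labels = NULL) {
  df <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(label = labels[i] %||% sprintf("result%d", i),
               method = r$method, beta = r$beta, se = r$se, or = r$or,
               ci_low = r$ci_low, ci_high = r$ci_high,
               egger_intercept = r$egger_intercept,
               intercept_p = r$intercept_p,
               n_instruments = r$n_instruments)
  }))
  write_tsv(df, path)
}
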