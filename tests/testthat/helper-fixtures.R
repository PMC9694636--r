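# Small in-code fixtures shared across test files.

# tiny genotype matrix with explicit dosages and a usable map
tiny_genotypes <- function(dosages, chrom = "1", pos = NULL,
                           effect_allele = "A", other_allele = "G") {
  m <- ncol(dosages)
  ids <- colnames(dosages) %||% paste0("rs", seq_len(m))
  map <- data.frame(snp = ids, chrom = rep_len(chrom, m),
                    pos = pos %||% (seq_len(m) * 1000L),
                    effect_allele = rep_len(effect_allele, m),
                    other_allele = rep_len(other_allele, m),
                    stringsAsFactors = FALSE)
  colnames(dosages) <- ids
  rownames(dosages) <- sprintf("S%06d", seq_len(nrow(dosages)))
  genotype_matrix(dosages, map = map)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# cohort with explicit codes; status defaults to control
tiny_cohort <- function(codes, status = rep("control", length(codes)),
                        bmi = 25) {
  ghd_cohort(sprintf("S%03d", seq_along(codes)), status, bmi = bmi,
             diagnosis_codes = codes)
}

# labels y ~ Bernoulli(plogis(b0 + X w)); returns list(X, y)
sim_logistic_data <- function(n, w, b0 = -1, seed = 1) {
  set.seed(seed)
  p <- length(w)
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  colnames(X) <- paste0("rs", seq_len(p))
  y <- rbinom(n, 1, plogis(b0 + drop(X %*% w)))
  list(X = X, y = y)
}
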