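# Independent oracles. These deliberately avoid the package's code paths:
# the AUC oracle enumerates pairs, the clumping oracle is a literal
# transcription of the greedy definition, and the logistic oracle maximizes
# the likelihood with optim().

# AUC by explicit enumeration of case-control pairs (ties count 1/2)
auc_by_enumeration <- function(scores, y) {
  cs <- scores[y == 1]; ct <- scores[y == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# greedy clumping, written directly from its definition with no shared code
clump_oracle <- function(rec, r2, r2_threshold, window_bp) {
  # rec: data.frame(snp, chrom, pos, p); r2: named square matrix
  claimed <- rep(FALSE, nrow(rec))
  retained <- character()
  repeat {
    open <- which(!claimed)
    if (!length(open)) break
    o <- open[order(rec$p[open], rec$snp[open])][1]
    retained <- c(retained, rec$snp[o])
    for (j in which(!claimed)) {
      if (j == o) next
      if (rec$chrom[j] == rec$chrom[o] &&
          abs(rec$pos[j] - rec$pos[o]) <= window_bp &&
          r2[rec$snp[o], rec$snp[j]] >= r2_threshold)
        claimed[j] <- TRUE
    }
    claimed[o] <- TRUE
  }
  retained
}

# random clumping instance of <= 12 SNPs on up to 2 chromosomes
random_clump_instance <- function(seed) {
  set.seed(seed)
  n <- sample(1:12, 1)
  rec <- data.frame(
    snp = sprintf("s%02d", sample(n)),
    chrom = as.character(sample(1:2, n, replace = TRUE)),
    pos = sample.int(500000L, n),
    p = signif(runif(n, 1e-10, 1e-2), 3),  # signif() provokes p ties
    stringsAsFactors = FALSE)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(rec$snp, rec$snp)
  list(rec = rec, r2 = m)
}

# maximum-likelihood logistic fit by direct optimisation (BFGS on the
# negative log-likelihood), independent of glm/IRLS
logistic_fit_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  gr <- function(b) drop(crossprod(X1, plogis(drop(X1 %*% b)) - y))
  opt <- optim(rep(0, ncol(X1)), nll, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  opt$par
}
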