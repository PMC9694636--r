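test_that("select_by_pvalue is strict and order-preserving", {
  rec <- snp_records(c("a", "b", "c"), "1", 1:3, "A", "G",
                     p = c(2e-6, 5e-5, 1e-5))
  out <- select_by_pvalue(rec, 1e-5)
  expect_equal(out$snp, "a")                       # 1e-5 exactly: excluded
  expect_equal(nrow(select_by_pvalue(rec, 1e-7)), 0)
  rec2 <- rec[c(3, 1, 2), ]
  expect_equal(select_by_pvalue(rec2, 1e-4)$snp, c("c", "a", "b"))
})

test_that("merge_snp_sources deduplicates, reports, and drops known-missing", {
  mk <- function(ids, src) snp_records(ids, "1", seq_along(ids), "A", "G",
                                       p = 1e-6, source = src)
  shared <- sprintf("sh%02d", 1:14)
  l1 <- mk(c(sprintf("a%03d", 1:315), shared), "neale")
  l2 <- mk(c(shared, sprintf("b%02d", 1:46)), "geneatlas")
  res <- merge_snp_sources(list(l1, l2),
                           known_missing = c("a001", "b01", "absent"))
  expect_equal(res$report$distinct, 373)  # 375 distinct minus 2 present-and-dropped
  expect_equal(sort(res$report$dropped_missing), c("a001", "b01"))
  expect_equal(as.integer(res$report$per_source[c("neale", "geneatlas")]),
               c(329L, 60L))
  expect_equal(sum(grepl("^sh", res$records$snp)), 14)
  expect_true(all(res$records$sources[grepl("^sh", res$records$snp)] ==
                    "neale;geneatlas"))
  # single list is the identity
  one <- merge_snp_sources(list(mk(c("x", "y"), "s")))
  expect_equal(one$records$snp, c("x", "y"))
})

test_that("conflicting effect alleles across sources fail loudly", {
  a <- snp_records("rs1", "1", 1, "A", "G", 1e-6, "s1")
  b <- snp_records("rs1", "1", 1, "C", "G", 1e-6, "s2")
  expect_error(merge_snp_sources(list(a, b)), "rs1",
               class = "ghdpgs_allele_conflict")
})

test_that("estimate_ld matches direct correlation and excludes constants", {
  set.seed(9)
  g1 <- rbinom(500, 2, 0.3)
  d <- cbind(a = g1, b = rbinom(500, 2, 0.4), dup = g1, mono = rep(1L, 500))
  res <- estimate_ld(tiny_genotypes(d))
  expect_equal(res$excluded, "mono")
  expect_equal(unname(res$ld$r2["a", "dup"]), 1)
  expect_equal(unname(diag(res$ld$r2)), rep(1, 3))
  expect_equal(unname(res$ld$r2["a", "b"]), unname(cor(g1, d[, "b"])^2))
  # independent SNPs at n = 10,000 have near-zero r2
  set.seed(10)
  d2 <- cbind(x = rbinom(10000, 2, 0.3), y = rbinom(10000, 2, 0.3))
  expect_lt(estimate_ld(tiny_genotypes(d2))$ld$r2["x", "y"], 0.01)
})

test_that("ld_clump reproduces the hand-traced greedy example", {
  rec <- snp_records(c("s1", "s2", "s3"), "1", c(1e5, 2e5, 3e5), "A", "G",
                     p = c(1e-8, 1e-7, 1e-6))
  r2 <- matrix(c(1, .5, .05, .5, 1, .05, .05, .05, 1), 3, 3)
  ld <- ld_matrix(rec$snp, r2)
  expect_equal(ld_clump(rec, ld, 0.1, 1e6)$snp, c("s1", "s3"))
  # single SNP trivially retained
  expect_equal(nrow(ld_clump(rec[1, ], ld, 0.1, 1e6)), 1)
  # high r2 across chromosomes is never clumped
  rec2 <- snp_records(c("u", "v"), c("1", "2"), c(100, 150), "A", "G",
                      p = c(1e-9, 1e-8))
  ld2 <- ld_matrix(c("u", "v"), matrix(c(1, .99, .99, 1), 2))
  expect_equal(nrow(ld_clump(rec2, ld2, 0.1, 1e6)), 2)
  # SNPs missing from the LD matrix are named in the failure
  expect_error(ld_clump(rec, ld_matrix("s1", matrix(1)), 0.1, 1e6),
               "s2", class = "ghdpgs_missing_ld")
})

test_that("clumping equals the brute-force oracle on random instances", {
  for (seed in 1:40) {
    inst <- random_clump_instance(seed)
    rec <- snp_records(inst$rec$snp, inst$rec$chrom, inst$rec$pos, "A", "G",
                       p = inst$rec$p)
    ld <- ld_matrix(inst$rec$snp, inst$r2)
    got <- ld_clump(rec, ld, 0.3, 100000)$snp
    want <- clump_oracle(inst$rec, inst$r2, 0.3, 100000)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("clumping is order-invariant and monotone in the r2 threshold", {
  inst <- random_clump_instance(99)
  rec <- snp_records(inst$rec$snp, inst$rec$chrom, inst$rec$pos, "A", "G",
                     p = inst$rec$p)
  ld <- ld_matrix(inst$rec$snp, inst$r2)
  base <- ld_clump(rec, ld, 0.3, 100000)$snp
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(ld_clump(shuf, ld, 0.3, 100000)$snp, base)
  sizes <- vapply(c(0.1, 0.3, 0.5, 0.8, 1), function(th)
    nrow(ld_clump(rec, ld, th, 100000)), integer(1))
  expect_true(all(diff(sizes) >= 0))
  # every removed SNP has r2 >= threshold with a retained SNP of <= p nearby
  removed <- setdiff(rec$snp, base)
  for (s in removed) {
    i <- match(s, rec$snp)
    ok <- any(vapply(base, function(r) {
      j <- match(r, rec$snp)
      rec$chrom[j] == rec$chrom[i] &&
        abs(rec$pos[j] - rec$pos[i]) <= 100000 &&
        inst$r2[r, s] >= 0.3 &&
        (rec$p[j] < rec$p[i] || (rec$p[j] == rec$p[i]))
    }, logical(1)))
    expect_true(ok, info = s)
  }
})
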