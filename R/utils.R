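#' Derive a child seed from a global seed
#'
#' All stochastic stages of the pipeline draw their own seed from one global
#' seed through this counter scheme, so that adding a stage never perturbs the
#' random stream of another. The scheme is `(seed mod 21474835) * 100 + counter`
#' with `counter` in 0..99, which stays strictly below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param counter integer stage counter in 0..99.
#' @return an integer seed.
#' @export
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(counter), length(counter) == 1L, counter >= 0, counter < 100)
  as.integer((abs(as.integer(seed)) %% 21474835L) * 100L + as.integer(counter))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_ghd <- function(msg, class) {
  stop(structure(
    class = c(class, "ghdpgs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# shared column order for GWAS summary-statistic tables
sumstat_cols <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                  "beta", "se", "p")
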