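#' Full pipeline configuration
#'
#' Gathers every tunable of the end-to-end run so the manifest can record
#' them all — no stage reads a silent default. Defaults mirror the package's
#' documented design choices: clumping at r2 0.1 within 250 kb, VIF screen at
#' 10, 10 balanced subsets at a 4:1 control:case ratio, 10x10 stratified CV,
#' Wald intervals at alpha 0.05, and MR instrument selection at p < 5e-8.
#'
#' @param sim a [sim_config()] describing the synthetic cohort (or `NULL`
#'   when `dosage_path`/`cohort_path` point at existing TSVs).
#' @param dosage_path,cohort_path optional input TSVs instead of simulation.
#' @param strict_preeclampsia,general_controls cohort rule switches
#'   (see [default_ghd_rules()]).
#' @param min_bmi BMI filter threshold (default 18.5).
#' @param select_p_cutoff GWAS p-value cutoff for candidate SNPs.
#' @param clump_r2,clump_window_bp LD clumping parameters.
#' @param vif_threshold collinearity screen threshold.
#' @param n_subsets,control_ratio balanced resampling scheme.
#' @param n_folds,n_repeats CV configuration.
#' @param alpha significance level for all Wald intervals.
#' @param top_fractions top-percentile strata for odds ratios.
#' @param run_mr run the MR demonstration stage.
#' @param mr_n_instruments,mr_causal_beta,mr_pleiotropy MR simulation knobs.
#' @param mr_threshold instrument p-value threshold.
#' @param write_plink also write PLINK .bed/.bim/.fam.
#' @param seed global seed; stages derive child seeds from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            dosage_path = NULL, cohort_path = NULL,
                            strict_preeclampsia = FALSE,
                            general_controls = FALSE,
                            min_bmi = 18.5,
                            select_p_cutoff = 1e-5,
                            clump_r2 = 0.1, clump_window_bp = 250000,
                            vif_threshold = 10,
                            n_subsets = 10, control_ratio = 4,
                            n_folds = 10, n_repeats = 10,
                            alpha = 0.05,
                            top_fractions = c(0.01, 0.02, 0.05, 0.10, 0.25),
                            run_mr = TRUE,
                            mr_n_instruments = 50, mr_causal_beta = 0.3,
                            mr_pleiotropy = 0, mr_threshold = 5e-8,
                            write_plink = FALSE,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$sim) && (is.null(dosage_path) || is.null(cohort_path)))
    abort_ghd("either a sim config or both dosage_path and cohort_path required",
              "ghdpgs_bad_config")
  stopifnot(min_bmi > 0, select_p_cutoff > 0, select_p_cutoff < 1,
            clump_r2 > 0, clump_r2 <= 1, clump_window_bp >= 0,
            vif_threshold > 1, alpha > 0, alpha < 1,
            all(top_fractions > 0), all(top_fractions < 0.5))
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the pipeline end to end
#'
#' Stages: simulate (or load) -> define cohort by diagnosis codes -> BMI
#' filter -> per-SNP GWAS -> p-value selection -> LD clumping -> balanced
#' resampling PGS training -> scoring -> top-percentile odds ratios ->
#' BMI x septile grid -> (optionally) MR demonstration. Every stage logs its
#' in/out counts; the manifest records every parameter, seed and count, and
#' rerunning the same config reproduces every output file byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; existing files overwritten).
#' @param quiet suppress stage log lines.
#' @return invisibly, a list with the key in-memory results (`model`,
#'   `scores`, `strata`, `grid`, `mr`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("ghdpgs")),
                   r_version = R.version.string,
                   config = config_manifest(config),
                   counts = list())
  note_count <- function(stage, ...) {
    manifest$counts[[stage]] <<- list(...)
  }

  # --- stage 1: genotypes + cohort
  if (!is.null(config$sim)) {
    sim <- simulate_cohort(config$sim)
    geno <- sim$genotypes; cohort <- sim$cohort
    true_w <- sim$true_weights
    say("simulate: %d samples x %d SNPs", nrow(geno$dosages), ncol(geno$dosages))
  } else {
    geno <- read_dosage_tsv(config$dosage_path)
    cohort <- read_cohort_tsv(config$cohort_path)
    true_w <- NULL
    say("load: %d samples x %d SNPs", nrow(geno$dosages), ncol(geno$dosages))
  }
  write_dosage_tsv(geno, file.path(out_dir, "genotypes.tsv"))
  if (isTRUE(config$write_plink))
    write_plink(geno, file.path(out_dir, "genotypes"), cohort)
  note_count("input", samples = nrow(geno$dosages), snps = ncol(geno$dosages))

  # --- stage 2: cohort definition + BMI filter
  rules <- default_ghd_rules(config$strict_preeclampsia, config$general_controls)
  lab <- assign_case_control(cohort, rules)
  say("define-cohort: %d cases / %d controls / %d excluded",
      lab$counts["cases"], lab$counts["controls"], lab$counts["excluded"])
  cohort <- lab$cohort
  cohort$status <- cohort$label
  kept <- cohort[cohort$label != "excluded", , drop = FALSE]
  class(kept) <- c("ghd_cohort", "data.frame")
  kept <- filter_bmi(kept, config$min_bmi)
  say("filter-bmi: %d samples retained", nrow(kept))
  note_count("cohort", cases = unname(lab$counts["cases"]),
             controls = unname(lab$counts["controls"]),
             excluded = unname(lab$counts["excluded"]),
             after_bmi_filter = nrow(kept))
  write_cohort_tsv(cohort, file.path(out_dir, "cohort.tsv"))
  keep_geno <- genotype_matrix(
    geno$dosages[match(kept$sample_id, geno$sample_ids), , drop = FALSE],
    sample_ids = kept$sample_id, snp_ids = geno$snp_ids, map = geno$map)

  # --- stage 3: GWAS + selection + clumping
  sumstats <- simulate_gwas_summary(keep_geno, kept)
  write_sumstats_tsv(sumstats, file.path(out_dir, "sumstats.tsv"))
  records <- snp_records(sumstats$snp, sumstats$chrom, sumstats$pos,
                         sumstats$effect_allele, sumstats$other_allele,
                         sumstats$p, source = "cohort_gwas")
  selected <- select_by_pvalue(records, config$select_p_cutoff)
  say("select-variants: %d of %d SNPs below p < %g",
      nrow(selected), nrow(records), config$select_p_cutoff)
  if (nrow(selected) < 2)
    abort_ghd(sprintf("only %d SNPs pass p < %g: nothing to clump/train on",
                      nrow(selected), config$select_p_cutoff),
              "ghdpgs_stage_failure")
  sel_geno <- genotype_matrix(
    keep_geno$dosages[, selected$snp, drop = FALSE],
    sample_ids = keep_geno$sample_ids, snp_ids = selected$snp,
    map = keep_geno$map[match(selected$snp, keep_geno$map$snp), ])
  ld <- estimate_ld(sel_geno)
  clumped <- ld_clump(selected[!selected$snp %in% ld$excluded, , drop = FALSE],
                      ld$ld, config$clump_r2, config$clump_window_bp)
  say("clump: %d -> %d SNPs (r2 >= %g within %d bp)",
      nrow(selected), nrow(clumped), config$clump_r2, config$clump_window_bp)
  write_tsv(as.data.frame(selected), file.path(out_dir, "selected.tsv"))
  write_tsv(as.data.frame(clumped), file.path(out_dir, "clumped.tsv"))
  note_count("variants", candidates = nrow(records), selected = nrow(selected),
             clumped = nrow(clumped))

  # --- stage 4: training
  scheme <- resample_scheme(config$n_subsets, config$control_ratio,
                            seed = child_seed(config$seed, 30L))
  model <- train_pgs(kept, keep_geno, clumped$snp, scheme,
                     n_folds = config$n_folds, n_repeats = config$n_repeats,
                     vif_threshold = config$vif_threshold)
  say("train: %d SNPs, mean CV AUC %.3f (subset %d of %d)",
      length(model$snp_ids), model$training_auc,
      model$provenance$selected_subset, config$n_subsets)
  write_scoring_file(model, file.path(out_dir, "pgs_model.tsv"),
                     map = keep_geno$map)
  note_count("train", model_snps = length(model$snp_ids),
             training_auc = model$training_auc)

  # --- stage 5: scoring + stratification
  scores <- compute_pgs(model, keep_geno)
  write_scores_tsv(scores, file.path(out_dir, "scores.tsv"))
  strata <- lapply(config$top_fractions, function(tf)
    top_vs_bottom_or(scores, kept$status, tf, alpha = config$alpha))
  strata_df <- do.call(rbind, lapply(strata, function(s)
    data.frame(stratum = s$stratum_label, a = s$estimate$cells$a,
               b = s$estimate$cells$b, c = s$estimate$cells$c,
               d = s$estimate$cells$d, or = s$estimate$odds_ratio,
               ci_low = s$estimate$ci_low, ci_high = s$estimate$ci_high,
               corrected = s$estimate$corrected)))
  write_tsv(strata_df, file.path(out_dir, "strata.tsv"))
  say("stratify: %s", paste(sprintf("%s OR %.2f", strata_df$stratum,
                                    strata_df$or), collapse = "; "))
  grid <- bmi_pgs_grid(kept, scores, alpha = config$alpha)
  write_tsv(grid, file.path(out_dir, "bmi_pgs_grid.tsv"))
  note_count("stratify", strata = nrow(strata_df), grid_cells = nrow(grid))

  # --- stage 6: MR demonstration (optional)
  mr_res <- NULL
  if (isTRUE(config$run_mr)) {
    iv <- simulate_mr_instruments(config$mr_n_instruments,
                                  config$mr_causal_beta, config$mr_pleiotropy,
                                  seed = child_seed(config$seed, 40L))
    iv_sel <- select_instruments(iv, config$mr_threshold)
    mr_res <- list(ivw = ivw_estimate(iv_sel, config$alpha),
                   egger = egger_estimate(iv_sel, config$alpha))
    write_instruments_tsv(iv_sel, file.path(out_dir, "mr_instruments.tsv"))
    write_mr_results_tsv(mr_res, file.path(out_dir, "mr_results.tsv"),
                         labels = names(mr_res))
    say("mr: IVW beta %.3f, Egger intercept p %.3f",
        mr_res$ivw$beta, mr_res$egger$intercept_p)
    note_count("mr", instruments = length(iv_sel$snp_ids))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, scores = scores, strata = strata_df,
                 grid = grid, mr = mr_res, true_weights = true_w,
                 cohort = kept, genotypes = keep_geno, manifest = manifest))
}

# flatten the config (and nested sim config) to manifest-friendly values
config_manifest <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$sim)) cfg$sim <- unclass(cfg$sim)
  cfg
}
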