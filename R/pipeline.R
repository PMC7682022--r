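#' Simulate the full synthetic study inputs
#'
#' Builds everything the downstream stages need from a configuration:
#' ancestral frequencies, per-population Balding-Nichols frequencies
#' (population A matched to the imputation reference panel, population B
#' divergent at the configured F_ST), per-population haplotype panels with
#' block LD, the diploid truth cohort with phased haplotypes, a PRS weight
#' model and a typed-variant mask. The imputation reference panel contains
#' population-A haplotypes only, emulating a reference resource matched to
#' the majority ancestry.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @return list: `truth` (`dosage_matrix`), `haplotypes` (2N x L),
#'   `ancestry`, `model` (`prs_model`), `mask` (typed logical),
#'   `ref_panel` (`haplotype_panel`, population A), `seeds`.
#' @export
simulate_study <- function(config = default_run_config()) {
  seeds <- derive_seeds(config$master_seed,
                        c("af", "freqB", "panelA", "panelB", "ref_panel",
                          "cohort", "model", "mask"))
  L <- config$n_variants
  af <- draw_ancestral_frequencies(L, config$maf_range, seeds[["af"]])
  freqA <- derive_population_frequencies(af, 0, label = "popA")
  freqB <- derive_population_frequencies(af, config$fst, seeds[["freqB"]],
                                         label = "popB")
  pops <- names(config$cohort)
  # One population-A panel draw supplies both the cohort haplotype pool and
  # the imputation reference panel: disjoint subsets of the same draw share
  # founder/LD structure, as a cohort and a matched reference resource do.
  # Population B gets its own draw at the diverged frequencies, so the
  # reference panel is mismatched to B in both frequency and haplotype
  # structure.
  n_ref <- config$panel_haplotypes
  n_pool <- config$pool_haplotypes %||% (2L * n_ref)
  panelA_full <- simulate_haplotype_panel(freqA, n_pool + n_ref,
                                          config$block_length,
                                          seeds[["panelA"]],
                                          config$n_founders,
                                          config$mutation_rate)
  panelA <- subset_panel(panelA_full, seq_len(n_pool))
  ref_panel <- subset_panel(panelA_full, n_pool + seq_len(n_ref))
  panelB <- simulate_haplotype_panel(freqB, n_pool, config$block_length,
                                     seeds[["panelB"]], config$n_founders,
                                     config$mutation_rate)
  panelA$population <- rep(pops[1], nrow(panelA$haplotypes))
  panelB$population <- rep(pops[2], nrow(panelB$haplotypes))
  ref_panel$population <- rep(pops[1], nrow(ref_panel$haplotypes))
  cohort_panel <- combine_panels(panelA, panelB)
  n_per_pop <- stats::setNames(as.integer(unlist(config$cohort)), pops)
  cohort <- simulate_cohort(cohort_panel, n_per_pop, seeds[["cohort"]])
  model <- generate_prs_model(L, config$weight_scale, config$n_high_weight,
                              config$high_weight_multiplier, seeds[["model"]],
                              variants = cohort$truth$variants)
  mask <- assign_typed_mask(L, config$fraction_typed, seeds[["mask"]])
  list(truth = cohort$truth, haplotypes = cohort$haplotypes,
       ancestry = cohort$ancestry, model = model, mask = mask,
       ref_panel = ref_panel, seeds = seeds)
}

#' Run one imputation process on a simulated study
#'
#' @param study output of [simulate_study()].
#' @param config a `run_config`.
#' @param process `"hmm_deterministic"`, `"hmm_sampled"` or
#'   `"parametric"`.
#' @param seed process seed (defaults to a stream derived from the master
#'   seed and the process name).
#' @return a `replicate_set`.
#' @export
run_process <- function(study, config, process, seed = NULL) {
  if (is.null(seed)) {
    seed <- derive_seeds(config$master_seed,
                         c("hmm_deterministic", "hmm_sampled",
                           "parametric"))[[process]]
  }
  switch(process,
    hmm_deterministic = emulate_hmm(study$haplotypes, study$mask,
                                    study$ref_panel, config$hmm$rho,
                                    config$hmm$theta, config$K,
                                    mode = "deterministic",
                                    master_seed = seed),
    hmm_sampled = emulate_hmm(study$haplotypes, study$mask, study$ref_panel,
                              config$hmm$rho, config$hmm$theta, config$K,
                              mode = "sampled", master_seed = seed),
    parametric = emulate_parametric(study$truth, study$mask,
                                    config$parametric$r2_target,
                                    config$parametric$sigma_run,
                                    config$K, master_seed = seed),
    stop("unknown process: ", process))
}

#' Analyse one process's replicate set
#'
#' Computes the full report for one replicate set: percentile frame,
#' percentile-range table, deviation-by-bin summary, tier re-classification
#' matrix, refined-tier re-classification rates, per-individual accuracy,
#' MAF-binned accuracy and the Gini/PVE contribution table.
#'
#' @param study output of [simulate_study()].
#' @param reps a `replicate_set`.
#' @param config a `run_config`.
#' @return named list of report objects.
#' @export
analyse_process <- function(study, reps, config = default_run_config()) {
  frame <- build_percentile_frame(study$truth, reps, study$model,
                                  study$ancestry)
  list(process = reps$process,
       frame = frame,
       range_table = percentile_range_table(frame, config$range_thresholds),
       deviation = deviation_by_bin(frame, config$n_bins),
       tier_matrix = reclassification_matrix(frame, config$tier_cuts),
       highrisk = highrisk_reclassification(frame),
       r2_mean = per_individual_r2_summary(reps, study$truth, "mean"),
       r2_min = per_individual_r2_summary(reps, study$truth, "min"),
       maf_accuracy = maf_binned_accuracy(reps, study$truth),
       contribution = gini_pve_table(reps, study$model, study$truth))
}

#' Run the full synthetic pipeline and write its reports
#'
#' Executes simulate -> emulate (one replicate set per requested process)
#' -> score -> variability -> accuracy -> contribution and writes every
#' table as TSV plus a JSON manifest of seeds and conventions under
#' `out_dir`. Identical config and master seed give bit-identical outputs.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if needed).
#' @param processes processes to run (default the deterministic and
#'   sampled haplotype-copying modes plus the parametric emulator).
#' @return invisibly, a list with the study, replicate sets and per-process
#'   reports.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = "results",
                         processes = c("hmm_deterministic", "hmm_sampled",
                                       "parametric")) {
  if (config$K < 2) stop("stage 'variability': K must be >= 2 (replicate ranges are undefined for K = 1)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  study <- stage("simulate", simulate_study(config))
  message(sprintf("simulate: %d samples (%s), %d variants (%d typed)",
                  nrow(study$truth$dosages),
                  paste(sprintf("%s=%d", names(config$cohort),
                                unlist(config$cohort)), collapse = ", "),
                  config$n_variants, sum(study$mask)))
  write_dosage_vcf(study$truth, file.path(out_dir, "truth.vcf.gz"))
  write_scoring_file(study$model, file.path(out_dir, "prs_model.tsv"))
  write_ancestry(study$ancestry, file.path(out_dir, "ancestry.tsv"))
  reports <- list()
  repsets <- list()
  for (p in processes) {
    reps <- stage(paste0("emulate:", p), run_process(study, config, p))
    validate_replicate_set(reps, study$truth)
    rep_out <- stage(paste0("analyse:", p), analyse_process(study, reps, config))
    message(sprintf("%s: median percentile range %.2f, mean R2 %.4f",
                    p, stats::median(percentile_range(rep_out$frame)),
                    mean(rep_out$r2_mean)))
    prefix <- file.path(out_dir, p)
    tsv <- function(df, name) {
      utils::write.table(df, paste0(prefix, "_", name, ".tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    tsv(rep_out$range_table, "range_table")
    tsv(rep_out$deviation, "deviation_by_bin")
    tsv(as.data.frame(as.table(rep_out$tier_matrix$primary),
                      responseName = "pct"), "tier_matrix")
    tsv(rep_out$highrisk, "highrisk_reclassification")
    tsv(rep_out$maf_accuracy$by_bin, "maf_accuracy")
    tsv(rep_out$contribution, "gini_pve")
    tsv(data.frame(sample = study$truth$samples,
                   mean_r2 = unname(rep_out$r2_mean),
                   min_r2 = unname(rep_out$r2_min)), "per_individual_r2")
    reports[[p]] <- rep_out
    repsets[[p]] <- reps
  }
  manifest <- list(master_seed = config$master_seed,
                   config = unclass(config),
                   stage_seeds = as.list(study$seeds),
                   processes = processes,
                   conventions = list(
                     percentile = "midrank within ancestry group",
                     tiers = "low < lower cut <= intermediate <= upper cut < high",
                     ranking = "each replicate ranked within its own score distribution",
                     gini = "per individual across K replicate dosages, averaged over individuals"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(study = study, replicates = repsets, reports = reports))
}
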