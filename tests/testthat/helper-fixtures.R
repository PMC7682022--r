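# Shared fixtures. The two large synthetic runs used by the acceptance
# tests are computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small two-population study for module-level tests.
small_study <- function(seed = 7, nA = 120L, nB = 40L, L = 60L) {
  cfg <- default_run_config(seed)
  cfg$n_variants <- L
  cfg$cohort <- list(popA = nA, popB = nB)
  cfg$panel_haplotypes <- 40L
  cfg$pool_haplotypes <- 80L
  cfg$block_length <- 30L
  list(cfg = cfg, study = simulate_study(cfg))
}

# Single-population matched-panel cohort at the contrast scale:
# 2000 individuals, 200 score SNPs, 25% typed, K = 6, deterministic and
# sampled haplotype-copying output plus full analyses.
contrast_run <- function() {
  cached("contrast_run", {
    cfg <- default_run_config(20260923L)
    cfg$cohort <- list(popA = 2000L)
    study <- simulate_study(cfg)
    det <- run_process(study, cfg, "hmm_deterministic")
    sam <- run_process(study, cfg, "hmm_sampled")
    list(cfg = cfg, study = study, det = det, sam = sam,
         rep_det = analyse_process(study, det, cfg),
         rep_sam = analyse_process(study, sam, cfg))
  })
}

# Two-population cohort (panel matched to A, FST 0.15 divergence to B),
# sampled-mode output, for the reference-mismatch contrast.
mismatch_run <- function() {
  cached("mismatch_run", {
    cfg <- default_run_config(40404L)
    cfg$cohort <- list(popA = 600L, popB = 600L)
    study <- simulate_study(cfg)
    sam <- run_process(study, cfg, "hmm_sampled")
    list(cfg = cfg, study = study, sam = sam,
         frame = build_percentile_frame(study$truth, sam, study$model,
                                        study$ancestry))
  })
}

# Truth-duplicate replicate set: K copies of the truth dosages.
identical_replicates <- function(truth, mask, K = 6L) {
  replicate_set(rep(list(truth$dosages), K), process = "identical",
                mask = mask)
}

# Random dosage matrix with HWE-ish genotypes at given frequencies.
random_truth <- function(n, freqs, seed) {
  set.seed(seed)
  X <- sapply(freqs, function(p) stats::rbinom(n, 2L, p))
  dosage_matrix(X, synthetic_variant_table(length(freqs)))
}
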