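#!/usr/bin/env Rscript
# Stage 3 — score and rank.
#
# Reads the truth and replicate VCFs back through the package's format
# adapters, computes the PRS for the truth and every replicate, converts
# scores to ancestry-stratified midrank percentiles, and writes one
# percentile table per process (sample, ancestry, WGS-based percentile,
# K replicate percentiles).

suppressPackageStartupMessages(library(prsvar))

data_dir <- "results/data"
cfg <- read_run_config(file.path(data_dir, "config.yaml"))
truth <- read_dosage_vcf(file.path(data_dir, "truth.vcf.gz"))
model <- read_scoring_file(file.path(data_dir, "prs_model.tsv"))
ancestry <- read_ancestry(file.path(data_dir, "ancestry.tsv"))
mask <- utils::read.delim(file.path(data_dir, "typed_mask.tsv"))$typed

for (p in c("hmm_deterministic", "hmm_sampled", "parametric")) {
  reps <- replicate_set(lapply(seq_len(cfg$K), function(k) {
    read_dosage_vcf(file.path(data_dir,
                              sprintf("%s_rep%d.vcf.gz", p, k)))$dosages
  }), process = p, mask = mask)
  frame <- build_percentile_frame(truth, reps, model, ancestry)
  tab <- data.frame(sample = frame$samples,
                    ancestry = frame$ancestry,
                    wgs = unname(frame$wgs))
  for (k in seq_len(frame$K)) tab[[paste0("rep", k)]] <- frame$reps[, k]
  utils::write.table(tab, file.path("results",
                                    paste0(p, "_percentiles.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: median replicate percentile range %.2f\n",
              p, median(percentile_range(frame))))
}
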