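#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study inputs.
#
# Generates a two-population cohort (majority population matched to the
# imputation reference panel, minority population diverged at FST = 0.15),
# a PRS weight model with a few dominant SNPs, and a typed/untyped mask,
# then writes the truth genotypes (VCF), scoring file, ancestry labels,
# typed mask and the run configuration under results/data/.

suppressPackageStartupMessages(library(prsvar))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- default_run_config(master_seed = 20260923L)
write_run_config(cfg, file.path(out, "config.yaml"))

study <- simulate_study(cfg)
write_dosage_vcf(study$truth, file.path(out, "truth.vcf.gz"))
write_scoring_file(study$model, file.path(out, "prs_model.tsv"))
write_ancestry(study$ancestry, file.path(out, "ancestry.tsv"))
utils::write.table(data.frame(id = study$truth$variants$id,
                              typed = study$mask),
                   file.path(out, "typed_mask.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

maf <- pmin(colMeans(study$truth$dosages) / 2,
            1 - colMeans(study$truth$dosages) / 2)
cat(sprintf("cohort: %d individuals (%s)\n", nrow(study$truth$dosages),
            paste(sprintf("%s=%d", names(cfg$cohort), unlist(cfg$cohort)),
                  collapse = ", ")))
cat(sprintf("variants: %d (%d typed, %d untyped); cohort MAF median %.3f\n",
            cfg$n_variants, sum(study$mask), sum(!study$mask), median(maf)))
cat(sprintf("score: %d SNPs, %d high-weight (x%g)\n", nrow(study$model),
            cfg$n_high_weight, cfg$high_weight_multiplier))
cat("written:", out, "\n")
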