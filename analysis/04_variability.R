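#!/usr/bin/env Rscript
# Stage 4 — percentile variability and risk-tier re-classification.
#
# From each process's percentile table: the percentile-change distribution
# (share of individuals whose replicate range exceeds 1/5/10/20 points, per
# ancestry stratum), deviation-by-decile boxplot summaries, the quintile
# tier re-classification matrix, and refined-tier re-classification rates
# with Wald 95% CIs.

suppressPackageStartupMessages(library(prsvar))

read_frame <- function(p) {
  tab <- utils::read.delim(file.path("results",
                                     paste0(p, "_percentiles.tsv")))
  reps <- as.matrix(tab[grep("^rep", names(tab))])
  percentile_frame(tab$wgs, reps, tab$ancestry)
}

for (p in c("hmm_deterministic", "hmm_sampled", "parametric")) {
  frame <- read_frame(p)
  rt <- percentile_range_table(frame)
  dv <- deviation_by_bin(frame, n_bins = 10)
  tm <- reclassification_matrix(frame)
  hr <- highrisk_reclassification(frame)
  w <- function(df, name) utils::write.table(
    df, file.path("results", paste0(p, "_", name, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  w(rt, "range_table")
  w(dv, "deviation_by_bin")
  w(as.data.frame(as.table(tm$primary), responseName = "pct"), "tier_matrix")
  w(hr, "highrisk_reclassification")
  over20 <- rt$pct[rt$row == ">20" & rt$stratum == "all"]
  offdiag <- 100 - sum(diag(tm$primary))
  cat(sprintf("%s: >20-point changes %.2f%% of cohort; quintile off-diagonal %.2f%%; top-5%% tier re-classification %.1f%%\n",
              p, over20, offdiag, hr$rate[hr$tier == "<5"]))
}
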