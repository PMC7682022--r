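#' Percentile-change distribution table
#'
#' For each individual the percentile change is the range (max - min) of the
#' K replicate percentiles. The table counts, per ancestry stratum and
#' combined, how many individuals have range <= 1 and how many exceed each
#' threshold (default 1, 5, 10, 20 percentile points), with percentages.
#'
#' @param frame `percentile_frame` with K >= 2.
#' @param thresholds increasing percentile-point thresholds.
#' @return data.frame with columns `row` (`"<=1"`, `">1"`, ...), `stratum`,
#'   `count`, `pct`; of class `change_distribution_table`.
#' @export
percentile_range_table <- function(frame, thresholds = c(1, 5, 10, 20)) {
  if (frame$K < 2) stop("range undefined for K < 2 replicates")
  rng <- apply(frame$reps, 1, max) - apply(frame$reps, 1, min)
  strata <- c(split(rng, frame$ancestry), list(all = rng))
  if (length(unique(frame$ancestry)) == 1) strata <- strata[length(strata)]
  rows <- c("<=1", paste0(">", thresholds))
  out <- do.call(rbind, lapply(names(strata), function(s) {
    r <- strata[[s]]
    counts <- c(sum(r <= 1), vapply(thresholds, function(t) sum(r > t), numeric(1)))
    data.frame(row = rows, stratum = s, count = counts,
               pct = 100 * counts / length(r), stringsAsFactors = FALSE)
  }))
  class(out) <- c("change_distribution_table", "data.frame")
  attr(out, "thresholds") <- thresholds
  out
}

#' Per-individual replicate percentile range
#'
#' @param frame `percentile_frame` with K >= 2.
#' @return numeric vector, max - min of the replicate percentiles per
#'   individual.
#' @export
percentile_range <- function(frame) {
  if (frame$K < 2) stop("range undefined for K < 2 replicates")
  apply(frame$reps, 1, max) - apply(frame$reps, 1, min)
}

#' Percentile deviation summaries by WGS-percentile bin
#'
#' Bins individuals by their WGS-based percentile into `n_bins` equal-width
#' bins of \[0, 100\]; per individual computes the average and the maximum
#' absolute deviation of the replicate percentiles from the WGS percentile,
#' and per bin returns boxplot-style summaries (quartiles and Tukey
#' whiskers) of both.
#'
#' @param frame `percentile_frame`.
#' @param n_bins number of equal-width bins (>= 2).
#' @return data.frame with one row per (bin, metric in avg_dev/max_dev):
#'   `bin`, `bin_lo`, `bin_hi`, `metric`, `n`, `q1`, `median`, `q3`,
#'   `whisker_lo`, `whisker_hi`. Empty bins are reported with `n = 0` and
#'   NA summaries.
#' @export
deviation_by_bin <- function(frame, n_bins = 10L) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  dev <- abs(frame$reps - frame$wgs)
  avg_dev <- rowMeans(dev)
  max_dev <- apply(dev, 1, max)
  edges <- seq(0, 100, length.out = n_bins + 1)
  bin <- cut(frame$wgs, breaks = edges, include.lowest = TRUE, labels = FALSE)
  summarize <- function(x) {
    if (length(x) == 0) return(rep(NA_real_, 5))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr])
    hi <- max(x[x <= q[3] + 1.5 * iqr])
    c(q, lo, hi)
  }
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    do.call(rbind, lapply(c(avg = "avg_dev", max = "max_dev"), function(m) {
      x <- if (m == "avg_dev") avg_dev[idx] else max_dev[idx]
      s <- summarize(x)
      data.frame(bin = b, bin_lo = edges[b], bin_hi = edges[b + 1],
                 metric = m, n = length(idx), q1 = s[1], median = s[2],
                 q3 = s[3], whisker_lo = s[4], whisker_hi = s[5],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "avg_dev") <- avg_dev
  attr(out, "max_dev") <- max_dev
  out
}

#' Risk-tier re-classification matrix
#'
#' Accumulates, over all (individual, replicate) pairs, a 3 x 3 matrix of
#' percentages where the row is the tier of that single replicate's
#' percentile and the column is the tier of the individual's mean replicate
#' percentile. A secondary matrix with rows given by each replicate's tier
#' and columns by the WGS-based tier is also returned, since the two
#' readings of "process-level vs average individual-level" tiers differ.
#'
#' @param frame `percentile_frame`.
#' @param cuts quintile-style two-cut tier definition (default 20/80).
#' @return list of class `tier_matrix`: `primary` and `wgs_vs_replicate`
#'   (3 x 3 percentage matrices summing to 100), plus `metadata` recording
#'   the conventions.
#' @export
reclassification_matrix <- function(frame, cuts = c(20, 80)) {
  labels <- c("low", "intermediate", "high")
  mean_tier <- assign_tier(rowMeans(frame$reps), cuts, labels)
  wgs_tier <- assign_tier(frame$wgs, cuts, labels)
  n_pairs <- length(frame$wgs) * frame$K
  primary <- matrix(0, 3, 3, dimnames = list(replicate = labels, mean = labels))
  secondary <- matrix(0, 3, 3, dimnames = list(replicate = labels, wgs = labels))
  for (k in seq_len(frame$K)) {
    rep_tier <- assign_tier(frame$reps[, k], cuts, labels)
    primary <- primary + table(rep_tier, mean_tier)
    secondary <- secondary + table(rep_tier, wgs_tier)
  }
  structure(list(primary = 100 * primary / n_pairs,
                 wgs_vs_replicate = 100 * secondary / n_pairs,
                 metadata = list(cuts = cuts, K = frame$K,
                                 row = "single-replicate tier",
                                 col_primary = "tier of mean replicate percentile",
                                 col_secondary = "WGS-based tier")),
            class = "tier_matrix")
}

#' @export
print.tier_matrix <- function(x, ...) {
  cat("<tier_matrix> row = single-replicate tier, col = mean-replicate tier (%):\n")
  print(round(x$primary, 2))
  invisible(x)
}

#' Refined-tier re-classification rates with Wald confidence intervals
#'
#' For each one-sided tier (e.g. `< 5`, `> 95` percentile), among the
#' individuals whose WGS-based percentile falls in the tier, the
#' re-classification rate is the percentage for whom at least two
#' replicates fall outside the tier. The 95% CI is the untruncated Wald
#' normal approximation `rate +/- 1.96 * sqrt(rate * (100 - rate) / m)`
#' with m the tier size (lower bounds may be negative, upper may exceed
#' 100). Empty tiers report NA.
#'
#' @param frame `percentile_frame` with K >= 2.
#' @param tier_cuts data.frame with columns `direction` (`"<"` or `">"`)
#'   and `cut`, or NULL for the default 5/10/15/20 and 80/85/90/95 scheme.
#' @param min_discordant replicates outside the tier required to call an
#'   individual re-classified (default 2).
#' @return data.frame: `tier`, `n`, `n_reclassified`, `rate`, `ci_lo`,
#'   `ci_hi` (percent scale).
#' @export
highrisk_reclassification <- function(frame, tier_cuts = NULL,
                                      min_discordant = 2L) {
  if (frame$K < 2) stop("needs K >= 2 replicates")
  if (is.null(tier_cuts)) {
    tier_cuts <- data.frame(direction = rep(c("<", ">"), each = 4),
                            cut = c(5, 10, 15, 20, 80, 85, 90, 95))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(tier_cuts)), function(i) {
    dir <- tier_cuts$direction[i]; cut <- tier_cuts$cut[i]
    in_tier <- if (dir == "<") frame$wgs < cut else frame$wgs > cut
    m <- sum(in_tier)
    if (m == 0) {
      return(data.frame(tier = paste0(dir, cut), n = 0L,
                        n_reclassified = NA_integer_, rate = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    }
    outside <- if (dir == "<") frame$reps[in_tier, , drop = FALSE] >= cut
               else frame$reps[in_tier, , drop = FALSE] <= cut
    recl <- rowSums(outside) >= min_discordant
    rate <- 100 * sum(recl) / m
    half <- 1.96 * sqrt(rate * (100 - rate) / m)
    data.frame(tier = paste0(dir, cut), n = m,
               n_reclassified = sum(recl), rate = rate,
               ci_lo = rate - half, ci_hi = rate + half,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
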