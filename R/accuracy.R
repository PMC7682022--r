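#' Dosage R-squared
#'
#' Squared Pearson correlation between imputed and truth dosage vectors,
#' the standard imputation accuracy measure against a sequencing-based gold
#' standard. Defined as 0 when either vector is constant (undefined
#' correlation; 0 is the conservative accuracy reading).
#'
#' @param imputed,truth numeric vectors of equal length >= 2.
#' @return squared correlation in \[0, 1\].
#' @export
dosage_r2 <- function(imputed, truth) {
  if (length(imputed) != length(truth)) stop("vectors must have equal length")
  if (length(imputed) < 2) stop("need at least 2 observations")
  if (stats::sd(imputed) == 0 || stats::sd(truth) == 0) return(0)
  stats::cor(imputed, truth)^2
}

#' Per-individual accuracy across replicates
#'
#' For each individual, computes the dosage R-squared across variants
#' (untyped only by default, since typed variants are copied from the truth
#' and would inflate accuracy) separately per replicate, then aggregates
#' across the K replicates by the mean or the minimum. The minimum exposes
#' individual-level accuracy excursions that the population-level mean
#' masks.
#'
#' @param reps `replicate_set`.
#' @param truth `dosage_matrix`.
#' @param aggregate `"mean"` or `"min"`.
#' @param scope `"untyped"` (default) or `"all"` variants.
#' @return named numeric vector, one value per sample.
#' @export
per_individual_r2_summary <- function(reps, truth,
                                      aggregate = c("mean", "min"),
                                      scope = c("untyped", "all")) {
  aggregate <- match.arg(aggregate)
  M <- per_individual_r2(reps, truth, scope)
  out <- if (aggregate == "mean") rowMeans(M) else apply(M, 1, min)
  stats::setNames(out, truth$samples)
}

#' Per-individual, per-replicate accuracy matrix
#'
#' @inheritParams per_individual_r2_summary
#' @return samples x K matrix of dosage R-squared values.
#' @export
per_individual_r2 <- function(reps, truth, scope = c("untyped", "all")) {
  scope <- match.arg(scope)
  cols <- if (scope == "untyped") which(!reps$mask) else seq_along(reps$mask)
  if (length(cols) < 2) stop("need at least 2 variants in scope")
  Xt <- truth$dosages[, cols, drop = FALSE]
  vapply(reps$replicates, function(R) {
    Xi <- R[, cols, drop = FALSE]
    vapply(seq_len(nrow(Xi)), function(i) dosage_r2(Xi[i, ], Xt[i, ]),
           numeric(1))
  }, numeric(nrow(truth$dosages)))
}

# Best-guess genotype call from a dosage: nearest of {0,1,2}, ties at
# 0.5 / 1.5 rounding down.
dosage_to_genotype <- function(dosage) {
  g <- pmin(pmax(ceiling(dosage - 0.5), 0), 2)
  storage.mode(g) <- "integer"
  g
}

#' Genotype F-score
#'
#' Macro-averaged F1 over the genotype classes 0/1/2: per class present in
#' the truth, F1 = 2PR / (P + R) from the 3 x 3 confusion table (0 when
#' P + R = 0); classes absent from the truth are skipped in the average.
#'
#' @param imputed_calls,truth_calls integer vectors with values in
#'   \{0, 1, 2\}.
#' @return F-score in \[0, 1\].
#' @export
genotype_fscore <- function(imputed_calls, truth_calls) {
  check_calls(imputed_calls, truth_calls)
  f1 <- vapply(sort(unique(truth_calls)), function(cl) {
    tp <- sum(imputed_calls == cl & truth_calls == cl)
    prec_den <- sum(imputed_calls == cl)
    rec_den <- sum(truth_calls == cl)
    p <- if (prec_den == 0) 0 else tp / prec_den
    r <- tp / rec_den
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

#' Imputation quality score (IQS)
#'
#' Chance-adjusted genotype agreement: a Cohen's-kappa-type statistic on
#' the 3 x 3 genotype contingency table, `(P_obs - P_exp) / (1 - P_exp)`
#' with P_obs the observed agreement fraction and P_exp the agreement
#' expected from the marginal products. IQS <= 1 and may be negative; the
#' degenerate case P_exp = 1 returns 1 when agreement is perfect, else 0.
#'
#' @inheritParams genotype_fscore
#' @return IQS value (<= 1).
#' @export
iqs <- function(imputed_calls, truth_calls) {
  check_calls(imputed_calls, truth_calls)
  n <- length(truth_calls)
  classes <- 0:2
  tab <- table(factor(imputed_calls, classes), factor(truth_calls, classes)) / n
  p_obs <- sum(diag(tab))
  p_exp <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - p_exp) < 1e-12) {
    return(if (p_obs >= 1 - 1e-12) 1 else 0)
  }
  (p_obs - p_exp) / (1 - p_exp)
}

check_calls <- function(imputed_calls, truth_calls) {
  if (length(imputed_calls) != length(truth_calls)) {
    stop("call vectors must have equal length")
  }
  if (!all(imputed_calls %in% 0:2) || !all(truth_calls %in% 0:2)) {
    stop("genotype classes must lie in {0, 1, 2}")
  }
  invisible(TRUE)
}

#' Accuracy metrics binned by minor allele frequency
#'
#' Computes per-variant, per-replicate accuracy metrics (dosage R-squared,
#' genotype F-score, IQS) against the truth and groups variants by the
#' truth-cohort MAF using half-open bins (a, b\] (a variant exactly on a
#' cut point goes to the lower bin). Per bin the min / median / max of each
#' metric across variants and replicates is reported. Rare variants are
#' harder to impute, so the rarest bins typically show the widest R-squared
#' range.
#'
#' @param reps `replicate_set`.
#' @param truth `dosage_matrix`.
#' @param bins increasing MAF cut points; defaults to
#'   `c(0, 0.005, 0.01, 0.05, 0.1, 0.5)`.
#' @param scope `"untyped"` (default) or `"all"` variants.
#' @return list with `per_variant` (long data.frame: variant, replicate,
#'   maf, bin, r2, fscore, iqs) and `by_bin` (bin, metric, n, min, median,
#'   max).
#' @export
maf_binned_accuracy <- function(reps, truth,
                                bins = c(0, 0.005, 0.01, 0.05, 0.1, 0.5),
                                scope = c("untyped", "all")) {
  scope <- match.arg(scope)
  cols <- if (scope == "untyped") which(!reps$mask) else seq_along(reps$mask)
  Xt <- truth$dosages[, cols, drop = FALSE]
  f <- colMeans(Xt) / 2
  maf <- pmin(f, 1 - f)
  bin <- cut(maf, breaks = bins, right = TRUE, include.lowest = FALSE)
  truth_calls <- round(Xt)
  per_variant <- do.call(rbind, lapply(seq_len(reps$K), function(k) {
    Xi <- reps$replicates[[k]][, cols, drop = FALSE]
    calls <- dosage_to_genotype(Xi)
    data.frame(variant = colnames(Xt) %||% as.character(cols),
               replicate = k, maf = maf, bin = bin,
               r2 = vapply(seq_along(cols), function(j)
                 dosage_r2(Xi[, j], Xt[, j]), numeric(1)),
               fscore = vapply(seq_along(cols), function(j)
                 genotype_fscore(calls[, j], truth_calls[, j]), numeric(1)),
               iqs = vapply(seq_along(cols), function(j)
                 iqs(calls[, j], truth_calls[, j]), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  by_bin <- do.call(rbind, lapply(levels(bin), function(b) {
    sub <- per_variant[!is.na(per_variant$bin) & per_variant$bin == b, ]
    do.call(rbind, lapply(c("r2", "fscore", "iqs"), function(m) {
      x <- sub[[m]]
      data.frame(bin = b, metric = m, n = length(x),
                 min = if (length(x)) min(x) else NA_real_,
                 median = if (length(x)) stats::median(x) else NA_real_,
                 max = if (length(x)) max(x) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(by_bin) <- NULL
  list(per_variant = per_variant, by_bin = by_bin)
}

#' Paired comparison of two processes' per-sample accuracies
#'
#' Two-sided paired Wilcoxon signed-rank test on the per-sample
#' differences; zero differences are dropped (the signed-rank convention).
#' If every difference is zero the result is flagged degenerate instead of
#' a test being forced.
#'
#' @param values_a,values_b numeric per-sample metrics, paired by sample.
#' @return list: `statistic`, `p_value`, `n_nonzero`, `degenerate`.
#' @export
paired_process_comparison <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("inputs must be paired by sample")
  d <- values_a - values_b
  nz <- sum(d != 0)
  if (nz == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_nonzero = 0L, degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            paired = TRUE, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = nz, degenerate = FALSE)
}

#' Best tag-SNP linkage disequilibrium per untyped variant
#'
#' For every untyped score SNP, the maximum squared dosage correlation
#' (r-squared) with any typed SNP in the cohort, plus the fractions of
#' untyped SNPs whose best tag exceeds each threshold (strict >). Untyped
#' SNPs well tagged by a typed SNP are imputed more consistently.
#'
#' @param untyped samples x variants dosage matrix of untyped SNPs.
#' @param typed samples x variants dosage matrix of typed SNPs (>= 1).
#' @param thresholds decreasing-coverage r-squared thresholds (default
#'   0.5, 0.8, 0.9).
#' @return list: `best_r2` (per untyped SNP), `fractions` (named, fraction
#'   of untyped SNPs with best r2 strictly above each threshold).
#' @export
best_tag_ld <- function(untyped, typed, thresholds = c(0.5, 0.8, 0.9)) {
  typed <- as.matrix(typed); untyped <- as.matrix(untyped)
  if (ncol(typed) < 1) stop("need at least one typed SNP")
  cc <- suppressWarnings(stats::cor(untyped, typed))
  cc[is.na(cc)] <- 0
  best <- apply(cc^2, 1, max)
  fr <- vapply(thresholds, function(t) mean(best > t), numeric(1))
  list(best_r2 = stats::setNames(best, colnames(untyped)),
       fractions = stats::setNames(fr, paste0(">", thresholds)))
}
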