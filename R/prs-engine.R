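#' Compute polygenic risk scores
#'
#' Standard weighted allele-counting PRS: for individual i,
#' `PRS_i = sum_j x_ij * beta_j` over exactly the model's variants, where
#' `x_ij` is the effect-allele dosage (0-2) and `beta_j` the effect weight
#' (log odds ratio per effect-allele dosage). The dosage matrix counts the
#' ALT allele; when a model row's effect allele is the variant's REF allele
#' the dosage is flipped (`x -> 2 - x`), and an effect allele matching
#' neither REF nor ALT is an error (allele orientation must be resolved
#' upstream).
#'
#' @param dosages `dosage_matrix` (or plain matrix whose columns are named
#'   by variant id, in which case every effect allele is assumed to be the
#'   counted allele).
#' @param model `prs_model` data.frame (see [generate_prs_model()],
#'   [read_scoring_file()]).
#' @return named numeric vector of per-sample scores.
#' @export
compute_prs <- function(dosages, model) {
  if (inherits(dosages, "dosage_matrix")) {
    X <- dosages$dosages
    variants <- dosages$variants
  } else {
    X <- as.matrix(dosages)
    variants <- NULL
  }
  missing_ids <- setdiff(model$rsID, colnames(X))
  if (length(missing_ids)) {
    stop("model variants absent from dosage matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  idx <- match(model$rsID, colnames(X))
  Xm <- X[, idx, drop = FALSE]
  w <- model$effect_weight
  if (!is.null(variants)) {
    ref <- variants$ref[idx]; alt <- variants$alt[idx]
    flip <- model$effect_allele == ref & model$effect_allele != alt
    bad <- model$effect_allele != alt & !flip
    if (any(bad)) {
      stop("effect allele matches neither REF nor ALT for: ",
           paste(model$rsID[bad], collapse = ", "))
    }
    if (any(flip)) Xm[, flip] <- 2 - Xm[, flip, drop = FALSE]
  }
  drop(Xm %*% w)
}

#' Ancestry-stratified percentile ranks
#'
#' Ranks each sample's score within its own ancestry group using the
#' midrank convention: `percentile_i = 100 * (c_less + 0.5 * c_equal) / n`,
#' where `c_less` counts group members with strictly smaller score and
#' `c_equal` counts members (including self) with an equal score. Groups
#' are ranked independently; a single-member group gets 50.
#'
#' @param scores numeric score vector (no NaN).
#' @param ancestry character/factor label per sample.
#' @return numeric vector of percentiles in \[0, 100\].
#' @export
percentile_rank <- function(scores, ancestry = rep("all", length(scores))) {
  if (any(is.na(scores))) stop("scores contain NA/NaN")
  if (length(ancestry) != length(scores)) stop("every sample needs an ancestry label")
  out <- numeric(length(scores))
  for (g in unique(ancestry)) {
    idx <- which(ancestry == g)
    # average rank = c_less + (c_equal + 1) / 2, so midrank = rank - 0.5
    out[idx] <- 100 * (rank(scores[idx], ties.method = "average") - 0.5) / length(idx)
  }
  names(out) <- names(scores)
  out
}

#' Assign quintile-style risk tiers
#'
#' Three tiers from two cut points (default 20/80): percentile strictly
#' below the lower cut is `low`, strictly above the upper cut is `high`,
#' and everything in between (boundaries included) is `intermediate` —
#' matching "< 20%tile" / "> 80%tile" row labels.
#'
#' @param percentiles numeric percentiles in \[0, 100\].
#' @param cuts length-2 increasing cut points in (0, 100).
#' @param labels tier labels, low to high.
#' @return factor of tier labels (levels in the given order).
#' @export
assign_tier <- function(percentiles, cuts = c(20, 80),
                        labels = c("low", "intermediate", "high")) {
  stopifnot(length(cuts) == 2, cuts[1] < cuts[2],
            cuts[1] > 0, cuts[2] < 100)
  tier <- ifelse(percentiles < cuts[1], labels[1],
                 ifelse(percentiles > cuts[2], labels[3], labels[2]))
  factor(tier, levels = labels)
}

#' Build a percentile frame from truth and replicate dosages
#'
#' Scores the truth (WGS-like gold standard) and every replicate with the
#' same PRS model, then converts scores to ancestry-stratified percentile
#' ranks. By default each replicate's scores are ranked within that
#' replicate's own score distribution (per ancestry group); with
#' `rank_within = "truth"` replicate scores are instead placed on the truth
#' score distribution.
#'
#' @param truth `dosage_matrix` of truth dosages.
#' @param reps `replicate_set` over the same cohort.
#' @param model `prs_model`.
#' @param ancestry label per sample.
#' @param rank_within `"replicate"` (default) or `"truth"`.
#' @return list of class `percentile_frame`: `wgs` (percentile vector),
#'   `reps` (samples x K percentile matrix), `ancestry`, `K`,
#'   `rank_within`.
#' @export
build_percentile_frame <- function(truth, reps, model, ancestry,
                                   rank_within = c("replicate", "truth")) {
  rank_within <- match.arg(rank_within)
  stopifnot(inherits(reps, "replicate_set"))
  truth_scores <- compute_prs(truth, model)
  wgs <- percentile_rank(truth_scores, ancestry)
  idx <- match(model$rsID, colnames(truth$dosages))
  flip <- model$effect_allele == truth$variants$ref[idx] &
    model$effect_allele != truth$variants$alt[idx]
  w <- model$effect_weight
  rep_pct <- vapply(reps$replicates, function(R) {
    Xm <- R[, idx, drop = FALSE]
    if (any(flip)) Xm[, flip] <- 2 - Xm[, flip, drop = FALSE]
    s <- drop(Xm %*% w)
    if (rank_within == "replicate") {
      percentile_rank(s, ancestry)
    } else {
      rank_against(s, truth_scores, ancestry)
    }
  }, numeric(nrow(truth$dosages)))
  structure(list(wgs = wgs, reps = rep_pct, ancestry = ancestry,
                 K = reps$K, rank_within = rank_within,
                 samples = truth$samples),
            class = "percentile_frame")
}

# Midrank percentile of `scores` within the reference distribution
# `ref_scores`, per ancestry group.
rank_against <- function(scores, ref_scores, ancestry) {
  out <- numeric(length(scores))
  for (g in unique(ancestry)) {
    idx <- which(ancestry == g)
    r <- ref_scores[idx]
    out[idx] <- vapply(scores[idx], function(s) {
      100 * (sum(r < s) + 0.5 * sum(r == s)) / length(r)
    }, numeric(1))
  }
  out
}

#' Construct a percentile frame directly from percentile values
#'
#' Convenience constructor for analyses that already have percentile ranks
#' (e.g. oracles and toy examples).
#'
#' @param wgs numeric WGS-based percentiles.
#' @param reps samples x K matrix of replicate percentiles.
#' @param ancestry label per sample (default one combined stratum).
#' @return a `percentile_frame`.
#' @export
percentile_frame <- function(wgs, reps, ancestry = rep("all", length(wgs))) {
  reps <- as.matrix(reps)
  stopifnot(nrow(reps) == length(wgs), length(ancestry) == length(wgs),
            all(wgs >= 0 & wgs <= 100), all(reps >= 0 & reps <= 100))
  structure(list(wgs = wgs, reps = reps, ancestry = ancestry,
                 K = ncol(reps), rank_within = "given",
                 samples = names(wgs) %||% paste0("S", seq_along(wgs))),
            class = "percentile_frame")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.percentile_frame <- function(x, ...) {
  cat(sprintf("<percentile_frame> %d samples, K=%d replicates, strata: %s\n",
              length(x$wgs), x$K,
              paste(unique(x$ancestry), collapse = ", ")))
  invisible(x)
}
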