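#' Per-SNP Gini coefficient of imputation consistency
#'
#' For one variant, each individual's K replicate dosages x_1..x_K yield a
#' Gini coefficient `G = sum_{a,b} |x_a - x_b| / (2 K^2 mean(x))` (over all
#' ordered pairs), with G defined as 0 when the mean is 0 or all values are
#' equal; the variant's Gini is the mean over individuals. G ranges from 0
#' to 1, where 0 corresponds to completely consistent imputation results
#' across replicates — typed variants, copied from the truth in every
#' replicate, have G = 0 exactly.
#'
#' @param reps `replicate_set` with K >= 2.
#' @param variant variant identifier (column name) or index; NULL (default)
#'   computes all variants.
#' @return named numeric vector of per-variant Gini coefficients (scalar
#'   when `variant` is given).
#' @export
snp_gini <- function(reps, variant = NULL) {
  if (reps$K < 2) stop("Gini undefined for K < 2 replicates")
  cols <- if (is.null(variant)) seq_len(ncol(reps$replicates[[1]])) else variant
  if (is.character(cols)) {
    cols <- match(cols, colnames(reps$replicates[[1]]))
    if (anyNA(cols)) stop("unknown variant identifier")
  }
  K <- reps$K
  pairs <- utils::combn(K, 2)
  N <- nrow(reps$replicates[[1]])
  out <- vapply(cols, function(j) {
    X <- matrix(vapply(reps$replicates, function(R) R[, j], numeric(N)),
                nrow = N)  # N x K
    S <- 0
    for (p in seq_len(ncol(pairs))) {
      S <- S + abs(X[, pairs[1, p]] - X[, pairs[2, p]])
    }
    S <- 2 * S                       # ordered pairs
    m <- rowMeans(X)
    g <- ifelse(m == 0 | S == 0, 0, S / (2 * K^2 * m))
    mean(g)
  }, numeric(1))
  names(out) <- colnames(reps$replicates[[1]])[cols]
  if (length(out) == 1 && !is.null(variant)) unname(out) else out
}

#' Per-individual Gini for a dosage replicate matrix
#'
#' Helper exposing the per-individual Gini underlying [snp_gini()]:
#' given an individuals x K matrix of replicate dosages for one variant,
#' returns each individual's Gini coefficient.
#'
#' @param X numeric matrix, individuals x K replicate dosages.
#' @return numeric vector of per-individual Gini values in \[0, 1\].
#' @export
gini_per_individual <- function(X) {
  X <- as.matrix(X)
  K <- ncol(X)
  if (K < 2) stop("Gini undefined for K < 2 replicates")
  pairs <- utils::combn(K, 2)
  S <- 0
  for (p in seq_len(ncol(pairs))) {
    S <- S + abs(X[, pairs[1, p]] - X[, pairs[2, p]])
  }
  S <- 2 * S
  m <- rowMeans(X)
  ifelse(m == 0 | S == 0, 0, S / (2 * K^2 * m))
}

#' Percent variance explained per score SNP
#'
#' Each SNP's contribution to the score is `v_j = beta_j^2 * Var(x_j)` with
#' the empirical cohort dosage variance of the truth dosages (so no
#' Hardy-Weinberg assumption is needed; under HWE Var(x_j) ~ 2 p_j (1-p_j)),
#' normalized to percent: `PVE_j = 100 * v_j / sum_k v_k`.
#'
#' @param model `prs_model`.
#' @param truth `dosage_matrix` containing every model variant.
#' @return named numeric vector of PVE values summing to 100.
#' @export
percent_variance_explained <- function(model, truth) {
  X <- if (inherits(truth, "dosage_matrix")) truth$dosages else as.matrix(truth)
  missing_ids <- setdiff(model$rsID, colnames(X))
  if (length(missing_ids)) {
    stop("model variants absent from dosage matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  Xm <- X[, match(model$rsID, colnames(X)), drop = FALSE]
  v <- model$effect_weight^2 * apply(Xm, 2, stats::var)
  if (sum(v) == 0) stop("degenerate score: all per-variant variances are zero")
  stats::setNames(100 * v / sum(v), model$rsID)
}

#' Gini / PVE contribution table
#'
#' Combines imputation consistency ([snp_gini()]) with score impact
#' ([percent_variance_explained()]) per score SNP, the decomposition behind
#' the quadrant view of score variability: a high-weight SNP with moderate
#' imputation variability drives single-SNP score excursions, while many
#' low-weight SNPs with high variability accumulate errors.
#'
#' @param reps `replicate_set`.
#' @param model `prs_model`.
#' @param truth `dosage_matrix`.
#' @return data.frame: `rsID`, `typed`, `effect_weight`, `gini`, `pve`.
#' @export
gini_pve_table <- function(reps, model, truth) {
  gini <- snp_gini(reps)
  pve <- percent_variance_explained(model, truth)
  idx <- match(model$rsID, colnames(truth$dosages))
  data.frame(rsID = model$rsID,
             typed = reps$mask[idx],
             effect_weight = model$effect_weight,
             gini = unname(gini[model$rsID]),
             pve = unname(pve[model$rsID]),
             stringsAsFactors = FALSE)
}

#' Label contribution quadrants
#'
#' Splits SNPs into quadrants by a Gini cut and a PVE cut, naming the two
#' highlighted classes: `single_snp_events` (high PVE, Gini above zero but
#' any level) vs `error_accumulation` (low PVE, high Gini).
#'
#' @param table data.frame from [gini_pve_table()].
#' @param gini_cut Gini threshold in (0, 1).
#' @param pve_cut PVE threshold in (0, 100).
#' @return the table with added `quadrant` label
#'   (`"high_pve_high_gini"` etc.) and an attribute `groups` listing the
#'   rsIDs of the two highlighted classes.
#' @export
contribution_quadrants <- function(table, gini_cut = 0.05, pve_cut = 1) {
  stopifnot(gini_cut > 0, gini_cut < 1, pve_cut > 0, pve_cut < 100)
  hi_g <- table$gini > gini_cut
  hi_p <- table$pve > pve_cut
  table$quadrant <- paste0(ifelse(hi_p, "high_pve", "low_pve"), "_",
                           ifelse(hi_g, "high_gini", "low_gini"))
  attr(table, "groups") <- list(
    single_snp_events = table$rsID[hi_p & table$gini > 0],
    error_accumulation = table$rsID[!hi_p & hi_g])
  table
}
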