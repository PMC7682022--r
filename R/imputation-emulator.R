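#' Parametric imputation emulator
#'
#' Emulates K replicate imputation runs by adding Gaussian error to the
#' truth dosages of untyped variants, calibrated so the expected squared
#' correlation between imputed and truth dosage equals `r2_target` per
#' variant. The error has two parts: a per-(individual, variant) component
#' shared by all replicates (systematic imputation difficulty) and an
#' independent per-replicate component with standard deviation `sigma_run`
#' (run-to-run stochasticity, e.g. from pre-phasing). With the truth dosage
#' variance V, the total error variance is V (1 - R2) / R2, so the
#' population-level accuracy is pinned by `r2_target` regardless of how
#' `sigma_run` partitions it. Results are clipped to \[0, 2\]; typed
#' variants are copied from the truth.
#'
#' @param truth `dosage_matrix` of truth dosages.
#' @param mask logical typed mask (TRUE = typed, copied verbatim).
#' @param r2_target target per-variant squared correlation, in (0, 1\].
#' @param sigma_run per-replicate error standard deviation (dosage units,
#'   >= 0). If `sigma_run^2` exceeds the total error variance for a variant,
#'   the per-replicate part is capped there and noted in the metadata.
#' @param K number of replicates (>= 1).
#' @param master_seed integer seed.
#' @return a `replicate_set` (process `"parametric"`). Metadata records the
#'   per-variant achieved post-clipping R2 and a warning flag when the mean
#'   achieved R2 falls short of the target by more than 0.02.
#' @export
emulate_parametric <- function(truth, mask, r2_target, sigma_run, K = 6L,
                               master_seed = 1L) {
  stopifnot(inherits(truth, "dosage_matrix"),
            r2_target > 0, r2_target <= 1, sigma_run >= 0, K >= 1)
  X <- truth$dosages
  N <- nrow(X); L <- ncol(X)
  if (length(mask) != L) stop("mask length must equal variant count")
  untyped <- which(!mask)
  V <- apply(X[, untyped, drop = FALSE], 2, stats::var)
  err_var <- V * (1 - r2_target) / r2_target
  rep_sd <- pmin(sigma_run, sqrt(err_var))
  shared_sd <- sqrt(pmax(0, err_var - rep_sd^2))
  capped <- sigma_run > 0 && any(sigma_run^2 > err_var + 1e-12)
  seeds <- derive_seeds(master_seed, c("shared", paste0("rep", seq_len(K))))
  shared <- withr_seed(seeds[["shared"]], {
    matrix(stats::rnorm(N * length(untyped), 0, rep(shared_sd, each = N)),
           nrow = N)
  })
  reps <- lapply(seq_len(K), function(k) {
    noise <- withr_seed(seeds[[paste0("rep", k)]], {
      matrix(stats::rnorm(N * length(untyped), 0, rep(rep_sd, each = N)),
             nrow = N)
    })
    R <- X
    R[, untyped] <- pmin(2, pmax(0, X[, untyped, drop = FALSE] + shared + noise))
    R
  })
  achieved <- vapply(untyped, function(j) {
    mean(vapply(reps, function(R) dosage_r2(R[, j], X[, j]), numeric(1)))
  }, numeric(1))
  warn <- mean(achieved) < r2_target - 0.02
  replicate_set(reps, process = "parametric", mask = mask,
                seeds = unname(seeds[-1]),
                metadata = list(r2_target = r2_target, sigma_run = sigma_run,
                                achieved_r2 = achieved,
                                sigma_run_capped = capped,
                                r2_shortfall_warning = warn))
}

#' Haplotype-copying (HMM) imputation emulator
#'
#' Imputes the untyped variants of each truth haplotype from its typed
#' alleles via the Li-Stephens copying chain over a reference panel
#' ([hmm_posterior()]). Two modes operationalize the contrast between
#' deterministic and stochastic imputation engines:
#' \describe{
#'   \item{deterministic}{each replicate's untyped dosage is the sum over
#'     the individual's two haplotypes of the posterior allele probability —
#'     identical across replicates (a seed-free posterior mean).}
#'   \item{sampled}{each replicate backward-samples one copying path per
#'     haplotype and emits the sampled alleles, so replicates differ from
#'     run to run.}
#' }
#' Typed sites are copied from the truth in both modes.
#'
#' @param truth_haplotypes 2N x L 0/1 matrix of phased truth haplotypes
#'   (rows 2i-1, 2i per individual), as returned by [simulate_cohort()].
#' @param mask logical typed mask over the L variants.
#' @param panel `haplotype_panel` reference panel on the same variants.
#' @param rho,theta Li-Stephens switch and mismatch probabilities.
#' @param K number of replicates.
#' @param mode `"deterministic"` or `"sampled"`.
#' @param master_seed integer seed (used only in sampled mode).
#' @param batch_size chains per forward-backward batch.
#' @return a `replicate_set` (process `"hmm_deterministic"` or
#'   `"hmm_sampled"`).
#' @export
emulate_hmm <- function(truth_haplotypes, mask, panel, rho = 0.05,
                        theta = 0.01, K = 6L,
                        mode = c("deterministic", "sampled"),
                        master_seed = 1L, batch_size = 512L) {
  mode <- match.arg(mode)
  hap <- if (inherits(panel, "haplotype_panel")) panel$haplotypes else panel
  L <- ncol(truth_haplotypes)
  if (ncol(hap) != L) stop("cohort variants do not match panel variants")
  if (length(mask) != L) stop("mask length must equal variant count")
  n_chains <- nrow(truth_haplotypes)
  stopifnot(n_chains %% 2 == 0)
  N <- n_chains %/% 2
  odd <- seq(1L, n_chains, by = 2L); even <- odd + 1L
  truth_dos <- truth_haplotypes[odd, , drop = FALSE] +
    truth_haplotypes[even, , drop = FALSE]
  if (!is.null(rownames(truth_haplotypes))) {
    rownames(truth_dos) <- sub("_h1$", "", rownames(truth_haplotypes)[odd])
  }
  observed <- truth_haplotypes[, mask, drop = FALSE]
  untyped <- !mask
  if (mode == "deterministic") {
    post <- hmm_posterior(observed, mask, panel, rho, theta, batch_size)
    imp <- truth_dos
    imp[, untyped] <- post[odd, untyped, drop = FALSE] +
      post[even, untyped, drop = FALSE]
    reps <- rep(list(imp), K)
    seeds <- rep(NA_integer_, K)
  } else {
    seeds <- derive_seeds(master_seed, paste0("rep", seq_len(K)))
    draws <- hmm_sample_alleles(observed, mask, panel, rho, theta,
                                n_paths = K, rng_seed = master_seed,
                                batch_size = batch_size)
    reps <- lapply(draws, function(A) {
      imp <- truth_dos
      imp[, untyped] <- A[odd, untyped, drop = FALSE] +
        A[even, untyped, drop = FALSE]
      imp
    })
    seeds <- unname(seeds)
  }
  replicate_set(reps, process = paste0("hmm_", mode), mask = mask,
                seeds = seeds,
                metadata = list(rho = rho, theta = theta, mode = mode,
                                panel_size = nrow(hap)))
}
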