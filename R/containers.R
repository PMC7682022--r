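#' Dosage matrix container
#'
#' Bundles a samples x variants matrix of effect-allele dosages with the
#' variant annotation needed for scoring and VCF round trips. Dosages are
#' expected counts of the ALT (counted) allele, in \[0, 2\]; hard genotypes
#' are 0/1/2.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (one row per matrix column, `pos` 1-based).
#' @param samples character vector of sample identifiers; defaults to the
#'   matrix rownames.
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(variants) == ncol(dosages),
            length(samples) == nrow(dosages))
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant identifiers: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  }
  # tolerate float-noise excursions (e.g. posterior sums a hair over 2)
  if (any(dosages < -1e-9 | dosages > 2 + 1e-9, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  dosages[] <- pmin(pmax(dosages, 0), 2)
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' Replicate set container
#'
#' Holds K imputed dosage matrices produced by one imputation process over
#' the same cohort, the typed-variant mask used, and per-replicate seeds.
#' Typed variants are copied from the truth in every replicate; untyped
#' dosages lie in \[0, 2\].
#'
#' @param replicates list of K numeric matrices sharing dimensions.
#' @param process character process label.
#' @param mask logical vector, TRUE for typed (directly genotyped) variants.
#' @param seeds integer vector of per-replicate seeds (may be NA for
#'   seed-free deterministic processes).
#' @param metadata list of free-form process metadata.
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(replicates, process, mask,
                          seeds = rep(NA_integer_, length(replicates)),
                          metadata = list()) {
  stopifnot(is.list(replicates), length(replicates) >= 1, is.logical(mask))
  d <- dim(replicates[[1]])
  for (r in replicates) {
    if (!identical(dim(r), d)) stop("replicate dimensions differ")
    if (any(r < -1e-9 | r > 2 + 1e-9)) stop("replicate dosages outside [0, 2]")
  }
  if (length(mask) != d[2]) stop("mask length must equal variant count")
  structure(list(replicates = replicates, process = process, mask = mask,
                 K = length(replicates), seeds = seeds, metadata = metadata),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> process '%s': K=%d replicates, %d samples x %d variants (%d typed)\n",
              x$process, x$K, nrow(x$replicates[[1]]), ncol(x$replicates[[1]]),
              sum(x$mask)))
  invisible(x)
}

#' Check that a replicate set is consistent with its truth matrix
#'
#' Verifies shared dimensions and exact typed-site fidelity (typed dosages
#' equal truth in every replicate).
#'
#' @param reps a `replicate_set`.
#' @param truth a `dosage_matrix` (or plain matrix) of truth dosages.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_replicate_set <- function(reps, truth) {
  tm <- if (inherits(truth, "dosage_matrix")) truth$dosages else truth
  for (k in seq_len(reps$K)) {
    r <- reps$replicates[[k]]
    if (!identical(dim(r), dim(tm))) stop("replicate ", k, " dimensions differ from truth")
    if (any(reps$mask) && !isTRUE(all.equal(r[, reps$mask, drop = FALSE],
                                            tm[, reps$mask, drop = FALSE],
                                            tolerance = 0))) {
      stop("replicate ", k, " modifies typed-variant dosages")
    }
  }
  invisible(TRUE)
}

#' Default variant annotation for synthetic cohorts
#'
#' One chromosome, evenly spaced positions, A>G SNPs (ALT = counted
#' allele).
#'
#' @param n_variants number of variants.
#' @param chrom chromosome label.
#' @param spacing base-pair spacing between adjacent variants.
#' @return data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
synthetic_variant_table <- function(n_variants, chrom = "1", spacing = 1000L) {
  data.frame(id = sprintf("snp%04d", seq_len(n_variants)),
             chrom = chrom,
             pos = as.integer(seq_len(n_variants)) * spacing,
             ref = "A", alt = "G",
             stringsAsFactors = FALSE)
}
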