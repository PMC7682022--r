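#' Draw ancestral allele frequencies
#'
#' Samples per-variant ancestral allele frequencies whose minor-allele
#' frequency (MAF) is uniform on `maf_range`; each frequency is then oriented
#' at random (p or 1-p with equal probability) so the counted allele is not
#' systematically the minor one.
#'
#' @param n_variants number of variants (> 0).
#' @param maf_range numeric length-2, 0 < lower < upper <= 0.5.
#' @param rng_seed integer seed.
#' @return numeric vector of allele frequencies in (0, 1).
#' @export
draw_ancestral_frequencies <- function(n_variants, maf_range = c(0.05, 0.5),
                                       rng_seed = 1L) {
  if (length(n_variants) != 1 || n_variants <= 0) stop("n_variants must be a positive count")
  lo <- maf_range[1]; hi <- maf_range[2]
  if (!(lo > 0 && lo < hi && hi <= 0.5)) {
    stop("maf_range must satisfy 0 < lower < upper <= 0.5")
  }
  withr_seed(rng_seed, {
    maf <- stats::runif(n_variants, lo, hi)
    flip <- stats::runif(n_variants) < 0.5
    ifelse(flip, 1 - maf, maf)
  })
}

#' Derive population-specific allele frequencies (Balding-Nichols)
#'
#' Draws per-variant population frequencies from the Balding-Nichols model:
#' Beta with mean p and variance fst * p * (1 - p), i.e. shapes
#' p(1-fst)/fst and (1-p)(1-fst)/fst. `fst = 0` returns the ancestral
#' frequencies unchanged.
#'
#' @param ancestral numeric vector of ancestral frequencies in (0, 1).
#' @param fst divergence parameter in \[0, 1).
#' @param rng_seed integer seed.
#' @param label population label.
#' @return list of class `population_freqs` with `label`, `freq`, `fst`.
#' @export
derive_population_frequencies <- function(ancestral, fst, rng_seed = 1L,
                                          label = "pop") {
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  stopifnot(all(ancestral > 0 & ancestral < 1))
  freq <- if (fst == 0) {
    ancestral
  } else {
    withr_seed(rng_seed, {
      stats::rbeta(length(ancestral),
                   shape1 = ancestral * (1 - fst) / fst,
                   shape2 = (1 - ancestral) * (1 - fst) / fst)
    })
  }
  structure(list(label = label, freq = freq, fst = fst),
            class = "population_freqs")
}

#' Simulate a haplotype reference panel with block linkage disequilibrium
#'
#' Variants are partitioned into consecutive blocks of `block_length`.
#' Within a block each haplotype copies one of `n_founders` founder patterns
#' (drawn Bernoulli at the target frequency) and then mutates each allele
#' back toward the target frequency with probability `mutation_rate`, so the
#' marginal per-variant frequency stays unbiased while haplotypes sharing a
#' founder are correlated: nonzero LD within blocks, ~zero LD across blocks.
#' With `block_length = 1` alleles are drawn iid Bernoulli(p) per haplotype,
#' so per-variant frequencies match the target within binomial sampling
#' error and inter-variant LD is zero by construction.
#'
#' @param freqs `population_freqs` (or numeric frequency vector).
#' @param n_haplotypes number of panel haplotypes (>= 2).
#' @param block_length variants per LD block (>= 1).
#' @param rng_seed integer seed.
#' @param n_founders founder patterns per block (controls within-block LD).
#' @param mutation_rate per-variant probability of resampling the allele at
#'   the target frequency.
#' @return list of class `haplotype_panel` with `haplotypes` (H x L 0/1
#'   matrix), `positions`, `population` (label per haplotype).
#' @export
simulate_haplotype_panel <- function(freqs, n_haplotypes, block_length,
                                     rng_seed = 1L, n_founders = 4L,
                                     mutation_rate = 0.005) {
  p <- if (inherits(freqs, "population_freqs")) freqs$freq else freqs
  label <- if (inherits(freqs, "population_freqs")) freqs$label else "pop"
  if (n_haplotypes < 2) stop("n_haplotypes must be >= 2")
  if (block_length < 1) stop("block_length must be >= 1")
  L <- length(p)
  H <- as.integer(n_haplotypes)
  hap <- withr_seed(rng_seed, {
    if (block_length == 1) {
      matrix(stats::rbinom(H * L, 1L, rep(p, each = H)), nrow = H, ncol = L)
    } else {
      out <- matrix(0L, nrow = H, ncol = L)
      starts <- seq(1L, L, by = block_length)
      for (s in starts) {
        idx <- s:min(s + block_length - 1L, L)
        pb <- p[idx]
        founders <- matrix(stats::rbinom(n_founders * length(idx), 1L,
                                         rep(pb, each = n_founders)),
                           nrow = n_founders)
        pick <- sample.int(n_founders, H, replace = TRUE)
        blk <- founders[pick, , drop = FALSE]
        mut <- matrix(stats::runif(H * length(idx)) < mutation_rate,
                      nrow = H)
        fresh <- matrix(stats::rbinom(H * length(idx), 1L, rep(pb, each = H)),
                        nrow = H)
        blk[mut] <- fresh[mut]
        out[, idx] <- blk
      }
      out
    }
  })
  structure(list(haplotypes = hap,
                 positions = as.integer(seq_len(L)) * 1000L,
                 population = rep(label, H)),
            class = "haplotype_panel")
}

#' Subset a haplotype panel
#'
#' Haplotypes within one generated panel are exchangeable, so disjoint
#' subsets of a single panel draw (e.g. a cohort pool and a reference
#' panel) share the same founder/LD structure, as a cohort and a matched
#' reference resource do in real data.
#'
#' @param panel a `haplotype_panel`.
#' @param idx haplotype row indices to keep.
#' @return a `haplotype_panel`.
#' @export
subset_panel <- function(panel, idx) {
  structure(list(haplotypes = panel$haplotypes[idx, , drop = FALSE],
                 positions = panel$positions,
                 population = panel$population[idx]),
            class = "haplotype_panel")
}

#' Combine haplotype panels from several populations
#'
#' @param ... `haplotype_panel` objects over the same variants.
#' @return a single `haplotype_panel` with concatenated haplotypes.
#' @export
combine_panels <- function(...) {
  panels <- list(...)
  L <- ncol(panels[[1]]$haplotypes)
  for (p in panels) stopifnot(ncol(p$haplotypes) == L)
  structure(list(haplotypes = do.call(rbind, lapply(panels, `[[`, "haplotypes")),
                 positions = panels[[1]]$positions,
                 population = unlist(lapply(panels, `[[`, "population"))),
            class = "haplotype_panel")
}

#' Simulate a diploid cohort from a haplotype panel
#'
#' Each individual receives two haplotypes sampled with replacement from the
#' panel haplotypes of its population; the truth dosage is the allele sum
#' (0/1/2). The phased truth haplotypes are retained for the
#' haplotype-copying emulator.
#'
#' @param panel `haplotype_panel` whose `population` labels cover the
#'   requested populations.
#' @param n_per_population named integer vector, individuals per population.
#' @param rng_seed integer seed.
#' @return list with `truth` (a `dosage_matrix`), `ancestry` (character
#'   label per sample) and `haplotypes` (2N x L 0/1 matrix, rows 2i-1 and 2i
#'   belong to individual i).
#' @export
simulate_cohort <- function(panel, n_per_population, rng_seed = 1L) {
  pops <- names(n_per_population)
  if (is.null(pops)) stop("n_per_population must be named by population")
  missing_pops <- setdiff(pops, unique(panel$population))
  if (length(missing_pops)) {
    stop("populations absent from panel: ", paste(missing_pops, collapse = ", "))
  }
  N <- sum(n_per_population)
  L <- ncol(panel$haplotypes)
  withr_seed(rng_seed, {
    hap_rows <- integer(2 * N)
    ancestry <- character(N)
    i <- 0L
    for (pop in pops) {
      pool <- which(panel$population == pop)
      n <- n_per_population[[pop]]
      draws <- sample(pool, 2L * n, replace = TRUE)
      hap_rows[(2L * i + 1L):(2L * (i + n))] <- draws
      ancestry[(i + 1L):(i + n)] <- pop
      i <- i + n
    }
    haps <- panel$haplotypes[hap_rows, , drop = FALSE]
    dos <- haps[seq(1, 2 * N, by = 2), , drop = FALSE] +
      haps[seq(2, 2 * N, by = 2), , drop = FALSE]
    variants <- synthetic_variant_table(L)
    samples <- sprintf("S%04d", seq_len(N))
    rownames(haps) <- paste0(rep(samples, each = 2), c("_h1", "_h2"))
    colnames(haps) <- variants$id
    list(truth = dosage_matrix(dos, variants, samples),
         ancestry = stats::setNames(ancestry, samples),
         haplotypes = haps)
  })
}

#' Generate a synthetic PRS weight model
#'
#' Weights are drawn symmetric about zero at scale `weight_scale`
#' (Normal(0, weight_scale^2)); `n_high_weight` randomly chosen variants have
#' their weight multiplied by `high_weight_multiplier`, emulating scores
#' dominated by a few large-effect loci.
#'
#' @param n_variants number of score variants.
#' @param weight_scale positive base scale of effect weights (log odds ratio
#'   per effect-allele dosage).
#' @param n_high_weight number of high-weight variants (<= n_variants).
#' @param high_weight_multiplier positive multiplier applied to those.
#' @param rng_seed integer seed.
#' @param variants optional variant annotation (defaults to the synthetic
#'   table used by [simulate_cohort()]).
#' @return data.frame of class `prs_model` with columns `rsID`, `chr_name`,
#'   `chr_position`, `effect_allele`, `other_allele`, `effect_weight`.
#' @export
generate_prs_model <- function(n_variants, weight_scale = 0.1,
                               n_high_weight = 0L, high_weight_multiplier = 5,
                               rng_seed = 1L, variants = NULL) {
  if (n_high_weight > n_variants) stop("n_high_weight must be <= n_variants")
  stopifnot(weight_scale > 0, high_weight_multiplier > 0)
  if (is.null(variants)) variants <- synthetic_variant_table(n_variants)
  withr_seed(rng_seed, {
    w <- stats::rnorm(n_variants, 0, weight_scale)
    if (n_high_weight > 0) {
      hi <- sample.int(n_variants, n_high_weight)
      w[hi] <- w[hi] * high_weight_multiplier
    }
    model <- data.frame(rsID = variants$id,
                        chr_name = variants$chrom,
                        chr_position = variants$pos,
                        effect_allele = variants$alt,
                        other_allele = variants$ref,
                        effect_weight = w,
                        stringsAsFactors = FALSE)
    class(model) <- c("prs_model", "data.frame")
    model
  })
}

#' Assign a typed / untyped variant mask
#'
#' Flags a uniformly random subset of `round(fraction_typed * n_variants)`
#' variants as typed (directly genotyped); the rest are untyped and must be
#' imputed.
#'
#' @param n_variants variant count.
#' @param fraction_typed fraction in (0, 1\].
#' @param rng_seed integer seed.
#' @return logical vector, TRUE = typed; at least one typed variant.
#' @export
assign_typed_mask <- function(n_variants, fraction_typed, rng_seed = 1L) {
  if (fraction_typed <= 0 || fraction_typed > 1) {
    stop("fraction_typed must lie in (0, 1]")
  }
  n_typed <- round(fraction_typed * n_variants)
  if (n_typed < 1) stop("fraction_typed yields zero typed variants")
  withr_seed(rng_seed, {
    mask <- rep(FALSE, n_variants)
    mask[sample.int(n_variants, n_typed)] <- TRUE
    mask
  })
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so independent stages never share streams.
withr_seed <- function(seed, expr) {
  force(seed)  # the seed may itself be drawn from the caller's RNG stream
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive per-stage seeds from one master seed
#'
#' All randomness in the pipeline flows from a single master seed; each named
#' stage gets its own reproducible derived stream.
#'
#' @param master_seed integer master seed.
#' @param stages character vector of stage names.
#' @return named integer vector of derived seeds (all < 2^31).
#' @export
derive_seeds <- function(master_seed, stages) {
  withr_seed(master_seed, {
    stats::setNames(sample.int(.Machine$integer.max, length(stages)), stages)
  })
}
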