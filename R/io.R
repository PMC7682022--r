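#' Read a dosage matrix from a VCF
#'
#' Reads biallelic records from a VCF (plain or gzipped) into a
#' `dosage_matrix`. The counted (effect-candidate) allele is ALT; the
#' per-sample dosage comes from the DS FORMAT field when present, else from
#' the GT allele sum. Multiallelic records are an error naming the site
#' (they must be excluded upstream, as are duplicates).
#'
#' @param path VCF file path.
#' @return a `dosage_matrix` with 1-based VCF positions preserved.
#' @export
read_dosage_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic record(s) at: ",
         paste(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]),
               collapse = ", "))
  }
  has_ds <- grepl("DS", v@gt[1, "FORMAT"])
  has_gt <- grepl("GT", v@gt[1, "FORMAT"])
  if (!has_ds && !has_gt) stop("VCF carries neither DS nor GT FORMAT fields")
  if (has_ds) {
    dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  variants <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  dosage_matrix(t(dos), variants, samples = colnames(dos))
}

#' Write a dosage matrix as VCF
#'
#' Emits VCF 4.2 with per-sample GT (dosage rounded to the nearest hard
#' call, ties rounding down) and DS (dosage, 3 decimals); records are
#' ordered by (chromosome, position) and samples follow the matrix order.
#' Output is gzip-compressed (use a `.vcf.gz` path).
#'
#' @param mat `dosage_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dosage_vcf <- function(mat, path) {
  stopifnot(inherits(mat, "dosage_matrix"))
  ord <- order(mat$variants$chrom, mat$variants$pos)
  variants <- mat$variants[ord, ]
  X <- mat$dosages[, ord, drop = FALSE]
  gt_call <- c("0/0", "0/1", "1/1")[dosage_to_genotype(X) + 1L]
  cells <- matrix(paste0(gt_call, ":", sprintf("%.3f", X)),
                  nrow = nrow(X))
  fix <- cbind(CHROM = variants$chrom, POS = as.character(variants$pos),
               ID = variants$id, REF = variants$ref, ALT = variants$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gt <- cbind(FORMAT = "GT:DS", t(cells))
  colnames(gt) <- c("FORMAT", mat$samples)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">")
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  tryCatch(vcfR::write.vcf(v, file = path),
           error = function(e) stop("failed writing VCF to '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a PGS-Catalog-style scoring file
#'
#' Tab-separated with a header; `#` comment lines (PGS Catalog metadata)
#' are skipped. Required columns: `rsID`, `chr_name`, `chr_position`,
#' `effect_allele`, `other_allele`, `effect_weight`. Duplicate variant
#' identifiers and unparseable weights are rejected by name.
#'
#' @param path scoring file path.
#' @return a `prs_model` data.frame.
#' @export
read_scoring_file <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("rsID", "chr_name", "chr_position", "effect_allele",
                "other_allele", "effect_weight")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("scoring file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- df$rsID[duplicated(df$rsID)]
  if (length(dup)) {
    stop("duplicate variant identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  w <- suppressWarnings(as.numeric(trimws(df$effect_weight)))
  if (anyNA(w)) {
    stop("unparseable effect_weight for: ",
         paste(df$rsID[is.na(w)], collapse = ", "))
  }
  model <- data.frame(rsID = trimws(df$rsID),
                      chr_name = trimws(df$chr_name),
                      chr_position = as.integer(trimws(df$chr_position)),
                      effect_allele = trimws(df$effect_allele),
                      other_allele = trimws(df$other_allele),
                      effect_weight = w,
                      stringsAsFactors = FALSE)
  class(model) <- c("prs_model", "data.frame")
  model
}

#' Write a PRS model as a scoring file
#'
#' @param model `prs_model`.
#' @param path output path (tab-separated).
#' @return the path, invisibly.
#' @export
write_scoring_file <- function(model, path) {
  utils::write.table(as.data.frame(model), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write ancestry labels
#'
#' Two-column tab-separated format: `sample`, `population`.
#'
#' @param path file path.
#' @return named character vector of population labels.
#' @export
read_ancestry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$population, df$sample)
}

#' @rdname read_ancestry
#' @param ancestry named character vector (names = samples).
#' @export
write_ancestry <- function(ancestry, path) {
  utils::write.table(data.frame(sample = names(ancestry),
                                population = unname(ancestry)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All knobs of the end-to-end synthetic study in one list: cohort sizes
#' per population, divergence (F_ST), score size, typed fraction, emulator
#' settings per process, replicate count, tier cuts and bin counts. The
#' defaults emulate a two-population cohort with a majority population
#' matched to the imputation reference panel and a divergent minority
#' population.
#'
#' @param master_seed integer master seed feeding every stage's derived
#'   stream.
#' @return a named list (class `run_config`).
#' @export
default_run_config <- function(master_seed = 1L) {
  structure(list(
    master_seed = as.integer(master_seed),
    n_variants = 200L,
    maf_range = c(0.05, 0.5),
    fst = 0.15,
    cohort = list(popA = 1700L, popB = 300L),
    panel_haplotypes = 120L,
    pool_haplotypes = 240L,
    block_length = 100L,
    n_founders = 4L,
    mutation_rate = 0.005,
    fraction_typed = 0.25,
    weight_scale = 0.1,
    n_high_weight = 4L,
    high_weight_multiplier = 5,
    K = 6L,
    hmm = list(rho = 0.005, theta = 0.01),
    parametric = list(r2_target = 0.9, sigma_run = 0.1),
    tier_cuts = c(20, 80),
    n_bins = 10L,
    range_thresholds = c(1, 5, 10, 20)
  ), class = "run_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' Round-trips [default_run_config()]-style lists through a human-readable
#' YAML file with identity.
#'
#' @param path config file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$master_seed <- as.integer(cfg$master_seed)
  for (f in c("n_variants", "panel_haplotypes", "block_length", "n_founders",
              "K", "n_high_weight", "n_bins")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (!is.null(cfg$cohort)) cfg$cohort <- lapply(cfg$cohort, as.integer)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config a `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
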