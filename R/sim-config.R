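#' Simulation configuration for the synthetic proteogenomic study
#'
#' Bundles and validates every parameter of the synthetic-data generators:
#' cohort sizes, the LD-block layout of the genotype panel, planted
#' SNP-to-aptamer effects, covariate effects, and the liability-threshold
#' disease model with protein mediation.
#'
#' @param n_samples named integer vector, samples per cohort
#'   (e.g. \code{c(cohortA = 1000, cohortB = 800)}).
#' @param n_variants total number of biallelic variants.
#' @param block_sizes integer vector of LD-block sizes; must sum to
#'   \code{n_variants}. Variants in different blocks are independent.
#' @param within_block_rho latent AR(1) haplotype correlation in [0, 1);
#'   adjacent variants in a block have latent correlation \code{rho},
#'   variants \code{k} apart \code{rho^k}.
#' @param maf_range length-2 vector in (0, 0.5]; per-variant minor allele
#'   frequencies are drawn uniformly from this interval.
#' @param block_chrom chromosome label per block (recycled).
#' @param block_start first base-pair position per block; defaults place
#'   consecutive blocks 2 Mb apart starting at 39.5 Mb so a sentinel block
#'   lands inside the canonical chr12 39-41.5 Mb window.
#' @param variant_spacing base pairs between consecutive variants in a block.
#' @param n_aptamers number of aptamers on the synthetic panel.
#' @param aptamer_map optional data.frame (aptamer_id, gene, chrom, start,
#'   end) mapping aptamers to coding regions; auto-generated when NULL.
#' @param planted_effects data.frame (variant_id, aptamer_id, beta) of true
#'   genetic effects in SD-protein per effect (alt) allele; may be empty.
#' @param covariate_effects list with elements \code{age}, \code{sex}
#'   (scalar or per-aptamer named vectors of effects per year / per male)
#'   and \code{array_sd} (SD of random per-array shifts).
#' @param noise_sd residual SD of the latent (log10-scale) protein level.
#' @param disease list with \code{mediation} (data.frame aptamer_id, theta:
#'   liability units per SD of the protein's genetic component),
#'   \code{direct_snp_effects} (data.frame variant_id, beta) and
#'   \code{prevalence} in (0, 1).
#' @param seed integer seed; all generators draw from one stream seeded here.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = c(cohort1 = 1000),
                       n_variants = 100,
                       block_sizes = n_variants,
                       within_block_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       block_chrom = "12",
                       block_start = NULL,
                       variant_spacing = 5000,
                       n_aptamers = 10,
                       aptamer_map = NULL,
                       planted_effects = NULL,
                       covariate_effects = list(age = 0, sex = 0, array_sd = 0),
                       noise_sd = 1,
                       disease = list(mediation = NULL,
                                      direct_snp_effects = NULL,
                                      prevalence = 0.1),
                       seed = 1L) {
  if (is.null(names(n_samples))) {
    names(n_samples) <- paste0("cohort", seq_along(n_samples))
  }
  if (sum(block_sizes) != n_variants) {
    pp_stop("block_sizes must sum to n_variants", "invalid_config")
  }
  if (within_block_rho < 0 || within_block_rho >= 1) {
    pp_stop("within_block_rho must be in [0, 1)", "invalid_config")
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    pp_stop("maf_range must lie in (0, 0.5]", "invalid_config")
  }
  prev <- disease$prevalence
  if (!is.null(prev) && (prev <= 0 || prev >= 1)) {
    pp_stop("disease prevalence must be in (0, 1)", "invalid_config")
  }
  n_blocks <- length(block_sizes)
  block_chrom <- rep_len(as.character(block_chrom), n_blocks)
  if (is.null(block_start)) {
    block_start <- 39.5e6 + (seq_len(n_blocks) - 1L) * 2e6
  }
  block_start <- rep_len(block_start, n_blocks)

  if (is.null(aptamer_map)) {
    aptamer_map <- default_aptamer_map(n_aptamers)
  }

  cfg <- structure(list(
    n_samples = n_samples, n_variants = n_variants,
    block_sizes = block_sizes, within_block_rho = within_block_rho,
    maf_range = maf_range, block_chrom = block_chrom,
    block_start = block_start, variant_spacing = variant_spacing,
    n_aptamers = n_aptamers, aptamer_map = aptamer_map,
    planted_effects = planted_effects,
    covariate_effects = covariate_effects,
    noise_sd = noise_sd, disease = disease, seed = as.integer(seed)
  ), class = "sim_config")

  if (!is.null(planted_effects) && nrow(planted_effects)) {
    bad <- setdiff(planted_effects$aptamer_id, aptamer_map$aptamer_id)
    if (length(bad)) {
      pp_stop(paste("planted effect on unknown aptamer:",
                    paste(bad, collapse = ", ")), "invalid_config")
    }
  }
  if (!is.null(disease$mediation) && nrow(disease$mediation)) {
    bad <- setdiff(disease$mediation$aptamer_id, aptamer_map$aptamer_id)
    if (length(bad)) {
      pp_stop(paste("mediation on unknown aptamer:",
                    paste(bad, collapse = ", ")), "invalid_config")
    }
  }
  cfg
}

# default aptamer -> gene map: genes tiled on chromosome 1 away from the
# default genotype blocks, 100 kb coding spans 3 Mb apart
default_aptamer_map <- function(n_aptamers) {
  start <- 1e6 + (seq_len(n_aptamers) - 1L) * 3e6
  data.frame(
    aptamer_id = sprintf("APT%04d", seq_len(n_aptamers)),
    gene = sprintf("GENE%04d", seq_len(n_aptamers)),
    chrom = "1",
    start = start,
    end = start + 1e5,
    stringsAsFactors = FALSE
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", sum(x$n_samples), "samples in", length(x$n_samples),
      "cohort(s);", x$n_variants, "variants in", length(x$block_sizes),
      "LD block(s); rho =", x$within_block_rho, ";", x$n_aptamers,
      "aptamers;", if (is.null(x$planted_effects)) 0 else nrow(x$planted_effects),
      "planted effect(s); seed", x$seed, "\n")
  invisible(x)
}
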