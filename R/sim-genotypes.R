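#' Simulate LD-blocked biallelic genotypes
#'
#' Generates dosages (0/1/2) for all cohorts under a latent-Gaussian AR(1)
#' haplotype model: within each LD block two independent haplotypes per
#' sample are drawn from an AR(1) latent Gaussian with parameter
#' \code{within_block_rho} and thresholded at the per-variant MAF quantile,
#' then summed. Variants in different blocks are independent. This gives
#' tunable pairwise r-squared without a reference LD panel.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{genotype_matrix}: list with
#'   \code{dosage} (samples x variants integer matrix, rownames sample IDs,
#'   colnames variant IDs "chr:pos:ref:alt"), \code{variants} (data.frame
#'   id, chrom, pos, ref, alt, maf, block) and \code{samples} (data.frame
#'   sample_id, cohort).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_total <- sum(config$n_samples)
  cohorts <- rep(names(config$n_samples), config$n_samples)
  sample_id <- sprintf("S%05d", seq_len(n_total))

  maf <- stats::runif(config$n_variants, config$maf_range[1], config$maf_range[2])
  variants <- variant_table(config, maf)

  dosage <- matrix(0L, nrow = n_total, ncol = config$n_variants,
                   dimnames = list(sample_id, variants$id))
  col0 <- 0L
  for (b in seq_along(config$block_sizes)) {
    m <- config$block_sizes[b]
    idx <- col0 + seq_len(m)
    thr <- stats::qnorm(maf[idx])
    h1 <- ar1_latent(n_total, m, config$within_block_rho)
    h2 <- ar1_latent(n_total, m, config$within_block_rho)
    dosage[, idx] <- (sweep(h1, 2, thr, "<") + sweep(h2, 2, thr, "<"))
    col0 <- col0 + m
  }
  storage.mode(dosage) <- "integer"

  structure(list(
    dosage = dosage,
    variants = variants,
    samples = data.frame(sample_id = sample_id, cohort = cohorts,
                         stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
}

# latent AR(1) Gaussian matrix: n rows, m columns, corr(z_i, z_j) = rho^|i-j|
ar1_latent <- function(n, m, rho) {
  z <- matrix(stats::rnorm(n * m), nrow = n, ncol = m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * z[, j]
  }
  z
}

variant_table <- function(config, maf) {
  block <- rep(seq_along(config$block_sizes), config$block_sizes)
  pos <- integer(config$n_variants)
  chrom <- character(config$n_variants)
  col0 <- 0L
  for (b in seq_along(config$block_sizes)) {
    m <- config$block_sizes[b]
    idx <- col0 + seq_len(m)
    pos[idx] <- config$block_start[b] + (seq_len(m) - 1L) * config$variant_spacing
    chrom[idx] <- config$block_chrom[b]
    col0 <- col0 + m
  }
  ref <- rep_len(c("A", "C", "G", "T"), config$n_variants)
  alt <- rep_len(c("G", "T", "A", "C"), config$n_variants)
  data.frame(
    id = make_variant_id(chrom, pos, ref, alt),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    maf = maf, block = block, stringsAsFactors = FALSE
  )
}

#' Empirical alternate-allele frequencies of a genotype matrix
#' @param genotypes a \code{genotype_matrix}.
#' @return named numeric vector of alt-allele frequencies.
#' @export
allele_freq <- function(genotypes) {
  colMeans(genotypes$dosage, na.rm = TRUE) / 2
}

#' Leading genotype principal components
#'
#' Computed from centered, scaled dosages of an LD-pruned variant subset
#' (as is standard for ancestry PCs: pruning keeps the components from
#' aligning with local LD blocks rather than sample structure); mirrors
#' the usual "first ten genetic PCs" covariate set.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param k number of components.
#' @param prune_r2 r-squared threshold for the pre-PCA LD pruning,
#'   default 0.2; NULL disables pruning.
#' @return matrix n_samples x k with columns PC1..PCk.
#' @export
genotype_pcs <- function(genotypes, k = 10, prune_r2 = 0.2) {
  g <- genotypes$dosage
  sds <- apply(g, 2, stats::sd)
  keep <- sds > 0
  if (!is.null(prune_r2)) {
    ld <- ld_matrix(genotypes, colnames(g)[keep])
    kept_ids <- ld_prune(colnames(g)[keep], ld, r2_max = prune_r2)
    keep <- keep & colnames(g) %in% kept_ids
  }
  gs <- scale(g[, keep, drop = FALSE])
  k <- min(k, ncol(gs), nrow(gs) - 1L)
  pc <- stats::prcomp(gs, rank. = k)$x[, seq_len(k), drop = FALSE]
  colnames(pc) <- paste0("PC", seq_len(k))
  rownames(pc) <- rownames(g)
  pc
}
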