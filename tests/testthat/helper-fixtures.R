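# fixture builders shared across test files; everything is generated in
# code at test time

# small raw aptamer fixture: `n` samples on two plates, `A` aptamers,
# lognormal-ish positive values, clean side tables (scale factors 1, CV 0.05)
make_raw_fixture <- function(n = 40, A = 6, seed = 100) {
  set.seed(seed)
  m <- matrix(10^(3 + 0.1 * rnorm(n * A)), n, A,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("APT%03d", 1:A)))
  plates <- rep(c("p1", "p2"), length.out = n)
  sf <- matrix(1, 2, A, dimnames = list(c("p1", "p2"), colnames(m)))
  cv <- matrix(0.05, 2, A, dimnames = list(c("p1", "p2"), colnames(m)))
  raw_aptamer_data(m, plates, scale_factors = sf, cvs = cv)
}

# genotype fixture with independent variants (one block per variant)
make_indep_genotypes <- function(n = 500, V = 10, maf = 0.3, seed = 1) {
  cfg <- sim_config(n_samples = c(a = n), n_variants = V,
                    block_sizes = rep(1, V), within_block_rho = 0,
                    maf_range = c(maf, maf), seed = seed)
  simulate_genotypes(cfg)
}

# hand-built ld_matrix from an explicit correlation matrix
make_ld <- function(r, ids = NULL, n = 1000) {
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(r)))
  dimnames(r) <- list(ids, ids)
  structure(list(r = r, n = n), class = "ld_matrix")
}

# marginal association records data.frame for summary-level tests
make_records <- function(variant_id, beta, se, n,
                         ea = "G", oa = "A", aptamer_id = "APT1") {
  t <- beta / se
  data.frame(variant_id = variant_id, aptamer_id = aptamer_id,
             beta = beta, se = se, t = t, p = 2 * pt(-abs(t), n - 2),
             n = n, effect_allele = ea, other_allele = oa,
             stringsAsFactors = FALSE)
}

# covariate-free marginal scan of one phenotype against genotype columns;
# used as an independent scalar oracle in several tests
oracle_marginal <- function(G, y) {
  out <- lapply(seq_len(ncol(G)), function(j) {
    fit <- summary(lm(y ~ G[, j]))$coefficients
    data.frame(variant_id = colnames(G)[j], beta = fit[2, 1], se = fit[2, 2],
               p = fit[2, 4], n = length(y), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
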