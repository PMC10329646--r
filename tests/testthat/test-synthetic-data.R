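test_that("simulated allele frequencies match the target MAF", {
  cfg <- sim_config(n_samples = c(a = 10000), n_variants = 5,
                    block_sizes = 5, within_block_rho = 0.5,
                    maf_range = c(0.3, 0.3), seed = 42)
  g <- simulate_genotypes(cfg)
  expect_true(all(abs(allele_freq(g) - 0.3) < 0.02))
  expect_true(all(g$dosage %in% 0:2))
})

test_that("rho = 0 gives independent variants, high rho gives strong LD", {
  cfg0 <- sim_config(n_samples = c(a = 10000), n_variants = 8,
                     block_sizes = 8, within_block_rho = 0,
                     maf_range = c(0.3, 0.3), seed = 7)
  g0 <- simulate_genotypes(cfg0)
  r <- cor(g0$dosage)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.05)

  # numerical oracle for the latent-threshold construction: the genotype
  # correlation of adjacent variants is the phi coefficient of the
  # dichotomized bivariate normal, which attenuates the latent rho
  phi_oracle <- function(rho, maf) {
    t <- qnorm(maf)
    p11 <- integrate(function(z)
      dnorm(z) * pnorm((t - rho * z) / sqrt(1 - rho^2)),
      -Inf, t)$value
    (p11 - maf^2) / (maf * (1 - maf))
  }
  for (rho in c(0.95, 0.995)) {
    cfg1 <- sim_config(n_samples = c(a = 10000), n_variants = 2,
                       block_sizes = 2, within_block_rho = rho,
                       maf_range = c(0.3, 0.3), seed = 7)
    g1 <- simulate_genotypes(cfg1)
    emp <- cor(g1$dosage[, 1], g1$dosage[, 2])
    expect_lt(abs(emp - phi_oracle(rho, 0.3)), 0.03)
  }
  # at rho = 0.995 the construction delivers proxy-grade LD (r2 > 0.81)
  expect_gt(phi_oracle(0.995, 0.3)^2, 0.81)
})

test_that("genotype counts are consistent with Hardy-Weinberg equilibrium", {
  cfg <- sim_config(n_samples = c(a = 10000), n_variants = 40,
                    block_sizes = rep(10, 4), within_block_rho = 0.8,
                    maf_range = c(0.05, 0.5), seed = 3)
  g <- simulate_genotypes(cfg)
  hwe_p <- apply(g$dosage, 2, function(d) {
    n <- length(d)
    p <- mean(d) / 2
    exp_counts <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(d + 1L, 3L)
    suppressWarnings(chisq.test(obs, p = exp_counts / n)$p.value)
  })
  expect_gte(mean(hwe_p > 1e-4), 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(maf_range = c(0, 0.5)), class = "invalid_config")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), class = "invalid_config")
  expect_error(sim_config(n_variants = 10, block_sizes = c(4, 4)),
               class = "invalid_config")
  expect_error(sim_config(within_block_rho = 1), class = "invalid_config")
  expect_error(sim_config(disease = list(prevalence = 0)),
               class = "invalid_config")
  expect_error(
    sim_config(n_aptamers = 2,
               planted_effects = data.frame(variant_id = "x",
                                            aptamer_id = "NOPE",
                                            beta = 1)),
    class = "invalid_config")
})

test_that("same seed reproduces identical genotypes and proteins", {
  cfg <- sim_config(n_samples = c(a = 200), n_variants = 10,
                    block_sizes = 10, seed = 9, n_aptamers = 3)
  g1 <- simulate_genotypes(cfg); g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  p1 <- simulate_proteins(g1, cfg); p2 <- simulate_proteins(g2, cfg)
  expect_identical(p1$raw$measurements, p2$raw$measurements)
})

test_that("planted SNP effect is recovered by OLS on the latent scale", {
  cfg <- sim_config(n_samples = c(a = 5000), n_variants = 1, block_sizes = 1,
                    maf_range = c(0.3, 0.3), n_aptamers = 2,
                    planted_effects = data.frame(variant_id = NA,
                                                 aptamer_id = "APT0001",
                                                 beta = 0.5),
                    noise_sd = 1, seed = 21)
  g <- simulate_genotypes(cfg)
  cfg$planted_effects$variant_id <- g$variants$id
  sim <- simulate_proteins(g, cfg)
  b <- coef(lm(sim$latent[, "APT0001"] ~ g$dosage[, 1]))[2]
  expect_lt(abs(b - 0.5), 0.05)
})

test_that("with no planted effects SNP-aptamer p-values are uniform", {
  cfg <- sim_config(n_samples = c(a = 400), n_variants = 20,
                    block_sizes = rep(1, 20), within_block_rho = 0,
                    n_aptamers = 10, noise_sd = 1, seed = 5)
  g <- simulate_genotypes(cfg)
  sim <- simulate_proteins(g, cfg)
  scan <- pqtl_scan(g, normalize_proteins(sim$raw))
  frac <- mean(scan$p < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(scan)) + 0.01)
})

test_that("planted effect on an unknown aptamer or variant errors", {
  cfg <- sim_config(n_samples = c(a = 50), n_variants = 2,
                    block_sizes = 2, n_aptamers = 2, seed = 1)
  g <- simulate_genotypes(cfg)
  cfg$planted_effects <- data.frame(variant_id = "1:1:A:G",
                                    aptamer_id = "APT0001", beta = 1)
  expect_error(simulate_proteins(g, cfg), class = "invalid_config")
})

test_that("injected missingness drives an aptamer below the call-rate gate", {
  cfg <- sim_config(n_samples = c(a = 300), n_variants = 2, block_sizes = 2,
                    n_aptamers = 4, seed = 13)
  g <- simulate_genotypes(cfg)
  sim <- simulate_proteins(g, cfg,
                           artifacts = list(missing = data.frame(
                             aptamer_id = "APT0002", rate = 0.4)))
  st <- call_rate_cascade(sim$raw)
  expect_true("APT0002" %in% st$report$removed_aptamers$aptamer_id)
  expect_identical(st$report$removed_aptamers$stage[
    st$report$removed_aptamers$aptamer_id == "APT0002"], "call_rate_1")
})

test_that("GWAS simulation: null is uniform, mediated cis SNP is significant", {
  cfg <- sim_config(n_samples = c(a = 2000), n_variants = 30,
                    block_sizes = rep(1, 30), within_block_rho = 0,
                    n_aptamers = 2, seed = 17,
                    disease = list(mediation = NULL,
                                   direct_snp_effects = NULL,
                                   prevalence = 0.1))
  g <- simulate_genotypes(cfg)
  gw <- simulate_disease_gwas(g, cfg)
  expect_gt(suppressWarnings(ks.test(gw$P, "punif"))$p.value, 0.01)

  cfg2 <- cfg
  cfg2$n_samples <- c(a = 8000)
  g2 <- simulate_genotypes(cfg2)
  cfg2$planted_effects <- data.frame(variant_id = g2$variants$id[1],
                                     aptamer_id = "APT0001", beta = 0.8)
  cfg2$disease$mediation <- data.frame(aptamer_id = "APT0001", theta = 0.5)
  gw2 <- simulate_disease_gwas(g2, cfg2)
  expect_lt(gw2$P[1], 5e-8)
})

test_that("GWAS files from the same seed are byte-identical", {
  cfg <- sim_config(n_samples = c(a = 500), n_variants = 5,
                    block_sizes = 5, seed = 23)
  g <- simulate_genotypes(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_gwas_tsv(simulate_disease_gwas(g, cfg), f1)
  write_gwas_tsv(simulate_disease_gwas(g, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate liability (no expected cases or controls) errors", {
  cfg <- sim_config(n_samples = c(a = 50), n_variants = 2, block_sizes = 2,
                    seed = 2, disease = list(prevalence = 1e-9))
  g <- simulate_genotypes(cfg)
  expect_error(simulate_disease_gwas(g, cfg), class = "degenerate_phenotype")
})

test_that("cell-type expression respects the specificity plan", {
  plan <- data.frame(gene = c("g1", "g2", "g3"),
                     cell_type = c("microglia", NA, "neuron"),
                     share = c(0.6, NA, 0.5), stringsAsFactors = FALSE)
  expr <- simulate_celltype_expression(plan$gene,
                                       c("microglia", "astrocyte", "neuron",
                                         "oligodendrocyte", "endothelial"),
                                       plan, seed = 31)
  calls <- assign_specificity(expr)
  expect_identical(calls$call[calls$gene == "g1"], "microglia")
  expect_identical(calls$call[calls$gene == "g2"], "none")
  # planned share exactly 0.5: strict more-than-half rule gives none
  expect_identical(calls$call[calls$gene == "g3"], "none")
})

test_that("explicit shares must sum to one", {
  plan <- data.frame(gene = "g1", cell_type = NA, share = NA)
  plan$shares <- list(c(a = 0.7, b = 0.7))
  expect_error(simulate_celltype_expression("g1", c("a", "b"), plan),
               class = "invalid_config")
})
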