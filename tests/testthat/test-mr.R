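# exposure summary rows in the shape select_instruments expects
make_exposure <- function(id, chrom, pos, beta, se, p = NULL, eaf = 0.3,
                          ea = "G", oa = "A") {
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  data.frame(variant_id = id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa,
             effect_allele_freq = eaf, beta = beta, se = se, p = p,
             stringsAsFactors = FALSE)
}

make_outcome <- function(id, beta, se, a1 = "G", a2 = "A") {
  data.frame(SNP = id, A1 = a1, A2 = a2, FREQ = 0.3, BETA = beta, SE = se,
             P = 2 * pnorm(-abs(beta / se)), N = 10000,
             stringsAsFactors = FALSE)
}

test_that("instrument screening applies p, F and harmonization rules", {
  ex <- rbind(
    make_exposure("v1", "1", 100, 0.5, 0.05),          # F = 100, kept
    make_exposure("v2", "1", 200, 0.30, 0.0555),       # p ~ 6.5e-8 > 5e-8
    make_exposure("v3", "1", 300, 0.4, 0.05, ea = "A", oa = "T", eaf = 0.5),
    make_exposure("v4", "1", 400, 0.6, 0.05)           # absent from outcome
  )
  out <- rbind(make_outcome("v1", 0.1, 0.02),
               make_outcome("v2", 0.1, 0.02),
               make_outcome("v3", 0.1, 0.02, a1 = "A", a2 = "T"))
  ld <- make_ld(diag(4), ids = paste0("v", 1:4))
  sel <- select_instruments(ex, out, ld)
  expect_identical(sel$instruments$variant_id, "v1")
  expect_equal(sel$instruments$F, 100)
  reasons <- setNames(sel$dropped$reason, sel$dropped$variant_id)
  expect_match(reasons[["v2"]], "p >= threshold")
  expect_match(reasons[["v3"]], "palindromic")
  expect_match(reasons[["v4"]], "absent")
})

test_that("weak instruments are excluded at F < 10", {
  ex <- make_exposure("v1", "1", 100, 0.3, 0.1)   # F = 9, p = 0.0027 -> p gate
  ex$p <- 1e-10                                   # force past the p gate
  out <- make_outcome("v1", 0.1, 0.02)
  sel <- select_instruments(ex, out, make_ld(diag(1), ids = "v1"))
  expect_null(sel$instruments)
  expect_match(sel$dropped$reason, "F < 10")
})

test_that("swapped outcome alleles flip the outcome beta", {
  ex <- make_exposure("v1", "1", 100, 0.5, 0.05)
  fwd <- make_outcome("v1", 0.1, 0.02)
  rev <- make_outcome("v1", -0.1, 0.02, a1 = "A", a2 = "G")
  ld <- make_ld(diag(1), ids = "v1")
  i1 <- select_instruments(ex, fwd, ld)$instruments
  i2 <- select_instruments(ex, rev, ld)$instruments
  expect_equal(i1$beta_outcome, i2$beta_outcome, tolerance = 1e-12)
  expect_equal(mr_estimate(i1)$theta, mr_estimate(i2)$theta, tolerance = 1e-12)
})

test_that("Wald ratio matches its closed form", {
  inst <- data.frame(variant_id = "v1", chrom = "1", pos = 1,
                     effect_allele = "G", beta_exposure = 0.5,
                     se_exposure = 0.05, beta_outcome = 0.1,
                     se_outcome = 0.02, F = 100)
  wr <- wald_ratio(inst)
  expect_equal(wr$theta, 0.2, tolerance = 1e-12)
  expect_equal(wr$se, 0.04, tolerance = 1e-12)
  expect_identical(wr$method, "wald")

  inst0 <- inst; inst0$beta_outcome <- 0
  wr0 <- wald_ratio(inst0)
  expect_equal(wr0$theta, 0)
  expect_equal(wr0$p, 1)

  instz <- inst; instz$beta_exposure <- 0
  expect_error(wald_ratio(instz), class = "zero_exposure")
})

test_that("IVW matches the hand closed form and the regression oracle", {
  inst <- data.frame(variant_id = c("v1", "v2"), chrom = "1", pos = 1:2,
                     effect_allele = "G",
                     beta_exposure = c(0.5, 0.25), se_exposure = 0.05,
                     beta_outcome = c(0.1, 0.05), se_outcome = 0.02,
                     F = c(100, 25))
  r <- mr_ivw(inst)
  expect_equal(r$theta, (125 + 31.25) / (625 + 156.25), tolerance = 1e-12)
  expect_equal(r$theta, 0.2, tolerance = 1e-12)

  set.seed(501)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    inst <- data.frame(variant_id = paste0("v", 1:k), chrom = "1", pos = 1:k,
                       effect_allele = "G",
                       beta_exposure = runif(k, 0.1, 0.6),
                       se_exposure = runif(k, 0.02, 0.1),
                       beta_outcome = rnorm(k, 0.1, 0.05),
                       se_outcome = runif(k, 0.01, 0.05), F = 100)
    r <- mr_ivw(inst)
    fit <- lm(beta_outcome ~ 0 + beta_exposure, data = inst,
              weights = 1 / inst$se_outcome^2)
    expect_equal(r$theta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("identical instrument ratios return that ratio exactly", {
  inst <- data.frame(variant_id = paste0("v", 1:3), chrom = "1", pos = 1:3,
                     effect_allele = "G",
                     beta_exposure = c(0.2, 0.4, 0.6),
                     se_exposure = 0.05,
                     beta_outcome = 0.2 * c(0.2, 0.4, 0.6),
                     se_outcome = c(0.02, 0.03, 0.01), F = 100)
  expect_equal(mr_ivw(inst)$theta, 0.2, tolerance = 1e-12)
})

test_that("IVW with one instrument equals the Wald ratio", {
  inst <- data.frame(variant_id = "v1", chrom = "1", pos = 1,
                     effect_allele = "G", beta_exposure = 0.4,
                     se_exposure = 0.05, beta_outcome = 0.12,
                     se_outcome = 0.03, F = 64)
  expect_equal(mr_ivw(inst), wald_ratio(inst))
})

test_that("an opposite-direction invalid instrument pulls theta toward zero", {
  valid <- data.frame(variant_id = c("v1", "v2"), chrom = "1", pos = 1:2,
                      effect_allele = "G",
                      beta_exposure = c(0.5, 0.4), se_exposure = 0.05,
                      beta_outcome = c(0.15, 0.12), se_outcome = 0.02, F = 100)
  invalid <- data.frame(variant_id = "v3", chrom = "1", pos = 3,
                        effect_allele = "G", beta_exposure = 0.5,
                        se_exposure = 0.05, beta_outcome = -0.15,
                        se_outcome = 0.02, F = 100)
  expect_lt(mr_ivw(rbind(valid, invalid))$theta, mr_ivw(valid)$theta)
})

test_that("sensitivity configurations partition instruments correctly", {
  inst <- data.frame(
    variant_id = c("chr12sent", "chr12out", "chr5trans"),
    chrom = c("12", "12", "5"),
    pos = c(40220632, 43e6, 60e6),
    effect_allele = "G",
    beta_exposure = c(0.5, 0.45, 0.4), se_exposure = 0.05,
    beta_outcome = c(0.15, 0.14, 0.12), se_outcome = 0.02, F = 100)
  sens <- mr_sensitivity(inst,
                         gene_region = list(chrom = "12", start = 40.1e6,
                                            end = 40.3e6))
  expect_equal(sens$n_snp[sens$configuration == "all"], 3L)
  # chr12:40220632 is inside the 39-41.5 Mb exclusion window
  expect_equal(sens$n_snp[sens$configuration == "exclude_region"], 2L)
  # cis-only keeps instruments within 1 Mb of the gene span
  expect_equal(sens$n_snp[sens$configuration == "cis_only"], 1L)

  # an instrument 2 Mb from the gene span is not cis
  far <- inst[2, ]; far$pos <- 42.3e6
  s2 <- mr_sensitivity(far, gene_region = list(chrom = "12", start = 40.1e6,
                                               end = 40.3e6))
  expect_equal(s2$n_snp[s2$configuration == "cis_only"], 0L)
})

test_that("an aptamer whose only instrument sits in the excluded region goes
           from significant to empty", {
  inst <- data.frame(variant_id = "v1", chrom = "12", pos = 40220632,
                     effect_allele = "G", beta_exposure = 0.5,
                     se_exposure = 0.05, beta_outcome = 0.15,
                     se_outcome = 0.02, F = 100)
  sens <- mr_sensitivity(inst, gene_region = NULL)
  expect_lt(sens$p[sens$configuration == "all"], 0.05)
  expect_identical(sens$method[sens$configuration == "exclude_region"], "none")
  expect_identical(sens$n_snp[sens$configuration == "exclude_region"], 0L)
})

test_that("planted causal effects are recovered end to end", {
  # exposure: pQTL of a protein with two independent planted SNPs;
  # outcome: liability GWAS with planted mediation theta = 0.3
  theta_true <- 0.3
  cfg <- sim_config(n_samples = c(a = 2000), n_variants = 6,
                    block_sizes = rep(1, 6), within_block_rho = 0,
                    maf_range = c(0.3, 0.3), n_aptamers = 2, seed = 37)
  g <- simulate_genotypes(cfg)
  cfg$planted_effects <- data.frame(
    variant_id = g$variants$id[c(1, 4)], aptamer_id = "APT0001",
    beta = c(0.5, 0.45))
  cfg$disease$mediation <- data.frame(aptamer_id = "APT0001", theta = theta_true)
  sim <- simulate_proteins(g, cfg)
  scan <- pqtl_scan(g, normalize_proteins(sim$raw), aptamers = "APT0001")

  gcfg <- cfg; gcfg$n_samples <- c(gw = 20000); gcfg$seed <- 1037L
  g2 <- simulate_genotypes(gcfg)
  gwas <- simulate_disease_gwas(g2, gcfg)

  ex <- scan
  vi <- g$variants[match(ex$variant_id, g$variants$id), ]
  ex$chrom <- vi$chrom; ex$pos <- vi$pos
  sel <- select_instruments(ex, gwas, ld_matrix(g))
  expect_identical(sort(sel$instruments$variant_id),
                   sort(g$variants$id[c(1, 4)]))
  est <- mr_estimate(sel$instruments)
  # the generator standardizes the mediated component, so the z-scored
  # exposure makes theta itself the estimand
  expect_lt(abs(est$theta - theta_true), 3 * est$se)
  expect_lt(est$p, 0.01)
})
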