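#' Simulate disease GWAS summary statistics under a liability-threshold model
#'
#' Disease liability is \code{sum(theta * genetic component of protein) +
#' direct SNP effects + standard Gaussian noise}; cases are samples whose
#' liability exceeds the (1 - prevalence) quantile. Because only the
#' genetic component of each protein enters the liability, the planted
#' mediation \code{theta} is exactly the causal protein-to-disease effect
#' a two-sample MR on the liability scale estimates.
#'
#' @param genotypes a \code{genotype_matrix}; by convention the GWAS cohort
#'   is simulated independently of the pQTL cohorts (two-sample design).
#' @param config the \code{\link{sim_config}} holding the disease block.
#' @param model \code{"linear"} regresses the continuous liability on
#'   dosage (effects on the liability scale); \code{"logistic"} fits a
#'   logistic regression of case status (effects are log-odds ratios).
#' @return data.frame in GWAS summary dialect: SNP, CHR, POS, A1 (effect =
#'   alt), A2, FREQ, BETA, SE, P, N, plus attribute \code{case_status}.
#' @export
simulate_disease_gwas <- function(genotypes, config, model = c("linear", "logistic")) {
  model <- match.arg(model)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  set.seed(config$seed + 2L)
  n <- nrow(genotypes$dosage)
  dis <- config$disease
  prev <- dis$prevalence
  if (prev * n < 1 || (1 - prev) * n < 1) {
    pp_stop("prevalence and sample size give fewer than one expected case or control",
            "degenerate_phenotype")
  }

  liability <- stats::rnorm(n)
  med <- dis$mediation
  if (!is.null(med) && nrow(med)) {
    eff <- config$planted_effects
    for (i in seq_len(nrow(med))) {
      rows <- eff[eff$aptamer_id == med$aptamer_id[i], , drop = FALSE]
      if (nrow(rows) == 0) next
      gencomp <- rep(0, n)
      for (j in seq_len(nrow(rows))) {
        gencomp <- gencomp + rows$beta[j] * genotypes$dosage[, rows$variant_id[j]]
      }
      # theta is per SD of the protein: standardize the mediated component
      # by the protein's latent SD (genetic + residual variance), so that a
      # two-sample MR of the z-scored protein on the liability recovers
      # theta itself
      sd_prot <- sqrt(stats::var(gencomp) + config$noise_sd^2)
      liability <- liability + med$theta[i] * gencomp / sd_prot
    }
  }
  dse <- dis$direct_snp_effects
  if (!is.null(dse) && nrow(dse)) {
    for (i in seq_len(nrow(dse))) {
      liability <- liability + dse$beta[i] * genotypes$dosage[, dse$variant_id[i]]
    }
  }
  case <- liability > stats::quantile(liability, 1 - prev)
  if (sum(case) == 0 || sum(!case) == 0) {
    pp_stop("liability threshold produced zero cases or zero controls",
            "degenerate_phenotype")
  }

  y <- if (model == "linear") liability else as.numeric(case)
  stats_tab <- if (model == "linear") {
    marginal_linear_scan(genotypes$dosage, y)
  } else {
    marginal_logistic_scan(genotypes$dosage, y)
  }

  v <- genotypes$variants
  out <- data.frame(
    SNP = v$id, CHR = v$chrom, POS = v$pos,
    A1 = v$alt, A2 = v$ref,
    FREQ = colMeans(genotypes$dosage) / 2,
    BETA = stats_tab$beta, SE = stats_tab$se, P = stats_tab$p,
    N = n, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "case_status") <- as.numeric(case)
  attr(out, "model") <- model
  out
}

# vectorized simple linear regression of y on each column of G
marginal_linear_scan <- function(G, y) {
  n <- length(y)
  gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  gg <- colSums(gc^2)
  beta <- as.numeric(crossprod(gc, yc)) / gg
  rss <- sum(yc^2) - beta^2 * gg
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / gg)
  tt <- beta / se
  zerovar <- gg == 0
  beta[zerovar] <- NA; se[zerovar] <- NA; tt[zerovar] <- NA
  list(beta = beta, se = se, p = p_from_t(tt, n - 2))
}

marginal_logistic_scan <- function(G, y) {
  res <- apply(G, 2, function(g) {
    if (stats::var(g) == 0) return(c(NA, NA, NA))
    fit <- stats::glm(y ~ g, family = stats::binomial())
    co <- summary(fit)$coefficients
    c(co["g", 1], co["g", 2], co["g", 4])
  })
  list(beta = res[1, ], se = res[2, ], p = res[3, ])
}
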