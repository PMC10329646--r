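#' Select and harmonize MR instruments
#'
#' From an exposure (pQTL) summary table and an outcome (disease GWAS)
#' table: keeps genome-wide significant exposure SNPs, prunes them to
#' pairwise independence via greedy LD clumping, intersects with the
#' outcome table, harmonizes alleles to the exposure effect allele
#' (flipping the outcome beta when alleles are swapped; dropping
#' palindromic A/T and C/G SNPs whose allele frequency is too close to 0.5
#' to resolve strand), and applies the weak-instrument F bound.
#'
#' @param exposure data.frame with variant_id, chrom, pos, effect_allele,
#'   other_allele, effect_allele_freq, beta, se, p (one aptamer's pQTLs).
#' @param outcome GWAS summary data.frame (SNP, A1, A2, FREQ, BETA, SE, P).
#' @param ld an \code{\link{ld_matrix}} over the exposure variants.
#' @param p_max exposure significance threshold, default 5e-8.
#' @param f_min minimum instrument F statistic \code{(beta/se)^2}, default 10.
#' @param clump_r2 LD clumping r-squared, default 0.001.
#' @param palindromic_band allele-frequency band within which palindromic
#'   SNPs are unresolvable, default c(0.42, 0.58).
#' @return list with \code{instruments} (data.frame variant_id, chrom, pos,
#'   effect_allele, beta_exposure, se_exposure, beta_outcome, se_outcome,
#'   F) and \code{dropped} (data.frame variant_id, reason).
#' @export
select_instruments <- function(exposure, outcome, ld, p_max = 5e-8,
                               f_min = 10, clump_r2 = 0.001,
                               palindromic_band = c(0.42, 0.58)) {
  dropped <- data.frame(variant_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  note <- function(ids, reason) {
    if (length(ids)) dropped <<- rbind(dropped, data.frame(
      variant_id = ids, reason = reason, stringsAsFactors = FALSE))
  }

  sig <- exposure[!is.na(exposure$p) & exposure$p < p_max, , drop = FALSE]
  note(setdiff(exposure$variant_id, sig$variant_id), "exposure p >= threshold")
  if (nrow(sig) == 0) return(list(instruments = NULL, dropped = dropped))

  kept <- ld_prune(sig[, c("variant_id", "p")], ld, r2_max = clump_r2)
  note(setdiff(sig$variant_id, kept), "pruned (LD clump)")
  sig <- sig[sig$variant_id %in% kept, , drop = FALSE]

  oidx <- match(sig$variant_id, outcome$SNP)
  note(sig$variant_id[is.na(oidx)], "absent from outcome GWAS")
  sig <- sig[!is.na(oidx), , drop = FALSE]
  oidx <- oidx[!is.na(oidx)]
  if (nrow(sig) == 0) return(list(instruments = NULL, dropped = dropped))

  ea <- sig$effect_allele; oa <- sig$other_allele
  a1 <- outcome$A1[oidx]; a2 <- outcome$A2[oidx]
  same <- a1 == ea & a2 == oa
  swap <- a1 == oa & a2 == ea
  mismatch <- !same & !swap
  note(sig$variant_id[mismatch], "allele mismatch with outcome")

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palin <- ea == comp[oa]
  freq <- sig$effect_allele_freq
  ambiguous <- palin & !is.na(freq) &
    freq >= palindromic_band[1] & freq <= palindromic_band[2]
  note(sig$variant_id[ambiguous & !mismatch], "palindromic, frequency ambiguous")

  keep <- !mismatch & !ambiguous
  sig <- sig[keep, , drop = FALSE]
  oidx <- oidx[keep]; swap <- swap[keep]
  if (nrow(sig) == 0) return(list(instruments = NULL, dropped = dropped))

  by <- outcome$BETA[oidx]
  by[swap] <- -by[swap]
  Fstat <- (sig$beta / sig$se)^2
  weak <- Fstat < f_min
  note(sig$variant_id[weak], sprintf("instrument F < %g", f_min))

  inst <- data.frame(
    variant_id = sig$variant_id, chrom = sig$chrom, pos = sig$pos,
    effect_allele = sig$effect_allele,
    beta_exposure = sig$beta, se_exposure = sig$se,
    beta_outcome = by, se_outcome = outcome$SE[oidx],
    F = Fstat, stringsAsFactors = FALSE, row.names = NULL
  )[!weak, , drop = FALSE]
  if (nrow(inst) == 0) inst <- NULL
  list(instruments = inst, dropped = dropped)
}

#' Wald ratio MR estimate (single instrument)
#'
#' \code{theta = beta_outcome / beta_exposure}; first-order delta-method
#' standard error \code{se_outcome / |beta_exposure|}; two-sided normal p.
#'
#' @param inst one-row instrument data.frame (see
#'   \code{\link{select_instruments}}).
#' @return data.frame method, n_snp, theta, se, p.
#' @export
wald_ratio <- function(inst) {
  stopifnot(nrow(inst) == 1)
  bx <- inst$beta_exposure
  if (abs(bx) < 1e-12) pp_stop("exposure effect is zero", "zero_exposure")
  theta <- inst$beta_outcome / bx
  se <- inst$se_outcome / abs(bx)
  data.frame(method = "wald", n_snp = 1L, theta = theta, se = se,
             p = p_from_z(theta / se), stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance-weighted MR estimate
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights \code{1/se_outcome^2}:
#' \code{theta = sum(bx*by/sy^2) / sum(bx^2/sy^2)},
#' \code{se = sqrt(1 / sum(bx^2/sy^2))}. With a single instrument this
#' delegates to the Wald ratio.
#'
#' @param inst instrument data.frame (>= 1 rows).
#' @return data.frame method, n_snp, theta, se, p.
#' @export
mr_ivw <- function(inst) {
  if (nrow(inst) < 2) return(wald_ratio(inst))
  bx <- inst$beta_exposure; by <- inst$beta_outcome; sy <- inst$se_outcome
  denom <- sum(bx^2 / sy^2)
  theta <- sum(bx * by / sy^2) / denom
  se <- sqrt(1 / denom)
  data.frame(method = "ivw", n_snp = nrow(inst), theta = theta, se = se,
             p = p_from_z(theta / se), stringsAsFactors = FALSE)
}

#' Run MR with the appropriate estimator
#' @param inst instrument data.frame or NULL.
#' @return one-row result (method "none" with NAs when no instruments).
#' @export
mr_estimate <- function(inst) {
  if (is.null(inst) || nrow(inst) == 0) {
    return(data.frame(method = "none", n_snp = 0L, theta = NA_real_,
                      se = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
  }
  mr_ivw(inst)
}

#' MR sensitivity configurations: all SNPs, exclude-region, cis-only
#'
#' Runs the estimator three ways: on every instrument; excluding
#' instruments inside a pleiotropic region (default the chr12 39-41.5 Mb
#' window); and keeping only cis instruments, i.e. within \code{cis_window}
#' bp upstream or downstream of the aptamer's gene coding region.
#'
#' @param inst instrument data.frame with chrom and pos.
#' @param exclude_region list(chrom, start, end); default chr12 39-41.5 Mb.
#' @param gene_region list(chrom, start, end) of the target gene's coding
#'   span, or NULL (cis-only configuration then reports no instruments).
#' @param cis_window cis distance in bp, default 1e6.
#' @return data.frame with one row per configuration (all, exclude_region,
#'   cis_only): method, n_snp, theta, se, p.
#' @export
mr_sensitivity <- function(inst,
                           exclude_region = list(chrom = "12",
                                                 start = 39e6, end = 41.5e6),
                           gene_region = NULL, cis_window = 1e6) {
  run <- function(x, cfg) {
    r <- mr_estimate(x)
    cbind(configuration = cfg, r, stringsAsFactors = FALSE)
  }
  if (is.null(inst) || nrow(inst) == 0) {
    return(rbind(run(NULL, "all"), run(NULL, "exclude_region"),
                 run(NULL, "cis_only")))
  }
  in_region <- inst$chrom == as.character(exclude_region$chrom) &
    inst$pos >= exclude_region$start & inst$pos <= exclude_region$end
  cis <- if (is.null(gene_region)) rep(FALSE, nrow(inst)) else {
    inst$chrom == as.character(gene_region$chrom) &
      inst$pos >= gene_region$start - cis_window &
      inst$pos <= gene_region$end + cis_window
  }
  rbind(
    run(inst, "all"),
    run(inst[!in_region, , drop = FALSE], "exclude_region"),
    run(inst[cis, , drop = FALSE], "cis_only")
  )
}
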