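#' Fixed-effect inverse-variance meta-analysis of pQTL records
#'
#' Combines per-cohort association records for the same (variant, aptamer)
#' pairs by inverse-variance weighting, with Cochran's Q and the I-squared
#' heterogeneity percentage. Effect alleles are harmonized to the first
#' contributing cohort: a record whose effect/other alleles are swapped has
#' its beta negated; an unresolvable allele mismatch drops that cohort from
#' the pair.
#'
#' @param records list of per-cohort association data.frames as produced by
#'   \code{\link{pqtl_scan}} (fields variant_id, aptamer_id, beta, se, n,
#'   effect_allele, other_allele).
#' @return data.frame with variant_id, aptamer_id, beta_meta, se_meta,
#'   z_meta, p_meta, Q, df_Q, p_Q, I2 (percent), k (cohorts contributing),
#'   n_total, direction (one "+"/"-"/"?" per cohort, in the order of
#'   \code{records}), effect_allele, other_allele.
#' @export
meta_fixed <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  stopifnot(is.list(records), length(records) >= 1)
  key <- function(d) paste(d$variant_id, d$aptamer_id, sep = "||")
  all_keys <- unique(unlist(lapply(records, key)))
  K <- length(all_keys)
  C <- length(records)

  B <- S <- N <- matrix(NA_real_, K, C)
  EA <- OA <- matrix(NA_character_, K, C)
  for (ci in seq_len(C)) {
    d <- records[[ci]]
    idx <- match(all_keys, key(d))
    ok <- !is.na(idx)
    B[ok, ci] <- d$beta[idx[ok]]
    S[ok, ci] <- d$se[idx[ok]]
    N[ok, ci] <- if (is.null(d$n)) NA_real_ else d$n[idx[ok]]
    EA[ok, ci] <- d$effect_allele[idx[ok]]
    OA[ok, ci] <- d$other_allele[idx[ok]]
  }

  # reference alleles: first cohort carrying each pair
  first_c <- apply(!is.na(EA), 1, function(r) which(r)[1])
  ref_ea <- EA[cbind(seq_len(K), first_c)]
  ref_oa <- OA[cbind(seq_len(K), first_c)]

  swapped <- !is.na(EA) & EA == ref_oa & OA == ref_ea
  B[swapped] <- -B[swapped]
  mismatch <- !is.na(EA) & !swapped & EA != ref_ea
  B[mismatch] <- NA; S[mismatch] <- NA

  valid <- !is.na(B) & !is.na(S) & S > 0
  B[!valid] <- NA; S[!valid] <- NA
  W <- 1 / S^2
  sw <- rowSums(W, na.rm = TRUE)
  kc <- rowSums(valid)
  beta_meta <- rowSums(W * B, na.rm = TRUE) / sw
  beta_meta[kc == 0] <- NA
  se_meta <- sqrt(1 / sw)
  se_meta[kc == 0] <- NA
  Q <- rowSums(((B - beta_meta) / S)^2, na.rm = TRUE)
  Q[kc == 0] <- NA
  df_Q <- pmax(kc - 1, 0)
  I2 <- ifelse(kc <= 1 | Q <= 0, 0, pmax(0, (Q - df_Q) / Q) * 100)
  I2[kc == 0] <- NA
  z <- beta_meta / se_meta

  dir_chr <- matrix("?", K, C)
  dir_chr[valid & B >= 0] <- "+"
  dir_chr[valid & B < 0] <- "-"
  direction <- apply(dir_chr, 1, paste, collapse = "")

  kk <- strsplit(all_keys, "||", fixed = TRUE)
  data.frame(
    variant_id = vapply(kk, `[`, "", 1L),
    aptamer_id = vapply(kk, `[`, "", 2L),
    beta_meta = beta_meta, se_meta = se_meta, z_meta = z,
    p_meta = p_from_z(z), Q = Q, df_Q = df_Q,
    p_Q = ifelse(df_Q > 0, stats::pchisq(Q, df_Q, lower.tail = FALSE), NA_real_),
    I2 = I2, k = kc, n_total = rowSums(N * valid, na.rm = TRUE),
    direction = direction,
    effect_allele = ref_ea, other_allele = ref_oa,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Cross-cohort consistency report
#'
#' Summarizes, per (variant, aptamer) pair, the fraction of cohorts whose
#' harmonized effect sign agrees with the meta-analytic sign, the
#' per-cohort effect range, and a heterogeneity flag at I-squared > 50
#' percent — the programmatic equivalent of inspecting a forest plot.
#'
#' @param records list of per-cohort association data.frames.
#' @param meta output of \code{\link{meta_fixed}} on the same records.
#' @param i2_flag heterogeneity flag threshold (percent), default 50.
#' @return data.frame with variant_id, aptamer_id, k, sign_concordance,
#'   beta_min, beta_max, I2, heterogeneity_flag.
#' @export
forest_consistency <- function(records, meta, i2_flag = 50) {
  key <- function(v, a) paste(v, a, sep = "||")
  mk <- key(meta$variant_id, meta$aptamer_id)
  K <- length(mk); C <- length(records)
  B <- matrix(NA_real_, K, C)
  for (ci in seq_len(C)) {
    d <- records[[ci]]
    idx <- match(mk, key(d$variant_id, d$aptamer_id))
    ok <- !is.na(idx)
    b <- d$beta[idx[ok]]
    flip <- d$effect_allele[idx[ok]] == meta$other_allele[ok]
    b[which(flip)] <- -b[which(flip)]
    B[ok, ci] <- b
  }
  valid <- !is.na(B)
  conc <- rowSums(sign(B) == sign(meta$beta_meta), na.rm = TRUE) /
    pmax(rowSums(valid), 1)
  conc[rowSums(valid) == 0] <- NA
  data.frame(
    variant_id = meta$variant_id, aptamer_id = meta$aptamer_id,
    k = rowSums(valid),
    sign_concordance = conc,
    beta_min = suppressWarnings(apply(B, 1, min, na.rm = TRUE)),
    beta_max = suppressWarnings(apply(B, 1, max, na.rm = TRUE)),
    I2 = meta$I2,
    heterogeneity_flag = !is.na(meta$I2) & meta$I2 > i2_flag,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
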