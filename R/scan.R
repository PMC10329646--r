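#' Covariate-adjusted linear pQTL scan
#'
#' For every (SNP, aptamer) pair, fits ordinary least squares of the
#' normalized protein level on the alt-allele dosage plus covariates and
#' reports the dosage coefficient. Per aptamer, complete cases are taken
#' over the protein and covariates, both the dosages and the protein are
#' residualized on the covariate design once (Frisch-Waugh-Lovell), and
#' all SNP slopes follow by matrix algebra; results are identical to
#' per-pair \code{lm} fits. SNPs with missing dosages fall back to a
#' per-pair complete-case fit.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param proteins samples x aptamers matrix of normalized levels (rownames
#'   sample IDs).
#' @param covariates optional data.frame of covariates (numeric or factor),
#'   aligned by its \code{sample_id} column when present, otherwise by row
#'   order against the sample intersection.
#' @param snps,aptamers optional subsets of variant / aptamer IDs.
#' @return data.frame of association records: variant_id, aptamer_id, beta
#'   (SD-protein per alt allele), se, t, p (two-sided, t with residual df),
#'   n, effect_allele, other_allele, effect_allele_freq, zero_variance flag.
#' @export
pqtl_scan <- function(genotypes, proteins, covariates = NULL,
                      snps = NULL, aptamers = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ids <- intersect(rownames(genotypes$dosage), rownames(proteins))
  if (!is.null(covariates) && "sample_id" %in% names(covariates)) {
    ids <- intersect(ids, covariates$sample_id)
    covariates <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
    covariates$sample_id <- NULL
  }
  if (length(ids) == 0) pp_stop("no overlapping samples", "no_samples")
  G <- genotypes$dosage[ids, , drop = FALSE]
  Y <- proteins[ids, , drop = FALSE]
  if (!is.null(snps)) G <- G[, snps, drop = FALSE]
  if (!is.null(aptamers)) Y <- Y[, aptamers, drop = FALSE]
  vinfo <- genotypes$variants[match(colnames(G), genotypes$variants$id), ]
  Xfull <- covariate_design(covariates, length(ids))

  out <- vector("list", ncol(Y))
  for (a in seq_len(ncol(Y))) {
    y <- Y[, a]
    ok <- !is.na(y) & stats::complete.cases(Xfull)
    res <- scan_one_aptamer(G[ok, , drop = FALSE], y[ok],
                            Xfull[ok, , drop = FALSE])
    out[[a]] <- data.frame(
      variant_id = colnames(G), aptamer_id = colnames(Y)[a],
      beta = res$beta, se = res$se, t = res$beta / res$se, p = res$p,
      n = res$n, effect_allele = vinfo$alt, other_allele = vinfo$ref,
      effect_allele_freq = colMeans(G, na.rm = TRUE) / 2,
      zero_variance = res$zero_var,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}

# one aptamer against all SNPs; FWL fast path, per-SNP fallback when the
# SNP itself has missing dosages
scan_one_aptamer <- function(G, y, X) {
  n <- length(y)
  k <- qr(X)$rank
  df <- n - k - 1
  nV <- ncol(G)
  beta <- se <- p <- rep(NA_real_, nV)
  nn <- rep(n, nV)
  zero_var <- rep(FALSE, nV)
  if (df < 1) return(list(beta = beta, se = se, p = p, n = nn, zero_var = zero_var))

  qx <- qr(X)
  yr <- qr.resid(qx, y)
  yy <- sum(yr^2)
  has_na <- colSums(is.na(G)) > 0

  if (any(!has_na)) {
    j <- which(!has_na)
    Gr <- qr.resid(qx, G[, j, drop = FALSE])
    gg <- colSums(Gr^2)
    b <- as.numeric(crossprod(Gr, yr)) / gg
    rss <- yy - b^2 * gg
    s <- sqrt(rss / df / gg)
    zv <- gg < .Machine$double.eps * n
    b[zv] <- NA; s[zv] <- NA
    beta[j] <- b; se[j] <- s
    p[j] <- p_from_t(b / s, df)
    zero_var[j] <- zv
  }
  for (j in which(has_na)) {
    ok <- !is.na(G[, j])
    g <- G[ok, j]
    nn[j] <- sum(ok)
    if (stats::var(g) == 0) { zero_var[j] <- TRUE; next }
    if (sum(ok) <= k + 1) next
    fit <- stats::lm(y[ok] ~ 0 + X[ok, , drop = FALSE] + g)
    co <- summary(fit)$coefficients
    beta[j] <- co["g", 1]; se[j] <- co["g", 2]; p[j] <- co["g", 4]
  }
  list(beta = beta, se = se, p = p, n = nn, zero_var = zero_var)
}
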