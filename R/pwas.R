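#' Train per-aptamer SNP weight models (top1 and elastic net)
#'
#' Fits the two weight learners on covariate-residualized protein levels
#' over the supplied cis+trans SNP set: \code{top1} (the single best
#' marginal SNP, weight = its marginal beta) and an elastic net
#' (\code{glmnet}, alpha 0.5, lambda by k-fold cross-validation). The model
#' with the higher k-fold cross-validation R-squared is retained; a model
#' whose cv R-squared is not positive is unusable and excluded from PWAS.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param y numeric vector of covariate-residualized protein levels, named
#'   by sample ID (see \code{\link{residualize}}).
#' @param snp_set data.frame (variant_id, role) with role "cis"/"trans",
#'   or a character vector of variant IDs (role then "cis").
#' @param folds cross-validation folds, default 5.
#' @param alpha elastic-net mixing parameter, default 0.5.
#' @param seed fold-assignment seed.
#' @return object of class \code{weight_model}: aptamer-agnostic list with
#'   \code{weights} data.frame (variant_id, role, weight, effect_allele,
#'   other_allele), \code{model} ("top1"/"enet"), \code{cv_r2}, per-model
#'   cv R-squared, and \code{usable} flag.
#' @export
train_weights <- function(genotypes, y, snp_set, folds = 5, alpha = 0.5,
                          seed = 1L) {
  if (is.character(snp_set)) {
    snp_set <- data.frame(variant_id = snp_set, role = "cis",
                          stringsAsFactors = FALSE)
  }
  ids <- intersect(rownames(genotypes$dosage), names(y))
  n <- length(ids)
  if (n < folds * 5) {
    pp_stop(sprintf("need at least %d samples for %d-fold training, got %d",
                    folds * 5, folds, n), "too_few_samples")
  }
  G <- genotypes$dosage[ids, snp_set$variant_id, drop = FALSE]
  yy <- y[ids]
  vinfo <- genotypes$variants[match(colnames(G), genotypes$variants$id), ]

  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))

  # --- top1: best marginal SNP, refit per training fold for honest cv R2
  marg <- marginal_linear_scan(G, yy)
  best <- which.min(marg$p)
  pred_top1 <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- foldid != f
    m <- marginal_linear_scan(G[tr, , drop = FALSE], yy[tr])
    b <- which.min(m$p)
    g_tr <- G[tr, b]; g_te <- G[!tr, b]
    a0 <- mean(yy[tr]) - m$beta[b] * mean(g_tr)
    pred_top1[!tr] <- a0 + m$beta[b] * g_te
  }
  r2_top1 <- cv_r2(yy, pred_top1)

  # --- elastic net via glmnet cross-validation; the conservative
  # lambda.1se convention keeps null proteins from slipping past the
  # usability gate on cv selection noise
  r2_enet <- -Inf
  enet_w <- NULL
  if (ncol(G) >= 2) {
    cvfit <- glmnet::cv.glmnet(G, yy, alpha = alpha, foldid = foldid,
                               standardize = TRUE)
    i1se <- which(cvfit$lambda == cvfit$lambda.1se)[1]
    r2_enet <- 1 - cvfit$cvm[i1se] / mean((yy - mean(yy))^2)
    co <- as.numeric(stats::coef(cvfit, s = "lambda.1se"))[-1]
    enet_w <- stats::setNames(co, colnames(G))
  }

  if (r2_enet > r2_top1 && !is.null(enet_w) && any(enet_w != 0)) {
    model <- "enet"; cvr2 <- r2_enet
    w <- enet_w[enet_w != 0]
  } else {
    model <- "top1"; cvr2 <- r2_top1
    w <- stats::setNames(marg$beta[best], colnames(G)[best])
  }
  keep <- match(names(w), snp_set$variant_id)
  vi <- vinfo[match(names(w), vinfo$id), ]
  structure(list(
    weights = data.frame(variant_id = names(w),
                         role = snp_set$role[keep],
                         weight = as.numeric(w),
                         effect_allele = vi$alt, other_allele = vi$ref,
                         chrom = vi$chrom, pos = vi$pos,
                         stringsAsFactors = FALSE, row.names = NULL),
    model = model, cv_r2 = cvr2,
    cv_r2_top1 = r2_top1, cv_r2_enet = if (is.finite(r2_enet)) r2_enet else NA_real_,
    usable = cvr2 > 0, n = n
  ), class = "weight_model")
}

cv_r2 <- function(y, pred) 1 - mean((y - pred)^2) / mean((y - mean(y))^2)

#' Residualize protein levels on covariates
#'
#' @param y numeric vector (named by sample) or single-column matrix.
#' @param covariates data.frame aligned to \code{y} (optionally with
#'   \code{sample_id} for alignment).
#' @return named numeric vector of OLS residuals.
#' @export
residualize <- function(y, covariates = NULL) {
  if (is.matrix(y)) y <- stats::setNames(y[, 1], rownames(y))
  if (is.null(covariates)) return(y - mean(y, na.rm = TRUE))
  if ("sample_id" %in% names(covariates)) {
    covariates <- covariates[match(names(y), covariates$sample_id), , drop = FALSE]
    covariates$sample_id <- NULL
  }
  ok <- stats::complete.cases(y, covariates)
  X <- covariate_design(covariates[ok, , drop = FALSE], sum(ok))
  r <- stats::setNames(rep(NA_real_, length(y)), names(y))
  r[ok] <- stats::lm.fit(X, y[ok])$residuals
  r[!is.na(r)]
}

#' PWAS association statistic
#'
#' Computes the functional association z-score of a weighted SNP model
#' against GWAS z-scores: \code{z = w'z / sqrt(w'Rw)}, with the LD matrix
#' regularized by clipping eigenvalues below \code{eig_min}. Weights are
#' harmonized to the GWAS effect alleles (z flipped when alleles are
#' swapped).
#'
#' @param model a \code{\link{train_weights}} model.
#' @param gwas GWAS summary data.frame (SNP, A1, A2, BETA, SE or Z).
#' @param ld an \code{\link{ld_matrix}} covering the model variants.
#' @param eig_min eigenvalue clip floor, default 1e-8.
#' @return data.frame with z, p, n_snps, model tag and a valid flag
#'   (FALSE when the quadratic form is not positive after regularization).
#' @export
pwas_assoc <- function(model, gwas, ld, eig_min = 1e-8) {
  w_tab <- model$weights
  gidx <- match(w_tab$variant_id, gwas$SNP)
  if (anyNA(gidx)) {
    pp_stop(paste("GWAS is missing model variants:",
                  paste(w_tab$variant_id[is.na(gidx)], collapse = ", ")),
            "missing_variants")
  }
  z <- if ("Z" %in% names(gwas)) gwas$Z[gidx] else gwas$BETA[gidx] / gwas$SE[gidx]
  swapped <- gwas$A1[gidx] == w_tab$other_allele &
    gwas$A2[gidx] == w_tab$effect_allele
  z[swapped] <- -z[swapped]
  w <- w_tab$weight
  R <- ld$r[w_tab$variant_id, w_tab$variant_id, drop = FALSE]
  eg <- eigen(R, symmetric = TRUE)
  ev <- pmax(eg$values, eig_min)
  denom <- sum((as.numeric(crossprod(eg$vectors, w)))^2 * ev)
  if (denom <= 0) {
    return(data.frame(z = NA_real_, p = NA_real_, n_snps = length(w),
                      model = model$model, valid = FALSE))
  }
  zp <- sum(w * z) / sqrt(denom)
  data.frame(z = zp, p = p_from_z(zp), n_snps = length(w),
             model = model$model, valid = TRUE, stringsAsFactors = FALSE)
}

#' Locus post-processing of PWAS results
#'
#' Flags significant features (BH across tested aptamers), merges
#' significant features whose weight-SNP spans come within \code{window}
#' base pairs on the same chromosome into loci, and within each locus
#' computes conditional z-scores against the locus's top feature from the
#' correlation of genetically predicted protein levels. Features whose
#' conditional p stays below the significance level are flagged
#' conditionally independent.
#'
#' @param results data.frame, one row per aptamer: aptamer_id, z, p.
#' @param models named list of \code{weight_model}s keyed by aptamer_id.
#' @param genotypes a \code{genotype_matrix} (for predicted-level LD).
#' @param window locus merge distance in bp, default 100000.
#' @param fdr_level BH significance level, default 0.05.
#' @return \code{results} augmented with q, significant, locus,
#'   z_conditional, p_conditional, conditionally_independent, top_in_locus.
#' @export
postprocess_loci <- function(results, models, genotypes, window = 1e5,
                             fdr_level = 0.05) {
  results$q <- bh_adjust(results$p)
  results$significant <- !is.na(results$q) & results$q <= fdr_level
  results$locus <- NA_integer_
  results$z_conditional <- results$z
  results$p_conditional <- results$p
  results$conditionally_independent <- results$significant
  results$top_in_locus <- FALSE

  sig <- which(results$significant)
  if (length(sig) == 0) return(results)

  spans <- t(vapply(results$aptamer_id[sig], function(a) {
    w <- models[[a]]$weights
    c(min(w$pos), max(w$pos))
  }, numeric(2)))
  chroms <- vapply(results$aptamer_id[sig], function(a) {
    paste(sort(unique(models[[a]]$weights$chrom)), collapse = ",")
  }, "")

  # merge intervals within `window` on the same chromosome string
  locus <- integer(length(sig))
  cur <- 0L
  for (ch in unique(chroms)) {
    members <- which(chroms == ch)
    members <- members[order(spans[members, 1])]
    run_end <- -Inf
    for (j in members) {
      if (spans[j, 1] > run_end + window) cur <- cur + 1L
      locus[j] <- cur
      run_end <- max(run_end, spans[j, 2])
    }
  }
  results$locus[sig] <- locus

  # predicted protein levels for conditional analysis
  pred <- vapply(results$aptamer_id[sig], function(a) {
    w <- models[[a]]$weights
    as.numeric(genotypes$dosage[, w$variant_id, drop = FALSE] %*% w$weight)
  }, numeric(nrow(genotypes$dosage)))
  colnames(pred) <- results$aptamer_id[sig]

  for (l in unique(locus)) {
    members <- sig[locus == l]
    top <- members[which.max(abs(results$z[members]))]
    results$top_in_locus[top] <- TRUE
    for (m in setdiff(members, top)) {
      rho <- stats::cor(pred[, results$aptamer_id[m]],
                        pred[, results$aptamer_id[top]])
      if (is.na(rho) || abs(rho) >= 1 - 1e-12) {
        results$z_conditional[m] <- 0
      } else {
        results$z_conditional[m] <-
          (results$z[m] - rho * results$z[top]) / sqrt(1 - rho^2)
      }
      results$p_conditional[m] <- p_from_z(results$z_conditional[m])
      results$conditionally_independent[m] <-
        results$p_conditional[m] <= fdr_level
    }
  }
  results
}
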