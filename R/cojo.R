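#' PheWAS of one variant across all aptamers with BH-FDR control
#'
#' Benjamini-Hochberg q-values are computed across the aptamer records for
#' the query variant; aptamers at q below the FDR level are returned sorted
#' by raw p.
#'
#' @param records data.frame of association records for a single variant
#'   (one row per aptamer; fields aptamer_id, p at minimum).
#' @param fdr_level FDR level, default 0.05.
#' @return list with \code{table} (records + q + significant flag, sorted
#'   by p) and \code{significant} (aptamer IDs passing).
#' @export
phewas <- function(records, fdr_level = 0.05) {
  if (is.null(records) || nrow(records) == 0) {
    return(list(table = records, significant = character(0)))
  }
  records$q <- bh_adjust(records$p)
  records$significant <- !is.na(records$q) & records$q <= fdr_level
  records <- records[order(records$p), , drop = FALSE]
  list(table = records,
       significant = records$aptamer_id[records$significant])
}

#' In-sample LD matrix
#'
#' Pearson correlation of dosages for the requested variants.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param variants optional variant IDs (default all).
#' @return list of class \code{ld_matrix}: \code{r} correlation matrix,
#'   \code{n} source sample size.
#' @export
ld_matrix <- function(genotypes, variants = NULL) {
  g <- genotypes$dosage
  if (!is.null(variants)) g <- g[, variants, drop = FALSE]
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  structure(list(r = r, n = nrow(g)), class = "ld_matrix")
}

# marginal records -> standardized correlations r_jy, recovered exactly
# from the t statistic of a covariate-free marginal fit:
#   t = r * sqrt(df / (1 - r^2)),  df = n - 2  =>  r = t / sqrt(df + t^2)
std_marginal <- function(marginal) {
  t <- marginal$beta / marginal$se
  df <- marginal$n - 2
  r <- t / sqrt(df + t^2)
  # per-allele <-> standardized conversion factor (genotype sd on protein-SD scale)
  sd_g <- ifelse(marginal$beta != 0, r / marginal$beta, NA_real_)
  list(r = stats::setNames(r, marginal$variant_id),
       sd_g = stats::setNames(sd_g, marginal$variant_id),
       n = marginal$n)
}

# joint fit of a selected set from summary-level r_y and LD, equivalent to
# multiple regression on z-scored individual-level data when LD is in-sample:
#   b = R^{-1} r_y ; sigma2 = (n-1)(1 - b'r_y)/(n-p-1) ; Var(b) = sigma2 R^{-1}/(n-1)
joint_fit <- function(r_y, R, n) {
  p <- length(r_y)
  Rinv <- tryCatch(solve(R), error = function(e) {
    pp_stop(paste("singular LD submatrix for variants:",
                  paste(names(r_y), collapse = ", ")), "collinear_ld")
  })
  b <- as.numeric(Rinv %*% r_y)
  df <- n - p - 1
  sigma2 <- (n - 1) * max(1 - sum(b * r_y), 0) / df
  se <- sqrt(sigma2 * diag(Rinv) / (n - 1))
  tt <- b / se
  data.frame(variant_id = names(r_y), beta_std = b, se_std = se, t = tt,
             p = p_from_t(tt, df), stringsAsFactors = FALSE, row.names = NULL)
}

#' Conditional association statistics from summary data
#'
#' For each free SNP, computes its effect conditional on a set of
#' conditioning SNPs from the joint normal-equations system implied by the
#' marginal summary statistics and the LD matrix. With in-sample LD this
#' reproduces individual-level multiple regression. Returned effects are on
#' both the standardized and the per-allele scale.
#'
#' @param marginal data.frame of marginal records (variant_id, beta, se, n)
#'   from a covariate-free scan of one aptamer.
#' @param ld an \code{\link{ld_matrix}} covering all variants involved.
#' @param conditioning character vector of conditioning variant IDs.
#' @param free optional variant IDs to compute conditional stats for
#'   (default: all marginal variants not in the conditioning set).
#' @param collinearity pairwise r-squared above which a free SNP is flagged
#'   collinear with the conditioning set and skipped, default 0.9.
#' @return data.frame variant_id, beta_cond (per-allele), se_cond, t, p,
#'   collinear flag, self flag (conditioning on itself gives beta 0).
#' @export
conditional_stats <- function(marginal, ld, conditioning, free = NULL,
                              collinearity = 0.9) {
  sm <- std_marginal(marginal)
  if (is.null(free)) free <- setdiff(marginal$variant_id, conditioning)
  R <- ld$r
  out <- lapply(free, function(v) {
    row <- marginal[marginal$variant_id == v, ][1, ]
    n <- row$n
    if (v %in% conditioning) {
      return(data.frame(variant_id = v, beta_cond = 0, se_cond = NA_real_,
                        t = NA_real_, p = NA_real_, collinear = FALSE,
                        self = TRUE, stringsAsFactors = FALSE))
    }
    if (length(conditioning) &&
        max(R[v, conditioning]^2) > collinearity) {
      return(data.frame(variant_id = v, beta_cond = NA_real_,
                        se_cond = NA_real_, t = NA_real_, p = NA_real_,
                        collinear = TRUE, self = FALSE,
                        stringsAsFactors = FALSE))
    }
    set <- c(conditioning, v)
    jf <- joint_fit(sm$r[set], R[set, set, drop = FALSE], n)
    j <- nrow(jf)
    sd_g <- sm$sd_g[v]
    data.frame(variant_id = v,
               beta_cond = jf$beta_std[j] / sd_g,
               se_cond = jf$se_std[j] / abs(sd_g),
               t = jf$t[j], p = jf$p[j], collinear = FALSE, self = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Stepwise conditional-joint SNP selection (COJO-style)
#'
#' Greedy forward selection on summary statistics: starting from the SNP
#' with the smallest marginal p below \code{p_entry}, repeatedly adds the
#' free SNP with the smallest conditional p below \code{p_entry} (skipping
#' SNPs whose r-squared with the selected set exceeds \code{collinearity}),
#' refits the joint model after each addition, and drops any selected SNP
#' whose joint p rises above \code{p_entry} (backward check). Ties break by
#' smaller p then lexicographic variant ID.
#'
#' @param marginal data.frame (variant_id, beta, se, n, p) for one aptamer.
#' @param ld an \code{\link{ld_matrix}}.
#' @param p_entry entry/stay p threshold, default 5e-8.
#' @param collinearity pairwise r-squared cutoff, default 0.9.
#' @param max_steps safety bound on iterations.
#' @return list of class \code{selection_result}: \code{selected}
#'   data.frame (variant_id, beta_joint (per-allele), se_joint, p_joint,
#'   beta_std, se_std), \code{trace} data.frame of add/drop events.
#' @export
stepwise_select <- function(marginal, ld, p_entry = 5e-8, collinearity = 0.9,
                            max_steps = 100) {
  marginal <- marginal[!is.na(marginal$p), , drop = FALSE]
  trace <- data.frame(step = integer(), action = character(),
                      variant_id = character(), p = numeric(),
                      stringsAsFactors = FALSE)
  empty <- function() {
    structure(list(
      selected = data.frame(variant_id = character(), beta_joint = numeric(),
                            se_joint = numeric(), p_joint = numeric(),
                            beta_std = numeric(), se_std = numeric(),
                            stringsAsFactors = FALSE),
      trace = trace), class = "selection_result")
  }
  if (nrow(marginal) == 0 || min(marginal$p) >= p_entry) return(empty())

  sm <- std_marginal(marginal)
  R <- ld$r
  ord <- order(marginal$p, marginal$variant_id)
  selected <- marginal$variant_id[ord[1]]
  trace <- rbind(trace, data.frame(step = 1L, action = "add",
                                   variant_id = selected,
                                   p = marginal$p[ord[1]]))
  step <- 1L
  repeat {
    step <- step + 1L
    if (step > max_steps) break
    free <- setdiff(marginal$variant_id, selected)
    cand <- NULL
    if (length(free)) {
      cs <- conditional_stats(marginal, ld, selected, free = free,
                              collinearity = collinearity)
      cs <- cs[!cs$collinear & !is.na(cs$p) & cs$p < p_entry, , drop = FALSE]
      if (nrow(cs)) {
        cs <- cs[order(cs$p, cs$variant_id), , drop = FALSE]
        cand <- cs$variant_id[1]
      }
    }
    if (is.null(cand)) break
    selected <- c(selected, cand)
    trace <- rbind(trace, data.frame(step = step, action = "add",
                                     variant_id = cand,
                                     p = cs$p[1]))
    # backward check on the refitted joint model
    repeat {
      n <- max(marginal$n[marginal$variant_id %in% selected])
      jf <- joint_fit(sm$r[selected], R[selected, selected, drop = FALSE], n)
      worst <- which.max(jf$p)
      if (jf$p[worst] <= p_entry || length(selected) == 1L) break
      dropped <- jf$variant_id[worst]
      trace <- rbind(trace, data.frame(step = step, action = "drop",
                                       variant_id = dropped,
                                       p = jf$p[worst]))
      selected <- setdiff(selected, dropped)
    }
  }

  n <- max(marginal$n[marginal$variant_id %in% selected])
  jf <- joint_fit(sm$r[selected], R[selected, selected, drop = FALSE], n)
  sd_g <- sm$sd_g[jf$variant_id]
  structure(list(
    selected = data.frame(
      variant_id = jf$variant_id,
      beta_joint = jf$beta_std / sd_g,
      se_joint = jf$se_std / abs(sd_g),
      p_joint = jf$p,
      beta_std = jf$beta_std, se_std = jf$se_std,
      stringsAsFactors = FALSE, row.names = NULL),
    trace = trace), class = "selection_result")
}

#' Greedy LD pruning
#'
#' Keeps variants in order of ascending p (ties by variant ID); any
#' remaining variant whose r-squared with an already-kept variant is
#' strictly greater than \code{r2_max} is dropped. Pairs at exactly
#' \code{r2_max} are both kept.
#'
#' @param variants data.frame with variant_id and p (or a character vector,
#'   in which case input order is the priority order).
#' @param ld an \code{\link{ld_matrix}} covering the variants.
#' @param r2_max pruning threshold on r-squared, default 0.85.
#' @return character vector of kept variant IDs.
#' @export
ld_prune <- function(variants, ld, r2_max = 0.85) {
  if (is.character(variants)) {
    variants <- data.frame(variant_id = variants,
                           p = seq_along(variants) * 1e-300,
                           stringsAsFactors = FALSE)
  }
  variants <- variants[order(variants$p, variants$variant_id), , drop = FALSE]
  kept <- character(0)
  r2 <- ld$r^2
  # strict inequality at the stored precision: a pair sitting exactly on the
  # threshold (up to float round-trip error) is retained
  eps <- 1e-12
  for (v in variants$variant_id) {
    if (length(kept) == 0 || all(r2[v, kept] <= r2_max + eps)) kept <- c(kept, v)
  }
  kept
}

#' Sentinel-driven discovery loop
#'
#' One round: PheWAS of the current SNP set, stepwise conditional selection
#' on each significant aptamer, union of selected SNPs, LD pruning, then
#' PheWAS of any newly found SNPs to extend the aptamer set. Runs a fixed
#' number of rounds (default 2: the sentinel pass plus one extension).
#'
#' @param sentinel variant ID seeding the loop.
#' @param scan data.frame of association records for all (variant, aptamer)
#'   pairs (from \code{\link{pqtl_scan}} or a meta-analysis reshaped to the
#'   same fields).
#' @param ld an \code{\link{ld_matrix}} over all scan variants.
#' @param fdr_level PheWAS FDR level, default 0.05.
#' @param p_entry stepwise entry threshold, default 5e-8.
#' @param r2_prune LD pruning threshold, default 0.85.
#' @param rounds number of rounds, default 2.
#' @return list with \code{variants} (pruned independent SNP set),
#'   \code{aptamers} (significant aptamer set), \code{rounds} (per-round
#'   detail), \code{phewas_tables}.
#' @export
discovery_loop <- function(sentinel, scan, ld, fdr_level = 0.05,
                           p_entry = 5e-8, r2_prune = 0.85, rounds = 2) {
  snp_set <- sentinel
  apt_set <- character(0)
  detail <- list()
  phewas_tables <- list()
  queried <- character(0)

  for (rd in seq_len(rounds)) {
    new_apts <- character(0)
    for (v in setdiff(snp_set, queried)) {
      ph <- phewas(scan[scan$variant_id == v, , drop = FALSE], fdr_level)
      phewas_tables[[v]] <- ph$table
      queried <- c(queried, v)
      new_apts <- union(new_apts, ph$significant)
    }
    apt_set <- union(apt_set, new_apts)
    sel_union <- snp_set
    for (a in apt_set) {
      ma <- scan[scan$aptamer_id == a, , drop = FALSE]
      sel <- stepwise_select(ma, ld, p_entry = p_entry)
      sel_union <- union(sel_union, sel$selected$variant_id)
    }
    # prune by best p across aptamers
    minp <- stats::aggregate(p ~ variant_id,
                             data = scan[scan$variant_id %in% sel_union, ],
                             FUN = min)
    snp_set <- ld_prune(minp, ld, r2_max = r2_prune)
    detail[[rd]] <- list(variants = snp_set, aptamers = apt_set)
    if (length(setdiff(snp_set, queried)) == 0 && rd > 1) break
  }
  list(variants = snp_set, aptamers = apt_set, rounds = detail,
       phewas_tables = phewas_tables)
}
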