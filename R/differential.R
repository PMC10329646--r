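#' Differential protein levels between phenotype groups
#'
#' Per aptamer, ordinary least squares of the normalized protein level on a
#' group indicator (comparison vs reference) plus covariates; BH q-values
#' across aptamers within the contrast.
#'
#' @param proteins samples x aptamers matrix of normalized levels.
#' @param phenotypes data.frame with sample_id, a \code{group} column (or
#'   the column named by \code{group_col}) and any covariate columns.
#' @param contrast length-2 character: c(reference, comparison) group labels.
#' @param covariates character vector of covariate column names in
#'   \code{phenotypes} (factors allowed), default none.
#' @param group_col name of the grouping column, default "group".
#' @return data.frame (class \code{group_contrast}): aptamer_id, contrast,
#'   effect (SD-protein, comparison minus reference), se, t, p, q, n_ref,
#'   n_cmp.
#' @export
group_compare <- function(proteins, phenotypes, contrast,
                          covariates = character(0), group_col = "group") {
  stopifnot(length(contrast) == 2)
  ph <- phenotypes[phenotypes[[group_col]] %in% contrast, , drop = FALSE]
  ph <- ph[ph$sample_id %in% rownames(proteins), , drop = FALSE]
  n_ref <- sum(ph[[group_col]] == contrast[1])
  n_cmp <- sum(ph[[group_col]] == contrast[2])
  if (n_ref < 2 || n_cmp < 2) {
    warning(sprintf("contrast %s_vs_%s skipped: group with < 2 samples",
                    contrast[1], contrast[2]))
    return(NULL)
  }
  Y <- proteins[ph$sample_id, , drop = FALSE]
  ind <- as.numeric(ph[[group_col]] == contrast[2])
  X0 <- covariate_design(
    if (length(covariates)) ph[, covariates, drop = FALSE] else NULL,
    nrow(ph))

  out <- lapply(colnames(Y), function(a) {
    y <- Y[, a]
    ok <- !is.na(y)
    if (sum(ok) < ncol(X0) + 2) {
      return(data.frame(aptamer_id = a, effect = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    fit <- stats::lm(y[ok] ~ 0 + X0[ok, , drop = FALSE] + ind[ok])
    co <- summary(fit)$coefficients
    j <- nrow(co)
    data.frame(aptamer_id = a, effect = co[j, 1], se = co[j, 2],
               t = co[j, 3], p = co[j, 4], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- bh_adjust(out$p)
  out$contrast <- paste(contrast[1], "vs", contrast[2], sep = "_")
  out$n_ref <- n_ref
  out$n_cmp <- n_cmp
  class(out) <- c("group_contrast", class(out))
  out[, c("aptamer_id", "contrast", "effect", "se", "t", "p", "q",
          "n_ref", "n_cmp")]
}

#' Sex-difference contrasts within phenotype strata
#'
#' Runs a male-vs-female contrast of protein levels within each stratum
#' (e.g. all samples, then cases, controls, prodromal, mutation carriers
#' separately), adjusted for the supplied covariates (sex itself is never a
#' covariate here); BH within each stratum.
#'
#' @param proteins samples x aptamers matrix of normalized levels.
#' @param phenotypes data.frame with sample_id, sex (0 = female, 1 = male
#'   or "female"/"male"), a group column, and covariates.
#' @param strata named list of group-label vectors defining each stratum;
#'   an entry \code{NULL} means all samples.
#' @param covariates covariate column names (default age + array if present).
#' @param group_col grouping column name, default "group".
#' @return data.frame of per-stratum contrasts with a \code{stratum} column.
#' @export
sex_difference <- function(proteins, phenotypes, strata = list(all = NULL),
                           covariates = intersect(c("age", "array"),
                                                  names(phenotypes)),
                           group_col = "group") {
  ph <- phenotypes
  sx <- ph$sex
  if (!is.numeric(sx)) sx <- as.numeric(tolower(as.character(sx)) %in% c("male", "m", "1"))
  ph$.sex_group <- ifelse(sx == 1, "male", "female")
  out <- list()
  for (s in names(strata)) {
    sub <- if (is.null(strata[[s]])) ph else
      ph[ph[[group_col]] %in% strata[[s]], , drop = FALSE]
    if (nrow(sub) == 0) {
      warning(sprintf("stratum '%s' empty; skipped", s))
      next
    }
    gc <- group_compare(proteins, sub, c("female", "male"),
                        covariates = covariates, group_col = ".sex_group")
    if (is.null(gc)) next
    gc$stratum <- s
    out[[s]] <- gc
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, c(out, make.row.names = FALSE))
}
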