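#' Simulate a gene-by-cell-type expression table with planted specificity
#'
#' Each gene's expression shares across cell types follow a specificity
#' plan: a gene planned specific to one cell type gives that type a share
#' above 0.5 (the downstream "more than 50% of sum-total expression" rule
#' then recovers the plan); genes planned non-specific split expression so
#' no type exceeds 0.5.
#'
#' @param genes character vector of gene IDs.
#' @param cell_types character vector of cell-type names (>= 2).
#' @param specificity_plan data.frame (gene, cell_type or NA, share). When
#'   \code{share} is NA a share is drawn in (0.55, 0.9) for specific genes
#'   and below 0.5 for non-specific ones. Explicit per-gene share vectors
#'   can be supplied via the \code{shares} column (list column, must sum
#'   to 1).
#' @param total_expression mean total expression per gene (lognormal draw).
#' @param seed integer seed.
#' @return matrix genes x cell types of nonnegative expression.
#' @export
simulate_celltype_expression <- function(genes, cell_types, specificity_plan,
                                         total_expression = 100, seed = 1L) {
  stopifnot(length(cell_types) >= 2)
  set.seed(seed)
  K <- length(cell_types)
  plan <- specificity_plan[match(genes, specificity_plan$gene), , drop = FALSE]
  expr <- matrix(0, length(genes), K, dimnames = list(genes, cell_types))
  for (i in seq_along(genes)) {
    if (!is.null(plan$shares) && !is.null(plan$shares[[i]])) {
      sh <- plan$shares[[i]]
      if (abs(sum(sh) - 1) > 1e-9) {
        pp_stop(paste0("shares for gene ", genes[i], " do not sum to 1"),
                "invalid_config")
      }
    } else {
      dom <- plan$cell_type[i]
      share <- plan$share[i]
      if (!is.na(dom)) {
        if (is.na(share)) share <- stats::runif(1, 0.55, 0.9)
        rest <- stats::runif(K - 1)
        sh <- stats::setNames(rep(0, K), cell_types)
        sh[dom] <- share
        sh[setdiff(cell_types, dom)] <- (1 - share) * rest / sum(rest)
      } else {
        if (is.na(share)) share <- stats::runif(1, 0.2, 0.45)
        # cap every share below 0.5 by spreading around the cap
        raw <- stats::runif(K, 0.5, 1)
        sh <- raw / sum(raw)
        while (max(sh) > 0.5) {          # nudge until no type dominates
          sh[which.max(sh)] <- sh[which.max(sh)] * 0.8
          sh <- sh / sum(sh)
        }
        names(sh) <- cell_types
      }
    }
    tot <- stats::rlnorm(1, log(total_expression), 0.5)
    expr[i, ] <- tot * sh[cell_types]
  }
  expr
}
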