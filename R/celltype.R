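#' Assign cell-type specificity calls from an expression table
#'
#' Per gene, expression shares are the per-cell-type sums divided by the
#' gene's sum-total expression. A gene is called specific to the cell type
#' holding strictly more than 50 percent of its sum-total expression;
#' otherwise the call is none. All-zero genes get call none with a flag.
#'
#' @param expression numeric matrix, genes x cell types (nonnegative).
#' @return data.frame gene, call ("none" or a cell type), max_share,
#'   all_zero flag, plus one share column per cell type.
#' @export
assign_specificity <- function(expression) {
  stopifnot(is.matrix(expression), ncol(expression) >= 2)
  if (any(expression < 0, na.rm = TRUE)) {
    pp_stop("expression must be nonnegative", "invalid_expression")
  }
  tot <- rowSums(expression, na.rm = TRUE)
  shares <- expression / ifelse(tot == 0, 1, tot)
  max_i <- max.col(shares, ties.method = "first")
  max_share <- shares[cbind(seq_len(nrow(shares)), max_i)]
  call <- ifelse(tot > 0 & max_share > 0.5, colnames(expression)[max_i], "none")
  out <- data.frame(gene = rownames(expression), call = call,
                    max_share = max_share, all_zero = tot == 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(shares))
}

#' Cell-type enrichment of a target gene set
#'
#' Fold change is the ratio between the fraction of cell-type-specific
#' genes in the target set and that fraction in the background set; the
#' p-value is the hypergeometric upper tail of drawing at least the
#' observed number of specific genes in a sample of the target's size from
#' the background composition (equivalently, one-sided Fisher).
#'
#' @param target character vector of target genes (subset of background).
#' @param background character vector of background genes.
#' @param calls specificity calls from \code{\link{assign_specificity}}.
#' @param cell_type cell type to test.
#' @return data.frame cell_type, target_specific, target_size,
#'   background_specific, background_size, fold_change, p, valid flag
#'   (FALSE when the background has no specific genes).
#' @export
celltype_enrichment <- function(target, background, calls, cell_type) {
  stopifnot(all(target %in% background))
  cb <- calls[match(background, calls$gene), ]
  spec_bg <- sum(cb$call == cell_type, na.rm = TRUE)
  spec_tg <- sum(cb$call[match(target, cb$gene)] == cell_type, na.rm = TRUE)
  Nb <- length(background); Nt <- length(target)
  if (spec_bg == 0) {
    return(data.frame(cell_type = cell_type, target_specific = spec_tg,
                      target_size = Nt, background_specific = 0,
                      background_size = Nb, fold_change = NA_real_,
                      p = NA_real_, valid = FALSE, stringsAsFactors = FALSE))
  }
  fc <- (spec_tg / Nt) / (spec_bg / Nb)
  p <- stats::phyper(spec_tg - 1, spec_bg, Nb - spec_bg, Nt,
                     lower.tail = FALSE)
  data.frame(cell_type = cell_type, target_specific = spec_tg,
             target_size = Nt, background_specific = spec_bg,
             background_size = Nb, fold_change = fc, p = p, valid = TRUE,
             stringsAsFactors = FALSE)
}

#' Enrichment across every cell type present in the calls
#' @inheritParams celltype_enrichment
#' @return row-bound \code{\link{celltype_enrichment}} results.
#' @export
celltype_enrichment_all <- function(target, background, calls) {
  types <- setdiff(unique(calls$call), "none")
  do.call(rbind, lapply(types, function(ct)
    celltype_enrichment(target, background, calls, ct)))
}
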