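#' @keywords internal
"_PACKAGE"

# internal: stop with a consistent error class so callers can test on it
pp_stop <- function(msg, class = "proteopheno_error", ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# two-sided p from a t statistic
p_from_t <- function(t, df) 2 * stats::pt(-abs(t), df = df)

# two-sided p from a z statistic
p_from_z <- function(z) 2 * stats::pnorm(-abs(z))

#' Benjamini-Hochberg adjusted q-values
#'
#' Thin wrapper over the canonical step-up procedure; kept as a named
#' function so every module applies the same multiple-testing correction.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of BH q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# variant ID convention used throughout: "chr:pos:ref:alt"
make_variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

parse_variant_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.numeric(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 3L),
    alt = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

# covariate data.frame -> design matrix without intercept column collisions
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0L)) {
    return(matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)")))
  }
  stopifnot(nrow(covariates) == n)
  stats::model.matrix(~., data = as.data.frame(covariates))
}
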