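#' Simulate aptamer-level protein measurements with planted genetic effects
#'
#' The latent (log10-scale) level of each aptamer is
#' \code{sum(beta * dosage) + age/sex/array covariate effects +
#' Gaussian(0, noise_sd)}. The raw export is \code{10^latent}, so the QC
#' module's log10 + z-score normalization inverts the scale. Per-plate
#' scale factors and CVs are emitted alongside so the QC filters have
#' realistic inputs; measurement artifacts (plate scale shifts, inflated
#' CVs, random missingness) can be injected via \code{artifacts}.
#'
#' @param genotypes a \code{genotype_matrix} from \code{\link{simulate_genotypes}}.
#' @param config the same \code{\link{sim_config}}.
#' @param n_plates plates per cohort; samples are assigned round-robin.
#' @param log10_center,log10_scale affine export calibration: raw
#'   measurements are \code{10^(log10_center + log10_scale * latent)}.
#'   The defaults (3, 0.15) give RFU-like magnitudes (~1000) with a
#'   realistic ~40 percent geometric dispersion; z-scoring of log10 values
#'   recovers the latent scale exactly whatever the calibration.
#' @param artifacts optional list with any of:
#'   \code{scale_shift} data.frame (aptamer_id, plate, delta) added to that
#'   aptamer's scale factor on that plate; \code{cv_inflate} data.frame
#'   (aptamer_id, cv) forcing that aptamer's per-plate CVs; \code{missing}
#'   data.frame (aptamer_id, rate) with the fraction of samples set missing.
#' @return list with \code{raw} (a \code{\link{raw_aptamer_data}}),
#'   \code{latent} (samples x aptamers matrix of latent levels),
#'   \code{covariates} (data.frame sample_id, cohort, age, sex, array),
#'   and \code{truth} (a \code{truth_ledger}).
#' @export
simulate_proteins <- function(genotypes, config, n_plates = 2, artifacts = NULL,
                              log10_center = 3, log10_scale = 0.15) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(genotypes$dosage)
  amap <- config$aptamer_map
  aptamers <- amap$aptamer_id
  A <- length(aptamers)

  cov <- draw_covariates(genotypes$samples, n_plates)

  eff <- config$planted_effects
  if (!is.null(eff) && nrow(eff)) {
    bad <- setdiff(eff$variant_id, genotypes$variants$id)
    if (length(bad)) {
      pp_stop(paste("planted effect on unknown variant:",
                    paste(bad, collapse = ", ")), "invalid_config")
    }
  }

  genetic <- matrix(0, n, A, dimnames = list(rownames(genotypes$dosage), aptamers))
  if (!is.null(eff) && nrow(eff)) {
    for (i in seq_len(nrow(eff))) {
      genetic[, eff$aptamer_id[i]] <- genetic[, eff$aptamer_id[i]] +
        eff$beta[i] * genotypes$dosage[, eff$variant_id[i]]
    }
  }

  ce <- config$covariate_effects
  age_eff <- expand_effect(ce$age, aptamers)
  sex_eff <- expand_effect(ce$sex, aptamers)
  array_sd <- if (is.null(ce$array_sd)) 0 else ce$array_sd
  arrays <- unique(cov$array)
  array_shift <- matrix(stats::rnorm(length(arrays) * A, 0, array_sd),
                        nrow = length(arrays), dimnames = list(arrays, aptamers))

  latent <- genetic +
    outer(cov$age - mean(cov$age), age_eff) +
    outer(cov$sex, sex_eff) +
    array_shift[cov$array, , drop = FALSE] +
    matrix(stats::rnorm(n * A, 0, config$noise_sd), n, A)
  dimnames(latent) <- list(rownames(genotypes$dosage), aptamers)

  raw <- 10^(log10_center + log10_scale * latent)
  plates <- cov$plate

  # vendor-style QC side tables: near-unit scale factors, small CVs
  plate_ids <- unique(plates)
  sf <- matrix(1 + stats::rnorm(length(plate_ids) * A, 0, 0.05),
               nrow = length(plate_ids), dimnames = list(plate_ids, aptamers))
  cvs <- matrix(stats::runif(length(plate_ids) * A, 0.02, 0.08),
                nrow = length(plate_ids), dimnames = list(plate_ids, aptamers))

  if (!is.null(artifacts$scale_shift)) {
    ss <- artifacts$scale_shift
    for (i in seq_len(nrow(ss))) sf[ss$plate[i], ss$aptamer_id[i]] <-
        sf[ss$plate[i], ss$aptamer_id[i]] + ss$delta[i]
  }
  if (!is.null(artifacts$cv_inflate)) {
    ci <- artifacts$cv_inflate
    for (i in seq_len(nrow(ci))) cvs[, ci$aptamer_id[i]] <- ci$cv[i]
  }
  if (!is.null(artifacts$missing)) {
    ms <- artifacts$missing
    for (i in seq_len(nrow(ms))) {
      drop <- stats::runif(n) < ms$rate[i]
      raw[drop, ms$aptamer_id[i]] <- NA_real_
    }
  }

  truth <- structure(list(
    effects = if (is.null(eff)) {
      data.frame(variant_id = character(), aptamer_id = character(),
                 beta = numeric(), stringsAsFactors = FALSE)
    } else eff,
    mediation = if (is.null(config$disease$mediation)) {
      data.frame(aptamer_id = character(), theta = numeric(),
                 stringsAsFactors = FALSE)
    } else config$disease$mediation,
    cohorts = genotypes$samples,
    aptamer_map = amap
  ), class = "truth_ledger")

  list(
    raw = raw_aptamer_data(raw, plates, scale_factors = sf, cvs = cvs),
    latent = latent,
    covariates = cov,
    truth = truth
  )
}

draw_covariates <- function(samples, n_plates) {
  n <- nrow(samples)
  plate <- character(n)
  array <- character(n)
  for (co in unique(samples$cohort)) {
    idx <- which(samples$cohort == co)
    plate[idx] <- sprintf("%s_plate%d", co,
                          (seq_along(idx) - 1L) %% n_plates + 1L)
    array[idx] <- sprintf("%s_array%d", co,
                          stats::rbinom(length(idx), 1, 0.5) + 1L)
  }
  data.frame(
    sample_id = samples$sample_id,
    cohort = samples$cohort,
    age = stats::runif(n, 45, 85),
    sex = stats::rbinom(n, 1, 0.5),
    array = array,
    plate = plate,
    stringsAsFactors = FALSE
  )
}

expand_effect <- function(x, aptamers) {
  if (is.null(x)) x <- 0
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(x, length(aptamers)), aptamers))
  }
  out <- stats::setNames(rep(0, length(aptamers)), aptamers)
  out[intersect(names(x), aptamers)] <- x[intersect(names(x), aptamers)]
  out
}

#' Look up a planted effect in a truth ledger
#' @param truth a \code{truth_ledger}.
#' @param variant_id,aptamer_id the effect key.
#' @return the planted beta, or 0 when no effect was planted on the pair.
#' @export
planted_effect <- function(truth, variant_id, aptamer_id) {
  hit <- truth$effects$variant_id == variant_id &
    truth$effects$aptamer_id == aptamer_id
  if (!any(hit)) return(0)
  sum(truth$effects$beta[hit])
}
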