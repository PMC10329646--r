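#' Raw aptamer measurement container
#'
#' Holds a samples x aptamers matrix of positive RFU-like measurements with
#' the per-plate QC side tables the SomaScan-style filters need.
#'
#' @param measurements numeric matrix, samples x aptamers; values positive
#'   or NA; rownames sample IDs, colnames aptamer IDs.
#' @param plates character vector of plate IDs, one per sample.
#' @param scale_factors optional plates x aptamers matrix of scale factors;
#'   when NULL the scale-factor filter is skipped with a warning (the
#'   5K-panel path, where vendor scale factors are unavailable).
#' @param cvs optional plates x aptamers matrix of cross-plate CVs.
#' @return object of class \code{raw_aptamer_data}.
#' @export
raw_aptamer_data <- function(measurements, plates, scale_factors = NULL,
                             cvs = NULL) {
  stopifnot(is.matrix(measurements), length(plates) == nrow(measurements))
  if (any(measurements <= 0, na.rm = TRUE)) {
    bad <- which(measurements <= 0, arr.ind = TRUE)[1, ]
    pp_stop(sprintf("nonpositive measurement at sample '%s', aptamer '%s'",
                    rownames(measurements)[bad[1]],
                    colnames(measurements)[bad[2]]),
            "nonpositive_value")
  }
  plates <- as.character(plates)
  if (!is.null(scale_factors)) {
    stopifnot(all(unique(plates) %in% rownames(scale_factors)),
              all(colnames(measurements) %in% colnames(scale_factors)))
  }
  structure(list(measurements = measurements, plates = plates,
                 scale_factors = scale_factors, cvs = cvs),
            class = "raw_aptamer_data")
}

new_qc_report <- function() {
  list(
    removed_aptamers = data.frame(aptamer_id = character(), stage = character(),
                                  reason = character(), stringsAsFactors = FALSE),
    removed_samples = data.frame(sample_id = character(), stage = character(),
                                 reason = character(), stringsAsFactors = FALSE),
    values_set_missing = 0L,
    call_rate_before = NULL,
    call_rate_after = NULL
  )
}

record_aptamer_removal <- function(report, ids, stage, reason) {
  if (length(ids)) {
    report$removed_aptamers <- rbind(
      report$removed_aptamers,
      data.frame(aptamer_id = ids, stage = stage, reason = reason,
                 stringsAsFactors = FALSE))
  }
  report
}

record_sample_removal <- function(report, ids, stage, reason) {
  if (length(ids)) {
    report$removed_samples <- rbind(
      report$removed_samples,
      data.frame(sample_id = ids, stage = stage, reason = reason,
                 stringsAsFactors = FALSE))
  }
  report
}

drop_aptamers <- function(data, ids) {
  keep <- setdiff(colnames(data$measurements), ids)
  data$measurements <- data$measurements[, keep, drop = FALSE]
  if (!is.null(data$scale_factors)) {
    data$scale_factors <- data$scale_factors[, keep, drop = FALSE]
  }
  if (!is.null(data$cvs)) data$cvs <- data$cvs[, keep, drop = FALSE]
  data
}

drop_samples <- function(data, ids) {
  keep <- !(rownames(data$measurements) %in% ids)
  data$measurements <- data$measurements[keep, , drop = FALSE]
  data$plates <- data$plates[keep]
  data
}

#' Scale-factor divergence filter
#'
#' Removes an aptamer when its scale factor diverges from the plate's
#' median scale factor by strictly more than \code{max_divergence}. The
#' median is taken across aptamers within each plate; by default an
#' aptamer failing on any plate is removed (\code{scope = "any_plate"});
#' \code{scope = "aggregate"} compares the per-aptamer median over plates
#' instead.
#'
#' @param data a \code{\link{raw_aptamer_data}}.
#' @param max_divergence removal threshold (strict inequality), default 0.5.
#' @param scope \code{"any_plate"} or \code{"aggregate"}.
#' @param report an accumulating QC report (internal chaining).
#' @return list(data, report).
#' @export
filter_scale_factor <- function(data, max_divergence = 0.5,
                                scope = c("any_plate", "aggregate"),
                                report = new_qc_report()) {
  scope <- match.arg(scope)
  if (is.null(data$scale_factors)) {
    warning("no scale factors available; scale-factor filter skipped")
    return(list(data = data, report = report))
  }
  sf <- data$scale_factors
  if (scope == "any_plate") {
    plate_med <- apply(sf, 1, stats::median, na.rm = TRUE)
    div <- abs(sweep(sf, 1, plate_med))
    bad <- colnames(sf)[apply(div > max_divergence, 2, any, na.rm = TRUE)]
  } else {
    apt_sf <- apply(sf, 2, stats::median, na.rm = TRUE)
    bad <- names(apt_sf)[abs(apt_sf - stats::median(apt_sf)) > max_divergence]
  }
  report <- record_aptamer_removal(
    report, bad, "scale_factor",
    sprintf("scale factor diverged from median by > %g", max_divergence))
  list(data = drop_aptamers(data, bad), report = report)
}

#' Cross-plate CV filter
#'
#' Removes an aptamer when its median cross-plate coefficient of variation
#' exceeds \code{max_cv} (strict inequality).
#'
#' @inheritParams filter_scale_factor
#' @param max_cv removal threshold, default 0.15.
#' @return list(data, report).
#' @export
filter_cv <- function(data, max_cv = 0.15, report = new_qc_report()) {
  if (is.null(data$cvs)) {
    warning("no CV table available; CV filter skipped")
    return(list(data = data, report = report))
  }
  med_cv <- apply(data$cvs, 2, stats::median, na.rm = TRUE)
  bad <- names(med_cv)[med_cv > max_cv]
  report <- record_aptamer_removal(
    report, bad, "cv", sprintf("median cross-plate CV > %g", max_cv))
  list(data = drop_aptamers(data, bad), report = report)
}

#' IQR outlier screen
#'
#' Per aptamer, values outside [Q1 - k*IQR, Q3 + k*IQR] are set to missing;
#' values exactly on a fence are kept. Quartiles use linear interpolation
#' (quantile type 7) by default.
#'
#' @inheritParams filter_scale_factor
#' @param k fence multiplier, default 1.5.
#' @param type quantile type passed to \code{stats::quantile}.
#' @return list(data, report).
#' @export
iqr_screen <- function(data, k = 1.5, type = 7, report = new_qc_report()) {
  m <- data$measurements
  n_set <- 0L
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    if (sum(ok) < 4) {
      warning(sprintf("aptamer '%s' has < 4 non-missing values; IQR screen skipped",
                      colnames(m)[j]))
      next
    }
    q <- stats::quantile(x[ok], c(0.25, 0.75), type = type, names = FALSE)
    iqr <- q[2] - q[1]
    out <- ok & (x < q[1] - k * iqr | x > q[2] + k * iqr)
    n_set <- n_set + sum(out)
    m[out, j] <- NA_real_
  }
  data$measurements <- m
  report$values_set_missing <- report$values_set_missing + n_set
  list(data = data, report = report)
}

#' Two-stage call-rate cascade
#'
#' Stage 1 removes samples and aptamers with call rate below \code{first}
#' (both computed on the incoming table). Call rates are then recomputed on
#' the surviving table and stage 2 removes at \code{second}, aptamers
#' before samples by default (order configurable).
#'
#' @inheritParams filter_scale_factor
#' @param first stage-1 threshold (removal at strictly below), default 0.65.
#' @param second stage-2 threshold, default 0.85.
#' @param stage2_order \code{"aptamers_first"} or \code{"samples_first"}.
#' @return list(data, report).
#' @export
call_rate_cascade <- function(data, first = 0.65, second = 0.85,
                              stage2_order = c("aptamers_first", "samples_first"),
                              report = new_qc_report()) {
  stage2_order <- match.arg(stage2_order)
  m <- data$measurements
  report$call_rate_before <- list(aptamer = colMeans(!is.na(m)),
                                  sample = rowMeans(!is.na(m)))

  apt_cr <- colMeans(!is.na(m))
  smp_cr <- rowMeans(!is.na(m))
  bad_apt <- colnames(m)[apt_cr < first]
  bad_smp <- rownames(m)[smp_cr < first]
  report <- record_aptamer_removal(report, bad_apt, "call_rate_1",
                                   sprintf("call rate < %g", first))
  report <- record_sample_removal(report, bad_smp, "call_rate_1",
                                  sprintf("call rate < %g", first))
  data <- drop_aptamers(drop_samples(data, bad_smp), bad_apt)
  check_nonempty(data)

  stage2 <- function(data, report, what) {
    m <- data$measurements
    if (what == "aptamers") {
      bad <- colnames(m)[colMeans(!is.na(m)) < second]
      report <- record_aptamer_removal(report, bad, "call_rate_2",
                                       sprintf("call rate < %g after recalculation", second))
      data <- drop_aptamers(data, bad)
    } else {
      bad <- rownames(m)[rowMeans(!is.na(m)) < second]
      report <- record_sample_removal(report, bad, "call_rate_2",
                                      sprintf("call rate < %g after recalculation", second))
      data <- drop_samples(data, bad)
    }
    list(data = data, report = report)
  }
  order2 <- if (stage2_order == "aptamers_first") c("aptamers", "samples") else
    c("samples", "aptamers")
  for (what in order2) {
    st <- stage2(data, report, what)
    data <- st$data; report <- st$report
    check_nonempty(data)
  }
  report$call_rate_after <- list(aptamer = colMeans(!is.na(data$measurements)),
                                 sample = rowMeans(!is.na(data$measurements)))
  list(data = data, report = report)
}

check_nonempty <- function(data) {
  if (nrow(data$measurements) == 0 || ncol(data$measurements) == 0) {
    pp_stop("all samples or all aptamers filtered out", "all_filtered")
  }
  invisible(data)
}

#' Log10 z-score normalization
#'
#' Per aptamer: \code{x -> (log10(x) - mean) / sd} over non-missing values,
#' with the sample (n-1) standard deviation. Constant aptamers (sd 0) are
#' dropped with a warning; nonpositive values are an error naming the cell.
#'
#' @param data a \code{\link{raw_aptamer_data}} or a bare positive matrix.
#' @return samples x aptamers matrix of normalized levels (class
#'   \code{protein_matrix} attributes preserved via \code{aptamer_map} attr
#'   when present on input).
#' @export
normalize_proteins <- function(data) {
  m <- if (inherits(data, "raw_aptamer_data")) data$measurements else data
  if (any(m <= 0, na.rm = TRUE)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    pp_stop(sprintf("nonpositive value at sample '%s', aptamer '%s'",
                    rownames(m)[bad[1]], colnames(m)[bad[2]]),
            "nonpositive_value")
  }
  lg <- log10(m)
  mu <- colMeans(lg, na.rm = TRUE)
  sdv <- apply(lg, 2, stats::sd, na.rm = TRUE)
  const <- !is.na(sdv) & sdv == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant aptamer(s): %s", sum(const),
                    paste(colnames(m)[const], collapse = ", ")))
  }
  keep <- which(!const & !is.na(sdv))
  out <- sweep(sweep(lg[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  out
}

#' Full QC cascade
#'
#' Chains scale-factor, CV, IQR and call-rate filters, then normalizes.
#'
#' @param data a \code{\link{raw_aptamer_data}}.
#' @param max_divergence,max_cv,iqr_k,call_rate_first,call_rate_second
#'   stage thresholds (see the individual filters).
#' @return list with \code{proteins} (normalized matrix) and \code{report}.
#' @export
qc_pipeline <- function(data, max_divergence = 0.5, max_cv = 0.15,
                        iqr_k = 1.5, call_rate_first = 0.65,
                        call_rate_second = 0.85) {
  report <- new_qc_report()
  report$aptamers_in <- ncol(data$measurements)
  report$samples_in <- nrow(data$measurements)
  st <- filter_scale_factor(data, max_divergence, report = report)
  st <- filter_cv(st$data, max_cv, report = st$report)
  st <- iqr_screen(st$data, iqr_k, report = st$report)
  st <- call_rate_cascade(st$data, call_rate_first, call_rate_second,
                          report = st$report)
  report <- st$report
  report$aptamers_out <- ncol(st$data$measurements)
  report$samples_out <- nrow(st$data$measurements)
  list(proteins = normalize_proteins(st$data), report = report,
       filtered = st$data)
}
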