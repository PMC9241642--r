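#' Normalize abundances by insect wet weight
#'
#' Divides every sample's peak areas by that insect's wet weight so that
#' samples from insects of different sizes are comparable. First step of the
#' preprocessing chain (stage raw -> weight_normalized).
#'
#' @param table a raw-stage [metab_table()].
#' @param weights optional positive numeric vector overriding
#'   `sample_meta$weight_g` (one value per sample).
#' @return the weight-normalized table.
#' @export
weight_normalize <- function(table, weights = NULL) {
  stopifnot(is_metab_table(table))
  if (table$stage != "raw")
    stopf("weight_normalize expects a raw-stage table, got '%s'", table$stage)
  w <- if (is.null(weights)) table$sample_meta$weight_g else weights
  if (length(w) != ncol(table$values))
    stopf("need one weight per sample")
  if (any(!is.finite(w)) || any(w <= 0)) stopf("weights must be positive")
  out <- table
  out$values <- sweep(table$values, 2, w, `/`)
  out$sample_meta$weight_g <- w
  out$stage <- "weight_normalized"
  out
}

# Replace non-detects (NA) and zeros by half the feature's minimum positive
# value -- the conventional missing-value imputation before a log transform.
# Features with no positive value at all stay all-NA.
replace_nondetect <- function(values) {
  t(apply(values, 1, function(v) {
    bad <- is.na(v) | v == 0
    if (any(bad)) {
      pos <- v[!is.na(v) & v > 0]
      v[bad] <- if (length(pos)) min(pos) / 2 else NA_real_
    }
    v
  }))
}

#' Log-transform abundances
#'
#' Replaces non-detects and zeros by half the feature's minimum positive
#' value, then takes logarithms (base 10 by default, the usual metabolomics
#' convention). Stage weight_normalized -> log.
#'
#' @param table a weight-normalized [metab_table()].
#' @param base logarithm base.
#' @return the log-stage table.
#' @export
log_transform <- function(table, base = 10) {
  stopifnot(is_metab_table(table))
  if (table$stage != "weight_normalized")
    stopf("log_transform expects a weight_normalized table, got '%s'",
          table$stage)
  if (any(table$values < 0, na.rm = TRUE))
    stopf("negative abundances cannot be log-transformed")
  out <- table
  v <- replace_nondetect(table$values)
  dimnames(v) <- dimnames(table$values)
  out$values <- log(v, base = base)
  out$stage <- "log"
  out
}

#' Pareto-scale features
#'
#' Centers each feature and divides by the square root of its standard
#' deviation -- a compromise between no scaling and unit-variance
#' autoscaling that tempers the dominance of high-abundance metabolites
#' while preserving some of the original variance structure. Constant
#' features map to all zeros (kept by default so feature indexing is
#' stable). Stage log -> pareto.
#'
#' @param table a log-stage [metab_table()].
#' @param drop_constant drop constant features instead of keeping them as
#'   zero rows.
#' @return the pareto-stage table.
#' @export
pareto_scale <- function(table, drop_constant = FALSE) {
  stopifnot(is_metab_table(table))
  if (table$stage != "log")
    stopf("pareto_scale expects a log-stage table, got '%s'", table$stage)
  out <- table
  v <- t(apply(table$values, 1, function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x, na.rm = TRUE)) / sqrt(s)
  }))
  dimnames(v) <- dimnames(table$values)
  if (drop_constant) {
    keep <- apply(table$values, 1, function(x) {
      s <- stats::sd(x, na.rm = TRUE)
      is.finite(s) && s > 0
    })
    v <- v[keep, , drop = FALSE]
  }
  out$values <- v
  out$stage <- "pareto"
  out
}

#' Per-time-point medians of replicate abundances
#'
#' Collapses replicates to the median within each time point; this is the
#' summary fed to trajectory clustering, where medians damp single-replicate
#' outliers.
#'
#' @param table a [metab_table()] at any stage.
#' @return numeric matrix (features x time points) with attribute
#'   `summary_kind = "timepoint_median"`; column order follows the order of
#'   appearance in the sample metadata.
#' @export
summarize_timepoints <- function(table) {
  stopifnot(is_metab_table(table))
  tps <- unique(as.character(table$sample_meta$time_point))
  out <- vapply(tps, function(tp) {
    cols <- table$sample_meta$time_point == tp
    if (!any(cols)) stopf("time point '%s' has no samples", tp)
    apply(table$values[, cols, drop = FALSE], 1, stats::median, na.rm = TRUE)
  }, numeric(nrow(table$values)))
  out <- matrix(out, nrow = nrow(table$values),
                dimnames = list(rownames(table$values), tps))
  attr(out, "summary_kind") <- "timepoint_median"
  out
}

#' Per-phase means of abundances
#'
#' Arithmetic mean over all samples of each infection phase (uninfected,
#' early, middle, late); this is the summary fed to the phase-wise
#' rate-of-change profile, so it is normally computed on raw-scale
#' (weight-normalized) abundances where ratios of means are meaningful.
#'
#' @param table a [metab_table()].
#' @return numeric matrix (features x phases) with attribute
#'   `summary_kind = "phase_mean"`; columns ordered
#'   uninfected, early, middle, late (phases present in the data).
#' @export
summarize_phases <- function(table) {
  stopifnot(is_metab_table(table))
  order_all <- c("uninfected", "early", "middle", "late")
  phases <- order_all[order_all %in% unique(as.character(table$sample_meta$phase))]
  if (!length(phases)) stopf("no recognized phases in sample metadata")
  out <- vapply(phases, function(ph) {
    cols <- table$sample_meta$phase == ph
    if (!any(cols)) stopf("phase '%s' has no samples", ph)
    rowMeans(table$values[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(table$values)))
  out <- matrix(out, nrow = nrow(table$values),
                dimnames = list(rownames(table$values), phases))
  attr(out, "summary_kind") <- "phase_mean"
  out
}
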