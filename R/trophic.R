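#' Parameters of the glutamic acid / phenylalanine trophic-position model
#'
#' Trophic position is estimated from the difference in nitrogen isotopic
#' enrichment between a "trophic" amino acid (glutamic acid, which gains
#' \eqn{^{15}}N with each feeding step) and a "source" amino acid
#' (phenylalanine, whose \eqn{^{15}}N is essentially unchanged up the chain):
#'
#' \deqn{TP = \frac{\delta^{15}N_{glu} - \delta^{15}N_{phe} - \beta}{\Delta_{glu\mbox{-}phe}} + \lambda}
#'
#' @param beta producer-level offset between glutamic acid and phenylalanine
#'   \eqn{\delta^{15}}N, in per mil. Approximately 8.4 for webs rooted in C3
#'   plants (and used here also for yeast-based laboratory diets).
#' @param delta_glu_phe trophic discrimination factor \eqn{\Delta_{glu-phe}}:
#'   the net per-trophic-level increase of the glu-phe \eqn{\delta^{15}}N gap,
#'   in per mil. Defaults to the canonical 7.6.
#' @param lambda_basal trophic level assigned to the basal resource
#'   (1 for primary producers).
#' @return an object of class `trophic_params`.
#' @examples
#' trophic_params()
#' @export
trophic_params <- function(beta = 8.4, delta_glu_phe = 7.6, lambda_basal = 1) {
  if (!is.numeric(delta_glu_phe) || length(delta_glu_phe) != 1 ||
      !is.finite(delta_glu_phe) || delta_glu_phe <= 0)
    stopf("`delta_glu_phe` must be a single positive number")
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta))
    stopf("`beta` must be a single finite number")
  if (!is.numeric(lambda_basal) || length(lambda_basal) != 1 ||
      !is.finite(lambda_basal))
    stopf("`lambda_basal` must be a single finite number")
  structure(
    list(beta = beta, delta_glu_phe = delta_glu_phe,
         lambda_basal = lambda_basal),
    class = "trophic_params")
}

#' @export
print.trophic_params <- function(x, ...) {
  cat(sprintf(
    "Trophic-position model parameters:\n  beta          = %.2f permil\n  delta_glu_phe = %.2f permil\n  lambda_basal  = %.1f\n",
    x$beta, x$delta_glu_phe, x$lambda_basal))
  invisible(x)
}

#' Trophic position from a glutamic acid / phenylalanine isotope pair
#'
#' @param d15N_glu \eqn{\delta^{15}}N of glutamic acid, per mil (vectorized).
#' @param d15N_phe \eqn{\delta^{15}}N of phenylalanine, per mil.
#' @param params a [trophic_params()] object.
#' @return numeric vector of trophic positions.
#' @examples
#' compute_tp(16.9, 8.5) # one discrimination step above a beta-offset baseline
#' @export
compute_tp <- function(d15N_glu, d15N_phe, params = trophic_params()) {
  stopifnot(inherits(params, "trophic_params"))
  if (any(!is.finite(d15N_glu)) || any(!is.finite(d15N_phe)))
    stopf("delta-15N values must be finite")
  (d15N_glu - d15N_phe - params$beta) / params$delta_glu_phe +
    params$lambda_basal
}

#' Per-node trophic-position summaries
#'
#' Computes each record's trophic position and summarizes per node as mean,
#' standard error (sample SD / sqrt(n); 0 when n = 1) and replicate count.
#'
#' @param isotopes data frame with columns `node`, `d15N_glu`, `d15N_phe`
#'   (the isotope-table layout written by [simulate_foodweb()]).
#' @param params a [trophic_params()] object.
#' @return data frame with columns `node`, `mean_tp`, `se_tp`, `n`.
#' @export
summarize_tp <- function(isotopes, params = trophic_params()) {
  check_isotope_table(isotopes)
  if (nrow(isotopes) == 0) stopf("isotope table has no records")
  tp <- compute_tp(isotopes$d15N_glu, isotopes$d15N_phe, params)
  nodes <- unique(as.character(isotopes$node))
  out <- do.call(rbind, lapply(nodes, function(nd) {
    v <- tp[isotopes$node == nd]
    data.frame(node = nd,
               mean_tp = mean(v),
               se_tp = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Trophic discrimination factor between a consumer and its diet
#'
#' TDF is the difference of mean glu-phe \eqn{\delta^{15}}N gaps:
#' mean(consumer \eqn{\delta_{glu}-\delta_{phe}}) minus the same for the diet.
#' On a noise-free web one full feeding step gives TDF equal to
#' \eqn{\Delta_{glu-phe}}.
#'
#' @param consumer,diet data frames of isotope records (columns `d15N_glu`,
#'   `d15N_phe`), e.g. subsets of a [simulate_foodweb()] table.
#' @return a one-row data frame with column `tdf_glu_phe` (per mil).
#' @export
compute_tdf <- function(consumer, diet) {
  for (df in list(consumer, diet))
    if (!is.data.frame(df) || nrow(df) == 0 ||
        !all(c("d15N_glu", "d15N_phe") %in% names(df)))
      stopf("consumer and diet must be nonempty isotope record data frames")
  gap <- function(df) mean(df$d15N_glu - df$d15N_phe)
  data.frame(tdf_glu_phe = gap(consumer) - gap(diet))
}

#' Expected trophic position of a consumer
#'
#' Under strict one-step feeding a consumer sits one full trophic level above
#' its diet; a measured TP well above this flags additional feeding loops
#' (e.g. intraguild predation or cannibalism).
#'
#' @param diet_tp trophic position of the diet.
#' @return `diet_tp + 1`.
#' @examples
#' expected_tp(2.5) # 3.5
#' @export
expected_tp <- function(diet_tp) {
  if (any(diet_tp < 0)) stopf("`diet_tp` must be nonnegative")
  diet_tp + 1
}

#' Trophic position implied by a measured discrimination factor
#'
#' Converts a measured TDF into trophic-level units by dividing by the
#' per-level discrimination, then offsets from the diet's position:
#' `diet_tp + tdf / delta_glu_phe`.
#'
#' @param diet_tp trophic position of the diet.
#' @param tdf measured trophic discrimination factor, per mil.
#' @param delta_glu_phe per-level discrimination, per mil (> 0).
#' @param digits if non-NULL, round the result half-up to this many decimals
#'   (report convention).
#' @return trophic position estimate.
#' @examples
#' tp_from_tdf(1.0, 6.53, digits = 1) # 1.9
#' @export
tp_from_tdf <- function(diet_tp, tdf, delta_glu_phe = 7.6, digits = NULL) {
  if (!is.numeric(delta_glu_phe) || delta_glu_phe <= 0)
    stopf("`delta_glu_phe` must be positive")
  out <- diet_tp + tdf / delta_glu_phe
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

check_isotope_table <- function(isotopes) {
  need <- c("node", "d15N_glu", "d15N_phe")
  if (!is.data.frame(isotopes) || !all(need %in% names(isotopes)))
    stopf("isotope table must be a data frame with columns %s",
          paste(need, collapse = ", "))
  invisible(isotopes)
}

#' Read / write isotope tables
#'
#' CSV layout: one row per sample with columns `sample_id`, `node`, `role`
#' (consumer, diet or complex), `d15N_glu`, `d15N_phe`.
#'
#' @param path file path.
#' @return `read_isotope_csv()` returns the isotope data frame.
#' @export
read_isotope_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_isotope_table(x)
  x
}

#' @rdname read_isotope_csv
#' @param isotopes isotope data frame.
#' @export
write_isotope_csv <- function(isotopes, path) {
  check_isotope_table(isotopes)
  utils::write.csv(isotopes, path, row.names = FALSE)
  invisible(path)
}
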