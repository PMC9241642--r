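#' Round half away from zero
#'
#' Report-style rounding in which halves round up in magnitude (1.85 -> 1.9),
#' matching the convention of printed summary tables, unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(1.85, 1) # 1.9
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Convert a log2 fold change to a linear ratio
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @return linear fold change, `2^log2fc`.
#' @examples
#' log2fc_to_ratio(1)    # 2
#' log2fc_to_ratio(7.37) # ~165
#' @export
log2fc_to_ratio <- function(log2fc) 2^log2fc

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
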