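#' Student's t test of a metabolite between uninfected samples and a phase
#'
#' Two-sided pooled-variance (classical Student) t test comparing a single
#' metabolite's abundance in the uninfected reference samples against one
#' infection phase. Welch's unequal-variance variant is available by flag.
#' No multiple-testing correction is applied by default (per-metabolite
#' screening at raw p < alpha); pass the p values to [stats::p.adjust()] for
#' Benjamini-Hochberg control if desired.
#'
#' @param table a [metab_table()] (typically log stage).
#' @param feature feature id.
#' @param phase phase to compare against the reference.
#' @param reference reference phase (default `"uninfected"`).
#' @param alpha significance level.
#' @param var_equal pooled variance (TRUE, Student) or Welch (FALSE).
#' @return one-row data frame: `feature_id`, `comparison`, `statistic`,
#'   `df`, `p_value`, `significant`.
#' @export
phase_ttest <- function(table, feature, phase, reference = "uninfected",
                        alpha = 0.05, var_equal = TRUE) {
  stopifnot(is_metab_table(table))
  if (!feature %in% rownames(table$values))
    stopf("unknown feature '%s'", feature)
  v <- table$values[feature, ]
  g_ref <- v[table$sample_meta$phase == reference]
  g_phase <- v[table$sample_meta$phase == phase]
  g_ref <- g_ref[!is.na(g_ref)]; g_phase <- g_phase[!is.na(g_phase)]
  if (length(g_ref) < 2 || length(g_phase) < 2)
    stopf("both groups need >= 2 samples (reference %d, phase %d)",
          length(g_ref), length(g_phase))
  ht <- stats::t.test(g_ref, g_phase, var.equal = var_equal)
  data.frame(feature_id = feature,
             comparison = sprintf("%s_vs_%s", reference, phase),
             statistic = unname(ht$statistic),
             df = unname(ht$parameter),
             p_value = ht$p.value,
             significant = ht$p.value < alpha)
}

#' ANOVA across time points with Tukey HSD post hoc comparisons
#'
#' One-way analysis of variance of a single metabolite's abundance across
#' time points, followed by Tukey honestly-significant-difference pairwise
#' comparisons. Comparisons against the uninfected reference time point and
#' between consecutive time points are flagged for convenience. The
#' screening described for this design compares individual time-point means
#' to the uninfected model and to each other; no second crossed factor is
#' present once a single metabolite is analyzed, so the model is one-way
#' across time points.
#'
#' @param table a [metab_table()].
#' @param feature feature id.
#' @param reference reference time point (default the first one).
#' @param alpha significance level.
#' @return list with `anova` (one-row data frame: F, df, p) and `tukey`
#'   (data frame of pairwise comparisons: `comparison`, `diff`, `p_adj`,
#'   `significant`, `vs_reference`, `consecutive`). Time points with fewer
#'   than 2 replicates are dropped with a warning.
#' @export
anova_tukey <- function(table, feature, reference = NULL, alpha = 0.05) {
  stopifnot(is_metab_table(table))
  if (!feature %in% rownames(table$values))
    stopf("unknown feature '%s'", feature)
  tp_levels <- unique(as.character(table$sample_meta$time_point))
  if (is.null(reference)) reference <- tp_levels[1]
  df <- data.frame(value = table$values[feature, ],
                   time_point = as.character(table$sample_meta$time_point))
  df <- df[!is.na(df$value), ]
  counts <- table(df$time_point)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warnf("dropping time point(s) with < 2 replicates: %s",
          paste(small, collapse = ", "))
    df <- df[!df$time_point %in% small, ]
  }
  if (length(unique(df$time_point)) < 2)
    stopf("need >= 2 time points with >= 2 replicates each")
  df$time_point <- factor(df$time_point,
                          levels = tp_levels[tp_levels %in% df$time_point])
  fit <- stats::aov(value ~ time_point, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$time_point
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  lv <- levels(df$time_point)
  consec <- vapply(pair, function(p)
    abs(match(p[1], lv) - match(p[2], lv)) == 1, logical(1))
  tukey <- data.frame(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    vs_reference = vapply(pair, function(p) reference %in% p, logical(1)),
    consecutive = consec)
  rownames(tukey) <- NULL
  list(anova = data.frame(feature_id = feature,
                          f_statistic = an[["F value"]][1],
                          df_between = an[["Df"]][1],
                          df_within = an[["Df"]][2],
                          p_value = an[["Pr(>F)"]][1]),
       tukey = tukey)
}

#' Fold-change filter for two-strain expression tables
#'
#' Flags genes whose mean-signal ratio between two strains exceeds the
#' cutoff in either direction: ratio strictly greater than `fc_threshold`
#' or strictly less than `1/fc_threshold` (a ratio exactly at the cutoff is
#' not flagged). Genes with a nonpositive signal in either strain are
#' skipped with a warning.
#'
#' @param expression data frame with a gene id column followed by two
#'   positive signal columns (reference strain, test strain).
#' @param fc_threshold strict fold-change cutoff (> 1), default 2.
#' @param total_orfs denominator for the reported percentage (defaults to
#'   the number of genes in the table).
#' @return list with `table` (gene_id, ratio, differential), `genes`
#'   (character vector of flagged ids), `n_differential`, and `percent`
#'   (of `total_orfs`, rounded to one decimal).
#' @examples
#' ex <- data.frame(gene_id = letters[1:5], a = 1, b = c(3, 0.4, 1.5, 2, 0.5))
#' fold_change_filter(ex)$genes # "a" and "b"
#' @export
fold_change_filter <- function(expression, fc_threshold = 2,
                               total_orfs = NULL) {
  if (fc_threshold <= 1) stopf("`fc_threshold` must be > 1")
  if (!is.data.frame(expression) || ncol(expression) < 3)
    stopf("`expression` needs a gene id column and two signal columns")
  gene_id <- as.character(expression[[1]])
  ref <- expression[[2]]; test <- expression[[3]]
  if (is.null(total_orfs)) total_orfs <- length(gene_id)
  ok <- is.finite(ref) & is.finite(test) & ref > 0 & test > 0
  if (any(!ok))
    warnf("skipping %d gene(s) with nonpositive signal", sum(!ok))
  ratio <- ifelse(ok, test / ref, NA_real_)
  differential <- ok & (ratio > fc_threshold | ratio < 1 / fc_threshold)
  list(table = data.frame(gene_id = gene_id, ratio = ratio,
                          differential = differential),
       genes = gene_id[differential],
       n_differential = sum(differential),
       percent = round_half_up(100 * sum(differential) / total_orfs, 1))
}

#' Pairwise and Venn-region overlaps of differential gene sets
#'
#' @param sets named list of character vectors (2 to 5 sets).
#' @return list with `pairwise` (symmetric matrix of intersection sizes;
#'   diagonal holds set sizes) and `regions` (data frame of exclusive
#'   Venn-region counts, one row per nonempty combination of sets; counts
#'   sum to the size of the union).
#' @export
regulon_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2)
    stopf("need a named list of >= 2 sets")
  if (length(sets) > 5) stopf("Venn regions supported for up to 5 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  k <- length(sets)
  pairwise <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k))
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = k)
  key <- apply(member, 1, function(m) paste(nm[m], collapse = "&"))
  counts <- table(key)
  regions <- data.frame(region = names(counts),
                        count = as.integer(counts))
  regions <- regions[order(-regions$count), ]
  rownames(regions) <- NULL
  list(pairwise = pairwise, regions = regions)
}
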