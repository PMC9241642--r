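#' Metabolite abundance table
#'
#' A features-by-samples matrix of chromatographic peak areas together with
#' per-sample metadata (time point, infection phase, replicate, insect wet
#' weight) and a processing-stage tag. Stages advance strictly in the order
#' raw -> weight_normalized -> log -> pareto, mirroring the
#' sample-normalization / transformation / scaling convention of metabolomics
#' preprocessing.
#'
#' Non-detected values are carried as `NA` (an explicit sentinel rather than
#' zero) so that the replacement policy is applied in one place, at the log
#' step.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param sample_meta data frame with columns `sample_id`, `time_point`,
#'   `phase`, `replicate`, `weight_g`, one row per column of `values`.
#' @param stage one of `"raw"`, `"weight_normalized"`, `"log"`, `"pareto"`.
#' @return an object of class `metab_table`.
#' @export
metab_table <- function(values, sample_meta, stage = "raw") {
  stages <- c("raw", "weight_normalized", "log", "pareto")
  stage <- match.arg(stage, stages)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  need <- c("sample_id", "time_point", "phase", "replicate", "weight_g")
  if (!is.data.frame(sample_meta) || !all(need %in% names(sample_meta)))
    stopf("`sample_meta` needs columns %s", paste(need, collapse = ", "))
  if (nrow(sample_meta) != ncol(values))
    stopf("sample_meta rows (%d) must match value columns (%d)",
          nrow(sample_meta), ncol(values))
  if (any(!is.finite(sample_meta$weight_g)) || any(sample_meta$weight_g <= 0))
    stopf("all sample weights must be positive")
  if (stage %in% c("raw", "weight_normalized") &&
      any(values < 0, na.rm = TRUE))
    stopf("abundances must be nonnegative before the log stage")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("met_%03d", seq_len(nrow(values)))
  colnames(values) <- sample_meta$sample_id
  structure(list(values = values, sample_meta = sample_meta, stage = stage),
            class = "metab_table")
}

#' @export
print.metab_table <- function(x, ...) {
  cat(sprintf(
    "Metabolite table: %d features x %d samples [stage: %s]\n",
    nrow(x$values), ncol(x$values), x$stage))
  cat(sprintf("  time points: %s\n",
              paste(unique(x$sample_meta$time_point), collapse = " ")))
  cat(sprintf("  phases: %s\n",
              paste(unique(x$sample_meta$phase), collapse = " ")))
  nd <- sum(is.na(x$values))
  if (nd > 0) cat(sprintf("  non-detects: %d (%.1f%%)\n", nd,
                          100 * nd / length(x$values)))
  invisible(x)
}

#' @rdname metab_table
#' @param x an object.
#' @export
is_metab_table <- function(x) inherits(x, "metab_table")

#' Read / write metabolite tables as CSV
#'
#' The dialect puts `feature_id` in the first column; the first four data
#' rows carry the sample metadata (`time_point`, `phase`, `replicate`,
#' `weight_g`) under the sample-id header, followed by one row per feature.
#' Non-detects are written as empty cells and read back as `NA`.
#'
#' @param table a [metab_table()].
#' @param path file path.
#' @return `read_metabolite_csv()` returns a [metab_table()].
#' @export
write_metabolite_csv <- function(table, path) {
  stopifnot(is_metab_table(table))
  m <- table$sample_meta
  head_rows <- rbind(
    c("time_point", as.character(m$time_point)),
    c("phase", as.character(m$phase)),
    c("replicate", as.character(m$replicate)),
    c("weight_g", format(m$weight_g, digits = 15, trim = TRUE)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", m$sample_id), collapse = ","), con)
  apply(head_rows, 1, function(r) writeLines(paste(r, collapse = ","), con))
  vals <- table$values
  for (i in seq_len(nrow(vals))) {
    v <- format(vals[i, ], digits = 15, trim = TRUE)
    v[is.na(vals[i, ])] <- ""
    writeLines(paste(c(rownames(vals)[i], v), collapse = ","), con)
  }
  writeLines(paste0("# stage,", table$stage), con)
  invisible(path)
}

#' @rdname write_metabolite_csv
#' @export
read_metabolite_csv <- function(path) {
  lines <- readLines(path)
  stage <- "raw"
  is_stage <- startsWith(lines, "# stage,")
  if (any(is_stage)) {
    stage <- sub("^# stage,", "", lines[which(is_stage)[1]])
    lines <- lines[!is_stage]
  }
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- cells[[1]]
  if (header[1] != "feature_id") stopf("not a metabolite CSV: %s", path)
  sample_id <- header[-1]
  grab <- function(i, name) {
    r <- cells[[i]]
    if (r[1] != name) stopf("expected metadata row '%s', found '%s'", name, r[1])
    r[-1]
  }
  meta <- data.frame(
    sample_id = sample_id,
    time_point = grab(2, "time_point"),
    phase = grab(3, "phase"),
    replicate = as.integer(grab(4, "replicate")),
    weight_g = as.numeric(grab(5, "weight_g")))
  feat <- cells[-(1:5)]
  values <- t(vapply(feat, function(r) {
    v <- r[-1]
    v[v == ""] <- NA
    as.numeric(v)
  }, numeric(length(sample_id))))
  rownames(values) <- vapply(feat, `[[`, "", 1)
  metab_table(values, meta, stage = stage)
}
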