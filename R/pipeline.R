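#' Trophic-position report for a food web
#'
#' Summarizes an isotope table into a report table with one row per
#' consumer-diet edge: the measured trophic discrimination factor, the
#' expected consumer position (diet TP + 1), the measured consumer position
#' with its standard error and replicate count. Nodes named in `edges` but
#' absent from the isotope table produce a row of `NA`s rather than an
#' error.
#'
#' @param isotopes isotope data frame (see [read_isotope_csv()]).
#' @param edges data frame with columns `consumer` and `diet` naming nodes
#'   of the web. If NULL, edges are inferred for nodes that share the table
#'   with exactly one other node -- normally you pass them explicitly.
#' @param params a [trophic_params()] object.
#' @param digits rounding (half-up) for the report columns; NULL for full
#'   precision.
#' @param out_dir if non-NULL, the report and per-node summary are written
#'   there as CSV.
#' @return data frame with columns `consumer`, `diet`, `tdf_glu_phe`,
#'   `tp_expected`, `tp_glu_phe`, `se`, `n`.
#' @examples
#' web <- simulate_foodweb(foodweb_config(seed = 1))
#' edges <- data.frame(consumer = "ij_nematodes",
#'                     diet = "insect_bacteria_complex")
#' run_trophic_pipeline(web$isotopes, edges)
#' @export
run_trophic_pipeline <- function(isotopes, edges, params = trophic_params(),
                                 digits = 1, out_dir = NULL) {
  check_isotope_table(isotopes)
  if (!is.data.frame(edges) || !all(c("consumer", "diet") %in% names(edges)))
    stopf("`edges` needs columns consumer, diet")
  per_node <- summarize_tp(isotopes, params)
  rnd <- function(x) if (is.null(digits)) x else round_half_up(x, digits)
  rows <- lapply(seq_len(nrow(edges)), function(i) {
    cons <- edges$consumer[i]; diet <- edges$diet[i]
    c_rec <- isotopes[isotopes$node == cons, , drop = FALSE]
    d_rec <- isotopes[isotopes$node == diet, , drop = FALSE]
    if (nrow(c_rec) == 0 || nrow(d_rec) == 0) {
      warnf("edge %s -> %s: missing records; row flagged NA", cons, diet)
      return(data.frame(consumer = cons, diet = diet, tdf_glu_phe = NA_real_,
                        tp_expected = NA_real_, tp_glu_phe = NA_real_,
                        se = NA_real_, n = NA_integer_))
    }
    tdf <- compute_tdf(c_rec, d_rec)$tdf_glu_phe
    diet_tp <- per_node$mean_tp[per_node$node == diet]
    cons_row <- per_node[per_node$node == cons, ]
    data.frame(consumer = cons, diet = diet,
               tdf_glu_phe = rnd(tdf),
               tp_expected = rnd(expected_tp(diet_tp)),
               tp_glu_phe = rnd(cons_row$mean_tp),
               se = rnd(cons_row$se_tp),
               n = cons_row$n)
  })
  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "trophic_report.csv"),
                     row.names = FALSE)
    utils::write.csv(per_node, file.path(out_dir, "trophic_per_node.csv"),
                     row.names = FALSE)
  }
  report
}

#' End-to-end metabolome analysis pipeline
#'
#' Runs the full time-course workflow on a raw metabolite table:
#' weight normalization; per-time-point medians -> Spearman distance ->
#' hierarchical clustering; per-phase means -> log rate of change ->
#' cluster report; log transform -> pareto scaling -> PLS-DA and VIP
#' scoring; per-metabolite phase t tests. Returns every intermediate plus a
#' run manifest; optionally writes all outputs as CSV (plus the manifest as
#' JSON) into `out_dir`. Given the same inputs and options the outputs are
#' byte-identical across runs.
#'
#' @param table a raw-stage [metab_table()].
#' @param k number of trajectory clusters.
#' @param linkage linkage method for [hierarchical_cluster()].
#' @param log_base base for [rate_of_change()].
#' @param n_components PLS-DA components.
#' @param labels class labels for PLS-DA (`"phase"` or `"time_point"`).
#' @param alpha significance level for the phase t tests.
#' @param vip_threshold strict VIP cutoff.
#' @param truth optional data frame (`feature_id`, `cluster`) of true
#'   cluster memberships; when given, the adjusted Rand index of the
#'   recovered partition is recorded in the manifest.
#' @param out_dir optional output directory.
#' @return list of class `metabolome_run` with elements `processed`
#'   (pareto-stage table), `timepoint_medians`, `phase_means`, `distance`,
#'   `clusters`, `changes`, `report`, `pls`, `vip_table`, `ttests`,
#'   `manifest`.
#' @export
run_metabolome_pipeline <- function(table, k = 10, linkage = "average",
                                    log_base = 2, n_components = 3,
                                    labels = "phase", alpha = 0.05,
                                    vip_threshold = 1, truth = NULL,
                                    out_dir = NULL) {
  stopifnot(is_metab_table(table))
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr,
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  norm <- stage("weight_normalize", weight_normalize(table))
  med <- stage("timepoint_medians", summarize_timepoints(norm))
  d <- stage("spearman_distance", spearman_distance_matrix(med))
  clusters <- stage("hierarchical_cluster",
                    hierarchical_cluster(d, k = k, linkage = linkage))
  phase_means <- stage("phase_means", summarize_phases(norm))
  changes <- stage("rate_of_change",
                   rate_of_change(phase_means, log_base = log_base))
  report <- stage("cluster_report", cluster_report(clusters, changes))
  logged <- stage("log_transform", log_transform(norm))
  scaled <- stage("pareto_scale", pareto_scale(logged))
  pls <- stage("plsda", fit_plsda(scaled, labels = labels,
                                  n_components = n_components))
  vip_table <- data.frame(feature_id = pls$feature_ids, pls$vip,
                          importance = vip_importance(pls),
                          row.names = NULL)
  phases <- setdiff(unique(as.character(table$sample_meta$phase)),
                    "uninfected")
  ttests <- stage("phase_ttests", do.call(rbind, lapply(
    rownames(logged$values), function(f) {
      do.call(rbind, lapply(phases, function(ph)
        phase_ttest(logged, f, ph, alpha = alpha)))
    })))

  manifest <- list(
    package_version = as.character(utils::packageVersion("trophomics")),
    parameters = list(k = k, linkage = linkage, log_base = log_base,
                      n_components = n_components, labels = labels,
                      alpha = alpha, vip_threshold = vip_threshold),
    input = list(n_features = nrow(table$values),
                 n_samples = ncol(table$values),
                 value_checksum = sum(table$values, na.rm = TRUE)),
    vip_sq_sum = sum(pls$vip[, pls$n_components]^2),
    feature_count = length(pls$feature_ids),
    n_vip_significant = length(vip_significant(vip_scores(pls), vip_threshold)),
    explained_x_pct = pls$explained_x_pct,
    pct_late_increase = report$pct_late_increase,
    warnings = warnings_log)
  if (!is.null(truth)) {
    ord <- match(names(clusters$assignment), truth$feature_id)
    manifest$ari <- mclust::adjustedRandIndex(clusters$assignment,
                                              truth$cluster[ord])
  }

  out <- structure(list(processed = scaled, timepoint_medians = med,
                        phase_means = phase_means, distance = d,
                        clusters = clusters, changes = changes,
                        report = report, pls = pls, vip_table = vip_table,
                        ttests = ttests, manifest = manifest),
                   class = "metabolome_run")
  if (!is.null(out_dir)) write_metabolome_run(out, out_dir)
  out
}

#' @export
print.metabolome_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Metabolome pipeline run: %d features x %d samples\n",
              m$input$n_features, m$input$n_samples))
  cat(sprintf("  clusters: k = %d; %d%% of features rise middle->late\n",
              x$clusters$k, m$pct_late_increase))
  cat(sprintf("  PLS-DA: explained X %% = %s; %d features with VIP > 1\n",
              paste(sprintf("%.1f", m$explained_x_pct), collapse = " "),
              m$n_vip_significant))
  if (!is.null(m$ari)) cat(sprintf("  ARI vs truth: %.3f\n", m$ari))
  invisible(x)
}

write_metabolome_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  wcsv <- function(x, f) utils::write.csv(x, p(f), row.names = TRUE)
  utils::write.csv(data.frame(feature_id = rownames(run$timepoint_medians),
                              run$timepoint_medians, row.names = NULL),
                   p("timepoint_medians.csv"), row.names = FALSE)
  utils::write.csv(data.frame(feature_id = rownames(run$phase_means),
                              run$phase_means, row.names = NULL),
                   p("phase_means.csv"), row.names = FALSE)
  wcsv(run$distance, "spearman_distance.csv")
  utils::write.csv(data.frame(feature_id = names(run$clusters$assignment),
                              cluster = unname(run$clusters$assignment)),
                   p("cluster_assignment.csv"), row.names = FALSE)
  utils::write.csv(data.frame(feature_id = rownames(run$changes),
                              run$changes, row.names = NULL),
                   p("phase_change.csv"), row.names = FALSE)
  utils::write.csv(run$report$by_cluster, p("cluster_report.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample_id = run$processed$sample_meta$sample_id,
                              label = run$pls$labels, run$pls$scores,
                              row.names = NULL),
                   p("pls_scores.csv"), row.names = FALSE)
  utils::write.csv(run$vip_table, p("vip.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(run$pls$explained_x_pct),
                              explained_x_pct = run$pls$explained_x_pct,
                              explained_y_ss = run$pls$explained_y_ss),
                   p("explained_variance.csv"), row.names = FALSE)
  utils::write.csv(run$ttests, p("phase_ttests.csv"), row.names = FALSE)
  # long format convenient for heat-map tools
  long <- data.frame(
    feature_id = rep(rownames(run$changes), times = ncol(run$changes)),
    transition = rep(colnames(run$changes), each = nrow(run$changes)),
    log_rate = as.vector(run$changes),
    cluster = rep(unname(run$clusters$assignment), times = ncol(run$changes)))
  utils::write.csv(long, p("phase_change_long.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
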