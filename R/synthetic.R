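#' Describe one node of a synthetic food web
#'
#' @param name node label.
#' @param tp true trophic position (>= the basal level of the web).
#' @param n number of replicate samples.
#' @param diet name of the node this one feeds on (NULL for basal resources
#'   or nodes whose diet is outside the simulated web).
#' @param mix if non-NULL, the node is a consumer-diet *complex*: a blend in
#'   which fraction `mix` of the biomass is consumer tissue at position `tp`
#'   and fraction `1 - mix` is the diet node's tissue. Must be in [0, 1] and
#'   requires `diet`.
#' @return a `foodweb_node` list.
#' @seealso [foodweb_config()], [simulate_foodweb()]
#' @export
foodweb_node <- function(name, tp, n = 3, diet = NULL, mix = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(tp) || length(tp) != 1) stopf("`tp` must be a number")
  if (n < 1) stopf("`n_replicates` must be >= 1")
  if (!is.null(mix)) {
    if (is.null(diet)) stopf("a blended node needs a `diet`")
    if (mix < 0 || mix > 1) stopf("`mix` must be in [0, 1]")
  }
  structure(list(name = name, tp = tp, n = as.integer(n),
                 diet = diet, mix = mix),
            class = "foodweb_node")
}

#' Configuration of the synthetic isotope food web
#'
#' The generative model mirrors the trophic-position equation: phenylalanine
#' \eqn{\delta^{15}}N is inherited unchanged up the chain (it is a "source"
#' amino acid), while glutamic acid is offset by \eqn{\beta} at the base and
#' gains \eqn{\Delta_{glu-phe}} per trophic level:
#' \deqn{\delta^{15}N_{phe} = \mu_{phe} + \epsilon_{phe}, \quad
#'       \delta^{15}N_{glu} = \delta^{15}N_{phe} + \beta +
#'         \Delta_{glu\mbox{-}phe}(TP - \lambda) + \epsilon_{glu}}
#' Blended complex nodes (e.g. a bacterium suffused through an insect
#' cadaver) are linear mixes of consumer and diet \eqn{\delta} values by
#' biomass fraction.
#'
#' The default web emulates the study system: yeast-soy medium (TP 1),
#' a bacterial culture one step up, an insect at TP 2.2, an insect-bacterium
#' complex blended to TP 2.5, and emerging infective-juvenile nematodes at
#' TP 4.6 with five replicates.
#'
#' Noise defaults are free parameters of the generator (replicate-level
#' isotopic variance is not a published quantity): the glutamic acid SD of
#' 1.36 permil puts the replicate SE of a five-sample node near 0.08 trophic
#' units, the scale seen in careful compound-specific work.
#'
#' @param nodes list of [foodweb_node()] objects.
#' @param basal_d15N_phe mean phenylalanine \eqn{\delta^{15}}N at the base of
#'   the web, per mil.
#' @param phe_noise_sd,glu_noise_sd replicate-level noise SDs, per mil.
#' @param params a [trophic_params()] object (beta, delta_glu_phe, lambda).
#' @param seed integer seed; identical configs give identical tables.
#' @return a `foodweb_config` list.
#' @export
foodweb_config <- function(nodes = default_foodweb_nodes(),
                           basal_d15N_phe = 1.0,
                           phe_noise_sd = 0.4,
                           glu_noise_sd = 1.36,
                           params = trophic_params(),
                           seed = 1L) {
  stopifnot(inherits(params, "trophic_params"))
  if (phe_noise_sd < 0 || glu_noise_sd < 0) stopf("noise SDs must be >= 0")
  if (!length(nodes)) stopf("`nodes` must be a nonempty list")
  nodes <- lapply(nodes, function(nd) {
    if (!inherits(nd, "foodweb_node")) stopf("each node must be a foodweb_node")
    if (nd$tp < params$lambda_basal)
      stopf("node '%s': true TP %.2f is below the basal level %.1f",
            nd$name, nd$tp, params$lambda_basal)
    nd
  })
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(names(nodes))) stopf("node names must be unique")
  for (nd in nodes)
    if (!is.null(nd$diet) && !nd$diet %in% names(nodes))
      stopf("node '%s' references unknown diet '%s'", nd$name, nd$diet)
  structure(list(nodes = nodes, basal_d15N_phe = basal_d15N_phe,
                 phe_noise_sd = phe_noise_sd, glu_noise_sd = glu_noise_sd,
                 params = params, seed = as.integer(seed)),
            class = "foodweb_config")
}

#' @rdname foodweb_config
#' @export
default_foodweb_nodes <- function() {
  list(
    foodweb_node("yeast_soy_medium", tp = 1.0, n = 3),
    foodweb_node("bacteria_in_vitro", tp = 2.0, n = 3, diet = "yeast_soy_medium"),
    foodweb_node("insect", tp = 2.2, n = 9),
    # bacterium suffused through the insect cadaver: ~30% consumer biomass one
    # level above the insect blends to an effective TP of 2.5
    foodweb_node("insect_bacteria_complex", tp = 3.2, n = 3,
                 diet = "insect", mix = 0.3),
    foodweb_node("ij_nematodes", tp = 4.6, n = 5,
                 diet = "insect_bacteria_complex"))
}

#' Simulate an isotope table from a food-web configuration
#'
#' @param config a [foodweb_config()].
#' @return list with `isotopes` (data frame: `sample_id`, `node`, `role`,
#'   `d15N_glu`, `d15N_phe`) and `truth` (data frame: `node`, `true_tp`,
#'   where a blend's true TP is the biomass-weighted mix).
#' @examples
#' web <- simulate_foodweb(foodweb_config(seed = 7))
#' summarize_tp(web$isotopes)
#' @export
simulate_foodweb <- function(config) {
  stopifnot(inherits(config, "foodweb_config"))
  pp <- config$params
  with_seed(config$seed, {
    rows <- list(); truth <- list()
    node_mean <- list() # per-node mean (glu, phe) for blending/inheritance
    for (nd in config$nodes) {
      phe <- config$basal_d15N_phe +
        stats::rnorm(nd$n, 0, config$phe_noise_sd)
      glu <- phe + pp$beta + pp$delta_glu_phe * (nd$tp - pp$lambda_basal) +
        stats::rnorm(nd$n, 0, config$glu_noise_sd)
      role <- if (is.null(nd$diet)) "diet" else "consumer"
      true_tp <- nd$tp
      if (!is.null(nd$mix)) {
        dm <- node_mean[[nd$diet]]
        glu <- nd$mix * glu + (1 - nd$mix) * dm["glu"]
        phe <- nd$mix * phe + (1 - nd$mix) * dm["phe"]
        role <- "complex"
        true_tp <- nd$mix * nd$tp + (1 - nd$mix) * dm["tp"]
      }
      node_mean[[nd$name]] <- c(glu = mean(glu), phe = mean(phe), tp = true_tp)
      rows[[nd$name]] <- data.frame(
        sample_id = sprintf("%s_r%d", nd$name, seq_len(nd$n)),
        node = nd$name, role = role, d15N_glu = glu, d15N_phe = phe)
      truth[[nd$name]] <- data.frame(node = nd$name, true_tp = unname(true_tp))
    }
    list(isotopes = do.call(rbind, c(rows, make.row.names = FALSE)),
         truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}

default_time_points <- function() {
  c("h0", "h1", "h12", "h24A", "h24D",
    "d2", "d4", "d6", "d8", "d10", "d12", "d16")
}

default_phase_map <- function() {
  c(h0 = "uninfected",
    h1 = "early", h12 = "early", h24A = "early", h24D = "early",
    d2 = "middle", d4 = "middle", d6 = "middle", d8 = "middle",
    d10 = "late", d12 = "late", d16 = "late")
}

#' Default planted trajectory clusters for the time-course generator
#'
#' Ten clusters of metabolite trajectories over the four infection phases
#' (uninfected, early, middle, late), specified as natural-log abundance
#' offsets per phase plus a small within-phase slope so that time points
#' inside a phase are not identical. Half of the clusters (125 of 170
#' features) rise from the middle to the late phase and half (45 features)
#' fall, emulating the bifurcation of trajectory shapes seen late in insect
#' bioconversion when infective juveniles accumulate.
#'
#' @return list of cluster descriptors `(cluster, n_features,
#'   phase_log_means, slope)`.
#' @export
default_timecourse_clusters <- function() {
  prof <- list(
    c1  = list(25, c(0.0, -0.8, -1.2,  1.4),  0.05),
    c2  = list(25, c(0.0, -0.4, -0.9,  1.1), -0.05),
    c3  = list(25, c(0.0, -1.6, -0.8,  0.9),  0.04),
    c4  = list(9,  c(0.0,  1.3,  0.4, -0.8), -0.04),
    c5  = list(25, c(0.0,  1.0,  0.2,  1.3),  0.03),
    c6  = list(9,  c(0.0, -0.5,  0.3, -1.5),  0.05),
    c7  = list(9,  c(0.0,  0.8, -0.2, -1.2), -0.03),
    c8  = list(9,  c(0.0, -0.9,  0.7, -0.4),  0.02),
    c9  = list(9,  c(0.0, -1.8, -0.6, -1.6), -0.02),
    c10 = list(25, c(0.0, -1.2,  0.6,  1.6),  0.05))
  mapply(function(nm, p) {
    list(cluster = nm, n_features = p[[1]], phase_log_means = p[[2]],
         slope = p[[3]])
  }, names(prof), prof, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Configuration of the synthetic metabolite time course
#'
#' Emulates the study's sampling design: 12 time points (uninfected hour 0;
#' early hours 1, 12, 24-alive, 24-dead; middle days 2-8; late days 10-16),
#' five replicate insects per point, with features organized in planted
#' trajectory clusters. Log-abundance of a feature is its per-feature
#' baseline plus the cluster's phase-level offset, a within-phase slope term
#' and Gaussian noise; abundances are the exponential (abstract
#' chromatographic peak areas). Insect wet weights are drawn per sample;
#' a small fraction of values can be replaced by the non-detect sentinel
#' (`NA`).
#'
#' @param time_points ordered time-point labels.
#' @param phase_map named character vector mapping every time point to one of
#'   uninfected/early/middle/late.
#' @param n_replicates replicate insects per time point.
#' @param clusters list of cluster descriptors, see
#'   [default_timecourse_clusters()].
#' @param noise_sd log-scale replicate noise SD.
#' @param feature_level_sd SD of per-feature baseline log-abundance offsets.
#' @param weight_mean,weight_sd insect wet weight distribution, grams
#'   (defaults typical of a fifth-instar waxworm, ~0.2 g).
#' @param dropout_rate fraction of values replaced by the non-detect
#'   sentinel, in [0, 1).
#' @param seed integer seed.
#' @return a `timecourse_config` list.
#' @export
timecourse_config <- function(time_points = default_time_points(),
                              phase_map = default_phase_map(),
                              n_replicates = 5,
                              clusters = default_timecourse_clusters(),
                              noise_sd = 0.25,
                              feature_level_sd = 0.5,
                              weight_mean = 0.2,
                              weight_sd = 0.03,
                              dropout_rate = 0.01,
                              seed = 1L) {
  if (!all(time_points %in% names(phase_map)))
    stopf("phase_map is missing time points: %s",
          paste(setdiff(time_points, names(phase_map)), collapse = ", "))
  phases <- c("uninfected", "early", "middle", "late")
  if (!all(phase_map %in% phases))
    stopf("phases must be one of: %s", paste(phases, collapse = ", "))
  if (n_replicates < 1) stopf("`n_replicates` must be >= 1")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("`dropout_rate` must be in [0, 1)")
  for (cl in clusters) {
    if (cl$n_features <= 0) stopf("each cluster needs n_features > 0")
    if (length(cl$phase_log_means) != 4)
      stopf("each cluster needs 4 phase-level log means")
  }
  structure(list(time_points = time_points,
                 phase_map = phase_map[time_points],
                 n_replicates = as.integer(n_replicates),
                 clusters = clusters, noise_sd = noise_sd,
                 feature_level_sd = feature_level_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "timecourse_config")
}

#' Simulate a metabolite time-course table with known cluster membership
#'
#' @param config a [timecourse_config()].
#' @return list with `table` (a raw-stage [metab_table()]) and `truth`
#'   (data frame: `feature_id`, `cluster`).
#' @examples
#' sim <- simulate_timecourse(timecourse_config(seed = 3))
#' sim$table
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "timecourse_config"))
  tp <- config$time_points
  phases <- unname(config$phase_map)
  # within-phase index: 0, 1, ... for successive time points of a phase
  idx <- stats::ave(seq_along(tp), phases, FUN = seq_along) - 1
  phase_of <- factor(phases, levels = c("uninfected", "early", "middle", "late"))
  n_rep <- config$n_replicates
  with_seed(config$seed, {
    meta <- data.frame(
      sample_id = as.vector(t(outer(tp, seq_len(n_rep),
                                    function(t, r) sprintf("%s_r%d", t, r)))),
      time_point = rep(tp, each = n_rep),
      phase = rep(phases, each = n_rep),
      replicate = rep(seq_len(n_rep), times = length(tp)),
      weight_g = 0)
    meta$weight_g <- pmax(stats::rnorm(nrow(meta), config$weight_mean,
                                       config$weight_sd),
                          config$weight_mean / 10)
    rows <- list(); truth <- list(); fid <- 0L
    for (cl in config$clusters) {
      level_by_tp <- cl$phase_log_means[as.integer(phase_of)] + cl$slope * idx
      for (j in seq_len(cl$n_features)) {
        fid <- fid + 1L
        base <- log(1e6) + stats::rnorm(1, 0, config$feature_level_sd)
        lg <- base + rep(level_by_tp, each = n_rep) +
          stats::rnorm(nrow(meta), 0, config$noise_sd)
        rows[[fid]] <- exp(lg)
        truth[[fid]] <- cl$cluster
      }
    }
    values <- do.call(rbind, rows)
    feature_ids <- sprintf("met_%03d", seq_len(fid))
    rownames(values) <- feature_ids
    colnames(values) <- meta$sample_id
    if (config$dropout_rate > 0) {
      drop <- stats::runif(length(values)) < config$dropout_rate
      values[drop] <- NA_real_
    }
    list(table = metab_table(values, meta, stage = "raw"),
         truth = data.frame(feature_id = feature_ids,
                            cluster = unlist(truth)))
  })
}

#' Configuration of the synthetic two-strain expression table
#'
#' Emulates a mean-signal microarray comparison between a reference strain
#' and a mutant: a fixed fraction of genes is truly differential with linear
#' fold change drawn from `fc_range` (randomly up- or down-regulated), the
#' rest have ratios strictly inside `(1/fc_threshold, fc_threshold)` so a
#' strict fold-change cutoff recovers exactly the planted set. Defaults
#' mirror a 3,733-ORF chromosome with 10.6% of genes differential.
#'
#' @param n_genes number of genes.
#' @param frac_differential fraction of genes planted as differential.
#' @param fc_range length-2 range (low, high) of true linear fold changes;
#'   `low` must exceed `fc_threshold`.
#' @param fc_threshold the downstream cutoff the null ratios must stay
#'   strictly inside.
#' @param baseline_log10_mean,baseline_log10_sd log10 distribution of
#'   reference signals.
#' @param seed integer seed.
#' @return an `expression_config` list.
#' @export
expression_config <- function(n_genes = 3733,
                              frac_differential = 396 / 3733,
                              fc_range = c(2.5, 8),
                              fc_threshold = 2,
                              baseline_log10_mean = 3,
                              baseline_log10_sd = 0.5,
                              seed = 1L) {
  if (frac_differential < 0 || frac_differential > 1)
    stopf("`frac_differential` must be in [0, 1]")
  if (fc_range[1] <= fc_threshold)
    stopf("`fc_range` low end must exceed the fold-change threshold")
  if (fc_threshold <= 1) stopf("`fc_threshold` must be > 1")
  structure(list(n_genes = as.integer(n_genes),
                 frac_differential = frac_differential,
                 fc_range = fc_range, fc_threshold = fc_threshold,
                 baseline_log10_mean = baseline_log10_mean,
                 baseline_log10_sd = baseline_log10_sd,
                 seed = as.integer(seed)),
            class = "expression_config")
}

#' Simulate a two-strain expression table with a planted differential set
#'
#' @param config an [expression_config()].
#' @return list with `table` (data frame: `gene_id`, `signal_ref`,
#'   `signal_test`) and `truth` (character vector of differential gene ids).
#' @examples
#' sim <- simulate_expression(expression_config(n_genes = 100, seed = 2))
#' length(sim$truth)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    gene_id <- sprintf("orf_%04d", seq_len(n))
    n_diff <- round(n * config$frac_differential)
    diff_idx <- sort(sample.int(n, n_diff))
    ratio <- numeric(n)
    # null genes: log-ratio noise truncated strictly inside the cutoff band
    band <- log(config$fc_threshold)
    eps <- stats::rnorm(n, 0, band / 4)
    eps <- pmin(pmax(eps, -band * 0.95), band * 0.95)
    ratio <- exp(eps)
    if (n_diff > 0) {
      fc <- stats::runif(n_diff, config$fc_range[1], config$fc_range[2])
      up <- sample(c(TRUE, FALSE), n_diff, replace = TRUE)
      ratio[diff_idx] <- ifelse(up, fc, 1 / fc)
    }
    signal_ref <- 10^stats::rnorm(n, config$baseline_log10_mean,
                                  config$baseline_log10_sd)
    list(table = data.frame(gene_id = gene_id,
                            signal_ref = signal_ref,
                            signal_test = signal_ref * ratio),
         truth = gene_id[diff_idx])
  })
}
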