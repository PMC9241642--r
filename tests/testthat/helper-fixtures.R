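# Shared in-code fixtures: tiny tables with hand-checkable values.

# A minimal metabolite table: `values` is features x samples; metadata spans
# two phases over `tps` time points with `reps` replicates.
tiny_table <- function(values, tps = c("h0", "h1"), reps = 2,
                       phases = c("uninfected", "early"), weights = 1) {
  n <- length(tps) * reps
  stopifnot(ncol(values) == n)
  meta <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    time_point = rep(tps, each = reps),
    phase = rep(phases, each = reps),
    replicate = rep(seq_len(reps), times = length(tps)),
    weight_g = rep_len(weights, n))
  metab_table(values, meta, stage = "raw")
}

# Zero-noise food web over a simple three-level chain.
noiseless_web <- function(nodes, seed = 1) {
  foodweb_config(nodes = nodes, phe_noise_sd = 0, glu_noise_sd = 0,
                 seed = seed)
}

# Two planted trajectory groups with opposite monotone phase trends.
two_group_config <- function(noise_sd = 0, n_features = 6, seed = 1) {
  timecourse_config(
    clusters = list(
      list(cluster = "up", n_features = n_features,
           phase_log_means = c(0, 1, 2, 3), slope = 0.05),
      list(cluster = "down", n_features = n_features,
           phase_log_means = c(3, 2, 1, 0), slope = -0.05)),
    noise_sd = noise_sd, dropout_rate = 0, seed = seed)
}
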