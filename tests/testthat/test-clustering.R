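test_that("Spearman trajectory distance reproduces hand-computed cases", {
  m <- rbind(a = c(1, 2, 3, 4),
             b = c(1, 3, 2, 4),
             c = c(4, 3, 2, 1),
             d = c(2, 4, 6, 8))
  d <- spearman_distance_matrix(m)
  # hand Spearman via sum of squared rank differences: 1 - 12*2/(4*15) = 0.8
  expect_equal(d["a", "b"], 0.2, tolerance = 1e-12)
  expect_equal(d["a", "a"], 0)           # identical series
  expect_equal(d["a", "c"], 0)           # anti-monotone, |rs| = 1
  expect_equal(d["a", "d"], 0)           # same ranks
  expect_equal(d, t(d))
})

test_that("distance axioms hold on arbitrary data", {
  set.seed(14)
  m <- matrix(rnorm(40 * 12), 40, dimnames = list(sprintf("f%02d", 1:40), NULL))
  d <- spearman_distance_matrix(m)
  expect_equal(diag(d), rep(0, 40), ignore_attr = TRUE)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("distances are invariant to strictly monotone transforms", {
  set.seed(15)
  m <- matrix(abs(rnorm(10 * 8)) + 0.1, 10,
              dimnames = list(sprintf("f%02d", 1:10), NULL))
  d0 <- spearman_distance_matrix(m)
  m2 <- m; m2[3, ] <- exp(2 * m2[3, ]) + 5   # strictly increasing transform
  expect_equal(spearman_distance_matrix(m2), d0, tolerance = 1e-12)
  m3 <- m; m3[3, ] <- -m3[3, ]               # strictly decreasing: |rs| safe
  expect_equal(spearman_distance_matrix(m3), d0, tolerance = 1e-12)
})

test_that("constant trajectories get distance 1 with a warning", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(3, 2, 1))
  expect_warning(d <- spearman_distance_matrix(m), "constant")
  expect_equal(d["b", "a"], 1)
  expect_equal(d["b", "b"], 0)
})

test_that("tree cutting spans the trivial and full partitions", {
  set.seed(16)
  m <- matrix(rnorm(8 * 6), 8, dimnames = list(letters[1:8], NULL))
  d <- spearman_distance_matrix(m)
  expect_equal(unname(hierarchical_cluster(d, k = 1)$assignment), rep(1, 8))
  expect_equal(sort(unname(hierarchical_cluster(d, k = 8)$assignment)), 1:8)
  expect_error(hierarchical_cluster(d, k = 9), "cannot cut")
})

test_that("planted clusters are recovered exactly at zero noise", {
  sim <- simulate_timecourse(timecourse_config(seed = 5, noise_sd = 0,
                                               dropout_rate = 0))
  med <- summarize_timepoints(weight_normalize(sim$table))
  cl <- hierarchical_cluster(spearman_distance_matrix(med), k = 10)
  ord <- match(names(cl$assignment), sim$truth$feature_id)
  expect_equal(mclust::adjustedRandIndex(cl$assignment,
                                         sim$truth$cluster[ord]), 1.0)
})

test_that("clustering is invariant to feature input order", {
  sim <- simulate_timecourse(timecourse_config(seed = 5, noise_sd = 0.05,
                                               dropout_rate = 0))
  med <- summarize_timepoints(sim$table)
  cl1 <- hierarchical_cluster(spearman_distance_matrix(med), k = 10)
  set.seed(2); perm <- sample(nrow(med))
  cl2 <- hierarchical_cluster(spearman_distance_matrix(med[perm, ]), k = 10)
  common <- names(cl1$assignment)
  expect_equal(mclust::adjustedRandIndex(cl1$assignment[common],
                                         cl2$assignment[common]), 1.0)
})

test_that("clusters are stable under replicate resampling", {
  sim <- simulate_timecourse(timecourse_config(seed = 17, noise_sd = 0.1,
                                               dropout_rate = 0))
  tb <- sim$table
  set.seed(18)
  runs <- lapply(1:4, function(i) {
    idx <- unlist(lapply(unique(tb$sample_meta$time_point), function(tp) {
      cols <- which(tb$sample_meta$time_point == tp)
      sample(cols, length(cols), replace = TRUE)
    }))
    boot <- metab_table(tb$values[, idx],
                        transform(tb$sample_meta[idx, ],
                                  sample_id = sprintf("b%03d", seq_along(idx))),
                        stage = "raw")
    hierarchical_cluster(spearman_distance_matrix(summarize_timepoints(boot)),
                         k = 10)$assignment
  })
  pairs <- combn(length(runs), 2)
  aris <- apply(pairs, 2, function(p)
    mclust::adjustedRandIndex(runs[[p[1]]], runs[[p[2]]]))
  expect_gte(mean(aris), 0.8)
})

test_that("phase rate of change is the log ratio of consecutive phase means", {
  pm <- matrix(c(10, 10, 10, 10,
                 10, 20, 10, 40,
                 8,  4,  8,  4), 3, byrow = TRUE,
               dimnames = list(c("flat", "var", "halver"),
                               c("uninfected", "early", "middle", "late")))
  rc <- rate_of_change(pm)
  expect_equal(unname(rc["flat", ]), c(0, 0, 0))
  expect_equal(unname(rc["var", ]), c(1, -1, 2))   # x2, /2, x4 in log2
  expect_equal(unname(rc["halver", ]), c(-1, 1, -1))
  expect_equal(colnames(rc),
               c("uninfected_to_early", "early_to_middle", "middle_to_late"))
  # base-10 option
  expect_equal(unname(rate_of_change(pm, log_base = 10)["var", 3]), log10(4))
})

test_that("nonpositive phase means get the half-minimum pseudo-count", {
  pm <- matrix(c(0, 10, 10, 10,
                 0, 0, 0, 0), 2, byrow = TRUE,
               dimnames = list(c("nd", "dead"),
                               c("uninfected", "early", "middle", "late")))
  rc <- rate_of_change(pm)
  expect_equal(unname(rc["nd", 1]), log2(10 / 5))  # 0 -> min positive / 2 = 5
  expect_true(all(is.na(rc["dead", ])))
  expect_error(rate_of_change(pm[, 1:3]), "4 phase columns")
})

test_that("cluster report summarizes per-cluster change and the late rise", {
  # 125 of 170 features rising middle->late is printed as 74%
  assignment <- setNames(rep(1:2, c(125, 45)), sprintf("f%03d", 1:170))
  clusters <- structure(list(tree = NULL, k = 2, assignment = assignment),
                        class = "trajectory_clusters")
  changes <- matrix(0, 170, 3,
                    dimnames = list(names(assignment),
                                    c("uninfected_to_early",
                                      "early_to_middle", "middle_to_late")))
  changes[1:125, "middle_to_late"] <- 1     # doubling late
  changes[1:125, "uninfected_to_early"] <- 1
  changes[126:170, "middle_to_late"] <- -0.5
  rep_out <- cluster_report(clusters, changes)
  expect_equal(rep_out$n_late_increase, 125)
  expect_equal(rep_out$pct_late_increase, 74)
  expect_equal(rep_out$by_cluster$mean_uninfected_to_early[1], 1)
  expect_equal(rep_out$by_cluster$pattern[1], "up-up-up")
  expect_equal(rep_out$by_cluster$pattern[2], "up-up-down")
  expect_equal(rep_out$by_cluster$n_features, c(125, 45))
})
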