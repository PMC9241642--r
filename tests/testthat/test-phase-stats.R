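# Table with one feature, 3 uninfected and 3 early samples set explicitly.
two_phase_table <- function(uninf, early) {
  v <- matrix(c(uninf, early), 1, dimnames = list("m1", NULL))
  meta <- data.frame(
    sample_id = sprintf("s%d", seq_along(c(uninf, early))),
    time_point = rep(c("h0", "h1"), c(length(uninf), length(early))),
    phase = rep(c("uninfected", "early"), c(length(uninf), length(early))),
    replicate = c(seq_along(uninf), seq_along(early)),
    weight_g = 1)
  metab_table(v, meta)
}

test_that("pooled t test matches the textbook formula", {
  tb <- two_phase_table(c(9, 10, 11), c(14, 15, 16))
  res <- phase_ttest(tb, "m1", "early")
  # textbook pooled-variance oracle
  x <- c(9, 10, 11); y <- c(14, 15, 16)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-9)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(t_oracle, 4), tolerance = 1e-9)
  expect_true(res$significant)

  same <- phase_ttest(two_phase_table(c(1, 2, 3), c(1, 2, 3)), "m1", "early")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(phase_ttest(two_phase_table(1, c(1, 2)), "m1", "early"),
               ">= 2 samples")
})

test_that("Welch variant is available by flag", {
  tb <- two_phase_table(c(9, 10, 11), c(10, 18, 26))
  student <- phase_ttest(tb, "m1", "early", var_equal = TRUE)
  welch <- phase_ttest(tb, "m1", "early", var_equal = FALSE)
  expect_lt(welch$df, student$df)
})

test_that("type-I error of the phase t test is near alpha under the null", {
  set.seed(77)
  reps <- 1000
  hits <- 0
  for (i in seq_len(reps)) {
    tb <- two_phase_table(rnorm(5, 10), rnorm(5, 10))
    hits <- hits + phase_ttest(tb, "m1", "early")$significant
  }
  expect_gte(hits / reps, 0.03)
  expect_lte(hits / reps, 0.07)
})

# One feature over 3 time points with `reps` replicates each.
three_tp_table <- function(g1, g2, g3) {
  v <- matrix(c(g1, g2, g3), 1, dimnames = list("m1", NULL))
  n <- length(c(g1, g2, g3))
  meta <- data.frame(
    sample_id = sprintf("s%d", 1:n),
    time_point = rep(c("h0", "h1", "h12"), c(length(g1), length(g2), length(g3))),
    phase = rep(c("uninfected", "early", "early"),
                c(length(g1), length(g2), length(g3))),
    replicate = 1, weight_g = 1)
  meta$replicate <- unlist(lapply(c(length(g1), length(g2), length(g3)), seq_len))
  metab_table(v, meta)
}

test_that("ANOVA and Tukey HSD match hand oracles", {
  res <- anova_tukey(three_tp_table(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)), "m1")
  # hand ANOVA: group means 2,5,8; MSB = 3*var(c(2,5,8)) = 27; MSW = 1
  expect_equal(res$anova$f_statistic, 27, tolerance = 1e-9)
  expect_equal(res$anova$df_between, 2)
  expect_equal(res$anova$df_within, 6)
  expect_equal(res$anova$p_value, pf(27, 2, 6, lower.tail = FALSE),
               tolerance = 1e-9)
  # studentized-range oracle: q = diff / sqrt(MSW/n)
  q <- abs(res$tukey$diff) / sqrt(1 / 3)
  expect_equal(res$tukey$p_adj, ptukey(q, 3, 6, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_true(all(res$tukey$significant))
  expect_equal(sum(res$tukey$vs_reference), 2)
  expect_equal(sum(res$tukey$consecutive), 2)

  flat <- anova_tukey(three_tp_table(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)), "m1")
  expect_equal(flat$anova$f_statistic, 0)
  expect_equal(flat$anova$p_value, 1)
  expect_false(any(flat$tukey$significant))
})

test_that("time points with single replicates are dropped with a warning", {
  tb <- three_tp_table(c(1, 2, 3), c(4, 5, 6), 7)
  expect_warning(res <- anova_tukey(tb, "m1"), "< 2 replicates")
  expect_equal(res$anova$df_between, 1)
  expect_error(suppressWarnings(anova_tukey(three_tp_table(1, 2, 3), "m1")),
               ">= 2 time points")
})

test_that("fold-change filter applies a strict two-fold cutoff", {
  ex <- data.frame(gene_id = letters[1:5], ref = 1,
                   test = c(3, 0.4, 1.5, 2.0, 0.5))
  flt <- fold_change_filter(ex)
  # brute-force enumeration over the 5 cases
  brute <- letters[1:5][sapply(c(3, 0.4, 1.5, 2.0, 0.5),
                               function(r) r > 2 || r < 0.5)]
  expect_equal(flt$genes, brute)
  expect_equal(flt$n_differential, 2)
  expect_false(flt$table$differential[flt$table$gene_id == "d"]) # exactly 2.0
  expect_false(flt$table$differential[flt$table$gene_id == "e"]) # exactly 0.5

  expect_equal(fold_change_filter(ex, total_orfs = 3733)$percent,
               round(100 * 2 / 3733, 1))
  expect_error(fold_change_filter(ex, fc_threshold = 1), "> 1")
})

test_that("fold-change filter is symmetric in up/down regulation", {
  sim <- simulate_expression(expression_config(n_genes = 200,
                                               frac_differential = 0.3,
                                               seed = 12))
  flt <- fold_change_filter(sim$table)
  inv <- sim$table
  inv[c("signal_ref", "signal_test")] <- inv[c("signal_test", "signal_ref")]
  expect_setequal(fold_change_filter(inv)$genes, flt$genes)
})

test_that("nonpositive signals are skipped with a warning", {
  ex <- data.frame(gene_id = c("a", "b", "c"), ref = c(1, 0, 1),
                   test = c(5, 5, -2))
  expect_warning(flt <- fold_change_filter(ex), "nonpositive")
  expect_equal(flt$genes, "a")
  expect_true(is.na(flt$table$ratio[2]))
})

test_that("regulon overlaps count pairwise intersections and Venn regions", {
  ov <- regulon_overlap(list(x = c("a", "b", "c"), y = c("b", "c", "d")))
  expect_equal(ov$pairwise["x", "y"], 2)
  expect_equal(ov$pairwise["x", "x"], 3)
  expect_equal(regulon_overlap(list(p = "a", q = "b"))$pairwise["p", "q"], 0)

  set.seed(31)
  sets <- lapply(setNames(1:5, paste0("s", 1:5)),
                 function(i) sample(letters, sample(5:15, 1)))
  ov5 <- regulon_overlap(sets)
  # inclusion-exclusion: exclusive region counts partition the union
  expect_equal(sum(ov5$regions$count), length(unique(unlist(sets))))
  # pairwise counts from brute-force membership
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(ov5$pairwise[i, j],
                 length(intersect(sets[[i]], sets[[j]])))
  expect_error(regulon_overlap(list(a = "x")), ">= 2 sets")
})
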