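# trophomics

Who eats whom inside a decomposing insect, and how does its chemistry change
while it happens? `trophomics` implements the two computational arms of that
question for an entomopathogenic nematode–bacterium–insect system:

1. **Compound-specific trophic-position estimation.** The trophic position
   (TP) of an organism is estimated from the difference in ¹⁵N enrichment
   between a *trophic* amino acid (glutamic acid, which gains ¹⁵N with every
   feeding step) and a *source* amino acid (phenylalanine, which does not):

   TP = (δ¹⁵N_glu − δ¹⁵N_phe − β) / Δ_glu-phe + λ

   with β the producer-level glu−phe offset (≈ 8.4‰ for C3-plant-based
   webs), Δ_glu-phe the per-trophic-level discrimination (7.6‰ by default)
   and λ the basal level (1). The package computes per-sample TPs, per-node
   means ± SE, trophic discrimination factors (TDF) between consumer–diet
   pairs, and expected-TP columns for summary tables.

2. **Time-course metabolomics.** Peak-area tables over an infection time
   course (12 time points in four phases — uninfected, early, middle, late —
   with 5 replicate insects each) are weight-normalized, log-transformed and
   pareto-scaled; group separation is assessed by PLS-DA (NIPALS) with VIP
   scoring; metabolite trajectories are clustered hierarchically on the
   Spearman rank-correlation distance 1 − |rs|; per-phase log₂ rates of
   abundance change are profiled per cluster; and per-metabolite t tests /
   ANOVA + Tukey HSD screen for significant shifts. A strict |fold change| >
   2 filter and regulon-overlap utilities cover two-strain expression
   comparisons.

Because raw data of this kind are rarely deposited, the package ships
synthetic-data generators (`simulate_foodweb()`, `simulate_timecourse()`,
`simulate_expression()`) whose ground truth makes every downstream stage
testable end to end.

## Worked example

```r
library(trophomics)

# --- trophic arm: a simulated web with an apex nematode -------------------
web <- simulate_foodweb(foodweb_config(seed = 11))
edges <- data.frame(
  consumer = c("bacteria_in_vitro", "insect_bacteria_complex", "ij_nematodes"),
  diet     = c("yeast_soy_medium", "insect", "insect_bacteria_complex"))
run_trophic_pipeline(web$isotopes, edges)
#>                  consumer                    diet tdf_glu_phe tp_expected tp_glu_phe  se n
#> 1       bacteria_in_vitro        yeast_soy_medium         7.1         1.9        1.9 0.0 3
#> 2 insect_bacteria_complex                  insect         2.1         3.2        2.4 0.0 3
#> 3            ij_nematodes insect_bacteria_complex        16.6         3.4        4.6 0.1 5
```

Reading the last row: the nematodes' measured TDF over their cadaver diet is
16.6‰ — about two full discrimination steps (2 × 7.6‰) rather than one — so
their measured TP (4.6) sits a full level above the one-step expectation
(3.4). That gap is the signature of loops in the web (consuming bacteria
that already fed on nematodes, or cannibalism) rather than random feeding on
the cadaver.

```r
# --- metabolome arm: full pipeline on a synthetic time course -------------
sim <- simulate_timecourse(timecourse_config(seed = 11))
run <- run_metabolome_pipeline(sim$table, k = 10, truth = sim$truth)
run
#> Metabolome pipeline run: 170 features x 60 samples
#>   clusters: k = 10; 74% of features rise middle->late
#>   PLS-DA: explained X % = 59.7 21.9 3.0; 107 features with VIP > 1
#>   ARI vs truth: 0.470
head(sort(vip_scores(run$pls), decreasing = TRUE), 3)
#>  met_060  met_074  met_058
#> 1.317908 1.314568 1.310105
```

Here 74% of metabolites rise from the middle to the late phase (the
generator plants 125 of 170 rising features, mimicking the late-phase
accumulation seen when juveniles stop reproducing and prepare to emerge);
component 1 of the PLS-DA carries most of the between-phase separation, and
VIP scores above 1 flag metabolites contributing more than an average
feature to it. At the default generator noise the cluster recovery (adjusted
Rand index 0.47) is deliberately imperfect; at low noise
(`noise_sd = 0.05`) recovery is exact — see the methods vignette.

A thin command-line wrapper for the same operations is in
`inst/scripts/trophomics-cli.R` (subcommands `simulate`, `trophic`,
`run-all`).

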