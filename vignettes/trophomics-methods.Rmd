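---
title: "Models and methods behind trophomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trophomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophomics)
```

This vignette documents the statistical models the package implements, the
parameters that matter, the assumptions baked into the synthetic-data
generators, and the numerical choices made where the design was genuinely
open. It states no empirical result beyond what the package's own tests and
examples compute.

## 1. The trophic-position model

Amino-acid compound-specific isotope analysis separates "trophic" amino
acids, whose ¹⁵N enrichment grows with each feeding step (glutamic acid),
from "source" amino acids that record the baseline of the web
(phenylalanine). Trophic position is

$$TP = \frac{\delta^{15}N_{glu} - \delta^{15}N_{phe} - \beta}{\Delta_{glu\text{-}phe}} + \lambda$$

The three constants live in `trophic_params()` and are never hard-coded:

| parameter | unit | default | meaning |
|---|---|---|---|
| `beta` | ‰ | 8.4 | producer-level glu−phe offset (C3-plant-based webs; yeast-based laboratory media are treated with the same β, a documented assumption) |
| `delta_glu_phe` | ‰ | 7.6 | net per-trophic-level ¹⁵N discrimination between glu and phe |
| `lambda_basal` | – | 1 | trophic level of the basal resource |

The 7.6‰ default for `delta_glu_phe` is the canonical value of the
glu/phe framework. It is deliberately prominent and configurable: the
supported consistency check is that a measured TDF of 6.53‰ over a diet at
TP 1.0 converts to `1.0 + 6.53/7.6 = 1.86`, printed as 1.9 under the
report's one-decimal round-half-up convention (`round_half_up()`). A
measured TDF between trophic compartments is the difference of mean glu−phe
gaps (`compute_tdf()`), and `tp_from_tdf()` converts it into trophic-level
units. `expected_tp()` encodes the one-step expectation (diet TP + 1);
departures of the measured TP from it, in units of whole levels, are the
diagnostic for feeding loops.

Summaries (`summarize_tp()`) report the mean per node, the standard error
as sample SD (n − 1 denominator) divided by √n (defined as 0 for a single
record), and n. Report rounding is half-up to one decimal, matching summary
tables in this field; full precision is available with `digits = NULL`.

### The food-web generator

`simulate_foodweb()` inverts the model exactly: phenylalanine δ¹⁵N is drawn
around the basal mean and inherited unchanged up the chain (no phe
discrimination parameter exists, by design), while glutamic acid is offset
by β plus Δ per level, plus noise. Consequently `compute_tp()` recovers the
configured true TP to machine precision on a noise-free table — the
generator-inversion property the tests rely on.

Blended "complex" nodes (a bacterial population suffused through an insect
cadaver) are linear mixes of consumer and diet δ values by biomass
fraction. Linearity is a modeling choice: δ values are per-mil deviations,
and a biomass-weighted average of tissue pools mixes them approximately
linearly. The default web places a ~30% consumer fraction one level above
the insect so the blend sits at TP 2.5.

Replicate-level isotopic variance is not a published quantity, so the noise
defaults are the generator's own assumptions, chosen once: glu-side SD
1.36‰ (equivalently 0.179 TP units), which makes the SE of a five-replicate
node ≈ 0.08 TP units — the precision scale of careful compound-specific
work — and phe-side SD 0.4‰. Because the generated glu value is built on
the *realized* phe value, phe noise cancels from the glu−phe gap and only
the glu-side SD propagates into TP estimates.

## 2. Metabolite preprocessing

The chain is fixed in the conventional order — sample normalization, then
transformation, then scaling — and enforced by a stage tag on
`metab_table` objects:

1. `weight_normalize()`: divide each sample by its insect wet weight (g).
2. `log_transform()`: base-10 log (configurable) after replacing
   non-detects and zeros by **half the feature's minimum positive value**.
   Non-detects are carried as `NA`, an explicit sentinel rather than zero,
   so the replacement policy lives in exactly one place.
3. `pareto_scale()`: per feature, subtract the mean and divide by the
   square root of the SD — tempering high-abundance dominance without
   fully flattening variance as autoscaling would. Constant features map
   to all-zero rows and are kept by default (stable feature indexing);
   `drop_constant = TRUE` removes them.

Two summaries feed the downstream stages, and they intentionally differ:
**medians per time point** (`summarize_timepoints()`) feed trajectory
clustering, where medians over the five replicates damp outliers; **means
per phase** (`summarize_phases()`) feed the rate-of-change profile, where
ratios of arithmetic means on the raw (weight-normalized) scale have a
direct fold-change reading. Both operations exist separately because each
downstream use calls for a different summary.

## 3. PLS-DA and VIP

`fit_plsda()` is an iterative NIPALS PLS2 against a one-hot class matrix
(both blocks column-centered). Classes default to the four infection
phases; a 12-class time-point mode exists because score plots in this field
are sometimes colored by time point — neither mode is claimed to reproduce
any particular published percentage, as the underlying raw data are not
public. Numerical choices: initialization with the first column of the
centered class matrix (deterministic given input order), convergence
tolerance 1e−10 on the relative change of the score vector, at most 500
iterations, and automatic reduction of the component count to the data
rank (with a warning). Scores are pairwise orthogonal and weights unit
norm; the test suite cross-checks scores and explained-X percentages
against an independent PLS implementation (mixOmics) to 1e−6.

VIP through cumulative depth $a$ uses the weights $w$ (not the loadings) in
the squared term,

$$VIP_j = \sqrt{p\,\frac{\sum_{b\le a} SSY_b\, w_{bj}^2}{\sum_{b\le a} SSY_b}},$$

with $SSY_b = (t_b't_b)(q_b'q_b)$ the explained class sum of squares, so
that $\sum_j VIP_j^2 = p$ identically at every depth. Multi-component
importance is reported as the average of the per-depth VIP scores
(`vip_importance()`). The significance rule is strict: VIP > 1, with
exactly 1 excluded. No permutation testing or Q²/R² cross-validation is
implemented — explained percentages are in-sample by design.

## 4. Trajectory clustering and phase rates of change

The trajectory distance is $d = 1 - |r_s|$ with $r_s$ the Spearman rank
correlation (average ranks on ties) between two features' per-time-point
medians. The absolute value groups co-varying trajectories regardless of
direction, and ranking makes the distance invariant to strictly monotone
transforms — so the clustering is unchanged by log transformation or
per-feature scaling. Constant trajectories have undefined correlation; they
are assigned distance 1 to every partner, with a warning, rather than
silently dropped.

Agglomeration uses average linkage (UPGMA) by default — the conventional
pairing with correlation-type distances; complete and single linkage are
available by flag. The linkage method was an open choice; average linkage
was selected once and kept. The tree is cut at `k = 10` clusters by
default (a parameter; no automatic k selection is offered). `hclust`'s
deterministic lowest-index merge order makes runs reproducible, and
partitions are invariant to feature input order up to relabeling.

`rate_of_change()` profiles each feature's phase transitions
(uninfected→early, early→middle, middle→late) as the log of the ratio of
consecutive phase means. Base 2 was chosen for its symmetric fold reading
(+1 doubling, −1 halving); the base is configurable. Nonpositive phase
means receive a pseudo-count of half the feature's minimum positive phase
mean; a feature with no positive phase mean is reported `NA`.
`cluster_report()` aggregates per cluster (size, mean log rate per
transition, up/down sign pattern) and reports the overall fraction of
features rising middle→late.

## 5. Significance screening and the fold-change filter

`phase_ttest()` is a classical pooled-variance Student t test (two-sided)
of the uninfected samples against one phase, at α = 0.05; Welch is a flag.
Raw p values are reported without multiple-testing correction by default —
the per-metabolite screening this mirrors annotates raw P < 0.05 — and
`stats::p.adjust` can be applied downstream. The per-metabolite ANOVA is
operationalized as **one-way across time points**: once a single metabolite
is analyzed, the described comparisons (each time-point mean vs the
uninfected model and vs each other) leave no second crossed factor, so a
one-way layout with Tukey HSD post hoc is the faithful model. Comparisons
involving the reference time point and consecutive time-point pairs are
flagged for convenience. Time points with fewer than two replicates are
dropped from the ANOVA with a warning.

`fold_change_filter()` flags genes whose mean-signal ratio exceeds the
cutoff strictly in either direction (r > 2 or r < 1/2 by default; exactly
2.0 is excluded), skipping nonpositive signals with a warning, and reports
the flagged percentage of a configurable ORF total to one decimal.
`regulon_overlap()` provides pairwise intersection counts and exclusive
Venn-region counts for up to five differential sets.

## 6. What the generators emulate — and what they do not

`simulate_timecourse()` reproduces the sampling design of the study system
(12 time points — uninfected h0; early h1/h12/h24-alive/h24-dead; middle
d2–d8; late d10–d16 — with 5 replicate insects each, both hour-24 samplings
inside the early phase) and plants 170 features in 10 trajectory clusters
specified by phase-level log means plus a small within-phase slope (so time
points inside a phase differ, which is what lets a time-point-labeled
PLS-DA separate more than phases). The default cluster profiles make 125 of
the 170 features rise from middle to late phase — five clusters rising and
five falling — emulating the late-phase bifurcation of cadaver chemistry.
Defaults: log-scale replicate noise SD 0.25, per-feature baseline SD 0.5
around peak areas of ~10⁶, insect weights ~N(0.2 g, 0.03 g) (a fifth-instar
waxworm), 1% non-detects.

The generators do **not** simulate mass-spectral reality: no retention
times, isotopologue envelopes, ionization suppression, batch effects or
heteroscedastic peak integration — abundances are abstract areas with
log-normal noise. Passing tests therefore demonstrate the *statistical
machinery* (normalization order, model identities, cluster recovery,
test calibration), not robustness to instrument artifacts. Likewise the
isotope generator draws independent Gaussian noise per replicate; real
replicate structure (shared extraction batches, drift) is out of scope.

## 7. Problem sizes and determinism

Examples and tests run at the study's native scale (170 × 60 metabolite
tables, ≤ 3,733-gene expression tables, food webs of ≤ a few hundred
records), where the full pipeline completes in seconds; Monte-Carlo
calibration of the t test uses 1,000 null replicates. Every stochastic
entry point takes an integer seed and restores the caller's RNG state, and
`run_metabolome_pipeline()` writes byte-identical outputs across repeated
runs on the same input, with a JSON manifest (parameters, input dimensions
and checksum, VIP normalization check, warnings, and — when ground truth is
supplied — the adjusted Rand index of cluster recovery) sufficient to
re-run.

## 8. Known limitations

* The TDF→TP conversion at a fixed 7.6‰ cannot reproduce summary rows whose
  source computations used unrounded per-sample data; only internally
  consistent conversions are asserted.
* Average-linkage trees on 1 − |rs| distances are sensitive to ties when
  trajectories are short; with 12 time points this is minor but is the
  reason medians (not single replicates) feed the distance.
* PLS-DA without cross-validation overstates separation on small n; the
  package's explained percentages are descriptive, and the label-permutation
  smoke test in the suite is a sanity check, not an inference procedure.
* The one-way ANOVA reading of the time-point screening ignores any
  plate/replicate factor; with five replicates per time point and no plate
  metadata, a richer mixed model is not identifiable here.
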