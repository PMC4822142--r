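---
title: "Mapping chronic-phase CML to disease-evolutionary time: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping chronic-phase CML to disease-evolutionary time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`cmlstage`: the compartment model of hematopoiesis, the two
expression-derived biomarkers, the pinning procedure that places
chronic-phase (CP) patients on a disease time axis, and the synthetic
cohort generator the test suite is built on. Where a design was genuinely
open, the section says what was chosen and why.

## 1. The compartment model

Hematopoiesis is described as a chain of `K = 32` maturation compartments.
Cells in compartment `k` divide at rate `r_k = r_1 ρ^(k-1)`; each division
either exports both daughters to compartment `k+1` (probability `ε`,
differentiation) or retains them (probability `1 − ε`, self-renewal). The
deterministic mean-field update is, for `k ≥ 2`,

$$\frac{dN_k}{dt} = 2\,\varepsilon\, r_{k-1} N_{k-1}
  + (1 - 2\varepsilon)\, r_k N_k ,$$

with compartment 1 held constant (the stem-cell niche). The healthy
steady state follows `N_k / N_{k-1} = 2ε / ((2ε − 1) ρ)`; with the default
`ε = 0.85` and `ρ = 1.26` this is the familiar ≈1.93 amplification per
compartment. All rate constants are taken from the established
compartment-model literature for human hematopoiesis, not fitted here:

| parameter | default | units | meaning |
|---|---|---|---|
| `n_compartments` | 32 | – | maturation stages per lineage |
| `replication_rate_base` | 1/365 | day⁻¹ | stem cells divide ~once a year |
| `replication_rate_ratio` | 1.26 | – | rate increase per compartment |
| `epsilon_healthy` | 0.85 | – | healthy differentiation probability |
| `epsilon_cml` | 0.72 | – | leukemic differentiation probability |
| `stem_cells_healthy` | 400 | cells | active healthy stem pool |
| `cml_init_cells` | 1 | cells | clone seeded at `t = 0` |
| `cd34_cutoff` | 23 | – | last CD34⁺ compartment, healthy cells |
| `cml_cd34_cutoff` | 32 | – | last CD34⁺ compartment, leukemic cells |
| `t_max_days`, `dt_days` | 2200, 1 | days | window and output step |

The leukemic lineage uses the same update with `ε = 0.72`. Reduced
differentiation raises the per-compartment amplification to ≈2.6, so a
single mutant stem cell expands into a clone that overtakes healthy
hematopoiesis within the simulated ~6-year window — the takeover is
S-shaped because the clone fills in toward its (much larger) quasi-steady
profile. Competition between the lineages is deliberately not modelled;
the healthy lineage stays at steady state throughout.

**CD34 phenotype.** Healthy cells lose CD34 once they mature past
compartment 23. For the leukemic lineage the differentiation block is
taken to delay CD34 loss: by default the entire clone is treated as a
CD34⁺ blast pool (`cml_cd34_cutoff = n_compartments`). This is the one
place where the model deviates from a strictly compartment-indexed CD34
assignment, and it is forced by an internal consistency argument: under
the update above, any clone capable of overtaking healthy hematopoiesis
within the window must have a *mature-amplified* equilibrium profile
(`ε_CML < ε_healthy`), so a lineage-blind pooled CD34⁺/CD34⁻ ratio would
*fall* once the clone dominates, contradicting the defining biology of CML
progression (expansion of immature CD34⁺ blasts). With the lineage-aware
phenotype the ratio is proportional to a constant plus the clone mass and
rises strictly monotonically for every counting cutoff — the property the
time mapping depends on. `cd34_ratio(traj, cutoff, cml_cutoff = cutoff)`
restores the lineage-blind reading for comparison.

**Integration.** The system is linear but stiff: per-day rates span four
orders of magnitude across 32 compartments, so a fixed-step explicit
update at `dt = 1` d is unstable for the top compartments. The model is
therefore integrated with `deSolve::lsoda` (`rtol = 1e-10`) and reported
on the daily grid; the test suite checks the healthy fixed point (relative
drift < 1e-6 over the full window), a closed-form solution of the
two-compartment reduction (relative error < 1e-6), and step-halving
convergence (< 0.1 % on meaningful counts).

## 2. Simulated expression entropy

The entropy machinery rests on one observation: a *mixture* of many i.i.d.
expression profiles is narrower than any single profile (central-limit
narrowing), so its histogram entropy is lower. A simulated gene-expression
matrix (SGEM) with one row per population (64 under the defaults) and one
column per gene (6,384, the size of the low-information-ratio gene
universe) is weighted by the model's population fractions `w(t)`; the
entropy `s_t` of the weighted mixture dips exactly where the population
mixing entropy `−Σ w log w` peaks — at the healthy/leukemic crossover.

Choices that were open and how they were fixed:

* **Density estimator.** Equal-width histogram with 64 bins over the
  sample's value range, natural logarithm. Simple, fast and reproducible;
  the absolute entropy level depends on the estimator, so the package
  treats absolute entropy thresholds as configurable and tests shape
  properties (interior minimum, alignment with the mixing maximum) rather
  than levels. For *cohort* scoring, `run_pipeline()` bins all samples
  over the pooled cohort range by default (`cohort_binning = "global"`),
  because per-sample ranges make entropies incomparable across samples; a
  per-sample option is retained.
* **SGEM entry distribution.** Uniform on [0, 1] by default, log-normal as
  an alternative. The distribution shifts the curve's level, not its
  non-monotonic shape; a Gaussian would be a poor choice since Gaussian
  mixtures of Gaussians stay Gaussian and carry no shape signal.
* **Minimum estimation.** The argmin of a single-seed curve is noisy, so
  `entropy_minimum_time()` averages the smoothed (moving average, window
  11) argmin over 10 independently seeded SGEMs and also returns the
  pointwise *mean curve*, which the pinning uses. Boundary minima are
  flagged as non-singular; flat curves are an error.

With the literature parameters the entropy minimum falls at ≈1,620 days
(the acceptance script recomputes this), about 73 % into the window and
within ~15 days of the mixing-entropy maximum; the location is essentially
independent of the CD34 counting cutoff because the population dynamics do
not depend on how CD34 status is counted.

## 3. CD34⁺ similarity score

The signature is built by ranking genes on their mean expression over
CD34⁺ reference samples after per-gene centering against the cohort mean
(`centering = "cohort-mean"`; a raw-ranking option exists). Centering
removes probe-level baselines so the ranking reflects reference-specific
regulation. The top and bottom 5 % form the up and down sets; ties break
deterministically by gene identifier. A sample's score is the signed
log10 p-value of a two-sided Wilcoxon rank-sum test between its up-set and
down-set values: the exact distribution when both sets have ≤ 25 genes and
no ties, the normal approximation with continuity correction otherwise;
p-values are floored at the smallest positive double so the signed log10
stays finite. Samples covering < 80 % of either gene set are refused
(configurable); `score_cohort()` flags per-sample failures instead of
aborting.

## 4. Pinning and the T1/T2 split

Patient scores (CP cohort) and the model CD34 ratio are independently
min-max normalized to [0, 1]. The default *two-step* match assigns each
patient the time with the nearest normalized CD34 ratio, then refines
within a CD34 neighbourhood (half-width 0.05 on the normalized axis) to
the time whose normalized simulated entropy is nearest the patient's
normalized observed entropy. A *joint* 2-D nearest-neighbour mode is
provided as an alternative reading of the same idea.

**Aligning the minima.** Because the score and ratio axes are related
monotonically but not linearly, the two normalized axes can be offset; the
method aligns them by shifting the patients' CD34 coordinates. Two
estimators of the shift are implemented:

* `align = "profile"` (default): least-squares registration — the shift
  (scanned over ±0.5 in steps of 0.005) minimizing the summed squared
  distance between each patient's normalized entropy and the normalized
  simulated entropy at the matched time. This uses the entire entropy
  profile of the cohort and aligns the minima as a consequence.
* `align = "vertex"`: the vertex of the quadratic (V-shape) fit of
  observed entropy on the CD34 axis is shifted onto the simulated argmin.
  This was the original design, kept for comparison; it proved fragile
  because the fitted vertex of a noisy, asymmetric V often lands at or
  beyond the edge of the score range, producing wholesale misalignment.
  When the V is unfittable or its vertex extrapolates outside the observed
  range, the method falls back to the unshifted joint match with a
  warning.

On synthetic cohorts with known ground truth the profile registration
recovers true CP times with median Spearman ρ ≈ 0.92 and classifies
early/late CP with balanced accuracy ≈ 0.95 (the acceptance tests compute
these over 20 generator seeds).

CP patients with matched time strictly before the boundary (the simulated
entropy-minimum time) are labelled T1, all others T2; a patient exactly on
the boundary is T2 by convention.

## 5. Downstream statistics

* **V-shape:** OLS of entropy on score and score²; the reported p-value is
  the two-sided test of the quadratic coefficient and the vertex
  `−β₁/(2β₂)` is only reported for an upward parabola. Type-I behaviour is
  verified by simulation (rejection rate within [0.03, 0.07] at α = 0.05
  over 1,000 null cohorts).
* **Differential expression:** per-gene two-sided two-sample t-tests
  (pooled variance by default, Welch optional) with Benjamini–Hochberg
  adjustment at FDR < 0.05, computed from row-wise moments. Genes with
  zero variance in both groups short-circuit: p = 1 on exact mean
  equality, otherwise p = 0 with a flag. Planted-effect simulations verify
  FDR control and power.
* **Entropy correlation:** Pearson by default (Spearman optional), with a
  sub-sampling challenge (default 80 % of pairs, without replacement,
  1,000 iterations) reporting the share of significant iterations. The
  sub-sampling fraction is explicit because the result is meaningless
  without it.
* **Stage grid:** CD34 range quartered, entropy range halved on observed
  min–max ranges; interval boundaries belong to the lower cell except the
  global maximum. The permutation control shuffles stage labels only
  (composition exactly preserved, positions fixed), 1,000 times, seeded.
  For a 42/9/8/28 cohort the expected AP share of any fixed subset is
  9/87 ≈ 10.3 %, which the control reproduces within Monte-Carlo error.

## 6. The synthetic cohort generator

The generator exists so that every stage of the pipeline can be exercised
against known ground truth. It emulates a microarray cohort of 42 CP, 9
AP, 8 APcyto and 28 BC samples over 6,384 genes (log-scale intensities):

* **CP samples** are population-weighted mixtures of per-population base
  profiles taken at a true time drawn uniformly over the 2,200-day window,
  plus Gaussian measurement noise (default 0.5 baseline SD).
* **Base profiles** are i.i.d. uniform (matching the SGEM, whose
  non-Gaussian shape carries the entropy signal) with planted
  CD34-associated genes: 10 % of genes, half shifted up by 1 baseline SD
  in CD34⁺ populations and down elsewhere, half the reverse — mirroring
  the two 5 % tails the signature extracts. The defaults matter: a much
  larger effect separates the up/down sets completely, saturates the
  rank-sum statistic at its extreme and destroys score resolution, while
  one-sided planting distorts the per-sample entropy.
* **Reference samples** are balanced pools over all CD34⁺ populations of
  both lineages, emulating CD34⁺ enrichment (which equalizes sorted
  populations rather than preserving steady-state proportions).
* **Advanced stages** are outside the chronic-phase model's scope; they
  are represented as leukemic-template-dominated mixtures (AP 0.5, APcyto
  0.4, BC 0.9 template mass) with stage-specific extra dispersion, enough
  to give rising CD34⁺ similarity and elevated entropy along CP → BC and
  exercise the grid and DE code paths. They carry no ground-truth time.
* **Blast counts** are drawn stage-dependently (CP/APcyto 0–9 %, AP
  15–29 %, BC 30–95 %) with a planted 10 % missingness in CP and BC, so
  the preparation rules (CP missing → 1; BC missing → excluded) are
  exercised.

What passing tests on this cohort do *not* show: the generator has no
probe-level artifacts, batch effects, correlated gene modules, or
platform-specific distributions, and its advanced-stage samples are
schematic. Recovery results on synthetic data bound what the pipeline can
do when its own model generated the data; they do not certify performance
on real cohorts.

## 7. Problem sizes and runtime choices

The default study conditions (32 compartments, daily grid over 2,200 days,
64 × 6,384 SGEMs, 10 SGEM seeds, 1,000 permutations, 20 generator seeds
for recovery) run in a few minutes on one CPU and are used as-is by the
acceptance checks. Unit tests scale the gene count down (300–3,000) where
only contracts, not cohort-level statistics, are being checked.

## 8. Known limitations

* The leukemic-lineage parameters (`ε = 0.72`, full CD34 retention) are a
  reconstruction from the cited model family plus a consistency argument,
  not a fit to patient data; the time axis is calibrated only by the
  conventional ~6-year latency.
* No lineage competition, no therapy, no patient-specific proliferation
  rates: the model represents an average untreated disease course.
* The entropy scale is estimator-dependent; only shape features are
  portable across binning schemes.
* Pinning assumes the cohort spans enough of the CD34 axis for min-max
  normalization to be meaningful; very homogeneous cohorts will map
  poorly, and the score axis carries little information in the first
  ~2 years of model time, where the clone is still microscopic.
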