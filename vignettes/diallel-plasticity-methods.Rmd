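---
title: "Models and methods: fold-change plasticity in a full diallel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: fold-change plasticity in a full diallel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelkit)
```

## The trait: fold-change plasticity

`diallelkit` scores the temperature plasticity of a quantitative trait
(flower diameter, FD, in mm) as the fold change between a warm and a cool
growth temperature, FC = FD(23 °C)/FD(17 °C). FC = 1 means a perfectly
stable genotype; FC < 1 means smaller flowers when warm, and a larger
|1 − FC| means greater plasticity. FC is the simplest two-environment
plasticity index and corresponds to the slope of the reaction norm across
the two temperatures; alternative indices (multi-environment slopes,
CV-based measures) are deliberately out of scope.

Measurements arrive as one row per flower, keyed by (mother, father,
temperature, biological replicate, flower). With `b` biological replicates
per genotype per temperature, the pipeline averages flowers within each
replicate and then forms **all b² ordered pairings** of a warm replicate
mean with a cool replicate mean — four FC replicates when b = 2. These b²
values share numerators and denominators, yet all downstream tests treat
them as exchangeable observations. This convention is deliberate (it
mirrors how such data are analysed in practice) and its statistical cost is
quantified at the end of this vignette rather than modelled away.

## Mode-of-inheritance classification

For each non-self cross the mid-parent value MPV is the arithmetic mean of
the two parents' mean FCs, treated downstream as a fixed constant (no error
propagation from the parental estimates). Classification is two-staged:

1. a one-sample two-tailed *t*-test of the cross's FC replicates against
   its MPV, with Benjamini–Hochberg adjustment across all tested crosses
   (132 in a 12-parent design); crosses not rejected at FDR q = 0.10 are
   called **additive**. The BH family size defaults to the number of tested
   crosses but is configurable (`bh_family`), since the appropriate family
   is a modelling choice, not a mathematical fact.
2. rejected crosses are tested against each parent's FC replicates with a
   two-sample two-tailed *t*-test, pooled-variance unless an F-test of the
   variance ratio rejects at α = 0.05 (then Welch's form), with BH
   adjustment across all stage-2 p-values jointly. A cross differing from
   the father only is **dominant_maternal**, from the mother only
   **dominant_paternal**; differing from both *and* lying outside the
   closed interval of the parental mean FCs is **overdominant**; any other
   stage-1 rejection is **nonadditive_unresolved**. Direction is
   `negative` when the hybrid mean FC falls below its MPV (toward greater
   plasticity for FCs below 1).

The α = 0.05 of the variance pre-test and q = 0.10 are defaults of
`run_config()`; both act on every family of the pipeline.

**Degenerate inputs.** Noise-free tables (used heavily in validation) have
zero-variance FC replicate sets, where a *t*-statistic is undefined. All
tests resolve this case by an exact-equality convention at absolute
tolerance 1e-8: p = 1 when the group means agree within tolerance, p = 0
otherwise. This makes noiseless fixtures classify deterministically instead
of erroring.

## Griffing's Method I combining abilities

The cell-mean FCs of the complete n × n table are decomposed as

$$x_{ij} = \mu + g_i + g_j + s_{ij} + r_{ij}$$

with $\sum_i g_i = 0$; $s_{ij} = s_{ji}$, $\sum_j s_{ij} = 0$ for every
$i$; and $r_{ij} = -r_{ji}$. All effects are **fixed**: the parents are the
population of interest, and no inference to unobserved parents is intended
(hence no random-effects/REML path). The estimates are closed forms on the
cell-mean marginals and coincide exactly with the constrained least-squares
projection; because the constrained model is saturated on the n² cells,
fitted cell means reproduce observed cell means, and the test suite checks
the closed forms against an independent normal-equations solver to 1e-8 —
the package-wide numerical tolerance for constraint and oracle checks.

The ANOVA partitions the among-cell sum of squares into GCA, SCA and
reciprocal components with df n−1, n(n−1)/2 and n(n−1)/2. Under the
constraints the three effect subspaces are mutually orthogonal, so the
component SS are computed as squared norms of the fitted effect patterns
(scaled by the per-cell replicate count) and sum to the among-cell SS
exactly. F statistics test each effect mean square against the within-cell
residual mean square; with a single replicate per cell, or unbalanced
replication, F and p are withheld and flagged.

Derived summaries:

* **Baker's ratio** 2·MS_GCA/(2·MS_GCA + MS_SCA) ∈ (0, 1]. The report
  flags values above 0.5 with the label "non-additive gene action", which
  is how the ratio was read in the study design this package follows; the
  conventional quantitative-genetics reading is the opposite (ratios near 1
  indicate *GCA/additive* predominance, since progeny means are then
  predictable from parental GCA). The code computes the printed formula
  exactly and reports both readings without endorsing either.
* **Variance components.** "Variance in GCA/SCA" is not uniquely defined
  for fixed effects; the package takes the sample variance (n−1
  denominator) of the estimated effects — the n GCA values and the
  n(n−1)/2 distinct off-diagonal SCA values (self SCAs excluded by
  default; `include_diagonal_sca = TRUE` adds them). Then VA = 4·Var(g),
  VD = 4·Var(s), and VE = MS_residual / (replicates per cell), i.e. the
  sampling variance of a cell mean. Two heritabilities are reported
  because the with-environment convention is ambiguous:
  h2_narrow = VA/(VA+VD+VE) and h2_no_env = VA/(VA+VD).

**Singularities.** Method I needs every ordered cell; missing cells make
the constrained design matrix rank-deficient. `detect_and_drop_singular_parents()`
computes the rank of that matrix over the available cells and, while it is
deficient, drops the parent with the fewest available cells (ties broken
alphabetically), logging each drop. Fewer than three remaining parents is a
fatal error. This mirrors the common field practice of removing an
accession that destabilizes the fit rather than abandoning the analysis.

## Heritability

The father–offspring regression uses one point per non-self cross
(reciprocals are separate points with their respective pollen parents):
offspring mean FC on the father's own mean FC, h² = 2b for a single-parent
regression. Genotype mean FCs are used rather than the four replicates,
because the replicate structure is pseudo-replicated. Estimates outside
[0, 1] are reported as-is with a flag, never clamped.

A result worth knowing when interpreting simulations: if every offspring
sits exactly at its MPV and the design is a balanced diallel over n
parents, the regression slope is not 1/2 but **(n−2)/(2(n−1))** — 0.4545
at n = 12 — because each father's crosses exclude the self and the mothers
are drawn from the same finite panel. The h² = 2b estimator therefore
carries an intrinsic ≈ n/(n−1) downward attenuation at panel sizes like 12
even before measurement noise; the recovery battery in the test suite
confirms the estimator still lands within ±0.1 of true narrow-sense
heritabilities of 0.2–0.8 at this design size.

Parents (selfs) and hybrids are compared as groups of genotype mean FCs by
a two-sided Wilcoxon rank-sum test — exact enumeration when both groups
have ≤ 25 members and no ties, the tie-corrected normal approximation
otherwise; the reported W is the Mann–Whitney U of the *hybrid* group, a
convention recorded in the output because W depends on it — and by
Levene's test in its Brown–Forsythe form (one-way ANOVA of absolute
deviations from group medians), the robust default of the common
implementations.

## The simulator

`simulate_diallel()` generates per-flower diameters for a configurable
full diallel with known truth. Defaults emulate a realistic 12-accession
study: two temperatures (17/23 °C), two biological replicates per genotype
per temperature grown as separate trials, six flowers per replicate,
baseline diameter 3.6 mm at 17 °C, and parental FCs equally spaced across
[0.79, 1.10].

* **Genetic layer.** Effects act on the FC scale (a `log_scale` switch is
  provided for robustness experiments). Mode `griffing` draws g, s, r from
  configurable SDs and projects them onto the Method I constraints, so
  noiseless runs recover truth exactly; modes
  `additive`/`dominant`/`overdominant` place each hybrid at
  MPV + d·(FC_dom − MPV) with d = 0, 1, > 1 and the dominant parent chosen
  maternally, paternally or at random.
* **Noise layers.** Biological replicate means are drawn around the
  genotype–temperature mean with SD `sigma_rep` = 0.06 mm (trial-to-trial
  variation), and flowers around the replicate mean with
  `sigma_flower` = 0.2 mm (flower-to-flower variation). These defaults
  were fixed once, on the grounds that they give parental
  temperature-contrast tests high but not saturating power across the
  default FC spread (genotypes with |FC − 1| ≳ 0.05 are detectable), which
  is the qualitative behaviour expected of such panels. No published
  within-genotype variance figures exist for this design, so these are
  assumptions, not estimates.
* **Determinism.** All draws flow from one integer seed through R's
  Mersenne–Twister/inversion RNG, recorded in the truth sidecar; the same
  seed reproduces the serialized table byte for byte.

Helper constructors pin down battery conditions: `additive_config_for_h2()`
solves `sigma_g` so that VA/(VA+VE) hits a target heritability (VE from the
delta-method variance of a genotype mean FC), and
`dominant_config_for_ratio()` solves the flower SD so that the smallest
|FC_dom − MPV| in the design equals a chosen multiple of one FC
replicate's SD.

What the generator does *not* emulate: flowering-time covariates,
vernalization or chamber effects, non-Gaussian measurement error,
unbalanced flower counts, genotyping failures, or selection of parents
conditional on observed plasticity. Passing tests therefore demonstrate
correctness of the *procedures* under a clean Gaussian two-layer design,
not robustness to every failure mode of real phenotyping.

## Calibration of the classifier: a known anticonservative bias

Two conventions of the classification procedure jointly inflate its
nominal error rates, and the effect is visible in the package's own
batteries:

* the b² cross-paired FC replicates are treated as independent, but the
  sample SD of four cross-paired values underestimates the SD of their
  mean by a factor of √3 (E[s²] = 4σ²/3 while Var(mean) = σ²);
* the MPV is treated as a known constant, but it is estimated from the
  parents' own FC replicates, adding a further 50 % untracked variance to
  the stage-1 contrast.

The combined inflation of the one-sample *t* is √4.5 ≈ 2.12 and is
scale-free — independent of every noise and effect parameter — so it cannot
be removed by choosing different study conditions, only by changing the
procedure itself (e.g. modelling the FC dependence or propagating MPV
error, both deliberately out of scope). Consequently, on fully additive
simulated diallels the observed non-additive call rate at q = 0.10 is
about 0.14 rather than ≤ 0.10 (500-replicate battery,
`simulate_null_additive_battery()`), and in full-dominance power batteries
the analogous over-rejection of the *null* parent comparison (~24 %,
scale-free for the same reason) caps the fraction of exactly-correct
labels near 0.75 even at large effect/noise ratios — the surplus calls land
in `overdominant`/`nonadditive_unresolved`, while the maternal/paternal
attribution of the dominant calls that are made is essentially always
correct (`inheritance_battery()`). Users comparing non-additive call
counts against the nominal FDR should keep this in mind; the corresponding
acceptance checks assert the nominal bounds and fail, documenting the bias
rather than hiding it.

## Known limitations

* Method I requires the complete n² table; beyond the drop-a-parent rule
  there is no missing-cell estimation path.
* The FC-replicate dependence and plug-in MPV biases above.
* Fixed-effects variance components rest on an ad hoc "variance of
  estimated effects" definition; with n = 12 parents, Var(g) has 11 df and
  is itself noisy.
* h² = 2b from father–offspring regression carries the finite-panel
  attenuation (n−2)/(2(n−1)) · 2 and is further attenuated by measurement
  noise in the father means (a classical errors-in-variables effect that
  is part of what the estimator is defined to measure).
* Exact Wilcoxon enumeration is only used for group sizes ≤ 25 without
  ties; parent-vs-hybrid comparisons at study scale use the tie-corrected
  normal approximation.
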