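---
title: "Methods behind comboscreen: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind comboscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboscreen)
```

comboscreen analyzes drug-combination screens in which every combination is
measured as a full dose-concentration matrix (by default 7 x 7 doses,
log-equispaced over a 1,000-fold range) across an annotated cancer cell line
panel. This vignette documents the statistical models, every tunable
parameter that matters, the choices made where the design was genuinely
open, and the limits of what the synthetic-data tests can show.

## Normalization and the inhibition scale

Raw viability signal (e.g. CellTiter-Glo luminescence) is mapped to a
growth-inhibition scale anchored per plate at 0 = mean of the DMSO-treated
negative controls (NC1) and 1 = mean of the cell-free blanks (B):

$$\mathrm{inhibition} = \frac{\mu_{NC1} - \mathrm{raw}}{\mu_{NC1} - \mu_B}.$$

Normalized values are deliberately **not clipped**: noisy wells legitimately
fall slightly below 0 or above 1, and downstream quality control should see
them. Clipping to $[0, 1]$ is applied only where a probability reading is
required — inside the logistic fit and the Bliss/HSA excess computations —
and reported outputs keep the pre-clip values (a combination Emax slightly
above 1 is an honest description of a noisy well).

## Plate quality control

Three gates are applied per plate, all configurable in `qcThresholds()`:

* **CV** of the DMSO negative controls, $\sigma_N / \mu_N$, must fall below
  0.18 (sample, $n-1$, standard deviations throughout — conventional for
  control wells).
* The **NC-0/NC-1 ratio** (mean untreated over mean DMSO signal) must lie in
  $[0.8, 1.2]$, guarding against solvent effects.
* The **Z-factor**, $1 - 3(\sigma_P + \sigma_N)/(\mu_N - \mu_P)$, must reach
  0.3 for each positive-control class (two cytotoxic agents and the blanks)
  — but only where the line is sensitive to that control
  ($\mu_{NC1}/\mu_{PC} \ge 4$); insensitive controls are skipped, not
  failed. A relaxed bound of 0.2 is available for the small fraction of
  lines with intrinsically weak separation.

Replicate consistency: the numeric criterion behind "significant
inconsistency" across replicates is not uniquely determined by practice, so
`replicateConsistency()` uses a transparent stand-in — a dose point is
flagged when the replicate range exceeds a tolerance $\tau$ (default 0.3 on
the inhibition scale; simple, monotone and unit-consistent), and a drug
fails when flagged at two or more dose points in one line or in two or more
replicate lines. $\tau$ is a parameter, and the rule is labelled a stand-in
here and in the function documentation.

## Dose-response model

Single-agent responses are fitted to a two-parameter logistic with
asymptotes fixed at 0 and 1:

$$E(d) = \frac{1}{1 + (\mathrm{IC}_{50}/d)^s},$$

the standard position-plus-shape choice when the plateaus are pinned by the
normalization anchors. Fits are per experiment (one cell line, one drug) by
least squares; a screen-wide non-linear mixed-effects formulation that pools
information across experiments is intentionally out of scope — the extracted
quantities (Emax at the top screened dose, IC50) are the same, and
per-experiment fits keep every result locally reproducible.

Numerical choices: the optimizer (`minpack.lm::nlsLM`) works on
$(\log \mathrm{IC}_{50}, \log s)$ to enforce positivity, is restarted from a
7 x 3 grid of log-spaced IC50 and slope values (best SSE wins), and is
bounded three decades beyond the tested range. Inputs are clipped to
$[0, 1]$ for fitting. An IC50 landing outside the tested dose range is
reported with a censoring flag (`"right"`/`"left"`) rather than trusted as
an extrapolated potency; on optimizer failure the fit is flagged
non-converged and Emax falls back to the observed top-dose inhibition.

**Combination Emax** is the second-highest inhibition value among the $k^2$
combination wells — an outlier-robust maximum (a single hot well cannot
define the combination's activity). Matrices whose top doses are beyond the
biologically relevant range can be trimmed with `trimMatrix()` (e.g.
7 x 7 to 5 x 5, dropping the two highest doses of both drugs); all scoring
machinery works unchanged on trimmed grids (9 sliding windows instead
of 25).

## Synergy scores

Per-well excess is computed against two null models, using the observed
(normalized, unfitted) single-agent inhibition as marginals, all values
clipped to $[0,1]$:

* **Bliss independence**: expected effect $E_A + E_B - E_A E_B$;
* **HSA** (highest single agent): expected effect $\max(E_A, E_B)$.

Since $E_A + E_B - E_A E_B \ge \max(E_A, E_B)$ on $[0,1]$, per-well Bliss
excess never exceeds HSA excess; the test suite asserts this on random
matrices.

Two summaries are reported per pair and model:

* the **matrix score** — the mean excess over all wells. The mean (rather
  than the per-well maximum) is the primary definition because it is the
  only reading under which dose-localized synergy can coexist with a
  negative whole-matrix score, a configuration that real screens show in
  abundance; the per-well maximum remains available via
  `matrixScore(..., statistic = "max")`.
* the **window score** — the largest mean excess over all contiguous
  3 x 3 sub-matrices (25 on a 7 x 7 grid), with the winning window's
  top-left corner reported 1-based, ties broken row-major (smallest row,
  then smallest column). The window score detects synergy confined to a
  narrow concentration range that the full-matrix average cancels out.

Whether the original analyses computed window means on clipped or raw
excess is not knowable from the outside; comboscreen clips (probability
semantics) and keeps pre-clip values in its outputs.

## Activity calls and prioritization

A (combination, cell line) pair is **active** when combination Emax
exceeds 0.5 and the HSA score exceeds 0.1, both strictly. Which HSA summary
feeds the call is genuinely open; comboscreen defaults to the **window**
score (`hsa_variant = "window"`), for a reason the package's own defaults
make concrete: with the matrix score defined as the 49-well mean, a 0.1
threshold is essentially unattainable for dose-localized synergy — the mean
dilutes a fully expressed 3 x 3 window boost of 0.3 to
$9 \times 0.3 / 49 \approx 0.055$ — and an activity rule that cannot fire
on exactly the localized synergy the window score exists to detect is
self-defeating. The window score is the highest window-smoothed excess,
i.e. the natural "highest value in the matrix" reading at the 9-well
smoothing scale. `hsa_variant = "matrix"` restores the mean-score reading.

Prioritization proceeds per (combination, cancer type):

1. responder rate = percentage of tested lines active, reported to one
   decimal, rounding half away from zero (3/7 prints as 42.9); pairs below
   10% are dropped ("at least 10%" is inclusive, so a type at exactly 10%
   counts as sensitive);
2. combinations sensitive in **half or more** of their tested cancer types
   are dropped entirely (broad activity predicts poor tolerability); the
   per-combination tested-type count, not the panel-wide count, is the
   denominator, since combinations screened on partial panels see fewer
   types;
3. pairs tested in fewer than 10 cell lines are dropped;
4. survivors are scored `responder_pct + specificity_score`, where the
   specificity score is the number of tested cancer types minus the number
   sensitive — activity and selectivity deliberately weighted equally,
   though both terms are exposed for re-weighting — and ranked descending
   (ties: responder percentage, then combination id), split into
   hematological and solid-tumor lists.

Steps 1–3 are pure predicates, so their order cannot change the surviving
set; the tests assert this. Mechanism categories are unordered pathway-pair
labels (`categorizeCombination()`): four base classes (cell death, DDR,
cell signaling, chemotherapy) paired unordered give ten possibilities, of
which chemo+chemo is never screened, leaving the nine categories the
generator's design cycles through.

## Biomarker discovery

Binary molecular features (MOBEM-style: mutations, CNAs, fusions,
methylation, plus expression binarized at $|Z| \ge 2$ **within the analysis
subset**, yielding `GENE_up`/`GENE_down` events) are tested against five
response metrics — both single-agent Emax values, combination Emax, Bliss
matrix and Bliss window — in three kinds of subgroup: pan-cancer, per
cancer type (types with more than 19 lines), and molecular baskets (all
lines carrying a given alteration).

Each test is a one-way ANOVA F-test of the metric on the feature
(equivalently the squared pooled-variance t-test; the suite's fast path
computes it in closed form and the test suite cross-checks it against
`t.test`). Pan-cancer runs add cancer type as a categorical covariate
(sequential sums of squares, feature fitted after tissue) — this soaks up
tissue-driven response differences that would otherwise masquerade as
feature effects; subgroup runs, already conditioned on context, do not.
Arms smaller than 3 lines are reported as skipped, never as $p = 1$.

Significance requires all three of: $p \le 0.001$; Benjamini–Hochberg FDR
$\le 10\%$, computed within each (subgroup x metric) family (the
per-analysis convention of pharmacogenomic ANOVA tooling; the family choice
is documented because it is not forced); and both Glass deltas
$|\bar y_+ - \bar y_-| / s_g \ge 1$, an effect-size floor immune to
sample-size inflation.

**Emergent biomarkers**: a significant association with a combination
metric is emergent when the same feature, in the same subgroup, is *not*
significant for either constituent drug's single-agent Emax of that
combination — monotherapy-driven markers are excluded. The matching scope
(same feature, same subgroup, same combination) is the strictest reading;
matching across subgroups would delete context-specific emergent biology.
Emergent units are partitioned three ways (Bliss-only, both, combination-
Emax-only); the partition is disjoint and exhaustive by construction and
the tests assert that its counts always sum to the emergent total.

## Pathway-pair enrichment

For each mechanism category, `enrichmentOverRandom()` compares the observed
active fraction $E_s = n_c / N_c$ with the fraction under uniform random
redistribution of the $n$ active labels over all pairs (a permutation
null): $n_b$ is the mean per-category active count over `nBoot` replicates
(default 10, matching 10-fold bootstrap practice; raise it for stability)
and $E_r = n_b / N_c$. A category is enriched when $E_s > E_r$. The
wording "random numbers from 1 to n assigned to each pathway combination"
admits a second reading (resampling category labels); the permutation null
is adopted because it conserves the active count exactly per replicate,
which is what "enrichment by random" requires. The empirical p-value
(fraction of replicates reaching the observed count) is an extension beyond
the binary verdict and is labelled as such.

## The synthetic-screen generator

`simulateScreen()` builds well-level screens with the structure the
analysis assumes, plus the ground truth recovery tests need:

* **Curves**: per (line, drug), IC50 log-uniform inside the tested range in
  a `drugSensitiveFraction` (default 0.3) of lines and one to two decades
  above the top dose elsewhere — targeted agents are potent in
  genotype-restricted minorities, and this is what gives combination Emax
  its wide spread; slope uniform on $[0.8, 2.5]$.
* **Matrices**: the noiseless well $(i,j)$ is the Bliss-additive surface of
  the two true curves; a `synergyFraction` (default 0.25) of pairs within
  sensitive cancer types receives a planted 3 x 3 window boost (default
  0.3), and truth is clipped at 1.
* **Window placement**: locations are sampled uniformly among corners where
  *every* well leaves headroom for the full boost. This is not cosmetic: if
  any window well saturates, the clipped boost moves the noiseless excess
  argmax off the planted corner and the planted location stops being the
  right answer even without noise — the ground truth would contradict its
  own construction. Where no corner has headroom the lowest-baseline corner
  is used.
* **Cancer-type selectivity**: each (combination, cancer type) is drawn
  sensitive with probability `typeSelectivity` (default 0.4); windows are
  planted only in sensitive types. Without this, planted synergy is
  uniform across types, every combination is broadly active, and the
  breadth filter empties the prioritization output by construction.
* **Noise**: i.i.d. Gaussian on the inhibition scale (default `noiseSd`
  0.05 — the production screen's well-level noise is not published, so this
  is a free parameter), added *without* clipping so normalization and QC
  see realistic out-of-range values. Control wells are drawn per plate with
  means and SDs whose defaults (negative-control CV 0.1228, Z-factor 0.498
  against the first positive control) sit at the quality mid-range of a
  passing screen.
* **Features and planted biomarkers**: independent Bernoulli features
  (prevalence uniform on $[0.1, 0.4]$); planted single-agent effects shift
  the drug's inhibition (and therefore its Emax and, downstream, the
  combination's response — monotherapy-driven combination activity);
  planted emergent effects shift combination wells only, never single-agent
  curves. Effect sizes are expressed in units of the affected metric's
  noise SD. `simulateResponseTable()` is a distributional shortcut past the
  well level (Gaussian metric baselines, same planting semantics) used
  where thousands of ANOVA tests must run quickly.
* **Determinism**: one global seed expands into per-entity substreams via a
  counter-based hash keyed on entity identifiers, so regenerating with more
  cell lines reproduces the existing ones byte-identically.

What the generator does **not** emulate: pharmacokinetics, Loewe-additive
(dose-shift) interaction surfaces, plate spatial artifacts (edge effects,
drift), correlated feature structure (co-occurring mutations), or
tissue-of-origin effects on response. Passing recovery tests therefore
demonstrate that the pipeline inverts its own generative assumptions — a
necessary check, not evidence about real screens, whose noise is neither
Gaussian nor independent.

## Problem sizes and calibration checks

The package's own calibration and recovery studies (test suite and
`scripts/acceptance.R`) use desk-scale screens chosen so each study
completes in seconds to a couple of minutes while keeping group sizes
statistically meaningful: a default screen of 120 cell lines across 10
cancer types (12 per type, so the 10-cell-line prioritization minimum
bites), 12 combinations over the 9 mechanism categories, 40 features;
window-recovery studies use 200 planted pairs (20 lines x 10 combinations,
`synergyFraction = 1`, `typeSelectivity = 1`); null calibration stacks 20
seeded screens of 100 lines x 6 combinations x 25 features x 5 metrics
(15,000 ANOVA tests). At these sizes the null suite's significant-call rate
must stay at or below the nominal $10^{-3}$ per-test bound, planted windows
must be localized in at least 95% of pairs, and planted emergent effects
recovered with sensitivity at least 0.8 — all recomputed from scratch by
the acceptance script.

## Known limitations

* Per-experiment logistic fits are noisier than a pooled mixed-effects fit
  for weakly responding lines; censoring flags mark where the IC50 is an
  extrapolation.
* Bliss/HSA marginals use observed single-agent wells; a fitted-marginal
  variant would trade robustness against single-well noise for model
  dependence.
* The emergent definition inherits the thresholding of its inputs: a
  feature marginally non-significant for monotherapy is "emergent", however
  close it was to the cut.
* Enrichment reports a binary verdict plus an empirical p at small `nBoot`;
  at the default 10 replicates the p-value granularity is 0.1.
* The ANOVA assumes homoscedastic Gaussian responses within arms; the
  Glass-delta gate partially protects against variance pathologies but the
  p-values are not rank-based.
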