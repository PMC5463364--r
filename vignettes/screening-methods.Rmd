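---
title: "Statistical methods of the dual-plate CRE1/AHK4 screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods of the dual-plate CRE1/AHK4 screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoscreen)
```

## The assay and its readout

The screen measures activation of the Arabidopsis cytokinin receptor
CRE1/AHK4 expressed in an *E. coli* reporter strain: receptor signalling
drives a lacZ (β-galactosidase) reporter, the enzyme converts the
non-fluorescent substrate 4-MUGal into the fluorophore 4-MU, and the
well's response is read as the ratio of end-point fluorescence to
culture density, RFU/OD600. Every well additionally contains a low
(50 nM) concentration of the natural agonist *trans*-zeatin as an
**internal standard**, so the baseline response is a predetermined weak
activation: agonists push the response up from that baseline and
antagonists pull it down, which is what lets one run classify both in a
single experiment.

A 96-position source rack — 93 test compounds plus a positive control
(50 μM tZ), a negative control (a known receptor antagonist) and a
neutral control (DMSO, carrying only the internal standard) — is
stamped in quadruplicate onto a 384-well plate. The default stamping
geometry places each source well on a 2×2 block of the assay plate; an
interleaved quadrant scheme is also available. The choice does not
affect any statistic (there is no spatial correction in this pipeline,
deliberately, because the assay protocol performs none), but the
layout is recorded so that every assay well maps back to its source
tube.

## Normalization and exclusion of failed wells

Each well's response is `rfu_end / od600` (`rfu_od_ratio()`). Wells
whose OD600 does not exceed the **growth floor** (default 0.05
absorbance units, configurable in `test_params()`) carry no
interpretable ratio: with essentially no culture there is no reporter
expression, and the ratio would divide by a near-zero, noise-dominated
denominator. Such wells are excluded from ratio statistics. A compound
for which fewer than two wells grew cannot be tested at all and is
routed to the `indeterminate_growth` category — its receptor effect is
simply not measurable by this reporter system.

## Significance against the internal-standard baseline

The DMSO wells quantify the response to the internal standard alone,
and they serve as the comparison group for every test: per compound, a
two-sample t-test of the quadruplicate RFU/OD600 ratios against the
DMSO wells' ratios. With 93 compounds and the two non-DMSO controls the
rack carries m = 95 independent comparisons, so the per-test level is
Šidák-adjusted:

α_ADJ = 1 − (1 − α)^(1/m) = 5.40 × 10⁻⁴ at α = 0.05, m = 95.

`run_screen()` recomputes m from the manifest when a rack deviates
from the standard 93 + 3 composition.

**Choice of t-test variant.** The pipeline defaults to the pooled
(Student) statistic with n₁ + n₂ − 2 degrees of freedom;
Welch's unequal-variance test is available via
`test_params(t_variant = "welch")`, and `welch_t_test()` exposes it
directly. The default was a genuinely open design point and was decided
by simulation at the screen's operating conditions (two groups of
four, a per-test level of 5 × 10⁻⁴): the Welch–Satterthwaite
approximation is severely conservative that far into the tail at n = 4
— its realized per-test size is roughly 3 × 10⁻⁴ instead of the
nominal 5.4 × 10⁻⁴ — which silently halves the screen's false-positive
budget and costs real power at the hit-calling boundary. The pooled
test holds its nominal size there, at the price of assuming comparable
replicate variances, which technical quadruplicates pipetted by the
same liquid handler do satisfy. Degenerate inputs follow fixed
conventions: two zero-variance groups with equal means give p = 1,
with unequal means p = 0, both flagged.

## Quality control: Z′-factors

Plate quality is summarized by two Z′-factors,
Z′ = 1 − 3(σ₁ + σ₂)/|μ₁ − μ₂|, one for the positive control against
the internal standard and one for the internal standard against the
negative control. On the calibration run's printed control statistics:

```{r zprime}
z_prime_factor(125728, 3235, 42427, 1292)  # positive vs internal standard
z_prime_factor(42427, 1292, 898, 143)      # internal standard vs negative
```

i.e. 0.84 and 0.90 at the conventional two-decimal reporting. A plate
whose positive-control mean does not exceed the internal standard (or
whose negative control does not fall below it) cannot anchor
classification; `hit_thresholds()` signals a QC failure and
`run_screen()` aborts with diagnostics rather than classify against
meaningless anchors.

## Five-class hit sorting

Classification anchors to the plate's own controls, not to fixed
response values. The hit-defining levels are arithmetic midpoints on
the linear ratio scale (the scale on which the assay reports its
responses; no transform is applied because none is part of the assay's
definition):

* strong-agonist level = (μ_IS + μ_pos)/2,
* strong-antagonist level = (μ_IS + μ_neg)/2.

Precedence of the rules, a deliberate pipeline decision (growth >
artifact > significance > magnitude):

1. complete growth failure → `indeterminate_growth`;
2. any fluorescence-artifact flag → `interference`;
3. p ≥ α_ADJ → `neutral`;
4. mean ratio ≥ strong-agonist level → `strong_agonist` (closed bound:
   "at least mid-way");
5. mean ratio above the internal standard → `agonist`;
6. mean ratio ≤ strong-antagonist level → `strong_antagonist` (closed
   bound on the strong side);
7. otherwise → `antagonist`.

Categories are exhaustive and mutually exclusive, and the assignment
is monotone in the response: a larger true response can never move a
compound toward the antagonist side.

A significant OD600 *decrease* of roughly 20% accompanies strong
receptor activation (intense reporter expression slows growth), so a
`growth_suppressed` flag on an agonist call is reported as a
corroborating `secondary_od_marker` annotation; it never changes the
category. Growth suppression and promotion are themselves decided by
the same two-sample test at α_ADJ on the OD600 replicates.

## The reference-plate counter-screen

Compounds can fluoresce like 4-MU or quench its fluorescence, producing
false agonist or antagonist calls. A second plate, treated identically
but never given substrate, isolates these optical properties:

* **pre-spike read** — raw fluorescence of compound + culture; a
  significant excess over the DMSO wells flags `autofluorescent`;
* **post-spike read** — after a fixed 4-MU spike in every well; a
  significant deficit flags `quencher`, a significant excess flags
  `additive_interaction`.

All three are directional verdicts layered on the same two-sided test
at the shared α_ADJ — one family-wise error policy for the whole
screen. Effect sizes (ratios to the DMSO mean) are reported for triage
but never thresholded: verdicts are significance-only. The tests run on
raw RFU, not ratios, since no enzymatic product is present and OD
normalization would only add noise. Any fluorescence flag demotes the
compound's category to `interference`; whether to re-assay such a
compound is left to the user. Note that the pre-spike and post-spike
channels are two separate test families: each family's false-flag rate
is held at α by the Šidák construction, so the probability of *some*
flag of *either* kind on a clean plate is bounded by roughly
1 − (1 − α)² rather than α.

## The synthetic plate generator

No raw plate data accompany the assay's published description, so the
package carries a generative model calibrated to the printed control
statistics, and all pipeline-level tests run against it.

* **Response noise.** A well's ratio is its expected response times a
  multiplicative Gaussian of the appropriate CV. The printed control
  dispersions — 42,427 ± 1,292, 125,728 ± 3,235, 898 ± 143 (CVs 3.0%,
  2.6%, 15.9%) — are three anchors of an SD-versus-mean curve; the
  generator interpolates SD piecewise-linearly between them (constant
  outside the span). At the anchors the simulated controls reproduce
  the printed CVs exactly. The interpolation, rather than reusing a
  class's raw CV everywhere, reflects that the negative control's
  15.9% CV is a property of its near-zero mean (SD 143), not of
  mid-range responses; variance growing with the mean is the behaviour
  real plate data show.
* **OD600.** Baseline 0.5 with 5% log-normal noise (kept positive by
  construction) — a plausible 5-h density for this culture format —
  scaled by the compound's growth effect and reduced by up to 20%
  (the printed magnitude) in proportion to the activation fraction,
  the compound's position between the negative- and positive-control
  responses. Because activation of the internal standard itself is
  fractional, every well shares that partial reduction; only the
  *relative* OD differences matter to the pipeline.
* **Reference plate.** The protocol publishes no reference-plate
  magnitudes, so they are free parameters chosen once: background
  1,000 RFU, spike 50,000 RFU (the standard dominating 50:1), 2%
  technical CV typical of replicate plate-reader reads of a pure dye.
  Pre-spike signal is background plus the compound's own fluorescence;
  post-spike adds the spike and multiplies by the compound's quench
  factor.
* **Randomness.** One integer seed drives everything; each well draws
  from a stream keyed by (plate, well), so adding or editing one
  compound's truth never perturbs any other well, and emitted files
  are byte-identical across runs of the same seed.

The model emulates the control calibration, multiplicative noise,
growth effects and optical artifacts. It deliberately does *not*
emulate spatial plate effects (edge evaporation, thermal gradients),
reader drift, carry-over, or compound degradation during incubation —
so passing tests demonstrate the statistics and logic of the pipeline,
not robustness to those instrumental pathologies, which the assay
protocol addresses upstream (heated-lid incubation, controlled
temperature).

The packaged **reference scenario** (`reference_truth()`) plants the
demonstration run's outcome — 19 agonists, 12 antagonists of which 3
strong, 1 growth suppressor, 61 neutral among 93 compounds — with
planted responses spread across each category's band but kept at least
about 5 internal-standard SDs clear of every decision boundary, so
recovery measures the pipeline rather than boundary luck.

Simulation-based checks in the test suite use 50 seeds for
class-recovery, 1,000 plates for the null false-hit calibration and
300 seeds for artifact-detection rates; these sizes put the Monte
Carlo error comfortably below the margins being asserted.

One consequence of the assay's common-control design is worth knowing:
because every compound is compared against the *same* four DMSO wells,
the 93 null tests are positively correlated, and the realized
family-wise false-hit rate on an all-neutral plate is ≈ 0.03 — inside
the nominal Šidák band but below the independent-test value of
1 − (1 − α_ADJ)⁹³ ≈ 0.049.

## Binding validation

A hit may act downstream of the receptor (on the signalling cascade or
the reporter enzyme), so validated hits must displace the radiolabelled
natural ligand [³H]tZ from the receptor's binding site in live cells.
The pipeline normalizes counts to **percent displacement**,
100 × (cpm_total − cpm_compound)/(cpm_total − cpm_reference), anchored
at the tracer-only control (0%) and the saturating 10 μM tZ reference
(100%); values outside [0, 100] are reported unclamped so assay
problems stay visible, and the statistic is invariant to any constant
counting background. Dose-dependence is established by a one-sided
Kendall rank trend of displacement against log₁₀ concentration at
α = 0.05 — deliberately *not* a four-parameter logistic fit, which
would be standard methodology but over-model a screen-stage readout
that claims only "dose-dependent competition". When the
per-concentration means bracket 50%, a half-displacement concentration
is interpolated log-linearly between the bracketing concentrations; it
is a descriptive summary, not a Ki (no tracer Kd is available).

## Numerical and degenerate-input conventions

* Sample SDs use the n − 1 denominator throughout; Z′ is stored at
  full precision and conventionally rounded to two decimals only for
  reporting.
* `sidak_alpha()` is computed via `expm1`/`log1p` for accuracy at
  small α.
* Dilution arithmetic (`dilution_concentration()`) uses the nominal
  final volume as protocols state it (2 μl into "40 ml" is 1/20,000),
  which reproduces stated protocol concentrations exactly; it returns
  exact arithmetic and never re-rounds to a protocol's printed value.
* Boundary ties in classification are closed on the strong side
  (≥ strong-agonist level, ≤ strong-antagonist level).
* Report and truth-table writers emit full-precision decimal text so
  write→read round-trips are exact.

## Known limitations

* No spatial plate-effect correction (B-score, median polish): the
  assay protocol performs none, and the generator plants none.
* Single-concentration screening cannot estimate potency (EC50/IC50)
  and cannot distinguish competitive from uncompetitive antagonism;
  both depress the reporter signal.
* The m = 95 correction treats the two non-DMSO controls as part of
  the tested family, following the assay's own accounting; with racks
  of other compositions m is recomputed from the manifest.
* Artifact verdicts are per-channel significance calls at n = 4; a
  compound quenching by only a few percent will pass the counter-screen
  and slightly bias its screening-plate response.
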