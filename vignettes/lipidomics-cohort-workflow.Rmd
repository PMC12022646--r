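---
title: "Methods: quantification, QC batch correction and variability analysis for targeted lipidomics cohorts"
author: "lipidcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, QC batch correction and variability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Scope

`lipidcohort` implements the statistical chain of a large targeted
(SRM) clinical lipidomics study with repeated measures: converting peak
areas to concentrations by stable isotope dilution, removing type-II
isotopic interference between coeluting same-class species, correcting
between-batch signal drift against periodic reference-plasma QC
injections, filtering species on analytical reproducibility, and then
asking the two scientific questions such cohorts are acquired for — how
individual and temporally stable are lipid profiles (variance
components, ICC, distance-based clustering), and how do they differ
between sexes (per-lipid mixed models with FDR control).

Because individual-level cohort data of this kind cannot be shared, the
package carries a first-class synthetic cohort generator whose defaults
encode the study design the methods were built for; every stage is
validated against the generator's ground truth rather than against an
inaccessible data set.

# Quantification by stable isotope dilution

In HILIC separation, lipids elute by polar head group, so every species
coelutes with the isotope-labelled internal standards (IS) of its own
class. The concentration estimate is

$$\hat c_{il} \;=\; \frac{A_{il}}{A_{i,\mathrm{IS}(l)}}\; \cdot\; c^{\mathrm{spike}}_{\mathrm{IS}(l)}$$

for injection $i$ and lipid $l$. Any per-injection factor (matrix
effect, source sensitivity) multiplies both channels and cancels in the
ratio; the package's scale-equivariance test asserts exactly this
contract. A zero analyte area is kept as a valid "below detection"
measurement, whereas a missing or non-positive IS area invalidates the
cell — the distinction matters downstream because CVs computed over
silently zeroed cells would be biased.

**IS assignment.** "Most structurally similar IS of the same class" is
not a fully specified rule; the package makes it deterministic: minimise
$|\Delta$carbons$|$, break ties by $|\Delta$double bonds$|$, then by
lexicographic IS id. Any other monotone tie-break would be equally
defensible; this one is auditable and order-independent, which the tests
verify by permuting the standards table.

No response-factor adjustment is applied for neutral lipids: saturated
IS acyl chains under- or over-estimate polyunsaturated TG and CE
species by an unknown factor, and correcting that requires external
calibration data that is out of scope here.

# Type-II isotopic overlap correction

At unit quadrupole resolution the M+2 isotopologue (two ¹³C) of a lipid
falls on the transition of the same-class, same-carbon species with one
*fewer* double bond: each double bond removes two hydrogens, so that
neighbour is exactly two mass units heavier. Interference therefore
flows from the more unsaturated species (donor, $db = d+1$) to the more
saturated one (acceptor, $db = d$); the most unsaturated species of a
chain receives no interference. (Note the direction: a species'
M+2 is *heavier* than it, so it contaminates the *heavier* = more
saturated neighbour.)

The interference fraction uses the carbon-only binomial model,

$$f(n) = \binom{n}{2} p^2 (1-p)^{n-2}, \qquad p = 0.0107,$$

the probability of exactly two ¹³C among $n$ carbons; isotopes of other
elements are negligible at this resolution. Correction proceeds in
topological order (decreasing double bonds within each (class, carbons)
chain):

$$A^{\mathrm{corr}}_{\mathrm{acceptor}} = A^{\mathrm{obs}}_{\mathrm{acceptor}} - f \cdot A^{\mathrm{corr}}_{\mathrm{donor}},$$

floored at zero. On noise-free data this inverts the forward
contamination model exactly (the tests require $<10^{-9}$ relative
error). In `precursor_and_fragment` mode $f$ is scaled by
$\binom{n_f}{2}/\binom{n}{2}$ — the chance that both heavy carbons sit
in the monitored fragment — when the registry provides fragment carbon
counts; otherwise the mode falls back to the precursor-only fraction
with a warning. This is a documented reconstruction of the published
correction approach for class-resolved SRM data; numerical parity with
any specific external tool is not claimed.

Correction is applied on the **area scale before quantification**
(isotopic overlap is a property of the measured signal); the container's
state machine encodes this order
(`raw_area -> isotope_corrected -> concentration -> batch_corrected`)
and refuses to move backwards.

# QC-anchored batch correction

Between-batch drift is estimated per lipid from reference-plasma QC
injections only, via the categorical regression `lipid ~ batch`, whose
coefficients are identically the per-batch QC means. All samples of a
batch are then shifted by `- batch_mean + grand_mean`, the grand mean
being the unweighted mean of the batch estimates. Two properties define
correctness and are asserted to machine precision: after correction the
per-lipid QC batch means all equal the grand mean (fixed point), and
fit+apply applied twice equals once (idempotence).

Numerical and design choices:

* **Scale.** The default corrects reported concentrations additively,
  as the method is written; a `log2` option handles strictly
  multiplicative drift. The synthetic generator injects offsets on
  either scale so the robustness of the additive default against
  multiplicative truth is itself tested (the recovery criterion passes
  with multiplicative offsets of SD 0.1 log2).
* **Estimability.** A batch mean requires at least two non-missing QC
  values; otherwise that batch gets the grand mean of the remaining
  batches imputed, flagged. QC missing values are dropped pairwise per
  lipid.
* **Negative corrected concentrations are retained**, only flagged:
  clipping at zero would bias downstream CVs and variance components.
  They are floored at zero only at the modelling transform (below).
* **Run order.** A nested-model F-test (`lipid ~ batch` vs
  `lipid ~ batch + order`) is provided to reproduce the decision that
  within-run drift terms are unnecessary; the covariate is off by
  default.
* **RMSE in the recovery tests** is computed on the concentration
  scale (the scale the correction operates on).

**Retention filter.** Species are kept when their post-correction
between-batch QC CV ($100\cdot$SD/mean) is below 30%. Reference plasma
is a different matrix from the study population, so a species that is
poorly measurable in the QC material can still be robust in study
samples; such species are rescued when detected (non-missing, $>0$) in
at least 80% of study samples, and every decision carries its reason.
The 80% detection cutoff is this package's parameterisation of a
narratively described rescue rule.

# Variability, ICC and individuality

**CVs.** The within-subject CV of a lipid is the arithmetic mean over
participants of each participant's CV across time points (the median is
reported alongside; participants need $\ge 2$ non-missing values); the
between-subject CV is the CV of participant means. Note two small-$n$
facts the tests account for: the sample SD of 3 points underestimates
$\sigma$ (factor $c_4(3)\approx 0.886$), and participant means of $T$
points carry $\sigma^2_w/T$ of within noise, so with equal variance
components the between CV sits a predictable $\sim$30% above the within
CV rather than exactly matching it.

**ICC.** Per lipid, a REML mixed model
`log2(conc + 1) ~ sex + (1 | participant)` yields
$\mathrm{ICC} = \sigma^2_b/(\sigma^2_b + \sigma^2_w)$, clipped to
$[0,1]$; non-convergence yields a missing value with a diagnostic,
never a silent zero. The `log2(x + 1)` transform matches the sex model
for cross-module consistency. Because analytical noise adds to the
residual, the estimated ICC is mildly attenuated relative to the purely
biological ratio (about 0.47–0.48 observed when the biological truth is
0.50 under ~8–15% analytical CV) — the parameter-recovery test passes
within its band with this attenuation included, which is the honest
end-to-end behaviour of the pipeline. Conversely, *uncorrected* batch
offsets inflate the apparent ICC, because whole participants are nested
within batches and a batch offset masquerades as shared individual
signal; the pipeline tests assert this direction explicitly.

**Individuality.** Twenty participants with complete time-point
triplets are sampled; columns are mean-centred and unit-variance
scaled; pairwise Euclidean distances are split into within-participant
and between-participant sets. The test statistic compares the 20
per-participant mean within-distances against the pooled
between-distances with a two-sided Welch t-test: the within side is
reduced to one value per participant to avoid pseudo-replication, while
the between side is left pooled. The shared-endpoint correlation among
between-distances makes this test conservative under the null (empirical
type-I error below nominal in the package's simulations), which is the
safe direction for a claim of individuality. Metric and linkage
(Euclidean, average) are conventions, configurable; the distance
summary is invariant to column order and global rescaling by
construction of the UV scaling. The dendrogram is exported as Newick.

**PCA** is ordinary SVD-based PCA of the mean-centred UV-scaled matrix,
cross-checked in the tests against an eigendecomposition of the
correlation matrix.

# Sex differences

Per lipid, the REML mixed model is

$$\log_2(c + 1) \sim \mathrm{sex} + \mathrm{age} + \mathrm{sex{:}age} + (1 + \mathrm{age} \mid \mathrm{participant}),$$

with sex coded female = 1, male = 0 (positive coefficients = higher in
females) and age centred at the cohort mean, so the sex coefficient *is*
the marginal female−male contrast at the mean age. Effects are reported
as percent differences $(2^\beta - 1)\times 100$, which fixes the log
base at 2. p-values are BH-adjusted across all modelled lipids.

Choices and fallbacks:

* **Random-slope singularity.** When the participant-level age-slope
  variance is (near) zero the full fit is singular; the lipid is refit
  with a random intercept only and flagged. Designs with fewer than
  three time points never attempt the slope.
* **Degrees of freedom.** Kenward–Roger machinery is not available in
  this dependency set; the package uses the between-subject
  approximation $df = n_{\mathrm{participants}} - 2$, which at cohorts
  of hundreds of participants is indistinguishable from finer
  approximations (the acceptance checks are df-method agnostic). The
  choice is recorded in the result table via the `df` column.
* **No z-standardisation by default.** Standardising the response to
  unit variance would make $(2^\beta-1)\times100$ no longer an exact
  percent difference; a `z_scale` flag exists for users who want
  standardised coefficients and accept approximate percent conversion.
* **Label-swap antisymmetry** ($\beta \to -\beta$ exactly) holds when
  the random structure is pinned; lipids sitting on the singularity
  boundary can switch structure between fits and blur the last digits,
  which is why the exactness test pins the structure.

# The synthetic cohort: what it states and what it omits

Defaults are the stated world, chosen once:

| Parameter | Default | Rationale |
|---|---|---|
| participants × time points | 364 × 3 (baseline, +5 y, +10 y) | cohort design the methods target |
| batches / QC cadence | 13 plates; QC every 12 study injections + start/end; 1 blank | plate layout with bracketing reference plasma |
| panel | 157 species, 22 classes (counts ∝ a 782-species panel, ~5× down) | desk-speed with preserved class structure |
| class scales | 5 nmol/L (PG) … 5×10⁶ nmol/L (CE) | six orders of magnitude span |
| biological variation | total SD 0.5 log2; ICC 0.6 | lipidome is strongly individualized |
| sex effects | every lipid, 5–30%, random sign | reported effect-size range |
| age trends | per-lipid slope SD 0.4%/year | small relative to sex effects |
| batch offsets | SD 0.1 log2, multiplicative (additive option) | ~7% between-batch drift |
| analytical CV | 8% most classes; 15% CE/DG/TG; 25% PS | ~8.5% median QC reproducibility; coeluting neutrals and near-LOD PS worse |
| age | N(52.7, 5.2²) at baseline | middle-aged healthy cohort |
| IS/areas | nominal IS area 10⁵; shared per-injection factor SD 0.25 log2 | exercises the ratio's matrix-effect cancellation |

Block randomization deals shuffled sex-interleaved participants to
batches in (F, M) pairs, so per-batch sex proportions track the cohort
and all of a participant's samples share one batch in randomized order
— both are asserted properties, not hopes.

The generator deliberately omits: within-run drift (beyond the optional
covariate's null), chromatographic artefacts and peak integration
error, non-lognormal heavy-tailed outliers, correlated lipids
(species are simulated independently given class scale), real
matrix-effect heterogeneity between reference plasma and cohort plasma
(the QC truth equals the species baseline), and missingness other than
optional left-censoring at a class LOD. A green test suite therefore
establishes that the estimators recover the stated generating model —
not that the model captures everything real data do.

# Known limitations

* Quantification accuracy for neutral lipids is bounded by the
  saturated-IS convention (no response factors).
* The isotope correction covers only Δdb = 1 (M+2) interference within
  a class; cross-class isobars are assumed chromatographically
  separated, and M+1 type-I effects are not modelled.
* The additive batch correction can over-correct low-abundance samples
  under strongly multiplicative drift; use the `log2` scale option in
  that regime.
* p-values rely on a simple df approximation; for small cohorts
  (tens of participants) a dedicated df method would be preferable.
* The individuality t-test is conservative under the null; its p-values
  should be read as bounds, not exact tail probabilities.
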