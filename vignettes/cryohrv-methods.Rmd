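---
title: "Methods: HRV features, the ANSI composite, and rank-based longitudinal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV features, the ANSI composite, and rank-based longitudinal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryohrv)
```

`cryohrv` implements the analytic chain of a two-arm whole-body
cold-stimulation (cryostimulation) study of cardiac autonomic control:
heart rate variability (HRV) features from RR-interval series, the
Autonomic Nervous System Index (ANSI) composite, and nonparametric
rank-based inference for the resulting longitudinal factorial design. This
vignette records the statistical model behind each stage, the tunable
parameters, the numerical choices, and the limits of what the synthetic
cohorts can establish.

## The design

Each subject belongs to one treatment arm (exposure at −55 °C or −110 °C;
by default 15 and 8 subjects, the sizes of the cohort the package's
defaults emulate) and is measured on four occasions: before (`pre`) and
after (`post`) the first (`T1`) and the last (`T10`) of ten daily
sessions. In split-plot terminology this is an F1-LD-F2 design: treatment
is the whole-plot (between-subject) factor, time and phase are sub-plot
(within-subject) factors. A cohort table is long-format with one row per
subject × time × phase and carries eleven analysis variables: `rr_mean`,
`rr_tp`, `rr_lfa`, `rr_hfa`, `rr_lfnu`, `rr_hfnu`, `rr_lfhf`,
`delta_lfnu`, `ansi`, `sap`, `dap`.

## HRV feature extraction

Input is a beat-by-beat RR-interval series in milliseconds (one value per
line in file form). Time-domain indices are the mean RR interval and the
total power `rr_tp`, i.e. the sample variance of the intervals (n−1
denominator), the classical vagal markers.

The frequency-domain path follows standard short-term HRV practice:

1. **Resampling.** The tachogram is interpolated with a natural cubic
   spline on the cumulative beat times and sampled at `fs = 4` Hz. The
   field's tools use rates between 2 and 8 Hz; 4 Hz places the Nyquist
   frequency (2 Hz) far above the bands of interest.
2. **Detrending.** The mean and a linear trend are removed; slow drift
   would otherwise inflate power below the LF band.
3. **AR fit.** An autoregressive model of fixed order 12 is fit by the
   Yule–Walker / Levinson–Durbin solution (`stats::ar.yw`), which is
   guaranteed stable on finite data. The order is configurable; 12 is a
   common compromise for 5-minute recordings — high enough to resolve one
   LF and one HF oscillation plus noise poles, low enough to avoid
   spurious peak splitting. No automatic order selection is performed, so
   outputs are deterministic in the input.
4. **Spectral decomposition.** The AR polynomial is factored into poles;
   each real pole or complex-conjugate pair defines one spectral component
   whose central frequency is the pole angle (in Hz at rate `fs`) and
   whose power is the residue of the AR spectral density at that pole
   (conjugate pairs summed, giving a real power). The residues sum to the
   modelled process variance, so component powers are an additive
   decomposition of the variance in ms².

Band powers use the conventional edges: LF `[0.04, 0.15)` Hz, HF
`[0.15, 0.40]` Hz, VLF below 0.04 Hz. These are consistent with the LF
(~0.1 Hz) and HF (~0.25 Hz, respiration-synchronous) centre frequencies
the analysis is built around. Normalized units exclude VLF:
`lf_nu = 100·lf_a/(lf_a+hf_a)`, `hf_nu = 100 − lf_nu`,
`lf_hf = lf_a/hf_a`. When neither band holds power the normalized units
are undefined (`NA`); when only HF is empty the ratio is `Inf` while the
normalized units remain defined. The orthostatic index `delta_lfnu` is the
stand-minus-rest difference in `lf_nu` from the paired recordings of one
occasion.

Numerical details worth knowing: residues of very weak components can come
out marginally negative (a known artifact of the residue method); they are
clamped to zero, which is why power conservation is verified to 10 % in
the tests rather than exactly. A flat (zero-variance) series yields an
empty component table. Inputs are assumed to be clean sinus-rhythm
interval series: there is no ectopic-beat or artifact correction.

The interpolation step acts as a mild low-pass filter at frequencies
approaching the mean beat rate, so HF power is recovered with slight
attenuation relative to LF at typical resting heart rates. The tests
account for this where powers of equal-amplitude rhythms are compared.

## The ANSI composite

The ANSI condenses three informative inputs — mean RR, RR variance, and
`delta_lfnu` — into one 0–100 score, free of age/sex bias by construction:

1. **First-stage percentile ranks.** Each input is percentile-ranked
   within the subject's age-by-sex class over the ranking population (the
   analyzed cohort by default, all occasions pooled; an external normative
   table can be supplied). The PR formula is a Hazen-type plotting
   position, `PR = 100·(midrank − 0.5)/n`: symmetric, tie-aware through
   mid-ranks, maps a singleton to 50, and never attains 0 or 100 on finite
   data — consistent with a score "ranging in [0, 100]". Classes default
   to decades 20–69 crossed with sex; the boundaries are configurable
   because no canonical partition exists.
2. **Radar triangle.** The three PRs are drawn as distances along three
   axes 120° apart; the enclosed triangle has area
   `(√3/4)·(ab + bc + ca)`. The formula is symmetric in its arguments, so
   the axis ordering is immaterial.
3. **Second-stage percentile rank.** Areas are PR-transformed over the
   whole ranking population (not within class: the first stage already
   removed age/sex location effects, and re-stratifying would shrink the
   reference set of an already small study).

The construction is invariant to any strictly increasing within-class
transform of an input and to class-wise constant shifts — it sees ranks,
not magnitudes. That is also its robustness: an outlying value can move
its own ranks but cannot exert leverage. Note that an outlier does
perturb its classmates' first-stage PRs by one class rank step, which can
re-order nearby triangle areas; the two-stage construction bounds
influence, it does not make other subjects' scores exactly fixed.

## Rank-based inference for the F1-LD-F2 design

Hypotheses are formulated on the cell-wise marginal distribution functions
`F_gts`: equality of the unweighted group averages for the treatment main
effect, of time averages for time, of phase averages for phase, and the
corresponding additive decompositions for the first- and second-order
interactions. No distributional assumptions are made and outliers carry no
leverage, which is why this methodology suits a 23-subject study of
skewed HRV variables.

**ANOVA-type statistic.** All `M = 4N` observations are pooled and
mid-ranked. Subject `i`'s four normalized placements
`(R − 0.5)/M` form a vector `Y_i`; cell-wise means give the relative-effect
vector `p̂` and the group-wise empirical covariances give
`V̂ = N ⊕ S_g/n_g`, respecting within-subject dependence and
between-subject independence. For each hypothesis with projection matrix
`T`, the statistic is `F = N·p̂'Tp̂ / tr(TV̂)`, referred to an
`F(f̂, f̂₀)` distribution with Box-approximated numerator df
`f̂ = tr(TV̂)²/tr((TV̂)²)`.

**Denominator degrees of freedom.** The package uses the group-wise Box
(Satterthwaite-type) denominator `f̂₀ = tr(TV̂)² / Σ_g tr(T_g V̂_g)²/(n_g−1)`
for *all seven* effects, not only those involving the whole-plot factor.
The large-sample convention refers sub-plot effects to `F(f̂, ∞)`, but the
variance estimate behind the phase contrast at 15 + 8 subjects carries an
effective df around 14, and the unbounded reference is visibly liberal at
that size (empirical size ≈ 0.065 instead of 0.05 in the package's own
null simulations; with the finite denominator every effect's empirical
size sits inside the 99 % Monte-Carlo band, and the test tracks an exact
within-subject permutation reference to ~0.01). `f̂₀` grows without bound
with the group sizes, so the large-sample behaviour is unchanged. The df
are reported in every result row.

**Baseline adjustment and relative effects.** Effect sizes are computed on
baseline-adjusted values `X̃ = X − x(T1, pre)`, which puts subjects on the
same footing; every subject's adjusted T1-pre value is exactly 0, so the
two arms' estimated effects coincide at T1-pre. The relative effect of a
condition `c` is the probability that a random observation from the pooled
set is smaller than one from `c` (ties counted half) — estimated as
`(mean mid-rank in c − 0.5)/M`, with 0.5 meaning no stochastic tendency.
Confidence intervals use an asymptotic normal approximation whose variance
is assembled from per-subject linearized contributions (each subject
contributes both through their observation in `c` and through all four of
their observations in the pooled reference), clipped to `[0, 1]`; a
logit-scale variant is available for estimates near the boundaries.
Decision rules: a condition differs from the pooled set iff its CI
excludes 0.5; two conditions differ iff their CIs are disjoint.

Because the published pre/post relative-effect pairs sum to one within
each time level, which identifies ranking within time, the package emits
*both* labelled scopes — jointly over the four time-by-phase conditions
(`"condition"`) and separately within each time level (`"within-time"`) —
rather than guessing which convention a given report used. Marginal phase
and time scopes and the per-treatment profile scope are also available.

No multiplicity correction is applied across the eleven variables (the
analyses are reported at a fixed 0.05 level, matching the practice the
package emulates); `stats::p.adjust` can be applied downstream if wanted.

## The synthetic cohort generator

The generator exists to make every stage testable and calibratable without
clinical data. Each core variable (`rr_mean`, `rr_tp`, `rr_lfa`, `rr_hfa`,
`delta_lfnu`, `sap`, `dap`) is a per-subject gaussian baseline plus
configurable additive treatment/time/phase shifts plus occasion-level
noise. Defaults: 15 + 8 subjects, ages uniform on 20–69, P(female) =
18/23, baselines near mid-life resting values of adults with obesity
(e.g. RR mean 900 ± 80 ms, total power 1400 ± 700 ms²), all effect sizes
zero (a global null), and within-subject noise at half the between-subject
spread (intraclass correlation 0.8 — repeated HRV measurements are
strongly subject-correlated). Power variables are floored at 1 to keep
them positive; normalized indices are derived from the absolute powers
(`rr_lfnu = 100·lfa/(lfa+hfa)`, etc.) so their defining identities hold by
construction, and configured effects on the absolute powers propagate to
them. The RR-series generator lays beats down sequentially with
sinusoidal LF/HF modulation evaluated at the cumulative beat time, a
randomized HF phase (avoiding accidental phase-locking in tests), and
white gaussian RR noise.

What the generator does *not* emulate: 1/f spectra and nonstationarity,
ectopy and artifacts, skewed/heavy-tailed marginals, respiratory-frequency
drift, or any realistic coupling between variables beyond the shared
subject baseline. Passing tests therefore demonstrate that the
*procedures* are correct and calibrated under controlled conditions — not
that any clinical conclusion holds in real data.

Simulation sizes used by the test and acceptance suites are chosen to keep
Monte-Carlo error meaningful at desk scale: 2,000 replicates for size
(99 % MC band ± 0.013 around 0.05), 500 per effect size for power curves,
10,000 permutations for the oracle comparison, 50 seeded series for
frequency-recovery summaries.

## Known limitations

- The AR residue decomposition clamps occasional small negative component
  powers to zero; exact power conservation is only approximate.
- HF power is slightly attenuated by tachogram interpolation at low beat
  rates (above), a property shared by all interpolation-based HRV
  pipelines.
- Normative reference tables for the ANSI are study-specific; ranking
  against the analyzed cohort makes scores relative to that cohort, and
  cross-study score comparisons require a common external reference.
- The rank procedures refuse incomplete designs by default; available-case
  handling of missing cells is out of scope.
- With very small groups (2–3 subjects per arm) the asymptotic CIs of
  relative effects are rough; the permutation machinery in the test suite
  is the safer reference at such sizes.
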