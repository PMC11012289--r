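---
title: "Models and design of the screening triage pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the screening triage pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screentriage)
```

`screentriage` implements a complete triage cascade for single-concentration
ultra-high-throughput enzyme-inhibition screens, together with a synthetic
campaign generator that makes every stage testable against known ground
truth. This vignette explains the underlying models, the parameters a user
might want to change, the numerical choices made where the mathematics was
open, and what the synthetic validation does and does not demonstrate.

## The cascade

A campaign proceeds through fixed, auditable stages, each a pure predicate
over the previous stage's measurements:

1. **Primary screen.** Every compound is read once at 10 µM in the
   fluorogenic assay on 1536-well plates (32 × 48; two columns of
   enzyme-plus-vehicle "high" controls, two of no-enzyme "low" controls,
   1408 compound wells). Plates are gated on
   `Z' = 1 − 3(σ_h + σ_l)/|μ_h − μ_l| ≥ 0.6` and `S/B = μ_h/μ_l ≥ 3`;
   failing plates are re-queued once with fresh reads.
2. **Active calling.** Per-plate robust Z-scores
   `z = (x − median)/(1.4826·MAD)` over the compound-well population;
   actives at `z ≤ −4` (inclusive, as are all thresholds below).
3. **Bayesian augmentation.** A Laplacian-corrected naive Bayes model over
   binary fingerprints is trained with the primary actives as positives and
   the whole screened library as background; the top 500 ranked compounds
   are unioned into the list, guarding against single-read false negatives.
4. **Confirmation and orthogonality.** The augmented set is re-read in the
   fluorescence assay (confirm at `z ≤ −4`); compounds at ≥ 30% effect in
   either read are tested in the absorbance assay. Progressed are the
   orthogonally confirmed (≥ 30%) plus two rescue routes: confirmation
   effect ≥ 50% or primary effect ≥ 80%.
5. **Potency and counter-screens.** Survivors get 7-point, 3-fold
   dose–response curves (20 µM top) in the fluorescence, absorbance and
   zinc-supplemented fluorescence assays, plus a two-replicate thermal
   shift run at 30 µM. The potency gate is a resolvable fluorescence curve
   with pIC50 ≥ 4.7; compounds whose activity survives only without added
   Zn²⁺ are flagged "lost" (chelation mechanism) and removed from the gate.
6. **Qualification.** Gate passers and thermal-shift-significant compounds,
   expanded with their same-cluster analogs among the tested set, are
   ranked (thermal-shift engagers first, then fluorescence pIC50, then QED,
   then compound id) under a per-cluster diversity cap of 6; the top 100
   are LCMS-checked, failures dropped, and the list capped at 50.

## Assay and signal models

**Competitive-inhibition model.** For a compound with inhibition constant
`Ki` (we parameterize as `pKi = −log10 Ki`), the half-inhibitory
concentration in a substrate-competitive assay follows Cheng–Prusoff:
`IC50 = Ki (1 + [S]/Km)`. The fluorogenic assay runs at `[S] = Km`
(IC50 = 2 Ki) and the chromogenic assay needs `[S] = 2.6 Km` for an adequate
window (IC50 = 3.6 Ki), so a purely competitive inhibitor appears
`log10(3.6/2) = 0.2553 ≈ 0.26` pIC50 units weaker in the absorbance
readout; a non-competitive inhibitor (`IC50 = Ki`) shows no shift. This
shift is both a generator property and a diagnostic the tests verify by
fitting simulated curves in both assays.

**Well signals.** A compound well's noise-free signal is
`low + (high − low)(1 − θ)` with fractional inhibition
`θ = c^h/(IC50^h + c^h)`. Artifact classes enter here rather than through
`θ`:

* *Quenchers* attenuate the enzyme-generated fluorescence above the
  no-enzyme background by a factor `a ~ U(0.2, 0.7)`, so they read as
  `(1 − a)·100 ∈ [30, 80]` percent apparent inhibition in fluorescence —
  and they *add* signal in the absorbance readout (negative apparent
  inhibition), which is what the orthogonal stage exploits. The upper bound
  0.7 makes "every quencher shows ≥ 30% apparent inhibition" true by
  construction; an attenuation weaker than that would simply make the
  compound invisible to the cascade in the first place.
* *Chromophores* absorb in the shared 355–405 nm excitation window, so they
  attenuate fluorescence too (`U(0.3, 0.8)`) and add 10–50% of the signal
  window to the absorbance baseline. Without the fluorescence term the
  class could never enter the funnel and its elimination would be untestable.
* *Aggregators* inhibit with a steep Hill slope (`h ∈ [3, 6]`) around an
  apparent pIC50 ~ N(5.5, 0.4) in every biochemical readout; they are the
  class the thermal shift assay (where they do nothing) de-prioritizes.
* Because the optical attenuations are concentration-independent in this
  model, a rescued quencher's dose–response is flat and therefore
  unidentifiable — the censoring rules remove it at the potency gate.

Wells receive multiplicative Gaussian noise at the assay's `well_cv`
(default 3%, matching sub-5% control CVs typical of this assay family) and,
optionally, a smooth low-order row/column gradient (amplitude ≤ 5% of the
high signal; the funnel uses 2%) that exercises the robustness of
median/MAD scoring.

**Potencies.** Genuine inhibitors draw `pKi ~ N(6.0, 0.7)` truncated to
[4.5, 8]. After the Cheng–Prusoff offset this puts confirmed-hit
fluorescence pIC50s in the ~4.7–7.7 range, straddling the 4.7 gate so the
gate actually selects.

**Thermal shift.** Genuine binders stabilize the protein saturably:
`ΔTm(c) = ΔTm_max · c/(c + Ki)` with `ΔTm_max ~ U(1, 8)` °C. Melt curves
are two-state: `F(T) = low(T)(1 − θ) + high(T)θ`,
`θ = logistic((T − Tm)/s)` with transition width `s = 1.5` °C on a
25–99 °C grid in 0.5 °C steps, plus additive noise (default 1% of the
fluorescence window).

**Library structure.** Class counts are allocated by exact
largest-remainder rounding, not sampling, so a 40,000-compound library at
the default fractions contains exactly 320 genuine inhibitors (0.8%, the
primary-active scale reported for large diverse collections against this
target class; the generator treats the fraction as a parameter since
published screens round it variously). Genuine actives are grouped into
chemotype clusters of ~6 with 20 signature fingerprint bits each (carried
with probability 0.8, plus 15 random background bits per compound), and
each active cluster carries ~30% inactive analogs — precisely the structure
that lets the naive Bayes stage recover analog false negatives, and that
the analog-expansion step at qualification mirrors.

## Estimators and numerical choices

* **Robust Z-scores** use the compound wells (not controls) as the null
  population — standard uHTS practice, tolerant of the small active
  fraction and of plate gradients. Whether the original campaigns used
  robust or moment estimators is typically unrecoverable from reports; the
  robust choice is ours. A zero MAD falls back to the sample SD, and a
  fully degenerate plate scores 0 everywhere. Cherry-pick
  (confirmation/orthogonal) plates are padded with vehicle wells so that
  the null population stays uncontaminated even when most picked compounds
  are genuinely active.
* **4PL fitting** works in log-concentration space with plateau bounds
  (bottom ∈ [−20, 20]%, top ∈ [0, 120]%, Hill ∈ [0.3, 5]) via bounded
  Levenberg–Marquardt (`minpack.lm::nls.lm`, ftol/ptol 1e-12). Three start
  points are tried and the best kept — the bounded LM
  surface has rare local minima, and model construction in higher-level
  wrappers can fail spuriously when a parameter converges to exactly 0. A
  second, weighted pass (weights `1/max(response, 2)²`, matching the
  roughly constant-CV error of replicate percent-inhibition readouts)
  refines the OLS solution; on noise-free data both stages share the same
  zero-residual optimum, so exactness tests are unaffected. Censoring to
  `"<4.70"` (the label derives from the 20 µM top concentration:
  −log10(2e-5) = 4.70) triggers when the fitted IC50 exceeds the top
  concentration, the maximal observed effect stays below 50%, the response
  span is under 15 points (flat, unidentifiable curves), or the fit fails.
  Reported pIC50s carry two decimals.
* **Michaelis–Menten fits** are unweighted nonlinear least squares with
  `Km₀ = median(S)`, `Vmax₀ = max(v)`; the steady-state window for
  progress-curve velocities is ≤ 10% substrate depletion (the standard
  initial-rate criterion; the exact window used in any given lab report is
  rarely stated, so it is a configurable here). Progress curves integrate
  `dP/dt = Vmax(S0 − P)/(Km + S0 − P)` with `lsoda` at a maximum step of
  0.1 min; the tests cross-check the integrator against the closed-form
  Lambert-W solution.
* **Tm extraction** smooths the melt curve with a Savitzky–Golay filter
  (window 9, order 2), takes centred finite differences, smooths the
  derivative once more with the same filter, and restricts the peak search
  to the ascending transition (up to the global fluorescence maximum,
  excluding post-peak dye dissociation). The peak is refined by a
  least-squares parabola over ±4 grid points. The second smoothing pass and
  the ±4 window are precision choices: with a 3-point refinement the
  vehicle-to-vehicle spread at 1% curve noise is ~0.12 °C, while the wider
  fit brings it to ~0.08 °C at a worst-case noise-free bias below
  0.02 °C — the precision the two-replicate, 3 × SD classification rule
  needs to separate the weakest modeled binders (≥ ~0.5 °C injected shift)
  from vehicle. Curves whose second derivative peak reaches half the main
  peak are flagged as multi-transition.
* **Naive Bayes** uses natural logarithms (any base gives the same
  ranking; ln is fixed for testability) and ties in the ranking break by
  ascending compound id, making augmentation deterministic.
* **Ranking and attrition.** The qualification ranking is deliberately
  deterministic — a reproducible stand-in for the medicinal-chemistry
  review of a real campaign: thermal-shift engagers first, then potency,
  then QED, then id; a greedy pass defers compounds once their cluster has
  6 picks, back-filling deferred compounds in rank order so the selection
  is a stable prefix (doubling the cap never removes a previously selected
  compound). LCMS is modeled as a per-compound boolean (18% failure rate
  among checked, applied to the top 100); out-of-stock attrition as a 1%
  availability flag applied before dose–response.
* **QED** is implemented from the published asymmetric-double-sigmoid
  desirability parameterization, floored at 1e-6 before the log. The
  unweighted geometric mean is the default; the mean-information-content
  weighted variant is available (`weights = "mean"`). Which variant a given
  campaign used is usually unstated, so downstream checks treat QED
  loosely. The synthetic library draws its eight QED input properties from
  lead-like distributions, since synthetic compounds have no structures.
* **Structure descriptors** go through OpenBabel (`ChemmineOB`). Its TPSA
  already follows the S/P-inclusive Ertl convention (a sulfone sulfur
  contributes 8.38 Å², needed to reproduce hydroxamic-sulfonamide hits'
  printed values); the N/O-only variant is obtained by subtracting an
  embedded Ertl S/P contribution table matched via SMARTS. Both
  conventions, and the QED implementation, are frozen against an
  independent toolkit's values in the tests. LogD is an input column — no
  in-package lipophilicity prediction; where none is supplied the OpenBabel
  logP is used and flagged as such.

## What the synthetic campaign does and does not show

The generator reproduces the *structure* of a real campaign — control
layouts, plate noise and gradients, class-conditional artifact behaviour,
substrate-load physics, saturable stabilization, cluster-correlated
fingerprints — with every latent variable known. Passing tests therefore
demonstrate that each stage implements its stated predicate, that the
estimators recover their generating truth at the stated precision, and that
the cascade's artifact-elimination logic works *for artifacts that behave
as modeled*. They do not demonstrate performance on real screens: real
nuisance compounds are concentration-dependent and mechanistically mixed,
real plate pathologies (dispense failures, edge evaporation, drift) are
richer than a smooth gradient plus i.i.d. noise, real fingerprints encode
chemistry rather than planted cluster signatures, and the generator's
class fractions and potency distribution are assumptions, not measurements.
The spatial-correction family (B-score, median polish) is intentionally out
of scope.

Default problem sizes — a 40,000-compound campaign for funnel-level
validation, 500 curves for potency-recovery statistics, 200 replicates for
Km and Tm precision — were chosen as the package's desk-scale study
conditions: large enough for stable statistics, small enough to run in
minutes on a single core.

## Session

```{r}
sessionInfo()
```
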