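---
title: "Measuring PTM-induced collision cross section shifts: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring PTM-induced collision cross section shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsdelta)
```

## Scope and model

`ccsdelta` analyzes trapped ion mobility (TIMS) measurements of
synthetic peptide pools in which modified peptides and their unmodified
counterparts share base sequences. The pipeline has a fixed stage
order — align on the 1/K₀ and RT scales, convert to CCS, filter,
select top evidence, aggregate replicates, match pairs, compute
statistics — because the alignment model is additive on the mobility
scale: per-run drift (ambient temperature and pressure changes) shifts
all 1/K₀ values of a run by a common offset, and CCS must be
(re)computed from corrected mobilities, never corrected directly.

**Alignment.** For each run, the correction is the median of
(measured − reference) over the spiked reference peptides detected in
that run, matched by sequence and charge. The median (rather than the
mean) makes a single misassigned reference feature inconsequential.
Runs matching fewer than `min_refs` (default 3, mirroring the
at-least-three-ions rule of TIMS voltage calibration) references are
flagged unalignable and dropped with a count — a run whose reference
spike-in failed cannot be placed on the common scale, and silently
keeping it would contaminate the replicate averages.

**CCS conversion.** The Mason-Schamp equation with: ion mass =
charge × m/z (no electron-mass correction; the effect is orders of
magnitude below measurement precision), N₂ as drift gas (28.013406 Da),
gas number density fixed at the Loschmidt constant so that reduced
mobility needs no pressure input, and T = 305 K by default. The
temperature is the one genuinely unknowable parameter: TIMS instruments
run on ambient air without temperature control, and the value assumed
by vendor software is not published. It is therefore exposed in
`physical_constants()` and written as a comment header into every
output table; absolute CCS values are only meaningful together with it.
Since CCS ∝ T^(−1/2), a 3 K error biases absolute CCS by ~0.5% but
cancels exactly in relative ΔCCS.

**Filtering and aggregation.** Kept: charges 2 and 3 (distinct mobility
regimes, analyzed separately and never mixed in a pair), modified
peptides with exactly one site not on the C-terminal residue, no
oxidation. Within each (run, modified sequence, charge) group the
highest-intensity feature wins; intensity ties break by earlier
retention time, then input order — the tie rule is not derivable from
the data and is fixed for reproducibility. Replicate aggregation is the
arithmetic mean of CCS and RT over runs (one to three technical
replicates in the motivating design).

**Pair statistics.** ΔCCS = (CCS_mod − CCS_unmod)/CCS_unmod per
(sequence, charge). The per-modification MED pools charges 2 and 3;
significance is a two-sided one-sample Wilcoxon signed-rank test
against zero with Benjamini-Hochberg correction, the family being the
set of modifications summarized in one call. The Wilcoxon
implementation drops exact zeros (classic convention — ecosystem
defaults differ, so the policy is pinned), enumerates the exact
tie-aware null via convolution for n ≤ 25, and uses the
tie-corrected normal approximation with continuity correction above.
Both the exact branch and the BH step-up are verified in the test suite
against independent brute-force oracles (full 2ⁿ sign-flip enumeration;
naive sort/adjust/cummin).

**Sequence dependence.** Per charge state, an OLS fit of unmodified CCS
on m/z defines the ion cloud; a peptide's residual separates extended
(positive) from compact (negative) gas-phase conformers. Regressing
pairwise ΔCCS on this residual gives the ΔCCS gradient. The regressed
quantity is the **absolute** shift in Å² by default, making the slope
dimensionless; the figure-axis units in the motivating analysis are
ambiguous, so a relative mode is available
(`deltaccs_gradient(..., mode = "relative")`). Rank concordance between
two modifications (Spearman ρ of per-sequence absolute shifts on shared
sequences) quantifies whether a homologous series preserves the
sequence ordering of shifts.

The MED-vs-mass correlation is reported as squared Pearson r — for a
simple regression this equals the OLS r², so the open choice between
the two formulations is moot. Charge-state profiles are count-based by
default with an intensity-weighted option, since "relative abundance"
can be read either way; ties in the predominant charge break toward the
lower charge.

## The synthetic generator: what it emulates, and what a green test proves

`generate_pools()` draws a pool of tryptic-like sequences (length 8–16,
terminal K/R, one internal K and one internal S planted as modification
targets) and builds, per charge:

    CCS_unmod = intercept_z + slope_z · m/z + r_s,
    CCS_mod   = CCS_unmod · (1 + shift + ε_rel) + g · r_s + ε_abs,

with r_s the per-sequence cloud residual drawn **once** and shared
across modifications — this creates the rank-concordance structure of a
homologous series by construction. Observed values add per-run drift
(additive on 1/K₀ and RT — identical in form to the alignment model, so
drift recovery is an identifiability test, not an approximation),
multiplicative CV-style measurement noise on CCS (precision is reported
as CV, hence multiplicative), log-normal intensities, and Bernoulli
missingness.

Defaults are the stated world of the validation design: 300 sequences,
20 runs, drift sd 0.01 Vs cm⁻² (1/K₀) and 0.2 min (RT), noise CV
0.25%, 10% missingness, 11 reference peptides (the public iRT
sequences, with synthetic reference values spanning CCS 320–430 Å² at
z = 2), and four modifications spanning the reported shift range:
formylation-like (−1.2%, gradient −0.3), methylation-like (0%),
biotinylation-like (+4.3%) and O-GlcNAcylation-like (+4.5%), each with
1% per-pair scatter. Cloud parameters (z = 2: CCS = 160 + 0.40·m/z,
residual sd 15 Å²; z = 3: 220 + 0.50·m/z, sd 18 Å²) were chosen once to
reproduce the observed 300–700 Å² / 300–1200 Th ranges.

Two realism constraints are modeled explicitly. First, the acquisition
window: ions whose true mobility falls outside 1/K₀ ∈ [0.65, 1.45]
(a 0.05 guard inside the instrument ramp of [0.6, 1.5]) are simply not
acquired and are recorded as unobserved in the ground truth; emitted
values outside [0.6, 1.5] are a hard error — never clipped. Second,
triply charged species require a minimum sequence length (default 12):
short peptides lack the backbone to hold three protons, and their 3+
ions would sit below the ramp edge.

What the generator does **not** emulate: search-engine behavior (false
identifications, localization errors), intensity-dependent detection,
nonlinear mobility drift, interference/co-elution, and any chemistry
linking a modification's structure to its shift — shifts and gradients
are free parameters. A green recovery test therefore establishes that
the pipeline's estimators are consistent and unbiased under its own
model assumptions, not that the assumptions hold on any instrument.

## Numerical choices and degenerate inputs

* OLS everywhere (`stats::lm`): voltage calibration (≥3 points,
  singular when all voltages coincide), ion clouds (≥3 records),
  gradients (≥3 pairs per modification, else omitted with a warning).
* Exact Wilcoxon switches to the normal approximation above n = 25;
  the crossover is configurable and the two branches agree to ~0.01 in
  p at the boundary.
* All-zero deltas give p = 1 with a warning; an empty modification is
  omitted from summaries with a warning rather than erroring the batch.
* Evidence rows with unparseable numerics are rejected row-by-row with
  a reason report (`attr(x, "rejects")`) — one corrupt row must not
  kill an 84-run batch.
* Unalignable runs are dropped and counted; whether the motivating
  analysis dropped or kept such runs is unstated, and dropping is the
  conservative choice for a precision-focused dataset.
* Reference 1/K₀/RT values are user input (the authoritative values
  live in unpublished supplementary material); the shipped
  `irt_reference_synthetic.tsv` is labelled synthetic and only anchors
  examples and tests.

## Known limitations

* Constant-offset alignment only; no LOESS/piecewise mobility or RT
  warping. Within-run nonlinear drift is indistinguishable from noise
  here.
* Positional isomers beyond the single-site filter are not resolved.
* The temperature assumption bounds absolute CCS accuracy (relative
  quantities are unaffected).
* The before-alignment CV of a simulated dataset is a knife-edge
  function of the drift-to-mobility ratio; with the default drift sd
  (0.01 Vs cm⁻²) and realistic median 1/K₀ (~1.0), population values
  sit at ~1%, and realized values fluctuate ±16% with the sampled
  drifts of a 20-run design. The validation suite documents this
  rather than inflating the drift.

## Session

```{r}
sessionInfo()
```
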