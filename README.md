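# ccsdelta

Quantify how post-translational modifications (PTMs) shift peptide
collision cross sections (CCS) measured by trapped ion mobility
spectrometry (TIMS).

## The problem

In TIMS-based proteomics, each detected peptide ion carries an inverse
reduced mobility 1/K₀ (Vs cm⁻²) that converts to a collision cross
section Ω (Å²) via the Mason-Schamp equation

    Ω = (3 z e / 16 N₀) · √(2π / (μ k_B T)) · (1/K₀),

with μ the reduced mass of the ion (z·m/z) and the N₂ drift-gas
molecule, N₀ the gas number density at STP, and T the drift-gas
temperature (default 305 K, configurable and recorded in every output).
Ambient conditions drift between LC-MS runs, so absolute CCS values are
only comparable after a run-wise alignment: for each run, the median
deviation of spiked reference (iRT) peptides from their reference 1/K₀
(and RT) values is subtracted from all measured values of that run.

A PTM changes a peptide's cross section. The headline statistic is the
relative shift of a modified peptide against its unmodified counterpart
at the same charge state,

    ΔCCS = (CCS_modified − CCS_unmodified) / CCS_unmodified,

summarized per modification as the median relative deviation (MED, %)
over charges 2 and 3, tested against zero with a one-sample Wilcoxon
signed-rank test and Benjamini-Hochberg correction. Because ΔCCS is
strongly sequence-dependent, the package also fits per-charge linear
CCS~m/z "ion clouds" to the unmodified peptides and regresses each
pair's absolute ΔCCS on the unmodified peptide's cloud residual: the
slope (the "ΔCCS gradient") is negative when extended conformers
compact upon modification.

The pipeline consumes MaxQuant-style `evidence.txt` tables (one row per
detected peptide feature) and is aimed at ion-mobility proteomics
groups building or validating PTM CCS datasets. A synthetic
evidence-table generator with full ground truth makes every stage
testable without instrument data.

## Worked example

```r
library(ccsdelta)

cfg   <- synthetic_config(seed = 42, n_sequences = 120, n_runs = 3)
pools <- generate_pools(cfg)
res   <- run_pipeline(pipeline_config(evidence = pools$features,
                                      refs     = pools$reference_table))
res
```

```
delta-CCS pipeline results
               stage rows
      input_evidence 1745
             aligned 1745
 records_all_charges  649
            filtered 1745
        top_evidence 1745
             records  649
               pairs  398

Modification summaries:
 modification_name n_pairs_total n_pairs_z2 n_pairs_z3  med_pct   p_value   q_value
      Biotinyl (K)           100         91          9  4.07427 3.956e-18 7.912e-18
        Formyl (K)            95         86          9 -1.00835 3.583e-10 4.777e-10
        Methyl (K)            98         78         20 -0.06463 5.877e-01 5.877e-01
      O-GlcNAc (S)           105         91         14  4.73874 5.920e-19 2.368e-18
```

The generator injected MED shifts of +4.3, −1.2, 0 and +4.5% — the
pipeline recovers them (±0.3% here; the scatter is the configured 1%
per-pair noise at ~100 pairs), flags the three true shifts as
significant after BH correction (q ≪ 0.05) and retains the null
(q = 0.59). Alignment recovers the injected per-run mobility drifts and
pushes the replicate precision to the injected noise floor:

```r
res$precision
#> CCS precision: median CV 0.223% over 466 peptides (3 runs, 72% complete)

subset(res$gradients, charge == 2)
#>  modification_name charge gradient_slope intercept n_pairs standard_error
#>       Biotinyl (K)      2      -0.101405   18.7160      91         0.0363
#>         Formyl (K)      2      -0.309490   -4.1751      86         0.0314
#>         Methyl (K)      2      -0.000734   -0.0117      78         0.0397
#>       O-GlcNAc (S)      2       0.032961   20.0492      91         0.0424
```

The formylation-like modification was generated with a ΔCCS gradient of
−0.3 (extended structures compact upon acylation); the regression of
ΔCCS on ion-cloud residual returns −0.309 ± 0.031. Single conversions
are available directly:

```r
ccs_from_inv_k0(0.9848, 1, 622.0289)   # Agilent 622 tune-mix ion
#> [1] 201.597                          # Å², at T = 305 K
```

## Command line

```sh
inst/scripts/ccsdelta simulate --seed 1 --out-dir sim
inst/scripts/ccsdelta run --evidence sim/evidence.tsv \
    --refs sim/reference.tsv --out-dir sim/out
inst/scripts/ccsdelta align --evidence sim/evidence.tsv \
    --refs sim/reference.tsv --out aligned.tsv --report corrections.tsv
```

## Package layout

- `R/evidence_io.R` — TSV readers/writers, MaxQuant column mapping
- `R/mobility_physics.R` — voltage calibration, Mason-Schamp conversion
- `R/reference_alignment.R` — run-wise median-deviation alignment, CV metrics
- `R/feature_selection.R` — filtering rules, top-evidence, replicate aggregation
- `R/pair_analysis.R` — modified/unmodified pairing, Δ quantities
- `R/ptm_stats.R` — MED/Wilcoxon/BH, charge profiles, ion clouds, gradients
- `R/synthetic_data.R` — ground-truth evidence generator
- `R/pipeline.R`, `R/cli.R` — orchestration and command line

See `vignettes/ccs-shift-analysis.Rmd` for the model, assumptions and
design decisions.
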