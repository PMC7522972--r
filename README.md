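# t1t2map

Two-dimensional T1–T2 relaxation correlation analysis of red-blood-cell
microenvironments, from raw inversion-recovery/CPMG decay matrices to
machine-learning classification of hemoglobin phenotypes.

## The problem

Time-domain NMR relaxometry on a benchtop magnet probes how water protons
interact with their molecular surroundings. A two-dimensional experiment —
an inversion-recovery preparation (encoding the spin–lattice time T1 over a
ladder of waiting times) followed by a CPMG echo train (encoding the
spin–spin time T2) — yields a decay matrix whose regularized 2D inverse
Laplace transform is a T1–T2 correlation map. For packed red blood cells
that map decomposes into discrete *relaxation reservoirs*:

* **R-peak** — bulk water (T1 ≈ 562 ms, T2 ≈ 141 ms in the oxygenated state),
* **S-peak** — the intermediate hydration layer (≈ 335 ms, 4.47 ms),
* **T-peak** — water bound directly to macromolecular protein (≈ 188 ms, 1.12 ms).

The **A-ratio** (T1/T2) of each reservoir indexes the strength of the
water–protein interaction: free water sits near 1 (the diagonal of the
log-log map), protein-bound water reaches into the hundreds. Hemoglobin
oxidation (the clinical picture of methemoglobinemia) collapses the R-peak
A-ratio from ≈ 4 to ≈ 1.8 and stretches the protein-bound T-peak into a
*relaxation tail* spanning more than a decade of T1 — a consequence of
distance-dependent paramagnetic relaxation from ferric iron. Structural
hemoglobin variants (HbE, HbD, beta-thalassemia) shift and broaden the
T-peak. The map is therefore a subject-specific *molecular fingerprint*
that supports supervised classification of disease, non-disease and variant
states.

The package implements that entire pipeline with a tested synthetic-data
generator standing in for the spectrometer:

| stage | functions |
|---|---|
| phenotype models & reference tables | `preset_phenotype()`, `aratio_table()`, `a_ratio()` |
| forward simulation & cohorts | `simulate_decay()`, `generate_cohort()` |
| 2D inverse Laplace transform | `build_kernels()`, `compress_problem()`, `fista_solve()`, `invert_decay()` |
| peak detection & quantification | `detect_peaks()`, `classify_peaks_rst()`, `tail_extent()` |
| fingerprint machine learning | `featurize()`, `reduce_dimension()`, `cluster_and_heatmap()`, `separation_test()`, `train_evaluate()` |
| file formats & orchestration | `read_decay()`/`write_decay()`, `read_spectrum()`/`write_spectrum()`, `pipeline_config()`, `run_pipeline()` |

## The model

The noiseless signal of a phenotype with reservoirs k = 1…K is

    s(t1, t2) = sum_k A_k (1 - 2 exp(-t1 / T1_k)) exp(-t2 / T2_k)

with fractional amplitudes summing to 1. The inversion recovers a
non-negative distribution F on a 100 × 100 log-spaced (T1, T2) grid by
approximately minimizing

    || M - K1 F K2' ||_F^2 + alpha_eff ||F||_F^2   subject to  F >= 0

where `K1[i,p] = 1 - 2 exp(-t1_i/T1_p)` and `K2[j,q] = exp(-t2_j/T2_q)`.
Echoes are first averaged into logarithmic bins, both kernels are compressed
by truncated SVD, an active-set non-negative least-squares solve places the
components, and FISTA (accelerated proximal gradient with a monotone
restart) runs 5000 iterations at the smoothing weight. `alpha = 1` is
interpreted on the noise-weighted (chi-squared) misfit scale, so noiseless
data receive an essentially exact solution. The methods vignette
(`vignettes/t1t2-methods.Rmd`) documents every numerical choice.

## Worked example

```r
library(t1t2map)

scheme <- acquisition_scheme(n_echoes = 4000, noise_sd = 0)  # 200 us echoes
decay  <- simulate_decay(preset_phenotype("oxygenated"), scheme)
map    <- invert_decay(decay)                                # 2D ILT
classify_peaks_rst(detect_peaks(map))
```

```
Peak report: 3 peak(s), tail extent 0.24 decades
  label t1_ms   t2_ms a_ratio  volume apex_intensity n_cells
1     R 562.0 140.901   3.989 0.95049      0.0611654     143
2     S 330.5   4.248  77.798 0.03609      0.0022049     143
3     T 182.4   1.035 176.241 0.01361      0.0008996     143
```

The three oxygenated reservoirs are recovered at their generating
coordinates (562/141, 335/4.47, 188/1.12 ms; every centroid within one grid
cell, i.e. about 10%), with volumes matching the generating amplitudes
0.95/0.035/0.015 and A-ratios near the reference values 3.99, 74.94 and
167.86. Running the same pipeline on the `"oxidized"` preset collapses the
R-peak A-ratio to 1.81 and stretches the protein-bound band: `tail_extent()`
returns 1.70 decades against 0.24 for the oxygenated map.

A full synthetic study — 32 subjects with 5% inter-subject jitter at
peak-signal SNR 500, inversion, peak reports, MDS embedding, hierarchical
clustering and four supervised classifiers under leave-one-out
cross-validation — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
res$results$neural_network
#> neural_network (leave-one-out CV): CA 1.000, AUC 1.000, ...
```

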