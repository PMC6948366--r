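# dbsdti

Pre- versus post-operative diffusion MRI comparison for deep brain
stimulation (DBS), on synthetic phantoms.

## The problem

DBS electrode implantation degrades post-operative diffusion MRI three ways
at once: susceptibility signal dropout near the electrode and its
connection wire, several-fold larger head motion (post-operative scans are
acquired awake, pre-operative ones under anesthesia), and an
order-of-magnitude SNR loss from safety-constrained acquisition. Whether
fiber tracts can still be reconstructed under those conditions — and how
each analysis stage responds to them — matters to anyone using
post-operative tractography to verify lead placement.

`dbsdti` implements the full pre/post comparison pipeline as tested,
desk-scale code, exercised on a synthetic DWI phantom with known ground
truth: phantom generation with artifact, motion and session-specific noise;
volume-to-b0 rigid motion correction with gradient reorientation; diffusion
tensor FA/MD/RD maps; mask-based SNR/CNR; artifact-aware per-ROI
statistics; Bayesian ball-and-stick fiber modeling (MCMC, up to two fibers
per voxel) with probabilistic streamline tractography; and the two
tract-retention statistics with voxel-wise Welch comparison. It is aimed at
methods researchers who want the machinery of such a comparison in a form
where every stage is verifiable against ground truth.

## The statistics at the core

With a seed mask S and per-seed-voxel counts `n_v` of streamline samples
reaching the classification target (out of N samples per voxel):

- **Index of connection probability** = Σ_{v∈S} n_v / |S| — mean successful
  samples per seed voxel.
- **Streamline density** = 100 · |{v ∈ S : n_v ≥ 1}| / |S| — percent of
  seed voxels connecting at all.
- **Percent change** = 100 · (pre − post) / pre, reported at one decimal,
  half away from zero.
- **Session quality**: SNR = Mean_GM / SD_AIR and
  CNR = (Mean_GM − Mean_WM) / SD_AIR, per volume, averaged across volumes.
- **Per-ROI decision tree**: two-sample Kolmogorov–Smirnov gate at
  α = 0.05 → paired Wilcoxon signed-rank if distributions differ, else
  paired t-test with 95% CI; p > α is reported as "similar"
  (similarity-by-nonrejection).
- **Voxel-wise tract comparison**: Welch's two-tailed heteroscedastic
  t-test on connection-probability values within the target ROI.

The underlying fiber model is ball-and-stick,
`S(g,b) = S0[(1−Σf_i)e^{−bd} + Σ f_i e^{−bd(g·v_i)²}]`, fitted per voxel by
Metropolis–Hastings with a Gamma prior on d and automatic-relevance
shrinkage on the stick fractions.

## Worked example

```r
library(dbsdti)

cfg <- study_config(master_seed = 42)   # default phantom + sessions
res <- run_study(cfg, outdir = "study-out")
print(res)
```

prints (exact numbers reproduce under the same master seed):

```
Pre/post phantom study
  SNR: pre 292.18, post 8.53;  CNR: pre -85.94, post -1.30
  motion: pre 0.15 mm, post 0.66 mm (ratio 4.45)
  ROIs affected by artifact: 18.8%
  connectivity:
  tract index_pre index_post index_pct_change density_pre density_post
 tract1  499.7500    0.00000            100.0      100.00         0.00
 tract2  295.1562  277.25000              6.1       62.50        62.50
 tract3  135.3750   75.84375             44.0       31.25        31.25
 density_pct_change      welch_p similar
                100 0.0001855926   FALSE
                  0 0.8837128358    TRUE
                  0 0.4413795992    TRUE
```

Reading it: the pre session sits at SNR ≈ 292, the awake post session at
≈ 8.5 with 4-fold more head motion — the acquisition contrast the study
conditions emulate. `tract1` is bisected by the electrode artifact: its
index of connection probability collapses from 499.8 (of 500 samples per
seed voxel) to 0 and its streamline density from 100% to 0%, and the
voxel-wise Welch test rejects similarity. The two tracts away from the
artifact keep their density (percent change 0) and stay "similar"
(p > 0.05) — tract retention degrades where, and only where, the artifact
and noise bite. `study-out/` receives the per-ROI comparison table, cohort
summary, SNR/CNR and motion reports, scalar maps and a manifest with all
seeds and parameters.

The artifact dose-response (the feasibility phenomenon in one table):

```r
dose_response(attenuations = c(1.0, 0.5, 0.1, 0.0))
```

returns the pre-session reference plus one row per attenuation with
monotonically falling index/density and rising percent change.

## Layout

- `R/`, `src/` — implementation (R front-end, Rcpp resampling/MCMC/tracking)
- `tests/testthat/` — unit, property and end-to-end suites
- `vignettes/dbsdti-methods.Rmd` — the methods vignette: model, priors,
  numerical choices, design decisions, limitations
- `inst/scripts/dbsdti.R` — thin CLI (`generate`, `run-study`, `track`)
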