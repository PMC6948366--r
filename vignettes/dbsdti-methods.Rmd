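---
title: "Methods: quantifying DBS-induced degradation of diffusion MRI on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying DBS-induced degradation of diffusion MRI on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep brain stimulation (DBS) electrodes degrade post-operative diffusion MRI
in three compounding ways: the implanted hardware causes susceptibility
signal dropout near the electrode and its connection wire; post-operative
scans are acquired awake (pre-operative scans under general anesthesia), so
head motion is several-fold larger; and safety constraints (SAR limits,
lower field strength) reduce SNR by more than an order of magnitude. The
question for anyone hoping to verify lead placement with post-operative
tractography is whether fiber tracts can still be recovered under those
conditions, and how each analysis stage — scalar maps, regional statistics,
probabilistic tractography — responds to them.

`dbsdti` re-implements that comparison as a fully synthetic, desk-scale
pipeline. Every stage is exercised on a phantom whose ground truth is known
exactly, so claims about bias, motion recovery, artifact dose-response and
tract retention are testable rather than anecdotal.

## The phantom

`phantom_spec()` describes a synthetic head on a 24^3 grid of 2 mm
isotropic voxels (the acquisition matrix of a clinical DTI protocol,
cropped to desk scale). The brain is an ellipsoid of radii (10.5, 9, 7.5)
voxels; real head outlines are not rotation-symmetric, and that asymmetry
is what makes rigid registration to a tissue-flat b0 well-posed. Fiber
bundles are tubes around spline centerlines; voxels inside a tube are white
matter carrying the local centerline tangent (up to two orientations where
tubes cross), remaining brain voxels are gray matter, and everything
outside is air. Spherical ROIs play the roles of seed structures, target
structures, and distractor gray-matter regions; an artifact sphere centred
on the first bundle's midpoint stands in for the dropout region around the
electrode wire.

The default study phantom (`default_phantom_spec()`) has three bundles
standing in for the nigrostriatal, dentato-rubro-thalamic and hyperdirect
pathways, 16 ROIs, and an artifact that bisects the first bundle and
overlaps three distractor ROIs (two substantially, one marginally), so
about a fifth of ROIs classify as artifact-affected — the same order as the
fraction reported in implanted patients.

### Signal model

The noiseless signal is the ball-and-stick forward model

$$S(g, b) = S_0\left[(1 - \textstyle\sum_i f_i)\, e^{-bd} +
  \sum_i f_i\, e^{-bd (g \cdot v_i)^2}\right],$$

with up to two sticks of fractions $f_i$ and orientations $v_i$, the
white-matter diffusivity $d$ used for ball and sticks alike, and isotropic
attenuation $e^{-b d_{tissue}}$ in gray matter and CSF. Tissue
diffusivities default to literature-range values (WM 1.2e-3, GM 0.9e-3,
CSF 3.0e-3 mm^2/s); they are configuration, not claims. The default
acquisition is one b0 plus 32 directions at b = 800 s/mm^2, the directions
spread by electrostatic repulsion of antipodal pairs.

### Noise

Noise is Rician — the magnitude of the signal plus complex Gaussian noise —
because diffusion images are magnitude images; its background mean
$\sigma\sqrt{\pi/2}$ and sd $\sigma\sqrt{2-\pi/2}$ are verified against
theory in the tests. Session noise defaults are $\sigma_{pre} = 2.4$ and
$\sigma_{post} = 93$ at $S_0 = 1000$, chosen so the mask-based SNR of the
two sessions lands in the regimes reported for anesthetized 3 T
pre-operative (~320) and implanted 1.5 T post-operative (~8) scans.

### Artifact before noise

`apply_artifact()` itself is a pure masked multiplication by an attenuation
factor in [0, 1]. The study pipeline, however, always attenuates the
*noiseless* signal and adds Rician noise last. This ordering is a
deliberate design choice: susceptibility dephasing attenuates the MR signal
before receiver noise enters, so the dropout region keeps the full noise
floor. Attenuating an already-noisy signal would scale signal and noise
together, and since the tensor fit and the ball-and-stick sampler are
scale-invariant per voxel (both estimate a free $S_0$), every attenuation
short of exact zero would be analytically invisible — no FA bias in the
dropout zone, no dose-response. With noise added last, attenuation
translates directly into lost contrast-to-noise, which is the phenomenon of
interest. The attenuation factor itself (default 0.15) is a free parameter;
only the qualitative fact of dropout is constrained.

### Motion

Per-volume rigid head motion draws independent Gaussian translations and
rotations (b0 fixed as reference). A session's motion is summarised as the
mean Euclidean magnitude of the per-volume translation (mm) and rotation
(degrees) vectors. Defaults (per-axis sd 0.1 mm/deg pre, 0.35 post) put the
mean translation magnitudes near 0.16 and 0.56 mm — the anesthetized/awake
contrast, a 3.5-fold ratio.

## Motion correction

Each diffusion-weighted volume is registered rigidly to the b0 by
maximising normalised mutual information (NMI). An intensity-difference
cost is inappropriate because contrast changes with diffusion direction;
NMI only assumes a consistent intensity mapping.

Two numerical choices matter and are worth recording:

* **Pre-smoothing and two stages.** The capture stage evaluates NMI
  (32 bins) on copies smoothed by a 1-voxel Gaussian, with a coarse grid
  search over translations then rotations and cyclic coordinate descent
  from two starts (the coarse rotation estimate and zero rotation — the
  second start guards against spurious-rotation basins). The precision
  stage uses a finer 48-bin histogram.
* **Symmetric half-transform resampling.** Resampling only the moving
  volume blurs it relative to the untouched reference, which biases any
  similarity cost toward the identity transform. In the precision stage
  both images are therefore resampled — the moving volume by half the
  candidate transform, the reference by the inverse half — so each carries
  exactly one interpolation and the blur bias cancels. This is what brings
  rotation recovery under a degree on a 24^3 grid.

Only a rigid (6-parameter) transform is estimated. The phantom's
ground-truth motion is rigid and eddy-current physics is out of scope, so
a full affine would add unidentifiable parameters with nothing to estimate
them from. Gradient directions are rotated by each estimated correction's
rotation component before tensor fitting. The registration achieves (and
the tests require) recovery of injected motion within 0.5 mm and 1 degree,
and sub-0.1-voxel estimates on motion-free input.

## Tensor fit and scalar maps

The tensor is estimated by weighted log-linear least squares with weights
equal to the squared signal — deterministic, non-iterative, and exact on
noiseless single-tensor data (the tests require eigenvalue recovery to
1e-9 relative). Signal values at or below zero are floored at
`.Machine$double.eps * S0` before the log, since Rician magnitude data
cannot be log-transformed at zero. Negative eigenvalues are clamped to zero
and flagged; clamped voxels stay in the maps but downstream ROI statistics
use valid voxels only.

Scalars follow the standard closed forms: FA
($\sqrt{3/2}\,\|\lambda-\bar\lambda\|/\|\lambda\|$, defined as 0 for the
all-zero tensor), MD (eigenvalue mean), RD (mean of the two minor
eigenvalues). A property exercised directly by the tests: mean FA over an
isotropic region rises monotonically as SNR falls — the Rician noise floor
masquerades as anisotropy, which is the mechanism behind globally elevated
post-operative FA.

## SNR and CNR

$SNR = \mathrm{Mean}_{GM}/\mathrm{SD}_{AIR}$ and
$CNR = (\mathrm{Mean}_{GM}-\mathrm{Mean}_{WM})/\mathrm{SD}_{AIR}$, computed
per volume (sample sd over the air mask) and averaged across all volumes,
b0 included (an `exclude_b0` flag exists, off by default). The air mask
keeps a 2-voxel guard band away from the head so partial-volume bleed from
motion and interpolation cannot inflate the background sd. On this
phantom's tissue contrast, average WM signal exceeds GM at b = 800, so CNR
is negative — the sign convention is part of the definition, and negative
session CNR values are expected and reported as such.

## Regional statistics

Per ROI and scalar, pre and post voxel values pair by index (both maps live
on the same phantom grid; real data would pair after registration — the
package requires equal grids and says so). The decision tree: a two-sample
Kolmogorov-Smirnov test gates at alpha = 0.05; if it rejects, a paired
Wilcoxon signed-rank test is run (zero differences dropped); otherwise a
paired t-test with a 95% confidence interval of the mean difference.
Exactly one branch p-value is populated per ROI. Degenerate inputs (all
paired differences zero) report p = 1 and are flagged rather than erroring.

Two conventions are inherited deliberately and labelled in reports:
"similar" means p > alpha on the chosen branch — similarity-by-nonrejection,
not an equivalence test — and no multiple-testing correction is applied
across ROIs (a Benjamini-Hochberg flag exists, off by default, for users
who want one). The KS gate is asymptotic (voxel data are tied); its type-I
rate runs slightly conservative, which the tests quantify (91-99% of null
comparisons take the t branch).

The cohort summary stratifies ROIs by artifact overlap (affected means
at least one shared voxel with the artifact mask) and reports, per scalar:
percent of ROIs with KS-different distributions; of those, percent with
signed-rank p > alpha ("equal medians"); of the KS-similar, percent with
t-test p > alpha ("equal means"); and percent with lower post means. Empty
strata report NA, never 0.

## Ball-and-stick posterior and tractography

`fit_ball_and_stick()` runs a per-voxel Metropolis-Hastings chain over
$(S_0, d, f_1, f_2, \theta_1, \phi_1, \theta_2, \phi_2)$ with Gaussian
likelihood whose precision is Gibbs-updated under a vague Gamma prior. The
priors: Gamma(shape 3, rate 2500) on the diffusivity (mean 1.2e-3 mm^2/s,
weakly informative); uniform-on-sphere for orientations (a $\sin\theta$
density term in the polar parameterisation); uniform on the fraction
simplex sharpened by an automatic-relevance (ARD) term
$\log p(f) \mathrel{+}= -\log f$ on both sticks, which shrinks unsupported
sticks to zero (isotropic voxels grow no spurious stick in ≥ 90% of
repeats). Proposal widths adapt during burn-in toward a 0.44 acceptance
rate; voxels ending outside [0.05, 0.95] acceptance are flagged. Defaults
(burn-in 1000, 1250 jumps thinned by 25 → 50 retained samples) follow
common Bayesian diffusion-fitting practice. A noise floor of
`1e-3 * S0` on sigma keeps noise-free inputs fittable.

Two numerical details: chains keep their identity at emission (re-ordering
sticks by fraction per sample would label-switch whenever $f_1 \approx
f_2$); and support classification merges sticks whose posterior mean dyads
lie within 30 degrees, because two coincident sticks are one fiber modeled
twice — the likelihood constrains only their summed fraction, and without
the merge a single-fiber voxel can report an arbitrary split. Posterior
mean orientations are computed as principal eigenvectors of the mean dyadic
tensor (orientations are axial; arithmetic means of signed vectors are
meaningless).

`track()` launches samples from every seed voxel: at each step it draws one
posterior realisation at the containing voxel (nearest-voxel lookup,
positions tracked continuously in mm, voxel lookup by flooring), picks a
supported stick with probability proportional to its fraction (ties are
fair coin flips by construction), sign-aligns with the previous direction,
terminates if the cosine with the previous step falls below the curvature
threshold, and advances by the step length. The curvature threshold uses
the minimum-cosine convention (0.2 is roughly a 78.5-degree bend); the
number alone does not fix a convention, so this one is stated. Streamlines
propagate in both directions from the seed (two half-tracts per sample).
Termination: target entry (success), brain-mask or grid exit, curvature
violation, loop (entry directions recorded on a half-resolution grid;
re-entry reversed beyond 90 degrees terminates), or the 2000-step cap.
Each seed-target pair is tracked independently.

Tracking parameters default to 5000 samples per seed voxel, 0.5 mm steps,
curvature 0.2, loopcheck on. The study driver and the tests run 500
samples per voxel; at p near the extremes the binomial sd of the retention
statistics at 500 samples is already far below the effects being measured,
and the tests confirm success counts scatter like binomial draws.

## Tract-retention statistics

The index of connection probability is the mean success count per seed
voxel — the raw count, not divided by samples-per-voxel, because the
published magnitudes (hundreds per voxel) are counts. Streamline density is
the percent of seed voxels with at least one successful streamline,
restricted to seed voxels (the natural reading of "nonzero voxels in the
resultant map" would allow any map voxel and could not yield a percentage
of the seed). Percent change is $100(pre-post)/pre$, reported at one
decimal rounded half away from zero — half-to-even rounding would print
54.25 as 54.2 where the published tables print 54.3. The voxel-wise
pre/post comparison is Welch's two-tailed heteroscedastic t-test on the
visitation-map values inside the target ROI, treating voxels as independent
observations (they are spatially autocorrelated; the verdict inherits that
caveat).

The dose-response experiment (`dose_response()`) fixes everything at the
study conditions (pre sigma 2.4, post sigma 93, identical derived seeds
across runs) and varies only the artifact attenuation over
{1.0, 0.5, 0.1, 0.0} on the bundle-bisecting mask. At the post-operative
noise level each step materially lowers the dropout region's
contrast-to-noise, so the index and density fall monotonically and the
percent change rises — the feasibility phenomenon in testable form. At
pre-operative noise levels the response would be flat until exact zero,
because orientation recovery saturates; this is why the experiment is
defined at the post-session noise level.

## Orchestration and reproducibility

`run_study()` chains the stages deterministically under a master seed.
Each stochastic stage derives its own stream as
`derive_seed(master, stage_name)` (a stage-name hash folded into the master
seed, always below 2^31), so stages can be rerun independently yet
reproducibly; reruns with the same master seed produce bitwise-identical
CSV outputs. Warnings from all stages (clamped voxels, flagged MCMC voxels,
non-converged registrations, skipped small ROIs) are collected into the
manifest rather than silenced.

## Problem sizes

The shipped tests and the acceptance script run at deliberately small
scale, chosen as the smallest sizes at which each property is
distinguishable from noise: 24^3 grids (10^3 for the FA-bias experiment,
14^3-20^3 for orchestration and tracking oracles), 8-33 volumes, 500
streamline samples per seed voxel (100 in oracles where success is
deterministic), 50 retained posterior samples per voxel, 500-1000 Monte
Carlo repeats for operating-characteristic checks, and 5-20 repeats for
parameter-recovery checks.

## What passing tests do and do not show

The phantom emulates the acquisition structure, the session contrast
(noise, motion, dropout) and ground-truth anatomy, so it can validate the
*machinery*: estimator correctness against closed forms, parameter
recovery, operating characteristics of the statistical gates, and the
directionality and monotonicity of artifact effects. It does not emulate
eddy-current distortion, susceptibility field geometry beyond a spherical
dropout, partial-volume mixtures at tissue boundaries, physiological noise,
spatially correlated noise, or realistic cortical geometry — so passing
tests say nothing about registration accuracy on real distorted data, about
atlas-to-subject transfer (out of scope by design; the phantom supplies
ground-truth labels), or about clinical interpretability of any particular
patient's tract loss. Known limitations worth restating: voxelwise pairing
requires equal grids; the Welch comparison ignores spatial autocorrelation;
similarity-by-nonrejection is not equivalence; and the published per-cell
statistical table cannot be reproduced row-by-row because the gate choices
behind each printed cell are not recoverable from it.
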