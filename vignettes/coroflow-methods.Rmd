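---
title: "coroflow: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coroflow: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`coroflow` is a desk-scale laboratory for studying point-cloud surrogate
models of coronary hemodynamics. It has three layers:

1. a **geometry generator** producing idealized stenosed coronary-aortic
   vessel trees, with population-style randomization and virtual bypass
   grafting;
2. a **reduced-order flow oracle** — a Hagen-Poiseuille hydraulic network
   with analytic in-segment profiles — standing in for a 3D CFD solver as
   the source of ground-truth velocity and pressure fields;
3. a **dual-input point-cloud regression network** trained to predict those
   fields at interior query points from wall coordinates alone, plus the
   error metrics, clinical indices (FFR, graft flow), method-agreement
   statistics, and error-attribution analyses used to judge it.

Everything is reproducible from one master seed; per-model child seeds are
derived by a fixed multiplicative rule (`derive_seed`), so any individual
model can be regenerated in isolation.

## Geometry

Trees are built from three built-in templates: an ascending aorta / arch /
descending trunk, an LAD split into proximal and distal runs at the stenosis
site, an LCX, an RA, and 0-3 supra-aortic side branches. Segments are
straight circular tubes between nodes; coordinates are right-handed
Cartesian meters with the origin at the inlet. Millimeters and degrees
appear only in configuration objects.

Population variation (`expand_model`) redraws, uniformly within closed
ranges: the stenosis rate (default 0.60-0.90), the number of stenoses (1-2),
the LAD-LCX bifurcation angle (30-90 deg), the number of side branches
(0-3), ascending and descending aortic diameters (20-30 / 15-20 mm), and the
arch angulation (80-140 deg). Two placement parameters are package
conventions with no literature counterpart and are therefore exposed and
documented as invented: the stenosis center (fraction 0.25-0.75 of the
proximal LAD run) and its axial extent (4 mm). Side-branch calibers and
branch lengths are likewise idealized template conventions. Angle
parameters move node coordinates only; they deliberately do not enter the
1D resistance model, so angle-only perturbations change the point clouds
but not the flow solution.

**Stenosis convention.** The rate is a *diameter*-reduction fraction (the
prevailing clinical convention): a rate $s$ narrows the local radius to
$R(1-s)$ at the throat. The radius profile is a cosine bump,
$r(x) = R - \tfrac{Rs}{2}\left(1 + \cos\frac{2\pi (x - x_c)}{w}\right)$
inside a window of extent $w$, which is $C^1$ at the window edges and
integrable in closed form elsewhere. One single implementation of $r(x)$
(`radius_profile`) is shared by the wall sampler, the resistance
quadrature, and the in-segment field evaluations, so the surface cloud and
the oracle can never disagree about where the wall is.

**Grafting.** `add_graft` deploys a 2 mm conduit (a LIMA analog) from the
aortic arch to the junction between the proximal and distal LAD runs. All
stenoses live on the proximal run, so the anastomosis is distal to the
culprit lesion by construction, pre-existing segments are untouched, and the
postoperative tree contains exactly one cycle.

**Sampling.** The wall ("model") cloud draws per-segment Poisson counts at a
target density (points per mm^2) with uniform axial and azimuthal
placement, each point exactly on $r(x)$. The interior ("query") cloud picks
segments proportionally to lumen volume, axial positions by rejection
against local cross-sectional area, radius as $\sqrt{U}$ (uniform over the
disk), so the cloud is uniform over the lumen volume; every point stores its
segment, axial fraction and radial fraction so analytic fields evaluate on
it without nearest-neighbor searches.

## Flow oracle

The solver is a linear (creeping-flow) hydraulic network: each segment has
resistance $R_h = \int 8\mu / (\pi r(x)^4)\, dx$ (closed form on uniform
parts, 1001-point composite Simpson over each stenosis window), nodal
pressures solve the Kirchhoff system with the inlet carrying
$Q = v_{in} \pi R_{in}^2$ and all outlets held at zero gauge pressure, and
mass conservation is asserted (relative imbalance below $10^{-10}$) on
every solve. Blood is Newtonian with density 1050 kg/m^3 and viscosity
0.0035 Pa s; the inlet velocity default is 1.125 m/s (a peak-systole
convention). Within a segment the velocity is the parabolic closure
$u(\rho) = 2\,\bar u(x) (1 - \rho^2)$ along the axis with
$\bar u = Q/(\pi r(x)^2)$ (no-slip at the wall, no transverse components),
and pressure drops linearly with the partial resistance integral.

Deliberate fidelity limits, chosen to keep the oracle exactly solvable and
its invariants assertable: no inertial or expansion losses across stenoses
(the system stays linear), no secondary or vortical flow, no pulsatility,
no fluid-structure interaction. Real aortic vortices therefore cannot
appear in these fields; the vortex-analysis machinery is exercised on
analytic rotation/Poiseuille fields instead, whose curl is known in closed
form ($|\omega| = 4\bar u \rho / r$ for the parabolic profile). Passing
tests consequently show that the pipeline's statistics behave correctly on
fields with known structure — not that the network has learned turbulence,
flow separation, or any feature of patient CFD beyond what a 1D model
carries.

## Datasets

Four corpora (pre/postoperative x velocity/pressure) are built and trained
independently. Pressure samples replicate the scalar into three identical
components so both field kinds share one N x 3 target layout. Train and
test splits descend from disjoint base models; the split invariant is
enforced at construction and re-checked when a corpus is read back from
disk. The canonical interchange is plain CSV with full-roundtrip numeric
precision (wall clouds `x,y,z`; query clouds `x,y,z,tx,ty,tz,region` plus
the lumen parameterization), with a YAML sidecar carrying metadata and the
vessel tree; STL and PLY exports exist for viewers. Coordinates and targets
are *not* normalized anywhere in the pipeline; a desk-scale default of
roughly 1:4 surface:query points mirrors common practice and is
configurable.

## Network

Two input channels take the wall cloud (M x 3) and the query cloud (N x 3).
Both run a per-point trunk FC1-FC2 (64/64 by default) whose weights are
shared across channels; sharing can be switched off, and a single-channel
baseline pools global features from the query cloud itself. The wall branch
continues FC3 to width 512, max-pools over points — the symmetric function
that removes dependence on point order — and the pooled 512-vector is tiled
to all N query points; the query branch continues FC4 to width 128; their
concatenation (N x 640) passes through FC5 (64) and FC6 to 3 outputs. All
hidden layers are rectifiers; the output is linear, since regression targets
are unbounded. Training minimizes mean absolute error with Adam
(lr 0.001, beta1 0.9, beta2 0.999, eps 1e-8), one model's full cloud pair
per optimization step, models reshuffled every epoch under the run seed.
An optional `points_per_step` setting splits each model's query cloud into
randomized chunks so an epoch takes more, smaller Adam steps — in our
experiments this improves the error reached per epoch at a higher
per-epoch cost; the default keeps whole-model steps.
The hot loop is compiled (RcppArmadillo) and exactly matches the R-level
forward pass; gradients were verified against finite differences.

Choices the architecture description leaves open, fixed here as: FC1/FC2
widths 64 (the convention of the architecture family this design inherits),
FC5 width 64 (desk-scale head; larger heads bought no accuracy at fixed
step counts in our experiments), tiling-after-pooling for the global
feature (a pooled feature must be point-count independent), uniform fan-in
initialization, no normalization layers, 50 epochs as the desk-scale
default. Two Adam epsilons appear in the source description; the 1e-8 value
is used as the numerical-stability epsilon and the other left unmapped.

## Evaluation

**Error functions.** NMAE normalizes the mean per-point error magnitude by
the range (max minus min) of truth magnitudes over the selected region of
the selected model; MRE averages per-point relative errors. For vector
fields "magnitude" is the Euclidean norm of the component difference —
scalar notation generalized so both metrics are rotation- and
scale-invariant. Points with truth magnitude below 1e-9 of the region
maximum are excluded from MRE (and counted). Regional reports compute both
metrics per region per model — the LAD split at the highest-grade stenosis
— then aggregate mean and *population* standard deviation across models.

A consequence worth knowing: with volume-uniform query sampling of a
no-slip parabolic profile, truth magnitudes near the wall approach zero
roughly uniformly, so per-point relative errors have a heavy
(log-divergent) tail and the *mean* relative error of a region can sit far
above its median even for visually excellent fits. The regional reports are
therefore best read alongside NMAE (range-normalized, tail-robust); the
acceptance harness records both.

**Clinical indices.** FFR is the ratio of mean pressure over a thin
cross-section 3 cm downstream of the culprit stenosis to the mean pressure
at the LAD entry, evaluated identically for oracle and network through a
field-accessor interface on deterministic sunflower-disk slabs (the
sunflower radial pattern makes the disk mean of a parabolic profile equal
the section mean exactly). Because the solver works in gauge pressure with
zero-pressure outlets, raw ratios are not clinical FFRs; a fixed 100 mmHg
(13332 Pa) aortic reference is added to numerator and denominator — an
explicit reporting convention, applied symmetrically to both methods,
parameterized, and returned with every result. It preserves monotonicity in
stenosis severity and keeps FFR in (0, 1]. Offsets that overrun the distal
LAD are clamped to 80% of its length with a warning. Graft flow is the slab
mean axial velocity at the graft inlet times $\pi d^2/4$.

**Agreement.** Pearson r with its p-value plus Bland-Altman mean difference
and limits at mean +- 1.96 SD. The SD of differences is the *population*
standard deviation (divisor n).

**Vorticity.** Velocity gradients on scattered points are estimated by
weighted least squares over k nearest neighbors (Gaussian weights,
bandwidth set by the neighborhood radius); the curl magnitude is
thresholded (default: 90th percentile) into a vortex mask, with
rank-deficient neighborhoods flagged and excluded. This is a stand-in for
tool-specific eigen-helicity criteria whose normalization is not published;
it recovers rigid-body rotation ($|\omega| = 2\omega_z$) and the Poiseuille
closed form to the tolerances asserted in the tests.

## Problem sizes and study conditions

The package's default study condition — used by the acceptance tests — is a
velocity corpus of 100 training models (10 bases x 10 expansions) and 20
test models from 2 disjoint bases, about 512 wall points (density
0.0335 /mm^2 on the default anatomy) and 2048 query points per model, and
50 training epochs. These sizes are the package's desk-scale choice,
mirroring a 10:1 base expansion scheme at roughly one-thousandth of
clinical point counts. The acceptance script runs a smaller demonstration
corpus; its sizes are printed in its output.

## Known limitations

* The oracle is 1D: no vortices, separation, pulsatility or non-Newtonian
  rheology; surrogate accuracy here bounds nothing about patient CFD.
* Mean relative error over volume-uniform clouds of no-slip fields is
  tail-dominated (see above); at desk-scale step counts the network's
  near-wall relative accuracy remains the binding constraint on MRE even
  when range-normalized errors are small.
* At desk-scale step counts (thousands of fixed-learning-rate MAE/Adam
  steps) the networks are far from converged: training loss is still
  falling when the epoch budget ends, regional mean relative errors remain
  large while NMAE is moderate, and architecture-ablation comparisons —
  which presuppose converged models — are dominated by optimization noise.
  Conclusions about the dual-channel and weight-sharing designs should be
  drawn only from runs long enough for the loss to plateau.
* Junction regions are idealized: segment tubes meet at nodes without
  blended geometry, and wall clouds near junctions can overlap slightly.
* FFR values carry the documented additive-reference convention and are
  comparable within this package, not against catheter measurements.
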