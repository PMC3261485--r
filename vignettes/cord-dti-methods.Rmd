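---
title: "Regional spinal cord DTI with synthetic phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional spinal cord DTI with synthetic phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordti)
```

## The problem

Diffusion tensor imaging (DTI) characterizes tissue microstructure through
the per-voxel apparent diffusion tensor of water. In the spinal cord the
standard scalar indices — fractional anisotropy (FA) and mean diffusivity
(MD) — are candidate biomarkers for injury and disease, but interpreting a
patient's values requires knowing how much they vary along the *healthy*
cord (cervical vs thoracic vs lumbar). `cordti` implements an analysis
pipeline for that question: tensor fitting, FA/MD maps, unsupervised
tissue segmentation by clustering in (MD, FA) feature space, and regional
comparison statistics — together with a synthetic cord-phantom generator
so the whole chain can be exercised and validated with known ground truth,
without access to scanner data.

## The signal and tensor model

For a diffusion-weighted measurement with b-value $b_i$ (s/mm²) and unit
gradient direction $g_i$, each tissue compartment $t$ with tensor $D_t$
contributes a monoexponential signal, and a voxel mixes compartments by
signal fraction:

$$S_i \;=\; S_0 \sum_t f_t \, e^{-b_i \, g_i^{\mathsf T} D_t \, g_i},
\qquad \textstyle\sum_t f_t \le 1 .$$

Mixing *signals* rather than tensors is the physically correct model of
the partial volume effect and is what produces the observed continuum of
intermediate FA/MD values at tissue interfaces. Noise is Rician — the
magnitude of a complex Gaussian-perturbed signal,
$\sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$ with
$\varepsilon_k \sim N(0,\sigma^2)$ — as in magnitude MR images.

Fitting inverts the single-tensor version of this model per voxel:
$\ln S_i = \ln S_0 - b_i\, g_i^{\mathsf T} D\, g_i$ is linear in the six
unique elements of $D$ plus $\ln S_0$, and is solved by ordinary least
squares on log-signals (a weighted second pass is available via
`weighted = TRUE`). OLS was chosen as the minimal deterministic default;
$S_0$ is estimated as the intercept rather than fixed to the measured
b = 0 volume, so noise in that single volume does not propagate into every
tensor element. Nonpositive signals are clamped to half the voxel's
smallest positive measurement before the log and the voxel is flagged;
flagged voxels are excluded from clustering. Eigenvalues come from the
closed-form trigonometric solution of the symmetric 3×3 characteristic
cubic, vectorized across voxels (an `eigen()` loop is the test oracle).
Negative eigenvalues from noise are retained in MD (avoiding bias) while
FA is clipped into [0, 1]. From the sorted eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ with mean $\hat\lambda$:

$$\mathrm{MD} = \hat\lambda = \tfrac13(\lambda_1+\lambda_2+\lambda_3),
\qquad
\mathrm{FA} = \sqrt{\tfrac32\,
\frac{(\lambda_1-\hat\lambda)^2+(\lambda_2-\hat\lambda)^2+(\lambda_3-\hat\lambda)^2}
     {\lambda_1^2+\lambda_2^2+\lambda_3^2}} .$$

All diffusivities are handled in units of $10^{-3}$ mm²/s, which makes MD
and FA both order-1 quantities; b-values are rescaled accordingly inside
the design matrix.

## The segmentation

Within a cord ROI the voxels form three modes in the (MD, FA) plane:
anisotropic white matter (WM), less anisotropic grey matter (GM), and
fast, near-isotropic CSF. The pipeline:

1. `build_density_surface()` — a 2-D histogram whose local maxima confirm
   the expected three modes (diagnostic only);
2. `kmeans_partition()` — Lloyd's algorithm with k-means++ seeding, 10
   restarts, best within-cluster sum of squares kept, deterministic given
   its seed. Distances are Euclidean in raw (MD, FA) coordinates: both
   axes are order-1, the restriction threshold stays geometrically
   interpretable, and this matches how FA-vs-MD scatter plots are read.
   A z-scoring option exists (`scale = TRUE`) but is off by default;
3. `restrict_clusters()` — the partial-volume restriction: cluster $c$
   keeps only voxels within $0.2 \times \min_{c' \ne c}
   \lVert \mu_c - \mu_{c'} \rVert$ of its centroid $\mu_c$. "Distance to
   the nearest adjacent centroid" is read as a cluster-level quantity
   (distance between centroids), giving one retention radius per cluster;
4. `assign_tissues()` — highest-MD centroid is CSF; of the rest, higher
   FA is WM, the other GM. Cluster-size expectations (WM largest, CSF
   smallest) are demoted to warnings because the MD/FA ordering alone is
   unambiguous for $k = 3$ and size cues are fragile on small ROIs;
5. `backmap()` — labels return to voxel coordinates for anatomical
   inspection against the phantom's ground truth.

## The phantom

`build_phantom()` voxelizes an analytic cross-section: a GM "butterfly"
(two dorsoventrally elongated wing ellipses joined by a commissural
bridge) inside an elliptical WM cord, inside a CSF rim, inside a
signal-free background. Cord semi-axes follow published anatomical
dimensions — cervical 6.5 × 4.2 mm, thoracic 5.0 × 4.0 mm, lumbar
5.2 × 4.4 mm — with a 1.8 mm CSF rim: a hand-drawn whole-cord ROI
includes near-pure CSF at the cord margin, which is what lets a CSF
cluster with free-water MD ≈ 3.0 appear at all. The butterfly is scaled
by bisection until GM occupies the requested share of the cord
cross-section (defaults 18 / 13.2 / 36.3 % for cervical / thoracic /
lumbar). Tissue fractions are computed by 5 × 5 in-plane supersampling,
so interface voxels carry mixed fractions; a deterministic sub-voxel
sinusoidal wobble of the cord center (phase from the seed) varies the
voxelization from slice to slice. WM and GM tensors are axially
symmetric, principal axis along the cord, with eigenvalues solved in
closed form to hit the region's normative (MD, FA) centroids exactly
(`axial_eigenvalues()`); CSF is modelled as near-isotropic free water
(MD 3.0, FA 0.05) — the much higher FA of *measured* CSF clusters arises
from noise and partial volume, which the simulation reproduces rather
than bakes into the tensor.

Acquisition defaults mirror a gated single-shot spinal EPI protocol:
20 diffusion directions at b = 700 s/mm² plus one b = 0 volume
(a fixed electrostatic-repulsion point set shipped as a versioned
fixture), 1.2 × 1.2 mm in-plane resolution, 3 mm slices, and 28
contiguous slices per region assembled from 7 interleaved 4-slice series
with an 18 mm intra-series gap (`plan_slices()` reproduces and checks
that geometry). SNR — defined as the b = 0 signal of a pure WM voxel over
the Gaussian channel noise σ — defaults to 20, a plausible figure for
cord EPI; $S_0$ = 1000 arbitrary units. Both are configurable and
recorded in every output's JSON sidecar along with all seeds and a
configuration hash.

## Statistics

The unit of analysis is one (MD, FA) pair per tissue per subject per
region: the mean over the subject's retained cluster voxels. Voxels
within a subject are not independent, so subject-level values — not
pooled voxels — enter the tests. Regional comparisons use Welch's
two-sample t-test (unequal sample sizes and variances, two-tailed) with
Bonferroni correction over the family of 18 comparisons (3 region pairs ×
3 tissues × 2 metrics) by default; subjects missing a tissue cluster
drop out of that tissue's comparisons, which is where unequal sample
sizes come from. Significance is reported both uncorrected at
$\alpha = 0.001$ and corrected at $\alpha = 0.05$. `regress_fa_on_gm()`
fits the structural explanation for the rostro-caudal FA profile:
regional WM FA against GM area percentage (with the shipped normative
values, $R^2 = 0.998$).

```{r regression}
nv <- cord_normative_values()
wm <- nv[nv$tissue == "WM", ]
regress_fa_on_gm(wm$fa, wm$gm_area_percent)[c("slope", "r_squared")]
```

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
noise-free fits must invert the forward model to machine precision;
closed-form eigenvalues are checked against `eigen()`; k-means against an
exhaustive enumeration of all partitions on ≤ 12-point instances; the
Welch test against a direct textbook-formula evaluation; slice plans
against brute-force position enumeration. Stochastic properties
(parameter recovery at SNR 20, type-I error calibration) run on a reduced
32 × 32 × 8 grid — the cord cross-section is identical to the full
64 × 64 × 28 default, so per-slice tissue composition is unchanged while
simulations stay fast; `null_study()` uses 200 replicates of two
identically-parameterized 9-subject groups and checks the raw-α = 0.05
rejection rate against its binomial 95% interval. Within a replicate the
six p-values share subjects and are therefore mildly correlated; the
interval is computed on the pooled count regardless.

## Known limitations

* **GM-cluster retention.** On the default phantom the 20% restriction
  retains well over half of the WM and CSF clusters (≈ 50–70%) but only
  ≈ 30–40% of the GM cluster. The WM↔CSF partial-volume continuum passes
  through the GM cluster's territory in (MD, FA) — WM/CSF mixtures are
  indistinguishable from GM by these two indices alone — and at 1.2 mm
  the thin GM butterfly contributes few pure voxels, so the GM cluster is
  continuum-dominated and spread well beyond its retention radius. This
  is a property of the stated imaging conditions, not of the seed or
  threshold; in vivo reports of > 50% retention in *every* cluster likely
  reflect smoother empirical distributions than this sharp-interface
  phantom produces.
* The phantom has no cardiac motion, EPI distortion, eddy currents,
  susceptibility effects, or coil profiles; passing tests say nothing
  about robustness to those. Tissue $S_0$ is shared (no T2/proton-density
  contrast), so b = 0 tissue contrast is absent.
* Geometry is extruded in z (no rostro-caudal taper); through-plane
  partial volume is limited to the sub-voxel wobble.
* Clustering pools all slices of a region, and tensors are fitted
  per-voxel without spatial regularization.
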