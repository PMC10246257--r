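---
title: "Validating MR-based PET attenuation correction with synthetic lesion insertion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating MR-based PET attenuation correction with synthetic lesion insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative brain PET requires correcting every line of response for photon
attenuation. On PET/CT the attenuation map comes from CT and is treated as
the reference (CTAC). On PET/MRI the map must be inferred from MRI, which
carries no direct electron-density information; the cranial bone — the
strongest attenuator around the brain — is the hardest tissue to recover.
The practical question is: *how much regional activity bias does each
MR-based attenuation correction (MRAC) method introduce relative to CTAC,
and can that bias be measured without patient emission data?*

petacval answers this at desk scale with a fully synthetic pipeline. A
digital brain-like phantom supplies the ground truth (activity, label atlas,
CT-derived attenuation map). Four degradation operators emulate the
characteristic failure modes of common MRAC families. Lesions are inserted
*in projection space* — forward projected, attenuated, normalized, with
scatter and Poisson noise added — then reconstructed with OSEM under each
attenuation map, and the regional MRAC-to-CTAC bias

$$ \mathrm{bias} = \frac{\bar{A}_{\mathrm{MRAC}} - \bar{A}_{\mathrm{CTAC}}}
                        {\bar{A}_{\mathrm{CTAC}}} $$

is tabulated per region, method, and arm.

## The forward model

All projection operations use a multi-slice 2-D parallel-beam model: a
sinogram is indexed by angle $\theta \in [0, \pi)$, signed radial offset
$s$, and axial slice. The forward projector is a Joseph-style ray-driven
line integral (stepping along the axis most orthogonal to the ray, linear
interpolation in the other coordinate); the backprojector spreads with the
identical weights, so the pair is an exact matrix adjoint — the single
numeric contract everything downstream leans on, verified to better than
$10^{-6}$ relative on random pairs.

Vendor sinogram formats use fully 3-D span/mashing geometries; the bias
mechanism under study (wrong attenuation factors along rays through bone) is
geometry-agnostic, so the projector is deliberately simple and pluggable
behind the `forward_project()` / `back_project()` contract.

Expected counts for an activity image $\lambda$ are

$$ \bar{y} = \tau \, n \cdot \frac{P\lambda}{a} + s_{\mathrm{scatter}}, $$

where $P$ is the projector, $a = \exp(P\mu)$ the attenuation correction
factors, $n$ the per-bin normalization efficiency, and $\tau$ a duration
scale. Scatter is modeled as a broad radial Gaussian (default FWHM 80 mm) of
the trues, rescaled so the global scatter fraction is met exactly (default
0.3). This is a deliberate stand-in for a physics-based scatter simulation:
it reproduces the *inventory* (a smooth, wide background worth 30% of
prompts) rather than the physics. Randoms are not modeled.

## The phantom and the four MRAC degradations

The phantom is brain-LIKE, not anatomical: concentric cylindrical shells —
scalp soft tissue (outer radius 92 mm), skull bone (86 mm, 8 mm thick), and
a 78 mm brain disc split into a cortical annulus and an interior core, each
partitioned angularly into named regions. Cortical regions are flagged
`near_skull = TRUE`, interior ones `FALSE`; these flags stand in for
anatomical adjacency to bone (e.g. superior frontal cortex vs deep gray
matter). Activity is a uniform grey-matter background (5000 Bq/mL) with
seeded per-region perturbations of ±10%; skull and air carry none. Tissue
attenuation uses literature 511 keV values: soft tissue 0.0096 /mm, fat
0.0090 /mm, cortical bone 0.0151 /mm.

The four degradations act on the ground-truth map:

| Variant | Operation | Default parameters |
|---|---|---|
| DIXON | skull replaced by soft tissue (bone invisible) | — |
| DIXONBONE | skull kept, scaled, 1-voxel erosion | scale 0.95 |
| UTE | skull re-assigned one fixed bone LAC + seeded boundary flips | 0.0110 /mm, 20% flips |
| DLDIXON | voxelwise noise inside the head, no systematic bone error | σ = 1% of soft μ, truncated at 5σ |
| CTAC | identity (reference) | — |

The UTE bone value of 0.0110 /mm is this package's choice (single-class UTE
segmentations are known to underestimate cortical bone); together with the
other defaults it realises the qualitative severity ordering that motivates
the toolkit — mean absolute skull μ-error DIXON > UTE > DIXONBONE > DLDIXON
> CTAC = 0 — which holds deterministically for every seed because the flip
and erosion fractions are fixed. All five parameters are configurable and
only the ordering, not the magnitudes, should be read as meaningful.

## Lesion insertion and the three arms

A lesion is a 4 mm-radius sphere (or an atlas region) with activity set
either absolutely or as a lesion-to-background ratio (LBR; mean background
over the lesion support × ratio), smoothed with a 4 mm Gaussian PSF, then
pushed through the forward chain. Composition with a background sinogram is
`add` (lesion counts added), `replace` (background bins overwritten on the
lesion's projection support only — the support being bins above $10^{-12}$
of the lesion sinogram maximum), or `lesion_only`.

The experiment driver reproduces a three-arm design:

* **with_background** — lesion counts added to the phantom's emission data;
* **lesion_only** — the lesion sinogram reconstructed alone;
* **original** — the plain phantom, regional means over every brain region.

Counts are simulated once per arm with the *true* CT attenuation map, and
every variant reconstructs those same counts; only the μ-map assumed by the
reconstruction changes. Sharing the noise realization across variants
isolates attenuation-induced bias from noise (the bias of a variant is then
nearly deterministic, because numerator and denominator reconstructions see
identical data). The default lesion positions are one sphere in the
cortical annulus a few millimetres from the inner skull surface
(`near_skull`) and one deep in the core (`interior`).

## Reconstruction

Ordinary-Poisson OSEM with the standard multiplicative update,
angle-interleaved subsets (subset $k$ takes angles $k, k+n_s, \dots$ — a
balanced choice), uniform initialization inside the field of view, scatter
entering the denominator additively (never pre-subtracted, so bins stay
non-negative), a $10^{-12}$ denominator floor, and zero — never NaN — for
voxels without sensitivity. Defaults are 3 iterations × 24 subsets with a
4 mm Gaussian post-filter (σ = FWHM/2.3548 per axis, reflective boundaries
so constants are preserved). With one subset the algorithm is MLEM and its
Poisson log-likelihood is non-decreasing, which the tests verify on noisy
and noiseless data. Regional means are taken on the post-filtered images
(matching the stated protocol; pass `post_filter_fwhm = 0` to disable) over
the *geometric* lesion support, since no delineation rule is imposed.

## Default problem sizes

The default grid is 128×128×16 voxels at 2 mm — a deliberate desk-scale
choice; the clinical-scale 344×344×127 grid remains selectable through the
configuration. The default sinogram (192 radial bins × 2 mm, 96 angles)
keeps 3 iterations × 24 subsets well-posed (4 angles per subset) and its
384 mm field of view covers the head with margin. The duration scale
default ($10^{-4}$) yields ≈ 2 × 10⁶ total counts for the default phantom,
the noise regime of a long brain acquisition at this scale. The validation
cohort is 11 seeded phantoms — one per seed, mirroring a small patient
cohort — with identical geometry and independent activity perturbations,
degradation realizations, and noise.

## Numerical and statistical choices

* **HU→LAC**: piecewise-linear with default breakpoints (−1000, 0) → (0,
  0.0096) → (1000, 0.0151) /mm, clamped outside; fully config-driven.
* **Resampling**: nearest neighbour in world coordinates; ties break to the
  lower source index, deterministically; no new values are ever invented.
* **Rasterization**: voxel-centre inclusion, no partial-volume weighting —
  PSF smoothing supplies edge softness downstream.
* **Quantiles**: linear interpolation (type 7) for all medians and IQRs.
* **Percent convention**: biases are fractions internally and percent (two
  decimals) in CSV outputs.
* **Seeding**: every stochastic operation takes an explicit seed and leaves
  the caller's RNG state untouched; sub-seeds are derived arithmetically so
  a single cohort seed reproduces everything byte-for-byte.
* **Scatter estimate at reconstruction**: by default the same scatter
  expectation that was simulated for the composed sinogram
  (inventory-matched); a re-estimated one can be supplied instead.

## What passing tests do and do not show

The phantom's shells, fixed LACs, angular regions and global scatter model
make the *mechanism* — bone misrepresentation → wrong attenuation factors →
regional bias, strongest near the skull — reproducible and measurable. They
do not reproduce anatomy, tracer kinetics, inter-patient variability or
scanner physics (no time-of-flight, randoms, dead time, detector gaps or
3-D oblique planes), so the cohort's bias *magnitudes* are not predictions
for any scanner; only signs, orderings and arm-consistency carry over as
qualitative claims. The DLDIXON variant has, by construction, no systematic
error, so its bias hovers at zero and its *sign* is not a stable quantity —
only its smallness is.

## Known limitations

* The projector is 2-D slice-parallel; axial effects (oblique rays, slice
  cross-talk) are absent by design.
* External inputs must be pre-aligned: the package performs no
  registration.
* The lesion-to-background rule uses the mean over the geometric support,
  so a lesion straddling regions of different uptake inherits a blended
  reference.
* One-voxel erosion and boundary-flip fractions are resolution-dependent
  emulations; at voxel sizes far from 2 mm they should be re-examined.
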