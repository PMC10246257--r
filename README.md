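# petacval

Quantifying the regional PET activity bias caused by MR-based attenuation
correction (MRAC), against CT-based attenuation correction (CTAC) as the
reference — entirely on synthetic digital brain phantoms, with lesions
inserted analytically in projection space.

## Who this is for

PET/MRI methods developers who want to evaluate an attenuation-correction
approach *without* patient emission data: the pipeline measures how a given
attenuation map's misrepresentation of cranial bone propagates through
reconstruction into regional uptake bias, and whether lesion-based synthetic
evaluation agrees with what plain (no-lesion) reconstructions would show.

## The method

For a brain region with reconstructed mean activity `A_MRAC` under an
MR-based map and `A_CTAC` under the CT map,

```
bias = (A_MRAC − A_CTAC) / A_CTAC        (reported in percent)
```

The pipeline (per phantom, per arm):

1. **Phantom** — concentric scalp/skull/brain shells with a named label
   atlas (cortical regions flagged `near_skull`), uniform grey-matter
   activity ±10% per-region perturbations, ground-truth 511 keV μ-map
   (soft 0.0096 /mm, bone 0.0151 /mm).
2. **MRAC emulation** — four degradations of the true μ-map: `DIXON`
   (bone → soft tissue), `DIXONBONE` (bone kept, ×0.95, 1-voxel erosion),
   `UTE` (single bone class 0.0110 /mm + 20% boundary misclassification),
   `DLDIXON` (1% voxelwise noise, no systematic error), plus `CTAC`
   (identity).
3. **Lesion insertion** — 4 mm-radius spheres (near-skull and interior),
   activity = 2× local background (LBR), 4 mm PSF; forward projected,
   attenuated (`ACF = exp(∫μ ds)`), normalized, 30% scatter and Poisson
   noise added; added to (or replacing) the background sinogram, or used
   alone.
4. **Reconstruction** — OSEM, 3 iterations × 24 subsets, 4 mm Gaussian
   post-filter, reconstructing the *same* counts with each variant μ-map.
5. **Analysis** — per-ROI means, bias vs the CTAC reconstruction, cohort
   medians and IQRs (type-7 quantiles) over 11 seeded phantoms.

Three arms mirror the standard evaluation design: `with_background`
(lesion + emission data), `lesion_only` (no emission data), and `original`
(plain phantom, atlas ROIs).

## Worked example

```r
library(petacval)

bundle  <- generate_phantom(seed = 1)           # 128x128x16 @ 2 mm, 8 ROIs
records <- run_experiment(bundle, seed = 1)     # all variants, all arms
subset(records, roi == "near_skull" & arm == "with_background",
       select = c(method, bias_percent))
```

```
     method bias_percent
1      CTAC   0.00000000
3     DIXON -13.39893587
5 DIXONBONE  -7.39888656
7       UTE -10.15564449
9   DLDIXON  -0.07234009
```

Reading: the near-skull lesion's mean activity, reconstructed from the same
noisy sinogram, drops by ~13% when the attenuation map has no bone at all
(DIXON), ~10% with a mis-valued single bone class (UTE), ~7% with an eroded
and rescaled bone model (DIXONBONE), and is essentially unbiased with a
noise-only pseudo-CT (DLDIXON). CTAC vs itself is identically zero. For the
interior lesion of the same phantom the magnitudes roughly halve (DIXON
−6.60%, UTE −5.01%, DIXONBONE −3.45%) — attenuation errors concentrate near
the bone that causes them.

Cohort-level summaries:

```r
cohort <- run_cohort(seeds = 1:11)
cohort_summary(subset(cohort, roi == "near_skull"), c("method", "arm"))
write_bias_tables(cohort, "out/")   # long CSV + median/IQR summary CSV
```

A command-line front end wrapping the same functions lives at
`inst/cli/petacval` (subcommands `phantom`, `mrac`, `insert`, `recon`,
`run-all`, `convert-hu`, `resample`).

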