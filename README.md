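# aidp — free-water diffusion MRI biomarkers and disease-specific classification of parkinsonism

Differentiating Parkinson disease (PD) from the atypical parkinsonian
syndromes — multiple system atrophy, parkinsonian variant (MSA) and
progressive supranuclear palsy (PSP) — is hard at the bedside and matters
for treatment and trial enrolment.  A validated approach pairs a standard
single-shell diffusion-weighted MRI sequence with free-water modelling and
a linear support vector machine to classify the three diagnoses from
regional imaging features.  `aidp` implements that analysis end to end in
R, together with a synthetic-cohort generator so the whole pipeline is
testable at desk scale without scanner data.

For whom: neuroimaging methodologists and biostatisticians who want a
tested, self-contained reference implementation of the analysis chain —
not a clinical tool.

## The model

Each voxel's diffusion signal is a two-compartment mixture of an
anisotropic tissue tensor D and an isotropic free-water (FW) compartment
with fixed diffusivity d_water = 3.0e-3 mm²/s:

    S(b, g) = S0 [ (1 − fw) exp(−b gᵀ D g) + fw exp(−b d_water) ]

Fitting this per voxel (eigenvalues of D constrained to
[0.1, 2.5]e-3 mm²/s, fw ∈ [0, 1]) yields the two biomarkers: the
free-water fraction **FW** and the FW-corrected fractional anisotropy of
the tissue tensor **FAt**, where

    FA = sqrt( 3/2 · Σᵢ(λᵢ − λ̄)² / Σᵢ λᵢ² ).

Mean FW and FAt over 132 atlas regions, plus age and sex, form a
266-feature vector.  A linear SVM (L2-regularised squared hinge; C tuned
by stratified 5-fold cross-validation on AUROC, ties to the strongest
regularisation; Platt-calibrated probabilities) is trained for four binary
endpoints: PD vs atypical parkinsonism (AP = MSA ∪ PSP), MSA vs PSP,
PD vs MSA and PD vs PSP.  Inference uses the DeLong AUROC variance
(CIs and one-sided z tests against a configurable null, default 0.80),
confusion-table metrics, Benjamini–Hochberg correction across endpoints,
pooled verification-run summaries, site-holdout evaluation, severity
regressions and neuropathology concordance accounting.

## Worked example

Fit one noiseless voxel with a planted free-water fraction of 0.25 and a
tissue FA of 0.6, then run a miniature end-to-end pipeline:

```r
library(aidp)

g <- protocol_gradients()                  # 30 directions + 5 b0, b = 1000
D <- tensor_from_fa_md(0.6, 0.7e-3, c(1, 0, 0))
sig <- sapply(seq_along(g$bvals), function(i) {
  b <- g$bvals[i]; gv <- g$bvecs[i, ]
  0.75 * exp(-b * drop(gv %*% D %*% gv)) + 0.25 * exp(-b * 3e-3)
})
fit <- fit_fw_voxel(sig, g)
cat(sprintf("fw = %.3f   FAt = %.3f   MD = %.2e mm^2/s\n",
            fit$fw, fit$fat, fit$md))
#> fw = 0.250   FAt = 0.600   MD = 7.00e-04 mm^2/s

cfg <- run_config(seed = 1, grid_shape = c(12, 12, 12), n_regions = 16,
                  sigma = 0.02, effect_strength = 2,
                  n_prospective = c(PD = 8, MSA = 6, PSP = 8),
                  n_retrospective = c(PD = 4, MSA = 3, PSP = 3),
                  test_counts = c(PD = 3, MSA = 2, PSP = 3),
                  C_grid = c(0.1, 1, 10))
res <- run_pipeline(cfg)
print(res$reports$PD_vs_AP)
#> PD_vs_AP [primary]: AUROC 1.000 (95% CI 1.000-1.000), p=0 vs null 0.80
#>   sens 1.000  spec 1.000  PPV 1.000  NPV 1.000  (TP 5 FP 0 TN 3 FN 0)
```

The voxel fit recovers the planted parameters exactly (the fit is an exact
nonlinear least-squares inverse of the noiseless forward model), and with
strongly planted regional effects at low noise the tiny demo cohort is
perfectly separable — the printed AUROC of 1.0 is forced by construction,
not evidence about real MRI (see the methods vignette for what the
synthetic world does and does not establish).

At the published scale, `generate_cohort(cohort_spec())` reproduces the
study's cohort accounting: 249 prospective + 396 retrospective subjects,
splitting into a training set of 500 (250 PD / 124 MSA / 126 PSP) and a
prospective testing set of 145 (60 / 27 / 58) — 22% of all data.

## Command line

```
Rscript -e 'aidp::aidp_cli()' simulate --config cfg.json --out dir/
Rscript -e 'aidp::aidp_cli()' fit --dwi x.nii.gz --bval x.bval --bvec x.bvec --out dir/
Rscript -e 'aidp::aidp_cli()' evaluate --predictions p.csv --out report.json
Rscript -e 'aidp::aidp_cli()' demo --seed 1
```
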