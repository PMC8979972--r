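# respsort

Retrospective respiratory sorting of free-breathing, non-ECG-gated
real-time cine cardiac MRI, with downstream left-ventricular
quantification and method-agreement statistics.

## The problem

Exercise CMR is most informative when images are acquired *during*
ongoing exercise and free breathing — but then there is no reliable ECG
for gating, and respiration translates the heart through the imaging
plane, so frames from different respiratory states must not be mixed when
measuring left-ventricular (LV) volumes. `respsort` reconstructs the
respiratory state of every frame from the images themselves and assembles
short-axis stacks in which end diastole (ED) and end systole (ES) are
both taken at one respiratory state (end expiration or end inspiration).
It is aimed at CMR physicists and physiologists post-processing real-time
cine acquisitions, and at methodologists who need a fully synthetic,
ground-truthed test bed for respiratory self-gating.

## The method

For each slice, the frames cropped to a diaphragm region of interest,
`x_1 … x_N`, become nodes of a weighted graph: each frame is joined to
its *k* temporally nearest neighbours (⌊k/2⌋ before, ⌈k/2⌉ after) and to
its `k_sim` most similar frames in intensity distance, with Gaussian
weights `W(i,j) = exp(−‖x_i − x_j‖² / 2σ²)` (σ² self-tuned to half the
median squared edge distance). The one-dimensional Laplacian-Eigenmaps
embedding `y` minimizes

    φ(y) = Σ_ij (y_i − y_j)² W(i,j),   y'Dy = 1,  y'D1 = 0,

i.e. `y` is the generalized eigenvector of `L y = λ D y` (`L = D − W`)
for the smallest nonzero λ. After sign orientation (maxima = end
expiration), respiratory extremes are local maxima/minima of the curve;
ED/ES frames are picked inside per-extreme windows (rest: ±15 frames at
end expiration, ±10 at end inspiration; exercise: ±8/±5) by a bright-blood
lumen proxy. Volumes follow by summation of discs, mass as myocardial
volume × 1.05 g/cm³, and agreement by Bland–Altman (bias ± 1.96 SD
limits), two-way mixed intraclass correlation and coefficient of
variation. A synthetic cine phantom with analytic per-frame truth
(translating diaphragm with a longer end-expiratory plateau, contracting
LV with incompressible myocardium, respiratory through-plane content
change, Gaussian noise) validates every stage.

## Worked example

```r
library(respsort)

## a seeded 4-slice free-breathing acquisition with known truth
resp <- resp_waveform_params(period_frames = 60, amplitude_px = 6)
ph <- generate_cine_stack(resp = resp, n_slices = 4, n_frames = 300,
                          noise_sd = noise_sd_from_snr(20), seed = 2026)

## embed, detect extrema, select ED/ES at end expiration, assemble
run <- respiratory_sort(ph$stack, phantom_resp_roi(resp = resp),
                        phantom_lv_roi(resp = resp),
                        mode = "rest", states = "exp")
print(run$curves[[1]])
#> resp_curve: 300 frames, lambda = 0.001575, residual = 4.9e-11
#>   orientation: expiration-up (k = 10, sigma2 = 5.016)
print(run$extrema[[1]])
#> resp_extrema: 4 end-expiration, 4 end-inspiration extrema
#>   period ~ 60.0 frames, smoothing 15, confidence 1.00

## quantify with (here: truth-derived) endo/epicardial masks
masks <- list(exp = lapply(1:4, function(i) {
  sel <- subset(run$selections, slice == i & state == "exp")
  list(ed = phantom_masks(ph$truth[[i]], sel$ed_frame),
       es = phantom_masks(ph$truth[[i]], sel$es_frame))
}))
fit <- quantify_stack(run$sorted, masks, state = "exp", bsa_m2 = 1.9)
print(fit)
#> LV quantification [exp], 4 slices:
#>   EDV 81.3 ml  ESV 35.8 ml  SV 45.5 ml  EF 56.0%
#>   LVM 51.2 g (ED)  52.0 g (ES)  LVMI 27.0 g/m2
```

The curve's `lambda` is the generalized eigenvalue of the embedding (its
residual reports solver convergence); `confidence` summarizes the
regularity of the detected breathing intervals. The quantified EDV/ESV
track this 4-slice phantom's analytic truth (81.3 / 36.1 ml) to well
under 5%, and mass at ED vs ES agrees because the phantom's myocardium is
incompressible. Method comparison uses the same units:

```r
ba <- bland_altman(c(160, 172, 181, 150), c(158, 175, 178, 149))
print(ba)
#> Bland-Altman (n = 4): bias 0.75 +/- 2.63 (SD)
#>   95% limits of agreement: [-4.4, 5.9]
```

A command-line dispatcher for the `phantom`, `embed`, `sort`, `quantify`
and `agree` steps ships at
`system.file("cli/respsort.R", package = "respsort")`.

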