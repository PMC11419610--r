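# flexdetect

Building blocks for detecting soft-bodied (flexible) marine organisms —
holothurians, starfish, jellyfish, octopus — in degraded underwater
imagery, implemented as standalone, individually tested R functions.

Detecting these animals is hard for three compounding reasons: their bodies
deform, so fixed convolutional sampling grids fit them poorly; they
camouflage, so foreground and background are locally similar; and
underwater optics yield low-contrast, blue-green, blurred frames. On top of
that, hand-drawn box annotations of blurry soft bodies are often loose or
wrong, and a regression loss that trusts every label degrades on such data.
The package provides the computational pieces that address each failure
mode:

* **Enhancement** — tiled contrast-limited adaptive histogram equalization
  (CLAHE): per-tile histograms clipped at `T = s_max · n / 255`, clipped
  mass redistributed uniformly, gray mappings
  `m(i) = round(255 · CDF(i) / n)` blended bilinearly between tiles — plus
  a boundary-detection channel `B = B_fine · [B_coarse > τ]` fused
  additively (`out = clip(CLAHE(img) + γ·255·B)`) to sharpen
  foreground/background silhouettes. Global histogram equalization is
  included as the baseline it reduces to.
* **Deformable convolution** — the reference operator
  `y(p₀) = Σₙ w(pₙ) · x(p₀ + pₙ + δ[p₀,n])` with bilinearly interpolated
  fractional offsets, an analytic backward pass, and the residual DCN block
  (CBL stem → two offset-predicting deformable layers → skip connection).
* **SimAM attention** — parameter-free 3-D weighting
  `X̂ = sigmoid(1/E) ⊙ X` with the per-element energy
  `E(t) = 4(σ²+λ)² / ((t−μ)² + 2σ² + 2λ)`, `λ = 1e-4`.
* **Wise-IoU losses** — `L_WIoUv1 = exp(d²/(w_c²+h_c²)*) · L_IoU` and
  `L_WIoUv3 = r · L_WIoUv1` with the dynamic non-monotonic focusing gain
  `r = β·α^(δ−β)`, where the outlier degree β is the detached instantaneous
  IoU loss over a momentum running mean; IoU and CIoU as baselines; a
  shared-model regression simulation demonstrating robustness to corrupted
  labels.
* **Fusion blocks** — bi-directional concatenation (BiC) across three
  pyramid depths and the SlimCSPSPPF cascaded max-pool pyramid with a CSP
  split.
* **Evaluation** — greedy confidence-ordered matching, exact
  all-point-interpolated AP, mAP50 (`mAP = Σ APᵢ / N`), P–R curves and the
  detection confusion matrix.
* **Synthetic scenes** — Fourier-deformed elliptical organisms of four
  classes on textured blue-green backgrounds, with an underwater
  degradation operator and seeded label corruption, so every block is
  testable without any external dataset.
* **Demo detector** — a miniature anchor-free model (frozen random trunk
  with DCN block and SimAM, trainable linear head) for end-to-end smoke
  experiments on one CPU.

The methods vignette (`vignettes/flexdetect-methods.Rmd`) documents every
model, default and design choice in detail.

## Worked example

```r
library(flexdetect)

# a synthetic underwater scene: generate, degrade, enhance
spec <- scene_spec(size = 96)
sc   <- generate_scene(spec, seed = 7)
deg  <- degrade_underwater(sc$image, spec$degrade, seed = 7)
enh  <- enhance(deg)
sprintf("RMS contrast: raw %.1f -> degraded %.1f -> enhanced %.1f",
        rms_contrast(sc$image), rms_contrast(deg), rms_contrast(enh))
#> "RMS contrast: raw 20.0 -> degraded 6.2 -> enhanced 22.4"
sprintf("boundary-band gradient energy: %.3f -> %.3f",
        boundary_band_energy(deg, sc$boxes), boundary_band_energy(enh, sc$boxes))
#> "boundary-band gradient energy: 0.074 -> 0.361"

# Wise-IoU distance factor of the worked box pair (corners (0,0,1,1)/(2,2,3,3))
r_wiou(c(0.5, 0.5, 1, 1), c(2.5, 2.5, 1, 1))
#> [1] 1.559623      # = exp(8/18)

# average precision of a 2-ground-truth / 3-prediction sweep (TP, FP, TP)
gts   <- boxes_df(c(0, 0), c(.2, .8), c(.2, .8), c(.1, .1), c(.1, .1))
preds <- boxes_df(c(0, 0, 0), c(.2, .6, .8), c(.2, .6, .8),
                  rep(.1, 3), rep(.1, 3), c(.9, .8, .7))
m <- match_detections(preds, gts)
average_precision(m$tp, m$conf, n_gt = 2)$ap
#> [1] 0.8333333     # 0.5·1 + 0.5·(2/3)

# end-to-end: train the demo detector head on 24 synthetic scenes
res <- demo_run(n_train = 24, n_val = 12, seed = 1)
sprintf("demo detector mAP50: untrained %.3f -> trained %.3f",
        res$map50_untrained, res$map50_trained)
#> "demo detector mAP50: untrained 0.000 -> trained 0.556"
print(res$report)
#> Detection evaluation report
#>   mAP50: 0.5560
#>   per-class AP50: 0.6500, 0.5539, 0.4603, 0.5597
#>   P/R at max-F1:0.5135/0.5938 (conf 0.531)
```

The enhancement numbers say the degradation collapsed contrast from 20.0 to
6.2 gray levels (sd of luma) and the enhancer restored it past the original
while quintupling the gradient energy in a 3-px band around true object
boundaries — contrast back, silhouettes sharper. The demo run shows the
untrained head detects nothing while a few seconds of head training reaches
mAP50 ≈ 0.56 on held-out scenes.

## Command line

A thin CLI over the same functions is installed at `exec/flexdetect`:

```sh
flexdetect synth --out data --n 200 --seed 7 --label-noise 0.1
flexdetect enhance --in data/images/val --out enhanced --tiles 8 --smax 4.0
flexdetect demo-train --out run --box-loss wiou3 --label-noise 0.15 --seed 1
flexdetect eval --manifest data/dataset.yaml --preds predictions/ --json report.json
```

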