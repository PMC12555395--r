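# gcassn

Semantic segmentation of 3D plant point clouds — assigning every scanned
point an organ label (stem, leaf, soil) — with a graph-convolution plus
self-attention network, implemented from first principles in R.

Plant scans are hard to segment: leaves twist and occlude each other,
stems branch and curve, point density is uneven, and the stem-to-petiole
transition blurs the class boundary. The network combines the two kinds
of evidence this needs:

* **Local geometry** via kNN graph convolution: for each point, the
  `k - 1` nearest neighbors (squared Euclidean distance
  `d²(x, y) = Σ (xᵢ - yᵢ)²`) form a local graph whose edge features
  `eᵢⱼ = Fⱼ - Fᵢ` are aggregated by a shared conv + batchnorm + ReLU and
  max-pooling: `F_graph = max(relu(bn(conv(F ∥ e))))`.
* **Global context** via self-attention with one shared, 4x down-scaled
  query/key projection (`Q = K = F·W_qk`, score `Q·Kᵀ`, row-softmax
  weights `A`, attended features `F_sa = A·(F·W_v)`), followed by a
  Laplacian-style residual enhancement
  `F_out = LBR(F_graph - F_sa) + F_graph` — since `A` is row-stochastic,
  `I - A` acts like the combinatorial graph Laplacian `D - E` and
  sharpens feature differences between points.

A learned, identity-initialized 3x3 transform (Trans-net) re-poses the
cloud first; three stacked GCASM units, a pooled global feature and a
per-point head produce `N x P` logits. Training uses the reference
recipe (SGD, momentum 0.9, weight decay 1e-4, batch 8, lr 0.1 halved
every 20 epochs, best epoch by test mIoU). Everything — forward passes,
all backward passes, the optimizer — is authored in this package and the
gradients are verified against finite differences in the test suite.

The package also ships a procedural generator of labeled synthetic
plants (spline-tube stems, bent elliptical leaves, optional soil plane,
density gradients, ambiguous junction zones), segmentation metrics
(per-class IoU, mIoU, mcIoU, accuracies), robustness perturbations
(point dropping, Gaussian jitter), and an ablation harness over the
design space (depth, k, neighborhood metrics, attention variants,
Trans-net on/off, noise levels) — so every stage runs with no external
dataset.

## Worked example

Train the reduced network (one GCASM layer, width 32, k = 10) on 24
synthetic two-class plants and evaluate on 8 held-out plants, 512 points
per cloud (about 3 minutes on one core):

```r
library(gcassn)

run <- run_scaled_experiment(train_seed = 1)
run$metrics
#> <seg_metrics> 4096 points | acc 0.9270 | mIoU 0.8331
#>   per-class IoU: 0.7614 0.9048

drop_sweep(run$fit$params, run$config, run$test_set)
#>   drop_fraction n_drop       acc      miou
#> 1          0.00      0 0.9270020 0.8331052
#> 2          0.25    128 0.9277344 0.8346554
#> 3          0.50    256 0.9130859 0.8060773
#> 4          0.75    384 0.9111328 0.8061751
```

The model reads 92.7 % of held-out points correctly (stem IoU 0.76,
leaf IoU 0.90 — stems are the thin minority class), and accuracy decays
gracefully, not catastrophically, as up to 75 % of the test points are
removed.

Lower-level pieces compose directly:

```r
cloud <- generate_plant(plant_spec(n_points = 2048, seed = 7))
cloud <- normalize_cloud(random_sample(cloud, 512, seed = 1))

cfg    <- model_config(n_classes = 3)        # full-size: 3 layers, width 64
params <- gcassn_init(cfg, seed = 1)
res    <- gcassn_forward(cloud, params, cfg) # N x 3 logits + labels
count_parameters(cfg)                        # ~1.7 M learnable scalars
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/gcass.R synth --n 35 --seed 7 --out data/
Rscript inst/cli/gcass.R train --data data/ --out run/ --epochs 30
Rscript inst/cli/gcass.R predict --model run/model.json --in data/plant_001.txt --out labels.txt
```

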