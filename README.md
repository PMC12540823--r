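# mambaseg

Lightweight state-space U-Net for brain-MRI lesion segmentation, implemented
as a self-contained R package: the network, its gradients and the AdamW
training loop are written in R with C++ (Rcpp/RcppArmadillo) kernels for the
convolutions and the state-space scans — no external deep-learning framework
is required.

## The problem and the model

Segmenting stroke or tumour lesions in multi-modal brain MRI is a
pixel-labelling problem with two persistent difficulties: lesions are rare
(heavy class imbalance) and their boundaries matter clinically. `mambaseg`
implements a compact (~8.7M parameter) encoder–decoder that addresses both:

* an **MBConv encoder** (mobile inverted bottlenecks with
  squeeze-excitation, as in EfficientNet-B0) producing a feature pyramid
  112²×32 → 56²×48 → 28²×80 → 14²×112 with a 7²×192 bridge for 224² inputs;
* **visual state-space (VSS) blocks** after every stage: a per-channel
  diagonal linear state-space model

  $$H(t) = A\,H(t-1) + B\,X(t), \qquad Y(t) = C\,H(t) + D\,X(t)$$

  scanned along four traversals of the image grid (SS2D) and averaged,
  wrapped in layer norm, channel expansion, a depthwise convolution and a
  SiLU gate — long-range spatial context at linear cost;
* **spatial and channel attention bridges** (7×7 convolution over pooled
  descriptors; global-average-pooling bottleneck) gating the bottleneck and
  decoder stages;
* a **U-Net style decoder** with patch expansion and skip concatenation, and
  a 1×1 softmax head at full resolution;
* a **hybrid loss**

  $$\mathcal{L} = \underbrace{\lambda_{len}\!\int_\Omega\!|\nabla\phi| +
  \lambda_{reg}\!\int_\Omega\!(\phi-g)^2}_{\text{Active Contour}} \;+\;
  \beta\,\underbrace{\big(-\alpha(1-p_t)^\gamma\log p_t\big)}_{\text{Focal}},
  \qquad \beta = 0.3,\ \alpha = 0.75,\ \gamma = 2 .$$

The evaluation suite reports DSC, precision, recall, F1, mIoU and the
surface distances ASSD and Hausdorff (mm). A seeded synthetic-data module
generates multi-modal NIfTI volumes with ellipsoidal lesions so the entire
pipeline is testable without any dataset download.

## Worked example

Generate a small synthetic dataset, train the CPU-scale preset briefly, and
evaluate on the held-out volumes:

```r
library(mambaseg)

dir <- "synthetic-demo"
generate_dataset(synthetic_spec(), n_volumes = 20, out_dir = dir, seed = 11)

set.seed(11)
net <- build_network(network_config("tiny"))
fit <- train_network(net, dir,
                     train_config(lr0 = 5e-3, max_steps = 300, seed = 11,
                                  augment = FALSE, patience = 30))
ev <- evaluate_dataset(fit$net, dir, split = "test")
ev$cases
ev$summary
```

```
    case       dsc precision    recall        f1      miou   assd_mm     hd_mm slice_dsc
1 vol017 0.8647558 0.8028486 0.9370079 0.8647558 0.8773840 1.1875510 32.124757 0.6640261
2 vol018 0.8112544 0.7163561 0.9351351 0.8112544 0.8395735 2.9923001 42.391037 0.5449888
3 vol019 0.8309305 0.7885572 0.8781163 0.8309305 0.8540604 0.5624551  2.236068 0.8484816
4 vol020 0.8519448 0.8260341 0.8795337 0.8519448 0.8686039 0.4618860  2.000000 0.7754240

  case       dsc  precision    recall        f1       miou  assd_mm    hd_mm
1 mean 0.8397214 0.78344899 0.90744826 0.8397214 0.85990545 1.301048 19.68797
2   sd 0.0235498 0.04731942 0.03306518 0.0235498 0.01662043 1.172309 20.71663
```

Each row is one held-out volume; `dsc` is the volume-level Dice overlap
between the predicted and true lesion masks, `assd_mm`/`hd_mm` are surface
distances in millimetres, and the `mean` row is the headline number (the
test suite asserts mean DSC ≥ 0.8 for this seeded run).

The full-size model is one preset away:

```r
net <- build_network(network_config("default"))  # 224x224x3, ~8.7M params
network_summary(net)                             # the stage table
count_parameters(net)
```

```
[1] 8710607
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/mambaseg.R simulate --out data --n 20 --seed 11
Rscript inst/cli/mambaseg.R train --data data --out ckpt.rds --preset tiny --steps 300
Rscript inst/cli/mambaseg.R evaluate --ckpt ckpt.rds --data data --split test --out metrics.csv
Rscript inst/cli/mambaseg.R summary --preset default
```

## Package layout

* `R/` — layers and network (`nn_*`, `build_network`, `net_forward`), losses,
  metrics, synthetic generator, preprocessing, training loop, CLI.
* `src/kernels.cpp` — conv2d/depthwise forward+backward (im2col + GEMM) and
  the batched state-space scan with backpropagation through time.
* `vignettes/mambaseg-methods.Rmd` — model, numerical choices, generator
  scope and limitations.
* `tests/testthat/` — oracle-based unit tests and the acceptance suite.
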