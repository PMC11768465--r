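---
title: "Methods: simulation, estimators, and the six-gate lifetime network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, estimators, and the six-gate lifetime network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wide-field time-gated FLIM cameras record, per pixel, a handful of
intensity samples along the fluorescence decay instead of a full
photon-arrival histogram.  In endoscopic use the instrument response
function (IRF) of the system cannot be measured: illumination is
non-uniform and a built-in excitation filter suppresses the reference
signal.  With only six gates and no IRF, classical re-convolution fitting
is unavailable, and the simpler estimators each have a known failure
mode: tail fitting ignores a gate window that is *wider* than the
lifetimes of interest (about 4 ns against 0.6--2 ns) and is biased
upward; rapid lifetime determination (RLD) shares that problem in
closed form; phasor analysis is exact for ideal decays but converts any
per-pixel timing offset -- for example from surface-height variation --
directly into a phase error.

`flimgate` implements the alternative: a spatially independent
convolutional network trained purely on synthetic decays whose
statistical structure matches the instrument, applied to peak-aligned,
max-normalized six-gate samples.  Peak alignment removes timing offsets
by construction; training across a range of IRF widths absorbs the IRF
without ever measuring it.

## The decay model

Each foreground pixel carries a mono-exponential decay with lifetime
$\tau$ and pre-exponential amplitude $A$, convolved with that pixel's
IRF and corrupted by Poisson noise:

$$D(t) = \mathrm{IRF}(t) \ast A e^{-t/\tau} + \varepsilon(t).$$

The IRF is a super-Gaussian of order $N$,

$$\mathrm{IRF}(t) = \exp\!\left[-2\left(\frac{2 (t - t_0)\,
(0.5\ln 2)^{1/(2N)}}{\mathrm{FWHM}}\right)^{2N}\right],$$

which equals 1 at $t_0$ and exactly $1/2$ at $t_0 \pm \mathrm{FWHM}/2$
for every order -- the factor $(0.5\ln 2)^{1/(2N)}$ is precisely what
makes the nominal FWHM the literal full width at half maximum, and the
package's test suite enforces that identity to $10^{-12}$ over random
parameters.  $N = 4$ approximates a sensor gate: flat-topped with steep
edges.  The gate window itself is represented entirely by this IRF (the
excitation pulse, tens of picoseconds, is negligible against a 4 ns
gate), and gate samples are point evaluations of the convolved trace.

Study conditions (the package defaults): $\tau \sim U[0.6, 2]$ ns,
$A \sim U[20, 100]$ counts, per-pixel $\mathrm{FWHM} \sim U[4, 4.5]$ ns,
$N = 4$, on digit-like spatial masks at up to $128 \times 128$ pixels
(16,384 distinct IRFs per image).

## The generation flow

Per pixel: simulate the decay, convolve with the pixel's IRF,
max-normalize, scale by $A$, add Poisson noise, max-normalize again,
find the peak (raw argmax, earliest tie), and sample six gates at the
peak and at five further points spaced `gate_spacing` apart; the 6-vector
is max-normalized once more so its first entry is 1.  The double
normalization means low- and high-count decays are presented to the
network at the same scale, leaving noise texture as the only SNR cue.

Numerical choices that the model text leaves open, fixed here once:

* **Dense grid**: 0--50 ns at $dt = 0.05$ ns, IRF center $t_0 = 10$ ns.
  Only the six sampled points matter downstream; the grid merely has to
  hold the peak plus five spacings of tail for $\tau \le 3$ ns.
* **Gate spacing**: 1 ns by default, configurable, and deliberately
  *identical* between training and inference -- the trained network and
  any stack it is applied to must share it, and `predict()` enforces
  that.
* **Noise**: Poisson on the scaled trace (shot noise).  A constant
  Poisson background level is available but defaults to 0, so background
  pixels are exactly zero; the noise term in the decay model is read as
  shot noise of the signal itself.
* **SNR**: defined as the square root of the total photon count of the
  decay; in decibels, $20\log_{10}\sqrt{\text{counts}} =
  10\log_{10}(\text{counts})$.  The source material mixes two
  conventions (a 10--25 dB test range against linear SNRs of 30--400 at
  the same amplitudes); this package standardizes on the count-based
  definition above and records the achieved per-pixel SNR rather than
  assuming the target.
* **Masks**: a procedural generator of digit-like Bezier strokes stands
  in for scanned handwriting; only the spatial support matters, and the
  generator avoids any external data dependency.  User-supplied masks
  are accepted.
* **Reproducibility**: a master seed derives independent per-image child
  seeds, so any image can be regenerated without replaying the whole
  dataset.

## Classical estimators

* `reconvolution_fit()` -- Levenberg--Marquardt least squares of
  $\mathrm{conv}(\mathrm{IRF}, A e^{-t/\tau}) + c$ against the dense
  trace (the engine is `minpack.lm::nls.lm`).  Initialization:
  $\tau_0 = 1$ ns, $A_0$ from the trace maximum, offset from the trace
  minimum; bounds $\tau \in [0.05, 10]$ ns.  The constant offset is
  fitted by default and can be disabled.  On noiseless simulator output
  it recovers $\tau$ to better than 0.1%.
* `tail_fit()` -- $B e^{-k\Delta/\tau}$ against the six samples, no IRF
  term, in nonlinear space (initialized from the log-linear regression;
  a log-linear fast path is provided but not default).  Exact on
  geometric vectors; biased upward when the gate is broad relative to
  $\tau$.  Non-positive samples are dropped; fewer than three remaining
  points, or a flat/rising profile, yields a flagged non-converged
  result rather than an exception.
* `rld()` -- $\tau = \Delta / \ln(I_1/I_2)$ from the first two post-peak
  samples; flagged when $I_1 \le I_2$.
* `phasor()` -- $g = \sum D\cos(\omega t)/\sum D$,
  $s = \sum D \sin(\omega t)/\sum D$, $\tau = s/(\omega g)$, with
  $\omega$ defaulting to one cycle per measurement window.  Noiseless
  mono-exponentials land on the universal semicircle
  $(g - \tfrac12)^2 + s^2 = \tfrac14$, which the tests assert.
* `fit_image()` applies any of these per pixel; failures and background
  pixels become flagged invalid pixels, never aborted images, and
  summaries report mean, *population* SD and valid-pixel counts.

## The network

All kernels are $1\times1$ in the spatial dimensions, so the network is
exactly a per-pixel function of the six gate samples -- which is why it
can be trained on synthetic pixels and applied to any image size, and
why pixel-permutation equivariance holds exactly.  The layout:

1. 3D convolution, kernel (1,1,6), 64 filters, BN, ReLU ("same" padding
   along the six-deep time axis);
2. a 3D residual block: two (1,1,6) convolutions with 32 filters
   (BN after each, ReLU between), plus an additive skip carrying a
   pointwise $1\times1\times1$ projection from 64 to 32 channels, ReLU
   after the addition;
3. reshape merging depth and channels: $6 \times 32 = 192$ per-pixel
   features;
4. (1,1) 2D convolution to 32 channels, BN, ReLU;
5. two 2D residual blocks (identity skips) at 32 channels;
6. a down-sampling head of four (1,1) convolutions with filter counts
   400, 60, 20, 1 -- BN + ReLU after the first three, a linear final
   convolution -- and a ReLU output so lifetimes are non-negative.

The head schedule is not stated by the reference description; it was
fixed by enumerating small strictly decreasing 4-tuples and counting
conventions until the published trainable-parameter count, **71,461**,
is reproduced exactly (BN scale/shift counted as trainable, running
statistics excluded).  That parameter count is asserted in the test
suite and acts as the anchor for the otherwise under-specified head.
Feature extraction for embedding diagnostics taps the output of stage 5
(32 features per pixel).

Implementation note: because every kernel is spatially $1\times1$, the
network is implemented as a per-pixel matrix engine (dense maps, a
depth-axis 1D convolution, batch normalization, ReLU) with hand-written
backpropagation, verified against central finite differences in the test
suite; the memory-bound elementwise steps are fused C++ kernels.
Inference additionally uses a deterministic row-independent matrix
multiply: optimized BLAS applies different micro-kernels to interior and
remainder rows, which would break *bitwise* pixel-permutation
equivariance at the last floating-point bit, so `predict()` accumulates
each output element in a fixed order instead (training keeps BLAS for
speed).

## Training

Loss: mean over the batch of squared residual norms,
$L(\Theta) = \frac1M \sum_i \lVert F(Y_i,\Theta) - Y_i'\rVert^2$ with
$M = 16$ images per batch, computed over *all* pixels including the
zero-lifetime background (a foreground-masked variant is available).
Optimizer: RMSprop with the published schedule -- learning-rate decay by
$e^{-0.1}$ after every 10 epochs, early stopping with 32-epoch patience
on the validation loss, best weights restored, 0.8/0.2 train/validation
split.

Two deliberate deviations from the printed recipe, both exposed as
configuration:

* **Learning rate.** The printed initial rate of 0.1 is kept as the
  default of `fltcnn_training_config()`, but desk-scale runs in this
  package use $10^{-3}$ (the standard RMSprop default).  RMSprop
  normalizes gradient magnitude, so the parameter step size is of order
  the learning rate itself; 0.1 ns-scale steps cannot resolve lifetimes
  to the hundredth of a nanosecond within a few hundred optimizer steps.
* **BN momentum 0.9** (not 0.99): desk-scale runs take only a few
  hundred steps, and a 0.99 momentum leaves the inference-mode running
  statistics materially stale relative to the trained weights.

The final 1-channel convolution's bias is initialized at 1 ns (the
middle of the training range) so the ReLU output starts alive.

## Scaled protocols and what they show

The reference experiment trains on 4,000 images of $128\times128$
pixels.  The package supports that size, but its tests and acceptance
script run a reduced protocol chosen to finish on a single CPU: **200
images of $32\times32$ pixels, 30 epochs** (about 160k training pixels,
300 optimizer steps).  Under that protocol the held-out noiseless MAE
over the training lifetime range is well under 0.15 ns.

* *MAE versus SNR*: subsets are generated at controlled SNR by tuning
  the amplitude so each decay's total count hits the target
  ($\text{counts} = \mathrm{SNR}^2$); the achieved SNR is recorded.  The
  reduced protocol uses three buckets at 10, 25 and 40 dB: under the
  count-based dB convention the training amplitudes correspond to
  roughly 34--41 dB, so the sweep spans noise-dominated through
  training-regime conditions, and subset-mean MAE must be
  non-increasing.
* *Lifetime sweep*: test lifetimes over 0.2--3 ns at amplitudes 10--100
  probe behavior beyond the training range; errors grow outside it.
* *Offset robustness*: a uniform-lifetime scene is simulated noiselessly
  twice, the second time with a linear ramp of per-pixel timing offsets
  applied as whole-bin right-shifts of the dense traces.  Peak-aligned
  estimators (the network, tail fit, RLD on aligned gates) are bitwise
  invariant; estimators sampling at fixed delays relative to the trigger
  (`phasor_fixed`, `rld_fixed`) shift.  The simulation is noiseless so
  the comparison isolates the offset effect.
* *Feature embedding*: per-pixel features are embedded with a compact
  exact t-SNE (perplexity-calibrated affinities, early exaggeration,
  momentum descent; written in-package).  Plot appearance is never
  asserted; instead the Spearman rank correlation between each point's
  lifetime and its nearest embedding neighbor's lifetime quantifies the
  lifetime gradient.

What passing these protocols does *not* show: the synthetic data are
mono-exponential with a stationary super-Gaussian IRF and Poisson noise
only.  Real tissue exhibits multi-exponential decays, autofluorescence
background, sensor read noise and afterpulsing, none of which are
modelled; accuracy on the synthetic conditions bounds nothing about
misspecified decays.  Bi-exponential models are out of scope by design.

## File formats

Stacks travel as multi-page TIFF (one page per time point, row/column/
time axis order) with a JSON sidecar carrying the gate spacing or dense
time grid and a scale factor -- the TIFF writer stores 32-bit samples
normalized to $[0,1]$, so values are rescaled on read (relative
precision about $2\times10^{-10}$); temporal metadata is never inferred
from pixel data.  Lifetime maps are written as a lifetime page plus a
binary validity page, with a CSV summary and a JSON provenance record
(seed, configuration, package version).  Run configurations round-trip
through YAML.  A thin command-line wrapper (`inst/cli/flimgate`) exposes
`simulate`, `estimate`, `train`, `evaluate` and `benchmark`.

## A worked session

```{r example}
library(flimgate)

cfg <- flim_sim_config(seed = 101)
train <- generate_dataset(cfg, 200, 32, 32)

model <- build_fltcnn(seed = 1)
model <- fltcnn_train(model, train,
                      fltcnn_training_config(lr_initial = 1e-3,
                                             max_epochs = 30, seed = 2))
plot(model)

test <- generate_dataset(flim_sim_config(seed = 999), 1, 32, 32)
stack <- gated_stack(test$gates[, , , 1], cfg$gate_spacing)
map_cnn <- predict(model, stack)
map_tail <- fit_image(stack, "tail")
rbind(summarize_map(map_cnn, test$mask[, , 1]),
      summarize_map(map_tail, test$mask[, , 1]))
```
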