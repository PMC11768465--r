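# flimgate

Fit-free fluorescence lifetime estimation from six time gates.

## The problem

Fluorescence lifetime imaging (FLIM) maps, per pixel, the characteristic
decay time of fluorescence emission — a contrast mechanism that, unlike
intensity, is independent of fluorophore concentration and illumination.
Wide-field time-gated cameras make FLIM fast enough for surgical guidance
by recording only a handful of nanosecond-gated intensity samples per
pixel, but that speed comes at a price for the analysis:

* with ~6 samples there is no photon histogram to fit;
* in an endoscopic system the instrument response function (IRF) cannot
  be measured, ruling out re-convolution fitting;
* the gate window (~4 ns) is *wider* than the lifetimes of interest
  (0.6–2 ns for near-infrared dyes such as ICG), so tail fitting and
  rapid lifetime determination (RLD) are biased;
* surface-height variation introduces per-pixel timing offsets that
  corrupt phase-based (phasor) estimates.

`flimgate` implements an IRF-free estimation pipeline for this regime:
a synthetic-decay simulator with the instrument's statistical structure,
the classical estimators for comparison, and a spatially independent
convolutional network (one lifetime per pixel from six gate samples,
71,461 trainable parameters) trained purely on the synthetic data.

## The model

Each pixel's decay is mono-exponential under a super-Gaussian IRF with
Poisson noise:

    D(t) = IRF(t) * A·exp(−t/τ) + ε(t)
    IRF(t) = exp[ −2( 2(t−t₀)·(0.5·ln2)^(1/2N) / FWHM )^(2N) ]

with per-pixel FWHM ~ U[4, 4.5] ns, order N = 4, τ ~ U[0.6, 2] ns,
A ~ U[20, 100] counts. Gates are six point samples of the convolved
trace, 1 ns apart, starting at the decay peak and max-normalized — peak
alignment makes the representation invariant to timing offsets, and the
network absorbs the unknown IRF by being trained across its range.
SNR is defined as √(total photon count). The methods vignette
(`vignettes/flimgate-methods.Rmd`) documents every modelling and
numerical choice.

## Worked example

```r
library(flimgate)

cfg <- flim_sim_config(seed = 7)
ds  <- generate_dataset(cfg, 1, 32, 32)
ds
#> <flim_dataset> 1 images of 32 x 32 pixels, 6 gates (spacing 1 ns)
#>   foreground fraction 0.15; median per-pixel SNR 77.1

stack <- gated_stack(ds$gates[, , , 1], cfg$gate_spacing)
rbind(summarize_map(fit_image(stack, "tail"), ds$mask[, , 1], "tail fit"),
      summarize_map(suppressWarnings(fit_image(stack, "rld")),
                    ds$mask[, , 1], "RLD"))
#>      label mean_tau    sd_tau   n method
#> 1 tail fit 1.816468 0.6093909 151   tail
#> 2      RLD 3.088118 2.8180887 151    rld
```

The true lifetimes average ~1.3 ns: with a 4 ns gate, the six-point tail
fit overestimates (mean 1.82 ns) and two-gate RLD is far worse (mean
3.09 ns, SD 2.8 ns) — the failure modes the network is built to avoid.
When the IRF *is* known, full-decay re-convolution fitting is exact:

```r
trace <- simulate_decay(tau = 1.3, amplitude = 60,
                        irf = irf_params(10, 4.2, 4), grid = time_grid())
reconvolution_fit(trace, irf_params(10, 4.2, 4))
#> <flim_fit> tau = 1.3 ns, A = 60, offset = 5.564e-11 (converged, 5 iter)
```

Training and applying the network (about 9 minutes at the reduced scale;
see the vignette for the protocol):

```r
train <- generate_dataset(flim_sim_config(seed = 101), 200, 32, 32)
model <- build_fltcnn(seed = 1)
model <- fltcnn_train(model, train,
                      fltcnn_training_config(lr_initial = 1e-3,
                                             max_epochs = 30, seed = 2))
map <- predict(model, stack)   # lifetime map, one τ per pixel
```

A command-line wrapper is installed at `inst/cli/flimgate`
(`simulate`, `estimate`, `train`, `evaluate`, `benchmark`).

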