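# Shared fixtures and independent oracles for the test suite.

# brute-force O(n^2) discrete convolution oracle (truncated, dt-scaled):
# c_k = dt * sum_{i <= k} a_i * b_{k-i}
direct_conv <- function(a, b, dt = 1) {
  n <- length(a)
  out <- numeric(n)
  for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(k)) s <- s + a[i] * b[k - i + 1]
    out[k] <- s
  }
  out * dt
}

# small, fast simulation configuration (short grid keeps per-test cost low;
# tail after the peak still fits 5 gate spacings for tau <= 3 ns)
quick_cfg <- function(...) {
  flim_sim_config(grid = time_grid(0, 0.05, 600L), ...)
}

# single-pixel configuration with fixed truth, for pipeline checks
pixel_cfg <- function(tau, amp = 50, ...) {
  flim_sim_config(mask_source = "user_supplied",
                  mask = matrix(TRUE, 1, 1),
                  tau_range = c(tau, tau), amp_range = c(amp, amp),
                  grid = time_grid(0, 0.05, 600L), ...)
}

# a tiny trained network shared by the training-dependent tests; trained
# once per test run (lazily) under a fixed seed on the study conditions at
# reduced scale
trained_model_cache <- new.env(parent = emptyenv())

get_scaled_trained_model <- function() {
  if (!is.null(trained_model_cache$model)) return(trained_model_cache$model)
  ds <- generate_dataset(flim_sim_config(seed = 101), 200, 32, 32)
  model <- build_fltcnn(seed = 1)
  tc <- fltcnn_training_config(lr_initial = 1e-3, batch_size = 16L,
                               max_epochs = 30L, seed = 2)
  model <- fltcnn_train(model, ds, tc)
  trained_model_cache$model <- model
  model
}
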