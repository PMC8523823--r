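# Shared fixtures, built lazily once per run. All synthetic inputs are
# generated in code; nothing is read from disk.
.fx <- new.env(parent = emptyenv())

# noiseless, jitter-free truth: the deterministic plant
fx_truth_clean <- function() {
  if (is.null(.fx$truth_clean))
    .fx$truth_clean <- synthetic_truth(noise_sd = 0, trial_jitter = 0,
                                       subject_jitter = 0)
  .fx$truth_clean
}

fx_trial_clean <- function() {
  if (is.null(.fx$trial_clean))
    .fx$trial_clean <- generate_trial(fx_truth_clean(), "plate", 1L, 1L)
  .fx$trial_clean
}

fx_model <- function(truth = fx_truth_clean()) {
  ankle_model(truth$activation, truth$muscles, truth$geometry,
              truth$gamma_df, truth$gamma_pf)
}

# small curve dataset with a known condition effect added on top of
# subject-specific smooth baselines
fx_curves <- function(S = 8L, C = 4L, N = 101L, effect = 0, sd = 1,
                      seed = 7L) {
  withr::with_seed(seed, {
    pct <- seq(0, 100, length.out = N)
    base <- sin(pct / 100 * pi)
    Y <- array(0, c(S, C, N))
    for (s in seq_len(S)) for (cc in seq_len(C)) {
      Y[s, cc, ] <- base * (5 + rnorm(1)) + rnorm(1) +
        stats::filter(rnorm(N, 0, sd), rep(1 / 4, 4), sides = 2,
                      circular = TRUE) +
        effect * (cc - 1) * base
    }
    curve_dataset(Y)
  })
}
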