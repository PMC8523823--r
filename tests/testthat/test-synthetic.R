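test_that("trial generation is bit-identical under the same stream", {
  tru <- synthetic_truth()
  a <- generate_trial(tru, "eva", 2L, 3L)
  b <- generate_trial(tru, "eva", 2L, 3L)
  expect_identical(a, b)
  # and differs across trial indices and conditions
  expect_false(identical(a$tau_id, generate_trial(tru, "eva", 3L, 3L)$tau_id))
  expect_false(identical(a$emg, generate_trial(tru, "epe", 2L, 3L)$emg))
})

test_that("a zero-noise trial is self-consistent with the truth forward model", {
  tr <- fx_trial_clean()
  js <- estimate_trial(fx_model(), tr)
  expect_lt(nrmse(js$native$tau, tr$tau_id), 1e-6)
})

test_that("generated excitations stay in [0, 1] across the design", {
  tru <- synthetic_truth(seed = 77)
  ds <- generate_dataset(tru, n_subjects = 2, trials_per_condition = 2)
  for (tr in ds$trials) {
    expect_true(all(tr$emg >= 0 & tr$emg <= 1))
    expect_true(all(attr(tr, "envelopes") >= 0 & attr(tr, "envelopes") <= 1))
  }
})

test_that("a compliant surface raises mid-stance plantar-flexion moment everywhere", {
  tru <- synthetic_truth(noise_sd = 0, trial_jitter = 0, subject_jitter = 0,
                         surface_effect = 0.10)
  base <- generate_trial(tru, "plate", 1L, 1L)
  soft <- generate_trial(tru, "epe", 1L, 1L)
  pct <- base$time / max(base$time) * 100
  mid <- which(pct >= 40 & pct <= 60)
  # dorsiflexion-positive: a stronger plantar-flexor drive pushes tau down
  expect_true(all(soft$tau_id[mid] < base$tau_id[mid]))
  expect_true(all(abs(soft$tau_id[mid]) > abs(base$tau_id[mid])))
})

test_that("dataset generation fills the full subject-condition-trial design", {
  tru <- synthetic_truth(rate = 50, stance_duration = 0.6)
  ds <- generate_dataset(tru, n_subjects = 10, trials_per_condition = 4)
  expect_length(ds$trials, 160)
  man <- ds$manifest
  expect_equal(nrow(unique(man[c("subject", "condition")])), 40)
  expect_true(all(table(man$subject, man$condition) == 4))
  # reproducible end to end
  ds2 <- generate_dataset(tru, n_subjects = 10, trials_per_condition = 4)
  expect_identical(ds$trials[[57]], ds2$trials[[57]])
})

test_that("zero subject jitter leaves every subject at the base truth", {
  tru <- synthetic_truth(subject_jitter = 0)
  ds <- generate_dataset(tru, n_subjects = 3, trials_per_condition = 1)
  for (st in ds$subject_truths) expect_identical(st$bursts, tru$bursts)
})

test_that("invalid generator inputs are rejected", {
  tru <- synthetic_truth()
  expect_error(generate_trial(tru, "ice"), "unknown condition")
  expect_error(generate_dataset(tru, n_subjects = 0), "positive")
  expect_error(generate_dataset(tru, 2, trials_per_condition = -1), "positive")
  expect_error(synthetic_truth(gamma_pf = 1.5), "strictly inside")
  bad <- default_bursts()
  bad$SOL$peak <- 1.2
  expect_error(synthetic_truth(bursts = bad), "peaks")
})

test_that("trial containers enforce their invariants", {
  expect_error(gait_trial(100, 1:10, matrix(0, 10, 1,
                                            dimnames = list(NULL, "TA")),
                          theta = 1:10, tau_id = 1:10, stance_start = 5,
                          stance_end = 3),
               "stance")
  expect_error(gait_trial(100, 1:10, matrix(0, 9, 1,
                                            dimnames = list(NULL, "TA")),
                          theta = 1:10, tau_id = 1:10))
})
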