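# cheap low-resolution truth for optimizer-mechanics tests
fast_truth <- function(...) {
  synthetic_truth(noise_sd = 0, rate = 50, stance_duration = 0.6, ...)
}

test_that("the objective is zero at the generating truth and scales as stated", {
  tru <- fast_truth(trial_jitter = 0)
  trials <- lapply(1:2, function(i) generate_trial(tru, "plate", i, 1))
  spec <- calibration_spec()
  p_truth <- c(C1 = tru$activation$C1, C2 = tru$activation$C2,
               A = tru$activation$A, gamma_df = tru$gamma_df,
               gamma_pf = tru$gamma_pf,
               stats::setNames(rep(1, 4), paste0("lm0_", names(tru$muscles))),
               stats::setNames(rep(1, 4), paste0("lst_", names(tru$muscles))))
  expect_lt(calibration_objective(p_truth, trials, spec), 1e-10)

  # constant 1 N m offset -> J = 1 exactly
  off <- trials[[1]]
  off$tau_id <- off$tau_id + 1
  expect_equal(calibration_objective(p_truth, list(off), spec), 1)

  # duplicating trials leaves the pooled mean unchanged
  expect_equal(calibration_objective(p_truth, list(off, off), spec), 1)
})

test_that("pathological candidates earn a finite penalty, not an error", {
  tru <- fast_truth(trial_jitter = 0)
  trials <- list(generate_trial(tru, "plate", 1, 1))
  spec <- calibration_spec()
  p_bad <- c(C1 = 2, C2 = 0, A = -1, gamma_df = 1, gamma_pf = 1,
             stats::setNames(rep(1, 4), paste0("lm0_", names(tru$muscles))),
             stats::setNames(rep(1, 4), paste0("lst_", names(tru$muscles))))
  expect_equal(calibration_objective(p_bad, trials, spec), 1e6)
})

test_that("the bounding transform round-trips and respects the bounds", {
  spec <- calibration_spec()
  lo <- spec$lower; hi <- spec$upper
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- lo + runif(length(lo)) * (hi - lo)
      x <- anklemsk:::bound_inverse(p, lo, hi)
      back <- anklemsk:::bound_transform(x, lo, hi)
      expect_equal(unname(back), unname(p), tolerance = 1e-7)
      # arbitrary unconstrained points always map inside the bounds
      z <- anklemsk:::bound_transform(rnorm(length(lo), 0, 10), lo, hi)
      expect_true(all(z >= lo - 1e-12 & z <= hi + 1e-12))
    }
  })
})

test_that("moment recovery degrades smoothly under inverse-dynamics noise", {
  # noise at 5% of the peak experimental moment
  clean <- generate_trial(synthetic_truth(noise_sd = 0, trial_jitter = 0),
                          "plate", 1, 1)
  sd5 <- 0.05 * max(abs(clean$tau_id))
  tru <- synthetic_truth(noise_sd = sd5)
  trials <- lapply(1:4, function(i) generate_trial(tru, "plate", i, 1))
  res <- calibrate(trials, calibration_spec(n_starts = 2, seed = 13))
  expect_lte(res$nrmse_mean, 0.15)
})

test_that("calibration is deterministic, bounded and beats its starts", {
  tru <- fast_truth()
  trials <- lapply(1:2, function(i) generate_trial(tru, "plate", i, 1))
  spec <- calibration_spec(n_starts = 2, maxit = 80, max_cycles = 1,
                           seed = 11)
  r1 <- calibrate(trials, spec)
  r2 <- calibrate(trials, spec)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$J, r2$J)
  expect_true(all(r1$par >= spec$lower & r1$par <= spec$upper))
  expect_true(all(r1$J <= r1$start_J0 + 1e-12))
  # the reported objective is reproduced by a cold re-evaluation
  expect_equal(calibration_objective(r1$par, trials, spec), r1$J,
               tolerance = 1e-8)
})
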