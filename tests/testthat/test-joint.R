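test_that("ankle moment is the signed sum of force times arm", {
  one <- ankle_moment(list(M = rep(100, 3)), list(M = rep(0.05, 3)))
  expect_equal(one, rep(5, 3))
  bal <- ankle_moment(list(TA = rep(50, 2), SOL = rep(40, 2)),
                      list(TA = rep(0.04, 2), SOL = rep(-0.05, 2)))
  expect_equal(bal, rep(0, 2))
  expect_equal(ankle_moment(list(A = numeric(4), B = numeric(4)),
                            list(A = rep(0.1, 4), B = rep(-0.1, 4))),
               numeric(4))
  expect_error(ankle_moment(list(A = 1:3), list(A = 1:2)), "length")
  expect_error(ankle_moment(list(A = 1:3), list(B = 1:3)), "named")
})

test_that("ankle moment is linear over muscle sets", {
  withr::with_seed(21, {
    f1 <- list(A = rnorm(5), B = rnorm(5))
    f2 <- list(C = rnorm(5))
    r1 <- list(A = rnorm(5), B = rnorm(5))
    r2 <- list(C = rnorm(5))
    expect_equal(ankle_moment(c(f1, f2), c(r1, r2)),
                 ankle_moment(f1, r1) + ankle_moment(f2, r2))
  })
})

test_that("joint stiffness combines MTU stiffness and the arm-slope term", {
  # single MTU, constant arm: K = Kmt r^2
  ks <- ankle_stiffness(list(M = rep(1000, 3)), list(M = rep(100, 3)),
                        list(M = rep(0.05, 3)), list(M = rep(0, 3)))
  expect_equal(ks$K, rep(2.5, 3))
  # with signed moment arms the slope term enters as -Fmt * dr/dtheta
  ks <- ankle_stiffness(list(M = rep(1000, 3)), list(M = rep(100, 3)),
                        list(M = rep(0.05, 3)), list(M = rep(0.01, 3)))
  expect_equal(ks$K_raw, rep(1.5, 3))
  # a dominant slope term drives the raw sum negative: clamped and flagged
  ks <- ankle_stiffness(list(M = rep(10, 2)), list(M = rep(500, 2)),
                        list(M = rep(0.05, 2)), list(M = rep(0.05, 2)))
  expect_true(all(ks$K_raw < 0))
  expect_equal(ks$K, rep(0, 2))
  expect_true(all(ks$flagged))
})

test_that("joint stiffness equals minus the moment-angle derivative at frozen activation", {
  tru <- fx_truth_clean()
  tr <- fx_trial_clean()
  mdl <- fx_model()
  js <- estimate_trial(mdl, tr, keep_states = TRUE)
  acts <- lapply(names(mdl$muscles), function(m)
    excitation_to_activation(tr$emg[, m], mdl$activation, tr$rate))
  names(acts) <- names(mdl$muscles)
  tau_at <- function(theta, k) {
    g <- evaluate_geometry(mdl$geometry, theta)
    s <- 0
    for (m in names(mdl$muscles)) {
      p <- mdl$muscles[[m]]
      p$Fmax <- p$Fmax * if (p$group == "dorsiflexor") mdl$gamma_df else mdl$gamma_pf
      st <- solve_equilibrium(acts[[m]][k], g[[m]]$lmt, p, tr$rate,
                              vtilde = js$states[[m]]$vtil[k])
      s <- s + st$Fmt * g[[m]]$r
    }
    s
  }
  h <- 1e-5
  for (k in c(20, 36, 55)) {
    slope <- (tau_at(tr$theta[k] + h, k) - tau_at(tr$theta[k] - h, k)) / (2 * h)
    expect_equal(js$native$K_raw[k], -slope,
                 tolerance = 0.01 * max(1, abs(slope)))
  }
})

test_that("time normalization resamples onto the stance grid", {
  expect_equal(as.numeric(time_normalize(rep(3.2, 50))), rep(3.2, 101))
  ramp <- time_normalize(seq(0, 10, length.out = 51))
  expect_equal(as.numeric(ramp), seq(0, 10, length.out = 101))
  y <- sin(seq(0, 3, length.out = 101))
  expect_equal(as.numeric(time_normalize(y)), y)  # same-grid identity
  expect_equal(attr(time_normalize(1:50), "pct"), seq(0, 100, 1))
  expect_error(time_normalize(1:10, c(5, 5)), "stance")
  expect_error(time_normalize(1:10, c(0, 10)), "stance")
})

test_that("NRMSE normalizes by the RMS of the experimental moment", {
  x <- c(1, -2, 3)
  expect_equal(nrmse(x, x), 0)
  expect_equal(nrmse(numeric(3), x), 1)
  expect_equal(nrmse(c(3, 0), c(3, 4)), 0.8)
  expect_error(nrmse(c(1, 2), c(0, 0)), "zero RMS")
})
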