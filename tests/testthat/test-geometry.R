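cubic_samples <- function(n = 12, lmt_coef = c(0.30, -0.04, 0.003, 0.001),
                          r_coef = c(0.05, -0.01, 0.002, -0.001)) {
  th <- seq(-0.4, 0.3, length.out = n)
  list(M = data.frame(
    theta = th,
    lmt = lmt_coef[1] + lmt_coef[2] * th + lmt_coef[3] * th^2 + lmt_coef[4] * th^3,
    r = r_coef[1] + r_coef[2] * th + r_coef[3] * th^2 + r_coef[4] * th^3))
}

test_that("an exact cubic is recovered to near machine precision", {
  lmt_coef <- c(0.30, -0.04, 0.003, 0.001)
  r_coef <- c(0.05, -0.01, 0.002, -0.001)
  g <- fit_geometry(cubic_samples(12, lmt_coef, r_coef), degree = 3)
  expect_equal(g$muscles$M$lmt_coef, lmt_coef, tolerance = 1e-10)
  expect_equal(g$muscles$M$r_coef, r_coef, tolerance = 1e-10)
  expect_lt(g$muscles$M$rms["lmt"], 1e-12)
})

test_that("underdetermined and degenerate fits are rejected", {
  s <- cubic_samples(12)
  expect_error(fit_geometry(list(M = s$M[1:3, ]), degree = 3), "distinct angle")
  dup <- s$M
  dup$theta <- rep(0.1, nrow(dup))
  expect_error(fit_geometry(list(M = dup), degree = 3), "distinct angle|rank")
})

test_that("residual RMS of a noisy fit stays near the noise level", {
  sd <- 1e-4
  for (seed in 1:5) {
    noisy <- withr::with_seed(seed, {
      s <- cubic_samples(40)
      s$M$lmt <- s$M$lmt + rnorm(40, 0, sd)
      s$M$r <- s$M$r + rnorm(40, 0, sd)
      s
    })
    g <- fit_geometry(noisy, degree = 3)
    expect_lte(g$muscles$M$rms[["lmt"]], 2 * sd)
    expect_lte(g$muscles$M$rms[["r"]], 2 * sd)
  }
})

test_that("the moment-arm derivative is the exact polynomial derivative", {
  th <- seq(-0.3, 0.3, length.out = 10)
  flat <- list(M = data.frame(theta = th, lmt = 0.3 - 0.04 * th,
                              r = rep(0.05, 10)))
  g <- fit_geometry(flat, degree = 2)
  ev <- evaluate_geometry(g, c(-0.1, 0, 0.2))
  expect_equal(ev$M$dr_dtheta, rep(0, 3), tolerance = 1e-10)

  lin <- list(M = data.frame(theta = th, lmt = 0.3 - 0.04 * th,
                             r = 0.05 - 0.012 * th))
  ev <- evaluate_geometry(fit_geometry(lin, degree = 2), c(-0.2, 0.1))
  expect_equal(ev$M$dr_dtheta, rep(-0.012, 2), tolerance = 1e-10)

  quad <- list(M = data.frame(theta = th, lmt = 0.3 - 0.04 * th,
                              r = 0.05 - 0.01 * th + 0.004 * th^2))
  g <- fit_geometry(quad, degree = 2)
  h <- 1e-5
  fd <- (evaluate_geometry(g, 0.1 + h)$M$r -
           evaluate_geometry(g, 0.1 - h)$M$r) / (2 * h)
  expect_equal(evaluate_geometry(g, 0.1)$M$dr_dtheta, fd, tolerance = 1e-6)
})

test_that("evaluation outside the fitted range is an error, not extrapolation", {
  g <- fit_geometry(cubic_samples(12), degree = 3)
  expect_error(evaluate_geometry(g, c(0.0, 0.9)), "sample 2")
  expect_error(evaluate_geometry(g, -0.5), "validity range")
})

test_that("the default geometry is tendon-excursion consistent", {
  cons <- excursion_consistency(default_geometry())
  expect_equal(cons$ratio, rep(1, 4), tolerance = 1e-6)
  expect_false(any(cons$flagged))
})

test_that("geometry samples can carry seeded noise and reproduce", {
  a <- generate_geometry_samples(noise_sd = 1e-4, seed = 9)
  b <- generate_geometry_samples(noise_sd = 1e-4, seed = 9)
  expect_identical(a, b)
})
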