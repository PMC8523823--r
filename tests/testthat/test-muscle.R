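test_that("tendon force follows the printed piecewise model", {
  Fmax <- 1000
  expect_equal(tendon_force(-0.01, Fmax), 0)
  expect_equal(tendon_force(0, Fmax), 0)
  # linear branch at the transition strain: 37.5 * 0.0127 - 0.2375
  expect_equal(tendon_force(0.0127, Fmax), 0.23875 * Fmax)
  expect_equal(tendon_force(0.02, Fmax), 0.5125 * Fmax)
})

test_that("tendon force is continuous at both branch points and monotone", {
  Fmax <- 1
  d <- 1e-9
  expect_lt(abs(tendon_force(d, Fmax) - tendon_force(-d, Fmax)), 1e-3)
  expect_lt(abs(tendon_force(0.0127 + d, Fmax) - tendon_force(0.0127 - d, Fmax)),
            1e-3)
  eps <- seq(-0.05, 0.08, by = 1e-4)
  expect_true(all(diff(tendon_force(eps, Fmax)) >= 0))
})

test_that("fiber force honors the curve normalizations", {
  Fmax <- 1234
  expect_equal(fiber_force(1, 1, 0, Fmax), Fmax)     # f_l(1)=f_v(0)=1
  expect_equal(fiber_force(0, 1, 0, Fmax), 0)        # passive zero at optimum
  expect_equal(fiber_force(1, 1, -1, Fmax), 0)       # shortening at vmax
  expect_error(fiber_force(NaN, 1, 0, Fmax), "finite")
})

test_that("slack configuration carries (near) zero force", {
  p <- default_muscles()$SOL
  lmt <- rep(p$lst + p$lm0 * cos(p$phi0), 30)
  st <- solve_equilibrium(rep(0, 30), lmt, p, rate = 100)
  # only the 0.005 activation floor loads the tendon
  expect_lt(max(abs(st$Ft)), 0.01 * p$Fmax)
  expect_lt(max(abs(st$eps)), 5e-3)
})

test_that("rigid-tendon mode matches the closed-form fiber geometry", {
  p <- default_muscles()$GAM
  lmt <- p$lst + p$lm0 * cos(p$phi0) + seq(0, 0.01, length.out = 20)
  st <- solve_equilibrium(rep(0.5, 20), lmt, p, rate = 100,
                          rigid_tendon = TRUE)
  h <- p$lm0 * sin(p$phi0)
  expect_equal(st$lm, sqrt((lmt - p$lst)^2 + h^2), tolerance = 1e-12)
  expect_equal(st$lt, rep(p$lst, 20))
})

test_that("steady equilibrium is independent of rate and record length", {
  p <- default_muscles()$TA
  lmt0 <- p$lst + p$lm0 * cos(p$phi0) + 0.002
  st1 <- solve_equilibrium(rep(0.5, 10), rep(lmt0, 10), p, rate = 100)
  st2 <- solve_equilibrium(rep(0.5, 200), rep(lmt0, 200), p, rate = 2000)
  expect_equal(tail(st1$lt, 1), tail(st2$lt, 1), tolerance = 1e-9)
  expect_equal(tail(st1$Fm, 1), tail(st2$Fm, 1), tolerance = 1e-5)
})

test_that("equilibrium residual and the pennation constraint hold on a gait trial", {
  tru <- fx_truth_clean()
  tr <- fx_trial_clean()
  mdl <- fx_model()
  for (m in names(mdl$muscles)) {
    p <- mdl$muscles[[m]]
    g <- if (p$group == "dorsiflexor") tru$gamma_df else tru$gamma_pf
    p$Fmax <- p$Fmax * g
    a <- excitation_to_activation(tr$emg[, m], mdl$activation, tr$rate)
    lmt <- evaluate_geometry(mdl$geometry, tr$theta)[[m]]$lmt
    st <- solve_equilibrium(a, lmt, p, tr$rate)
    # force balance Ft = Fm cos(phi)
    expect_lt(max(abs(st$Ft - st$Fm * cos(st$phi))), 1e-6)
    # geometric closure lm cos(phi) + lt = lmt
    expect_lt(max(abs(st$lm * cos(st$phi) + st$lt - lmt)), 1e-9)
    # constant-thickness pennation rule
    expect_equal(st$lm * sin(st$phi), rep(p$lm0 * sin(p$phi0), nrow(st)),
                 tolerance = 1e-9)
  }
})

test_that("analytic stiffness matches central finite differences to 0.1%", {
  p <- default_muscles()$SOL
  lmt0 <- p$lst + p$lm0 * cos(p$phi0) + 0.006  # linear tendon branch
  st <- solve_equilibrium(rep(0.8, 5), rep(lmt0, 5), p, rate = 100)
  ks <- mtu_stiffness(st, p, rep(0.8, 5))
  k <- 3

  # Kt vs finite difference of the tendon force in lt
  h <- 1e-7
  fd_kt <- (tendon_force((st$lt[k] + h - p$lst) / p$lst, p$Fmax) -
              tendon_force((st$lt[k] - h - p$lst) / p$lst, p$Fmax)) / (2 * h)
  expect_equal(ks$Kt[k], fd_kt, tolerance = 1e-3)

  # Km vs finite difference of the projected fiber force along the MTU line
  hh <- p$lm0 * sin(p$phi0)
  proj <- function(x) {
    lm <- sqrt(x^2 + hh^2)
    ltil <- lm / p$lm0
    Fm <- p$Fmax * (force_length_active(ltil) *
                      force_velocity(st$vtil[k]) * 0.8 +
                      force_length_passive(ltil))
    Fm * x / lm
  }
  x0 <- st$lm[k] * cos(st$phi[k])
  fd_km <- (proj(x0 + h) - proj(x0 - h)) / (2 * h)
  expect_equal(ks$Km[k], fd_km, tolerance = 1e-3)
})

test_that("series combination behaves at its limits", {
  st <- structure(data.frame(lm = 0.05, lt = 0.25, phi = 0, ltil = 1,
                             vtil = 0, eps = 0.02, Fm = 100, Ft = 100,
                             Fmt = 100),
                  class = c("mtu_state", "data.frame"))
  p <- muscle_params("X", Fmax = 1000, lm0 = 0.05, lst = 0.25, phi0 = 0)
  ks <- mtu_stiffness(st, p, a = 1)
  # linear-branch tendon: Kt = 37.5 * Fmax / lst
  expect_equal(ks$Kt, 37.5 * 1000 / 0.25)
  # harmonic combination Km = Kt = 2 -> Kmt = 1
  comb <- function(km, kt) km * kt / (km + kt)
  expect_equal(comb(2, 2), 1)
  # rigid tendon (Kt -> Inf): Kmt = Km
  attr(st, "rigid_tendon") <- TRUE
  ks_r <- mtu_stiffness(st, p, a = 1)
  expect_equal(ks_r$Kmt, ks_r$Km)
})
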