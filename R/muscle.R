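#' Hill-model muscle parameters
#'
#' @param name muscle label (e.g. `"TA"`, `"SOL"`, `"GAL"`, `"GAM"`).
#' @param Fmax maximum isometric force (N).
#' @param lm0 optimal fiber length (m).
#' @param lst tendon slack length (m).
#' @param phi0 pennation angle at optimal fiber length (rad), in
#'   \eqn{[0, \pi/2)}. Fiber thickness is assumed constant:
#'   \eqn{l_m \sin\Phi = l_{m0} \sin\Phi_0}.
#' @param vmax maximum contraction velocity in optimal fiber lengths per
#'   second (default 10).
#' @param group `"dorsiflexor"` or `"plantarflexor"`; selects which
#'   calibration strength coefficient scales `Fmax`.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(name, Fmax, lm0, lst, phi0, vmax = 10,
                          group = c("dorsiflexor", "plantarflexor")) {
  group <- match.arg(group)
  stopifnot(Fmax > 0, lm0 > 0, lst > 0, phi0 >= 0, phi0 < pi / 2, vmax > 0)
  structure(list(name = name, Fmax = Fmax, lm0 = lm0, lst = lst,
                 phi0 = phi0, vmax = vmax, group = group),
            class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf("muscle_params %s (%s): Fmax=%.0f N lm0=%.3f m lst=%.3f m phi0=%.1f deg vmax=%.0f lm0/s\n",
              x$name, x$group, x$Fmax, x$lm0, x$lst, x$phi0 * 180 / pi, x$vmax))
  invisible(x)
}

# --- normalized Hill curves ------------------------------------------------
# Standard phenomenological forms; constants are exposed as defaults so the
# shapes can be adjusted without touching the dynamics.

#' Active force--length curve
#'
#' Gaussian bell \eqn{f(\tilde l_m) = \exp(-(\tilde l_m - 1)^2 / w)} with
#' \eqn{f(1) = 1}.
#' @param ltil fiber length normalized to optimal fiber length.
#' @param width bell width parameter (default 0.45).
#' @return Normalized active force scale in (0, 1].
#' @export
force_length_active <- function(ltil, width = 0.45) {
  exp(-(ltil - 1)^2 / width)
}

fl_active_deriv <- function(ltil, width = 0.45) {
  -2 * (ltil - 1) / width * force_length_active(ltil, width)
}

#' Passive force--length curve
#'
#' Exponential toe \eqn{f_P(\tilde l_m) = (e^{k(\tilde l_m - 1)} - 1)/(e^{k/2} - 1)}
#' for \eqn{\tilde l_m > 1}, zero at or below optimal length.
#' @inheritParams force_length_active
#' @param k exponential rate (default 10; the denominator uses `k/2` so the
#'   passive force reaches 1 Fmax at 1.5 optimal lengths).
#' @return Normalized passive force (>= 0).
#' @export
force_length_passive <- function(ltil, k = 10) {
  ifelse(ltil > 1, (exp(k * (ltil - 1)) - 1) / (exp(k / 2) - 1), 0)
}

fl_passive_deriv <- function(ltil, k = 10) {
  ifelse(ltil > 1, k * exp(k * (ltil - 1)) / (exp(k / 2) - 1), 0)
}

#' Force--velocity curve
#'
#' Hill hyperbola for shortening (zero force at the maximum contraction
#' velocity \eqn{\tilde v_m = -1}) and a saturating eccentric branch with a
#' plateau at `flen` times isometric force.
#' @param vtil fiber velocity normalized to `vmax` (shortening negative).
#' @param af Hill shape constant for shortening (default 0.25).
#' @param flen eccentric plateau (default 1.4).
#' @return Normalized velocity force scale (>= 0).
#' @export
force_velocity <- function(vtil, af = 0.25, flen = 1.4) {
  ifelse(vtil < 0,
         pmax(0, (1 + vtil) / (1 - vtil / af)),
         1 + (flen - 1) * vtil / (vtil + 0.2))
}

#' Tendon force from strain
#'
#' Piecewise tendon force--strain model: slack below zero strain, a
#' quadratic toe region up to the transition strain 0.0127, and a linear
#' branch beyond,
#' \deqn{F_t = 0 \;(\varepsilon \le 0); \quad 1480.3\,F_{max}\varepsilon^2
#'   \;(0 < \varepsilon \le 0.0127); \quad (37.5\varepsilon - 0.2375)F_{max}
#'   \;(\varepsilon \ge 0.0127).}
#' The printed coefficients make the junction continuous to about
#' \eqn{10^{-5} F_{max}}.
#'
#' @param eps tendon strain \eqn{(l_t - l_{st}) / l_{st}} (any real value).
#' @param Fmax maximum isometric force (N).
#' @return Tendon force (N), non-negative and non-decreasing in `eps`.
#' @export
tendon_force <- function(eps, Fmax) {
  stopifnot(is.numeric(eps), is.numeric(Fmax), all(Fmax > 0))
  ifelse(eps <= 0, 0,
         ifelse(eps < 0.0127,
                1480.3 * Fmax * eps^2,
                (37.5 * eps - 0.2375) * Fmax))
}

# dFt/deps; divide by lst to get dFt/dlt
tendon_force_deriv <- function(eps, Fmax) {
  ifelse(eps <= 0, 0,
         ifelse(eps < 0.0127, 2 * 1480.3 * Fmax * eps, 37.5 * Fmax))
}

#' Fiber force
#'
#' Hill-type fiber force along the fiber direction,
#' \deqn{F_m = F_{max}\left[f(\tilde l_m) f(\tilde v_m) a + f_P(\tilde l_m)\right].}
#'
#' @param a activation in \eqn{[0, 1]}.
#' @param ltil normalized fiber length.
#' @param vtil normalized fiber velocity (shortening negative).
#' @param Fmax maximum isometric force (N).
#' @return Fiber force (N).
#' @export
fiber_force <- function(a, ltil, vtil, Fmax) {
  if (anyNA(a) || anyNA(ltil) || anyNA(vtil) ||
      !all(is.finite(a), is.finite(ltil), is.finite(vtil)))
    stop("non-finite inputs to fiber_force", call. = FALSE)
  if (any(a < -1e-9) || any(a > 1 + 1e-9))
    stop("activation must lie in [0, 1]", call. = FALSE)
  Fmax * (force_length_active(ltil) * force_velocity(vtil) * a +
            force_length_passive(ltil))
}

# --- elastic-tendon equilibrium -------------------------------------------

# Equilibrium residual Ft(lt) - Fm(lm(lt)) cos(Phi(lt)) at given velocity,
# vectorized over time steps; used to verify solver output against the
# R-level curve definitions. h = lm0*sin(phi0) is the constant fiber
# thickness; x = lmt - lt is the muscle length along the tendon line.
mtu_resid <- function(lt, lmt, a, vtil, p) {
  h <- p$lm0 * sin(p$phi0)
  x <- lmt - lt
  lm <- sqrt(x^2 + h^2)
  cosphi <- x / lm
  ltil <- lm / p$lm0
  eps <- (lt - p$lst) / p$lst
  Fm <- p$Fmax * (force_length_active(ltil) * force_velocity(vtil) * a +
                    force_length_passive(ltil))
  Ft <- tendon_force(eps, p$Fmax)
  list(r = Ft - Fm * cosphi, lm = lm, cosphi = cosphi, ltil = ltil,
       eps = eps, Fm = Fm, Ft = Ft)
}

#' Solve the elastic-tendon fiber/tendon equilibrium along a trial
#'
#' For each time step finds the tendon length \eqn{l_t \in (0, l_{mt})}
#' such that the tendon force balances the fiber force projected on the
#' tendon line, \eqn{F_t(\varepsilon) = F_m \cos\Phi}, under the
#' constant-thickness pennation rule \eqn{l_m \sin\Phi = l_{m0} \sin\Phi_0}.
#' Normalized fiber velocity is the two-point backward finite difference
#' of the solved fiber length against the previous accepted step (zero at
#' the first step) and is treated implicitly: it enters the residual of
#' the step being solved, which keeps the force--velocity coupling stable
#' at gait sampling rates. The sweep is sequential with the previous
#' step's root as the initial guess; each step uses a safeguarded Newton
#' iteration inside a sign bracket (compiled). A small activation floor
#' (0.005) avoids the degenerate flat residual of a fully inactive muscle
#' with an elastic tendon.
#'
#' @param a activation series in \eqn{[0, 1]}.
#' @param lmt MTU length series (m), same length as `a`.
#' @param p a [muscle_params()] object.
#' @param rate sampling rate (Hz).
#' @param rigid_tendon if `TRUE` the tendon is inextensible
#'   (\eqn{l_t \equiv l_{st}}) and fiber kinematics follow in closed form.
#' @param vtilde optional fixed normalized-velocity series; when supplied
#'   the velocity is frozen at these values (used e.g. to linearize the
#'   chain at frozen velocity).
#' @param resid_tol accepted equilibrium residual (N), default `1e-6`.
#' @return An object of class `mtu_state`: a data frame with per-step
#'   `lm`, `lt`, `phi`, `ltil`, `vtil`, `eps`, `Fm`, `Ft`, `Fmt` plus
#'   attributes `muscle` and `resid_max`.
#' @export
solve_equilibrium <- function(a, lmt, p, rate, rigid_tendon = FALSE,
                              vtilde = NULL, resid_tol = 1e-6) {
  stopifnot(inherits(p, "muscle_params"), length(a) == length(lmt),
            rate > 0)
  n <- length(a)
  a_eff <- pmin(pmax(a, 0.005), 1)
  h <- p$lm0 * sin(p$phi0)

  if (rigid_tendon) {
    lt <- rep(p$lst, n)
    x <- lmt - lt
    if (any(x <= 0))
      stop("rigid-tendon mode: MTU shorter than tendon slack length", call. = FALSE)
    lm <- sqrt(x^2 + h^2)
    vt <- c(0, diff(lm) * rate) / (p$vmax * p$lm0)
    rs <- mtu_resid(lt, lmt, a_eff, vt, p)
    return(new_mtu_state(p, lm, lt, rs, vt, resid_max = 0, rigid = TRUE))
  }

  fixed_v <- !is.null(vtilde)
  vt_in <- if (fixed_v) rep(vtilde, length.out = n) else numeric(n)
  sol <- .mtu_solve_cpp(a_eff, lmt, p$Fmax, p$lm0, p$lst, p$phi0, p$vmax,
                        rate, vt_in, fixed_v, tol = min(resid_tol, 1e-8) / 10)
  if (sol$resid_max > resid_tol) {
    rs0 <- mtu_resid(sol$lt, lmt, a_eff, sol$vtil, p)
    i <- which.max(abs(rs0$r))
    stop(sprintf(
      "equilibrium failure for %s: residual %.3g N > %.1g N at step %d (a=%.3f lmt=%.4f lt=%.4f ltil=%.3f eps=%.4f)",
      p$name, sol$resid_max, resid_tol, i, a_eff[i], lmt[i], sol$lt[i],
      rs0$ltil[i], rs0$eps[i]), call. = FALSE)
  }
  rs <- mtu_resid(sol$lt, lmt, a_eff, sol$vtil, p)
  new_mtu_state(p, sol$lm, sol$lt, rs, sol$vtil,
                resid_max = sol$resid_max, rigid = FALSE)
}

new_mtu_state <- function(p, lm, lt, rs, vt, resid_max, rigid) {
  st <- data.frame(lm = lm, lt = lt, phi = acos(pmin(pmax(rs$cosphi, -1), 1)),
                   ltil = rs$ltil, vtil = vt, eps = rs$eps,
                   Fm = rs$Fm, Ft = rs$Ft, Fmt = rs$Ft)
  attr(st, "muscle") <- p$name
  attr(st, "resid_max") <- resid_max
  attr(st, "rigid_tendon") <- rigid
  class(st) <- c("mtu_state", "data.frame")
  st
}

#' Fiber, tendon and MTU stiffness along a solved trajectory
#'
#' Computes, per time step, the muscle component stiffness `Km` (analytic
#' length-derivative of the Hill fiber force at frozen activation and
#' velocity, projected on the tendon line by \eqn{\cos^2\Phi} with the
#' geometric pennation-change term \eqn{F_m \sin^2\Phi / l_m}), the tendon
#' stiffness `Kt` (analytic derivative of the tendon force--strain model),
#' and their series combination
#' \deqn{K_{mt} = (1/K_m + 1/K_t)^{-1}.}
#' `Kmt` is zero whenever either component is zero. Steps with negative
#' `Km` (descending limb with little passive support) keep the signed
#' series formula and are flagged.
#'
#' @param state an [solve_equilibrium()] result.
#' @param p the matching [muscle_params()].
#' @param a activation series used for the solve (floored internally like
#'   the solver).
#' @return A data frame with columns `Km`, `Kt`, `Kmt` (N/m) and logical
#'   `flagged`.
#' @export
mtu_stiffness <- function(state, p, a) {
  stopifnot(inherits(state, "mtu_state"), inherits(p, "muscle_params"),
            nrow(state) == length(a))
  a_eff <- pmin(pmax(a, 0.005), 1)
  fv <- force_velocity(state$vtil)
  dFm_dlm <- p$Fmax / p$lm0 *
    (fl_active_deriv(state$ltil) * fv * a_eff + fl_passive_deriv(state$ltil))
  cosphi <- cos(state$phi)
  sin2 <- 1 - cosphi^2
  Km <- dFm_dlm * cosphi^2 + state$Fm * sin2 / state$lm
  Kt <- if (isTRUE(attr(state, "rigid_tendon"))) rep(Inf, nrow(state))
        else tendon_force_deriv(state$eps, p$Fmax) / p$lst
  Kmt <- numeric(nrow(state))
  zero <- (Km == 0) | (Kt == 0)
  ok <- !zero & is.finite(Kt)
  Kmt[ok] <- Km[ok] * Kt[ok] / (Km[ok] + Kt[ok])
  inf_t <- !zero & !is.finite(Kt)
  Kmt[inf_t] <- Km[inf_t]
  bad <- !is.finite(Kmt)
  Kmt[bad] <- 0
  data.frame(Km = Km, Kt = Kt, Kmt = Kmt, flagged = (Km < 0) | bad)
}
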