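#' Calibration problem specification
#'
#' Defines the free parameters, their bounds, and the optimizer settings
#' for subject-specific model calibration. The free parameters are the
#' shared activation constants `C1`, `C2` (in \eqn{[-1, 1]}, kept a hair
#' inside the endpoints for recursion stability) and shape factor `A` (in
#' \eqn{[-3, 0]}), the group strength coefficients `gamma_df` (dorsiflexor)
#' and `gamma_pf` (plantar flexors) in \eqn{[0.5, 1.5]}, and per-muscle
#' multipliers on optimal fiber length (\eqn{\pm 2.5\%}) and tendon slack
#' length (\eqn{\pm 5\%}). Activation parameters are shared across muscles
#' and strength is shared within the flexor groups because a single net
#' joint moment cannot identify per-muscle activation constants. The
#' electromechanical delay is not calibrated; it stays at `delay`.
#'
#' @param muscles named list of nominal [muscle_params()].
#' @param geometry an `mtu_geometry` model covering the muscles.
#' @param delay fixed electromechanical delay (s, default 0.040).
#' @param n_starts number of seeded Latin-hypercube interior multistarts
#'   (default 4; the objective is multimodal).
#' @param maxit Nelder-Mead iteration budget per polish cycle.
#' @param max_cycles simplex restarts per multistart (a fresh simplex at
#'   the incumbent; counters simplex collapse in 13 dimensions).
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param seed integer seed for the multistart draw.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(muscles = default_muscles(),
                             geometry = default_geometry(),
                             delay = 0.040, n_starts = 4L, maxit = 600L,
                             max_cycles = 4L, reltol = 1e-9, seed = 1L) {
  stopifnot(is.list(muscles), inherits(geometry, "mtu_geometry"),
            n_starts >= 1L, maxit >= 10L, max_cycles >= 1L)
  mus <- names(muscles)
  eps <- 1e-6
  lower <- c(C1 = -1 + eps, C2 = -1 + eps, A = -3, gamma_df = 0.5,
             gamma_pf = 0.5,
             stats::setNames(rep(0.975, length(mus)), paste0("lm0_", mus)),
             stats::setNames(rep(0.95, length(mus)), paste0("lst_", mus)))
  upper <- c(C1 = 1 - eps, C2 = 1 - eps, A = 0, gamma_df = 1.5,
             gamma_pf = 1.5,
             stats::setNames(rep(1.025, length(mus)), paste0("lm0_", mus)),
             stats::setNames(rep(1.05, length(mus)), paste0("lst_", mus)))
  structure(list(muscles = muscles, geometry = geometry, delay = delay,
                 lower = lower, upper = upper, n_starts = as.integer(n_starts),
                 maxit = as.integer(maxit), max_cycles = as.integer(max_cycles),
                 reltol = reltol, seed = as.integer(seed)),
            class = "calibration_spec")
}

# smooth sine-squared reparameterization onto [lo, hi]; Nelder-Mead has no
# native bounds and hard clipping flattens the simplex
bound_transform <- function(x, lo, hi) lo + (hi - lo) * sin(x)^2
bound_inverse <- function(p, lo, hi) {
  f <- pmin(pmax((p - lo) / (hi - lo), 1e-12), 1 - 1e-12)
  asin(sqrt(f))
}

#' Build an ankle model from a calibration parameter vector
#'
#' @param params named vector over the [calibration_spec()] parameters.
#' @param spec the matching `calibration_spec`.
#' @return An [ankle_model()] with multipliers and strength coefficients
#'   applied.
#' @export
build_calibrated_model <- function(params, spec) {
  stopifnot(inherits(spec, "calibration_spec"),
            all(names(spec$lower) %in% names(params)))
  act <- activation_params(C1 = unname(params["C1"]), C2 = unname(params["C2"]),
                           A = unname(params["A"]), d = spec$delay)
  mus <- spec$muscles
  for (m in names(mus)) {
    mus[[m]]$lm0 <- mus[[m]]$lm0 * unname(params[paste0("lm0_", m)])
    mus[[m]]$lst <- mus[[m]]$lst * unname(params[paste0("lst_", m)])
  }
  ankle_model(act, mus, spec$geometry,
              gamma_df = unname(params["gamma_df"]),
              gamma_pf = unname(params["gamma_pf"]))
}

# cache trial inputs that do not depend on the candidate parameters
prepare_calibration_trials <- function(trials, spec) {
  lapply(trials, function(tr) {
    stopifnot(inherits(tr, "gait_trial"))
    if (isTRUE(tr$emg_is_raw))
      stop("calibration trials must carry excitation envelopes", call. = FALSE)
    mus <- names(spec$muscles)
    list(exc = tr$emg[, mus, drop = FALSE],
         geom = evaluate_geometry(spec$geometry, tr$theta),
         rate = tr$rate, tau_id = tr$tau_id, n = length(tr$tau_id))
  })
}

objective_from_prepared <- function(params, prepared, spec) {
  model <- try(build_calibrated_model(params, spec), silent = TRUE)
  if (inherits(model, "try-error")) return(1e6)
  sse <- 0; ntot <- 0
  for (i in seq_along(prepared)) {
    pt <- prepared[[i]]
    fc <- try(forward_chain(model, pt$exc, pt$geom, pt$rate,
                            with_stiffness = FALSE), silent = TRUE)
    if (inherits(fc, "try-error")) return(1e6)
    sse <- sse + sum((fc$tau - pt$tau_id)^2)
    ntot <- ntot + pt$n
  }
  sse / ntot
}

#' Calibration objective
#'
#' The mean squared difference between the EMG-driven moment and the
#' experimental moment, pooled over all samples of all calibration trials:
#' \deqn{J = \frac{1}{N} \sum_{i=1}^{N} (\tau_{EMG}(i) - \tau_{ID}(i))^2.}
#' Forward-chain failures (equilibrium breakdown for a pathological
#' candidate) return a large finite penalty rather than an error so the
#' simplex can recover.
#'
#' @param params named candidate parameter vector (within bounds).
#' @param trials list of [gait_trial()] with excitation envelopes.
#' @param spec a [calibration_spec()].
#' @return The scalar objective `J` (N^2 m^2).
#' @export
calibration_objective <- function(params, trials, spec) {
  objective_from_prepared(params, prepare_calibration_trials(trials, spec), spec)
}

#' Calibrate subject-specific model parameters
#'
#' Minimizes [calibration_objective()] with Nelder-Mead under the
#' parameter bounds, using a smooth sine-squared reparameterization of
#' each coordinate onto its interval and several seeded Latin-hypercube
#' interior starts. Each start is polished by restarting the simplex at
#' the incumbent until the objective stops improving. Deterministic given
#' `spec$seed`.
#'
#' @param trials list of [gait_trial()] from one subject (all trials
#'   pooled into the objective).
#' @param spec a [calibration_spec()].
#' @return An object of class `calibration_result`: fitted `par` (named,
#'   within bounds), final objective `J`, per-trial and mean `nrmse`,
#'   per-start initial/final objectives, total function evaluations,
#'   `convergence` flag and the index of the best start.
#' @export
calibrate <- function(trials, spec = calibration_spec()) {
  stopifnot(length(trials) >= 1L, inherits(spec, "calibration_spec"))
  prepared <- prepare_calibration_trials(trials, spec)
  lo <- spec$lower; hi <- spec$upper
  npar <- length(lo)
  u <- with_seed(spec$seed, lhs::randomLHS(spec$n_starts, npar))
  starts <- sweep(sweep(0.1 + 0.8 * u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(starts) <- names(lo)

  evals <- 0L
  run_start <- function(p0) {
    fn <- function(x) {
      evals <<- evals + 1L
      p <- stats::setNames(bound_transform(x, lo, hi), names(lo))
      objective_from_prepared(p, prepared, spec)
    }
    x <- bound_inverse(p0, lo, hi)
    J_prev <- Inf; converged <- FALSE
    for (cycle in seq_len(spec$max_cycles)) {
      opt <- stats::optim(x, fn, method = "Nelder-Mead",
                          control = list(maxit = spec$maxit,
                                         reltol = spec$reltol))
      x <- opt$par
      if (opt$convergence == 0 ||
          (is.finite(J_prev) &&
             (J_prev - opt$value) < 1e-6 * max(1e-12, abs(J_prev)))) {
        converged <- TRUE
        J_prev <- opt$value
        break
      }
      J_prev <- opt$value
    }
    list(par = stats::setNames(bound_transform(x, lo, hi), names(lo)),
         J = J_prev, J0 = objective_from_prepared(p0, prepared, spec),
         converged = converged)
  }

  runs <- lapply(seq_len(spec$n_starts), function(i) run_start(starts[i, ]))
  Js <- vapply(runs, `[[`, numeric(1), "J")
  best <- which.min(Js)
  par <- runs[[best]]$par
  # cold re-evaluation of the reported optimum (round-trip consistency)
  J <- objective_from_prepared(par, prepared, spec)
  model <- build_calibrated_model(par, spec)
  nr <- vapply(seq_along(prepared), function(i) {
    pt <- prepared[[i]]
    fc <- forward_chain(model, pt$exc, pt$geom, pt$rate,
                        with_stiffness = FALSE)
    nrmse(fc$tau, pt$tau_id)
  }, numeric(1))
  structure(list(par = par, J = J, nrmse = nr, nrmse_mean = mean(nr),
                 start_J0 = vapply(runs, `[[`, numeric(1), "J0"),
                 start_J = Js, best_start = best, evals = evals,
                 convergence = any(vapply(runs, `[[`, logical(1), "converged")),
                 spec = spec),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "calibration_result: J=%.4g, mean NRMSE=%.3f over %d trials, best start %d/%d (%d evaluations, converged=%s)\n",
    x$J, x$nrmse_mean, length(x$nrmse), x$best_start, length(x$start_J),
    x$evals, x$convergence))
  p <- x$par
  cat(sprintf("  C1=%.3f C2=%.3f A=%.3f gamma_df=%.3f gamma_pf=%.3f\n",
              p["C1"], p["C2"], p["A"], p["gamma_df"], p["gamma_pf"]))
  invisible(x)
}
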