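#' Fit polynomial MTU geometry surrogates
#'
#' Fits, per muscle, least-squares polynomials describing how
#' muscle-tendon-unit (MTU) length `lmt` (m) and moment arm `r` (m) vary
#' with ankle angle (rad, dorsiflexion positive). The fitted surrogate is
#' only ever evaluated inside the sampled angle range: polynomials are
#' untrustworthy outside their fit interval and the moment-arm derivative
#' entering joint stiffness would be silently corrupted by extrapolation.
#'
#' Sign convention: dorsiflexor (TA) moment arms are positive, plantar
#' flexor arms negative, matching dorsiflexion-positive angles and moments.
#'
#' @param samples a named list, one element per muscle, each a data frame
#'   with columns `theta` (rad), `lmt` (m), `r` (m).
#' @param degree polynomial degree, an integer in 2..5 (default 3; ankle
#'   MTU length and arm curves over the stance range are smooth and
#'   low-order).
#' @return An object of class `mtu_geometry`: per-muscle coefficient sets
#'   (ascending powers), the fitted degree, the valid angle interval and
#'   per-quantity residual RMS values.
#' @export
fit_geometry <- function(samples, degree = 3L) {
  stopifnot(is.list(samples), length(samples) >= 1L, !is.null(names(samples)))
  degree <- as.integer(degree)
  if (degree < 2L || degree > 5L)
    stop("polynomial degree must be in 2..5", call. = FALSE)
  fit_one <- function(theta, y, what, muscle) {
    keep <- stats::complete.cases(theta, y)
    theta <- theta[keep]; y <- y[keep]
    if (length(unique(theta)) < degree + 2L)
      stop(sprintf("muscle %s: need >= degree+2 = %d distinct angle samples to fit %s, got %d",
                   muscle, degree + 2L, what, length(unique(theta))), call. = FALSE)
    X <- outer(theta, 0:degree, `^`)
    fit <- stats::lm.fit(X, y)
    if (fit$rank < degree + 1L)
      stop(sprintf("muscle %s: rank-deficient polynomial fit for %s (duplicate angles?)",
                   muscle, what), call. = FALSE)
    list(coef = unname(fit$coefficients),
         rms = sqrt(mean(fit$residuals^2)))
  }
  muscles <- lapply(names(samples), function(m) {
    s <- samples[[m]]
    stopifnot(all(c("theta", "lmt", "r") %in% names(s)))
    fl <- fit_one(s$theta, s$lmt, "lmt", m)
    fr <- fit_one(s$theta, s$r, "r", m)
    list(lmt_coef = fl$coef, r_coef = fr$coef,
         rms = c(lmt = fl$rms, r = fr$rms),
         range = range(s$theta))
  })
  names(muscles) <- names(samples)
  rng <- c(max(vapply(muscles, function(m) m$range[1], numeric(1))),
           min(vapply(muscles, function(m) m$range[2], numeric(1))))
  structure(list(muscles = muscles, degree = degree, range = rng),
            class = "mtu_geometry")
}

#' @export
print.mtu_geometry <- function(x, ...) {
  cat(sprintf("mtu_geometry: degree %d, valid angle range [%.3f, %.3f] rad, muscles: %s\n",
              x$degree, x$range[1], x$range[2],
              paste(names(x$muscles), collapse = ", ")))
  invisible(x)
}

polyval_asc <- function(coef, x) {
  # Horner, coefficients in ascending powers
  y <- rep(coef[length(coef)], length(x))
  for (k in rev(seq_len(length(coef) - 1L))) y <- y * x + coef[k]
  y
}

polyder_asc <- function(coef) {
  n <- length(coef)
  if (n <= 1L) return(0)
  coef[-1L] * seq_len(n - 1L)
}

#' Evaluate MTU geometry at ankle angles
#'
#' Evaluates the fitted polynomials to obtain per-muscle MTU length,
#' moment arm and the analytic moment-arm derivative \eqn{dr/d\theta} at
#' each supplied angle. Angles outside the model's valid interval raise an
#' error naming the offending sample; no extrapolation is ever performed.
#'
#' @param model an [fit_geometry()] result.
#' @param theta numeric vector of ankle angles (rad).
#' @return A named list, one element per muscle, each containing numeric
#'   vectors `lmt`, `r` and `dr_dtheta` of `length(theta)`.
#' @export
evaluate_geometry <- function(model, theta) {
  stopifnot(inherits(model, "mtu_geometry"), is.numeric(theta))
  tol <- 1e-9
  bad <- which(!is.finite(theta) | theta < model$range[1] - tol |
                 theta > model$range[2] + tol)
  if (length(bad))
    stop(sprintf("angle sample %d (%.4f rad) outside the geometry validity range [%.4f, %.4f]",
                 bad[1], theta[bad[1]], model$range[1], model$range[2]),
         call. = FALSE)
  out <- lapply(model$muscles, function(m) {
    list(lmt = polyval_asc(m$lmt_coef, theta),
         r = polyval_asc(m$r_coef, theta),
         dr_dtheta = polyval_asc(polyder_asc(m$r_coef), theta))
  })
  names(out) <- names(model$muscles)
  out
}

#' Tendon-excursion consistency of a fitted geometry
#'
#' Compares the fitted moment arm against `-dlmt/dtheta` (tendon-excursion
#' principle) over the valid range and reports the median agreement ratio
#' per muscle. Because length and arm are fitted independently the two
#' need not match exactly; ratios outside \eqn{[0.5, 2]} are flagged, not
#' rejected.
#'
#' @param model an [fit_geometry()] result.
#' @param n number of probe angles across the valid range.
#' @return A data frame with one row per muscle: `ratio` (median of
#'   `r / (-dlmt/dtheta)`) and logical `flagged`.
#' @export
excursion_consistency <- function(model, n = 51L) {
  stopifnot(inherits(model, "mtu_geometry"))
  th <- seq(model$range[1], model$range[2], length.out = n)
  rows <- lapply(names(model$muscles), function(nm) {
    m <- model$muscles[[nm]]
    r <- polyval_asc(m$r_coef, th)
    dl <- polyval_asc(polyder_asc(m$lmt_coef), th)
    ratio <- stats::median(r / (-dl))
    data.frame(muscle = nm, ratio = ratio,
               flagged = !is.finite(ratio) || ratio < 0.5 || ratio > 2)
  })
  do.call(rbind, rows)
}
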