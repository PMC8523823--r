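#' Activation-dynamics parameters
#'
#' Bundles the constants of the recursive neural-activation filter and the
#' nonlinear excitation-to-activation shaping function.
#'
#' The second-order recursion
#' \deqn{u(t) = \alpha e(t-d) - \beta_1 u(t-1) - \beta_2 u(t-2)}
#' models the twitch response of muscle fibres to excitation onset, with
#' \eqn{\beta_1 = C_1 + C_2}, \eqn{\beta_2 = C_1 C_2} and
#' \eqn{\alpha = 1 + \beta_1 + \beta_2}, which forces unit DC gain: a
#' sustained excitation produces an equal steady-state neural activation.
#' The recursion poles are \eqn{-C_1} and \eqn{-C_2}, so stability requires
#' \eqn{|C_1| < 1} and \eqn{|C_2| < 1}.
#'
#' @param C1,C2 recursion constants, each strictly inside (-1, 1).
#' @param A nonlinear shape factor, in \eqn{[-3, 0]}; values with
#'   \eqn{|A| < 10^{-6}} select the linear fallback \eqn{a(t) = u(t)}.
#' @param d electromechanical delay in seconds (non-negative). Converted to
#'   a whole number of samples at the working rate when the filter is run.
#' @return An object of class `activation_params`.
#' @seealso [neural_activation()], [activation_nonlinearity()]
#' @export
activation_params <- function(C1 = 0.1, C2 = -0.25, A = -1.5, d = 0.040) {
  stopifnot(is.numeric(C1), is.numeric(C2), is.numeric(A), is.numeric(d),
            length(C1) == 1L, length(C2) == 1L, length(A) == 1L, length(d) == 1L)
  if (!is.finite(C1) || abs(C1) >= 1)
    stop("C1 must satisfy |C1| < 1 (recursion pole at -C1)", call. = FALSE)
  if (!is.finite(C2) || abs(C2) >= 1)
    stop("C2 must satisfy |C2| < 1 (recursion pole at -C2)", call. = FALSE)
  if (!is.finite(A) || A > 0 || A < -3)
    stop("shape factor A must lie in [-3, 0]", call. = FALSE)
  if (!is.finite(d) || d < 0)
    stop("electromechanical delay d must be >= 0 s", call. = FALSE)
  structure(list(C1 = C1, C2 = C2, A = A, d = d), class = "activation_params")
}

#' @export
print.activation_params <- function(x, ...) {
  co <- activation_coefficients(x)
  cat(sprintf(
    "activation_params: C1=%.4g C2=%.4g (alpha=%.4g beta1=%.4g beta2=%.4g) A=%.4g d=%.4g s\n",
    x$C1, x$C2, co["alpha"], co["beta1"], co["beta2"], x$A, x$d))
  invisible(x)
}

#' Recursion coefficients derived from (C1, C2)
#'
#' @param p an [activation_params()] object.
#' @return Named numeric vector with `alpha`, `beta1`, `beta2`.
#' @export
activation_coefficients <- function(p) {
  stopifnot(inherits(p, "activation_params"))
  beta1 <- p$C1 + p$C2
  beta2 <- p$C1 * p$C2
  c(alpha = 1 + beta1 + beta2, beta1 = beta1, beta2 = beta2)
}

#' Neural activation from excitation
#'
#' Runs the delayed second-order recursive filter mapping a muscle
#' excitation series (processed, normalized EMG in \eqn{[0, 1]}) to neural
#' activation. The electromechanical delay is applied as an integer sample
#' shift `round(d * rate)` with zero fill at the head; initial conditions
#' are \eqn{u(-1) = u(-2) = 0}.
#'
#' @param e numeric excitation series, values in \eqn{[0, 1]} (a small
#'   tolerance is allowed for filtering round-off).
#' @param p an [activation_params()] object.
#' @param rate sampling rate in Hz.
#' @return Numeric series `u(t)` of the same length as `e`.
#' @examples
#' p <- activation_params(C1 = 0, C2 = 0, A = -1, d = 0)
#' u <- neural_activation(c(0, 1, 1, 1), p, rate = 100)  # identity case
#' @export
neural_activation <- function(e, p, rate) {
  stopifnot(inherits(p, "activation_params"), is.numeric(e), length(e) >= 1L,
            is.numeric(rate), length(rate) == 1L, rate > 0)
  if (anyNA(e) || any(e < -1e-9) || any(e > 1 + 1e-9))
    stop("excitation values must lie in [0, 1]", call. = FALSE)
  e <- pmin(pmax(e, 0), 1)
  co <- activation_coefficients(p)
  lag <- as.integer(round(p$d * rate))
  if (lag > 0L) {
    n <- length(e)
    e <- c(numeric(min(lag, n)), e)[seq_len(n)]
  }
  u <- stats::filter(co["alpha"] * e,
                     filter = c(-co["beta1"], -co["beta2"]),
                     method = "recursive", init = c(0, 0))
  as.numeric(u)
}

#' Nonlinear excitation-to-force shaping
#'
#' Maps neural activation to muscle activation through
#' \deqn{a(t) = \frac{e^{A u(t)} - 1}{e^{A} - 1},}
#' a monotone map with \eqn{a(0) = 0}, \eqn{a(1) = 1}. Neural activation is
#' clipped to \eqn{[0, 1]} beforehand (transient recursion overshoot would
#' otherwise leave the admissible activation range). When \eqn{|A| < 10^{-6}}
#' the analytic limit \eqn{a = u} is used.
#'
#' @param u neural activation series.
#' @param A nonlinear shape factor in \eqn{[-3, 0]}.
#' @return Activation series `a(t)` in \eqn{[0, 1]}.
#' @export
activation_nonlinearity <- function(u, A) {
  stopifnot(is.numeric(u), is.numeric(A), length(A) == 1L)
  if (!is.finite(A) || A > 0 || A < -3)
    stop("shape factor A must lie in [-3, 0]", call. = FALSE)
  u <- pmin(pmax(u, 0), 1)
  if (abs(A) < 1e-6) return(u)
  (exp(A * u) - 1) / (exp(A) - 1)
}

#' Excitation to activation in one call
#'
#' Convenience composition of [neural_activation()] and
#' [activation_nonlinearity()].
#'
#' @inheritParams neural_activation
#' @return Activation series `a(t)` in \eqn{[0, 1]}.
#' @export
excitation_to_activation <- function(e, p, rate) {
  activation_nonlinearity(neural_activation(e, p, rate), p$A)
}
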