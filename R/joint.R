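#' Ankle moment from MTU forces and moment arms
#'
#' \deqn{\tau_{EMG} = \sum_i F_{mt,i} \, r_i} with signed moment arms
#' (dorsiflexor positive, plantar flexor negative), so positive output is a
#' dorsiflexion moment.
#'
#' @param fmt named list of per-muscle MTU force series (N).
#' @param arms named list of per-muscle moment-arm series (m), same muscles
#'   and lengths as `fmt`.
#' @return Numeric moment series (N m).
#' @export
ankle_moment <- function(fmt, arms) {
  check_muscle_series(fmt, arms)
  Reduce(`+`, Map(`*`, fmt, arms[names(fmt)]))
}

#' Ankle rotational stiffness from MTU stiffness and forces
#'
#' Aggregates per-muscle MTU stiffness and force to joint rotational
#' stiffness. With signed moment arms \eqn{r_i} (so that
#' \eqn{r_i = -\partial l_{mt,i}/\partial\theta}) the linearization of the
#' joint moment gives
#' \deqn{K_{ankle} = -\frac{d\tau}{d\theta}
#'   = \sum_i \left( K_{mt,i} r_i^2 - F_{mt,i}\,\frac{dr_i}{d\theta} \right).}
#' The moment-arm-slope term enters with a minus sign here because `arms`
#' are signed moment arms; formulations written for excursion-based arms
#' (\eqn{r = +\partial l_{mt}/\partial\theta}) carry the same term with a
#' plus sign. Per-muscle `Kmt` values are floored at zero before summation
#' and the aggregate is reported clamped at zero; both clamps are counted
#' in the returned flags.
#'
#' @param kmt named list of per-muscle MTU stiffness series (N/m).
#' @param fmt named list of per-muscle MTU force series (N).
#' @param arms named list of signed moment-arm series (m).
#' @param arm_slopes named list of moment-arm derivative series
#'   \eqn{dr/d\theta} (m/rad).
#' @return A list with `K` (clamped stiffness series, N m/rad), `K_raw`
#'   (unclamped signed series), and logical `flagged` marking steps where
#'   any clamp was active.
#' @export
ankle_stiffness <- function(kmt, fmt, arms, arm_slopes) {
  check_muscle_series(kmt, fmt)
  check_muscle_series(kmt, arms)
  check_muscle_series(kmt, arm_slopes)
  mus <- names(kmt)
  neg_kmt <- Reduce(`|`, lapply(kmt, function(k) k < 0))
  raw <- Reduce(`+`, lapply(mus, function(m) {
    pmax(kmt[[m]], 0) * arms[[m]]^2 - fmt[[m]] * arm_slopes[[m]]
  }))
  list(K = pmax(raw, 0), K_raw = raw, flagged = neg_kmt | (raw < 0))
}

check_muscle_series <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)) || !setequal(names(a), names(b)))
    stop("per-muscle series must be named lists over the same muscles", call. = FALSE)
  la <- vapply(a, length, integer(1))
  lb <- vapply(b, length, integer(1))[names(a)]
  if (length(unique(c(la, lb))) != 1L)
    stop("per-muscle series have mismatched lengths", call. = FALSE)
  invisible(TRUE)
}

#' Resample a stance-phase series onto the 0--100% grid
#'
#' Linear-interpolation resampling of a sampled series onto `n` evenly
#' spaced stance-percentage nodes (default 101: 0, 1, ..., 100, the
#' conventional grid for 1D curve statistics on gait data, with 0% at heel
#' strike and 100% at toe-off).
#'
#' @param y numeric series.
#' @param stance integer vector `c(start, end)` of the stance-phase sample
#'   bounds within `y` (defaults to the whole series).
#' @param n number of output nodes (default 101).
#' @return Numeric vector of length `n` with attribute `"pct"` holding the
#'   stance-percentage grid.
#' @export
time_normalize <- function(y, stance = c(1L, length(y)), n = 101L) {
  stopifnot(is.numeric(y), length(stance) == 2L)
  s <- as.integer(stance)
  if (s[1] < 1L || s[2] > length(y) || s[1] >= s[2])
    stop("invalid stance bounds", call. = FALSE)
  if (s[2] - s[1] + 1L < 2L)
    stop("need at least 2 samples inside stance", call. = FALSE)
  seg <- y[s[1]:s[2]]
  pct_in <- seq(0, 100, length.out = length(seg))
  pct_out <- seq(0, 100, length.out = n)
  out <- stats::approx(pct_in, seg, xout = pct_out)$y
  attr(out, "pct") <- pct_out
  out
}

#' Normalized root-mean-square error
#'
#' RMSE of `predicted - experimental` divided by the RMS of the
#' experimental series: the model-fit statistic used to report agreement
#' between the EMG-driven moment and the inverse-dynamics moment.
#'
#' @param predicted,experimental equal-length numeric series.
#' @return A single non-negative number (0 for identical series, 1 for a
#'   zero prediction).
#' @export
nrmse <- function(predicted, experimental) {
  stopifnot(length(predicted) == length(experimental))
  denom <- sqrt(mean(experimental^2))
  if (!is.finite(denom) || denom == 0)
    stop("NRMSE undefined: experimental series has zero RMS", call. = FALSE)
  sqrt(mean((predicted - experimental)^2)) / denom
}
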