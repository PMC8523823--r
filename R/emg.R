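#' Raw EMG to linear envelope
#'
#' Standard gait-lab EMG conditioning: band-pass 30--450 Hz, full-wave
#' rectification, low-pass 6 Hz, all with zero-phase (forward-backward)
#' second-order Butterworth filters. "Second-order" refers to the designed
#' filter before the forward-backward pass, so the effective attenuation is
#' fourth-order. Start/end transients are suppressed by odd (mirror)
#' reflection padding of three low-pass cutoff periods; residual negative
#' undershoot after the final low-pass is clipped to zero because the
#' envelope feeds activation dynamics that require values in \eqn{[0, 1]}.
#'
#' @param raw numeric vector of raw EMG samples (any units; the pipeline is
#'   linear up to rectification, so scaling the input scales the envelope).
#' @param rate sampling rate in Hz; must exceed 900 Hz so that the 450 Hz
#'   band edge stays below Nyquist.
#' @param band band-pass edges in Hz (default `c(30, 450)`).
#' @param lowpass envelope low-pass cutoff in Hz (default 6).
#' @return Numeric envelope of the same length as `raw` (unnormalized).
#' @seealso [normalize_envelopes()]
#' @export
process_raw_emg <- function(raw, rate, band = c(30, 450), lowpass = 6) {
  stopifnot(is.numeric(raw), is.numeric(rate), length(rate) == 1L)
  if (!is.finite(rate) || rate <= 2 * band[2])
    stop(sprintf("sampling rate must exceed %g Hz (band edge %g Hz at Nyquist)",
                 2 * band[2], band[2]), call. = FALSE)
  if (anyNA(raw)) stop("raw EMG contains NA", call. = FALSE)
  pad <- 3L * as.integer(ceiling(rate / lowpass))
  if (length(raw) < pad)
    stop(sprintf("signal too short: %d samples < %d (3 low-pass cutoff periods) needed for stable zero-phase filtering",
                 length(raw), pad), call. = FALSE)
  bp <- signal::butter(2, band / (rate / 2), type = "pass")
  lp <- signal::butter(2, lowpass / (rate / 2), type = "low")
  x <- filtfilt_reflect(bp, raw, pad)
  x <- abs(x)
  x <- filtfilt_reflect(lp, x, pad)
  pmax(x, 0)
}

# Zero-phase filtering with odd-reflection end padding: the signal is
# extended by point-mirrored copies (2*x[1] - x, 2*x[n] - x) so the filter
# warms up on a continuation with matching value and slope, then the filter
# is applied forward and backward and the padding is dropped.
filtfilt_reflect <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filter(filt, xp))
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[(pad + 1L):(pad + n)]
}

#' Normalize envelopes across a subject's trials
#'
#' Divides every envelope of one subject-muscle by the single maximum
#' processed value observed over all of that subject's recorded trials, so
#' excitations lie in \eqn{[0, 1]} and at least one sample in the
#' collection equals 1.
#'
#' @param envelopes a list of numeric envelope vectors (one per trial) for
#'   one subject and muscle, or a single numeric vector.
#' @return A list of normalized envelopes (or a single vector if a vector
#'   was supplied). The normalization reference is attached as attribute
#'   `"reference"`.
#' @export
normalize_envelopes <- function(envelopes) {
  single <- is.numeric(envelopes) && !is.list(envelopes)
  if (single) envelopes <- list(envelopes)
  stopifnot(is.list(envelopes), length(envelopes) >= 1L,
            all(vapply(envelopes, is.numeric, logical(1))))
  ref <- max(vapply(envelopes, function(x) max(x, -Inf), numeric(1)))
  if (!is.finite(ref) || ref <= 0)
    stop("cannot normalize: maximum processed value over the trial collection is not positive",
         call. = FALSE)
  out <- lapply(envelopes, function(x) x / ref)
  attr(out, "reference") <- ref
  if (single) {
    v <- out[[1L]]
    attr(v, "reference") <- ref
    return(v)
  }
  out
}
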