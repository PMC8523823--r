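#' Default four-muscle ankle parameter set
#'
#' Nominal Hill parameters for the tibialis anterior (TA), soleus (SOL)
#' and the lateral/medial gastrocnemius (GAL/GAM), at generic adult-male
#' magnitudes of the kind produced by scaling a lower-limb musculoskeletal
#' model.
#'
#' @return Named list of [muscle_params()].
#' @export
default_muscles <- function() {
  deg <- pi / 180
  list(
    TA  = muscle_params("TA",  905,  0.098, 0.223,  5 * deg, group = "dorsiflexor"),
    SOL = muscle_params("SOL", 3549, 0.050, 0.250, 25 * deg, group = "plantarflexor"),
    GAL = muscle_params("GAL", 683,  0.064, 0.385,  8 * deg, group = "plantarflexor"),
    GAM = muscle_params("GAM", 1558, 0.060, 0.390, 17 * deg, group = "plantarflexor"))
}

# Canonical angle-dependence of MTU length and moment arm used by the
# generator: linear signed moment arms with mild slopes and MTU lengths
# integrated from them (lmt' = -r), so the surrogate geometry is exactly
# tendon-excursion consistent. L0 places each MTU at tendon slack length
# in the neutral (0 rad) pose.
canonical_geometry_curves <- function(muscles = default_muscles()) {
  arms <- list(TA  = c(0.040, -0.004),
               SOL = c(-0.048, -0.003),
               GAL = c(-0.044, -0.003),
               GAM = c(-0.046, -0.003))
  lapply(names(arms), function(m) {
    p <- muscles[[m]]
    r <- arms[[m]]
    L0 <- p$lst + p$lm0 * cos(p$phi0)
    list(r_coef = r, lmt_coef = c(L0, -r[1], -r[2] / 2))
  }) |> stats::setNames(names(arms))
}

#' Default MTU geometry surrogate
#'
#' Samples the canonical ankle geometry curves (see
#' [generate_geometry_samples()]) over \eqn{[-0.40, 0.30]} rad and fits the
#' degree-3 polynomial surrogate used throughout the synthetic pipeline.
#'
#' @return An `mtu_geometry` model.
#' @export
default_geometry <- function() {
  fit_geometry(generate_geometry_samples(), degree = 3L)
}

#' Geometry sample triplets from the canonical curves
#'
#' Produces per-muscle `(theta, lmt, r)` samples of the canonical ankle
#' geometry, optionally with seeded Gaussian measurement noise, for
#' exercising [fit_geometry()].
#'
#' @param n number of angle samples (default 25).
#' @param range angle range in rad (default `c(-0.40, 0.30)`).
#' @param noise_sd additive noise standard deviation (m) applied to both
#'   `lmt` and `r` (default 0).
#' @param seed optional integer seed for the noise.
#' @return Named list of data frames with columns `theta`, `lmt`, `r`.
#' @export
generate_geometry_samples <- function(n = 25L, range = c(-0.40, 0.30),
                                      noise_sd = 0, seed = NULL) {
  curves <- canonical_geometry_curves()
  th <- seq(range[1], range[2], length.out = n)
  gen <- function(cv) {
    data.frame(theta = th,
               lmt = polyval_asc(cv$lmt_coef, th),
               r = polyval_asc(cv$r_coef, th))
  }
  out <- lapply(curves, gen)
  if (noise_sd > 0) {
    out <- with_seed(seed, lapply(out, function(s) {
      s$lmt <- s$lmt + stats::rnorm(n, 0, noise_sd)
      s$r <- s$r + stats::rnorm(n, 0, noise_sd)
      s
    }))
  }
  out
}

#' Ground truth for synthetic gait trials
#'
#' Defines the known-truth study conditions the generator emulates: the
#' activation and Hill parameters of the plant, Gaussian excitation-burst
#' phasing over stance (TA bursting in early stance and again near
#' toe-off, the plantar flexors in mid/late stance), a smooth stance-phase
#' ankle-angle trajectory, surface-compliance conditions that scale the
#' plantar-flexor burst peaks, additive Gaussian noise on the
#' inverse-dynamics-style moment, and per-subject / per-trial burst
#' jitter.
#'
#' All ground-truth parameters must lie strictly inside the calibration
#' bounds so that parameter recovery is well posed.
#'
#' @param activation truth [activation_params()].
#' @param muscles named list of [muscle_params()] (default
#'   [default_muscles()]).
#' @param geometry `mtu_geometry` surrogate (default [default_geometry()]).
#' @param gamma_df,gamma_pf truth strength coefficients, strictly inside
#'   (0.5, 1.5).
#' @param bursts named list (per muscle) of data frames with columns
#'   `center`, `width` (both percent of stance) and `peak` (in \eqn{[0,1]}),
#'   at most 2 bursts per muscle.
#' @param noise_sd standard deviation (N m) of the additive Gaussian noise
#'   on the experimental moment.
#' @param surface_effect fractional increase of plantar-flexor burst peaks
#'   per compliance level.
#' @param conditions named integer vector mapping surface labels to
#'   compliance levels; the default keeps the force plate and rubber at
#'   the same level (both are much stiffer than plantar tissue) and steps
#'   up for the two foams.
#' @param subject_jitter,trial_jitter relative jitter applied to burst
#'   peaks (and, scaled down, to burst centers) per subject / per trial.
#' @param rate sampling rate of the synthetic plant (Hz); the default 100
#'   matches a motion-capture kinematics time base.
#' @param stance_duration stance-phase duration (s).
#' @param angle_amp multiplier on the canonical angle trajectory.
#' @param bodyweight body weight (N) used for the GRF-like curves.
#' @param raw_emg if `TRUE`, trials carry amplitude-modulated band-limited
#'   noise ("raw" EMG) at `raw_rate` instead of envelopes.
#' @param raw_rate sampling rate used in raw-EMG mode (Hz, default 1500).
#' @param seed integer base seed; every per-subject/-condition/-trial
#'   random stream is derived from it.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(activation = activation_params(C1 = 0.1, C2 = -0.25,
                                                           A = -1.5, d = 0.040),
                            muscles = default_muscles(),
                            geometry = default_geometry(),
                            gamma_df = 0.95, gamma_pf = 1.1,
                            bursts = default_bursts(),
                            noise_sd = 2,
                            surface_effect = 0.08,
                            conditions = c(plate = 0L, rubber = 0L,
                                           eva = 1L, epe = 2L),
                            subject_jitter = 0.08, trial_jitter = 0.03,
                            rate = 100, stance_duration = 0.7,
                            angle_amp = 1, bodyweight = 620,
                            raw_emg = FALSE, raw_rate = 1500,
                            seed = 20211005) {
  stopifnot(inherits(activation, "activation_params"),
            inherits(geometry, "mtu_geometry"))
  # strict interiority w.r.t. calibration bounds
  if (abs(activation$C1) >= 1 || abs(activation$C2) >= 1 ||
      activation$A <= -3 || activation$A >= 0)
    stop("truth activation parameters must lie strictly inside the calibration bounds",
         call. = FALSE)
  if (gamma_df <= 0.5 || gamma_df >= 1.5 || gamma_pf <= 0.5 || gamma_pf >= 1.5)
    stop("truth strength coefficients must lie strictly inside (0.5, 1.5)",
         call. = FALSE)
  if (!setequal(names(bursts), names(muscles)))
    stop("bursts must be specified for exactly the model muscles", call. = FALSE)
  for (b in bursts) {
    stopifnot(all(c("center", "width", "peak") %in% names(b)), nrow(b) <= 2L)
    if (any(b$peak < 0 | b$peak > 1) || any(b$width <= 0))
      stop("burst peaks must lie in [0, 1] and widths must be positive",
           call. = FALSE)
  }
  stopifnot(noise_sd >= 0, length(conditions) >= 1L,
            !is.null(names(conditions)), subject_jitter >= 0,
            trial_jitter >= 0, rate > 0, stance_duration > 0)
  structure(list(activation = activation, muscles = muscles,
                 geometry = geometry, gamma_df = gamma_df,
                 gamma_pf = gamma_pf, bursts = bursts, noise_sd = noise_sd,
                 surface_effect = surface_effect, conditions = conditions,
                 subject_jitter = subject_jitter, trial_jitter = trial_jitter,
                 rate = rate, stance_duration = stance_duration,
                 angle_amp = angle_amp, bodyweight = bodyweight,
                 raw_emg = raw_emg, raw_rate = raw_rate,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Default excitation burst phasing
#'
#' Gait-phased Gaussian bursts over stance percent: TA active around heel
#' strike and again just before toe-off; SOL/GAL/GAM ramping through mid
#' stance to a push-off peak.
#'
#' @return Named list of burst data frames.
#' @export
default_bursts <- function() {
  list(
    TA  = data.frame(center = c(4, 97), width = c(7, 6), peak = c(0.50, 0.25)),
    SOL = data.frame(center = 68, width = 17, peak = 0.85),
    GAL = data.frame(center = 62, width = 15, peak = 0.60),
    GAM = data.frame(center = 66, width = 16, peak = 0.80))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d muscles, conditions %s (effect %.2f/level), noise sd %.2f N m, %g Hz, seed %d\n",
    length(x$muscles), paste(names(x$conditions), collapse = "/"),
    x$surface_effect, x$noise_sd, x$rate, x$seed))
  invisible(x)
}

# canonical stance-phase ankle angle (rad, dorsiflexion positive): brief
# plantarflexion after heel strike, progressive dorsiflexion through mid
# stance, rapid plantarflexion into push-off.
stance_angle <- function(pct, amp = 1) {
  deg <- pi / 180
  f <- stats::splinefun(c(0, 8, 45, 70, 100),
                        c(0, -6, 7, 11, -17) * deg, method = "natural")
  amp * f(pct)
}

sum_bursts <- function(pct, bursts) {
  e <- numeric(length(pct))
  for (i in seq_len(nrow(bursts)))
    e <- e + bursts$peak[i] *
      exp(-(pct - bursts$center[i])^2 / (2 * bursts$width[i]^2))
  pmin(pmax(e, 0), 1)
}

# integer stream seed below 2^31, derived by counter-based splitting
derive_seed <- function(seed, subject = 0L, cond = 0L, trial = 0L) {
  as.integer(((abs(as.numeric(seed)) %% 97561) * 21011 +
                subject * 104729 + cond * 7919 + trial * 131) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' A single stance-phase gait trial
#'
#' Container for one stance phase: per-muscle EMG (excitation envelopes
#' or raw), ankle angle, experimental ankle moment, GRF-like curves and
#' metadata. All series share one length and sampling rate.
#'
#' @param rate sampling rate (Hz).
#' @param time time vector (s).
#' @param emg numeric matrix, one named column per muscle.
#' @param theta ankle angle (rad, dorsiflexion positive).
#' @param tau_id experimental ankle moment (N m, dorsiflexion positive).
#' @param grf_v,grf_ap optional vertical / anterior-posterior ground
#'   reaction force (N).
#' @param condition surface label.
#' @param subject subject identifier.
#' @param trial_index trial number within subject and condition.
#' @param stance_start,stance_end sample indices bounding the stance phase.
#' @param emg_is_raw `TRUE` when `emg` holds raw signals rather than
#'   excitation envelopes.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(rate, time, emg, theta, tau_id, grf_v = NULL,
                       grf_ap = NULL, condition = "plate", subject = 1L,
                       trial_index = 1L, stance_start = 1L,
                       stance_end = length(time), emg_is_raw = FALSE) {
  n <- length(time)
  stopifnot(rate > 0, is.matrix(emg), nrow(emg) == n,
            !is.null(colnames(emg)), length(theta) == n,
            length(tau_id) == n,
            is.null(grf_v) || length(grf_v) == n,
            is.null(grf_ap) || length(grf_ap) == n)
  stance_start <- as.integer(stance_start); stance_end <- as.integer(stance_end)
  if (stance_start < 1L || stance_end > n || stance_start >= stance_end)
    stop("stance indices must satisfy 1 <= start < end <= length", call. = FALSE)
  structure(list(rate = rate, time = time, emg = emg, theta = theta,
                 tau_id = tau_id, grf_v = grf_v, grf_ap = grf_ap,
                 condition = condition, subject = subject,
                 trial_index = as.integer(trial_index),
                 stance_start = stance_start, stance_end = stance_end,
                 emg_is_raw = isTRUE(emg_is_raw)),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "gait_trial: subject %s, %s, trial %d; %d samples @ %g Hz (%s EMG), peak |tau_ID| %.1f N m\n",
    x$subject, x$condition, x$trial_index, length(x$time), x$rate,
    if (x$emg_is_raw) "raw" else "envelope", max(abs(x$tau_id))))
  invisible(x)
}

#' Generate one synthetic stance-phase trial
#'
#' Builds excitations as sums of Gaussian bursts over stance percent (the
#' plantar-flexor burst peaks scaled by the condition's compliance level),
#' runs the truth model forward through the full chain to obtain the
#' "experimental" moment, adds seeded Gaussian noise, and attaches
#' GRF-like curves. Fully reproducible from
#' `(truth$seed, condition, trial_index, subject)`.
#'
#' @param truth a [synthetic_truth()].
#' @param condition one of `names(truth$conditions)`.
#' @param trial_index trial counter (drives the derived random stream).
#' @param subject subject identifier (integer; drives the stream only --
#'   subject-level jitter is applied by [generate_dataset()]).
#' @return A [gait_trial()]. The noiseless forward moment, the stiffness
#'   curve of the truth model and the true envelopes are attached as
#'   attributes `"tau_true"`, `"stiffness_true"` and `"envelopes"`.
#' @export
generate_trial <- function(truth, condition, trial_index = 1L, subject = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!condition %in% names(truth$conditions))
    stop(sprintf("unknown condition '%s' (configured: %s)", condition,
                 paste(names(truth$conditions), collapse = ", ")), call. = FALSE)
  cond_idx <- match(condition, names(truth$conditions))
  level <- truth$conditions[[condition]]
  rate <- if (truth$raw_emg) truth$raw_rate else truth$rate
  tm <- seq(0, truth$stance_duration, by = 1 / rate)
  n <- length(tm)
  pct <- tm / truth$stance_duration * 100
  theta <- stance_angle(pct, truth$angle_amp)
  mus <- names(truth$muscles)

  sd_seed <- derive_seed(truth$seed, subject, cond_idx, trial_index)
  trial_data <- with_seed(sd_seed, {
    exc <- matrix(0, n, length(mus), dimnames = list(NULL, mus))
    for (m in mus) {
      b <- truth$bursts[[m]]
      if (truth$muscles[[m]]$group == "plantarflexor")
        b$peak <- pmin(b$peak * (1 + truth$surface_effect * level), 1)
      if (truth$trial_jitter > 0) {
        b$peak <- pmin(pmax(b$peak *
          (1 + stats::rnorm(nrow(b), 0, truth$trial_jitter)), 0), 1)
        b$center <- b$center + stats::rnorm(nrow(b), 0, 20 * truth$trial_jitter)
      }
      exc[, m] <- sum_bursts(pct, b)
    }
    noise <- stats::rnorm(n, 0, truth$noise_sd)
    grf_noise <- matrix(stats::rnorm(2 * n, 0, 5), n, 2)
    raw_carrier <- if (truth$raw_emg)
      matrix(stats::rnorm(n * length(mus)), n, length(mus)) else NULL
    list(exc = exc, noise = noise, grf_noise = grf_noise,
         raw_carrier = raw_carrier)
  })
  exc <- trial_data$exc

  model <- ankle_model(truth$activation, truth$muscles, truth$geometry,
                       truth$gamma_df, truth$gamma_pf)
  geom <- evaluate_geometry(truth$geometry, theta)
  fc <- forward_chain(model, exc, geom, rate)
  tau_id <- fc$tau + trial_data$noise

  bw <- truth$bodyweight
  grf_v <- bw * (1.1 * exp(-(pct - 28)^2 / (2 * 14^2)) +
                   1.1 * exp(-(pct - 72)^2 / (2 * 14^2))) +
    trial_data$grf_noise[, 1]
  grf_ap <- bw * (-0.15 * exp(-(pct - 20)^2 / (2 * 9^2)) +
                    0.18 * exp(-(pct - 80)^2 / (2 * 9^2))) +
    trial_data$grf_noise[, 2]

  emg_out <- exc
  if (truth$raw_emg) {
    bp <- signal::butter(2, c(30, 450) / (rate / 2), type = "pass")
    emg_out <- vapply(seq_along(mus), function(j) {
      carrier <- as.numeric(signal::filter(bp, trial_data$raw_carrier[, j]))
      carrier * exc[, j]
    }, numeric(n))
    colnames(emg_out) <- mus
  }

  tr <- gait_trial(rate = rate, time = tm, emg = emg_out, theta = theta,
                   tau_id = tau_id, grf_v = grf_v, grf_ap = grf_ap,
                   condition = condition, subject = subject,
                   trial_index = trial_index, emg_is_raw = truth$raw_emg)
  attr(tr, "tau_true") <- fc$tau
  attr(tr, "stiffness_true") <- fc$K
  attr(tr, "envelopes") <- exc
  tr
}

#' Generate a full synthetic walking dataset
#'
#' Produces `n_subjects` x conditions x `trials_per_condition` stance
#' trials. Each subject receives a jittered copy of the base truth (burst
#' peaks and centers perturbed with seeded Gaussian jitter, identically
#' across that subject's conditions, so condition labels stay exchangeable
#' when the surface effect is zero).
#'
#' @param truth a [synthetic_truth()].
#' @param n_subjects number of subjects (>= 1).
#' @param trials_per_condition trials per subject and condition (>= 1).
#' @return An object of class `gait_dataset`: `trials` (list of
#'   [gait_trial()]), `manifest` (data frame of subject/condition/trial),
#'   `truth` and the per-subject `subject_truths`.
#' @export
generate_dataset <- function(truth, n_subjects = 10L,
                             trials_per_condition = 4L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_subjects <- as.integer(n_subjects)
  trials_per_condition <- as.integer(trials_per_condition)
  if (n_subjects < 1L || trials_per_condition < 1L)
    stop("subject and trial counts must be positive", call. = FALSE)
  conds <- names(truth$conditions)
  trials <- list(); rows <- list(); subject_truths <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) {
    st <- jitter_truth(truth, s)
    subject_truths[[s]] <- st
    for (ci in seq_along(conds)) {
      for (tr in seq_len(trials_per_condition)) {
        k <- k + 1L
        trials[[k]] <- generate_trial(st, conds[ci], tr, subject = s)
        rows[[k]] <- data.frame(idx = k, subject = s, condition = conds[ci],
                                trial = tr)
      }
    }
  }
  structure(list(trials = trials, manifest = do.call(rbind, rows),
                 truth = truth, subject_truths = subject_truths),
            class = "gait_dataset")
}

jitter_truth <- function(truth, subject) {
  if (truth$subject_jitter == 0) return(truth)
  with_seed(derive_seed(truth$seed, subject), {
    st <- truth
    for (m in names(st$bursts)) {
      b <- st$bursts[[m]]
      b$peak <- pmin(pmax(b$peak *
        (1 + stats::rnorm(nrow(b), 0, truth$subject_jitter)), 0), 1)
      b$center <- b$center + stats::rnorm(nrow(b), 0, 25 * truth$subject_jitter)
      st$bursts[[m]] <- b
    }
    st
  })
}

#' @export
print.gait_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("gait_dataset: %d trials (%d subjects x %d conditions x %d trials)\n",
              nrow(m), length(unique(m$subject)),
              length(unique(m$condition)), max(m$trial)))
  invisible(x)
}
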