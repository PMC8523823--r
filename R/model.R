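#' Assemble an EMG-driven ankle model
#'
#' Bundles everything the forward chain needs: activation-dynamics
#' parameters (shared across muscles), per-muscle Hill parameters, the
#' polynomial MTU geometry, and the two group strength coefficients that
#' scale maximum isometric forces (one for the dorsiflexor, one for the
#' plantar flexors).
#'
#' @param activation an [activation_params()] object.
#' @param muscles named list of [muscle_params()]; names must match the
#'   geometry model's muscles.
#' @param geometry an [fit_geometry()] result covering the same muscles.
#' @param gamma_df,gamma_pf strength coefficients in \eqn{[0.5, 1.5]}
#'   multiplying `Fmax` of the dorsiflexor / plantar-flexor group.
#' @return An object of class `ankle_model`.
#' @export
ankle_model <- function(activation, muscles, geometry,
                        gamma_df = 1, gamma_pf = 1) {
  stopifnot(inherits(activation, "activation_params"),
            inherits(geometry, "mtu_geometry"),
            is.list(muscles), !is.null(names(muscles)),
            all(vapply(muscles, inherits, logical(1), "muscle_params")))
  if (!all(names(muscles) %in% names(geometry$muscles)))
    stop("geometry model does not cover all muscles", call. = FALSE)
  if (gamma_df < 0.5 || gamma_df > 1.5 || gamma_pf < 0.5 || gamma_pf > 1.5)
    stop("strength coefficients must lie in [0.5, 1.5]", call. = FALSE)
  structure(list(activation = activation, muscles = muscles,
                 geometry = geometry, gamma_df = gamma_df,
                 gamma_pf = gamma_pf),
            class = "ankle_model")
}

#' @export
print.ankle_model <- function(x, ...) {
  cat(sprintf("ankle_model: %d muscles (%s), gamma_df=%.3f gamma_pf=%.3f\n",
              length(x$muscles), paste(names(x$muscles), collapse = ", "),
              x$gamma_df, x$gamma_pf))
  invisible(x)
}

# muscle params with the group strength coefficient folded into Fmax
scaled_muscle <- function(model, name) {
  p <- model$muscles[[name]]
  g <- if (p$group == "dorsiflexor") model$gamma_df else model$gamma_pf
  p$Fmax <- p$Fmax * g
  p
}

# Fast forward chain on precomputed inputs. exc is an n x muscle matrix of
# excitations; geom is evaluate_geometry() output at the trial's angles.
forward_chain <- function(model, exc, geom, rate, with_stiffness = TRUE) {
  mus <- names(model$muscles)
  fmt <- list(); kmt <- list(); states <- list(); neg_flag <- NULL
  for (m in mus) {
    p <- scaled_muscle(model, m)
    a <- excitation_to_activation(exc[, m], model$activation, rate)
    st <- solve_equilibrium(a, geom[[m]]$lmt, p, rate)
    fmt[[m]] <- st$Fmt
    if (with_stiffness) {
      ks <- mtu_stiffness(st, p, a)
      kmt[[m]] <- ks$Kmt
      neg_flag <- if (is.null(neg_flag)) ks$flagged else neg_flag | ks$flagged
    }
    states[[m]] <- st
  }
  tau <- ankle_moment(fmt, lapply(geom[mus], `[[`, "r"))
  out <- list(tau = tau, fmt = fmt, states = states)
  if (with_stiffness) {
    ks <- ankle_stiffness(kmt, fmt, lapply(geom[mus], `[[`, "r"),
                          lapply(geom[mus], `[[`, "dr_dtheta"))
    out$K <- ks$K
    out$K_raw <- ks$K_raw
    out$kmt <- kmt
    out$flagged <- ks$flagged | neg_flag
  }
  out
}

#' Estimate joint moment and stiffness for one trial
#'
#' Runs the full EMG-driven chain on a gait trial: excitation to
#' activation, MTU geometry at the trial's ankle angles, elastic-tendon
#' Hill dynamics per muscle, and aggregation to ankle moment and
#' rotational stiffness, then resamples both onto the 101-node
#' stance-percentage grid.
#'
#' @param model an [ankle_model()].
#' @param trial a [gait_trial()]; its `emg` matrix must hold excitations
#'   (envelopes) for the model's muscles. Raw-EMG trials must be processed
#'   with [process_raw_emg()] / [normalize_envelopes()] first.
#' @param n nodes of the stance grid (default 101).
#' @param keep_states if `TRUE`, attach per-muscle [solve_equilibrium()]
#'   trajectories.
#' @return An object of class `joint_series`: stance-percentage grid
#'   `pct`, curves `tau` (N m, dorsiflexion positive) and `stiffness`
#'   (N m/rad, clamped at zero), native-resolution series under `native`
#'   (including the unclamped `K_raw`), the fraction of clamped steps
#'   `clamped_frac`, the `nrmse` against the trial's experimental moment
#'   (when present), and trial metadata.
#' @export
estimate_trial <- function(model, trial, n = 101L, keep_states = FALSE) {
  stopifnot(inherits(model, "ankle_model"), inherits(trial, "gait_trial"))
  if (isTRUE(trial$emg_is_raw))
    stop("trial carries raw EMG; process and normalize it first", call. = FALSE)
  mus <- names(model$muscles)
  if (!all(mus %in% colnames(trial$emg)))
    stop("trial excitation matrix does not cover the model's muscles", call. = FALSE)
  geom <- evaluate_geometry(model$geometry, trial$theta)
  fc <- forward_chain(model, trial$emg[, mus, drop = FALSE], geom, trial$rate)
  stance <- c(trial$stance_start, trial$stance_end)
  out <- list(
    pct = seq(0, 100, length.out = n),
    tau = as.numeric(time_normalize(fc$tau, stance, n)),
    stiffness = as.numeric(time_normalize(fc$K, stance, n)),
    native = list(time = trial$time, tau = fc$tau, K = fc$K,
                  K_raw = fc$K_raw),
    clamped_frac = mean(fc$flagged),
    nrmse = if (!is.null(trial$tau_id)) nrmse(fc$tau, trial$tau_id) else NA_real_,
    subject = trial$subject, condition = trial$condition,
    trial_index = trial$trial_index)
  if (keep_states) out$states <- fc$states
  structure(out, class = "joint_series")
}

#' @export
print.joint_series <- function(x, ...) {
  cat(sprintf(
    "joint_series (subject %s, %s, trial %s): peak |tau| %.1f N m, peak K %.0f N m/rad, NRMSE %.3f, %.1f%% clamped steps\n",
    x$subject, x$condition, x$trial_index, max(abs(x$tau)),
    max(x$stiffness), x$nrmse, 100 * x$clamped_frac))
  invisible(x)
}
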