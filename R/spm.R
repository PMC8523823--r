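#' Subject-by-condition curve dataset
#'
#' Container for stance-phase curves in a complete repeated-measures
#' design: one curve per subject and condition (trials already averaged),
#' all on a shared stance-percentage grid.
#'
#' @param curves numeric array `subjects x conditions x nodes`, with
#'   dimnames for subjects and conditions (grid nodes optional).
#' @param pct stance-percentage grid (default 0..100 over the third
#'   dimension).
#' @return An object of class `curve_dataset`.
#' @export
curve_dataset <- function(curves, pct = NULL) {
  stopifnot(is.array(curves), length(dim(curves)) == 3L)
  d <- dim(curves)
  if (d[1] < 2L || d[2] < 2L)
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  if (anyNA(curves))
    stop("incomplete design: curve array contains NA", call. = FALSE)
  if (is.null(pct)) pct <- seq(0, 100, length.out = d[3])
  stopifnot(length(pct) == d[3])
  if (is.null(dimnames(curves)))
    dimnames(curves) <- list(paste0("S", seq_len(d[1])),
                             paste0("C", seq_len(d[2])), NULL)
  structure(list(curves = curves, pct = pct), class = "curve_dataset")
}

#' @export
print.curve_dataset <- function(x, ...) {
  d <- dim(x$curves)
  cat(sprintf("curve_dataset: %d subjects x %d conditions (%s) on %d nodes\n",
              d[1], d[2], paste(dimnames(x$curves)[[2]], collapse = "/"), d[3]))
  invisible(x)
}

#' Average trial curves into a subject-by-condition dataset
#'
#' Time-normalizes the chosen per-trial series onto the stance grid and
#' averages trials within each subject-condition cell (the subject is the
#' repeated-measures unit of analysis).
#'
#' @param dataset a [generate_dataset()] result (or any list with `trials`
#'   and `manifest` of the same shape).
#' @param field which series to extract: the experimental moment, a GRF
#'   component, or a muscle's excitation envelope.
#' @param muscle muscle name, required for `field = "excitation"`.
#' @param n stance-grid size (default 101).
#' @return A [curve_dataset()].
#' @export
curves_from_trials <- function(dataset,
                               field = c("tau_id", "grf_v", "grf_ap",
                                         "excitation"),
                               muscle = NULL, n = 101L) {
  field <- match.arg(field)
  man <- dataset$manifest
  subjects <- sort(unique(man$subject))
  conds <- unique(man$condition)
  Y <- array(NA_real_, c(length(subjects), length(conds), n),
             dimnames = list(paste0("S", subjects), conds, NULL))
  for (si in seq_along(subjects)) {
    for (ci in seq_along(conds)) {
      idx <- man$idx[man$subject == subjects[si] & man$condition == conds[ci]]
      if (!length(idx))
        stop("incomplete design: missing subject-condition cell", call. = FALSE)
      cur <- sapply(idx, function(k) {
        tr <- dataset$trials[[k]]
        y <- switch(field,
                    tau_id = tr$tau_id, grf_v = tr$grf_v, grf_ap = tr$grf_ap,
                    excitation = {
                      if (is.null(muscle)) stop("muscle required", call. = FALSE)
                      if (isTRUE(tr$emg_is_raw)) attr(tr, "envelopes")[, muscle]
                      else tr$emg[, muscle]
                    })
        time_normalize(y, c(tr$stance_start, tr$stance_end), n)
      })
      Y[si, ci, ] <- rowMeans(cur)
    }
  }
  curve_dataset(Y)
}

#' Collect estimated joint curves into a dataset
#'
#' @param series_list list of [estimate_trial()] results covering a
#'   complete subject-by-condition design.
#' @param field `"tau"` or `"stiffness"`.
#' @return A [curve_dataset()] of subject-condition means.
#' @export
curves_from_series <- function(series_list, field = c("tau", "stiffness")) {
  field <- match.arg(field)
  subj <- vapply(series_list, function(s) as.integer(s$subject), integer(1))
  cond <- vapply(series_list, function(s) as.character(s$condition), character(1))
  subjects <- sort(unique(subj)); conds <- unique(cond)
  n <- length(series_list[[1]]$pct)
  Y <- array(NA_real_, c(length(subjects), length(conds), n),
             dimnames = list(paste0("S", subjects), conds, NULL))
  for (si in seq_along(subjects)) for (ci in seq_along(conds)) {
    sel <- which(subj == subjects[si] & cond == conds[ci])
    if (!length(sel))
      stop("incomplete design: missing subject-condition cell", call. = FALSE)
    Y[si, ci, ] <- rowMeans(sapply(sel, function(k) series_list[[k]][[field]]))
  }
  curve_dataset(Y)
}

# Node-wise one-way repeated-measures ANOVA decomposition on the flattened
# (subject*condition) x node matrix. The matrix is centered per node and
# subject effects are removed up front; only the condition sum of squares
# depends on the (possibly permuted) condition labels. Working on
# subject-centered residuals keeps degenerate cases (identical curves)
# free of catastrophic cancellation.
rm_prep <- function(M, subj_idx, S, C) {
  Mc <- sweep(M, 2, colMeans(M))
  sm <- rowsum(Mc, subj_idx) / C
  Mw <- Mc - sm[subj_idx, , drop = FALSE]  # within-subject residuals
  list(Mw = Mw, ss_within = colSums(Mw^2), S = S, C = C)
}

rm_anova_ss <- function(prep, cond_idx) {
  cm <- rowsum(prep$Mw, cond_idx) / prep$S
  ss_cond <- prep$S * colSums(cm^2)
  ss_err <- pmax(prep$ss_within - ss_cond, 0)
  list(ss_cond = ss_cond, ss_err = ss_err)
}

# F with guards for degenerate nodes: both sums (relatively) zero -> 0;
# zero interaction variance with a real condition effect -> Inf
rm_f_stat <- function(ss, prep, dfn, dfd) {
  scale <- pmax(prep$ss_within, 1e-300)
  cond0 <- ss$ss_cond <= 1e-12 * scale
  err0 <- ss$ss_err <= 1e-12 * scale
  Fv <- (ss$ss_cond / dfn) / (ss$ss_err / dfd)
  Fv[err0 & !cond0] <- Inf
  Fv[cond0] <- 0
  Fv
}

#' Repeated-measures ANOVA F-field over the stance grid
#'
#' At every grid node computes the one-way repeated-measures ANOVA F
#' statistic for the condition effect (condition mean square over the
#' condition-by-subject interaction mean square), independently per node.
#' Subject main effects are removed by the design, so per-subject offsets
#' do not change the field. Nodes with zero interaction variance yield
#' `Inf` and are flagged.
#'
#' @param data a [curve_dataset()].
#' @return Numeric F vector over the grid, with logical attribute
#'   `"flagged"` marking infinite nodes and attribute `"df"` holding the
#'   numerator/denominator degrees of freedom.
#' @export
f_field <- function(data) {
  stopifnot(inherits(data, "curve_dataset"))
  d <- dim(data$curves)
  S <- d[1]; C <- d[2]; N <- d[3]
  M <- matrix(aperm(data$curves, c(2, 1, 3)), S * C, N)
  prep <- rm_prep(M, rep(seq_len(S), each = C), S, C)
  ss <- rm_anova_ss(prep, rep(seq_len(C), times = S))
  Fv <- rm_f_stat(ss, prep, C - 1, (C - 1) * (S - 1))
  attr(Fv, "flagged") <- !is.finite(Fv)
  attr(Fv, "df") <- c(C - 1, (C - 1) * (S - 1))
  Fv
}

# contiguous suprathreshold clusters with linearly interpolated extents
find_clusters <- function(Fv, pct, thr) {
  above <- is.finite(Fv) & Fv > thr | is.infinite(Fv)
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0),
                                     extent = numeric(0), peak = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    i <- starts[k]; j <- ends[k]
    left <- if (i == 1L) pct[1] else {
      den <- Fv[i] - Fv[i - 1L]
      pct[i - 1L] + if (is.finite(den) && den > 0)
        (thr - Fv[i - 1L]) / den * (pct[i] - pct[i - 1L]) else pct[i] - pct[i - 1L]
    }
    right <- if (j == length(Fv)) pct[length(pct)] else {
      den <- Fv[j] - Fv[j + 1L]
      pct[j + 1L] - if (is.finite(den) && den > 0)
        (thr - Fv[j + 1L]) / den * (pct[j + 1L] - pct[j]) else pct[j + 1L] - pct[j]
    }
    data.frame(start = left, end = right, extent = right - left,
               peak = max(Fv[i:j]))
  })
  do.call(rbind, out)
}

all_perms <- function(C) {
  if (C == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(C - 1L)
  do.call(rbind, lapply(seq_len(C), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation inference on the F-field (1D SPM)
#'
#' Nonparametric suprathreshold-cluster inference for the one-way
#' repeated-measures design: condition labels are permuted within each
#' subject, the critical threshold is the \eqn{(1-\alpha)} quantile (upper
#' order statistic) of the permutation distribution of the field maximum,
#' and each observed suprathreshold cluster receives a p-value from the
#' permutation distribution of the maximum cluster extent above that same
#' threshold. Extents are measured in stance percent with linear
#' interpolation of the threshold crossings, so the extent statistic is
#' continuous. If the number of distinct within-subject relabelings does
#' not exceed `n_perm`, the null distribution is enumerated exhaustively
#' instead (and the result is then independent of `seed`). Sphericity is
#' not corrected: the permutation null does not require it.
#'
#' @param data a [curve_dataset()].
#' @param alpha family-wise significance level (default 0.05).
#' @param n_perm number of random permutations (>= 100; default 999).
#' @param seed integer seed for the permutation draw.
#' @return An object of class `spm_result`: the F-field, the critical
#'   threshold, a cluster table (`start`, `end`, `extent`, `peak`, `p`,
#'   `significant`), `alpha`, the number of permutations used and whether
#'   they were exhaustive.
#' @export
permutation_inference <- function(data, alpha = 0.05, n_perm = 999L,
                                  seed = 1L) {
  stopifnot(inherits(data, "curve_dataset"), alpha > 0, alpha < 1)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("need n_perm >= 100", call. = FALSE)
  d <- dim(data$curves)
  S <- d[1]; C <- d[2]; N <- d[3]
  M <- matrix(aperm(data$curves, c(2, 1, 3)), S * C, N)
  subj_idx <- rep(seq_len(S), each = C)
  cond_base <- rep(seq_len(C), times = S)
  dfn <- C - 1; dfd <- (C - 1) * (S - 1)

  prep <- rm_prep(M, subj_idx, S, C)
  F_obs <- rm_f_stat(rm_anova_ss(prep, cond_base), prep, dfn, dfd)

  n_exhaustive <- factorial(C)^S
  exhaustive <- is.finite(n_exhaustive) && n_exhaustive <= n_perm
  perm_labels <- if (exhaustive) {
    perms1 <- all_perms(C)
    idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms1))), S)))
    labs <- lapply(seq_len(nrow(idx)), function(i)
      as.integer(t(perms1[idx[i, ], , drop = FALSE])))
    labs[-1L]  # drop the identity; it is the observed labeling
  } else {
    with_seed(seed, lapply(seq_len(n_perm), function(i)
      as.integer(unlist(lapply(seq_len(S), function(s) sample.int(C))))))
  }
  n_used <- length(perm_labels)

  perm_F <- lapply(perm_labels, function(lab)
    rm_f_stat(rm_anova_ss(prep, lab), prep, dfn, dfd))
  perm_max <- vapply(perm_F, function(f) suppressWarnings(max(f[is.finite(f)], 0)),
                     numeric(1))
  kk <- ceiling((1 - alpha) * (n_used + 1L))
  thr <- if (kk > n_used) Inf else sort(perm_max)[kk]

  clus <- find_clusters(F_obs, data$pct, thr)
  if (nrow(clus)) {
    perm_ext <- vapply(perm_F, function(f) {
      cl <- find_clusters(f, data$pct, thr)
      if (nrow(cl)) max(cl$extent) else 0
    }, numeric(1))
    clus$p <- vapply(clus$extent, function(e)
      (1 + sum(perm_ext >= e)) / (n_used + 1L), numeric(1))
    clus$significant <- clus$p < alpha
  } else {
    clus$p <- numeric(0); clus$significant <- logical(0)
  }
  structure(list(F = as.numeric(F_obs), pct = data$pct, threshold = thr,
                 clusters = clus, alpha = alpha, n_perm = n_used,
                 exhaustive = exhaustive, seed = seed,
                 df = c(dfn, dfd)),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf(
    "spm_result: F(%d,%d) field, threshold %.3f (alpha=%.3g, %d %s permutations)\n",
    x$df[1], x$df[2], x$threshold, x$alpha, x$n_perm,
    if (x$exhaustive) "exhaustive" else "random"))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: %.1f-%.1f%% stance (extent %.1f), p=%.4f%s\n",
                  i, x$clusters$start[i], x$clusters$end[i],
                  x$clusters$extent[i], x$clusters$p[i],
                  if (x$clusters$significant[i]) " *" else ""))
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' Cohen's f effect size over a stance window
#'
#' Computes, per node, \eqn{f = \sqrt{SS_{cond} / SS_{err}}} from the
#' repeated-measures decomposition and averages it over the requested
#' stance-percent window. Invariant to global and per-subject constant
#' offsets.
#'
#' @param data a [curve_dataset()].
#' @param window stance-percent interval `c(from, to)` (default the whole
#'   grid).
#' @return Mean Cohen's f over the window, with per-node values as
#'   attribute `"per_node"`.
#' @export
effect_size_f <- function(data, window = c(0, 100)) {
  stopifnot(inherits(data, "curve_dataset"), length(window) == 2L)
  sel <- which(data$pct >= window[1] & data$pct <= window[2])
  if (!length(sel)) stop("empty stance window", call. = FALSE)
  d <- dim(data$curves)
  S <- d[1]; C <- d[2]; N <- d[3]
  M <- matrix(aperm(data$curves, c(2, 1, 3)), S * C, N)
  prep <- rm_prep(M, rep(seq_len(S), each = C), S, C)
  ss <- rm_anova_ss(prep, rep(seq_len(C), times = S))
  fnode <- sqrt(ss$ss_cond / ss$ss_err)
  fnode[ss$ss_cond <= 1e-12 * pmax(prep$ss_within, 1e-300)] <- 0
  out <- mean(fnode[sel])
  attr(out, "per_node") <- fnode[sel]
  out
}
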