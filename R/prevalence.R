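#' Prevalence of a region's representation near the port
#'
#' The session-level statistic behind the neurofeedback effect: among
#' feedback-phase informative 6 ms bins while the animal is within 17 cm of
#' the center port ("eligible" bins), the fraction whose posterior places
#' strictly more than 40% of its mass in the named region. Detection-window
#' bins can be excised (the tone-triggering representation plus the 90 ms
#' before it) so the statistic reflects spontaneous representation only.
#'
#' @param decoded a `decoded_posterior` (6 ms bins) covering the feedback
#'   phase.
#' @param trajectory a `position_trace`.
#' @param geometry a `track_geometry`.
#' @param region region name for [region_mask()].
#' @param arm arm index for arm-specific regions.
#' @param exclude_windows optional n x 2 matrix of time intervals (s) to
#'   remove from the eligible set (see [tone_exclusion_windows()]).
#' @param mass_threshold qualifying mass (strict inequality).
#' @param max_port_distance eligibility distance, cm (strict).
#' @return list of class `prevalence_result`: `prevalence`, `qualifying`,
#'   `eligible`, `region`, `tone_bins_removed`.
#' @export
region_prevalence <- function(decoded, trajectory, geometry, region, arm = 1,
                              exclude_windows = NULL, mass_threshold = 0.40,
                              max_port_distance = 17) {
  fb0 <- attr(trajectory, "feedback_start")
  fi <- pmax(findInterval(decoded$t, trajectory$t), 1)
  pd <- distance_to_center_port(cbind(trajectory$x[fi], trajectory$y[fi]),
                                geometry)
  eligible <- decoded$informative & decoded$t >= fb0 & pd < max_port_distance
  if (!is.null(exclude_windows) && nrow(exclude_windows) > 0) {
    for (k in seq_len(nrow(exclude_windows)))
      eligible <- eligible & !(decoded$t >= exclude_windows[k, 1] &
                                 decoded$t <= exclude_windows[k, 2])
  }
  if (!any(eligible)) stop("undefined prevalence: zero eligible bins")
  mask <- region_mask(geometry, region, arm)
  mass <- as.numeric(decoded$posterior[eligible, , drop = FALSE] %*% mask)
  qualifying <- sum(mass > mass_threshold)
  structure(list(prevalence = qualifying / sum(eligible),
                 qualifying = qualifying, eligible = sum(eligible),
                 region = region, arm = arm,
                 tone_bins_removed = !is.null(exclude_windows)),
            class = "prevalence_result")
}

#' Excision windows for tone-triggering representations
#'
#' One interval per detection: from 120 ms before the detection time (the
#' 30 ms triggering window plus the 90 ms preceding it) to the detection
#' time.
#'
#' @param events a `detection_events`.
#' @param pre_s seconds before detection to excise.
#' @return n x 2 matrix of (start, end) times.
#' @export
tone_exclusion_windows <- function(events, pre_s = 0.12) {
  if (nrow(events) == 0) return(matrix(numeric(0), 0, 2))
  cbind(events$time - pre_s, events$time)
}

#' Keep sessions with near-maximal reward
#'
#' Sessions with more than `frac` of the maximum possible rewards (90% of
#' 75) are retained so reward amount is matched across conditions.
#'
#' @param sessions data.frame with a `rewards` column.
#' @param max_rewards maximum possible rewards.
#' @param frac retention fraction (strict inequality).
#' @return the retained subset.
#' @export
high_reward_filter <- function(sessions, max_rewards = 75, frac = 0.9) {
  sessions[sessions$rewards > frac * max_rewards, , drop = FALSE]
}

#' Two-sided Mann-Whitney U test from the rank formula
#'
#' U is computed from midranks; for small groups (both sizes at most 8) the
#' two-sided p-value is found by exhaustive enumeration over all group
#' assignments of the pooled values; otherwise the normal approximation with
#' tie correction is used. All values tied gives p = 1.
#'
#' @param x,y numeric samples.
#' @return list `U` (statistic for `x`), `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1)
    return(list(U = U1, p = 1, method = "degenerate"))
  if (max(n1, n2) <= 8) {
    mu <- n1 * n2 / 2
    obs_dev <- abs(U1 - mu)
    idx <- utils::combn(N, n1)
    cnt <- 0L
    for (j in seq_len(ncol(idx))) {
      Uj <- sum(r[idx[, j]]) - n1 * (n1 + 1) / 2
      if (abs(Uj - mu) >= obs_dev - 1e-12) cnt <- cnt + 1L
    }
    return(list(U = U1, p = cnt / ncol(idx), method = "exact"))
  }
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sig2 <= 0) return(list(U = U1, p = 1, method = "normal"))
  z <- (U1 - n1 * n2 / 2) / sqrt(sig2)
  list(U = U1, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Compare prevalence between session types
#'
#' Two-sided Mann-Whitney comparison of per-session prevalences between the
#' head-direction control condition and the neurofeedback condition.
#'
#' @param prevalence_hd,prevalence_nf numeric vectors (at least 3 each).
#' @return list `U`, `p`, `method`, group medians.
#' @export
compare_session_types <- function(prevalence_hd, prevalence_nf) {
  if (length(prevalence_hd) < 3 || length(prevalence_nf) < 3)
    stop("need at least 3 sessions per group")
  mw <- mann_whitney(prevalence_hd, prevalence_nf)
  c(mw, list(median_hd = stats::median(prevalence_hd),
             median_nf = stats::median(prevalence_nf)))
}

#' Longitudinal trend of prevalence across sessions
#'
#' Ordinary least squares of (optionally z-scored, optionally per-group
#' z-scored) prevalence against session index; the p-value is the two-sided
#' t-test on the slope. A constant series returns slope 0 and p = 1 by
#' convention.
#'
#' @param prevalence numeric vector of per-session prevalences.
#' @param index session index (defaults to sequence order).
#' @param zscore z-score the prevalences first.
#' @param by optional grouping factor (e.g. animal) for within-group
#'   z-scoring.
#' @return list `slope`, `p`, `fitted`.
#' @export
longitudinal_trend <- function(prevalence, index = seq_along(prevalence),
                               zscore = FALSE, by = NULL) {
  if (length(prevalence) < 5) stop("need at least 5 sessions")
  y <- prevalence
  if (zscore) {
    zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
    y <- if (is.null(by)) zs(y) else stats::ave(y, by, FUN = zs)
  }
  fit <- .ols(index, y)
  list(slope = fit$slope, p = fit$p, fitted = fit$fitted)
}
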