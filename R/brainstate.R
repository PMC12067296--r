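# analytic signal via FFT (frequency-domain Hilbert transform); input is
# zero-padded to a fast composite length so stats::fft stays O(n log n)
.analytic_signal <- function(x) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  (stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

# zero-phase FFT band-pass: zeroes all frequency components outside the band
.fft_bandpass <- function(x, fs, lo, hi) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)[seq_len(n0)]
}

# smoothed band envelope (analytic-signal magnitude)
.band_envelope <- function(x, fs, band, smooth_s = 0.004) {
  xb <- .fft_bandpass(x, fs, band[1], band[2])
  env <- Mod(.analytic_signal(xb))
  .ma_smooth(env, max(1, round(smooth_s * fs)))
}

#' Detect sharp-wave ripples in an LFP trace
#'
#' Band-passes 150-250 Hz, takes the analytic-signal envelope smoothed over
#' 4 ms, and marks events where the envelope exceeds the mean plus
#' `threshold_sd` SDs for at least `min_duration`; each event is extended to
#' the surrounding mean + `boundary_sd` SD crossings, and events separated
#' by less than `merge_gap` are merged.
#'
#' @param lfp an `lfp_trace` (fields `t0`, `fs`, `samples`).
#' @param band ripple band, Hz.
#' @param threshold_sd core detection threshold, SDs above the mean.
#' @param boundary_sd boundary extension threshold.
#' @param min_duration minimum core duration, s.
#' @param smooth_s envelope smoothing, s.
#' @param merge_gap merge events closer than this, s.
#' @return n x 2 matrix of (start, end) times with attributes
#'   `envelope_mean`, `envelope_sd`.
#' @export
detect_swr <- function(lfp, band = c(150, 250), threshold_sd = 3,
                       boundary_sd = 1, min_duration = 0.015,
                       smooth_s = 0.004, merge_gap = 0.010) {
  fs <- lfp$fs
  if (length(lfp$samples) < 10 * fs)
    stop("LFP shorter than 10 s: baseline estimate unstable")
  env <- .band_envelope(lfp$samples, fs, band, smooth_s)
  m <- mean(env); s <- stats::sd(env)
  hi <- env > m + threshold_sd * s
  lo <- env > m + boundary_sd * s

  r <- rle(hi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  core <- which(r$values & r$lengths >= min_duration * fs)
  if (length(core) == 0) {
    out <- matrix(numeric(0), 0, 2)
    attr(out, "envelope_mean") <- m; attr(out, "envelope_sd") <- s
    return(out)
  }
  # extend each core run to its enclosing boundary-threshold run
  rl <- rle(lo)
  lo_ends <- cumsum(rl$lengths); lo_starts <- lo_ends - rl$lengths + 1
  lo_runs <- which(rl$values)
  iv <- t(vapply(core, function(k) {
    j <- lo_runs[lo_starts[lo_runs] <= starts[k] & lo_ends[lo_runs] >= ends[k]]
    if (length(j) == 0) c(starts[k], ends[k]) else c(lo_starts[j[1]], lo_ends[j[1]])
  }, numeric(2)))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  # merge near-adjacent events
  merged <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] - merged[nrow(merged), 2] < merge_gap * fs)
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[k, 2])
    else merged <- rbind(merged, iv[k, ])
  }
  out <- cbind(lfp$t0 + (merged[, 1] - 1) / fs, lfp$t0 + (merged[, 2] - 1) / fs)
  attr(out, "envelope_mean") <- m; attr(out, "envelope_sd") <- s
  out
}

#' Label each time bin with a brain state
#'
#' A bin is `swr` when it overlaps a detected ripple interval, else `moving`
#' when head speed exceeds 4 cm/s, else `still`. The three states are
#' mutually exclusive and exhaustive.
#'
#' @param trajectory a `position_trace`.
#' @param swr_intervals n x 2 matrix from [detect_swr()].
#' @param bin_t bin center times, s.
#' @param bin_width bin width, s.
#' @param speed_threshold stillness cutoff, cm/s.
#' @return character vector of states per bin.
#' @export
label_states <- function(trajectory, swr_intervals, bin_t,
                         bin_width = 0.006, speed_threshold = 4) {
  fi <- pmax(findInterval(bin_t, trajectory$t), 1)
  state <- ifelse(trajectory$head_speed[fi] > speed_threshold, "moving", "still")
  if (!is.null(swr_intervals) && nrow(swr_intervals) > 0) {
    for (k in seq_len(nrow(swr_intervals))) {
      ov <- bin_t + bin_width / 2 > swr_intervals[k, 1] &
        bin_t - bin_width / 2 < swr_intervals[k, 2]
      state[ov] <- "swr"
    }
  }
  state
}

#' Theta phase at given times
#'
#' Band-passes the LFP around theta, takes the analytic-signal phase and
#' reports it with the convention phase 0 = trough of the reference LFP,
#' increasing through the cycle (peak at pi), in [0, 2*pi).
#'
#' @param times query times, s.
#' @param lfp an `lfp_trace`.
#' @param band theta band, Hz.
#' @return phases in radians.
#' @export
theta_phase_at <- function(times, lfp, band = c(6, 10)) {
  xb <- .fft_bandpass(lfp$samples, lfp$fs, band[1], band[2])
  ph <- Arg(.analytic_signal(xb))
  idx <- pmin(pmax(round((times - lfp$t0) * lfp$fs) + 1, 1), length(ph))
  (ph[idx] + pi) %% (2 * pi)
}

#' Rayleigh test for circular uniformity
#'
#' Mean resultant length `Rbar = |sum exp(i phi)| / n`, statistic
#' `Z = n Rbar^2`, with the standard finite-n series correction for the
#' p-value. With fewer than 10 phases the uncorrected `exp(-Z)` is reported
#' with a warning.
#'
#' @param phases radians.
#' @return list `Rbar`, `Z`, `p`, `n`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  Rbar <- Mod(sum(exp(1i * phases))) / n
  Z <- n * Rbar^2
  if (n < 10) {
    warning("n < 10: Rayleigh p reported without correction terms")
    return(list(Rbar = Rbar, Z = Z, p = min(1, exp(-Z)), n = n))
  }
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(Rbar = Rbar, Z = Z, p = min(max(p, 0), 1), n = n)
}

# two-proportion z-test (pooled), two-sided, no continuity correction
.two_prop_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Brain-state composition of remote-representation bins
#'
#' Fractions of bins in each state (swr / still / moving) per condition, a
#' chi-square test over the state-by-condition contingency table, and
#' post-hoc two-proportion z-tests for the moving and swr fractions between
#' each pair of conditions. Expected cell counts below 5 trigger an exact
#' (Fisher) fallback, flagged in the output.
#'
#' @param state_sets named list: one character vector of states per
#'   condition.
#' @return list `fractions` (conditions x states), `chisq` (statistic, df,
#'   p), `posthoc` (data.frame of pairwise z-tests), `exact_fallback`.
#' @export
state_composition <- function(state_sets) {
  states <- c("swr", "still", "moving")
  if (any(vapply(state_sets, length, 0) < 20))
    stop("need at least 20 bins per condition")
  tab <- t(vapply(state_sets, function(s)
    as.numeric(table(factor(s, levels = states))), numeric(3)))
  colnames(tab) <- states
  fractions <- tab / rowSums(tab)

  use <- colSums(tab) > 0
  suppressWarnings(ch <- stats::chisq.test(tab[, use, drop = FALSE],
                                           correct = FALSE))
  exact_fallback <- any(ch$expected < 5)
  pval <- ch$p.value
  if (exact_fallback && nrow(tab) <= 3)
    pval <- stats::fisher.test(tab[, use, drop = FALSE],
                               simulate.p.value = nrow(tab) > 2,
                               B = 2000)$p.value

  conds <- rownames(tab)
  ph <- list()
  if (length(conds) >= 2) {
    prs <- utils::combn(length(conds), 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      for (st in c("moving", "swr")) {
        zt <- .two_prop_z(tab[a, st], sum(tab[a, ]), tab[b, st], sum(tab[b, ]))
        ph[[length(ph) + 1]] <- data.frame(
          cond1 = conds[a], cond2 = conds[b], state = st,
          z = zt$z, p = zt$p, stringsAsFactors = FALSE)
      }
    }
  }
  list(fractions = fractions,
       chisq = list(statistic = unname(ch$statistic), df = unname(ch$parameter),
                    p = pval),
       posthoc = if (length(ph)) do.call(rbind, ph) else NULL,
       exact_fallback = exact_fallback)
}
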