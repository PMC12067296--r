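# Constructed inputs shared across test files: fabricated posterior
# streams, exact-position segments, planted assemblies, and surrogate
# ripple LFPs.

# fabricate an averaged-posterior stream with given per-bin target-end mass
# and a trajectory pinned at the center port
make_stream <- function(g, mass_target, mass_box = 0, tet_count = 8,
                        eligible = TRUE, t0 = 100) {
  n <- length(mass_target)
  nb <- g$n_bins
  endb <- which(region_mask(g, "target_end", 1))
  boxb <- which(region_mask(g, "box"))
  restb <- setdiff(seq_len(nb), c(endb, boxb))
  avg <- matrix(0, n, nb)
  for (i in seq_len(n)) {
    avg[i, endb] <- mass_target[i] / length(endb)
    avg[i, boxb] <- mass_box / length(boxb)
    avg[i, restb] <- (1 - mass_target[i] - mass_box) / length(restb)
  }
  stream <- structure(list(
    t = t0 + (seq_len(n) - 0.5) * 0.006, bin_width = 0.006, avg = avg,
    eligible = rep_len(eligible, n), n_informative = rep(5, n),
    window_tet_count = rep_len(tet_count, n)), class = "avg_posterior")
  tn <- ceiling(t0 + n * 0.006 + 5)
  traj <- data.frame(t = seq(0, tn, by = 1 / 30), x = 0, y = 2,
                     head_direction = 0, linear = 2, segment = "box",
                     head_speed = 0, off_track = FALSE, phase = "feedback",
                     stringsAsFactors = FALSE)
  attr(traj, "pos_hz") <- 30
  attr(traj, "feedback_start") <- 0
  class(traj) <- c("position_trace", "data.frame")
  list(stream = stream, traj = traj)
}

# fabricate a feedback-phase decoded posterior whose target-end mass is
# given per bin, with the animal parked at the port
make_decoded <- function(g, mass_target, informative = TRUE) {
  n <- length(mass_target)
  endb <- which(region_mask(g, "target_end", 1))
  restb <- setdiff(seq_len(g$n_bins), endb)
  P <- matrix(0, n, g$n_bins)
  for (i in seq_len(n)) {
    P[i, endb] <- mass_target[i] / length(endb)
    P[i, restb] <- (1 - mass_target[i]) / length(restb)
  }
  dec <- structure(list(t = 10 + (seq_len(n) - 0.5) * 0.006,
                        bin_width = 0.006, posterior = P,
                        informative = rep_len(informative, n),
                        n_spikes = rep(1L, n),
                        tet_specific = matrix(TRUE, n, 1),
                        n_contributing_tetrodes = rep(1L, n)),
                   class = "decoded_posterior")
  tn <- 15 + n * 0.006
  traj <- data.frame(t = seq(0, tn, by = 1 / 30), x = 0, y = 2,
                     head_direction = 0, linear = 2, segment = "box",
                     head_speed = 0, off_track = FALSE, phase = "feedback",
                     stringsAsFactors = FALSE)
  attr(traj, "pos_hz") <- 30; attr(traj, "feedback_start") <- 0
  class(traj) <- c("position_trace", "data.frame")
  list(dec = dec, traj = traj)
}

# build a posterior segment whose per-bin represented position is exact:
# mass is split linearly between the two bin centers bracketing each position
seg_from_positions <- function(g, pos) {
  seg <- matrix(0, length(pos), g$n_bins)
  for (i in seq_along(pos)) {
    j <- findInterval(pos[i], g$bin_centers)
    j <- min(max(j, 1), g$n_bins - 1)
    w <- (pos[i] - g$bin_centers[j]) / diff(g$bin_centers[j + 0:1])
    seg[i, j] <- 1 - w
    seg[i, j + 1] <- w
  }
  seg
}

# synthetic LFP with ripples injected at known times over a noise floor
make_ripple_lfp <- function(seed, n_ripples, dur_s = 120, fs = 1500,
                            snr = 6) {
  set.seed(seed)
  x <- rnorm(dur_s * fs, 0, 15)
  tt <- (seq_along(x) - 1) / fs
  intervals <- NULL
  if (n_ripples > 0) {
    env <- remoterep:::.band_envelope(x, fs, c(150, 250))
    A <- mean(env) + snr * sd(env)
    centers <- seq(3, dur_s - 3, length.out = n_ripples)
    for (ct in centers) {
      dur <- runif(1, 0.05, 0.1)
      k <- round((ct - dur / 2) * fs):round((ct + dur / 2) * fs)
      hann <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(k))))
      x[k] <- x[k] + A * hann * sin(2 * pi * 200 * tt[k])
      intervals <- rbind(intervals, c(tt[k[1]], tt[k[length(k)]]))
    }
  }
  list(lfp = structure(list(t0 = 0, fs = fs, samples = x),
                       class = "lfp_trace"),
       intervals = intervals)
}

interval_overlap <- function(a, b) a[1] < b[2] && b[1] < a[2]

# spike trains with a planted co-firing assembly in units 1..8
planted_units <- function(seed, n_units = 60, minutes = 8, p_event = 0.02) {
  set.seed(seed)
  t_end <- minutes * 60
  base <- lapply(seq_len(n_units), function(i)
    sort(runif(rpois(1, 1.2 * t_end), 0, t_end)))
  ev <- sort(runif(rpois(1, p_event / 0.03 * t_end), 0, t_end))
  for (i in 1:8)
    base[[i]] <- sort(c(base[[i]], ev + runif(length(ev), 0, 0.02)))
  base
}
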