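#' Synthetic Y-maze session configuration
#'
#' Bundles every knob of the synthetic session generator. The defaults emulate
#' the study conditions: a cued exploration phase with 12 visits to each arm,
#' a feedback phase spent almost entirely within reach of the center port,
#' ~60 place cells on 8 tetrodes with unimodal spatial tuning, tetrode-specific
#' mark clusters, movement-gated ~8 Hz theta, and ripples injected during
#' stillness. One global `seed` expands into per-component substreams
#' (trajectory, tuning, spiking, event injection, LFP) so a single component
#' can be re-randomized while the others stay fixed.
#'
#' @param seed integer master seed.
#' @param n_cells number of place cells.
#' @param n_tetrodes number of tetrodes; cells are assigned round-robin.
#' @param exploration_minutes duration of the exploration phase. Port dwell
#'   times are sized so exactly `visits_per_arm` visits to each arm fill it.
#' @param feedback_minutes duration of the feedback phase.
#' @param visits_per_arm arm visits during exploration (12 in the task).
#' @param field_width_sigma Gaussian place-field width, cm.
#' @param peak_rate,baseline_rate in-field peak and out-of-field floor, Hz.
#' @param fraction_in_target fraction of cells whose field center lies in the
#'   distal 25 cm of the target arm.
#' @param mark_cluster_sd spherical spread of a cell's spike-amplitude marks, uV.
#' @param mark_cluster_separation minimum distance between mark-cluster means
#'   of cells sharing a tetrode, uV.
#' @param still_rate_factor multiplier on place-field rate while the animal is
#'   still (< 4 cm/s); place cells fire far less during immobility.
#' @param event_rate_multiplier spiking gain during injected remote events
#'   relative to the movement-rate tuning curve.
#' @param injected_events list of [event_spec()] objects.
#' @param n_ripples ripples injected into the feedback-phase LFP (during
#'   stillness); `swr_times` may instead give explicit times.
#' @param swr_times explicit ripple center times (s), or `NULL` to place them.
#' @param ripple_snr ripple envelope amplitude in units of SDs above the
#'   ripple-band noise envelope mean.
#' @param theta_freq theta frequency, Hz.
#' @param run_speed running speed during arm traversals, cm/s.
#' @param target_arm arm (1 or 2) whose distal 25 cm is the feedback target.
#' @param arm_length,box_extent,bin_size track geometry, cm.
#' @param pos_hz position sampling rate (camera rate).
#' @param lfp_hz LFP sampling rate.
#' @param poke_prob,poke_latency nosepoke response model: probability that a
#'   tone is answered, and the uniform latency range (s).
#' @return object of class `session_config`.
#' @export
session_config <- function(seed = 1L, n_cells = 60, n_tetrodes = 8,
                           exploration_minutes = 15, feedback_minutes = 10,
                           visits_per_arm = 12,
                           field_width_sigma = 10, peak_rate = 30,
                           baseline_rate = 0.1, fraction_in_target = 0.2,
                           mark_cluster_sd = 20, mark_cluster_separation = 80,
                           still_rate_factor = 0.15, event_rate_multiplier = 3,
                           injected_events = list(),
                           n_ripples = 0, swr_times = NULL, ripple_snr = 6,
                           theta_freq = 8, run_speed = 20, target_arm = 1,
                           arm_length = 120, box_extent = 40, bin_size = 5,
                           pos_hz = 30, lfp_hz = 1500,
                           poke_prob = 0.95, poke_latency = c(0.2, 1.0)) {
  stopifnot(n_cells >= n_tetrodes, peak_rate >= 0, baseline_rate >= 0,
            exploration_minutes > 0, feedback_minutes >= 0)
  structure(as.list(environment()), class = "session_config")
}

#' Specify an injected remote-representation event
#'
#' @param time event onset, seconds from session start (must lie in the
#'   feedback phase).
#' @param kind `"jump"` (representation confined to the distal 25 cm of the
#'   target arm), `"jump_arm_base"` (as jump, with a transient fraction of
#'   mass at the first 15 cm of the arm before detection), or
#'   `"medium_trajectory"` / `"long_trajectory"` (fast linear sweep toward the
#'   arm end covering `span` cm, then holding at the end).
#' @param target_arm represented arm.
#' @param duration_ms total event duration.
#' @param span sweep extent (cm) for trajectory kinds.
#' @export
event_spec <- function(time, kind = c("jump", "jump_arm_base",
                                      "medium_trajectory", "long_trajectory"),
                       target_arm = 1, duration_ms = NULL, span = NULL) {
  kind <- match.arg(kind)
  if (is.null(span))
    span <- switch(kind, medium_trajectory = 80, long_trajectory = 100, NA_real_)
  if (is.null(duration_ms))
    duration_ms <- switch(kind, jump = 120, jump_arm_base = 132,
                          ceiling(span / .event_speed(kind)) + 12)
  structure(list(time = time, kind = kind, target_arm = target_arm,
                 duration_ms = duration_ms, span = span),
            class = "event_spec")
}

# per-component substream from the master seed; keeps seeds well below 2^31
.substream <- function(seed, k) {
  set.seed((abs(as.integer(seed)) %% 1000003L) * 131L + as.integer(k))
}

# centered moving average with shrinking windows at the edges
.ma_smooth <- function(x, k) {
  n <- length(x)
  h <- k %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# skeleton-distance matrix between linear coordinate vectors a and b
.lin_dist_matrix <- function(geometry, a, b) {
  sa <- .seg_index(geometry, a); sb <- .seg_index(geometry, b)
  starts <- c(0, geometry$box_extent, geometry$box_extent + geometry$arm_length)
  dJ <- function(lin, seg) ifelse(seg == 1L, geometry$box_extent - lin, lin - starts[seg])
  D <- outer(dJ(a, sa), dJ(b, sb), "+")
  same <- outer(sa, sb, "==")
  D[same] <- abs(outer(a, b, "-"))[same]
  D
}

#' Simulate the animal's trajectory
#'
#' Exploration: exactly `visits_per_arm` randomized out-and-back visits to
#' each arm at roughly `run_speed`, with port dwells sized to fill
#' `exploration_minutes`. Feedback: the animal sits near the center port
#' (within 17 cm at least 80% of the time) in stillness bouts broken by brief
#' repositioning movements. Head direction follows travel during movement and
#' wanders slowly around "forward" during stillness.
#'
#' @param config a [session_config()].
#' @param geometry a [build_track()] geometry.
#' @return a `position_trace` data.frame: `t`, `x`, `y`, `head_direction`,
#'   `linear`, `segment`, `head_speed`, `off_track`, `phase`; with attributes
#'   `feedback_start` (s) and `visits`.
#' @export
simulate_trajectory <- function(config, geometry) {
  .substream(config$seed, 1L)
  dt <- 1 / config$pos_hz
  end1 <- geometry$box_extent + geometry$arm_length
  end2 <- end1 + geometry$arm_length

  # --- exploration: piecewise-linear linear-position waypoints -------------
  arms <- sample(rep(1:2, config$visits_per_arm))
  travel <- 2 * sum(geometry$box_extent + geometry$arm_length - 4) *
    length(arms) / config$run_speed
  expl_s <- config$exploration_minutes * 60
  dwell_total <- max(0, expl_s - travel)
  dwell <- dwell_total / (2 * length(arms))   # one arm-port + one center dwell per visit
  tt <- 0; wp_t <- 0; wp_x <- 2  # start just off the port
  for (a in arms) {
    endx <- if (a == 1) end1 - 2 else end2 - 2
    run <- (endx - 2 + geometry$box_extent) / config$run_speed  # approx; exact below
    d_out <- abs(endx - wp_x[length(wp_x)])
    # out via junction: distance on skeleton
    d_out <- lin_dist(geometry, wp_x[length(wp_x)], endx)
    t_out <- d_out / config$run_speed
    wp_t <- c(wp_t, tt + t_out, tt + t_out + dwell)
    wp_x <- c(wp_x, endx, endx)
    tt <- tt + t_out + dwell
    d_back <- lin_dist(geometry, endx, 2)
    t_back <- d_back / config$run_speed
    wp_t <- c(wp_t, tt + t_back, tt + t_back + dwell)
    wp_x <- c(wp_x, 2, 2)
    tt <- tt + t_back + dwell
  }
  expl_end <- max(wp_t)
  t_expl <- seq(0, expl_end, by = dt)
  # interpolate along the skeleton: between waypoints the path passes the
  # junction, so interpolate the signed path length, not the raw coordinate
  lin_expl <- numeric(length(t_expl))
  seg_idx <- findInterval(t_expl, wp_t, rightmost.closed = TRUE)
  seg_idx[seg_idx < 1] <- 1
  for (i in seq_along(t_expl)) {
    k <- seg_idx[i]
    if (k >= length(wp_t)) { lin_expl[i] <- wp_x[length(wp_x)]; next }
    a0 <- wp_x[k]; a1 <- wp_x[k + 1]
    f <- if (wp_t[k + 1] > wp_t[k]) (t_expl[i] - wp_t[k]) / (wp_t[k + 1] - wp_t[k]) else 0
    d <- lin_dist(geometry, a0, a1)
    trav <- f * d
    s0 <- .seg_index(geometry, a0); s1 <- .seg_index(geometry, a1)
    if (s0 == s1 || d == 0) {
      lin_expl[i] <- a0 + sign(a1 - a0) * trav
    } else {
      # through the junction: walk to the junction first, then outward
      starts <- c(0, geometry$box_extent, geometry$box_extent + geometry$arm_length)
      dJ0 <- if (s0 == 1L) geometry$box_extent - a0 else a0 - starts[s0]
      if (trav <= dJ0) {
        lin_expl[i] <- a0 + (if (s0 == 1L) trav else -trav)
      } else {
        rem <- trav - dJ0
        lin_expl[i] <- if (s1 == 1L) geometry$box_extent - rem else starts[s1] + rem
      }
    }
  }

  # --- feedback: stillness bouts near the port with brief movements --------
  fb_s <- config$feedback_minutes * 60
  fb_t0 <- expl_end + dt
  pts_t <- c(fb_t0); pts_xy <- matrix(c(0, 2), ncol = 2)
  tt <- fb_t0
  cur <- c(0, 2)
  while (fb_s > 0 && tt < fb_t0 + fb_s) {
    still_d <- min(max(stats::rexp(1, 1 / 6), 2.5), 15)
    tt <- tt + still_d
    excursion <- stats::runif(1) < 0.08
    nxt <- if (excursion)
      c(stats::runif(1, -5, 5), stats::runif(1, 20, min(30, geometry$box_extent - 2)))
    else
      c(stats::runif(1, -5, 5), stats::runif(1, 0.5, 9))
    move_d <- max(sqrt(sum((nxt - cur)^2)) / 12, 0.4)
    pts_t <- c(pts_t, tt, tt + move_d)
    pts_xy <- rbind(pts_xy, cur, nxt)
    tt <- tt + move_d
    cur <- nxt
  }
  if (fb_s > 0) {
    t_fb <- seq(fb_t0, fb_t0 + fb_s, by = dt)
    fx <- stats::approx(c(fb_t0 - 1, pts_t), c(0, pts_xy[, 1]), xout = t_fb, rule = 2)$y
    fy <- stats::approx(c(fb_t0 - 1, pts_t), c(2, pts_xy[, 2]), xout = t_fb, rule = 2)$y
  } else {
    t_fb <- numeric(0); fx <- numeric(0); fy <- numeric(0)
  }

  xy_expl <- lin_to_xy(geometry, lin_expl)
  xy <- rbind(xy_expl, cbind(fx, fy))
  t_all <- c(t_expl, t_fb)
  n <- length(t_all)
  # smooth low-amplitude jitter (does not disturb stillness detection)
  jit <- cbind(.ma_smooth(stats::rnorm(n, 0, 1.2), 31),
               .ma_smooth(stats::rnorm(n, 0, 1.2), 31))
  xy <- xy + jit

  lz <- linearize(xy, geometry)
  step <- sqrt(rowSums((xy - rbind(xy[1, ], xy[-n, ]))^2))
  step[1] <- step[2]
  head_speed <- .ma_smooth(step / dt, 5)

  # head direction: travel direction while moving, slow wander while still
  dvec <- xy - rbind(xy[1, ], xy[-n, ])
  ang <- atan2(dvec[, 1] * -1, dvec[, 2])  # 0 = facing +y (toward arms), + = left
  ang[1] <- 0
  moving <- head_speed > 4
  wander <- numeric(n); w <- 0
  innov <- stats::rnorm(n, 0, 0.09)
  for (i in seq_len(n)) { w <- 0.985 * w + innov[i]; wander[i] <- w }
  hd <- ifelse(moving, ang, wander)
  hd <- atan2(.ma_smooth(sin(hd), 7), .ma_smooth(cos(hd), 7))

  trace <- data.frame(t = t_all, x = xy[, 1], y = xy[, 2],
                      head_direction = hd,
                      linear = lz$linear, segment = lz$segment,
                      head_speed = head_speed, off_track = lz$off_track,
                      phase = c(rep("exploration", length(t_expl)),
                                rep("feedback", length(t_fb))),
                      stringsAsFactors = FALSE)
  attr(trace, "feedback_start") <- fb_t0
  attr(trace, "visits") <- data.frame(arm = arms)
  attr(trace, "pos_hz") <- config$pos_hz
  class(trace) <- c("position_trace", "data.frame")
  trace
}

#' Simulate place-cell tuning curves and mark clusters
#'
#' Each cell gets a unimodal Gaussian tuning curve over linearized position
#' (skeleton distance to the field center), peaking at `peak_rate` with floor
#' `baseline_rate`. A `fraction_in_target` of cells have field centers inside
#' the distal 25 cm of the target arm. Cells are assigned round-robin to
#' tetrodes and each receives a 4D mark-cluster mean separated from its
#' tetrode-mates by at least `mark_cluster_separation` uV.
#'
#' @param config a [session_config()].
#' @param geometry a [build_track()] geometry.
#' @return object of class `place_tuning`: `centers`, `sigma`, `peak`,
#'   `baseline`, `cell_tetrode`, `mark_means` (n_cells x 4).
#' @export
simulate_place_cells <- function(config, geometry) {
  .substream(config$seed, 2L)
  n <- config$n_cells
  n_target <- round(config$fraction_in_target * n)
  end_t <- geometry$box_extent + config$target_arm * geometry$arm_length
  if (config$target_arm == 2) end_t <- geometry$box_extent + 2 * geometry$arm_length
  lo_t <- end_t - 25
  centers_t <- stats::runif(n_target, lo_t + 2, end_t - 2)
  # remaining centers uniform over the rest of the track
  rest <- numeric(0)
  while (length(rest) < n - n_target) {
    cand <- stats::runif(2 * n, 1, geometry$total_length - 1)
    cand <- cand[cand < lo_t | cand >= end_t]
    rest <- c(rest, cand)
  }
  centers <- c(centers_t, rest[seq_len(n - n_target)])
  cell_tetrode <- ((seq_len(n) - 1L) %% config$n_tetrodes) + 1L

  mark_means <- matrix(NA_real_, n, 4)
  for (tet in seq_len(config$n_tetrodes)) {
    idx <- which(cell_tetrode == tet)
    got <- matrix(numeric(0), 0, 4)
    while (nrow(got) < length(idx)) {
      cand <- matrix(stats::runif(4, 150, 420), 1, 4)
      ok <- nrow(got) == 0 ||
        min(sqrt(rowSums(sweep(got, 2, cand[1, ])^2))) >= config$mark_cluster_separation
      if (ok) got <- rbind(got, cand)
    }
    mark_means[idx, ] <- got
  }
  structure(list(centers = centers, sigma = config$field_width_sigma,
                 peak = config$peak_rate, baseline = config$baseline_rate,
                 cell_tetrode = cell_tetrode, mark_means = mark_means,
                 n_cells = n),
            class = "place_tuning")
}

#' Evaluate tuning-curve rates at linear positions
#'
#' @param tuning a `place_tuning`.
#' @param geometry track geometry.
#' @param lin vector of linear positions, cm.
#' @return n_cells x length(lin) matrix of rates, Hz.
#' @export
tuning_rate <- function(tuning, geometry, lin) {
  D <- .lin_dist_matrix(geometry, tuning$centers, lin)
  tuning$baseline + (tuning$peak - tuning$baseline) * exp(-D^2 / (2 * tuning$sigma^2))
}

#' Generate marked spikes from tuning curves and a trajectory
#'
#' Inhomogeneous Poisson spiking: each cell's rate is its tuning curve
#' evaluated at the animal's linearized position, scaled by
#' `still_rate_factor` while head speed is below 4 cm/s. Each spike's 4D mark
#' is drawn from its cell's cluster (`mark_cluster_sd` spherical spread).
#'
#' @param tuning a `place_tuning`.
#' @param trajectory a `position_trace`.
#' @param config a [session_config()].
#' @return object of class `marked_spikes`: list `tetrodes` (per tetrode:
#'   `times`, `marks`) and `cells` (ground-truth cell index per spike, to be
#'   moved into the session's ground-truth sidecar).
#' @export
generate_marked_spikes <- function(tuning, trajectory, config) {
  .substream(config$seed, 3L)
  dt <- 1 / attr(trajectory, "pos_hz")
  rates <- tuning_rate(tuning, .gt_geometry(config), trajectory$linear)
  still <- trajectory$head_speed <= 4
  rates[, still] <- rates[, still] * config$still_rate_factor
  counts <- matrix(stats::rpois(length(rates), rates * dt), nrow = nrow(rates))
  idx <- which(counts > 0, arr.ind = TRUE)
  reps <- counts[counts > 0]
  cell <- rep(idx[, 1], reps)
  frame <- rep(idx[, 2], reps)
  times <- trajectory$t[frame] + stats::runif(length(frame), 0, dt)
  marks <- tuning$mark_means[cell, , drop = FALSE] +
    matrix(stats::rnorm(4 * length(cell), 0, config$mark_cluster_sd), ncol = 4)
  .assemble_marked_spikes(times, marks, cell, tuning, config)
}

.gt_geometry <- function(config)
  build_track(config$arm_length, config$box_extent, config$bin_size)

.assemble_marked_spikes <- function(times, marks, cell, tuning, config) {
  tet_of <- tuning$cell_tetrode[cell]
  tetrodes <- vector("list", config$n_tetrodes)
  cells <- vector("list", config$n_tetrodes)
  for (tet in seq_len(config$n_tetrodes)) {
    sel <- which(tet_of == tet)
    o <- sel[order(times[sel])]
    tetrodes[[tet]] <- list(times = times[o], marks = marks[o, , drop = FALSE])
    cells[[tet]] <- cell[o]
  }
  structure(list(tetrodes = tetrodes, cells = cells), class = "marked_spikes")
}

# sweep speed (cm/ms) of trajectory-kind events. Sweeps are longer than the
# 96 ms classification window, so the represented distance a detection's
# segment can cover is set by the speed alone (~ speed x 96 ms), decoupling
# the event category from the exact detection latency.
.event_speed <- function(kind) if (kind == "medium_trajectory") 0.38 else 0.64

# represented linear position for an injected event at offsets tt (seconds
# from event onset)
.event_positions <- function(ev, tt, geometry) {
  endx <- geometry$box_extent + ev$target_arm * geometry$arm_length
  base <- geometry$box_extent + (ev$target_arm - 1) * geometry$arm_length
  ms <- tt * 1000
  n <- length(tt)
  pos <- numeric(n)
  if (ev$kind == "jump") {
    pos <- stats::runif(n, endx - 22, endx - 3)
  } else if (ev$kind == "jump_arm_base") {
    # alternating blocks of base / end representation before settling at
    # the end: base mass appears in pre-detection bins without producing a
    # monotone (trajectory-like) position ramp
    at_base <- (ms < 18) | (ms >= 30 & ms < 42) | (ms >= 54 & ms < 66)
    pos <- stats::runif(n, endx - 22, endx - 3)
    pos[at_base] <- stats::runif(sum(at_base), base + 1, base + 14)
  } else {
    # constant-speed sweep from end - span toward the arm end, then hold
    v <- .event_speed(ev$kind) * 1000   # cm/s
    pos <- (endx - ev$span) + v * tt + stats::rnorm(n, 0, 1)
    pos <- pmin(pmax(pos, base + 1), endx - 2)
  }
  pos
}

#' Inject remote-representation events into a spike train
#'
#' Within each event window the locally-driven spiking is replaced by spiking
#' generated as if the animal occupied the represented positions (jump:
#' positions inside the distal 25 cm only; trajectory kinds: a fast sweep
#' covering `span` cm toward the arm end, then holding there), at
#' `event_rate_multiplier` times the movement-rate tuning curve, superposed on
#' baseline background from all cells.
#'
#' @param spikes a `marked_spikes`.
#' @param trajectory a `position_trace`.
#' @param tuning a `place_tuning`.
#' @param events list of [event_spec()].
#' @param config a [session_config()].
#' @param geometry track geometry.
#' @return a `marked_spikes` with attribute `event_log` (data.frame of the
#'   injected ground truth).
#' @export
inject_remote_events <- function(spikes, trajectory, tuning, events, config,
                                 geometry) {
  if (length(events) == 0) {
    attr(spikes, "event_log") <- .empty_event_log()
    return(spikes)
  }
  .substream(config$seed, 4L)
  t0 <- vapply(events, `[[`, 0, "time")
  t1 <- t0 + vapply(events, `[[`, 0, "duration_ms") / 1000
  o <- order(t0)
  if (any(t1[o][-length(o)] > t0[o][-1]))
    stop("injected events overlap")
  fb0 <- attr(trajectory, "feedback_start")
  if (any(t0 < fb0)) stop("event times must lie in the feedback phase")

  sub <- 0.002  # 2 ms generation grid
  new_t <- list(); new_m <- list(); new_c <- list()
  for (ev in events) {
    tt <- seq(0, ev$duration_ms / 1000 - sub / 2, by = sub)
    pos <- .event_positions(ev, tt, geometry)
    R <- tuning_rate(tuning, geometry, pos) * config$event_rate_multiplier
    cnt <- matrix(stats::rpois(length(R), R * sub), nrow = nrow(R))
    idx <- which(cnt > 0, arr.ind = TRUE)
    reps <- cnt[cnt > 0]
    cell <- rep(idx[, 1], reps)
    stime <- ev$time + tt[rep(idx[, 2], reps)] + stats::runif(length(cell), 0, sub)
    # baseline background from every cell
    nb <- stats::rpois(1, tuning$n_cells * tuning$baseline * ev$duration_ms / 1000)
    if (nb > 0) {
      bcell <- sample.int(tuning$n_cells, nb, replace = TRUE)
      cell <- c(cell, bcell)
      stime <- c(stime, ev$time + stats::runif(nb, 0, ev$duration_ms / 1000))
    }
    marks <- tuning$mark_means[cell, , drop = FALSE] +
      matrix(stats::rnorm(4 * length(cell), 0, config$mark_cluster_sd), ncol = 4)
    new_t[[length(new_t) + 1]] <- stime
    new_m[[length(new_m) + 1]] <- marks
    new_c[[length(new_c) + 1]] <- cell
  }
  add_t <- unlist(new_t); add_c <- unlist(new_c)
  add_m <- do.call(rbind, new_m)

  # strip locally-driven spikes inside event windows, then merge
  all_t <- numeric(0); all_c <- integer(0); all_m <- matrix(numeric(0), 0, 4)
  for (tet in seq_along(spikes$tetrodes)) {
    ts <- spikes$tetrodes[[tet]]$times
    keep <- rep(TRUE, length(ts))
    for (k in seq_along(t0)) keep <- keep & !(ts >= t0[k] & ts < t1[k])
    all_t <- c(all_t, ts[keep])
    all_c <- c(all_c, spikes$cells[[tet]][keep])
    all_m <- rbind(all_m, spikes$tetrodes[[tet]]$marks[keep, , drop = FALSE])
  }
  all_t <- c(all_t, add_t); all_c <- c(all_c, add_c); all_m <- rbind(all_m, add_m)
  out <- .assemble_marked_spikes(all_t, all_m, all_c, tuning, config)
  attr(out, "event_log") <- data.frame(
    time = t0, end = t1,
    kind = vapply(events, `[[`, "", "kind"),
    target_arm = vapply(events, `[[`, 0, "target_arm"),
    duration_ms = vapply(events, `[[`, 0, "duration_ms"),
    span = vapply(events, `[[`, 0, "span"),
    stringsAsFactors = FALSE)
  out
}

.empty_event_log <- function()
  data.frame(time = numeric(0), end = numeric(0), kind = character(0),
             target_arm = numeric(0), duration_ms = numeric(0),
             span = numeric(0), stringsAsFactors = FALSE)

#' Simulate a surrogate LFP trace
#'
#' Theta-band oscillation amplitude-modulated by movement, a broadband noise
#' floor, and ripple bursts (200 Hz carrier, 50-100 ms Hann envelope) injected
#' at `swr_times` during stillness. Ripple amplitude is calibrated against the
#' trace's own ripple-band envelope statistics so a burst peaks at
#' `ripple_snr` SDs above the envelope mean.
#'
#' @param trajectory a `position_trace`.
#' @param config a [session_config()].
#' @param swr_times explicit ripple centers (s); defaults to placing
#'   `config$n_ripples` during feedback-phase stillness.
#' @return object of class `lfp_trace`: `t0`, `fs`, `samples` (uV), and
#'   ground-truth `ripple_intervals` (n x 2 matrix, synthetic only).
#' @export
simulate_lfp <- function(trajectory, config, swr_times = NULL) {
  .substream(config$seed, 5L)
  fs <- config$lfp_hz
  t0 <- trajectory$t[1]
  t_end <- trajectory$t[nrow(trajectory)]
  nt <- floor((t_end - t0) * fs) + 1
  tt <- t0 + (seq_len(nt) - 1) / fs

  noise_sd <- 15
  x <- stats::rnorm(nt, 0, noise_sd)
  # movement-gated theta
  sp <- stats::approx(trajectory$t, trajectory$head_speed, xout = tt, rule = 2)$y
  amp <- .ma_smooth(ifelse(sp > 4, 45, 8), round(fs / 2))
  x <- x + amp * sin(2 * pi * config$theta_freq * (tt - t0))

  if (is.null(swr_times)) swr_times <- config$swr_times
  if (is.null(swr_times) && config$n_ripples > 0) {
    fb0 <- attr(trajectory, "feedback_start")
    still_t <- trajectory$t[trajectory$t > fb0 + 2 & trajectory$head_speed < 3]
    cand <- still_t[still_t < t_end - 1]
    picked <- numeric(0)
    for (ct in sample(cand)) {
      if (all(abs(ct - picked) > 1.5)) picked <- c(picked, ct)
      if (length(picked) == config$n_ripples) break
    }
    swr_times <- sort(picked)
  }
  if (is.null(swr_times)) swr_times <- numeric(0)

  intervals <- matrix(numeric(0), 0, 2)
  if (length(swr_times) > 0) {
    spd_at <- stats::approx(trajectory$t, trajectory$head_speed,
                            xout = swr_times, rule = 2)$y
    if (any(spd_at > 4))
      warning("ripple time(s) during movement; injected anyway")
    # calibrate against the pre-injection ripple-band envelope
    env <- .band_envelope(x, fs, c(150, 250), smooth_s = 0.004)
    m <- mean(env); s <- stats::sd(env)
    A <- m + config$ripple_snr * s
    for (ct in swr_times) {
      dur <- stats::runif(1, 0.05, 0.1)
      i0 <- max(1, round((ct - dur / 2 - t0) * fs))
      i1 <- min(nt, i0 + round(dur * fs))
      k <- i0:i1
      hann <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(k))))
      x[k] <- x[k] + A * hann * sin(2 * pi * 200 * (tt[k] - tt[k[1]]))
      intervals <- rbind(intervals, c(tt[i0], tt[i1]))
    }
  }
  structure(list(t0 = t0, fs = fs, samples = x, ripple_intervals = intervals),
            class = "lfp_trace")
}

#' Generate a complete synthetic session bundle
#'
#' Runs trajectory, tuning, spiking, event injection, and LFP generation, and
#' assembles the analysis-facing session (position, spikes, lfp, sorted
#' units with exploration place maps, metadata) alongside a `ground_truth`
#' sidecar (per-spike cell identity, injected event log, ripple intervals,
#' true tuning) that no analysis function reads.
#'
#' @param config a [session_config()].
#' @return object of class `synth_session`.
#' @export
synth_session <- function(config) {
  geometry <- .gt_geometry(config)
  trajectory <- simulate_trajectory(config, geometry)
  tuning <- simulate_place_cells(config, geometry)
  spikes0 <- generate_marked_spikes(tuning, trajectory, config)
  spikes <- inject_remote_events(spikes0, trajectory, tuning,
                                 config$injected_events, config, geometry)
  lfp <- simulate_lfp(trajectory, config)

  # "sorted units": per-cell spike times plus exploration place maps,
  # emulating what an external spike sorter + standard rate-map step provides
  cell_times <- vector("list", config$n_cells)
  for (tet in seq_along(spikes$tetrodes)) {
    ct <- spikes$cells[[tet]]; ts <- spikes$tetrodes[[tet]]$times
    for (cid in unique(ct))
      cell_times[[cid]] <- sort(c(cell_times[[cid]], ts[ct == cid]))
  }
  expl <- trajectory$phase == "exploration" & trajectory$head_speed > 4
  dt <- 1 / attr(trajectory, "pos_hz")
  occ_bins <- findInterval(trajectory$linear[expl], geometry$bin_edges,
                           rightmost.closed = TRUE)
  occ <- tabulate(occ_bins, nbins = geometry$n_bins) * dt
  expl_t0 <- trajectory$t[1]; expl_t1 <- attr(trajectory, "feedback_start")
  t_lookup <- trajectory$t
  place_maps <- matrix(0, config$n_cells, geometry$n_bins)
  for (cid in seq_len(config$n_cells)) {
    st <- cell_times[[cid]]
    st <- st[st >= expl_t0 & st < expl_t1]
    if (length(st) == 0) next
    fi <- findInterval(st, t_lookup)
    ok <- expl[pmax(fi, 1)]
    sb <- findInterval(trajectory$linear[pmax(fi[ok], 1)], geometry$bin_edges,
                       rightmost.closed = TRUE)
    cnt <- tabulate(sb, nbins = geometry$n_bins)
    rate <- ifelse(occ > 0.2, cnt / pmax(occ, 1e-9), 0)
    place_maps[cid, ] <- rate
  }
  units <- list(times = cell_times, place_maps = place_maps)

  ground_truth <- list(
    spike_cells = spikes$cells,
    event_log = attr(spikes, "event_log"),
    ripple_intervals = lfp$ripple_intervals,
    tuning = tuning)
  spikes$cells <- NULL
  attr(spikes, "event_log") <- NULL
  lfp_pub <- lfp; lfp_pub$ripple_intervals <- NULL

  structure(list(
    config = config, geometry = geometry, position = trajectory,
    spikes = spikes, lfp = lfp_pub, units = units,
    metadata = list(target_arm = config$target_arm,
                    feedback_start = attr(trajectory, "feedback_start"),
                    session_end = trajectory$t[nrow(trajectory)],
                    poke_prob = config$poke_prob,
                    poke_latency = config$poke_latency),
    ground_truth = ground_truth), class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  nsp <- sum(vapply(x$spikes$tetrodes, function(tt) length(tt$times), 0))
  cat(sprintf(
    "synthetic session: %d cells / %d tetrodes, %d spikes, %.1f min exploration + %.1f min feedback\n",
    x$config$n_cells, x$config$n_tetrodes, nsp,
    x$metadata$feedback_start / 60,
    (x$metadata$session_end - x$metadata$feedback_start) / 60))
  invisible(x)
}

#' Pick event times in feedback-phase stillness near the port
#'
#' Helper for building injection schedules: returns up to `n` times during
#' feedback-phase stillness (head speed below 4 cm/s, within `max_dist` cm of
#' the port for the whole event window), separated by at least `spacing` s.
#'
#' @param trajectory a `position_trace`.
#' @param geometry track geometry.
#' @param n number of times wanted.
#' @param spacing minimum separation, s.
#' @param duration_s event duration to protect, s.
#' @param max_dist maximum port distance, cm.
#' @return numeric vector of onset times (may be shorter than `n`).
#' @export
still_event_times <- function(trajectory, geometry, n, spacing = 8,
                              duration_s = 0.15, max_dist = 10) {
  fb0 <- attr(trajectory, "feedback_start")
  d <- distance_to_center_port(cbind(trajectory$x, trajectory$y), geometry)
  ok <- trajectory$t > fb0 + 1 & trajectory$head_speed < 3.5 & d < max_dist
  # require stillness to persist over the event window
  dt <- 1 / attr(trajectory, "pos_hz")
  k <- ceiling(duration_s / dt) + 2
  okr <- ok
  for (j in seq_len(k)) okr <- okr & c(ok[-seq_len(j)], rep(FALSE, j))
  cand <- trajectory$t[okr]
  # snap onsets to the 6 ms decode grid (anchored at feedback start) so
  # injected representation blocks align with decoding bins
  cand <- fb0 + round((cand - fb0) / 0.006) * 0.006
  out <- numeric(0)
  for (ct in cand) {
    if (length(out) == 0 || ct - out[length(out)] >= spacing) out <- c(out, ct)
    if (length(out) == n) break
  }
  out
}
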