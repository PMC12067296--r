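test_that("exploration makes exactly the configured visits to each arm", {
  fx <- fix_small()
  tr <- fx$session$position
  visits <- attr(tr, "visits")
  expect_equal(sum(visits$arm == 1), fx$config$visits_per_arm)
  expect_equal(sum(visits$arm == 2), fx$config$visits_per_arm)
  # the trace actually reaches both arm ends that many times
  g <- fx$geometry
  for (a in 1:2) {
    hi <- g$box_extent + a * g$arm_length
    in_end <- tr$linear > hi - 10 & tr$linear <= hi &
      tr$segment == paste0("arm", a) & tr$phase == "exploration"
    entries <- sum(diff(c(FALSE, in_end)) == 1)
    expect_equal(entries, fx$config$visits_per_arm)
  }
})

test_that("zero feedback minutes ends the trace at exploration end", {
  g <- default_geometry()
  cfg <- session_config(seed = 2, n_cells = 8, n_tetrodes = 4,
                        exploration_minutes = 1.5, feedback_minutes = 0,
                        visits_per_arm = 2)
  tr <- simulate_trajectory(cfg, g)
  expect_true(all(tr$phase == "exploration"))
})

test_that("stored head speed matches an independent recomputation", {
  fx <- fix_small()
  tr <- fx$session$position
  dt <- 1 / attr(tr, "pos_hz")
  step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / dt
  raw <- c(step[1], step)
  # centered moving average, window 5, shrinking at the edges
  n <- length(raw); sm <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - 2):min(n, i + 2)
    sm[i] <- mean(raw[j])
  }
  expect_equal(tr$head_speed, sm, tolerance = 1e-6)
})

test_that("feedback phase keeps the animal near the port and mostly still", {
  fx <- fix_default()
  tr <- fx$session$position
  g <- fx$geometry
  fb <- tr$phase == "feedback"
  d <- distance_to_center_port(cbind(tr$x[fb], tr$y[fb]), g)
  expect_gte(mean(d < 17), 0.8)
  expect_gte(mean(tr$head_speed[fb] < 4), 0.5)
})

test_that("tuning curves peak at the configured rate with the right target share", {
  g <- default_geometry()
  cfg <- session_config(seed = 5, n_cells = 60, fraction_in_target = 0.2)
  tun <- simulate_place_cells(cfg, g)
  R <- tuning_rate(tun, g, tun$centers)
  expect_equal(unname(diag(R)), rep(cfg$peak_rate, 60), tolerance = 1e-9)
  end_lo <- g$box_extent + g$arm_length - 25
  end_hi <- g$box_extent + g$arm_length
  n_in <- sum(tun$centers >= end_lo & tun$centers < end_hi)
  expect_equal(n_in, 12)  # 0.2 * 60
})

test_that("spike generation follows the tuning (rate and mark structure)", {
  g <- default_geometry()
  cfg <- session_config(seed = 6, n_cells = 12, n_tetrodes = 4,
                        exploration_minutes = 3, feedback_minutes = 0,
                        visits_per_arm = 4, mark_cluster_sd = 0)
  tr <- simulate_trajectory(cfg, g)
  tun <- simulate_place_cells(cfg, g)
  sp <- generate_marked_spikes(tun, tr, cfg)
  # degenerate mark spread: every spike of a cell sits on its cluster mean
  for (tet in 1:4) {
    cells <- sp$cells[[tet]]
    if (!length(cells)) next
    expect_equal(sp$tetrodes[[tet]]$marks,
                 tun$mark_means[cells, , drop = FALSE],
                 ignore_attr = TRUE)
  }
  # realized total spike count close to the rate integral (Poisson 95% band)
  dt <- 1 / cfg$pos_hz
  R <- tuning_rate(tun, g, tr$linear)
  still <- tr$head_speed <= 4
  R[, still] <- R[, still] * cfg$still_rate_factor
  lambda <- sum(R * dt)
  total <- sum(vapply(sp$tetrodes, function(tt) length(tt$times), 0))
  expect_lt(abs(total - lambda), 4 * sqrt(lambda))
})

test_that("a cell whose field is never visited emits no spikes at zero baseline", {
  g <- default_geometry()
  cfg <- session_config(seed = 7, n_cells = 8, n_tetrodes = 4,
                        baseline_rate = 0)
  tun <- simulate_place_cells(cfg, g)
  tun$centers[1] <- g$total_length - 2  # far end of arm 2
  tun$sigma <- 2
  # animal sits at the port the whole time: never inside cell 1 field
  n <- 900
  tr <- data.frame(t = (seq_len(n) - 1) / 30, x = 0, y = 2,
                   head_direction = 0, linear = 2, segment = "box",
                   head_speed = 0, off_track = FALSE, phase = "exploration",
                   stringsAsFactors = FALSE)
  attr(tr, "pos_hz") <- 30
  attr(tr, "feedback_start") <- Inf
  class(tr) <- c("position_trace", "data.frame")
  sp <- generate_marked_spikes(tun, tr, cfg)
  cell1 <- sum(unlist(lapply(sp$cells, function(cc) sum(cc == 1))))
  expect_equal(cell1, 0)
})

test_that("empirical rate maps recover field locations", {
  fx <- fix_small()
  s <- fx$session; g <- fx$geometry
  tun <- s$ground_truth$tuning
  maps <- s$units$place_maps
  for (cid in seq_len(nrow(maps))) {
    n_spk <- length(s$units$times[[cid]])
    if (n_spk < 100) next
    peak_bin <- which.max(maps[cid, ])
    err <- lin_dist(g, g$bin_centers[peak_bin], tun$centers[cid])
    expect_lt(err, 2 * g$bin_size)
  }
})

test_that("identical seed and config give identical sessions", {
  cfg <- session_config(seed = 12, n_cells = 10, n_tetrodes = 4,
                        exploration_minutes = 1.5, feedback_minutes = 0.5,
                        visits_per_arm = 2, n_ripples = 2)
  s1 <- synth_session(cfg)
  s2 <- synth_session(cfg)
  expect_identical(s1$position, s2$position)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$lfp, s2$lfp)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("overlapping injected events are rejected", {
  g <- default_geometry()
  cfg <- session_config(seed = 8, n_cells = 10, n_tetrodes = 4,
                        exploration_minutes = 1.5, feedback_minutes = 1,
                        visits_per_arm = 2)
  tr <- simulate_trajectory(cfg, g)
  tun <- simulate_place_cells(cfg, g)
  sp <- generate_marked_spikes(tun, tr, cfg)
  fb0 <- attr(tr, "feedback_start")
  evs <- list(event_spec(fb0 + 5, "jump"), event_spec(fb0 + 5.05, "jump"))
  expect_error(inject_remote_events(sp, tr, tun, evs, cfg, g), "overlap")
})

test_that("jump events draw spikes from arm-end cells and log ground truth", {
  g <- default_geometry()
  cfg <- session_config(seed = 9, n_cells = 30, n_tetrodes = 4,
                        exploration_minutes = 1.5, feedback_minutes = 1,
                        visits_per_arm = 2, baseline_rate = 0)
  tr <- simulate_trajectory(cfg, g)
  tun <- simulate_place_cells(cfg, g)
  sp <- generate_marked_spikes(tun, tr, cfg)
  fb0 <- attr(tr, "feedback_start")
  ev <- event_spec(fb0 + 10, "jump", duration_ms = 120)
  out <- inject_remote_events(sp, tr, tun, list(ev), cfg, g)
  log <- attr(out, "event_log")
  expect_equal(nrow(log), 1)
  expect_equal(log$kind, "jump")
  # injected spikes come from cells whose field sits near the arm end
  end_lo <- g$box_extent + g$arm_length - 25
  for (tet in seq_along(out$tetrodes)) {
    ts <- out$tetrodes[[tet]]$times
    in_ev <- ts >= ev$time & ts < ev$time + 0.12
    cells <- out$cells[[tet]][in_ev]
    if (length(cells))
      expect_true(all(lin_dist(g, tun$centers[cells], end_lo + 12.5) < 45))
  }
})

test_that("long trajectory events sweep at least 45 cm inside the target arm", {
  ev <- event_spec(100, "long_trajectory", span = 50)
  g <- default_geometry()
  set.seed(1)
  tt <- seq(0, ev$duration_ms / 1000, by = 0.002)
  pos <- remoterep:::.event_positions(ev, tt, g)
  expect_gte(max(pos) - min(pos), 45)
  arm1 <- pos >= g$box_extent & pos < g$box_extent + g$arm_length
  expect_true(all(arm1))
})

test_that("surrogate LFP has movement theta and calibrated ripples", {
  g <- default_geometry()
  cfg <- session_config(seed = 10, n_cells = 8, n_tetrodes = 4,
                        exploration_minutes = 2, feedback_minutes = 3,
                        visits_per_arm = 3, n_ripples = 20)
  tr <- simulate_trajectory(cfg, g)
  lfp <- simulate_lfp(tr, cfg)
  expect_equal(nrow(lfp$ripple_intervals), 20)

  # spectral peak of a movement stretch within 7.5-8.5 Hz
  i0 <- tr$t[which(tr$head_speed > 10)[1]] + 1
  seg <- lfp$samples[round((i0 - lfp$t0) * lfp$fs) + seq_len(3 * lfp$fs)]
  sp <- stats::spec.pgram(ts(seg, frequency = lfp$fs), plot = FALSE,
                          spans = 5)
  peak <- sp$freq[which.max(sp$spec)]
  expect_gt(peak, 7.5); expect_lt(peak, 8.5)

  # null LFP: ripple-band envelope never reaches the 6 SD calibration level
  cfg0 <- session_config(seed = 15, n_cells = 8, n_tetrodes = 4,
                         exploration_minutes = 2, feedback_minutes = 3,
                         visits_per_arm = 3, n_ripples = 0)
  lfp0 <- simulate_lfp(simulate_trajectory(cfg0, g), cfg0)
  env <- remoterep:::.band_envelope(lfp0$samples, lfp0$fs, c(150, 250))
  expect_lt(max(env), mean(env) + 6 * sd(env))
})
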