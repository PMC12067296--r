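# Shared fixtures, built lazily and cached for the whole test run. The
# heavier sessions (full-scale decode, 50-jump detection session) are reused
# across test files to keep the suite fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

default_geometry <- function() build_track(120, 40, 5)

# small session: quick decode for unit-level checks
fix_small <- function() fixture("small", function() {
  g <- default_geometry()
  cfg <- session_config(seed = 11, n_cells = 40, n_tetrodes = 6,
                        exploration_minutes = 4, feedback_minutes = 1,
                        visits_per_arm = 5)
  s <- synth_session(cfg)
  m <- fit_encoding_model(s$spikes, s$position, g)
  d <- decode_session(s$spikes, m, g, t_start = 0,
                      t_end = s$metadata$feedback_start)
  list(geometry = g, config = cfg, session = s, model = m, decoded = d)
})

# full-scale session at the package's default configuration (15 min
# exploration, 60 cells / 8 tetrodes) with the exploration phase decoded
fix_default <- function() fixture("default", function() {
  g <- default_geometry()
  cfg <- session_config(seed = 1, feedback_minutes = 0.5)
  s <- synth_session(cfg)
  m <- fit_encoding_model(s$spikes, s$position, g)
  d <- decode_session(s$spikes, m, g, t_start = 0,
                      t_end = s$metadata$feedback_start)
  list(geometry = g, config = cfg, session = s, model = m, decoded = d)
})

# session with injected events of the given kinds (recycled over the slots
# found), feedback phase decoded
make_event_session <- function(seed, kinds, n_events, feedback_minutes,
                               exploration_minutes = 6, spacing = 9.5) {
  g <- default_geometry()
  cfg0 <- session_config(seed = seed, exploration_minutes = exploration_minutes,
                         feedback_minutes = feedback_minutes, visits_per_arm = 6)
  tr <- simulate_trajectory(cfg0, g)
  ev_t <- still_event_times(tr, g, n_events, spacing = spacing,
                            duration_s = 0.3)
  kinds <- rep_len(kinds, length(ev_t))
  evs <- mapply(function(t, k) event_spec(t, k), ev_t, kinds,
                SIMPLIFY = FALSE)
  args <- cfg0[setdiff(names(cfg0), "injected_events")]
  cfg <- do.call(session_config, modifyList(args, list(injected_events = evs)))
  s <- synth_session(cfg)
  m <- fit_encoding_model(s$spikes, s$position, g)
  d <- decode_session(s$spikes, m, g, t_start = s$metadata$feedback_start,
                      t_end = s$metadata$session_end)
  list(geometry = g, config = cfg, session = s, model = m, decoded = d)
}

# 50 injected jump events (detection-recovery conditions)
fix_jumps <- function() fixture("jumps", function()
  make_event_session(seed = 21, kinds = "jump", n_events = 50,
                     feedback_minutes = 9))

# jump-dominated mixed-kind session, matching the observed predominance of
# direct jumps among detected remote representations
fix_mixed <- function() fixture("mixed", function()
  make_event_session(seed = 22,
                     kinds = c(rep("jump", 7), "jump_arm_base",
                               rep("jump", 7), "jump_arm_base",
                               rep("jump", 7), "medium_trajectory",
                               rep("jump", 7), "long_trajectory"),
                     n_events = 40, feedback_minutes = 8))

# a synthetic tiny encoding model constructed from explicit marks/positions,
# for oracle comparisons (5 position bins, 2 tetrodes, 10 encoding spikes)
fix_tiny_model <- function() {
  g <- build_track(arm_length = 25, box_extent = 10, bin_size = 12)
  stopifnot(g$n_bins == 5)
  set.seed(77)
  occ <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  tet <- lapply(1:2, function(i) {
    marks <- matrix(runif(5 * 4, 120, 300), 5, 4)
    pos <- runif(5, 0, g$total_length)
    Dxp <- outer(seq_len(g$n_bins), seq_along(pos),
                 function(a, b) lin_dist(g, g$bin_centers[a], pos[b]))
    list(marks = marks, positions = pos, Kx = exp(-Dxp^2 / (2 * 6^2)))
  })
  model <- structure(list(
    tetrodes = tet, occupancy = occ, valid_bins = rep(TRUE, 5),
    mark_bandwidth = 20, position_bandwidth = 6, amplitude_threshold = 100,
    occupancy_floor = 1e-5, n_bins = 5), class = "encoding_model")
  list(geometry = g, model = model)
}

# independent brute-force spatial likelihood: plain double loop over
# encoding spikes and bins, written without reusing the package's kernels
brute_likelihood <- function(mark, marks, positions, occ, geometry,
                             mark_bw = 20, pos_bw = 6) {
  nb <- geometry$n_bins
  l <- numeric(nb)
  for (b in seq_len(nb)) {
    acc <- 0
    for (i in seq_along(positions)) {
      km <- exp(-sum((mark - marks[i, ])^2) / (2 * mark_bw^2))
      dx <- lin_dist(geometry, geometry$bin_centers[b], positions[i])
      acc <- acc + km * exp(-dx^2 / (2 * pos_bw^2))
    }
    l[b] <- acc / occ[b]
  }
  l / sum(l)
}

# wrapped-normal circular sample (approximates a von Mises with
# concentration kappa ~ 1/sd^2), for circular-statistics power checks
rwrapped <- function(n, mu = 0, sd = 1) (rnorm(n, mu, sd)) %% (2 * pi)
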