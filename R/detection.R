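#' Closed-loop detection criteria
#'
#' The trigger conditions of the remote-representation neurofeedback: on the
#' 30 ms running average of the decoded posterior, strictly more than 40% of
#' the mass in the distal 25 cm of the target arm, strictly less than 20% in
#' the opposite arm and in the box, at least `min_specific_tetrodes` tetrodes
#' contributing a spatially specific spike within the 30 ms window, and the
#' animal strictly within 17 cm of the center port. All inequalities are
#' strict, matching the printed thresholds. One rat in the study required
#' only a single specific tetrode; that is the `min_specific_tetrodes`
#' override.
#'
#' @param target_arm arm whose distal 25 cm is the target region.
#' @param p_target_min minimum posterior mass in the target arm end.
#' @param p_opposite_max maximum mass in the opposite (whole) arm.
#' @param p_box_max maximum mass in the box.
#' @param min_specific_tetrodes minimum tetrodes with a spatially specific
#'   spike in the window.
#' @param max_port_distance maximum physical distance to the port, cm.
#' @param lockout suppression period after each tone, s.
#' @param nosepoke_window time allowed to poke for reward, s.
#' @param max_rewards session ends after this many rewards.
#' @param max_duration_min session ends after this many feedback minutes.
#' @param specificity_factor max-to-uniform ratio defining spatial
#'   specificity.
#' @export
detection_criteria <- function(target_arm = 1, p_target_min = 0.40,
                               p_opposite_max = 0.20, p_box_max = 0.20,
                               min_specific_tetrodes = 2,
                               max_port_distance = 17, lockout = 5,
                               nosepoke_window = 3, max_rewards = 75,
                               max_duration_min = 30,
                               specificity_factor = 3) {
  stopifnot(p_target_min > p_opposite_max,
            p_target_min >= 0, p_target_min <= 1)
  structure(as.list(environment()), class = "detection_criteria")
}

#' Is a spike's spatial likelihood spatially specific?
#'
#' A spike is spatially specific when the peak of its normalized likelihood
#' exceeds `factor` times the uniform level `1/n_bins`; flat (noise-like)
#' likelihoods fail.
#'
#' @param likelihood normalized probability vector over bins.
#' @param factor max-to-uniform threshold.
#' @return logical.
#' @export
spatial_specificity <- function(likelihood, factor = 3) {
  max(likelihood) > factor / length(likelihood)
}

#' Evaluate the remote-representation criteria on one averaged window
#'
#' @param avg_posterior normalized 30 ms averaged posterior (vector over bins).
#' @param n_specific_tetrodes tetrodes with a spatially specific spike in the
#'   window.
#' @param port_distance animal distance to the center port, cm.
#' @param geometry a `track_geometry`.
#' @param criteria a [detection_criteria()].
#' @return list `ok` (logical) and `snapshot` (the four mass fractions,
#'   tetrode count and distance the decision was based on).
#' @export
evaluate_remote_criteria <- function(avg_posterior, n_specific_tetrodes,
                                     port_distance, geometry, criteria) {
  arm <- criteria$target_arm
  opp <- 3 - arm
  m_target <- sum(avg_posterior[region_mask(geometry, "target_end", arm)])
  m_opp <- sum(avg_posterior[region_mask(geometry, "arm", opp)])
  m_box <- sum(avg_posterior[region_mask(geometry, "box")])
  ok <- m_target > criteria$p_target_min &&
    m_opp < criteria$p_opposite_max &&
    m_box < criteria$p_box_max &&
    n_specific_tetrodes >= criteria$min_specific_tetrodes &&
    port_distance < criteria$max_port_distance
  list(ok = ok,
       snapshot = list(mass_target = m_target, mass_opposite = m_opp,
                       mass_box = m_box,
                       n_tetrodes = n_specific_tetrodes,
                       port_distance = port_distance))
}

# vectorized criteria over all eligible averaged bins; returns logical vector
.criteria_vector <- function(avg, port_dist, geometry, criteria) {
  arm <- criteria$target_arm
  mt <- as.numeric(avg$avg %*% region_mask(geometry, "target_end", arm))
  mo <- as.numeric(avg$avg %*% region_mask(geometry, "arm", 3 - arm))
  mb <- as.numeric(avg$avg %*% region_mask(geometry, "box"))
  ok <- avg$eligible &
    mt > criteria$p_target_min & mo < criteria$p_opposite_max &
    mb < criteria$p_box_max &
    avg$window_tet_count >= criteria$min_specific_tetrodes &
    port_dist < criteria$max_port_distance
  list(ok = ok, mass_target = mt, mass_opposite = mo, mass_box = mb)
}

.resolve_poke <- function(t_det, nosepokes, poke_policy, window) {
  if (!is.null(nosepokes)) {
    lat <- nosepokes[nosepokes > t_det] - t_det
    lat <- lat[lat < window]
    if (length(lat)) return(list(rewarded = TRUE, latency = min(lat)))
    return(list(rewarded = FALSE, latency = NA_real_))
  }
  if (stats::runif(1) < poke_policy$prob) {
    lat <- stats::runif(1, poke_policy$latency[1], poke_policy$latency[2])
    if (lat < window) return(list(rewarded = TRUE, latency = lat))
  }
  list(rewarded = FALSE, latency = NA_real_)
}

#' Scan a decoded session for remote-representation detections
#'
#' Scans averaged-posterior bins (feedback phase) in time order. The first
#' eligible bin satisfying all criteria emits a tone event; a lockout then
#' suppresses re-triggering. An event is rewarded when a nosepoke occurs
#' within the nosepoke window (observed `nosepokes` times, or a simulated
#' poke policy). The scan ends at `max_duration_min` of feedback or at
#' `max_rewards` rewards, whichever comes first.
#'
#' @param posterior a `decoded_posterior` (averaged internally) or an
#'   `avg_posterior`.
#' @param trajectory a `position_trace`.
#' @param geometry a `track_geometry`.
#' @param criteria a [detection_criteria()].
#' @param nosepokes observed nosepoke times (s), or `NULL` to simulate.
#' @param poke_policy list `prob`, `latency` (range, s) for simulation.
#' @param poke_seed RNG seed for the simulated poke responses (keeps event
#'   lists deterministic for identical inputs).
#' @return data.frame of class `detection_events`: time, kind, the criteria
#'   snapshot, rewarded flag and nosepoke latency.
#' @export
detect_events <- function(posterior, trajectory, geometry, criteria,
                          nosepokes = NULL,
                          poke_policy = list(prob = 0.95, latency = c(0.2, 1)),
                          poke_seed = 1L) {
  avg <- if (inherits(posterior, "decoded_posterior"))
    running_average_posterior(posterior) else posterior
  fi <- pmax(findInterval(avg$t, trajectory$t), 1)
  port_dist <- distance_to_center_port(
    cbind(trajectory$x[fi], trajectory$y[fi]), geometry)
  fb0 <- attr(trajectory, "feedback_start")
  cv <- .criteria_vector(avg, port_dist, geometry, criteria)
  in_fb <- avg$t >= fb0 & avg$t < fb0 + criteria$max_duration_min * 60
  qual <- which(cv$ok & in_fb)

  set.seed(poke_seed)
  out <- list(); last_t <- -Inf; rewards <- 0L
  for (i in qual) {
    tt <- avg$t[i]
    if (tt - last_t < criteria$lockout) next
    pk <- .resolve_poke(tt, nosepokes, poke_policy, criteria$nosepoke_window)
    out[[length(out) + 1]] <- data.frame(
      time = tt, bin = i, kind = "remote_rep",
      mass_target = cv$mass_target[i], mass_opposite = cv$mass_opposite[i],
      mass_box = cv$mass_box[i], n_tetrodes = avg$window_tet_count[i],
      port_distance = port_dist[i],
      rewarded = pk$rewarded, latency = pk$latency,
      stringsAsFactors = FALSE)
    last_t <- tt
    if (pk$rewarded) rewards <- rewards + 1L
    if (rewards >= criteria$max_rewards) break
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(time = numeric(0), bin = integer(0), kind = character(0),
               mass_target = numeric(0), mass_opposite = numeric(0),
               mass_box = numeric(0), n_tetrodes = numeric(0),
               port_distance = numeric(0), rewarded = logical(0),
               latency = numeric(0), stringsAsFactors = FALSE)
  attr(ev, "rewards") <- rewards
  class(ev) <- c("detection_events", "data.frame")
  ev
}

#' Re-evaluate every emitted event against its criteria snapshot
#'
#' Audit: each event's stored mass fractions, tetrode count and distance must
#' themselves satisfy the criteria. Returns TRUE only if all do.
#'
#' @param events a `detection_events`.
#' @param criteria the [detection_criteria()] used.
#' @return logical vector, one per event.
#' @export
audit_events <- function(events, criteria) {
  if (nrow(events) == 0) return(logical(0))
  events$mass_target > criteria$p_target_min &
    events$mass_opposite < criteria$p_opposite_max &
    events$mass_box < criteria$p_box_max &
    events$n_tetrodes >= criteria$min_specific_tetrodes &
    events$port_distance < criteria$max_port_distance
}

#' Angular tolerance ramp for head-direction feedback
#'
#' Tolerance tightens linearly from +/-20 degrees at reward 0 to +/-3 degrees
#' at reward 25, and stays at 3 degrees thereafter.
#'
#' @param n_rewards rewards received so far in the session.
#' @return tolerance in degrees.
#' @export
hd_tolerance <- function(n_rewards) {
  pmax(20 - pmin(n_rewards, 25) * 17 / 25, 3)
}

#' Head-direction feedback control condition
#'
#' An event fires when the head angle is within the current tolerance of the
#' target direction (30 degrees left of forward for arm 1, 30 degrees right
#' for arm 2) while the animal is within 17 cm of the port. The tolerance
#' tightens with reward count ([hd_tolerance()]); lockout, nosepoke and
#' session-limit logic match the remote-representation detector.
#'
#' @param trajectory a `position_trace` with `head_direction` (radians,
#'   0 = forward, positive = left).
#' @param geometry a `track_geometry`.
#' @param criteria a [detection_criteria()] (`target_arm` selects the side).
#' @param nosepokes,poke_policy,poke_seed as in [detect_events()].
#' @return a `detection_events` data.frame with head-angle snapshots.
#' @export
head_direction_feedback <- function(trajectory, geometry, criteria,
                                    nosepokes = NULL,
                                    poke_policy = list(prob = 0.95,
                                                       latency = c(0.2, 1)),
                                    poke_seed = 1L) {
  fb0 <- attr(trajectory, "feedback_start")
  target_deg <- if (criteria$target_arm == 1) 30 else -30
  sel <- which(trajectory$t >= fb0 &
                 trajectory$t < fb0 + criteria$max_duration_min * 60)
  hd_deg <- trajectory$head_direction[sel] * 180 / pi
  err <- abs(((hd_deg - target_deg + 180) %% 360) - 180)
  pd <- distance_to_center_port(cbind(trajectory$x[sel], trajectory$y[sel]),
                                geometry)
  set.seed(poke_seed)
  out <- list(); last_t <- -Inf; rewards <- 0L
  for (j in seq_along(sel)) {
    tol <- hd_tolerance(rewards)
    if (!(err[j] < tol && pd[j] < criteria$max_port_distance)) next
    tt <- trajectory$t[sel[j]]
    if (tt - last_t < criteria$lockout) next
    pk <- .resolve_poke(tt, nosepokes, poke_policy, criteria$nosepoke_window)
    out[[length(out) + 1]] <- data.frame(
      time = tt, kind = "head_direction", head_error_deg = err[j],
      tolerance_deg = tol, port_distance = pd[j],
      rewarded = pk$rewarded, latency = pk$latency, stringsAsFactors = FALSE)
    last_t <- tt
    if (pk$rewarded) rewards <- rewards + 1L
    if (rewards >= criteria$max_rewards) break
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(time = numeric(0), kind = character(0),
               head_error_deg = numeric(0), tolerance_deg = numeric(0),
               port_distance = numeric(0), rewarded = logical(0),
               latency = numeric(0), stringsAsFactors = FALSE)
  attr(ev, "rewards") <- rewards
  class(ev) <- c("detection_events", "data.frame")
  ev
}
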