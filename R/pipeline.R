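#' Analyse a session bundle
#'
#' Runs the full analysis chain on a session: encoding-model fit on the
#' exploration phase, 6 ms clusterless decoding of both phases, inclusion
#' quality and decoding error, remote-representation detection on the 30 ms
#' running average, event classification, target and control prevalence
#' (with and without tone excision), SWR detection and brain-state
#' composition, theta phase of detections, and PCA/ICA assembly analysis
#' with activation ratios. Only the analysis-facing components of the bundle
#' are read; the ground-truth sidecar is never touched.
#'
#' @param session a `synth_session` (or equivalent list).
#' @param criteria optional [detection_criteria()]; defaults to the session's
#'   target arm with standard thresholds.
#' @param decode_exploration set FALSE to skip the exploration decode (saves
#'   time when only feedback-phase results are needed).
#' @return list of class `session_analysis`.
#' @export
analyze_session <- function(session, criteria = NULL,
                            decode_exploration = TRUE) {
  session$ground_truth <- NULL  # structural leak-proofing
  geometry <- session$geometry
  traj <- session$position
  fb0 <- session$metadata$feedback_start
  t_end <- session$metadata$session_end
  arm <- session$metadata$target_arm
  seed <- session$config$seed
  if (is.null(criteria)) criteria <- detection_criteria(target_arm = arm)

  model <- fit_encoding_model(session$spikes, traj, geometry)

  quality <- NULL; med_err <- NULL; n_expl <- NULL
  if (decode_exploration) {
    dec_e <- decode_session(session$spikes, model, geometry,
                            t_start = traj$t[1], t_end = fb0)
    med_err <- decoding_error(dec_e, traj, geometry)
    n_expl <- sum(dec_e$informative)
    quality <- tryCatch(decoding_quality(dec_e, traj, geometry, arm),
                        error = function(e) NULL)
  }

  dec_f <- decode_session(session$spikes, model, geometry,
                          t_start = fb0, t_end = t_end)
  avg <- running_average_posterior(dec_f)
  events <- detect_events(avg, traj, geometry, criteria,
                          poke_policy = list(prob = session$metadata$poke_prob,
                                             latency = session$metadata$poke_latency),
                          poke_seed = seed + 11L)
  classified <- classify_events(events, dec_f, traj, geometry, arm)

  excl <- tone_exclusion_windows(events)
  prev <- function(region, a, ex) tryCatch(
    region_prevalence(dec_f, traj, geometry, region, a, exclude_windows = ex),
    error = function(e) NULL)
  prevalence <- list(
    target = prev("target_end", arm, NULL),
    target_excised = prev("target_end", arm, excl),
    control_base = prev("arm_base", arm, NULL),
    control_base_excised = prev("arm_base", arm, excl))

  swr <- tryCatch(detect_swr(session$lfp), error = function(e) NULL)
  states <- label_states(traj, swr, dec_f$t)
  fi <- pmax(findInterval(dec_f$t, traj$t), 1)
  pd <- distance_to_center_port(cbind(traj$x[fi], traj$y[fi]), geometry)
  end_mass <- as.numeric(dec_f$posterior %*% region_mask(geometry, "target_end", arm))
  eligible <- dec_f$informative & pd < criteria$max_port_distance
  in_tone <- rep(FALSE, length(dec_f$t))
  if (nrow(excl) > 0)
    for (k in seq_len(nrow(excl)))
      in_tone <- in_tone | (dec_f$t >= excl[k, 1] & dec_f$t <= excl[k, 2])
  remote_bins <- which(eligible & end_mass > 0.4 & !in_tone)
  composition <- NULL
  if (length(remote_bins) >= 20 && sum(eligible) >= 20) {
    set.seed(seed + 17L)
    rnd <- sample(which(eligible), min(length(remote_bins) * 2, sum(eligible)))
    composition <- tryCatch(
      state_composition(list(remote = states[remote_bins],
                             random = states[rnd])),
      error = function(e) NULL)
  }

  theta <- NULL
  if (nrow(events) >= 10) {
    ph <- theta_phase_at(events$time, session$lfp)
    theta <- c(rayleigh_test(ph), list(phases = ph))
  }

  # cell assemblies over the whole session
  assemblies <- NULL
  Z <- tryCatch(suppressWarnings(
    bin_and_zscore(session$units$times, epoch = c(traj$t[1], t_end))),
    error = function(e) NULL)
  if (!is.null(Z)) {
    amod <- detect_assemblies(Z, seed = seed + 13L)
    kept <- attr(Z, "kept")
    labels <- label_assemblies(amod, session$units$place_maps[kept, , drop = FALSE],
                               geometry, arm)
    ratios <- NULL
    if (amod$n_significant > 0 && nrow(events) >= 10) {
      zt <- attr(Z, "t")
      zfi <- pmax(findInterval(zt, traj$t), 1)
      zpd <- distance_to_center_port(cbind(traj$x[zfi], traj$y[zfi]), geometry)
      zelig <- zt >= fb0 & zpd < criteria$max_port_distance
      S <- assembly_strength(amod$weights, Z)
      if (is.null(dim(S))) S <- matrix(S, 1)
      ratios <- lapply(seq_len(amod$n_significant), function(j)
        activation_ratio(S[j, ], zt, events$time, zelig, seed = seed + 19L + j))
    }
    assemblies <- list(model = amod, labels = labels, ratios = ratios)
  }

  structure(list(
    criteria = criteria, encoding = model,
    decoding = list(median_error_cm = med_err, quality = quality,
                    n_informative_bins = n_expl),
    decoded_feedback = dec_f, averaged = avg,
    events = events, classified = classified,
    prevalence = prevalence, swr = swr, states = states,
    composition = composition, theta = theta, assemblies = assemblies),
    class = "session_analysis")
}

#' Fraction of injected events recovered by the detector
#'
#' An injected event counts as recovered when at least one detection falls
#' within its window extended by `tol` seconds.
#'
#' @param events a `detection_events`.
#' @param event_log ground-truth log (columns `time`, `end`).
#' @param tol slack after the event window, s.
#' @return recall in `[0, 1]`.
#' @export
detection_recall <- function(events, event_log, tol = 0.12) {
  if (nrow(event_log) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(event_log)), function(k)
    any(events$time >= event_log$time[k] - 0.03 &
          events$time <= event_log$end[k] + tol), FALSE)
  mean(hit)
}

#' Category agreement between detections and injected events
#'
#' Each detection is matched to the injected event whose window (with slack)
#' contains it; the fraction of matched detections whose classified category
#' equals the injected kind is returned, overall and per kind.
#'
#' @param classified output of [classify_events()].
#' @param event_log ground-truth log.
#' @param tol slack after the event window, s.
#' @return list `overall`, `by_kind`, `n_matched`.
#' @export
classification_recovery <- function(classified, event_log, tol = 0.12) {
  if (nrow(classified) == 0 || nrow(event_log) == 0)
    return(list(overall = NA_real_, by_kind = NULL, n_matched = 0L))
  match_kind <- rep(NA_character_, nrow(classified))
  for (i in seq_len(nrow(classified))) {
    k <- which(classified$time[i] >= event_log$time - 0.03 &
                 classified$time[i] <= event_log$end + tol)
    if (length(k)) match_kind[i] <- event_log$kind[k[1]]
  }
  ok <- !is.na(match_kind)
  agree <- classified$category[ok] == match_kind[ok]
  by_kind <- tapply(agree, match_kind[ok], mean)
  list(overall = mean(agree), by_kind = by_kind, n_matched = sum(ok))
}

#' Run the full pipeline on a synthetic configuration
#'
#' Generates the session, analyses it ([analyze_session()]), evaluates the
#' result against the generator's ground truth (detection recall and
#' classification recovery; evaluation only, after all analysis stages), and
#' optionally writes a summary JSON plus CSV tables. Identical config and
#' seed produce byte-identical summaries.
#'
#' @param config a [session_config()].
#' @param out_dir output directory, or NULL to skip writing.
#' @param criteria optional [detection_criteria()].
#' @param decode_exploration passed through to [analyze_session()].
#' @return list `session`, `analysis`, `summary` (invisible).
#' @export
run_pipeline <- function(config, out_dir = NULL, criteria = NULL,
                         decode_exploration = TRUE) {
  session <- synth_session(config)
  public <- session
  public$ground_truth <- NULL
  analysis <- analyze_session(public, criteria,
                              decode_exploration = decode_exploration)

  gt <- session$ground_truth
  evaluation <- list(
    detection_recall = detection_recall(analysis$events, gt$event_log),
    classification = classification_recovery(analysis$classified, gt$event_log))

  pv <- function(p) if (is.null(p)) NULL else p$prevalence
  summary <- list(
    seed = config$seed,
    n_cells = config$n_cells, n_tetrodes = config$n_tetrodes,
    target_arm = config$target_arm,
    exploration_minutes = config$exploration_minutes,
    feedback_minutes = config$feedback_minutes,
    median_decode_error_cm = analysis$decoding$median_error_cm,
    inclusion_fraction = if (!is.null(analysis$decoding$quality))
      analysis$decoding$quality$fraction else NULL,
    session_included = if (!is.null(analysis$decoding$quality))
      analysis$decoding$quality$included else NULL,
    n_events = nrow(analysis$events),
    n_rewards = attr(analysis$events, "rewards"),
    category_fractions = as.list(category_fractions(analysis$classified)),
    prevalence_target = pv(analysis$prevalence$target),
    prevalence_target_excised = pv(analysis$prevalence$target_excised),
    prevalence_control_base = pv(analysis$prevalence$control_base),
    n_swr = if (is.null(analysis$swr)) 0L else nrow(analysis$swr),
    n_assemblies = if (is.null(analysis$assemblies)) 0L else
      analysis$assemblies$model$n_significant,
    detection_recall = evaluation$detection_recall,
    classification_recovery = evaluation$classification$overall)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    utils::write.csv(analysis$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$classified,
                     file.path(out_dir, "classified_events.csv"),
                     row.names = FALSE)
  }
  invisible(list(session = session, analysis = analysis,
                 evaluation = evaluation, summary = summary))
}

#' Names of the session bundle validation checks
#'
#' The documented schema: one entry per check performed by
#' [validate_session()] on a bare session (a decoded posterior adds one
#' normalization check).
#' @export
validation_checks <- function() c(
  "components_present", "position_monotone", "spikes_sorted",
  "marks_finite", "lfp_uniform", "speed_nonnegative",
  "region_masks_consistent", "feedback_start_in_range")

#' Validate a session bundle
#'
#' Structural checks on a session: required components, monotone position
#' timestamps, sorted spike times, finite marks, uniform LFP sampling,
#' non-negative speeds, region-mask consistency, and a feedback start inside
#' the recorded range. When a decoded posterior is supplied its informative
#' rows must be normalized to 1 within 1e-9.
#'
#' @param session a session bundle.
#' @param decoded optional `decoded_posterior`.
#' @return data.frame `check`, `pass`.
#' @export
validate_session <- function(session, decoded = NULL) {
  checks <- validation_checks()
  pass <- logical(length(checks))
  names(pass) <- checks
  comp <- c("geometry", "position", "spikes", "lfp", "units", "metadata")
  pass["components_present"] <- all(comp %in% names(session))
  pass["position_monotone"] <- !is.unsorted(session$position$t, strictly = TRUE)
  pass["spikes_sorted"] <- all(vapply(session$spikes$tetrodes, function(tt)
    !is.unsorted(tt$times), TRUE))
  pass["marks_finite"] <- all(vapply(session$spikes$tetrodes, function(tt)
    all(is.finite(tt$marks)), TRUE))
  pass["lfp_uniform"] <- is.numeric(session$lfp$fs) && session$lfp$fs > 0 &&
    all(is.finite(session$lfp$samples))
  pass["speed_nonnegative"] <- all(session$position$head_speed >= 0)
  pass["region_masks_consistent"] <- tryCatch({
    g <- session$geometry
    all(g$region_masks$box | g$region_masks$arm1 | g$region_masks$arm2) &&
      !any(g$region_masks$target_end_arm1 & !g$region_masks$arm1)
  }, error = function(e) FALSE)
  pass["feedback_start_in_range"] <-
    session$metadata$feedback_start > session$position$t[1] &&
    session$metadata$feedback_start <= session$metadata$session_end + 1
  out <- data.frame(check = checks, pass = unname(pass),
                    stringsAsFactors = FALSE)
  if (!is.null(decoded)) {
    sums <- rowSums(decoded$posterior[decoded$informative, , drop = FALSE])
    out <- rbind(out, data.frame(check = "posterior_normalized",
                                 pass = all(abs(sums - 1) < 1e-9),
                                 stringsAsFactors = FALSE))
  }
  out
}
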