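# ordinary least squares from the normal equations; shared by event
# classification and the longitudinal trend statistics
.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(list(slope = 0, intercept = my, p = 1, fitted = rep(my, n)))
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  rss <- sum((y - fitted)^2)
  if (n <= 2 || rss <= 0) {
    p <- if (slope == 0) 1 else 0
    return(list(slope = slope, intercept = intercept, p = p, fitted = fitted))
  }
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       p = 2 * stats::pt(-abs(tval), n - 2), fitted = fitted)
}

#' Classify a detected remote representation
#'
#' A detected event (its 6 ms posterior bins, the detection bin plus 90 ms
#' before it) is assigned to exactly one category, tested in precedence
#' order: long trajectory (significant linear regression of the
#' posterior-mass-weighted mean target-arm position against time, fitted
#' values covering at least 45 cm of the arm), medium trajectory (same with
#' at least 35 cm), jump-and-arm-base (detection-window mass above 0.4 in the
#' distal 25 cm and mass above 0.2 in the 15 cm arm-base region in some
#' pre-detection bin), jump (end mass above 0.4 alone), else other.
#' Trajectory tests come first because a full sweep also satisfies the jump
#' mass criterion.
#'
#' @param segment n x n_bins matrix of 6 ms posteriors ending at the
#'   detection bin; at least 16 rows (15 pre-detection + detection).
#' @param geometry a `track_geometry`.
#' @param target_arm arm index.
#' @param informative logical per segment row (defaults to all).
#' @param arm_mass_min minimum target-arm mass for a bin to enter the
#'   regression.
#' @param alpha significance level for the regression slope.
#' @param base_mass_min arm-base mass defining the jump-and-arm-base variant.
#' @param window_bins bins forming the detection window for the jump mass.
#' @return list of class `classified_event`: `category`, regression `slope`,
#'   `p`, `coverage` (cm), `jump_mass`, `base_mass_max`.
#' @export
classify_event <- function(segment, geometry, target_arm,
                           informative = rep(TRUE, nrow(segment)),
                           arm_mass_min = 0.2, alpha = 0.05,
                           base_mass_min = 0.2, window_bins = 5) {
  if (nrow(segment) < 16)
    stop("segment too short: need the detection bin plus 90 ms (16 bins)")
  arm_mask <- region_mask(geometry, "arm", target_arm)
  end_mask <- region_mask(geometry, "target_end", target_arm)
  base15 <- region_mask(geometry, "arm_base15", target_arm)

  n <- nrow(segment)
  m_arm <- as.numeric(segment %*% arm_mask)
  m_end <- as.numeric(segment %*% end_mask)
  m_base <- as.numeric(segment %*% base15)

  det_win <- (n - window_bins + 1):n
  dw_inf <- det_win[informative[det_win]]
  jump_mass <- if (length(dw_inf)) mean(m_end[dw_inf]) else 0
  pre <- seq_len(n - 1)
  base_mass_max <- if (any(informative[pre])) max(m_base[pre][informative[pre]]) else 0

  # trajectory test: mass-weighted mean arm position vs time
  qual <- which(informative & m_arm >= arm_mass_min)
  slope <- NA_real_; pval <- NA_real_; coverage <- 0
  if (length(qual) >= 3) {
    centers <- geometry$bin_centers
    wpos <- as.numeric((segment[qual, , drop = FALSE] %*%
                          (centers * arm_mask))) / m_arm[qual]
    fit <- .ols(qual * 0.006, wpos)
    slope <- fit$slope; pval <- fit$p
    coverage <- max(fit$fitted) - min(fit$fitted)
  }
  is_traj <- length(qual) >= 3 && !is.na(pval) && pval < alpha
  category <- if (is_traj && coverage >= 45) "long_trajectory"
  else if (is_traj && coverage >= 35) "medium_trajectory"
  else if (jump_mass > 0.4 && base_mass_max > base_mass_min) "jump_arm_base"
  else if (jump_mass > 0.4) "jump"
  else "other"

  structure(list(category = category, slope = slope, p = pval,
                 coverage = coverage, jump_mass = jump_mass,
                 base_mass_max = base_mass_max),
            class = "classified_event")
}

#' Jump distance of a detected event
#'
#' Skeleton distance between the animal's linearized position at detection
#' and the represented position: the mass-weighted mode (argmax bin center)
#' of the first segment bin whose target-arm-end mass exceeds 0.4.
#'
#' @param segment the event's posterior segment (as in [classify_event()]).
#' @param animal_linear the animal's linear position at detection, cm.
#' @param geometry a `track_geometry`.
#' @param target_arm arm index.
#' @return distance in cm (NA when no bin qualifies).
#' @export
jump_distance <- function(segment, animal_linear, geometry, target_arm) {
  end_mask <- region_mask(geometry, "target_end", target_arm)
  m_end <- as.numeric(segment %*% end_mask)
  k <- which(m_end > 0.4)[1]
  if (is.na(k)) return(NA_real_)
  mode_bin <- which.max(segment[k, ])
  lin_dist(geometry, geometry$bin_centers[mode_bin], animal_linear)
}

#' Peripheral-region flags for a detected event
#'
#' Whether any segment bin places more than `threshold` mass in the first
#' 5 cm of the target arm (the arm base visible from the box) or in the last
#' 5 cm (the exact reward-port location).
#'
#' @param segment posterior segment matrix.
#' @param geometry a `track_geometry`.
#' @param target_arm arm index.
#' @param threshold mass threshold.
#' @param informative logical per row.
#' @return list `visual_field_flag`, `reward_port_flag`.
#' @export
peripheral_flags <- function(segment, geometry, target_arm, threshold = 0.2,
                             informative = rep(TRUE, nrow(segment))) {
  vf <- region_mask(geometry, "visual_field", target_arm)
  rp <- region_mask(geometry, "reward_port", target_arm)
  mv <- as.numeric(segment %*% vf)[informative]
  mr <- as.numeric(segment %*% rp)[informative]
  list(visual_field_flag = any(mv > threshold),
       reward_port_flag = any(mr > threshold))
}

#' Classify all detections of a session
#'
#' Extracts, for each detection, the 6 ms posterior segment covering the
#' detection bin plus the 90 ms before it, and applies [classify_event()],
#' [jump_distance()] and [peripheral_flags()].
#'
#' @param events a `detection_events` from [detect_events()].
#' @param decoded the session's `decoded_posterior` (6 ms bins).
#' @param trajectory a `position_trace`.
#' @param geometry a `track_geometry`.
#' @param target_arm arm index.
#' @param pre_bins pre-detection bins to include (15 = 90 ms).
#' @param ... passed to [classify_event()].
#' @return data.frame: one row per event with category, regression stats,
#'   jump distance and peripheral flags.
#' @export
classify_events <- function(events, decoded, trajectory, geometry, target_arm,
                            pre_bins = 15, ...) {
  if (nrow(events) == 0)
    return(data.frame(time = numeric(0), category = character(0),
                      slope = numeric(0), p = numeric(0),
                      coverage = numeric(0), jump_distance = numeric(0),
                      visual_field_flag = logical(0),
                      reward_port_flag = logical(0), stringsAsFactors = FALSE))
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    bi <- findInterval(events$time[i], decoded$t + decoded$bin_width / 2) + 1L
    bi <- min(max(bi, pre_bins + 1L), length(decoded$t))
    idx <- (bi - pre_bins):bi
    seg <- decoded$posterior[idx, , drop = FALSE]
    inf <- decoded$informative[idx]
    cl <- classify_event(seg, geometry, target_arm, informative = inf, ...)
    fl <- peripheral_flags(seg, geometry, target_arm, informative = inf)
    fj <- pmax(findInterval(events$time[i], trajectory$t), 1)
    jd <- jump_distance(seg, trajectory$linear[fj], geometry, target_arm)
    out[[i]] <- data.frame(time = events$time[i], category = cl$category,
                           slope = cl$slope, p = cl$p, coverage = cl$coverage,
                           jump_distance = jd,
                           visual_field_flag = fl$visual_field_flag,
                           reward_port_flag = fl$reward_port_flag,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Category frequency summary
#'
#' @param classified output of [classify_events()].
#' @return named numeric vector of category fractions (sums to 1).
#' @export
category_fractions <- function(classified) {
  lev <- c("jump", "jump_arm_base", "medium_trajectory", "long_trajectory",
           "other")
  tab <- table(factor(classified$category, levels = lev))
  f <- as.numeric(tab) / max(1, nrow(classified))
  names(f) <- lev
  f
}
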