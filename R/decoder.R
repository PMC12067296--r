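#' Fit the clusterless marked point-process encoding model
#'
#' The encoding model stores, per tetrode, every above-threshold spike's 4D
#' amplitude mark paired with the animal's linearized position at spike time,
#' restricted to the exploration phase during movement (head speed above
#' 4 cm/s). Occupancy is the speed-filtered position histogram, smoothed with
#' a Gaussian kernel over skeleton distance and normalized to sum 1. Decoding
#' divides by occupancy, floored at `occupancy_floor` of total mass; bins
#' below the floor receive zero likelihood.
#'
#' @param spikes a `marked_spikes`.
#' @param trajectory a `position_trace` (its exploration phase is used).
#' @param geometry a `track_geometry`.
#' @param mark_bandwidth Gaussian kernel bandwidth in mark space, uV.
#' @param position_bandwidth Gaussian kernel bandwidth over skeleton
#'   distance, cm (also used to smooth occupancy).
#' @param amplitude_threshold spikes must exceed this on at least one
#'   channel, uV.
#' @param min_spikes tetrodes with fewer encoding spikes are excluded with a
#'   warning.
#' @param occupancy_floor occupancy floor as a fraction of total mass.
#' @return object of class `encoding_model`.
#' @export
fit_encoding_model <- function(spikes, trajectory, geometry,
                               mark_bandwidth = 20, position_bandwidth = 6,
                               amplitude_threshold = 100, min_spikes = 50,
                               occupancy_floor = 1e-5) {
  fb0 <- attr(trajectory, "feedback_start")
  if (is.null(fb0)) fb0 <- Inf
  moving <- trajectory$head_speed > 4
  expl <- trajectory$t < fb0

  # occupancy from speed-filtered exploration positions
  sel <- expl & moving
  occ_hist <- tabulate(findInterval(trajectory$linear[sel], geometry$bin_edges,
                                    rightmost.closed = TRUE),
                       nbins = geometry$n_bins)
  Dbb <- .lin_dist_matrix(geometry, geometry$bin_centers, geometry$bin_centers)
  Kbb <- exp(-Dbb^2 / (2 * position_bandwidth^2))
  # normalized kernel smoothing (avoids attenuating occupancy at track ends,
  # which would inflate 1/occupancy likelihoods there)
  occ <- as.numeric(Kbb %*% occ_hist) / rowSums(Kbb)
  occ <- occ / sum(occ)
  valid_bins <- occ >= occupancy_floor

  tet <- vector("list", length(spikes$tetrodes))
  for (i in seq_along(spikes$tetrodes)) {
    ts <- spikes$tetrodes[[i]]$times
    mk <- spikes$tetrodes[[i]]$marks
    keep <- ts < fb0 & apply(mk, 1, max) > amplitude_threshold
    # movement filter: spike falls in a moving frame
    fi <- pmax(findInterval(ts, trajectory$t), 1)
    keep <- keep & moving[fi] & expl[fi]
    if (sum(keep) < min_spikes) {
      warning("tetrode ", i, " excluded: only ", sum(keep), " encoding spikes")
      tet[[i]] <- NULL
      next
    }
    pos <- trajectory$linear[fi[keep]]
    Dxp <- .lin_dist_matrix(geometry, geometry$bin_centers, pos)
    tet[[i]] <- list(marks = mk[keep, , drop = FALSE], positions = pos,
                     Kx = exp(-Dxp^2 / (2 * position_bandwidth^2)))
  }
  structure(list(tetrodes = tet, occupancy = occ, valid_bins = valid_bins,
                 mark_bandwidth = mark_bandwidth,
                 position_bandwidth = position_bandwidth,
                 amplitude_threshold = amplitude_threshold,
                 occupancy_floor = occupancy_floor,
                 n_bins = geometry$n_bins),
            class = "encoding_model")
}

#' @export
print.encoding_model <- function(x, ...) {
  ns <- vapply(x$tetrodes, function(tt) if (is.null(tt)) 0L else length(tt$positions), 0L)
  cat(sprintf("clusterless encoding model: %d/%d tetrodes, %d encoding spikes\n",
              sum(ns > 0), length(ns), sum(ns)))
  cat(sprintf("  mark bw %g uV, position bw %g cm, threshold %g uV\n",
              x$mark_bandwidth, x$position_bandwidth, x$amplitude_threshold))
  invisible(x)
}

# likelihood matrix for a block of query marks on one tetrode:
# columns are normalized spatial likelihoods, one per query spike
.likelihood_matrix <- function(marks, model, tetrode, chunk = 512L) {
  enc <- model$tetrodes[[tetrode]]
  if (is.null(enc)) stop("tetrode ", tetrode, " has no encoding model")
  if (is.null(dim(marks))) marks <- matrix(marks, ncol = 4)
  nq <- nrow(marks)
  nb <- model$n_bins
  occ <- pmax(model$occupancy, model$occupancy_floor)
  out <- matrix(0, nb, nq)
  low_info <- logical(nq)
  e2 <- rowSums(enc$marks^2)
  for (i0 in seq(1, nq, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nq)
    Q <- marks[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(Q^2), e2, "+") - 2 * Q %*% t(enc$marks)
    W <- exp(-pmax(d2, 0) / (2 * model$mark_bandwidth^2))
    L <- (enc$Kx %*% t(W)) / occ
    L[!model$valid_bins, ] <- 0
    tot <- colSums(L)
    bad <- tot <= 1e-300
    if (any(bad)) {
      L[, bad] <- 1 / nb
      tot[bad] <- 1
      low_info[(i0:i1)[bad]] <- TRUE
    }
    out[, i0:i1] <- sweep(L, 2, tot, "/")
  }
  attr(out, "low_info") <- low_info
  out
}

#' Spatial likelihood of a single spike's mark
#'
#' Kernel estimate of position given a 4D amplitude mark: a product Gaussian
#' kernel in mark space weights the encoding spikes, each contributing a
#' Gaussian bump (skeleton distance) around its paired position; the sum is
#' divided by occupancy and normalized over bins. Encoding spikes closest to
#' the query mark therefore dominate.
#'
#' @param mark length-4 numeric vector, uV.
#' @param model an `encoding_model`.
#' @param tetrode tetrode index.
#' @return normalized probability vector over position bins; attribute
#'   `low_info` is TRUE when all kernel weights underflowed (uniform output).
#' @export
spike_spatial_likelihood <- function(mark, model, tetrode) {
  L <- .likelihood_matrix(matrix(mark, ncol = 4), model, tetrode)
  out <- L[, 1]
  attr(out, "low_info") <- attr(L, "low_info")[1]
  out
}

#' Decode a session into 6 ms posteriors
#'
#' Within each time bin the spatial likelihoods of all above-threshold spikes
#' (across tetrodes) are combined by product and renormalized. Bins with no
#' spikes are uniform and flagged uninformative. Each bin also records the
#' number of spikes and the set of tetrodes that contributed at least one
#' spatially specific spike (see [spatial_specificity()]).
#'
#' @param spikes a `marked_spikes`.
#' @param model an `encoding_model`.
#' @param geometry a `track_geometry`.
#' @param t_start,t_end decoding window, s.
#' @param bin_width time bin, s (6 ms).
#' @param specificity_factor max-to-uniform ratio defining a spatially
#'   specific spike.
#' @return object of class `decoded_posterior` with `t` (bin centers),
#'   `posterior` (n_time x n_bins), `informative`, `n_spikes`,
#'   `tet_specific` (n_time x n_tetrodes logical),
#'   `n_contributing_tetrodes`.
#' @export
decode_session <- function(spikes, model, geometry, t_start, t_end,
                           bin_width = 0.006, specificity_factor = 3) {
  nb <- geometry$n_bins
  n_time <- max(1L, ceiling((t_end - t_start) / bin_width))
  edges <- t_start + bin_width * (0:n_time)
  logpost <- matrix(0, n_time, nb)
  n_spk <- integer(n_time)
  ntt <- length(spikes$tetrodes)
  tet_specific <- matrix(FALSE, n_time, ntt)
  unif_cut <- specificity_factor / nb

  for (tet in seq_len(ntt)) {
    if (is.null(model$tetrodes[[tet]])) next
    ts <- spikes$tetrodes[[tet]]$times
    mk <- spikes$tetrodes[[tet]]$marks
    keep <- ts >= t_start & ts < edges[n_time + 1] &
      apply(mk, 1, max) > model$amplitude_threshold
    if (!any(keep)) next
    ts <- ts[keep]; mk <- mk[keep, , drop = FALSE]
    bidx <- pmin(pmax(floor((ts - t_start) / bin_width) + 1L, 1L), n_time)
    L <- .likelihood_matrix(mk, model, tet)
    specific <- apply(L, 2, max) > unif_cut
    logL <- log(pmax(L, 1e-300))
    agg <- rowsum(t(logL), group = bidx)
    rows <- as.integer(rownames(agg))
    logpost[rows, ] <- logpost[rows, ] + agg
    n_spk <- n_spk + tabulate(bidx, nbins = n_time)
    sp_rows <- unique(bidx[specific])
    tet_specific[sp_rows, tet] <- TRUE
  }

  informative <- n_spk > 0L
  posterior <- matrix(1 / nb, n_time, nb)
  if (any(informative)) {
    lp <- logpost[informative, , drop = FALSE]
    lp <- lp - apply(lp, 1, max)
    p <- exp(lp)
    posterior[informative, ] <- p / rowSums(p)
  }
  structure(list(t = (edges[-1] + edges[-(n_time + 1)]) / 2,
                 bin_width = bin_width, posterior = posterior,
                 informative = informative, n_spikes = n_spk,
                 tet_specific = tet_specific,
                 n_contributing_tetrodes = rowSums(tet_specific)),
            class = "decoded_posterior")
}

#' @export
print.decoded_posterior <- function(x, ...) {
  cat(sprintf("decoded posterior: %d bins of %.0f ms, %.1f%% informative\n",
              length(x$t), x$bin_width * 1000, 100 * mean(x$informative)))
  invisible(x)
}

#' 30 ms running average of the decoded posterior
#'
#' Causal average over the last `window_bins` (default 5, i.e. 30 ms of 6 ms
#' bins), using informative constituent bins only. Windows with fewer than
#' `min_informative` informative bins are flagged ineligible. Tetrode
#' participation is pooled over the window: a tetrode counts if it had at
#' least one spatially specific spike anywhere in the window.
#'
#' @param decoded a `decoded_posterior`.
#' @param window_bins window length in bins.
#' @param min_informative minimum informative bins for eligibility.
#' @return object of class `avg_posterior`: `t`, `avg`, `eligible`,
#'   `n_informative`, `window_tet_count`.
#' @export
running_average_posterior <- function(decoded, window_bins = 5,
                                      min_informative = 2) {
  P <- decoded$posterior * decoded$informative
  n <- nrow(P)
  csP <- apply(P, 2, cumsum)
  if (is.null(dim(csP))) csP <- matrix(csP, nrow = n)
  csN <- cumsum(as.numeric(decoded$informative))
  lag <- function(M, k) rbind(matrix(0, k, ncol(M)), M[seq_len(n - k), , drop = FALSE])
  w <- window_bins
  sumP <- csP - lag(csP, min(w, n))
  cnt <- csN - c(rep(0, min(w, n)), csN[seq_len(max(0, n - w))])
  avg <- sumP / pmax(cnt, 1)
  eligible <- cnt >= min_informative
  avg[!eligible, ] <- 1 / ncol(P)

  TS <- apply(decoded$tet_specific, 2, cumsum)
  if (is.null(dim(TS))) TS <- matrix(TS, nrow = n)
  tsw <- TS - rbind(matrix(0, min(w, n), ncol(TS)),
                    TS[seq_len(max(0, n - w)), , drop = FALSE])
  structure(list(t = decoded$t, bin_width = decoded$bin_width, avg = avg,
                 eligible = eligible, n_informative = cnt,
                 window_tet_count = rowSums(tsw > 0)),
            class = "avg_posterior")
}

#' Session inclusion quality of the decode
#'
#' During exploration outward runs, restricted to moments when the animal is
#' in the distal 25 cm of the target arm, computes the fraction of
#' informative 6 ms bins whose posterior argmax lies anywhere in the target
#' arm. Sessions are included when the fraction reaches `threshold` (0.65).
#'
#' @param decoded a `decoded_posterior` covering the exploration phase.
#' @param trajectory a `position_trace`.
#' @param geometry a `track_geometry`.
#' @param target_arm arm index.
#' @param threshold inclusion cutoff.
#' @return list `fraction`, `n_bins`, `included`.
#' @export
decoding_quality <- function(decoded, trajectory, geometry, target_arm,
                             threshold = 0.65) {
  fi <- pmax(findInterval(decoded$t, trajectory$t), 1)
  lin <- trajectory$linear[fi]
  spd <- trajectory$head_speed[fi]
  phase <- trajectory$phase[fi]
  # outward: linear coordinate increasing (both arms increase outward)
  dlin <- c(0, diff(trajectory$linear)) * attr(trajectory, "pos_hz")
  outward <- .ma_smooth(dlin, 15)[fi] > 0
  end_mask <- region_mask(geometry, "target_end", target_arm)
  in_end <- end_mask[pmin(pmax(findInterval(
    lin, geometry$bin_edges, rightmost.closed = TRUE), 1), geometry$n_bins)]
  sel <- decoded$informative & phase == "exploration" & spd > 4 & outward & in_end
  if (!any(sel)) stop("undefined decoding quality: no qualifying bins")
  arm_mask <- region_mask(geometry, "arm", target_arm)
  amax <- max.col(decoded$posterior[sel, , drop = FALSE], ties.method = "first")
  frac <- mean(arm_mask[amax])
  list(fraction = frac, n_bins = sum(sel), included = frac >= threshold)
}

#' Median decoding error during movement
#'
#' Convenience summary: skeleton distance between the posterior argmax bin
#' center and the animal's true linear position, over informative movement
#' bins.
#'
#' @param decoded a `decoded_posterior`.
#' @param trajectory a `position_trace`.
#' @param geometry a `track_geometry`.
#' @return median absolute error, cm.
#' @export
decoding_error <- function(decoded, trajectory, geometry) {
  fi <- pmax(findInterval(decoded$t, trajectory$t), 1)
  sel <- decoded$informative & trajectory$head_speed[fi] > 4
  amax <- max.col(decoded$posterior[sel, , drop = FALSE], ties.method = "first")
  err <- lin_dist(geometry, geometry$bin_centers[amax], trajectory$linear[fi][sel])
  stats::median(err)
}
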