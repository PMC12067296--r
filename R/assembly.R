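#' Bin unit spike trains and z-score
#'
#' Spike counts of each sorted unit in 30 ms bins over an epoch; each unit's
#' row is then z-scored. Units with zero count variance in the epoch are
#' dropped with a warning.
#'
#' @param unit_times list of per-unit spike time vectors, s.
#' @param epoch length-2 numeric `(t0, t1)`, s.
#' @param bin_ms bin width, ms.
#' @return z-scored matrix (kept units x bins) with attributes `kept`
#'   (original unit indices), `t` (bin centers) and `bin_ms`.
#' @export
bin_and_zscore <- function(unit_times, epoch, bin_ms = 30) {
  stopifnot(length(unit_times) >= 2)
  bw <- bin_ms / 1000
  nb <- floor((epoch[2] - epoch[1]) / bw)
  if (nb < 100) stop("epoch too short: need at least 100 bins")
  edges <- epoch[1] + bw * (0:nb)
  M <- t(vapply(unit_times, function(st) {
    st <- st[st >= epoch[1] & st < edges[nb + 1]]
    tabulate(floor((st - epoch[1]) / bw) + 1L, nbins = nb)
  }, integer(nb)))
  v <- apply(M, 1, stats::var)
  keep <- v > 0
  if (any(!keep))
    warning(sum(!keep), " unit(s) with zero count variance dropped")
  M <- M[keep, , drop = FALSE]
  Z <- (M - rowMeans(M)) / apply(M, 1, stats::sd)
  attr(Z, "kept") <- which(keep)
  attr(Z, "t") <- (edges[-1] + edges[-(nb + 1)]) / 2
  attr(Z, "bin_ms") <- bin_ms
  Z
}

#' Marchenko-Pastur significance bound
#'
#' Largest eigenvalue expected from an uncorrelated units-by-bins matrix:
#' `(1 + sqrt(n_units / n_bins))^2`.
#'
#' @param n_units,n_bins matrix dimensions.
#' @export
marchenko_pastur_bound <- function(n_units, n_bins) {
  (1 + sqrt(n_units / n_bins))^2
}

# symmetric fixed-point ICA (cube contrast) on pre-whitened rows
.ica_symmetric <- function(Xw, seed = 1L, max_iter = 200, tol = 1e-8) {
  k <- nrow(Xw); B <- ncol(Xw)
  set.seed(seed)
  W <- matrix(stats::rnorm(k * k), k)
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  for (it in seq_len(max_iter)) {
    WX <- W %*% Xw
    G <- WX^3
    W_new <- (G %*% t(Xw)) / B - 3 * diag(rowMeans(WX^2), k) %*% W
    W_new <- orth(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) break
  }
  W
}

#' Detect co-firing cell assemblies (PCA + ICA)
#'
#' Eigendecomposition of the unit correlation matrix; eigenvalues above the
#' Marchenko-Pastur bound define the number of assemblies. ICA (symmetric
#' fixed-point, cube contrast) is run on the data projected onto the
#' significant subspace; each resulting weight vector is normalized to unit
#' length with its sign set so the largest-magnitude weight is positive.
#'
#' @param Z z-scored matrix from [bin_and_zscore()].
#' @param seed RNG seed for the ICA initialization.
#' @return object of class `assembly_model`: `weights` (units x
#'   n_significant), `eigenvalues`, `lambda_max`, `n_significant`.
#' @export
detect_assemblies <- function(Z, seed = 1L) {
  N <- nrow(Z); B <- ncol(Z)
  C <- tcrossprod(Z) / B
  eg <- eigen(C, symmetric = TRUE)
  lam_max <- marchenko_pastur_bound(N, B)
  k <- sum(eg$values > lam_max)
  if (k == 0) {
    return(structure(list(weights = matrix(numeric(0), N, 0),
                          eigenvalues = eg$values, lambda_max = lam_max,
                          n_significant = 0L), class = "assembly_model"))
  }
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  lam <- eg$values[seq_len(k)]
  Y <- t(V) %*% Z
  Yw <- Y / sqrt(lam * B)           # whitened: rows unit-variance
  W <- if (k == 1) matrix(1, 1, 1) else .ica_symmetric(Yw, seed = seed)
  A <- V %*% t(W)                   # unit-space weight vectors (columns)
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  for (j in seq_len(ncol(A)))
    if (A[which.max(abs(A[, j])), j] < 0) A[, j] <- -A[, j]
  structure(list(weights = A, eigenvalues = eg$values, lambda_max = lam_max,
                 n_significant = k), class = "assembly_model")
}

#' @export
print.assembly_model <- function(x, ...) {
  cat(sprintf("assembly model: %d significant assemblies (MP bound %.4f)\n",
              x$n_significant, x$lambda_max))
  invisible(x)
}

#' Assembly activation strength
#'
#' Quadratic form of the z-scored population vector with the assembly's
#' outer-product projector, diagonal removed so single-unit firing
#' contributes nothing: `R_k(t) = z' (w w' - diag(w^2)) z`.
#'
#' @param weights unit-norm weight vector (or the `assembly_model`'s weights
#'   matrix; then one row of output per assembly).
#' @param Z z-scored matrix (units x bins).
#' @return numeric vector per bin (or n_assemblies x bins matrix).
#' @export
assembly_strength <- function(weights, Z) {
  if (is.null(dim(weights))) weights <- matrix(weights, ncol = 1)
  out <- matrix(0, ncol(weights), ncol(Z))
  for (j in seq_len(ncol(weights))) {
    wz <- weights[, j] * Z
    out[j, ] <- colSums(wz)^2 - colSums(wz^2)
  }
  if (nrow(out) == 1) out[1, ] else out
}

#' High-weight units of an assembly
#'
#' Units whose weight exceeds the mean plus `n_sd` SDs of that assembly's
#' weight vector.
#'
#' @param weights weight vector.
#' @param n_sd threshold in SDs.
#' @return integer indices.
#' @export
high_weight_units <- function(weights, n_sd = 2) {
  which(weights > mean(weights) + n_sd * stats::sd(weights))
}

#' Label assemblies as target or non-target
#'
#' An assembly is labeled `target` when the weight-weighted average of its
#' high-weight units' place-map mass fraction inside the target arm end
#' exceeds the same quantity for every other candidate 25 cm region (both
#' arm ends, both arm bases, and a central box region of equal length).
#' Assemblies with no high-weight units are labeled non-target and flagged.
#'
#' @param model an `assembly_model`.
#' @param place_maps units x bins matrix of occupancy-normalized rates
#'   (rows aligned with the model's units).
#' @param geometry a `track_geometry`.
#' @param target_arm arm index.
#' @param n_sd high-weight threshold in SDs.
#' @return data.frame: `assembly`, `label`, `score_target`, `best_region`,
#'   `flagged`.
#' @export
label_assemblies <- function(model, place_maps, geometry, target_arm,
                             n_sd = 2) {
  regions <- list(
    target_end_arm1 = region_mask(geometry, "target_end", 1),
    target_end_arm2 = region_mask(geometry, "target_end", 2),
    arm_base_arm1 = region_mask(geometry, "arm_base", 1),
    arm_base_arm2 = region_mask(geometry, "arm_base", 2))
  # central 25 cm of the box as the box candidate
  ctr <- geometry$box_extent / 2
  regions$box_central <- geometry$region_masks$box &
    abs(geometry$bin_centers - ctr) <= 12.5
  target_name <- paste0("target_end_arm", target_arm)

  out <- vector("list", model$n_significant)
  for (j in seq_len(model$n_significant)) {
    w <- model$weights[, j]
    hw <- high_weight_units(w, n_sd)
    if (length(hw) == 0) {
      out[[j]] <- data.frame(assembly = j, label = "non_target",
                             score_target = NA_real_, best_region = NA,
                             flagged = TRUE, stringsAsFactors = FALSE)
      next
    }
    pm <- place_maps[hw, , drop = FALSE]
    tot <- pmax(rowSums(pm), 1e-12)
    score <- vapply(regions, function(msk) {
      frac <- rowSums(pm[, msk, drop = FALSE]) / tot
      sum(w[hw] * frac) / sum(w[hw])
    }, 0)
    best <- names(score)[which.max(score)]
    out[[j]] <- data.frame(assembly = j,
                           label = if (best == target_name) "target" else "non_target",
                           score_target = unname(score[target_name]),
                           best_region = best, flagged = FALSE,
                           stringsAsFactors = FALSE)
  }
  if (model$n_significant == 0)
    return(data.frame(assembly = integer(0), label = character(0),
                      score_target = numeric(0), best_region = character(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Assembly activation ratio at event times vs random times
#'
#' Ratio of the mean activation strength in the bins containing the event
#' times to the mean at `n_random` random bins drawn from the eligible set,
#' with a two-sided Mann-Whitney p-value.
#'
#' @param strength per-bin strength vector.
#' @param bin_t bin center times, s.
#' @param event_times detection times, s.
#' @param eligible logical per bin: candidate pool for the random draw
#'   (e.g. feedback-phase bins within port range).
#' @param n_random random bins to draw.
#' @param seed RNG seed for the draw.
#' @param max_strength_min optional filter: return NULL unless
#'   `max(strength)` exceeds this (used to restrict to strongly activating
#'   assemblies).
#' @return list `ratio`, `p`, `event_mean`, `random_mean`, or NULL if
#'   filtered out.
#' @export
activation_ratio <- function(strength, bin_t, event_times, eligible,
                             n_random = 500, seed = 1L,
                             max_strength_min = NULL) {
  if (length(event_times) < 10) stop("need at least 10 events")
  if (!is.null(max_strength_min) && max(strength) <= max_strength_min)
    return(NULL)
  bw <- if (length(bin_t) > 1) bin_t[2] - bin_t[1] else 0.03
  eb <- findInterval(event_times, bin_t - bw / 2)
  eb <- eb[eb >= 1 & eb <= length(strength)]
  set.seed(seed)
  pool <- which(eligible)
  rb <- sample(pool, min(n_random, length(pool)), replace = length(pool) < n_random)
  ev_m <- mean(strength[eb]); rd_m <- mean(strength[rb])
  mw <- mann_whitney(strength[eb], strength[rb])
  list(ratio = ev_m / rd_m, p = mw$p, event_mean = ev_m, random_mean = rd_m,
       n_events = length(eb))
}

#' Count high-weight cells active before a detection
#'
#' @param model an `assembly_model`.
#' @param assembly assembly index.
#' @param unit_times list of per-unit spike times (aligned with model rows).
#' @param event_time detection time, s.
#' @param pre_window window before detection, s (90 ms default).
#' @param n_sd high-weight threshold.
#' @return list `count`, `fraction`, `n_high_weight`.
#' @export
count_active_high_weight_cells <- function(model, assembly, unit_times,
                                           event_time, pre_window = 0.09,
                                           n_sd = 2) {
  hw <- high_weight_units(model$weights[, assembly], n_sd)
  active <- vapply(unit_times[hw], function(st)
    any(st >= event_time - pre_window & st < event_time), FALSE)
  list(count = sum(active),
       fraction = if (length(hw)) sum(active) / length(hw) else NA_real_,
       n_high_weight = length(hw))
}
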