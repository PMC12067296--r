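#' Y-maze track geometry and linearization
#'
#' The task environment is a central box with a reward port and two radiating
#' arms. All spatial analyses operate on a linearized coordinate: position 0 at
#' the box (port) end, increasing through the box to the arm junction, then
#' outward along each arm. The linear axis is discretized into bins of
#' `bin_size` cm, and named regions (the distal 25 cm "target end" of each arm,
#' the 25 cm control region at the arm base, the 15 cm base region used by
#' event classification, the first 5 cm of the arm visible from the box, and
#' the last 5 cm around the reward port) are boolean masks over those bins.
#'
#' @param arm_length length of each arm in cm (must be at least 25 so the
#'   named regions fit; 50 cm or more is recommended).
#' @param box_extent length of the central box segment in cm.
#' @param bin_size linear discretization in cm. Region masks are defined by
#'   bin-center membership in half-open `[start, end)` intervals, so a
#'   `bin_size` that divides 5 lands regions exactly on bin edges.
#' @param arm_angle half-angle between each arm and the box axis, radians.
#'
#' @return An object of class `track_geometry` with fields `n_bins`,
#'   `bin_centers`, `segment_of_bin`, `region_masks` (named list of logical
#'   vectors), skeleton `nodes`, and `center_port_xy`.
#'
#' @examples
#' geom <- build_track(arm_length = 120, box_extent = 40, bin_size = 5)
#' sum(geom$region_masks$target_end_arm1)  # 25 cm / 5 cm = 5 bins
#' @export
build_track <- function(arm_length = 120, box_extent = 40, bin_size = 5,
                        arm_angle = pi / 6) {
  if (arm_length < 25)
    stop("region-infeasible: arm_length must be >= 25 cm so the 25 cm end/base regions fit")
  if (bin_size <= 0 || box_extent <= 0) stop("bin_size and box_extent must be positive")

  total <- box_extent + 2 * arm_length
  n_bins <- ceiling(total / bin_size)
  edges <- seq(0, by = bin_size, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2

  seg_starts <- c(box = 0, arm1 = box_extent, arm2 = box_extent + arm_length)
  seg_of <- function(lin) {
    lin <- pmin(pmax(lin, 0), total - 1e-9)
    ifelse(lin < box_extent, "box",
           ifelse(lin < box_extent + arm_length, "arm1", "arm2"))
  }
  segment_of_bin <- seg_of(centers)

  in_interval <- function(lo, hi) centers >= lo & centers < hi
  arm_lo <- c(box_extent, box_extent + arm_length)
  arm_hi <- arm_lo + arm_length
  masks <- list(
    box  = segment_of_bin == "box",
    arm1 = segment_of_bin == "arm1",
    arm2 = segment_of_bin == "arm2"
  )
  for (a in 1:2) {
    lo <- arm_lo[a]; hi <- arm_hi[a]
    masks[[paste0("target_end_arm", a)]]   <- in_interval(hi - 25, hi)
    masks[[paste0("arm_base_arm", a)]]     <- in_interval(lo, lo + 25)
    masks[[paste0("arm_base15_arm", a)]]   <- in_interval(lo, lo + 15)
    masks[[paste0("visual_field_arm", a)]] <- in_interval(lo, lo + 5)
    masks[[paste0("reward_port_arm", a)]]  <- in_interval(hi - 5, hi)
  }

  # skeleton: port -> junction along +y, arms diverging at +/- arm_angle
  port <- c(0, 0)
  junction <- c(0, box_extent)
  dir1 <- c(-sin(arm_angle), cos(arm_angle))
  dir2 <- c(sin(arm_angle), cos(arm_angle))
  nodes <- list(port = port, junction = junction,
                arm1_end = junction + arm_length * dir1,
                arm2_end = junction + arm_length * dir2)

  geom <- structure(list(
    arm_length = arm_length, box_extent = box_extent, bin_size = bin_size,
    arm_angle = arm_angle, total_length = total, n_bins = n_bins,
    bin_edges = edges, bin_centers = centers, segment_of_bin = segment_of_bin,
    region_masks = masks, nodes = nodes, center_port_xy = port,
    seg_starts = seg_starts
  ), class = "track_geometry")

  # partition consistency, asserted on every build
  arm_of_mask <- sub(".*_(arm[12])$", "\\1", grep("_arm[12]$", names(masks), value = TRUE))
  for (i in seq_along(arm_of_mask)) {
    nm <- grep("_arm[12]$", names(masks), value = TRUE)[i]
    if (any(masks[[nm]] & !masks[[arm_of_mask[i]]]))
      stop("internal error: region mask ", nm, " escapes its segment")
  }
  stopifnot(all(masks$box | masks$arm1 | masks$arm2),
            !any(masks$box & masks$arm1), !any(masks$arm1 & masks$arm2),
            all(masks$reward_port_arm1 <= masks$target_end_arm1),
            all(masks$reward_port_arm2 <= masks$target_end_arm2))
  geom
}

#' @export
print.track_geometry <- function(x, ...) {
  cat("Y-maze track geometry\n")
  cat(sprintf("  box %g cm + 2 arms x %g cm, %d bins of %g cm\n",
              x$box_extent, x$arm_length, x$n_bins, x$bin_size))
  cat("  regions:", paste(names(x$region_masks), collapse = ", "), "\n")
  invisible(x)
}

#' Look up a named region mask
#'
#' @param geometry a `track_geometry`.
#' @param region one of `"box"`, `"arm"`, `"target_end"`, `"arm_base"`,
#'   `"arm_base15"`, `"visual_field"`, `"reward_port"`, `"track"`.
#' @param arm arm index (1 or 2) for arm-specific regions.
#' @return logical vector over linear bins.
#' @export
region_mask <- function(geometry, region, arm = 1) {
  if (region == "track") return(rep(TRUE, geometry$n_bins))
  if (region == "box") return(geometry$region_masks$box)
  if (region == "arm") return(geometry$region_masks[[paste0("arm", arm)]])
  m <- geometry$region_masks[[paste0(region, "_arm", arm)]]
  if (is.null(m)) stop("unknown region: ", region)
  m
}

# segment index (1 box, 2 arm1, 3 arm2) of a linear coordinate
.seg_index <- function(geometry, lin) {
  lin <- pmin(pmax(lin, 0), geometry$total_length - 1e-9)
  1L + (lin >= geometry$box_extent) + (lin >= geometry$box_extent + geometry$arm_length)
}

#' Convert a linear coordinate back to 2D skeleton coordinates
#'
#' @param geometry a `track_geometry`.
#' @param lin numeric vector of linear positions in cm.
#' @return n x 2 matrix of xy positions on the track skeleton.
#' @export
lin_to_xy <- function(geometry, lin) {
  seg <- .seg_index(geometry, lin)
  starts <- c(0, geometry$box_extent, geometry$box_extent + geometry$arm_length)
  t <- lin - starts[seg]
  J <- geometry$nodes$junction
  a <- geometry$arm_angle
  dirs <- rbind(c(0, 1), c(-sin(a), cos(a)), c(sin(a), cos(a)))
  origin <- rbind(c(0, 0), J, J)
  origin[seg, , drop = FALSE] + t * dirs[seg, , drop = FALSE]
}

#' Distance between linear positions along the track skeleton
#'
#' Positions on the same segment are compared directly; otherwise the path
#' runs through the arm junction.
#'
#' @param geometry a `track_geometry`.
#' @param a,b numeric vectors of linear positions (recycled).
#' @return numeric vector of skeleton distances in cm.
#' @export
lin_dist <- function(geometry, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  sa <- .seg_index(geometry, a); sb <- .seg_index(geometry, b)
  # distance of each coordinate to the junction
  dJ <- function(lin, seg) {
    starts <- c(0, geometry$box_extent, geometry$box_extent + geometry$arm_length)
    t <- lin - starts[seg]
    ifelse(seg == 1L, geometry$box_extent - lin, t)
  }
  ifelse(sa == sb, abs(a - b), dJ(a, sa) + dJ(b, sb))
}

#' Project 2D positions onto the track skeleton
#'
#' Each xy point is projected onto the nearest of the three skeleton segments
#' (box axis, arm 1, arm 2). Points farther than `tolerance` from every
#' segment are flagged off-track; their projection is still returned so the
#' caller can carry the last valid position forward.
#'
#' @param xy numeric length-2 vector or n x 2 matrix of positions in cm.
#' @param geometry a `track_geometry`.
#' @param tolerance maximum snap distance in cm (default 10).
#' @return list with `linear` (cm), `segment` (character), `off_track`
#'   (logical) and `snap_distance` (cm).
#' @export
linearize <- function(xy, geometry, tolerance = 10) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  J <- geometry$nodes$junction
  a <- geometry$arm_angle
  segs <- list(
    list(p0 = c(0, 0), dir = c(0, 1), len = geometry$box_extent, start = 0),
    list(p0 = J, dir = c(-sin(a), cos(a)), len = geometry$arm_length,
         start = geometry$box_extent),
    list(p0 = J, dir = c(sin(a), cos(a)), len = geometry$arm_length,
         start = geometry$box_extent + geometry$arm_length)
  )
  n <- nrow(xy)
  best_d <- rep(Inf, n); best_lin <- numeric(n); best_seg <- integer(n)
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    rel <- sweep(xy, 2, s$p0)
    t <- pmin(pmax(rel %*% s$dir, 0), s$len)
    proj <- cbind(s$p0[1] + t * s$dir[1], s$p0[2] + t * s$dir[2])
    d <- sqrt(rowSums((xy - proj)^2))
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_lin[upd] <- s$start + t[upd]
    best_seg[upd] <- k
  }
  list(linear = best_lin,
       segment = c("box", "arm1", "arm2")[best_seg],
       off_track = best_d > tolerance,
       snap_distance = best_d)
}

#' Euclidean distance to the center reward port
#'
#' The closed-loop trigger requires the rat's physical distance to the center
#' port to be strictly below 17 cm; this is the plain 2D distance used there.
#'
#' @param xy length-2 vector or n x 2 matrix of positions in cm.
#' @param geometry a `track_geometry`.
#' @return numeric vector of distances in cm.
#' @export
distance_to_center_port <- function(xy, geometry) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  sqrt((xy[, 1] - geometry$center_port_xy[1])^2 +
       (xy[, 2] - geometry$center_port_xy[2])^2)
}
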