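# Shared fixture builders and independent oracles.  Oracles deliberately
# use different formulas than the implementation they check.

# Independent point-to-ray distance:  d(c) = || (c-o) - ((c-o).u) u ||
# with u the unit ray direction -- no cross products involved.
oracle_ray_distance <- function(origin, direction, points) {
  u <- direction / sqrt(sum(direction^2))
  rel <- sweep(points, 2L, origin)
  along <- drop(rel %*% u)
  sqrt(rowSums((rel - outer(along, u))^2))
}

# Brute-force localization oracle: index (into the candidate table) of
# the candidate nearest the back-projection ray of p2d.
oracle_localize_index <- function(geom, p2d, cand) {
  r <- pixel_to_ray(geom, p2d)
  d <- oracle_ray_distance(r$origin_mm, r$direction,
                           as.matrix(cand[, c("x", "y", "z")]))
  list(index = which.min(d), dist = min(d), all = d)
}

# Random C-arm pose within clinically plausible angulation.
random_pose <- function() {
  carm_pose(stats::runif(1, -90, 90), stats::runif(1, -40, 40),
            sod_mm = stats::runif(1, 650, 850),
            sid_mm = stats::runif(1, 950, 1200))
}

# Smooth random 3D polyline near the iso-center (a random walk with a
# moving-average smoother), as a single-branch tree.
random_curve_tree <- function(n = 150, scale = 60) {
  steps <- matrix(stats::rnorm(3 * (n + 8)), ncol = 3L)
  sm <- apply(steps, 2L, function(v) stats::filter(v, rep(1 / 5, 5),
                                                   sides = 2L))
  sm <- sm[stats::complete.cases(sm), , drop = FALSE]
  P <- apply(sm, 2L, cumsum)
  P <- sweep(P, 2L, colMeans(P))
  P <- P * (scale / max(abs(P)))
  keep <- c(TRUE, rowSums((P[-1L, , drop = FALSE] -
                             P[-nrow(P), , drop = FALSE])^2) > 1e-12)
  centerline_tree(centerline_branch(P[keep, , drop = FALSE], "curve"))
}

# Floyd-Warshall all-pairs shortest paths on the tree point graph --
# independent oracle for geodesic neighborhoods (small trees only).
oracle_geodesic <- function(tree) {
  pts <- as.data.frame(tree)
  n <- nrow(pts)
  key <- paste(pts$branch_id, pts$index)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  add_edge <- function(i, j, w) {
    D[i, j] <<- min(D[i, j], w); D[j, i] <<- D[i, j]
  }
  row0 <- 0L
  for (b in tree$branches) {
    nb <- nrow(b$points_mm)
    for (k in seq_len(nb - 1L))
      add_edge(row0 + k, row0 + k + 1L, diff(b$cum_arclen_mm)[k])
    if (!is.null(b$parent)) {
      pi <- match(paste(b$parent$branch_id, b$parent$index), key)
      gap <- sqrt(sum((b$points_mm[1L, ] -
                         as.matrix(pts[pi, c("x", "y", "z")]))^2))
      add_edge(pi, row0 + 1L, max(gap, 1e-12))
    }
    row0 <- row0 + nb
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    upd <- D[i, k] + D[k, ]
    better <- upd < D[i, ]
    D[i, better] <- upd[better]
  }
  list(dist = D, points = pts, key = key)
}

# Y-shaped tree: trunk along z with a side branch from its midpoint.
make_y_tree <- function(spacing = 1) {
  trunk <- centerline_branch(cbind(0, 0, seq(0, 20, by = spacing)), "trunk")
  side <- centerline_branch(
    sweep(outer(seq(spacing, 15, by = spacing),
                c(1, 0, 1) / sqrt(2)), 2L, c(0, 0, 10), "+"),
    "side", parent = list(branch_id = "trunk",
                          index = which(seq(0, 20, by = spacing) == 10)))
  centerline_tree(list(trunk, side))
}

# Straight vessel through the iso-center along +z, with a marker
# trajectory offset radially from the centerline -- the tracking and
# radial-offset test bed.  Frame-to-frame travel is step_mm.
straight_vessel_scene <- function(n_frames = 60, radial_offset_mm = 0,
                                  step_mm = 0.5, spacing_mm = 0.5,
                                  z0 = -15) {
  tree <- centerline_tree(centerline_branch(cbind(0, 0, seq(-40, 40,
                                                            by = spacing_mm)),
                                            "vessel"))
  z <- z0 + step_mm * (seq_len(n_frames) - 1L)
  # the device hugs one side of the vessel: a single azimuth per
  # pull-through with slow drift, not an independent draw per frame
  azim <- stats::runif(1, 0, 2 * pi) +
    cumsum(stats::rnorm(n_frames, 0, 0.02))
  traj <- cbind(radial_offset_mm * cos(azim), radial_offset_mm * sin(azim), z)
  list(tree = tree, trajectory_mm = traj, on_centerline = cbind(0, 0, z))
}

# Half-pixel quantization displacement bound mapped to the iso-center
# plane (mm): pixel footprint at iso-center times sqrt(2)/2.
quantization_bound_mm <- function(pose) {
  max(pose$pixel_spacing_mm) * pose$sod_mm / pose$sid_mm * sqrt(2) / 2
}

temp_path <- function(ext) tempfile(fileext = ext)
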