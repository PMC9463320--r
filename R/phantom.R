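# Synthetic digital phantom: a parametric aortic-arch + carotid-branch
# centerline tree with markers at controlled arc positions and radial
# offsets (emulating a guidewire that need not run along the vessel
# center), forward-projected through the C-arm model with optional pixel
# quantization and picking noise, plus rendered image sequences and
# two-view datasets.  All generation is seed-deterministic.

#' Specification of the synthetic vascular phantom
#'
#' The arch is a circular arc (default radius 35 mm, span 180 degrees)
#' in a plane tilted out of the coronal plane; a straight branch
#' (default 80 mm, emulating a common carotid artery of vessel radius
#' 3.2 mm) attaches at a parameterized arc position and runs cranially.
#' Markers sit at stated arc positions along the branch, displaced
#' radially from the centerline by the stated offset in a seeded random
#' azimuth -- the worst-case geometry for centerline-based localization,
#' whose intrinsic error is bounded by the vessel radius.
#'
#' @param arch_radius_mm Arch radius (default 35).
#' @param arch_span_deg Arch angular span (default 180).
#' @param arch_tilt_deg Tilt of the arch plane about the x-axis
#'   (default 15), giving the tree genuine depth variation.
#' @param branch_length_mm Branch length (default 80).
#' @param branch_angle_deg Branch tilt from the cranial (+z) axis
#'   (default 20).
#' @param branch_attach_deg Arc angle at which the branch attaches
#'   (default 95, near the arch apex).
#' @param vessel_radius_mm Named vector `c(arch =, branch =)` of vessel
#'   radii; default `c(arch = 12, branch = 3.2)`.
#' @param marker_arc_positions_mm Marker arc positions along the branch
#'   (mm from the attachment); defaults to five positions spread over
#'   the branch.
#' @param marker_radial_offset_mm Radial marker offset(s), recycled over
#'   markers; each must not exceed the branch vessel radius in absolute
#'   value. Default 0 (markers on the centerline).
#' @param sample_spacing_mm Native sampling of the generated polylines
#'   (default 0.5).
#' @param seed Integer seed controlling the marker azimuths.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(arch_radius_mm = 35, arch_span_deg = 180,
                         arch_tilt_deg = 15, branch_length_mm = 80,
                         branch_angle_deg = 20, branch_attach_deg = 95,
                         vessel_radius_mm = c(arch = 12, branch = 3.2),
                         marker_arc_positions_mm = c(12.3, 24.7, 37.1,
                                                     49.9, 62.3),
                         marker_radial_offset_mm = 0,
                         sample_spacing_mm = 0.5,
                         seed = 1L) {
  check_scalar(arch_radius_mm, "arch_radius_mm", positive = TRUE)
  check_scalar(arch_span_deg, "arch_span_deg", positive = TRUE)
  check_scalar(branch_length_mm, "branch_length_mm", positive = TRUE)
  check_scalar(sample_spacing_mm, "sample_spacing_mm", positive = TRUE)
  if (is.null(names(vessel_radius_mm)))
    names(vessel_radius_mm) <- c("arch", "branch")
  if (any(vessel_radius_mm <= 0))
    stop("'vessel_radius_mm' must be positive", call. = FALSE)
  if (branch_attach_deg <= 0 || branch_attach_deg >= arch_span_deg)
    stop("'branch_attach_deg' must lie strictly inside the arch span",
         call. = FALSE)
  if (any(marker_arc_positions_mm < 0 |
          marker_arc_positions_mm > branch_length_mm))
    stop("'marker_arc_positions_mm' must lie within the branch length",
         call. = FALSE)
  off <- rep_len(marker_radial_offset_mm,
                 length(marker_arc_positions_mm))
  if (any(abs(off) > vessel_radius_mm[["branch"]] + 1e-12))
    stop(sprintf("'marker_radial_offset_mm' must not exceed the branch vessel radius (%.3g mm)",
                 vessel_radius_mm[["branch"]]), call. = FALSE)
  structure(list(arch_radius_mm = arch_radius_mm,
                 arch_span_deg = arch_span_deg,
                 arch_tilt_deg = arch_tilt_deg,
                 branch_length_mm = branch_length_mm,
                 branch_angle_deg = branch_angle_deg,
                 branch_attach_deg = branch_attach_deg,
                 vessel_radius_mm = vessel_radius_mm,
                 marker_arc_positions_mm = as.numeric(marker_arc_positions_mm),
                 marker_radial_offset_mm = off,
                 sample_spacing_mm = sample_spacing_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the synthetic phantom
#'
#' Builds the arch + branch [centerline_tree()], the 3D marker positions
#' (offset radially from the branch centerline in seeded random
#' azimuths), the ground-truth branch/arc-position of each marker, and
#' three non-collinear fiducial points (arch start, arch end, branch
#' end) usable for registration experiments.  Deterministic for a fixed
#' spec (including its seed).
#'
#' @param spec A [phantom_spec()].
#' @return `list(tree, markers_mm, truth, fiducials_mm, spec)` where
#'   `truth` is a data frame (`branch_id`, `arc_pos_mm`,
#'   `radial_offset_mm`, `cx`, `cy`, `cz` -- the on-centerline point).
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("'spec' must be a phantom_spec", call. = FALSE)
  tilt <- rot_x(deg2rad(spec$arch_tilt_deg))
  arc_len <- spec$arch_radius_mm * deg2rad(spec$arch_span_deg)
  n_arch <- max(2L, ceiling(arc_len / spec$sample_spacing_mm) + 1L)
  th <- seq(0, deg2rad(spec$arch_span_deg), length.out = n_arch)
  arch_pts <- t(tilt %*% rbind(spec$arch_radius_mm * cos(th), 0,
                               spec$arch_radius_mm * sin(th)))
  arch <- centerline_branch(arch_pts, "aortic_arch",
                            radius_mm = rep(spec$vessel_radius_mm[["arch"]],
                                            n_arch))
  th_at <- deg2rad(spec$branch_attach_deg)
  attach_pt <- drop(tilt %*% (spec$arch_radius_mm * c(cos(th_at), 0,
                                                      sin(th_at))))
  attach_idx <- which.min(abs(th - th_at))
  phi <- deg2rad(spec$branch_angle_deg)
  bdir <- unitv(drop(tilt %*% c(sin(phi), 0, cos(phi))))
  n_br <- max(2L, ceiling(spec$branch_length_mm / spec$sample_spacing_mm) + 1L)
  s_br <- seq(0, spec$branch_length_mm, length.out = n_br)
  branch_pts <- matrix(attach_pt, n_br, 3L, byrow = TRUE) + outer(s_br, bdir)
  branch <- centerline_branch(branch_pts, "carotid",
                              radius_mm = rep(spec$vessel_radius_mm[["branch"]],
                                              n_br),
                              parent = list(branch_id = "aortic_arch",
                                            index = attach_idx))
  tree <- centerline_tree(list(arch, branch))
  # orthonormal frame perpendicular to the (straight) branch direction
  ref <- if (abs(bdir[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(cross3(bdir, ref))
  e2 <- cross3(bdir, e1)
  nm <- length(spec$marker_arc_positions_mm)
  azim <- with_seed(spec$seed, stats::runif(nm, 0, 2 * pi))
  on_cl <- matrix(attach_pt, nm, 3L, byrow = TRUE) +
    outer(spec$marker_arc_positions_mm, bdir)
  radial <- outer(cos(azim), e1) + outer(sin(azim), e2)
  markers <- on_cl + radial * spec$marker_radial_offset_mm
  truth <- data.frame(branch_id = "carotid",
                      arc_pos_mm = spec$marker_arc_positions_mm,
                      radial_offset_mm = spec$marker_radial_offset_mm,
                      cx = on_cl[, 1L], cy = on_cl[, 2L], cz = on_cl[, 3L],
                      stringsAsFactors = FALSE)
  fiducials <- rbind(arch_pts[1L, ], arch_pts[n_arch, ],
                     branch_pts[n_br, ])
  rownames(fiducials) <- c("arch_start", "arch_end", "branch_end")
  list(tree = tree, markers_mm = markers, truth = truth,
       fiducials_mm = fiducials, spec = spec)
}

#' Project phantom markers to 2D working points
#'
#' Forward projection through the C-arm model with optional seeded
#' Gaussian pixel noise (emulating manual picking error) applied before
#' optional rounding to integer pixels (the raster quantization of a
#' real pick).
#'
#' @param geom A [pose_to_geometry()] result.
#' @param markers_mm n x 3 marker matrix.
#' @param quantize Round to integer pixels? Default `FALSE`.
#' @param noise_px Standard deviation of Gaussian pixel noise per axis
#'   (default 0).
#' @param seed Seed for the noise draw (required when `noise_px > 0`).
#' @return n x 2 matrix (`row_px`, `col_px`).
#' @export
project_markers <- function(geom, markers_mm, quantize = FALSE,
                            noise_px = 0, seed = NULL) {
  px <- project_points(geom, markers_mm)
  if (noise_px > 0) {
    if (is.null(seed))
      stop("'seed' is required when 'noise_px' > 0", call. = FALSE)
    px <- px + with_seed(seed,
                         matrix(stats::rnorm(length(px), 0, noise_px),
                                nrow(px), 2L))
  }
  if (quantize) px <- round(px)
  colnames(px) <- c("row_px", "col_px")
  px
}

#' Render a synthetic fluoroscopy frame sequence
#'
#' One frame per 3D trajectory position: an isotropic Gaussian intensity
#' blob at the projected pixel plus optional seeded additive Gaussian
#' noise.  The per-frame true pixel positions are returned alongside;
#' frames whose blob lies entirely outside the raster are blank and
#' flagged.
#'
#' @param geom A [pose_to_geometry()] result (its detector size sets the
#'   frame size).
#' @param trajectory_mm n x 3 matrix of marker positions, one per frame.
#' @param blob_sigma_px Gaussian blob sigma in pixels (default 2).
#' @param blob_amplitude Peak blob intensity (default 1).
#' @param noise_sd Additive Gaussian noise standard deviation
#'   (default 0); the peak signal-to-noise ratio is
#'   `blob_amplitude / noise_sd`.
#' @param seed Seed for the noise (required when `noise_sd > 0`).
#' @return `list(frames, truth_px, out_of_view)`.
#' @export
render_frames <- function(geom, trajectory_mm, blob_sigma_px = 2,
                          blob_amplitude = 1, noise_sd = 0, seed = NULL) {
  traj <- as_points3(trajectory_mm, "trajectory_mm")
  px <- project_points(geom, traj)
  nr <- geom$detector_size_px[1L]; nc <- geom$detector_size_px[2L]
  n <- nrow(traj)
  if (noise_sd > 0 && is.null(seed))
    stop("'seed' is required when 'noise_sd' > 0", call. = FALSE)
  noise <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(n * nr * nc, 0, noise_sd))
  out_of_view <- logical(n)
  frames <- vector("list", n)
  margin <- 3 * blob_sigma_px
  rows <- 0:(nr - 1L); cols <- 0:(nc - 1L)
  for (k in seq_len(n)) {
    r0 <- px[k, 1L]; c0 <- px[k, 2L]
    if (r0 < -margin || r0 > nr - 1L + margin ||
        c0 < -margin || c0 > nc - 1L + margin) {
      out_of_view[k] <- TRUE
      img <- matrix(0, nr, nc)
    } else {
      img <- blob_amplitude *
        outer(exp(-(rows - r0)^2 / (2 * blob_sigma_px^2)),
              exp(-(cols - c0)^2 / (2 * blob_sigma_px^2)))
    }
    if (noise_sd > 0)
      img <- img + matrix(noise[((k - 1L) * nr * nc + 1L):(k * nr * nc)],
                          nr, nc)
    frames[[k]] <- img
  }
  list(frames = frames,
       truth_px = cbind(row_px = px[, 1L], col_px = px[, 2L]),
       out_of_view = out_of_view)
}

#' Build a consistent two-view dataset of the phantom markers
#'
#' Projects the same markers through two C-arm poses, for epipolar
#' reference reconstruction.  Pose pairs separated by less than 5
#' degrees (between central ray directions) are refused; pairs below 30
#' degrees -- the minimum practical separation for a stable two-view
#' reconstruction -- produce a warning but are generated.
#'
#' @param phantom A [make_phantom()] result (or any list with
#'   `markers_mm`).
#' @param pose_a,pose_b [carm_pose()] objects for the two views.
#' @param quantize,noise_px,seed Passed to [project_markers()] (the two
#'   views use distinct sub-seeds).
#' @return `list(geom_a, geom_b, points_a, points_b, markers_mm,
#'   separation_deg)`.
#' @export
make_two_view_dataset <- function(phantom, pose_a, pose_b,
                                  quantize = FALSE, noise_px = 0,
                                  seed = NULL) {
  ga <- pose_to_geometry(pose_a)
  gb <- pose_to_geometry(pose_b)
  sep <- rad2deg(acos(max(-1, min(1, sum(ga$normal * gb$normal)))))
  if (sep < 5)
    stop(sprintf("view separation %.2f deg is too small for triangulation (need >= 5 deg)",
                 sep), call. = FALSE)
  if (sep < 30)
    warning(sprintf("view separation %.1f deg is below the recommended 30 deg",
                    sep), call. = FALSE)
  markers <- as_points3(phantom$markers_mm %||% phantom, "markers_mm")
  sa <- if (!is.null(seed)) sub_seed(seed, 1L)
  sb <- if (!is.null(seed)) sub_seed(seed, 2L)
  list(geom_a = ga, geom_b = gb,
       points_a = project_markers(ga, markers, quantize, noise_px, sa),
       points_b = project_markers(gb, markers, quantize, noise_px, sb),
       markers_mm = markers, separation_deg = sep)
}

#' Construct a two-branch scene with superimposed projections
#'
#' A deterministic stress scene for wrong-branch failures of single-view
#' localization: branch `vessel_true` is a straight cranio-caudal vessel
#' holding a sequence of 20 true marker positions; branch
#' `vessel_ghost`, attached at the far end of `vessel_true`, is placed
#' exactly on the projection rays of those markers (at larger depth), so
#' both branches superimpose in the projection.  With
#' `marker_node_offset_mm > 0` the markers fall between the sampled
#' points of the true branch while the ghost branch lies exactly on the
#' rays: unconstrained localization then selects the ghost branch, while
#' a continuity-restricted sequence started from the true initial
#' position stays on the true branch.  With the offset 0 both branches
#' hit the rays exactly and the localization is flagged ambiguous.
#'
#' @param pose A [carm_pose()]; default identity angulation at
#'   SOD 750 / SID 1000.
#' @param n_markers Number of sequential marker positions (default 20).
#' @param marker_node_offset_mm Arc offset of the markers from the
#'   sampled points of the true branch (default 0.2; use 0 for exact
#'   ties).
#' @param depth_scale Depth factor placing the ghost branch along the
#'   marker rays (default 1.15).
#' @return `list(tree, geom, markers_mm, points2d, init, true_branch)`
#'   where `init` is the `(branch_id, index)` of the sampled point
#'   nearest the first marker.
#' @export
make_superimposed_scene <- function(pose = carm_pose(0, 0, 750, 1000),
                                    n_markers = 20L,
                                    marker_node_offset_mm = 0.2,
                                    depth_scale = 1.15) {
  geom <- pose_to_geometry(pose)
  z_nodes <- seq(-30, 30, by = 0.5)
  A <- cbind(0, 0, z_nodes)
  z_m <- seq(-25, by = 1, length.out = n_markers) + marker_node_offset_mm
  markers <- cbind(0, 0, z_m)
  s <- geom$source_mm
  ghost <- sweep(sweep(markers, 2L, s) * depth_scale, 2L, s, "+")
  tree <- centerline_tree(list(
    centerline_branch(A, "vessel_true"),
    centerline_branch(ghost, "vessel_ghost",
                      parent = list(branch_id = "vessel_true",
                                    index = length(z_nodes)))))
  pts2d <- project_points(geom, markers)
  init_idx <- which.min(abs(z_nodes - z_m[1L]))
  list(tree = tree, geom = geom, markers_mm = markers, points2d = pts2d,
       init = list(branch_id = "vessel_true", index = init_idx),
       true_branch = "vessel_true")
}
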