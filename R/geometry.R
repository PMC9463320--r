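# C-arm projection geometry: pinhole camera model mapping gantry
# angulation and source/detector distances to a source position and a
# detector frame in the fixed X-ray ("XR") coordinate system.
#
# Coordinate convention (right-handed, origin at the iso-center):
#   +x patient-left, +y patient-posterior (source-to-detector direction at
#   identity angulation), +z patient-cranial.
# Primary angulation (LAO positive) rotates about +z and is applied first;
# secondary angulation (cranial positive) rotates about the rotated x-axis.
# Lengths are millimetres; interface angles are degrees.

#' C-arm acquisition pose
#'
#' Bundles the acquisition parameters of a monoplane C-arm view: gantry
#' angulation, source-to-isocenter distance (SOD), source-to-detector
#' distance (SID), and the detector raster.  The ratio SID/SOD is the
#' geometric magnification of structures at the iso-center.
#'
#' @param primary_angle_deg Primary angulation in degrees; LAO (left
#'   anterior oblique) positive, RAO negative.
#' @param secondary_angle_deg Secondary angulation in degrees; cranial
#'   positive, caudal negative.
#' @param sod_mm Source-to-isocenter distance in mm.
#' @param sid_mm Source-to-detector distance in mm; must exceed `sod_mm`.
#' @param pixel_spacing_mm Detector pixel spacing `(row, col)` in mm.
#' @param detector_size_px Detector raster size `(rows, cols)` in pixels.
#' @param table_offset_mm Optional 3-vector added to the iso-center
#'   position (residual table translation); default zero.
#' @return An object of class `"carm_pose"`.
#' @seealso [pose_to_geometry()]
#' @export
#' @examples
#' carm_pose(30, 0, sod_mm = 750, sid_mm = 1000)
carm_pose <- function(primary_angle_deg = 0, secondary_angle_deg = 0,
                      sod_mm = 750, sid_mm = 1000,
                      pixel_spacing_mm = c(0.37, 0.37),
                      detector_size_px = c(512L, 512L),
                      table_offset_mm = c(0, 0, 0)) {
  check_scalar(primary_angle_deg, "primary_angle_deg")
  check_scalar(secondary_angle_deg, "secondary_angle_deg")
  check_scalar(sod_mm, "sod_mm", positive = TRUE)
  check_scalar(sid_mm, "sid_mm", positive = TRUE)
  if (sid_mm <= sod_mm)
    stop("'sid_mm' must be greater than 'sod_mm'", call. = FALSE)
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    stop("'pixel_spacing_mm' must be two positive values (row, col)",
         call. = FALSE)
  if (length(detector_size_px) != 2L || any(detector_size_px < 2))
    stop("'detector_size_px' must be (rows, cols) with both >= 2",
         call. = FALSE)
  structure(list(
    primary_angle_deg   = as.numeric(primary_angle_deg),
    secondary_angle_deg = as.numeric(secondary_angle_deg),
    sod_mm              = as.numeric(sod_mm),
    sid_mm              = as.numeric(sid_mm),
    pixel_spacing_mm    = as.numeric(pixel_spacing_mm),
    detector_size_px    = as.integer(detector_size_px),
    table_offset_mm     = as_point3(table_offset_mm, "table_offset_mm")
  ), class = "carm_pose")
}

#' @export
print.carm_pose <- function(x, ...) {
  cat(sprintf("C-arm pose: %s %.1f deg / %s %.1f deg, SOD %.0f mm, SID %.0f mm\n",
              if (x$primary_angle_deg >= 0) "LAO" else "RAO",
              abs(x$primary_angle_deg),
              if (x$secondary_angle_deg >= 0) "CRAN" else "CAUD",
              abs(x$secondary_angle_deg), x$sod_mm, x$sid_mm))
  cat(sprintf("  detector %d x %d px at %.3g x %.3g mm/px\n",
              x$detector_size_px[1], x$detector_size_px[2],
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  invisible(x)
}

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L, 3L)
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L)
}

#' Derive the projection geometry of a C-arm pose
#'
#' Computes the X-ray source position and the detector frame (center,
#' in-plane unit axes, and normal) for a [carm_pose()].  At identity
#' angulation the source lies at `(0, -SOD, 0)` and the detector center at
#' `(0, SID - SOD, 0)`; the primary rotation (about +z, LAO positive) is
#' applied before the secondary rotation (about the rotated x-axis,
#' cranial positive), both about the iso-center.
#'
#' The detector `u` axis is the image column direction, `v` the image row
#' direction (rows increase caudally), and `normal` points from the
#' source toward the detector.
#'
#' @param pose A [carm_pose()].
#' @return An object of class `"projection_geometry"` with fields
#'   `source_mm`, `detector_origin_mm`, `u_axis`, `v_axis`, `normal`,
#'   `isocenter_mm`, plus the pose scalars.
#' @export
pose_to_geometry <- function(pose) {
  if (!inherits(pose, "carm_pose"))
    stop("'pose' must be a carm_pose object", call. = FALSE)
  R <- rot_z(deg2rad(pose$primary_angle_deg)) %*%
    rot_x(deg2rad(pose$secondary_angle_deg))
  iso <- pose$table_offset_mm
  source_mm <- iso + drop(R %*% c(0, -pose$sod_mm, 0))
  normal <- drop(R %*% c(0, 1, 0))
  structure(list(
    source_mm          = source_mm,
    detector_origin_mm = source_mm + pose$sid_mm * normal,
    u_axis             = drop(R %*% c(1, 0, 0)),
    v_axis             = drop(R %*% c(0, 0, -1)),
    normal             = normal,
    isocenter_mm       = iso,
    sod_mm             = pose$sod_mm,
    sid_mm             = pose$sid_mm,
    pixel_spacing_mm   = pose$pixel_spacing_mm,
    detector_size_px   = pose$detector_size_px,
    pose               = pose
  ), class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat("Projection geometry\n")
  cat(sprintf("  source   : (%.2f, %.2f, %.2f) mm\n",
              x$source_mm[1], x$source_mm[2], x$source_mm[3]))
  cat(sprintf("  detector : (%.2f, %.2f, %.2f) mm, SID %.0f mm\n",
              x$detector_origin_mm[1], x$detector_origin_mm[2],
              x$detector_origin_mm[3], x$sid_mm))
  invisible(x)
}

detector_center_px <- function(geom) (geom$detector_size_px - 1) / 2

#' 2D working point in pixel coordinates
#'
#' A picked or tracked 2D device position on the detector raster.
#' Pixels are 0-based at pixel centers; the detector center pixel
#' `((rows-1)/2, (cols-1)/2)` coincides with the detector origin.
#'
#' @param row_px,col_px Pixel coordinates (may be fractional).
#' @return An object of class `"working_point"`.
#' @export
working_point <- function(row_px, col_px) {
  if (!is.finite(row_px) || !is.finite(col_px))
    stop("working point coordinates must be finite", call. = FALSE)
  structure(list(row_px = as.numeric(row_px), col_px = as.numeric(col_px)),
            class = "working_point")
}

as_working_points <- function(p) {
  if (inherits(p, "working_point"))
    return(matrix(c(p$row_px, p$col_px), 1L, 2L,
                  dimnames = list(NULL, c("row_px", "col_px"))))
  if (is.data.frame(p)) p <- as.matrix(p[, c("row_px", "col_px")])
  if (is.null(dim(p))) p <- matrix(as.numeric(p), 1L, 2L)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L || any(!is.finite(p)))
    stop("working points must be finite (row_px, col_px) pairs", call. = FALSE)
  colnames(p) <- c("row_px", "col_px")
  p
}

#' A 3D ray (origin plus unit direction)
#'
#' @param origin_mm 3-vector ray origin in mm.
#' @param direction 3-vector direction; normalized on construction.
#' @return An object of class `"ray"`.
#' @export
ray <- function(origin_mm, direction) {
  structure(list(origin_mm = as_point3(origin_mm, "origin_mm"),
                 direction = unitv(as_point3(direction, "direction"))),
            class = "ray")
}

# Vectorized perspective projection of an n x 3 point matrix onto the
# detector, in pixel coordinates.  Depth is measured along the detector
# normal from the source.
project_points <- function(geom, p3d) {
  P <- as_points3(p3d, "p3d")
  s <- geom$source_mm
  d <- sweep(P, 2L, s)                       # rays source -> point
  depth <- drop(d %*% geom$normal)
  if (any(depth <= 1e-9) || any(depth >= geom$sid_mm - 1e-9))
    stop("degenerate projection: point not strictly between source and detector",
         call. = FALSE)
  t <- geom$sid_mm / depth
  hit <- sweep(d * t, 2L, s, "+")            # intersection with detector
  dl <- sweep(hit, 2L, geom$detector_origin_mm)
  cen <- detector_center_px(geom)
  cbind(row_px = cen[1] + drop(dl %*% geom$v_axis) / geom$pixel_spacing_mm[1],
        col_px = cen[2] + drop(dl %*% geom$u_axis) / geom$pixel_spacing_mm[2])
}

#' Project a 3D point onto the detector
#'
#' Perspective projection through the X-ray source onto the detector
#' plane, converted to pixel coordinates.  A point displaced `d` mm
#' perpendicular to the central ray at the iso-center lands
#' `d * SID/SOD / pixel_spacing` pixels from the detector center
#' (similar-triangles magnification).
#'
#' @param geom A [pose_to_geometry()] result.
#' @param p3d A 3-vector (mm) or an n x 3 matrix of points.
#' @return A [working_point()] for a single point, otherwise an n x 2
#'   matrix with columns `row_px`, `col_px`.
#' @export
project_point <- function(geom, p3d) {
  single <- is.null(dim(p3d))
  px <- project_points(geom, p3d)
  if (single) working_point(px[1L, 1L], px[1L, 2L]) else px
}

#' Embed a 2D pixel on the detector plane in 3D
#'
#' Returns the 3D position (mm, XR coordinates) of a pixel on the
#' physical detector plane:
#' `detector_origin + (col - c_col) * spacing * u + (row - c_row) * spacing * v`.
#'
#' @inheritParams project_point
#' @param p2d A [working_point()] or `(row_px, col_px)` pair(s).
#' @return A 3-vector for a single point, otherwise an n x 3 matrix.
#' @export
pixel_to_detector_point <- function(geom, p2d) {
  P <- as_working_points(p2d)
  cen <- detector_center_px(geom)
  dv <- (P[, 1L] - cen[1]) * geom$pixel_spacing_mm[1]
  du <- (P[, 2L] - cen[2]) * geom$pixel_spacing_mm[2]
  out <- matrix(geom$detector_origin_mm, nrow(P), 3L, byrow = TRUE) +
    outer(du, geom$u_axis) + outer(dv, geom$v_axis)
  if (nrow(out) == 1L) drop(out) else out
}

#' Back-project a pixel into its 3D projection ray
#'
#' The ray from the X-ray source through the pixel's position on the
#' detector plane; every 3D point projecting to this pixel lies on it.
#'
#' @inheritParams pixel_to_detector_point
#' @return A [ray()] with origin at the source.
#' @export
pixel_to_ray <- function(geom, p2d) {
  dp <- pixel_to_detector_point(geom, p2d)
  if (!is.null(dim(dp))) stop("pixel_to_ray expects a single pixel", call. = FALSE)
  ray(geom$source_mm, dp - geom$source_mm)
}

#' Map a point onto the iso-center evaluation plane
#'
#' Central projection onto the plane through the iso-center parallel to
#' the detector, expressed in in-plane `(u, v)` millimetre coordinates.
#' A 3D point is projected through the source; a 2D pixel is scaled from
#' the detector toward the source by SOD/SID.  A 3D point and the pixel
#' it projects to map to identical in-plane coordinates, which makes this
#' plane the natural space for 2D accuracy evaluation.
#'
#' @inheritParams project_point
#' @param p A 3-vector / n x 3 matrix of 3D points (mm), a
#'   [working_point()], or an n x 2 pixel matrix.
#' @return A 2-vector `(u_mm, v_mm)` or an n x 2 matrix.
#' @export
to_isocenter_plane <- function(geom, p) {
  s <- geom$source_mm
  if (inherits(p, "working_point") ||
      (!is.null(dim(p)) && ncol(p) == 2L) ||
      (is.null(dim(p)) && length(p) == 2L && !inherits(p, "ray"))) {
    dp <- pixel_to_detector_point(geom, p)
    if (is.null(dim(dp))) dp <- matrix(dp, 1L, 3L)
    q <- sweep(sweep(dp, 2L, s) * (geom$sod_mm / geom$sid_mm), 2L, s, "+")
  } else {
    P <- as_points3(p, "p")
    d <- sweep(P, 2L, s)
    depth <- drop(d %*% geom$normal)
    if (any(depth <= 1e-9))
      stop("degenerate depth: point at or behind the source plane", call. = FALSE)
    q <- sweep(d * (geom$sod_mm / depth), 2L, s, "+")
  }
  rel <- sweep(q, 2L, geom$isocenter_mm)
  out <- cbind(u_mm = drop(rel %*% geom$u_axis),
               v_mm = drop(rel %*% geom$v_axis))
  if (nrow(out) == 1L) drop(out) else out
}

#' Read / write a C-arm geometry configuration
#'
#' JSON with keys `primary_angle_deg`, `secondary_angle_deg`, `sod_mm`,
#' `sid_mm`, `pixel_spacing_mm`, `detector_size_px` and optional
#' `table_offset_mm`.
#'
#' @param path File path.
#' @return `read_geometry()` returns a [carm_pose()];
#'   `write_geometry()` returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("primary_angle_deg", "secondary_angle_deg", "sod_mm", "sid_mm")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("geometry config is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  carm_pose(cfg$primary_angle_deg, cfg$secondary_angle_deg,
            cfg$sod_mm, cfg$sid_mm,
            pixel_spacing_mm = cfg$pixel_spacing_mm %||% c(0.37, 0.37),
            detector_size_px = cfg$detector_size_px %||% c(512L, 512L),
            table_offset_mm = cfg$table_offset_mm %||% c(0, 0, 0))
}

#' @rdname read_geometry
#' @param pose A [carm_pose()].
#' @export
write_geometry <- function(pose, path) {
  if (!inherits(pose, "carm_pose"))
    stop("'pose' must be a carm_pose object", call. = FALSE)
  jsonlite::write_json(unclass(pose)[c("primary_angle_deg",
                                       "secondary_angle_deg", "sod_mm",
                                       "sid_mm", "pixel_spacing_mm",
                                       "detector_size_px", "table_offset_mm")],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
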