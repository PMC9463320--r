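# Fiducial-based 3D-3D point-set registration (orthogonal Procrustes /
# Umeyama for rigid and similarity, linear least squares for affine) and
# two-view epipolar triangulation, which provides the reference 3D
# reconstruction against which monoplane localization is scored.

#' Fit a 3D point-set transform from fiducial pairs
#'
#' Least-squares fit of a transform mapping `model` points onto `xr`
#' points.  `"rigid"` (rotation + translation) and `"similarity"`
#' (+ isotropic scale) use the SVD-based orthogonal Procrustes
#' construction; reflections are rejected (`det(R) = +1`), since anatomy
#' cannot mirror.  `"affine"` solves the full 12-parameter linear map and
#' needs at least 4 non-coplanar pairs.  Three non-collinear fiducials --
#' the minimum a clinical workflow provides -- exactly determine the
#' similarity fit, which is therefore the default mode.
#'
#' @param model n x 3 matrix of model-space fiducials (mm).
#' @param xr n x 3 matrix of the same fiducials reconstructed in XR
#'   space (mm).
#' @param mode `"similarity"` (default), `"rigid"`, or `"affine"`.
#' @return An object of class `"point_transform"`: fields `linear`
#'   (3 x 3), `translation`, `rotation`, `scale`, `mode`, `residuals_mm`
#'   (per-pair fiducial registration error), `rmse_mm`.
#' @export
fit_point_transform <- function(model, xr,
                                mode = c("similarity", "rigid", "affine")) {
  mode <- match.arg(mode)
  X <- as_points3(model, "model")
  Y <- as_points3(xr, "xr")
  n <- nrow(X)
  if (nrow(Y) != n) stop("'model' and 'xr' must pair up", call. = FALSE)
  if (mode %in% c("rigid", "similarity")) {
    if (n < 3L) stop("rigid/similarity fit needs >= 3 pairs", call. = FALSE)
    mx <- colMeans(X); my <- colMeans(Y)
    Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
    sv_x <- svd(Xc)$d
    if (sv_x[2L] < 1e-9 * max(sv_x[1L], 1))
      stop("degenerate fiducial configuration: model points are collinear",
           call. = FALSE)
    C <- crossprod(Yc, Xc) / n              # cov(y, x)
    sv <- svd(C)
    S <- diag(c(1, 1, sign(det(sv$u) * det(sv$v))))
    R <- sv$u %*% S %*% t(sv$v)
    scale <- if (mode == "similarity")
      sum(diag(S) * sv$d) / (sum(Xc^2) / n) else 1
    if (scale <= 0) stop("degenerate fit: non-positive scale", call. = FALSE)
    linear <- scale * R
    trans <- my - drop(linear %*% mx)
    rotation <- R
  } else {
    if (n < 4L) stop("affine fit needs >= 4 pairs", call. = FALSE)
    A <- cbind(X, 1)
    qrA <- qr(A)
    if (qrA$rank < 4L)
      stop("degenerate fiducial configuration: points are coplanar; affine fit needs 4 non-coplanar pairs",
           call. = FALSE)
    B <- qr.coef(qrA, Y)                   # 4 x 3
    linear <- t(B[1:3, , drop = FALSE])
    trans <- drop(B[4L, ])
    rotation <- NULL
    scale <- NA_real_
  }
  tf <- structure(list(linear = linear, translation = trans,
                       rotation = rotation, scale = scale, mode = mode),
                  class = "point_transform")
  res <- sqrt(rowSums((apply_transform(tf, X) - Y)^2))
  tf$residuals_mm <- res
  tf$rmse_mm <- sqrt(mean(res^2))
  tf
}

#' Apply a fitted point transform
#'
#' @param tf A [fit_point_transform()] result.
#' @param points 3-vector or n x 3 matrix (mm).
#' @return Transformed point(s), same shape as the input.
#' @export
apply_transform <- function(tf, points) {
  single <- is.null(dim(points))
  P <- as_points3(points, "points")
  out <- sweep(P %*% t(tf$linear), 2L, tf$translation, "+")
  if (single) drop(out) else out
}

#' @export
print.point_transform <- function(x, ...) {
  cat(sprintf("%s point transform, RMSE %.4g mm over %d pairs\n",
              x$mode, x$rmse_mm, length(x$residuals_mm)))
  if (!is.na(x$scale)) cat(sprintf("  scale %.6g\n", x$scale))
  invisible(x)
}

#' Serialize a point transform as a 4 x 4 homogeneous matrix (JSON)
#'
#' @inheritParams apply_transform
#' @param path Output JSON path (row-major 4 x 4 matrix).
#' @export
write_transform <- function(tf, path) {
  M <- rbind(cbind(tf$linear, tf$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = as.numeric(t(M))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- matrix(js$matrix, 4L, 4L, byrow = TRUE)
  structure(list(linear = M[1:3, 1:3], translation = M[1:3, 4L],
                 rotation = NULL, scale = NA_real_, mode = "loaded",
                 residuals_mm = numeric(0), rmse_mm = NA_real_),
            class = "point_transform")
}

#' Triangulate a 3D point from two projection rays
#'
#' Two-view epipolar reconstruction: the returned point is the midpoint
#' of the common perpendicular segment between the two back-projection
#' rays; `gap_mm` is that segment's length (0 when the rays intersect
#' exactly).  View pairs should be well separated (30 degrees or more in
#' practice); near-parallel rays are rejected.
#'
#' @param ray_a,ray_b [ray()] objects (e.g. from [pixel_to_ray()] in two
#'   views).
#' @return `list(point_mm, gap_mm)`.
#' @export
triangulate_two_views <- function(ray_a, ray_b) {
  if (!inherits(ray_a, "ray") || !inherits(ray_b, "ray"))
    stop("arguments must be ray objects", call. = FALSE)
  d1 <- ray_a$direction; d2 <- ray_b$direction
  sine <- vnorm(cross3(d1, d2))
  if (sine <= 1e-6)
    stop(sprintf("degenerate two-view geometry: rays are near-parallel (angle %.3g deg)",
                 rad2deg(asin(min(1, sine)))), call. = FALSE)
  w0 <- ray_a$origin_mm - ray_b$origin_mm
  b <- sum(d1 * d2)
  d <- sum(d1 * w0); e <- sum(d2 * w0)
  den <- 1 - b^2
  t1 <- (b * e - d) / den
  t2 <- (e - b * d) / den
  p1 <- ray_a$origin_mm + t1 * d1
  p2 <- ray_b$origin_mm + t2 * d2
  list(point_mm = (p1 + p2) / 2, gap_mm = vnorm(p1 - p2))
}

#' Triangulate paired 2D picks from two calibrated views
#'
#' Convenience wrapper composing [pixel_to_ray()] and
#' [triangulate_two_views()] over matched point lists.
#'
#' @param geom_a,geom_b [pose_to_geometry()] results for the two views.
#' @param points_a,points_b Matched n x 2 pixel matrices
#'   (`row_px`, `col_px`).
#' @return `list(points_mm = n x 3 matrix, gaps_mm = numeric n)`.
#' @export
triangulate_points <- function(geom_a, points_a, geom_b, points_b) {
  A <- as_working_points(points_a); B <- as_working_points(points_b)
  if (nrow(A) != nrow(B)) stop("point lists must pair up", call. = FALSE)
  pts <- matrix(NA_real_, nrow(A), 3L)
  gaps <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    tri <- triangulate_two_views(pixel_to_ray(geom_a, A[i, ]),
                                 pixel_to_ray(geom_b, B[i, ]))
    pts[i, ] <- tri$point_mm
    gaps[i] <- tri$gap_mm
  }
  list(points_mm = pts, gaps_mm = gaps)
}

#' Fiducial registration error summary
#'
#' 3D Euclidean distances between transformed model fiducials and their
#' XR-space reconstructions, summarized as mean/std/median/max.
#'
#' @inheritParams fit_point_transform
#' @param tf The fitted transform to evaluate.
#' @return An [error_summary()] of the per-fiducial 3D distances.
#' @export
registration_error <- function(model, xr, tf) {
  d <- ed3d(apply_transform(tf, as_points3(model)), as_points3(xr))
  summarize_errors(d)
}

#' Read fiducial pairs from CSV
#'
#' Expected columns: `set` (one of `model`, `xr`), `label`, `x`, `y`,
#' `z`; rows are matched across sets by `label`.
#'
#' @param path CSV path.
#' @return `list(model = n x 3, xr = n x 3, labels = character)`.
#' @export
read_fiducials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("set", "label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("fiducial CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  m <- df[df$set == "model", ]
  x <- df[df$set == "xr", ]
  labels <- intersect(m$label, x$label)
  if (length(labels) < 3L)
    stop("need >= 3 fiducial labels present in both sets", call. = FALSE)
  list(model = as.matrix(m[match(labels, m$label), c("x", "y", "z")]),
       xr = as.matrix(x[match(labels, x$label), c("x", "y", "z")]),
       labels = labels)
}
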