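# Accuracy metrics: 3D Euclidean distance (3D-ED) against a reference
# reconstruction, 2D Euclidean distance (2D-ED) on the iso-center plane
# parallel to the image plane (used when no 3D ground truth exists), and
# the mean/std/median/max summary convention.

#' Pairwise 3D Euclidean distances
#'
#' @param points_a,points_b Matched n x 3 matrices (mm).
#' @return Numeric vector of distances (mm).
#' @export
ed3d <- function(points_a, points_b) {
  A <- as_points3(points_a, "points_a")
  B <- as_points3(points_b, "points_b")
  if (nrow(A) != nrow(B))
    stop("'points_a' and 'points_b' must have equal length", call. = FALSE)
  sqrt(rowSums((A - B)^2))
}

#' 2D distances on the iso-center evaluation plane
#'
#' Projects localized 3D positions and picked 2D pixels onto the plane
#' through the iso-center parallel to the detector (see
#' [to_isocenter_plane()]) and returns the in-plane Euclidean distances
#' in mm.  This is the accuracy metric available when no 3D reference
#' exists: a detector-space picking offset of `k` mm appears here scaled
#' by SOD/SID.
#'
#' @param geom A [pose_to_geometry()] result.
#' @param localized_3d n x 3 matrix of localized 3D positions (mm).
#' @param picked_2d n x 2 pixel matrix (`row_px`, `col_px`).
#' @return Numeric vector of distances (mm).
#' @export
ed2d_isocenter <- function(geom, localized_3d, picked_2d) {
  P3 <- as_points3(localized_3d, "localized_3d")
  P2 <- as_working_points(picked_2d)
  if (nrow(P3) != nrow(P2))
    stop("'localized_3d' and 'picked_2d' must have equal length", call. = FALSE)
  a <- to_isocenter_plane(geom, P3)
  b <- to_isocenter_plane(geom, P2)
  if (is.null(dim(a))) a <- matrix(a, 1L, 2L)
  if (is.null(dim(b))) b <- matrix(b, 1L, 2L)
  sqrt(rowSums((a - b)^2))
}

#' Summarize a distance sample
#'
#' Mean, sample standard deviation (n - 1 denominator; 0 for a single
#' observation), median (midpoint convention for even n), and maximum.
#'
#' @param distances Non-empty numeric vector of non-negative distances.
#' @return An object of class `"error_summary"` with fields `mean_mm`,
#'   `std_mm`, `median_mm`, `max_mm`, `n`.
#' @export
summarize_errors <- function(distances) {
  d <- as.numeric(distances)
  if (!length(d) || anyNA(d) || any(!is.finite(d)))
    stop("'distances' must be a non-empty finite numeric vector", call. = FALSE)
  if (any(d < 0)) stop("'distances' must be non-negative", call. = FALSE)
  structure(list(mean_mm = mean(d),
                 std_mm = if (length(d) > 1L) stats::sd(d) else 0,
                 median_mm = stats::median(d),
                 max_mm = max(d),
                 n = length(d)),
            class = "error_summary")
}

#' @rdname summarize_errors
#' @export
error_summary <- summarize_errors

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("m = %.2f mm, std = %.2f mm, mdn = %.2f mm, max = %.2f mm (n = %d)\n",
              x$mean_mm, x$std_mm, x$median_mm, x$max_mm, x$n))
  invisible(x)
}

#' @export
as.data.frame.error_summary <- function(x, ...) {
  data.frame(mean_mm = x$mean_mm, std_mm = x$std_mm, median_mm = x$median_mm,
             max_mm = x$max_mm, n = x$n)
}
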