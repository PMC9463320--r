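# Monoplane 3D localization: among the candidate centerline points c,
# select the one whose ray to the X-ray source s is most parallel to the
# back-projection ray of the picked 2D point, by minimizing the
# cross-product objective
#
#     || (c - s) x (p'_2D - s) ||^2 ,
#
# where p'_2D is the picked pixel embedded on the detector plane in 3D.
# Since ||(c - s) x w|| = ||w|| * dist(c, ray) for fixed w = p'_2D - s,
# the argmin coincides with the candidate closest to the projection ray
# in the perpendicular sense; the objective is kept in its raw
# (unnormalized) cross-product form.

# Candidate table (flattened tree, ordered by branch then index) with an
# optional row subset given as a data.frame(branch_id, index).
candidate_table <- function(tree, candidates = NULL, points = NULL) {
  pts <- points %||% tree_points(tree)
  if (is.null(candidates)) return(pts)
  if (!all(c("branch_id", "index") %in% names(candidates)))
    stop("'candidates' must have columns branch_id and index", call. = FALSE)
  sel <- match(paste(candidates$branch_id, candidates$index),
               paste(pts$branch_id, pts$index))
  if (anyNA(sel))
    stop("candidate subset contains points not in the tree", call. = FALSE)
  out <- pts[sort(sel), , drop = FALSE]   # keep deterministic tree order
  if (!nrow(out)) stop("empty candidate set", call. = FALSE)
  out
}

#' Localize a 2D working point in 3D on a centerline tree
#'
#' Selects the candidate centerline point minimizing the cross-product
#' objective `||(c - s) x (p'_2D - s)||^2`, i.e. the point whose
#' projection ray is most parallel to the working point's back-projection
#' ray.  Ties are broken by smaller perpendicular distance to the ray,
#' then by lower `(branch_id, index)`.  The result is flagged
#' `ambiguous` when the best point on any *other* branch comes within a
#' relative tolerance of the minimum -- the superimposed-centerline
#' situation in which single-view localization cannot distinguish
#' branches and an operator or the continuity restriction of
#' [localize_sequence()] must disambiguate.
#'
#' The tree must already be registered into XR coordinates (see
#' [fit_point_transform()]); the function does not check frames.
#'
#' @param geom A [pose_to_geometry()] result.
#' @param p2d A [working_point()] or `(row_px, col_px)` pair.
#' @param tree A [centerline_tree()] in XR coordinates.
#' @param candidates Optional data frame (`branch_id`, `index`)
#'   restricting the candidate set (e.g. a [centerline_neighborhood()]).
#' @param ambiguity_tol Relative objective tolerance for the ambiguity
#'   flag (default 0.01, i.e. 1%).
#' @return An object of class `"localization_result"`: `point_mm`,
#'   `branch_id`, `index`, `objective`, `perp_dist_mm`, `ambiguous`,
#'   `n_candidates`.
#' @export
localize <- function(geom, p2d, tree, candidates = NULL,
                     ambiguity_tol = 0.01) {
  cand <- candidate_table(tree, candidates)
  localize_impl(geom, p2d, cand, ambiguity_tol)
}

localize_impl <- function(geom, p2d, cand, ambiguity_tol = 0.01) {
  if (!nrow(cand)) stop("empty candidate set", call. = FALSE)
  p <- as_working_points(p2d)
  if (nrow(p) != 1L) stop("localize() expects a single working point", call. = FALSE)
  s <- geom$source_mm
  w <- pixel_to_detector_point(geom, p) - s
  cx <- cand$x - s[1L]; cy <- cand$y - s[2L]; cz <- cand$z - s[3L]
  vx <- cy * w[3L] - cz * w[2L]
  vy <- cz * w[1L] - cx * w[3L]
  vz <- cx * w[2L] - cy * w[1L]
  obj <- vx * vx + vy * vy + vz * vz
  best <- which.min(obj)                   # first minimum = lowest (branch, index)
  wn2 <- sum(w * w)
  perp <- sqrt(obj / wn2)
  # numerical floor: objectives below a 1e-6 mm perpendicular distance
  # are indistinguishable from an exact hit
  floor_obj <- (1e-6)^2 * wn2
  other <- cand$branch_id != cand$branch_id[best]
  ambiguous <- any(other) &&
    min(obj[other]) <= obj[best] * (1 + ambiguity_tol) + floor_obj
  structure(list(point_mm = c(cand$x[best], cand$y[best], cand$z[best]),
                 branch_id = cand$branch_id[best],
                 index = cand$index[best],
                 objective = obj[best],
                 perp_dist_mm = perp[best],
                 ambiguous = ambiguous,
                 n_candidates = nrow(cand)),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("3D localization: branch '%s' index %d at (%.2f, %.2f, %.2f) mm\n",
              x$branch_id, x$index, x$point_mm[1], x$point_mm[2],
              x$point_mm[3]))
  cat(sprintf("  perp. ray distance %.4g mm over %d candidates%s\n",
              x$perp_dist_mm, x$n_candidates,
              if (x$ambiguous) " [AMBIGUOUS: near-tie on another branch]" else ""))
  invisible(x)
}

#' Localize an ordered 2D point sequence with continuity restriction
#'
#' Localizes each working point of a sequence (e.g. a device pulled
#' through a vessel across frames).  The first point is localized over
#' the full tree, or fixed to an operator-approved initial position when
#' `init` is given; every subsequent point is localized only among
#' centerline points within `window_mm` geodesic distance of the
#' previous result.  This continuity restriction removes wrong-branch
#' assignments caused by branches that superimpose in projection but are
#' distant along the vessel tree.
#'
#' @inheritParams localize
#' @param points2d n x 2 matrix or data frame of pixel coordinates
#'   (`row_px`, `col_px`), in temporal order.
#' @param window_mm Geodesic continuity window in mm (> 0); default 10.
#'   Must exceed the device's inter-frame travel while staying below the
#'   along-tree distance to any superimposed branch.
#' @param init Optional initial 3D position: a `"localization_result"`
#'   or `list(branch_id =, index =)`.  When given, the first frame's
#'   result is fixed to this point.
#' @param geom Either a single geometry (static gantry) or a list of
#'   per-frame geometries.
#' @return A data frame with one row per frame: `frame`, `row_px`,
#'   `col_px`, `branch_id`, `index`, `x`, `y`, `z`, `arclen_mm`,
#'   `objective`, `perp_dist_mm`, `ambiguous`, `n_candidates`.
#' @export
localize_sequence <- function(geom, points2d, tree, window_mm = 10,
                              init = NULL, ambiguity_tol = 0.01) {
  P <- as_working_points(points2d)
  n <- nrow(P)
  if (!n) stop("'points2d' must be non-empty", call. = FALSE)
  check_scalar(window_mm, "window_mm", positive = TRUE)
  geoms <- if (inherits(geom, "projection_geometry")) rep(list(geom), n)
           else geom
  if (length(geoms) != n)
    stop("'geom' must be one geometry or one per frame", call. = FALSE)
  tg <- tree_graph(tree)
  results <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    if (i == 1L && !is.null(init)) {
      cand <- candidate_table(tree,
                              data.frame(branch_id = init$branch_id,
                                         index = init$index),
                              points = tg$points)
      res <- localize_impl(geoms[[i]], P[i, ], cand, ambiguity_tol)
    } else {
      cand_sub <- if (is.null(prev)) NULL else {
        nb <- centerline_neighborhood(tree, prev$branch_id, prev$index,
                                      window_mm, graph = tg)
        if (!nrow(nb))
          stop(sprintf("empty continuity neighborhood at frame %d; increase 'window_mm' (currently %g mm)",
                       i, window_mm), call. = FALSE)
        nb
      }
      cand <- candidate_table(tree, cand_sub, points = tg$points)
      res <- localize_impl(geoms[[i]], P[i, ], cand, ambiguity_tol)
    }
    results[[i]] <- res
    prev <- res
  }
  arclen <- vapply(results, function(r)
    tree$branches[[r$branch_id]]$cum_arclen_mm[r$index], 0)
  data.frame(frame = seq_len(n),
             row_px = P[, 1L], col_px = P[, 2L],
             branch_id = vapply(results, `[[`, "", "branch_id"),
             index = vapply(results, `[[`, 0L, "index"),
             x = vapply(results, function(r) r$point_mm[1L], 0),
             y = vapply(results, function(r) r$point_mm[2L], 0),
             z = vapply(results, function(r) r$point_mm[3L], 0),
             arclen_mm = arclen,
             objective = vapply(results, `[[`, 0, "objective"),
             perp_dist_mm = vapply(results, `[[`, 0, "perp_dist_mm"),
             ambiguous = vapply(results, `[[`, TRUE, "ambiguous"),
             n_candidates = vapply(results, `[[`, 0L, "n_candidates"),
             stringsAsFactors = FALSE)
}

#' Fraction of localizations on the correct branch
#'
#' @param results A [localize_sequence()] data frame, a list of
#'   localization results, or a character vector of branch ids.
#' @param truth_branch_ids Character vector of true branch ids, same
#'   length.
#' @return Fraction in `[0, 1]`.
#' @export
branch_accuracy <- function(results, truth_branch_ids) {
  got <- if (is.data.frame(results)) results$branch_id
         else if (is.list(results)) vapply(results, `[[`, "", "branch_id")
         else as.character(results)
  if (!length(got)) stop("'results' must be non-empty", call. = FALSE)
  if (length(got) != length(truth_branch_ids))
    stop("'results' and 'truth_branch_ids' must have equal length",
         call. = FALSE)
  mean(got == as.character(truth_branch_ids))
}
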