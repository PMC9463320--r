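# Branched vascular centerline trees: ordered 3D polylines with arc-length
# parameterization, optional per-point radii, and parent/child topology.
# The flattened point set of a registered tree is the candidate set for
# monoplane 3D localization.

#' Create a centerline branch
#'
#' An ordered 3D polyline with cumulative arc length, an optional
#' per-point vessel radius, and an optional attachment to a parent
#' branch.
#'
#' @param points_mm n x 3 matrix of ordered points (mm), n >= 2, with
#'   strictly positive consecutive spacing.
#' @param branch_id Character identifier, unique within a tree.
#' @param radius_mm Optional per-point vessel radius (length n).
#' @param parent Optional `list(branch_id =, index =)` naming the parent
#'   branch and the 1-based point index where this branch attaches.
#' @return An object of class `"centerline_branch"`.
#' @export
centerline_branch <- function(points_mm, branch_id, radius_mm = NULL,
                              parent = NULL) {
  P <- as_points3(points_mm, "points_mm")
  if (nrow(P) < 2L)
    stop("a centerline branch needs at least 2 points", call. = FALSE)
  seg <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  if (any(seg <= 0))
    stop(sprintf("branch '%s' has zero-length segment(s); consecutive points must be distinct",
                 branch_id), call. = FALSE)
  if (!is.null(radius_mm)) {
    radius_mm <- as.numeric(radius_mm)
    if (length(radius_mm) != nrow(P) || any(!is.finite(radius_mm)) ||
        any(radius_mm <= 0))
      stop(sprintf("branch '%s': 'radius_mm' must be %d positive values",
                   branch_id, nrow(P)), call. = FALSE)
  }
  if (!is.null(parent)) {
    if (!all(c("branch_id", "index") %in% names(parent)))
      stop("'parent' must be list(branch_id =, index =)", call. = FALSE)
    parent <- list(branch_id = as.character(parent$branch_id),
                   index = as.integer(parent$index))
  }
  structure(list(branch_id = as.character(branch_id),
                 points_mm = P,
                 cum_arclen_mm = c(0, cumsum(seg)),
                 radius_mm = radius_mm,
                 parent = parent),
            class = "centerline_branch")
}

#' Assemble branches into a centerline tree
#'
#' @param branches A list of [centerline_branch()] objects with unique
#'   ids; parent references must resolve to earlier-declared branches and
#'   in-range attachment indices.
#' @return An object of class `"centerline_tree"`.
#' @export
centerline_tree <- function(branches) {
  if (inherits(branches, "centerline_branch")) branches <- list(branches)
  if (!length(branches) ||
      !all(vapply(branches, inherits, TRUE, "centerline_branch")))
    stop("'branches' must be a non-empty list of centerline_branch objects",
         call. = FALSE)
  ids <- vapply(branches, `[[`, "", "branch_id")
  if (anyDuplicated(ids))
    stop("branch ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(branches) <- ids
  for (b in branches) {
    if (is.null(b$parent)) next
    pb <- branches[[b$parent$branch_id]]
    if (is.null(pb))
      stop(sprintf("branch '%s' references unknown parent '%s'",
                   b$branch_id, b$parent$branch_id), call. = FALSE)
    if (b$parent$index < 1L || b$parent$index > nrow(pb$points_mm))
      stop(sprintf("branch '%s': attachment index %d out of range for parent '%s'",
                   b$branch_id, b$parent$index, b$parent$branch_id),
           call. = FALSE)
  }
  structure(list(branches = branches), class = "centerline_tree")
}

#' @export
print.centerline_tree <- function(x, ...) {
  np <- vapply(x$branches, function(b) nrow(b$points_mm), 0L)
  cat(sprintf("Centerline tree: %d branch(es), %d points, total length %.1f mm\n",
              length(x$branches), sum(np), tree_length(x)))
  for (b in x$branches)
    cat(sprintf("  %s: %d points, %.1f mm%s\n", b$branch_id,
                nrow(b$points_mm), max(b$cum_arclen_mm),
                if (is.null(b$parent)) "" else
                  sprintf(" (from %s @ %d)", b$parent$branch_id,
                          b$parent$index)))
  invisible(x)
}

#' Total polyline length of a tree
#' @param tree A [centerline_tree()].
#' @return Total arc length in mm (junction gaps excluded).
#' @export
tree_length <- function(tree) {
  sum(vapply(tree$branches, function(b) max(b$cum_arclen_mm), 0))
}

# Flatten a tree to one point table (branch order preserved, index
# ascending) -- the candidate enumeration used by the localizer.
tree_points <- function(tree) {
  dfs <- lapply(tree$branches, function(b) {
    data.frame(branch_id = b$branch_id,
               index = seq_len(nrow(b$points_mm)),
               x = b$points_mm[, 1L], y = b$points_mm[, 2L],
               z = b$points_mm[, 3L],
               arclen_mm = b$cum_arclen_mm,
               radius_mm = if (is.null(b$radius_mm)) NA_real_ else b$radius_mm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.centerline_tree <- function(x, ...) tree_points(x)

#' Resample a centerline tree at uniform arc-length spacing
#'
#' Each branch is re-parameterized by arc length with uniform spacing
#' (the final segment may be shorter so that the endpoint is preserved
#' exactly); coordinates and radii are linearly interpolated between the
#' original points.  Parent attachment indices are remapped to the
#' resampled point nearest in arc length.
#'
#' The localizer can only return sampled points, so half the spacing is
#' the intrinsic sampling contribution to its 3D error; spacing should be
#' chosen below the projection's pixel footprint at the iso-center.
#'
#' @param tree A [centerline_tree()].
#' @param spacing_mm Target spacing in mm (> 0); default 0.5.
#' @return A resampled [centerline_tree()].
#' @export
resample_centerline <- function(tree, spacing_mm = 0.5) {
  check_scalar(spacing_mm, "spacing_mm", positive = TRUE)
  old <- tree$branches
  new <- lapply(old, function(b) {
    L <- max(b$cum_arclen_mm)
    s <- seq(0, L, by = spacing_mm)
    if (L - s[length(s)] > 1e-9 * max(1, L)) s <- c(s, L)
    s[length(s)] <- L                      # endpoint exact
    P <- vapply(1:3, function(k)
      stats::approx(b$cum_arclen_mm, b$points_mm[, k], xout = s)$y,
      numeric(length(s)))
    # exact endpoints (approx() is exact at knots, this guards rounding)
    P[1L, ] <- b$points_mm[1L, ]
    P[length(s), ] <- b$points_mm[nrow(b$points_mm), ]
    r <- if (is.null(b$radius_mm)) NULL else
      stats::approx(b$cum_arclen_mm, b$radius_mm, xout = s)$y
    list(points = P, radius = r, s = s)
  })
  rebuilt <- vector("list", length(old))
  for (i in seq_along(old)) {
    b <- old[[i]]
    parent <- b$parent
    if (!is.null(parent)) {
      pb <- old[[parent$branch_id]]
      target <- pb$cum_arclen_mm[parent$index]
      j <- match(parent$branch_id, names(old))
      parent$index <- which.min(abs(new[[j]]$s - target))
    }
    rebuilt[[i]] <- centerline_branch(new[[i]]$points, b$branch_id,
                                      radius_mm = new[[i]]$radius,
                                      parent = parent)
  }
  centerline_tree(rebuilt)
}

# Undirected weighted graph over all tree points: consecutive points
# within a branch (edge weight = segment length) plus a junction edge
# from each child's first point to its parent attachment point (weight =
# Euclidean gap, or a minimal positive weight when coincident).
tree_graph <- function(tree) {
  pts <- tree_points(tree)
  key <- paste(pts$branch_id, pts$index)
  offset <- c(0, cumsum(vapply(tree$branches,
                               function(b) nrow(b$points_mm), 0L)))
  names(offset) <- c(names(tree$branches), "")
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_along(tree$branches)) {
    b <- tree$branches[[i]]
    n <- nrow(b$points_mm)
    idx <- offset[i] + seq_len(n)
    from <- c(from, idx[-n]); to <- c(to, idx[-1L])
    w <- c(w, diff(b$cum_arclen_mm))
    if (!is.null(b$parent)) {
      pj <- match(b$parent$branch_id, names(tree$branches))
      pidx <- offset[pj] + b$parent$index
      gap <- vnorm(b$points_mm[1L, ] -
                     tree$branches[[pj]]$points_mm[b$parent$index, ])
      from <- c(from, pidx); to <- c(to, idx[1L])
      w <- c(w, max(gap, 1e-12))
    }
  }
  g <- igraph::make_empty_graph(n = nrow(pts), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  list(graph = g, points = pts, key = key)
}

#' Geodesic neighborhood of a centerline point
#'
#' All tree points whose along-tree (geodesic, through branch junctions)
#' distance from the query point is at most `window_mm`; the query point
#' itself is always included.  Geodesic rather than Euclidean proximity
#' is what excludes branches that are superimposed in projection but far
#' along the vessel tree -- the mechanism behind the continuity
#' restriction of sequential localization.
#'
#' @param tree A [centerline_tree()].
#' @param branch_id,index Query point (1-based index within its branch).
#' @param window_mm Geodesic radius in mm (>= 0).
#' @param graph Optional precomputed result of the internal tree graph
#'   builder (reused across calls by [localize_sequence()]).
#' @return A data frame with columns `branch_id`, `index`,
#'   `geodesic_mm`.
#' @export
centerline_neighborhood <- function(tree, branch_id, index, window_mm,
                                    graph = NULL) {
  if (window_mm < 0) stop("'window_mm' must be >= 0", call. = FALSE)
  tg <- graph %||% tree_graph(tree)
  v <- match(paste(branch_id, index), tg$key)
  if (is.na(v))
    stop(sprintf("no point (branch '%s', index %s) in the tree",
                 branch_id, index), call. = FALSE)
  d <- drop(igraph::distances(tg$graph, v = v))
  sel <- which(d <= window_mm + 1e-9)
  out <- tg$points[sel, c("branch_id", "index")]
  out$geodesic_mm <- d[sel]
  rownames(out) <- NULL
  out
}
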