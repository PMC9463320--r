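# Template tracking of a device marker across 2D frames by zero-mean
# normalized cross-correlation (ZNCC), feeding per-frame monoplane 3D
# localization.  Frames are numeric matrices indexed [row, col]; pixel
# coordinates are 0-based at pixel centers, matching the geometry module.

#' Initialize a template track
#'
#' Extracts the template patch centered on the given pixel of the first
#' frame.  The template stays fixed across frames by default (no drift);
#' an exponential template update is available via `update_alpha`.
#'
#' @param image Numeric matrix (grayscale frame), `image[row, col]`.
#' @param center_px `(row, col)` 0-based integer pixel of the marker.
#' @param template_size_px Odd `(height, width)` of the template patch,
#'   both >= 3; a single odd number is accepted. Default 21.
#' @param search_radius_px Maximum per-frame displacement searched, in
#'   pixels (>= 1); default 20.
#' @param update_alpha Template update weight in `[0, 1)`; 0 (default)
#'   keeps the initial template fixed.
#' @param template Optional appearance-model template (odd-sized numeric
#'   matrix) used instead of the extracted patch -- matched filtering
#'   with a designed marker model, which avoids baking one frame's noise
#'   into the template.  Its dimensions override `template_size_px`.
#' @param subpixel Default sub-pixel refinement policy applied by
#'   [track_next()] (3-point parabolic interpolation around the integer
#'   correlation peak); `FALSE` by default.
#' @return An object of class `"track_state"`.
#' @export
init_track <- function(image, center_px, template_size_px = c(21L, 21L),
                       search_radius_px = 20, update_alpha = 0,
                       template = NULL, subpixel = FALSE) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix", call. = FALSE)
  if (!is.null(template)) {
    if (!is.matrix(template) || !is.numeric(template))
      stop("'template' must be a numeric matrix", call. = FALSE)
    template_size_px <- dim(template)
  }
  if (length(template_size_px) == 1L)
    template_size_px <- rep(template_size_px, 2L)
  template_size_px <- as.integer(template_size_px)
  if (any(template_size_px < 3L) || any(template_size_px %% 2L == 0L))
    stop("'template_size_px' must be odd and >= 3", call. = FALSE)
  if (search_radius_px < 1)
    stop("'search_radius_px' must be >= 1", call. = FALSE)
  if (update_alpha < 0 || update_alpha >= 1)
    stop("'update_alpha' must be in [0, 1)", call. = FALSE)
  center_px <- as.integer(round(center_px))
  patch <- template %||% extract_patch(image, center_px, template_size_px)
  # the window must fit the image even for a supplied template
  invisible(extract_patch(image, center_px, template_size_px))
  structure(list(template = patch,
                 center_px = as.numeric(center_px),
                 template_size_px = template_size_px,
                 search_radius_px = as.numeric(search_radius_px),
                 update_alpha = update_alpha,
                 subpixel = isTRUE(subpixel),
                 score = NA_real_),
            class = "track_state")
}

#' Gaussian marker appearance template
#'
#' An isotropic Gaussian intensity model of a blob-like device marker,
#' centered on the template, for matched-filter tracking via the
#' `template` argument of [init_track()].
#'
#' @param size_px Odd template side length in pixels.
#' @param sigma_px Gaussian sigma of the marker appearance in pixels.
#' @return A `size_px` x `size_px` numeric matrix with unit peak.
#' @export
gaussian_template <- function(size_px = 21L, sigma_px = 2) {
  size_px <- as.integer(size_px)
  if (size_px < 3L || size_px %% 2L == 0L)
    stop("'size_px' must be odd and >= 3", call. = FALSE)
  check_scalar(sigma_px, "sigma_px", positive = TRUE)
  h <- (size_px - 1L) / 2
  g <- exp(-((-h):h)^2 / (2 * sigma_px^2))
  outer(g, g)
}

# 0-based center, odd (h, w); errors when the window leaves the image.
extract_patch <- function(image, center_px, size_px) {
  h2 <- (size_px[1L] - 1L) %/% 2L
  w2 <- (size_px[2L] - 1L) %/% 2L
  r <- center_px[1L]; c <- center_px[2L]
  if (r - h2 < 0L || r + h2 > nrow(image) - 1L ||
      c - w2 < 0L || c + w2 > ncol(image) - 1L)
    stop(sprintf("template window at (%d, %d) exceeds image bounds (%d x %d)",
                 r, c, nrow(image), ncol(image)), call. = FALSE)
  image[(r - h2):(r + h2) + 1L, (c - w2):(c + w2) + 1L, drop = FALSE]
}

#' Track the marker into the next frame
#'
#' Evaluates the zero-mean normalized cross-correlation between the
#' template and every candidate window whose center lies within the
#' search radius of the current center (and whose window fits inside the
#' image), and moves the track to the best-scoring center.  Exact score
#' ties are broken by the smallest displacement, then row-major order.
#' Optional 3-point parabolic interpolation around the integer peak
#' refines the center to sub-pixel precision (off by default).
#'
#' @param state A [init_track()] / previous `track_next()` state.
#' @param image Next frame (numeric matrix of the same size regime).
#' @param subpixel Logical; parabolic sub-pixel refinement of the peak.
#'   Defaults to the policy stored in the state.
#' @return The updated `"track_state"`; field `score` holds the winning
#'   correlation in `[-1, 1]`.
#' @export
track_next <- function(state, image, subpixel = state$subpixel) {
  if (!inherits(state, "track_state"))
    stop("'state' must be a track_state", call. = FALSE)
  tz <- state$template - mean(state$template)
  tn <- sqrt(sum(tz * tz))
  if (tn == 0)
    stop("tracking lost: template has zero variance", call. = FALSE)
  h2 <- (state$template_size_px[1L] - 1L) %/% 2L
  w2 <- (state$template_size_px[2L] - 1L) %/% 2L
  rad <- as.integer(ceiling(state$search_radius_px))
  c0 <- as.integer(round(state$center_px))
  rows <- max(h2, c0[1L] - rad):min(nrow(image) - 1L - h2, c0[1L] + rad)
  cols <- max(w2, c0[2L] - rad):min(ncol(image) - 1L - w2, c0[2L] + rad)
  if (!length(rows) || !length(cols) || rows[1L] > rows[length(rows)] ||
      cols[1L] > cols[length(cols)])
    stop("search window lies outside the image", call. = FALSE)
  score <- matrix(-Inf, length(rows), length(cols))
  any_var <- FALSE
  npx <- length(tz)
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    win <- image[(rows[i] - h2):(rows[i] + h2) + 1L,
                 (cols[j] - w2):(cols[j] + w2) + 1L]
    wz <- win - sum(win) / npx
    wn <- sqrt(sum(wz * wz))
    if (wn > 0) {
      any_var <- TRUE
      score[i, j] <- sum(tz * wz) / (tn * wn)
    }
  }
  if (!any_var)
    stop("tracking lost: flat (zero-variance) search region", call. = FALSE)
  best <- max(score)
  hits <- which(score >= best, arr.ind = TRUE)
  if (nrow(hits) > 1L) {
    disp <- (rows[hits[, 1L]] - state$center_px[1L])^2 +
      (cols[hits[, 2L]] - state$center_px[2L])^2
    hits <- hits[order(disp, hits[, 1L], hits[, 2L]), , drop = FALSE]
  }
  br <- rows[hits[1L, 1L]]; bc <- cols[hits[1L, 2L]]
  center <- c(br, bc)
  if (subpixel) {
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    center <- center + c(parabolic_offset(score, i, j, dim = 1L),
                         parabolic_offset(score, i, j, dim = 2L))
  }
  state$center_px <- as.numeric(center)
  state$score <- best
  if (state$update_alpha > 0) {
    patch <- extract_patch(image, c(br, bc), state$template_size_px)
    state$template <- (1 - state$update_alpha) * state$template +
      state$update_alpha * patch
  }
  state
}

# One-dimensional 3-point parabolic peak refinement along matrix dim.
parabolic_offset <- function(score, i, j, dim) {
  get <- function(di, dj) {
    ii <- i + di; jj <- j + dj
    if (ii < 1L || ii > nrow(score) || jj < 1L || jj > ncol(score))
      return(NA_real_)
    v <- score[ii, jj]
    if (is.finite(v)) v else NA_real_
  }
  if (dim == 1L) { m <- get(-1L, 0L); p <- get(1L, 0L) }
  else { m <- get(0L, -1L); p <- get(0L, 1L) }
  c0 <- score[i, j]
  if (is.na(m) || is.na(p)) return(0)
  den <- m - 2 * c0 + p
  if (den >= 0) return(0)                  # not a proper peak
  off <- 0.5 * (m - p) / den
  max(-0.5, min(0.5, off))
}

#' Track a marker across frames and localize each position in 3D
#'
#' Composes [track_next()] over a frame sequence with
#' [localize_sequence()]: the marker is followed in 2D by normalized
#' cross-correlation and each tracked pixel is localized on the
#' registered centerline tree under the continuity restriction.  If
#' tracking fails mid-sequence the frames tracked so far are still
#' localized and the failure is reported in `status`.
#'
#' @param frames Non-empty list of numeric matrices (the image
#'   sequence).
#' @param geom A [pose_to_geometry()] result (or list, one per frame).
#' @param tree A registered [centerline_tree()].
#' @param init_px `(row, col)` marker pixel in `frames[[1]]`.
#' @param window_mm Continuity window for [localize_sequence()].
#' @param init Optional initial 3D position passed to
#'   [localize_sequence()].
#' @param ... Further arguments to [init_track()] (template size, search
#'   radius, update alpha).
#' @return `list(track, results, status)`: `track` is a per-frame data
#'   frame (`frame`, `row_px`, `col_px`, `score`), `results` the
#'   localization data frame, `status` `"ok"` or
#'   `"lost_at_frame_<k>: <reason>"`.
#' @export
track_and_localize <- function(frames, geom, tree, init_px, window_mm = 10,
                               init = NULL, ...) {
  if (!length(frames)) stop("'frames' must be non-empty", call. = FALSE)
  state <- init_track(frames[[1L]], init_px, ...)
  centers <- matrix(NA_real_, length(frames), 2L)
  scores <- rep(NA_real_, length(frames))
  centers[1L, ] <- state$center_px
  status <- "ok"
  n_ok <- 1L
  if (length(frames) > 1L) for (k in 2L:length(frames)) {
    state <- tryCatch(track_next(state, frames[[k]]), error = identity)
    if (inherits(state, "error")) {
      status <- sprintf("lost_at_frame_%d: %s", k, conditionMessage(state))
      break
    }
    centers[k, ] <- state$center_px
    scores[k] <- state$score
    n_ok <- k
  }
  track <- data.frame(frame = seq_len(n_ok),
                      row_px = centers[seq_len(n_ok), 1L],
                      col_px = centers[seq_len(n_ok), 2L],
                      score = scores[seq_len(n_ok)])
  results <- localize_sequence(geom_subset(geom, n_ok),
                               track[, c("row_px", "col_px")], tree,
                               window_mm = window_mm, init = init)
  list(track = track, results = results, status = status)
}

geom_subset <- function(geom, n) {
  if (inherits(geom, "projection_geometry")) geom else geom[seq_len(n)]
}
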