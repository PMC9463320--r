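# Centerline file formats: a CSV/JSON dialect and a minimal legacy VTK
# ASCII polydata reader/writer (one polyline cell per branch, optional
# "Radius" point-data array).  The JSON dialect is the only one that
# carries branch topology; CSV and VTK store branches as independent
# polylines.

#' Read / write centerline trees
#'
#' Supported formats: `"csv"` (columns `branch_id, x, y, z[, radius]`),
#' `"json"` (branch list including parent topology), and `"vtk"` (legacy
#' ASCII polydata with one `LINES` cell per branch and an optional
#' `Radius` point-data array).  CSV and VTK drop parent topology; JSON
#' round-trips it.
#'
#' @param path File path.
#' @param format One of `"csv"`, `"json"`, `"vtk"`; default guessed from
#'   the file extension.
#' @return `read_centerline()` returns a [centerline_tree()];
#'   `write_centerline()` returns `path` invisibly.
#' @export
read_centerline <- function(path, format = NULL) {
  format <- format %||% guess_centerline_format(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         csv = read_centerline_csv(path),
         json = read_centerline_json(path),
         vtk = read_centerline_vtk(path),
         stop("unknown centerline format: ", format, call. = FALSE))
}

#' @rdname read_centerline
#' @param tree A [centerline_tree()].
#' @export
write_centerline <- function(tree, path, format = NULL) {
  if (!inherits(tree, "centerline_tree"))
    stop("'tree' must be a centerline_tree", call. = FALSE)
  format <- format %||% guess_centerline_format(path)
  switch(format,
         csv = write_centerline_csv(tree, path),
         json = write_centerline_json(tree, path),
         vtk = write_centerline_vtk(tree, path),
         stop("unknown centerline format: ", format, call. = FALSE))
  invisible(path)
}

guess_centerline_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = "csv", json = "json", vtk = "vtk", vtp = "vtk",
         stop("cannot guess centerline format from extension '.", ext,
              "'; pass 'format'", call. = FALSE))
}

num_fmt <- function(x) sprintf("%.9g", x)

read_centerline_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("branch_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("centerline CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!stats::complete.cases(df[, c("x", "y", "z")]))
  if (length(bad))
    stop(sprintf("centerline CSV has missing coordinate(s) at data row %d",
                 bad[1L]), call. = FALSE)
  branches <- lapply(split(df, factor(df$branch_id,
                                      levels = unique(df$branch_id))),
                     function(d)
                       centerline_branch(as.matrix(d[, c("x", "y", "z")]),
                                         d$branch_id[1L],
                                         radius_mm = if ("radius" %in% names(d) &&
                                                         !anyNA(d$radius))
                                           d$radius))
  centerline_tree(unname(branches))
}

write_centerline_csv <- function(tree, path) {
  pts <- tree_points(tree)
  df <- data.frame(branch_id = pts$branch_id,
                   x = num_fmt(pts$x), y = num_fmt(pts$y),
                   z = num_fmt(pts$z), stringsAsFactors = FALSE)
  if (!all(is.na(pts$radius_mm))) df$radius <- num_fmt(pts$radius_mm)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_centerline_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(js$branches)) stop("centerline JSON lacks 'branches'", call. = FALSE)
  branches <- lapply(js$branches, function(b) {
    P <- matrix(unlist(b$points_mm), ncol = 3L, byrow = TRUE)
    parent <- if (!is.null(b$parent))
      list(branch_id = b$parent$branch_id, index = b$parent$index)
    centerline_branch(P, b$branch_id,
                      radius_mm = if (length(b$radius_mm)) unlist(b$radius_mm),
                      parent = parent)
  })
  centerline_tree(unname(branches))
}

write_centerline_json <- function(tree, path) {
  out <- list(branches = lapply(unname(tree$branches), function(b) {
    x <- list(branch_id = b$branch_id,
              points_mm = apply(b$points_mm, 1L, as.numeric, simplify = FALSE))
    if (!is.null(b$radius_mm)) x$radius_mm <- b$radius_mm
    if (!is.null(b$parent)) x$parent <- b$parent
    x
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
}

write_centerline_vtk <- function(tree, path) {
  pts <- tree_points(tree)
  n <- nrow(pts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "centerline tree", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(paste(num_fmt(pts$x), num_fmt(pts$y), num_fmt(pts$z)), con)
  sizes <- vapply(tree$branches, function(b) nrow(b$points_mm), 0L)
  writeLines(sprintf("LINES %d %d", length(sizes), sum(sizes + 1L)), con)
  off <- c(0L, cumsum(sizes))
  for (i in seq_along(sizes))
    writeLines(paste(c(sizes[i], off[i] + seq_len(sizes[i]) - 1L),
                     collapse = " "), con)
  if (!all(is.na(pts$radius_mm))) {
    writeLines(c(sprintf("POINT_DATA %d", n), "SCALARS Radius double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(num_fmt(pts$radius_mm), con)
  }
}

read_centerline_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fail <- function(i, msg)
    stop(sprintf("%s (line %d of %s)", msg, i, basename(path)), call. = FALSE)
  ip <- grep("^POINTS", lines)
  if (!length(ip)) fail(1L, "no POINTS section in VTK polydata")
  n <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1L]][2L])
  if (is.na(n) || n < 1L) fail(ip, "malformed POINTS header")
  coords <- numeric(0)
  i <- ip
  while (length(coords) < 3L * n) {
    i <- i + 1L
    if (i > length(lines)) fail(length(lines), "POINTS section truncated")
    tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    if (anyNA(tok)) fail(i, "non-numeric coordinates in POINTS")
    coords <- c(coords, tok)
  }
  P <- matrix(coords[seq_len(3L * n)], ncol = 3L, byrow = TRUE)
  il <- grep("^LINES", lines)
  if (!length(il)) fail(1L, "no LINES section in VTK polydata")
  nl <- as.integer(strsplit(trimws(lines[il]), "\\s+")[[1L]][2L])
  cells <- vector("list", nl)
  for (k in seq_len(nl)) {
    row <- as.integer(strsplit(trimws(lines[il + k]), "\\s+")[[1L]])
    if (anyNA(row) || length(row) != row[1L] + 1L)
      fail(il + k, "malformed LINES cell")
    cells[[k]] <- row[-1L] + 1L           # VTK indices are 0-based
  }
  radius <- NULL
  ir <- grep("^SCALARS\\s+Radius", lines)
  if (length(ir)) {
    vals <- as.numeric(unlist(strsplit(trimws(
      lines[(ir + 2L):length(lines)]), "\\s+")))
    radius <- vals[seq_len(n)]
    if (anyNA(radius)) fail(ir + 2L, "malformed Radius point data")
  }
  branches <- lapply(seq_along(cells), function(k) {
    idx <- cells[[k]]
    if (any(idx < 1L | idx > n)) fail(il + k, "point index out of range")
    centerline_branch(P[idx, , drop = FALSE], sprintf("branch_%02d", k),
                      radius_mm = if (!is.null(radius)) radius[idx])
  })
  centerline_tree(branches)
}
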