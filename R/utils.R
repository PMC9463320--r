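# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(x) sqrt(sum(x * x))

unitv <- function(x) {
  n <- vnorm(x)
  if (!is.finite(n) || n < 1e-300)
    stop("cannot normalize a zero-length vector", call. = FALSE)
  x / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

as_point3 <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric 3-vector", what), call. = FALSE)
  x
}

as_points3 <- function(x, what = "points") {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L || any(!is.finite(x)))
    stop(sprintf("'%s' must be a finite n x 3 numeric matrix", what), call. = FALSE)
  dimnames(x) <- NULL
  x
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a sub-seed from a base seed, keeping it inside the 32-bit
# integer range R requires.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

check_scalar <- function(x, field, positive = FALSE, finite = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", field), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0 (got %g)", field, x), call. = FALSE)
  invisible(as.numeric(x))
}
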