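# Internal helpers shared across modules. All coordinates are nm,
# right-handed, z = tomographic axis.

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Any unit vector orthogonal to n.
orthobasis <- function(n) {
  n <- unitize(n)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(cross3(n, ref))
  v <- cross3(n, u)
  list(u = u, v = v, n = n)
}

# Rotate unit vector `from` toward unit vector `to` by at most `max_deg`.
rotate_toward <- function(from, to, max_deg) {
  cosang <- max(-1, min(1, sum(from * to)))
  ang <- acos(cosang)
  cap <- max_deg * pi / 180
  if (ang <= cap) return(to)
  # slerp by cap/ang
  t <- cap / ang
  w <- sin((1 - t) * ang) / sin(ang) * from + sin(t * ang) / sin(ang) * to
  unitize(w)
}

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rotation matrix from axis-angle (axis any 3-vector, angle radians).
rotation_matrix <- function(axis, angle) {
  a <- unitize(axis)
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  x <- a[1]; y <- a[2]; z <- a[3]
  matrix(c(
    x * x * C + c_,     x * y * C - z * s,  x * z * C + y * s,
    y * x * C + z * s,  y * y * C + c_,     y * z * C - x * s,
    z * x * C - y * s,  z * y * C + x * s,  z * z * C + c_
  ), nrow = 3, byrow = TRUE)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s must be finite", what), call. = FALSE)
}
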