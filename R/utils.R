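# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
vnorm <- function(v) sqrt(sum(v^2))

#' @noRd
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stopf("cannot normalize a zero-length vector")
  v / n
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle between two vectors, degrees, in [0, 180].
#' @noRd
vec_angle <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# Rotation matrix (3x3) for rotation by `theta_deg` about unit `axis`
# (row-vector convention: x %*% R rotates x).
#' @noRd
rotation_about <- function(axis, theta_deg) {
  u <- unit(axis)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  R <- matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
    nrow = 3, byrow = TRUE)
  t(R)
}

# Minimum squared distance between two coordinate blocks (plain Euclidean).
#' @noRd
min_dist2_block <- function(xa, xb) {
  # rows of xa vs rows of xb; vectorized over the smaller block
  if (nrow(xa) > nrow(xb)) return(min_dist2_block(xb, xa))
  best <- Inf
  for (i in seq_len(nrow(xa))) {
    d2 <- (xb[, 1] - xa[i, 1])^2 + (xb[, 2] - xa[i, 2])^2 + (xb[, 3] - xa[i, 3])^2
    m <- min(d2)
    if (m < best) best <- m
  }
  best
}
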