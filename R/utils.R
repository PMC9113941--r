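# Small vector-geometry helpers shared across modules. All angles in degrees
# unless a function name says otherwise; all coordinates in Angstrom.

vnorm <- function(x) sqrt(sum(x * x))

unitv <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  x / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

## wrap an angle in degrees into (-180, 180]
wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

## fold an angle between two undirected axes into [0, 90]
fold90 <- function(a) {
  a <- abs(wrap180(a))
  ifelse(a > 90, 180 - a, a)
}

## unsigned angle between two vectors, degrees in [0, 180]
angle_between <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

## Rodrigues rotation matrix: angle degrees about (unnormalized) axis
rotation_about <- function(axis, angle_deg) {
  k <- unitv(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## coerce an n x 3 matrix-like object, with checks
as_points <- function(x, what = "points") {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(what, " must be an n x 3 matrix")
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop(what, " contain non-finite coordinates")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
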