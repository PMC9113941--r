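#' Anchor base-pair indices for the nucleosome reference frame
#'
#' The per-nucleosome frame is anchored at three base pairs: the central base
#' pair of the wrapped core (point 1, on the dyad), the base pair 38 bp
#' upstream of it (point 2) and the base pair 39 bp downstream (point 3).
#' Points 2 and 3 sit on the two different DNA gyres across from the dyad.
#'
#' @param core_start 1-based index of the first core base pair within the
#'   track.
#' @param core_len core length in base pairs; must be odd so that a central
#'   base pair exists (canonical 147).
#' @param upstream,downstream offsets of points 2 and 3 from the central base
#'   pair (defaults 38 and 39).
#' @return integer vector `c(i1, i2, i3)` of track indices.
#' @export
#' @examples
#' anchor_indices(1, 147)   # c(74, 36, 113)
#' anchor_indices(31, 147)  # shifted by a 30-bp entry linker
anchor_indices <- function(core_start, core_len = 147L,
                           upstream = 38L, downstream = 39L) {
  core_start <- as.integer(core_start)
  core_len <- as.integer(core_len)
  if (core_len %% 2L == 0L)
    stop("core_len must be odd: a ", core_len,
         "-bp core has no central base pair")
  i1 <- core_start + (core_len - 1L) %/% 2L
  i2 <- i1 - as.integer(upstream)
  i3 <- i1 + as.integer(downstream)
  core_end <- core_start + core_len - 1L
  if (i2 < core_start || i3 > core_end)
    stop("anchor offsets (", upstream, ", ", downstream,
         ") leave the core [", core_start, ", ", core_end, "]")
  c(i1 = i1, i2 = i2, i3 = i3)
}

#' Build the per-nucleosome reference frame
#'
#' From the three anchor base-pair centroids the frame derives: `v`, the
#' gyre-to-gyre vector from point 2 to point 3, approximating the normal of
#' the nucleosome disc; `u`, from the midpoint of points 2/3 toward point 1,
#' approximating the dyad axis; and `w`, the normalized cross product of `u`
#' and `v`. The plane spanned by `u` and `v` is the plane perpendicular to
#' the disc (used for the angle beta); the plane spanned by `u` and `w` is
#' the disc plane (used for alpha).
#'
#' @param track a [bp_track] object (or bare n x 3 centroid matrix with
#'   `core_start`/`core_len` supplied).
#' @param core_start,core_len,upstream,downstream see [anchor_indices()];
#'   taken from the track when it is a `bp_track`.
#' @return an object of class `nuc_frame`: list with anchor points `p1`,
#'   `p2`, `p3`, unit vectors `u`, `v`, `w`, and orthonormal 2-column bases
#'   `disc_basis` (u, w) and `perp_basis` (u, v orthonormalized against u).
#' @export
build_frame <- function(track, core_start = NULL, core_len = NULL,
                        upstream = 38L, downstream = 39L) {
  if (inherits(track, "bp_track")) {
    core_start <- core_start %||% track$core_start
    core_len <- core_len %||% track$core_len
    pts <- track$centroids
  } else {
    pts <- as_points(track, "centroids")
    if (is.null(core_start) || is.null(core_len))
      stop("core_start and core_len are required for a bare centroid matrix")
  }
  idx <- anchor_indices(core_start, core_len, upstream, downstream)
  if (max(idx) > nrow(pts)) stop("track shorter than the anchor indices")
  p1 <- pts[idx[1], ]; p2 <- pts[idx[2], ]; p3 <- pts[idx[3], ]

  v_raw <- p3 - p2
  u_raw <- p1 - (p2 + p3) / 2
  if (vnorm(v_raw) < 1e-9 || vnorm(u_raw) < 1e-9)
    stop("degenerate frame: coincident anchor points")
  u <- unitv(u_raw)
  v <- unitv(v_raw)
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  if (vnorm(cr) < 1e-6)
    stop("degenerate frame: anchor points are collinear (u parallel to v)")
  w <- unitv(cr)
  ## Gram-Schmidt: component of v orthogonal to u; equals w x u exactly
  v_perp <- unitv(v - sum(v * u) * u)

  structure(list(
    p1 = p1, p2 = p2, p3 = p3,
    u = u, v = v, w = w,
    disc_basis = cbind(b1 = u, b2 = w),
    perp_basis = cbind(b1 = u, b2 = v_perp),
    anchors = idx
  ), class = "nuc_frame")
}

#' @export
print.nuc_frame <- function(x, ...) {
  cat("<nuc_frame> anchors bp", paste(x$anchors, collapse = "/"), "\n")
  cat("  u (dyad approx):       ", sprintf("% .4f", x$u), "\n")
  cat("  v (disc-normal approx):", sprintf("% .4f", x$v), "\n")
  cat("  w (u x v):             ", sprintf("% .4f", x$w), "\n")
  invisible(x)
}

## apply a rigid (or general linear+shift) map to a frame
transform_frame <- function(frame, rotation, translation = c(0, 0, 0)) {
  tp <- function(p) as.numeric(rotation %*% p + translation)
  tv <- function(p) as.numeric(rotation %*% p)
  structure(list(
    p1 = tp(frame$p1), p2 = tp(frame$p2), p3 = tp(frame$p3),
    u = tv(frame$u), v = tv(frame$v), w = tv(frame$w),
    disc_basis = cbind(b1 = tv(frame$disc_basis[, 1]),
                       b2 = tv(frame$disc_basis[, 2])),
    perp_basis = cbind(b1 = tv(frame$perp_basis[, 1]),
                       b2 = tv(frame$perp_basis[, 2])),
    anchors = frame$anchors
  ), class = "nuc_frame")
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' ordered point sets, with the standard determinant guard so a reflection is
#' never returned. The transform maps `ref_points` onto `tgt_points`.
#'
#' @param ref_points,tgt_points n x 3 matrices, same n >= 3, not all
#'   collinear.
#' @return object of class `rigid_transform`: list with 3 x 3 `rotation`
#'   (det +1), length-3 `translation`, and the minimized `rmsd` in Angstrom.
#' @export
superpose <- function(ref_points, tgt_points) {
  A <- as_points(ref_points, "ref_points")
  B <- as_points(tgt_points, "tgt_points")
  if (nrow(A) != nrow(B)) stop("point sets differ in size")
  if (nrow(A) < 3) stop("superposition needs at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  ## collinearity check on the reference
  if (sum(svd(A0)$d > 1e-8) < 2)
    stop("degenerate configuration: points are collinear")
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cb - as.numeric(R %*% ca)
  fitted <- sweep(A0 %*% t(R), 2, cb, FUN = "+")
  rmsd <- sqrt(mean(rowSums((fitted - B) ^ 2)))
  structure(list(rotation = R, translation = tvec, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or vectors
#'
#' @param tf a `rigid_transform` from [superpose()].
#' @param x n x 3 matrix or length-3 vector.
#' @param vector if `TRUE`, apply the rotation only (for direction vectors).
#' @return transformed coordinates, same shape as `x`.
#' @export
apply_transform <- function(tf, x, vector = FALSE) {
  stopifnot(inherits(tf, "rigid_transform"))
  one <- is.null(dim(x))
  m <- if (one) matrix(x, 1, 3) else as_points(x)
  out <- m %*% t(tf$rotation)
  if (!vector) out <- sweep(out, 2, tf$translation, FUN = "+")
  if (one) as.numeric(out) else out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}
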