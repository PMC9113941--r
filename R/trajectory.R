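#' Linker DNA vector on one side of a nucleosome
#'
#' The linker trajectory on each side is summarized by one vector, from the
#' centroid of the base pair 5 bp into the positioning sequence (point 4,
#' counted inclusively from the core edge) to the centroid of the base pair
#' 10 bp outside of it (point 5). A side whose linker has fewer than
#' `outside_offset` resolved base pairs yields `defined = FALSE` (not an
#' error); all downstream angles are then `NA`.
#'
#' @param track a [bp_track] with a complete core.
#' @param side `"entry"` or `"exit"`.
#' @param into_offset base pairs into the core for point 4 (default 5, i.e.
#'   the 5th core base pair from that side's edge).
#' @param outside_offset base pairs outside the core for point 5 (default
#'   10, the 10th linker base pair outward).
#' @return object of class `linker_vector`: list with `side`, `p4`, `p5`,
#'   unit `direction` (p4 -> p5, pointing away from the core) and `defined`.
#' @export
linker_vector <- function(track, side = c("entry", "exit"),
                          into_offset = 5L, outside_offset = 10L) {
  side <- match.arg(side)
  stopifnot(inherits(track, "bp_track"))
  n <- nrow(track$centroids)
  cs <- track$core_start
  ce <- cs + track$core_len - 1L
  if (side == "entry") {
    i4 <- cs + (into_offset - 1L)
    i5 <- cs - outside_offset
  } else {
    i4 <- ce - (into_offset - 1L)
    i5 <- ce + outside_offset
  }
  if (i5 < 1L || i5 > n) {
    return(structure(list(side = side, p4 = NULL, p5 = NULL,
                          direction = NULL, defined = FALSE),
                     class = "linker_vector"))
  }
  p4 <- track$centroids[i4, ]
  p5 <- track$centroids[i5, ]
  structure(list(side = side, p4 = p4, p5 = p5,
                 direction = unitv(p5 - p4), defined = TRUE),
            class = "linker_vector")
}

#' Signed angle of a vector after projection onto a frame plane
#'
#' Projects `vec` onto the selected plane of the nucleosome frame (removing
#' the component along the plane normal) and returns the signed angle from
#' `u` to the projection, in degrees in (-180, 180]. The sign is read from
#' the plane's second basis vector: `w` for the disc plane (angle alpha),
#' the orthonormalized gyre vector for the perpendicular plane (angle
#' beta).
#'
#' @param frame a [build_frame()] result.
#' @param vec 3-vector (any nonzero length).
#' @param plane `"disc"` (span u, w) or `"perp"` (span u, v).
#' @return signed degrees, or `NA` if the projection is numerically zero
#'   (vector parallel to the plane normal).
#' @export
projected_angle <- function(frame, vec, plane = c("disc", "perp")) {
  plane <- match.arg(plane)
  stopifnot(inherits(frame, "nuc_frame"))
  basis <- if (plane == "disc") frame$disc_basis else frame$perp_basis
  a <- sum(vec * basis[, 1])
  b <- sum(vec * basis[, 2])
  if (sqrt(a * a + b * b) <= 1e-9 * vnorm(vec)) return(NA_real_)
  wrap180(rad2deg(atan2(b, a)))
}

#' Linker trajectory angles alpha and beta
#'
#' beta is the angle between the nucleosome dyad and the linker DNA duplex
#' axis after projection onto the plane perpendicular to the nucleosome
#' disc; alpha is the same angle after projection onto the plane of the
#' nucleosome disc. Both are signed, per linker side.
#'
#' @param track a [bp_track]; alternatively pass a precomputed `frame` and
#'   list of `linkers`.
#' @param frame optional [build_frame()] result (computed from `track` when
#'   omitted).
#' @param linkers optional named list `list(entry = , exit = )` of
#'   [linker_vector()] results.
#' @param into_offset,outside_offset see [linker_vector()].
#' @return object of class `traj_angles`: data frame with columns `side`,
#'   `alpha`, `beta`, `defined`.
#' @export
trajectory_angles <- function(track = NULL, frame = NULL, linkers = NULL,
                              into_offset = 5L, outside_offset = 10L) {
  if (is.null(frame)) frame <- build_frame(track)
  if (is.null(linkers))
    linkers <- list(
      entry = linker_vector(track, "entry", into_offset, outside_offset),
      exit = linker_vector(track, "exit", into_offset, outside_offset))
  one <- function(lv) {
    if (!lv$defined) return(c(alpha = NA_real_, beta = NA_real_))
    c(alpha = projected_angle(frame, lv$direction, "disc"),
      beta = projected_angle(frame, lv$direction, "perp"))
  }
  ent <- one(linkers$entry); ext <- one(linkers$exit)
  out <- data.frame(
    side = c("entry", "exit"),
    alpha = c(ent["alpha"], ext["alpha"]),
    beta = c(ent["beta"], ext["beta"]),
    defined = c(linkers$entry$defined, linkers$exit$defined),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("traj_angles", "data.frame")
  out
}

#' Deviation of linker angles from a superposed reference nucleosome
#'
#' The reference mononucleosome's 147 core base-pair centroids are rigid-body
#' superposed (Kabsch) onto the target's core; its linker vectors are mapped
#' through the fitted rotation; then, per defined target side, delta-beta is
#' the unsigned angle between the target and mapped-reference linker vectors
#' after projecting both onto the target frame's perpendicular plane
#' (delta-alpha analogously in the disc plane). With consistent signed
#' angles this equals `|signed angle(target) - signed angle(reference,
#' mapped)|`, and the two readings are asserted identical in the test suite.
#'
#' @param target,reference [bp_track]s with complete cores; the reference
#'   must have both linker sides defined.
#' @param reference_id identifier recorded in the result.
#' @param into_offset,outside_offset see [linker_vector()].
#' @return object of class `delta_angles`: list with data frame `per_side`
#'   (`side`, `delta_alpha`, `delta_beta`, `defined`), scalars
#'   `avg_delta_alpha`, `avg_delta_beta` (means over defined sides),
#'   `reference_id`, and the superposition `rmsd`.
#' @export
delta_angles <- function(target, reference, reference_id = "reference",
                         into_offset = 5L, outside_offset = 10L) {
  stopifnot(inherits(target, "bp_track"), inherits(reference, "bp_track"))
  ref_link <- list(
    entry = linker_vector(reference, "entry", into_offset, outside_offset),
    exit = linker_vector(reference, "exit", into_offset, outside_offset))
  if (!ref_link$entry$defined || !ref_link$exit$defined)
    stop("reference '", reference_id, "' must have both linker sides ",
         "defined (>= ", outside_offset, " bp each)")
  if (target$core_len != reference$core_len)
    stop("target and reference core lengths differ")

  tf <- superpose(core_centroids(reference), core_centroids(target))
  tgt_frame <- build_frame(target)
  tgt_link <- list(
    entry = linker_vector(target, "entry", into_offset, outside_offset),
    exit = linker_vector(target, "exit", into_offset, outside_offset))

  one <- function(side) {
    tl <- tgt_link[[side]]
    if (!tl$defined)
      return(c(delta_alpha = NA_real_, delta_beta = NA_real_))
    rdir <- apply_transform(tf, ref_link[[side]]$direction, vector = TRUE)
    da <- proj_delta(tgt_frame, tl$direction, rdir, "disc")
    db <- proj_delta(tgt_frame, tl$direction, rdir, "perp")
    c(delta_alpha = da, delta_beta = db)
  }
  ent <- one("entry"); ext <- one("exit")
  per_side <- data.frame(
    side = c("entry", "exit"),
    delta_alpha = c(ent["delta_alpha"], ext["delta_alpha"]),
    delta_beta = c(ent["delta_beta"], ext["delta_beta"]),
    defined = c(tgt_link$entry$defined, tgt_link$exit$defined),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    per_side = per_side,
    avg_delta_alpha = mean(per_side$delta_alpha, na.rm = TRUE),
    avg_delta_beta = mean(per_side$delta_beta, na.rm = TRUE),
    reference_id = reference_id,
    rmsd = tf$rmsd
  ), class = "delta_angles")
}

## unsigned angle between the in-plane projections of two vectors
## (atan2 form: exact at zero, unlike acos)
proj_delta <- function(frame, vec_a, vec_b, plane) {
  basis <- if (plane == "disc") frame$disc_basis else frame$perp_basis
  pa <- c(sum(vec_a * basis[, 1]), sum(vec_a * basis[, 2]))
  pb <- c(sum(vec_b * basis[, 1]), sum(vec_b * basis[, 2]))
  if (vnorm(pa) <= 1e-9 || vnorm(pb) <= 1e-9) return(NA_real_)
  cr <- pa[1] * pb[2] - pa[2] * pb[1]
  dt <- pa[1] * pb[1] + pa[2] * pb[2]
  abs(rad2deg(atan2(cr, dt)))
}

#' @export
print.delta_angles <- function(x, ...) {
  cat("<delta_angles> vs", x$reference_id,
      sprintf("(core rmsd %.3f A)\n", x$rmsd))
  print(x$per_side, digits = 4)
  cat(sprintf("  avg delta-alpha %.3f  avg delta-beta %.3f (deg)\n",
              x$avg_delta_alpha, x$avg_delta_beta))
  invisible(x)
}
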