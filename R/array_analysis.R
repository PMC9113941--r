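#' Pairwise nucleosome stacking geometry
#'
#' Quantifies the relative arrangement of two nucleosomes: distance between
#' core-centroid means, angle between the disc normals (the gyre-to-gyre
#' `v` axes, folded to \[0, 90\]), angle between the dyad `u` axes (dyad
#' tilt, folded), and the component of the center-to-center vector
#' perpendicular to the mean disc normal (lateral offset). A pair is
#' classed as stacked when the centers are within `max_distance` and the
#' disc normals within `max_normal_angle`; stacked pairs split into
#' `"face-to-face aligned"` vs `"face-to-face offset"` at
#' `offset_split` Angstrom of lateral offset.
#'
#' All fields are symmetric under exchanging the two nucleosomes.
#'
#' @param track_a,track_b [bp_track]s with complete cores.
#' @param max_distance,max_normal_angle,offset_split classification
#'   thresholds (defaults 75 Angstrom, 30 degrees, 15 Angstrom).
#' @return object of class `stack_geometry`: list with `pair`,
#'   `center_distance`, `normal_angle`, `dyad_tilt`, `lateral_offset`
#'   (numbers), `stacked` (logical) and `interface_class`.
#' @export
stack_metrics <- function(track_a, track_b, max_distance = 75,
                          max_normal_angle = 30, offset_split = 15) {
  fa <- build_frame(track_a); fb <- build_frame(track_b)
  ca <- colMeans(core_centroids(track_a))
  cb <- colMeans(core_centroids(track_b))
  d <- cb - ca
  center_distance <- vnorm(d)
  normal_angle <- fold90(angle_between(fa$v, fb$v))
  dyad_tilt <- fold90(angle_between(fa$u, fb$u))
  ## mean disc normal with signs aligned
  vb <- if (sum(fa$v * fb$v) < 0) -fb$v else fb$v
  nhat <- unitv(fa$v + vb)
  lateral_offset <- vnorm(d - sum(d * nhat) * nhat)
  stacked <- center_distance <= max_distance &&
    normal_angle <= max_normal_angle
  interface_class <- if (!stacked) "not stacked"
    else if (lateral_offset <= offset_split) "face-to-face aligned"
    else "face-to-face offset"
  structure(list(pair = c(track_a$label, track_b$label),
                 center_distance = center_distance,
                 normal_angle = normal_angle, dyad_tilt = dyad_tilt,
                 lateral_offset = lateral_offset, stacked = stacked,
                 interface_class = interface_class,
                 thresholds = c(max_distance = max_distance,
                                max_normal_angle = max_normal_angle,
                                offset_split = offset_split)),
            class = "stack_geometry")
}

#' @export
print.stack_geometry <- function(x, ...) {
  cat("<stack_geometry>", paste(x$pair, collapse = " - "), ":",
      x$interface_class, "\n")
  cat(sprintf("  center %.1f A, normal angle %.1f deg, dyad tilt %.1f deg, lateral offset %.1f A\n",
              x$center_distance, x$normal_angle, x$dyad_tilt,
              x$lateral_offset))
  invisible(x)
}

#' Detect stacked nucleosome pairs in an array
#'
#' Classifies every pair of nucleosomes with [stack_metrics()] and returns
#' the stacked ones sorted by center distance.
#'
#' @param tracks list of two or more [bp_track]s.
#' @param ... thresholds forwarded to [stack_metrics()].
#' @return list with `pairs` (data frame of stacked pairs: labels, the four
#'   metrics, interface class; zero rows when none) and `all` (the full
#'   list of `stack_geometry` objects).
#' @export
detect_stacks <- function(tracks, ...) {
  if (length(tracks) < 2) stop("need at least two nucleosomes")
  combos <- utils::combn(length(tracks), 2)
  all <- apply(combos, 2, function(ij)
    stack_metrics(tracks[[ij[1]]], tracks[[ij[2]]], ...))
  rows <- do.call(rbind, lapply(all, function(s) data.frame(
    a = s$pair[1], b = s$pair[2], center_distance = s$center_distance,
    normal_angle = s$normal_angle, dyad_tilt = s$dyad_tilt,
    lateral_offset = s$lateral_offset, stacked = s$stacked,
    interface_class = s$interface_class, stringsAsFactors = FALSE)))
  pairs <- rows[rows$stacked, , drop = FALSE]
  pairs <- pairs[order(pairs$center_distance), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, all = all)
}

#' Classify H1-binding compatibility from linker-angle deviations
#'
#' A nucleosome is called compatible with on-dyad H1 binding when the
#' deviation delta-beta of every defined linker side from the reference is
#' at most `threshold` degrees (inclusive): one strongly deviating linker
#' suffices to lose the stabilizing H1-linker contact. A nucleosome with no
#' defined linker side yields an indeterminate call (a first-class state,
#' never coerced to `FALSE`).
#'
#' @param delta a [delta_angles()] result.
#' @param threshold degrees, default 6.
#' @param nucleosome label recorded in the call.
#' @param observed_h1 optional annotation of observed occupancy.
#' @return object of class `h1_call`: list with `nucleosome`, `per_side`
#'   delta-beta values, `avg_delta_beta`, `compatible` (`TRUE`/`FALSE`/`NA`
#'   for indeterminate), `status`, `threshold`, `observed_h1`.
#' @export
classify_h1 <- function(delta, threshold = 6, nucleosome = "nuc",
                        observed_h1 = NA) {
  stopifnot(inherits(delta, "delta_angles"))
  db <- delta$per_side$delta_beta[delta$per_side$defined]
  db <- db[!is.na(db)]
  if (length(db) == 0) {
    compatible <- NA
    status <- "indeterminate"
  } else {
    compatible <- all(db <= threshold)
    status <- if (compatible) "compatible" else "incompatible"
  }
  structure(list(nucleosome = nucleosome,
                 per_side = delta$per_side[, c("side", "delta_beta",
                                               "defined")],
                 avg_delta_beta = delta$avg_delta_beta,
                 compatible = compatible, status = status,
                 threshold = threshold, observed_h1 = observed_h1),
            class = "h1_call")
}

#' @export
print.h1_call <- function(x, ...) {
  cat("<h1_call>", x$nucleosome, ":", x$status,
      sprintf("(avg delta-beta %.2f deg, threshold %.1f)\n",
              x$avg_delta_beta, x$threshold))
  invisible(x)
}

#' Coarse steric screen for H1 placement
#'
#' Maps the reference's H1 pseudo-atom footprint onto a target nucleosome
#' by superposing the reference core base-pair centroids onto the target
#' core, then counts environment points lying within `cutoff + radius` of
#' any footprint sphere center. A deviated linker trajectory that sweeps
#' into the H1 wedge shows up as clashes; a relaxed trajectory does not.
#'
#' @param target a [bp_track] (complete core).
#' @param reference a [synthetic_reference()]-style `nuc_reference`
#'   carrying a footprint (error if absent).
#' @param environment n x 3 matrix of environment coordinates, typically
#'   every base-pair centroid of the array except the target's own core
#'   (the target's linkers belong in the environment: their trajectory is
#'   what can occlude H1).
#' @param cutoff clearance added to each sphere radius, Angstrom
#'   (default 4).
#' @return object of class `steric_screen`: list with `count` and
#'   `contacts` (data frame: sphere name, environment row, distance,
#'   clash distance).
#' @export
steric_screen <- function(target, reference, environment, cutoff = 4) {
  reference <- as_reference(reference)
  if (is.null(reference$footprint))
    stop("reference '", reference$id, "' carries no H1 footprint")
  stopifnot(inherits(target, "bp_track"))
  env <- as_points(environment, "environment")
  tf <- superpose(core_centroids(reference$track), core_centroids(target))
  centers <- apply_transform(tf, as.matrix(
    reference$footprint[, c("x", "y", "z")]))
  contacts <- NULL
  for (i in seq_len(nrow(centers))) {
    dd <- sqrt(rowSums(sweep(env, 2, centers[i, ]) ^ 2))
    lim <- cutoff + reference$footprint$radius[i]
    hit <- which(dd < lim)
    if (length(hit))
      contacts <- rbind(contacts, data.frame(
        sphere = reference$footprint$name[i], env_row = hit,
        distance = dd[hit], clash_distance = lim,
        stringsAsFactors = FALSE))
  }
  if (is.null(contacts))
    contacts <- data.frame(sphere = character(0), env_row = integer(0),
                           distance = numeric(0),
                           clash_distance = numeric(0),
                           stringsAsFactors = FALSE)
  structure(list(count = nrow(contacts), contacts = contacts,
                 cutoff = cutoff, target = target$label,
                 reference_id = reference$id),
            class = "steric_screen")
}

#' @export
print.steric_screen <- function(x, ...) {
  cat("<steric_screen>", x$target, "vs", x$reference_id, ":",
      x$count, "clash(es) at cutoff", x$cutoff, "A\n")
  invisible(x)
}
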