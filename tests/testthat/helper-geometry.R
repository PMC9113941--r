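# Shared helpers: small geometric constructions used across test files.

## deterministic random proper rotation (det +1)
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  axis <- stats::rnorm(3)
  nucgeom:::rotation_about(axis, stats::runif(1, 0, 360))
}

## apply a rigid motion to a bp_track
move_track <- function(track, R, t) {
  bp_track(sweep(track$centroids %*% t(R), 2, t, FUN = "+"),
           core_start = track$core_start, core_len = track$core_len,
           label = track$label, h1_present = track$h1_present)
}

## canonical mononucleosome track: core plus straight linkers realizing the
## given measured (alpha, beta) per side; entry/exit NULL drops that linker
mono_track <- function(entry = reference_angles()$entry,
                       exit = reference_angles()$exit,
                       linker_len = 30L, label = "mono") {
  core <- build_core()
  C <- core$track$centroids
  fr <- core$truth$frame
  en <- if (!is.null(entry))
    nucgeom:::linker_points(C, fr, "entry", entry[1], entry[2], linker_len)
  ex <- if (!is.null(exit))
    nucgeom:::linker_points(C, fr, "exit", exit[1], exit[2], linker_len)
  pts <- rbind(if (!is.null(en)) en[rev(seq_len(nrow(en))), ], C, ex)
  bp_track(pts, core_start = if (is.null(en)) 1L else linker_len + 1L,
           core_len = nrow(C), label = label)
}

## closed-form superhelix point for the canonical core parameters
superhelix_point <- function(i, radius = 41.9, pitch = 25.9,
                             turns = 146 / 77, core_len = 147L) {
  i1 <- (core_len + 1L) / 2L
  phi <- -2 * pi * turns / (core_len - 1) * (i - i1)
  c(radius * cos(phi), radius * sin(phi),
    pitch * turns / (core_len - 1) * (i - i1))
}

## minimal pseudo-atom PDB/mmCIF writer helpers live in the package;
## tests that need tiny atom models build them with this
write_mini_pdb <- function(path, atoms) {
  # atoms: data.frame chain, resno, resname, name, element, x, y, z
  fmt <- "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  lines <- sprintf(fmt, seq_len(nrow(atoms)), atoms$name, atoms$resname,
                   atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
                   atoms$element)
  writeLines(c(lines, "END"), path)
  path
}
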