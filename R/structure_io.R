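#' Base-pair centroid track
#'
#' The universal substrate of all geometry operations: the ordered 3-D
#' centroids of the base pairs of one nucleosome plus its flanking linker
#' DNA, listed 5'→3' along strand I, with the register of the 147-bp core
#' annotated.
#'
#' @param centroids n x 3 matrix of base-pair centroids (Angstrom).
#' @param core_start 1-based index of the first core base pair.
#' @param core_len core length in bp (default 147).
#' @param label nucleosome label, e.g. `"nuc1"`.
#' @param h1_present annotation: was a linker histone observed on this
#'   nucleosome (from the registry/model)? Never inferred by the package;
#'   the classifier predicts compatibility independently so the two can be
#'   compared.
#' @return object of class `bp_track`.
#' @export
bp_track <- function(centroids, core_start, core_len = 147L,
                     label = "nuc", h1_present = NA) {
  centroids <- as_points(centroids, "centroids")
  core_start <- as.integer(core_start)
  core_len <- as.integer(core_len)
  n <- nrow(centroids)
  if (core_start < 1L || core_len < 1L)
    stop("core_start and core_len must be positive")
  if (core_start + core_len - 1L > n)
    stop("core [", core_start, ", ", core_start + core_len - 1L,
         "] does not fit in a ", n, "-bp track")
  structure(list(centroids = centroids, core_start = core_start,
                 core_len = core_len, label = as.character(label),
                 h1_present = h1_present),
            class = "bp_track")
}

#' @export
print.bp_track <- function(x, ...) {
  n <- nrow(x$centroids)
  cat("<bp_track> ", x$label, ": ", n, " bp (core ", x$core_start, "-",
      x$core_start + x$core_len - 1L, ", entry linker ",
      entry_linker_len(x), " bp, exit linker ", exit_linker_len(x),
      " bp)\n", sep = "")
  invisible(x)
}

#' @rdname bp_track
#' @param x a `bp_track`.
#' @export
entry_linker_len <- function(x) x$core_start - 1L

#' @rdname bp_track
#' @export
exit_linker_len <- function(x)
  nrow(x$centroids) - (x$core_start + x$core_len - 1L)

core_centroids <- function(x)
  x$centroids[x$core_start:(x$core_start + x$core_len - 1L), , drop = FALSE]

#' Read an atomic model from PDB or mmCIF
#'
#' Thin wrapper over bio3d returning a flat atom table. Only ATOM/HETATM
#' records of the first model are kept; hydrogens are retained but flagged.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return object of class `atom_model`: data frame with columns `chain`,
#'   `resno`, `resname`, `atom`, `element`, `x`, `y`, `z`, `hydrogen`, and
#'   attributes `source`/`format`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif",
                     stop("cannot guess the format of '", path,
                          "'; pass format = \"pdb\" or \"mmcif\""))
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE)
    else suppressWarnings(bio3d::read.cif(path)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  at <- parsed$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM/HETATM records in '", path, "'")
  el <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                              substr(trimws(at$elety), 1, 1), at$elesy)))
  model <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    resname = trimws(as.character(at$resid)),
    atom = trimws(as.character(at$elety)),
    element = el,
    x = at$x, y = at$y, z = at$z,
    hydrogen = el %in% c("H", "D"),
    stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(model[, c("x", "y", "z")]))))
    stop("non-finite coordinates in '", path, "'")
  key <- paste(model$chain, model$resno, model$atom)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (chain, residue, atom) records in '", path, "': ",
         paste(utils::head(dups, 3), collapse = "; "))
  }
  structure(model, class = c("atom_model", "data.frame"),
            source = path, format = format)
}

#' Read and validate an array registry
#'
#' The registry maps DNA chains/residue ranges of a model to per-nucleosome
#' base-pair tracks. It is a YAML document with a top-level `array_label`
#' and a `nucleosomes` list; each entry carries `label`, `strand_i` and
#' `strand_j` blocks (`chain`, `first`, `last`), a `pairing` rule
#' (`antiparallel`: strand-I position k pairs with strand-J residue
#' `last - k + 1`), `core_start`, `core_len` (default 147), and optional
#' `h1_chain` / `h1` annotation.
#'
#' @param path YAML file path.
#' @return object of class `array_registry` (list of validated entries with
#'   an `array_label` attribute).
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$nucleosomes) || !length(doc$nucleosomes))
    stop("registry '", path, "' has no 'nucleosomes' entries")
  entries <- lapply(doc$nucleosomes, validate_registry_entry)
  labels <- vapply(entries, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("registry: duplicate nucleosome labels")
  structure(entries, class = "array_registry",
            array_label = doc$array_label %||% "array")
}

validate_registry_entry <- function(e) {
  need <- c("label", "strand_i", "strand_j", "core_start")
  miss <- setdiff(need, names(e))
  if (length(miss))
    stop("registry entry missing field(s): ", paste(miss, collapse = ", "))
  for (s in c("strand_i", "strand_j")) {
    b <- e[[s]]
    if (!all(c("chain", "first", "last") %in% names(b)))
      stop("registry entry '", e$label, "': ", s,
           " needs chain/first/last")
    if (b$last < b$first)
      stop("registry entry '", e$label, "': ", s, " range is reversed")
  }
  len_i <- e$strand_i$last - e$strand_i$first + 1L
  len_j <- e$strand_j$last - e$strand_j$first + 1L
  if (len_i != len_j)
    stop("registry entry '", e$label, "': strand ranges have unequal ",
         "lengths (", len_i, " vs ", len_j, ")")
  e$pairing <- e$pairing %||% "antiparallel"
  if (!identical(e$pairing, "antiparallel"))
    stop("registry entry '", e$label, "': unsupported pairing rule '",
         e$pairing, "'")
  e$core_len <- as.integer(e$core_len %||% 147L)
  e$core_start <- as.integer(e$core_start)
  if (e$core_start < 1L || e$core_start + e$core_len - 1L > len_i)
    stop("registry entry '", e$label, "': core [", e$core_start, ", ",
         e$core_start + e$core_len - 1L, "] outside the ", len_i,
         "-bp track")
  e$h1 <- isTRUE(e$h1) || !is.null(e$h1_chain)
  e
}

#' Extract a base-pair centroid track from an atomic model
#'
#' Base pair i is the strand-I residue at position i of the registry range
#' together with its positionally paired strand-J residue (antiparallel
#' map). Its centroid is the unweighted mean of all non-hydrogen atom
#' positions of the two nucleotides (`atoms = "heavy"`), or of the two C1'
#' atoms (`atoms = "c1"`, sensitivity mode).
#'
#' Base pairs with no resolved atoms are gaps: a gap inside the core is a
#' hard error; linker gaps truncate the track at the innermost gap of that
#' side (so a short remaining linker downstream reports undefined angles
#' rather than wrong ones).
#'
#' @param model an [read_structure()] result.
#' @param entry one validated registry entry (element of
#'   [read_registry()]'s list).
#' @param atoms `"heavy"` (default) or `"c1"`.
#' @return a [bp_track].
#' @export
extract_track <- function(model, entry, atoms = c("heavy", "c1")) {
  atoms <- match.arg(atoms)
  entry <- validate_registry_entry(entry)
  n <- entry$strand_i$last - entry$strand_i$first + 1L
  sel <- if (atoms == "heavy") !model$hydrogen
         else (!model$hydrogen) & model$atom %in% c("C1'", "C1*")
  mm <- model[sel, , drop = FALSE]
  xyz <- as.matrix(mm[, c("x", "y", "z")])

  cent <- matrix(NA_real_, n, 3)
  gaps <- integer(0)
  for (k in seq_len(n)) {
    ri <- entry$strand_i$first + (k - 1L)
    rj <- entry$strand_j$last - (k - 1L)
    pick <- (mm$chain == entry$strand_i$chain & mm$resno == ri) |
            (mm$chain == entry$strand_j$chain & mm$resno == rj)
    if (!any(pick)) { gaps <- c(gaps, k); next }
    cent[k, ] <- colMeans(xyz[pick, , drop = FALSE])
  }
  core_end <- entry$core_start + entry$core_len - 1L
  core_gaps <- gaps[gaps >= entry$core_start & gaps <= core_end]
  if (length(core_gaps))
    stop("nucleosome '", entry$label, "': base-pair gap(s) inside the ",
         "core at position(s) ", paste(core_gaps, collapse = ", "),
         " - the core must be complete")
  ## truncate at innermost linker gap on each side
  lo <- 1L; hi <- n
  pre <- gaps[gaps < entry$core_start]
  if (length(pre)) lo <- max(pre) + 1L
  post <- gaps[gaps > core_end]
  if (length(post)) hi <- min(post) - 1L
  bp_track(cent[lo:hi, , drop = FALSE],
           core_start = entry$core_start - lo + 1L,
           core_len = entry$core_len,
           label = entry$label, h1_present = entry$h1)
}

#' Write the per-nucleosome, per-side analysis report
#'
#' One row per (nucleosome, linker side); angles in degrees, printed at 3
#' decimals; undefined angles rendered as `NA` (never 0); deterministic
#' column order; tab-separated, UTF-8, '.' decimal separator.
#'
#' @param rows data frame with (at least) columns `array`, `nucleosome`,
#'   `side`, `alpha`, `beta`, `delta_alpha`, `delta_beta`,
#'   `avg_delta_alpha`, `avg_delta_beta`, `stack_partner`, `dyad_tilt`,
#'   `h1_call`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop("report rows must be a nonempty data frame")
  cols <- c("array", "nucleosome", "side", "alpha", "beta",
            "delta_alpha", "delta_beta", "avg_delta_alpha",
            "avg_delta_beta", "stack_partner", "dyad_tilt", "h1_call")
  miss <- setdiff(cols, names(rows))
  if (length(miss))
    stop("report rows missing column(s): ", paste(miss, collapse = ", "))
  out <- rows[, cols]
  numc <- c("alpha", "beta", "delta_alpha", "delta_beta",
            "avg_delta_alpha", "avg_delta_beta", "dyad_tilt")
  for (cc in numc)
    out[[cc]] <- ifelse(is.na(out[[cc]]), NA_character_,
                        sprintf("%.3f", as.numeric(out[[cc]])))
  ok <- tryCatch({
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write report to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read back a report written by [write_report()]
#' @param path report path.
#' @return data frame (numeric angle columns, `NA` preserved).
#' @export
read_report <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE)
}
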