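## Emission of synthetic arrays as coordinate fixtures: a pseudo-atom
## mmCIF (or PDB) with two single-atom nucleotides per base pair placed
## symmetrically about the centroid, a matching YAML registry, and the
## ground-truth table. Round-tripping through read_structure() /
## extract_track() reproduces the centroids exactly (to coordinate
## precision).

#' Write a synthetic array to disk as a coordinate fixture
#'
#' Each base pair i of the full-array track becomes two pseudo-atoms (atom
#' name `BP`, element P): strand I chain `I` residue i and strand J chain
#' `J` residue `N - i + 1` (antiparallel numbering), offset +/- 1 Angstrom
#' along x so their mean is exactly the centroid. The registry maps each
#' nucleosome's range back to a [bp_track]; the ground-truth table records
#' the construction angles.
#'
#' @param array a [build_array()] result.
#' @param dir output directory (created if missing).
#' @param format `"mmcif"` (default) or `"pdb"` for the coordinate file.
#' @return named character vector of the three file paths (`coords`,
#'   `registry`, `ground_truth`), invisibly.
#' @export
emit_fixture <- function(array, dir, format = c("mmcif", "pdb")) {
  stopifnot(inherits(array, "synthetic_array"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  coords <- array$coords
  N <- nrow(coords)
  off <- c(1, 0, 0)
  atoms <- data.frame(
    chain = rep(c("I", "J"), each = N),
    resno = c(seq_len(N), N - seq_len(N) + 1L),
    x = c(coords[, 1] + off[1], coords[, 1] - off[1]),
    y = c(coords[, 2] + off[2], coords[, 2] - off[2]),
    z = c(coords[, 3] + off[3], coords[, 3] - off[3]),
    stringsAsFactors = FALSE)
  coord_path <- file.path(dir, paste0("coords.",
                                      if (format == "pdb") "pdb" else "cif"))
  if (format == "mmcif") write_pseudo_cif(atoms, coord_path,
                                          array$spec$label)
  else bio3d::write.pdb(file = coord_path,
                        xyz = as.numeric(t(as.matrix(
                          atoms[, c("x", "y", "z")]))),
                        resno = atoms$resno, chain = atoms$chain,
                        resid = rep("DN", nrow(atoms)),
                        elety = rep("BP", nrow(atoms)),
                        elesy = rep("P", nrow(atoms)))

  spec <- array$spec
  reg <- lapply(seq_len(spec$n_nucleosomes), function(k) {
    tr <- array$tracks[[k]]
    up <- entry_linker_len(tr)
    start <- (k - 1L) * spec$nrl + 1L - up
    end <- start + nrow(tr$centroids) - 1L
    list(label = tr$label,
         strand_i = list(chain = "I", first = start, last = end),
         strand_j = list(chain = "J", first = N - end + 1L,
                         last = N - start + 1L),
         pairing = "antiparallel",
         core_start = tr$core_start, core_len = tr$core_len,
         h1 = isTRUE(tr$h1_present))
  })
  reg_path <- file.path(dir, "registry.yaml")
  yaml::write_yaml(list(array_label = spec$label, nrl = spec$nrl,
                        nucleosomes = reg), reg_path)

  gt_path <- file.path(dir, "ground_truth.tsv")
  utils::write.table(array$ground_truth, gt_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(c(coords = coord_path, registry = reg_path,
              ground_truth = gt_path))
}

## minimal atom_site loop; read back with bio3d::read.cif
write_pseudo_cif <- function(atoms, path, label) {
  hdr <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_", label)),
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  rec <- sprintf(
    "ATOM %d P BP . DN %s 1 %d ? %.5f %.5f %.5f 1.00 0.00 ? %d DN %s BP 1",
    seq_len(nrow(atoms)), atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$resno, atoms$chain)
  writeLines(c(hdr, rec), path)
}
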