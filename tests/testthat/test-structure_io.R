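test_that("read_structure round-trips a minimal PDB and rejects duplicates", {
  path <- tempfile(fileext = ".pdb")
  atoms <- data.frame(chain = c("I", "J"), resno = c(1L, 1L),
                      resname = "DA", name = "C1'", element = "C",
                      x = c(1.25, -1.25), y = c(2.5, -2.5), z = c(3, -3))
  write_mini_pdb(path, atoms)
  m <- read_structure(path)
  expect_s3_class(m, "atom_model")
  expect_equal(nrow(m), 2)
  expect_equal(m$x, atoms$x, tolerance = 1e-6)
  expect_equal(sort(unique(m$chain)), c("I", "J"))
  expect_false(any(m$hydrogen))

  dup <- rbind(atoms, atoms[1, ])
  path2 <- tempfile(fileext = ".pdb")
  write_mini_pdb(path2, dup)
  expect_error(read_structure(path2), "duplicate")

  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
  expect_error(read_structure(path, format = "auto"), NA)
})

test_that("mmCIF and PDB fixtures of the same array give matching tracks", {
  arr <- build_array(nrl_preset(177))
  d1 <- tempfile(); d2 <- tempfile()
  fx_cif <- emit_fixture(arr, d1, format = "mmcif")
  fx_pdb <- emit_fixture(arr, d2, format = "pdb")
  reg <- read_registry(fx_cif["registry"])
  m_cif <- read_structure(fx_cif["coords"])
  m_pdb <- read_structure(fx_pdb["coords"])
  for (k in c(1, 3)) {
    t_cif <- extract_track(m_cif, reg[[k]])
    t_pdb <- extract_track(m_pdb, reg[[k]])
    expect_lt(max(abs(t_cif$centroids - t_pdb$centroids)), 1e-3)
  }
})

test_that("extract_track averages paired residues and is atom-order invariant", {
  ## one bp: two single-atom residues -> centroid is the midpoint
  path <- tempfile(fileext = ".pdb")
  atoms <- data.frame(chain = c("I", "J"), resno = c(5L, 9L),
                      resname = "DA", name = "P", element = "P",
                      x = c(0, 2), y = c(0, 0), z = c(0, 0))
  write_mini_pdb(path, atoms)
  entry <- list(label = "n1",
                strand_i = list(chain = "I", first = 5L, last = 5L),
                strand_j = list(chain = "J", first = 9L, last = 9L),
                core_start = 1L, core_len = 1L)
  tr <- extract_track(read_structure(path), entry)
  expect_equal(as.numeric(tr$centroids[1, ]), c(1, 0, 0))

  ## 3-atom nucleotides with known means; permuted atom order agrees
  set.seed(42)
  cent <- matrix(rnorm(9, sd = 5), 3, 3)
  rows <- list()
  for (i in 1:3) for (a in 1:3) {
    off <- switch(a, c(1, 0, 0), c(-0.5, 0.8, 0), c(-0.5, -0.8, 0))
    rows[[length(rows) + 1]] <- data.frame(
      chain = "I", resno = i, resname = "DA",
      name = paste0("C", a, "'"), element = "C",
      x = cent[i, 1] + off[1], y = cent[i, 2] + off[2],
      z = cent[i, 3] + off[3])
    rows[[length(rows) + 1]] <- data.frame(
      chain = "J", resno = 4 - i, resname = "DT",
      name = paste0("C", a, "'"), element = "C",
      x = cent[i, 1] - off[1], y = cent[i, 2] - off[2],
      z = cent[i, 3] - off[3])
  }
  tab <- do.call(rbind, rows)
  entry3 <- list(label = "n1",
                 strand_i = list(chain = "I", first = 1L, last = 3L),
                 strand_j = list(chain = "J", first = 1L, last = 3L),
                 core_start = 1L, core_len = 3L)
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  write_mini_pdb(p1, tab)
  write_mini_pdb(p2, tab[sample(nrow(tab)), ])
  t1 <- extract_track(read_structure(p1), entry3)
  t2 <- extract_track(read_structure(p2), entry3)
  expect_equal(t1$centroids, cent, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(t1$centroids, t2$centroids)
})

test_that("registry validation rejects malformed entries", {
  entry <- list(label = "n1",
                strand_i = list(chain = "I", first = 1L, last = 10L),
                strand_j = list(chain = "J", first = 1L, last = 9L),
                core_start = 1L, core_len = 5L)
  expect_error(nucgeom:::validate_registry_entry(entry), "unequal")
  entry$strand_j$last <- 10L
  entry$core_start <- 8L
  expect_error(nucgeom:::validate_registry_entry(entry), "outside")
})

test_that("core gaps are fatal, linker gaps truncate to undefined sides", {
  arr <- build_array(nrl_preset(177))
  d <- tempfile()
  fx <- emit_fixture(arr, d)
  reg <- read_registry(fx["registry"])
  lines <- readLines(fx["coords"])
  ## nuc4 track: find its exit-linker global bp indices and delete bp 6-10
  ## on BOTH strands (strand J numbers run antiparallel: N - i + 1)
  e4 <- reg[[4]]
  N <- max(vapply(reg, function(e) e$strand_i$last, 1L))
  core_end_global <- e4$strand_i$first + (e4$core_start + e4$core_len - 1L) - 1L
  kill_i <- (core_end_global + 6L):(core_end_global + 10L)
  kill_j <- N - kill_i + 1L
  toks <- strsplit(lines, " +")
  is_atom <- vapply(toks, function(t) t[1] == "ATOM", TRUE)
  seqid <- rep(NA_integer_, length(lines))
  seqid[is_atom] <- vapply(toks[is_atom], function(t) as.integer(t[9]), 1L)
  chain <- rep(NA_character_, length(lines))
  chain[is_atom] <- vapply(toks[is_atom], function(t) t[7], "")
  drop <- is_atom & ((chain == "I" & seqid %in% kill_i) |
                       (chain == "J" & seqid %in% kill_j))
  path2 <- tempfile(fileext = ".cif")
  writeLines(lines[!drop], path2)
  tr <- extract_track(read_structure(path2), e4)
  expect_lt(exit_linker_len(tr), 10L)
  ang <- trajectory_angles(tr)
  expect_true(is.na(ang$beta[ang$side == "exit"]))
  expect_false(ang$defined[ang$side == "exit"])
  ## entry side untouched
  expect_false(is.na(ang$beta[ang$side == "entry"]))

  ## deleting a core bp (both strands) is a hard error
  core_bp <- e4$strand_i$first + e4$core_start + 10L
  drop3 <- is_atom & ((chain == "I" & seqid == core_bp) |
                        (chain == "J" & seqid == N - core_bp + 1L))
  path3 <- tempfile(fileext = ".cif")
  writeLines(lines[!drop3], path3)
  expect_error(extract_track(read_structure(path3), e4), "core")
})

test_that("write_report renders NA cells, fixed columns, and round-trips", {
  rows <- data.frame(
    array = "a", nucleosome = c("n1", "n1"), side = c("entry", "exit"),
    alpha = c(NA, 63.1234), beta = c(NA, 2.9876),
    delta_alpha = c(NA, 5.001), delta_beta = c(NA, 12.0004),
    avg_delta_alpha = 5.001, avg_delta_beta = 12.0004,
    stack_partner = c(NA, "n3"), dyad_tilt = c(NA, 4.01),
    h1_call = "incompatible", stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_report(rows, path)
  txt <- readLines(path)
  expect_length(txt, 3)  # header + 2 rows
  expect_match(txt[1], "^array\tnucleosome\tside\talpha\tbeta")
  expect_match(txt[2], "\tNA\t")
  expect_false(grepl("\t0\\.000\t", txt[2]))  # missing is NA, never 0
  back <- read_report(path)
  expect_equal(back$alpha[2], 63.123)
  expect_true(is.na(back$alpha[1]))
  ## re-writing the read file is bit-identical at printed precision
  path2 <- tempfile(fileext = ".tsv")
  write_report(back, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(write_report(rows[0, ], tempfile()), "nonempty")
  expect_error(write_report(rows[, -4], tempfile()), "missing")
})
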