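# Fixtures are generated in code at test time; nothing binary on disk.

write_fixture <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

methane_sdf <- function() write_fixture(c(
  "methane", "  fixture", "",
  "  5  4  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.6300    0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.6300   -0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.6300    0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.6300   -0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
  "M  END", "$$$$"), ".sdf")

# Benzene: hexagonal ring (order-4 aromatic ring bonds) plus 6 hydrogens.
benzene_sdf <- function() {
  ang <- (0:5) * pi / 3
  atoms <- c(
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            1.39 * cos(ang), 1.39 * sin(ang), 0, "C"),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            2.47 * cos(ang), 2.47 * sin(ang), 0, "H"))
  ring <- sprintf("%3d%3d%3d  0", 1:6, c(2:6, 1), 4)
  ch <- sprintf("%3d%3d%3d  0", 1:6, 7:12, 1)
  write_fixture(c("benzene", "  fixture", "",
                  " 12 12  0  0  0  0  0  0  0  0999 V2000",
                  atoms, ring, ch, "M  END", "$$$$"), ".sdf")
}

# Pentavalent carbon: five single bonds at one carbon.
texas_carbon_sdf <- function() write_fixture(c(
  "texas", "  fixture", "",
  "  6  5  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.0900    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -1.0900    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000    1.0900    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000   -1.0900    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000    0.0000    1.0900 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
  "  1  6  1  0", "M  END", "$$$$"), ".sdf")

pdb_atom_line <- function(serial, name, alt, resid, chain, resno, x, y, z,
                          occ = 1, elem = substr(name, 1, 1),
                          record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resid, chain, resno, x, y, z, occ, 20,
          elem)
}

# Three residues along x plus a water and a sodium ion.
toy_protein_pdb <- function() {
  lines <- c(
    pdb_atom_line(1, "N", " ", "ALA", "A", 1, 0, 0, 0, elem = "N"),
    pdb_atom_line(2, "CA", " ", "ALA", "A", 1, 1.45, 0, 0, elem = "C"),
    pdb_atom_line(3, "C", " ", "ALA", "A", 1, 2.0, 1.4, 0, elem = "C"),
    pdb_atom_line(4, "N", " ", "GLY", "A", 2, 3.3, 1.5, 0, elem = "N"),
    pdb_atom_line(5, "CA", " ", "GLY", "A", 2, 4.0, 2.8, 0, elem = "C"),
    pdb_atom_line(6, "N", " ", "SER", "A", 3, 12.0, 0, 0, elem = "N"),
    pdb_atom_line(7, "CA", " ", "SER", "A", 3, 13.45, 0, 0, elem = "C"),
    pdb_atom_line(8, "O", " ", "HOH", "A", 101, 8, 8, 8, elem = "O",
                  record = "HETATM"),
    pdb_atom_line(9, "NA", " ", "NA", "A", 102, 9, 9, 9, elem = "NA",
                  record = "HETATM"),
    "END")
  write_fixture(lines, ".pdb")
}

# Two altloc conformers of one CA with different occupancies.
altloc_pdb <- function() write_fixture(c(
  pdb_atom_line(1, "N", " ", "ALA", "A", 1, 0, 0, 0, elem = "N"),
  pdb_atom_line(2, "CA", "A", "ALA", "A", 1, 1.45, 0, 0, occ = 0.4,
                elem = "C"),
  pdb_atom_line(3, "CA", "B", "ALA", "A", 1, 1.55, 0.1, 0, occ = 0.6,
                elem = "C"),
  "END"), ".pdb")

# Small deterministic ligand structures for direct construction.
toy_ligand <- function(elements, coords, bonds, charges = NULL,
                       name = "toy") {
  ligand_structure(elements, coords, charges, bonds, name = name)
}

chain3_ligand <- function() toy_ligand(
  c("C", "C", "C"),
  rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)),
  data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)))

# Tiny cached dataset + model shared across slow-ish tests.
tiny_env <- new.env()
tiny_dataset <- function() {
  if (is.null(tiny_env$data)) {
    spec <- synthetic_spec(n_pairs = 4L, windows_per_leg = 6L,
                           heavy_atom_range = c(5L, 8L), seed = 11L)
    tiny_env$data <- gen_dataset(spec, n_dist_basis = 8L)
  }
  tiny_env$data
}
tiny_config <- function(...) {
  alch_config(overrides = utils::modifyList(
    list(d_hidden = 12L, n_layers = 2L, d_lambda_basis = 8L,
         d_dist_basis = 8L, n_epochs = 30L, warmup_steps = 20L,
         batch_size = 24L, seed = 1L), list(...)))
}
tiny_params <- function(seed = 7L) init_params(tiny_config(), seed = seed)

# Random rigid motion: proper rotation from QR plus translation.
rigid_motion <- function(coords, seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  tvec <- stats::rnorm(3, sd = 5)
  sweep(coords %*% Q, 2, tvec, "+")
}

# Apply a rigid motion to a ligand and pocket together (shared frame).
transform_complex <- function(ligand, pocket, seed) {
  all_coords <- rbind(ligand$coords, cbind(pocket$x, pocket$y, pocket$z))
  moved <- rigid_motion(all_coords, seed)
  nl <- nrow(ligand$coords)
  lig2 <- ligand; lig2$coords <- moved[seq_len(nl), , drop = FALSE]
  pk2 <- pocket
  pk2$x <- moved[-seq_len(nl), 1]
  pk2$y <- moved[-seq_len(nl), 2]
  pk2$z <- moved[-seq_len(nl), 3]
  list(ligand = lig2, pocket = pk2)
}

# Permute ligand atoms (reindexing bonds accordingly).
permute_ligand <- function(lig, perm) {
  inv <- order(perm)
  ligand_structure(lig$elements[perm], lig$coords[perm, , drop = FALSE],
                   lig$formal_charges[perm],
                   data.frame(i = inv[lig$bonds$i], j = inv[lig$bonds$j],
                              order = lig$bonds$order),
                   name = lig$name)
}
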