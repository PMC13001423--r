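# Shared fixtures: hand-written PDB text, direct complex_structure
# construction, and a deterministic default synthetic spec.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM", element = substr(name, 1, 1),
                          occ = 1, alt = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resno, x, y, z, occ, 0,
          element)
}

# minimal complex: 3 residues (ALA, GLY, TRP) + 2-atom ligand; optional
# water and second HETATM group
write_mini_pdb <- function(path, add_water = FALSE, second_ligand = FALSE) {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0, element = "C"),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.2, 1.2, 0, element = "C"),
    pdb_atom_line(4, "O", "ALA", "A", 1, 1.8, 2.3, 0, element = "O"),
    pdb_atom_line(5, "N", "GLY", "A", 2, 3.5, 1.1, 0, element = "N"),
    pdb_atom_line(6, "CA", "GLY", "A", 2, 4.4, 2.2, 0, element = "C"),
    pdb_atom_line(7, "C", "GLY", "A", 2, 5.8, 1.8, 0, element = "C"),
    pdb_atom_line(8, "N", "TRP", "A", 3, 6.6, 2.8, 0, element = "N"),
    pdb_atom_line(9, "CA", "TRP", "A", 3, 8.0, 2.6, 0, element = "C"),
    pdb_atom_line(10, "MG1", "LIG", "B", 101, 5.0, 5.0, 2.0,
                  record = "HETATM", element = "C"),
    pdb_atom_line(11, "MG2", "LIG", "B", 101, 6.2, 5.5, 2.0,
                  record = "HETATM", element = "O")
  )
  if (add_water)
    lines <- c(lines, pdb_atom_line(12, "O", "HOH", "W", 201, 20, 20, 20,
                                    record = "HETATM", element = "O"))
  if (second_ligand)
    lines <- c(lines, pdb_atom_line(13, "C1", "XYZ", "B", 102, 30, 30, 30,
                                    record = "HETATM", element = "C"))
  writeLines(c(lines, "END"), path)
  path
}

# build a complex_structure directly from atom tables (no file round trip)
build_cx <- function(prot_df, lig_df, hydrogens = NULL) {
  prot_df$type <- "ATOM"; prot_df$o <- 1
  if (is.null(prot_df$insert)) prot_df$insert <- ""
  if (is.null(prot_df$chain)) prot_df$chain <- "A"
  lig_df$type <- "HETATM"; lig_df$o <- 1
  if (is.null(lig_df$insert)) lig_df$insert <- ""
  if (is.null(lig_df$chain)) lig_df$chain <- "X"
  if (is.null(lig_df$resid)) lig_df$resid <- "LIG"
  if (is.null(lig_df$resno)) lig_df$resno <- 900
  rkey <- paste(prot_df$chain, prot_df$resno, prot_df$insert)
  first <- !duplicated(rkey)
  protein <- data.frame(chain = prot_df$chain[first],
                        resno = prot_df$resno[first],
                        insert = prot_df$insert[first],
                        resid = prot_df$resid[first],
                        j = seq_len(sum(first)), stringsAsFactors = FALSE)
  prot_df$j <- match(rkey, rkey[first])
  lig_df$i <- seq_len(nrow(lig_df))
  atoms <- rbind(
    prot_df[, c("type", "elety", "resid", "chain", "resno", "insert",
                "x", "y", "z", "o", "element")],
    lig_df[, c("type", "elety", "resid", "chain", "resno", "insert",
               "x", "y", "z", "o", "element")])
  if (!is.null(hydrogens)) {
    hydrogens$type <- "ATOM"; hydrogens$o <- 1
    if (is.null(hydrogens$insert)) hydrogens$insert <- ""
    if (is.null(hydrogens$chain)) hydrogens$chain <- "A"
    atoms <- rbind(atoms, hydrogens[, names(atoms)])
  }
  structure(list(atoms = atoms, protein = protein, prot_atoms = prot_df,
                 ligand = lig_df, ligand_name = lig_df$resid[1],
                 source_id = "built"),
            class = "complex_structure")
}

# a six-type planted spec used by several suites
six_type_spec <- function(seed = 1) {
  synthetic_complex_spec(
    n = 12, m = 12,
    contacts = data.frame(
      type = c("hbond", "salt_bridge", "hydrophobic", "vdw",
               "cation_pi", "pipi"),
      i = c(1, 2, 3, 4, 5, 6),   # pipi ring occupies 6..11
      j = c(1, 3, 5, 7, 9, 11),
      dist = c(3.0, 4.5, 3.6, 3.2, 4.5, 4.0)),
    seed = seed)
}

# random single-atom-contact specs for oracle comparisons
random_contact_spec <- function(seed) {
  set.seed(seed)
  types <- c("hbond", "salt_bridge", "hydrophobic", "vdw", "cation_pi")
  nc <- sample(1:4, 1)
  tt <- sample(types, nc, replace = TRUE)
  n <- 10; m <- 8
  dd <- vapply(tt, function(t) {
    w <- crossbind:::.synth_window(t)
    runif(1, w[1] + 0.05, w[2] - 0.05)
  }, numeric(1))
  synthetic_complex_spec(
    n = n, m = m,
    contacts = data.frame(type = tt, i = sample(m, nc), j = sample(n, nc),
                          dist = dd),
    seed = seed)
}
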