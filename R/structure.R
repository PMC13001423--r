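# Parsing of protein-ligand complex structures, ligand selection, pocket
# localization and sequence extraction. All heavy lifting of the PDB/mmCIF
# formats is delegated to bio3d.

.water_names <- c("HOH", "WAT", "DOD", "H2O", "DIS")

#' Default ligand-candidacy blocklist
#'
#' Residue names excluded from ligand candidacy besides waters: common
#' buffer components, cryoprotectants, monatomic ions, and common
#' covalently-attached glycan units.
#'
#' @return Character vector of 3-letter residue names.
#' @export
default_ligand_blocklist <- function() {
  c(
    # ions
    "NA", "CL", "K", "MG", "ZN", "CA", "MN", "FE", "FE2", "CU", "NI", "CO",
    "CD", "HG", "IOD", "BR", "CS", "LI", "SR", "BA", "RB",
    # buffers / cryo / additives
    "SO4", "PO4", "GOL", "EDO", "ACT", "DMS", "PEG", "PG4", "MPD", "TRS",
    "EPE", "MES", "FMT", "NO3", "NH4", "BME", "IMD", "CIT", "TLA", "ACY",
    # common glycan units (covalently attached sugars)
    "NAG", "NDG", "BMA", "MAN", "GAL", "FUC", "XYS", "GLC", "SIA"
  )
}

# 3-letter -> 1-letter amino acid codes, including common modified residues.
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  SEC = "U", PYL = "O",
  # frequent modified residues mapped to their parent
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C", CSD = "C",
  CME = "C", OCS = "C", KCX = "K", MLY = "K", HYP = "P", PCA = "Q",
  FME = "M", HIC = "H"
)

.guess_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    bad <- is.na(e) | e == ""
  } else {
    e <- rep("", length(elety))
    bad <- rep(TRUE, length(elety))
  }
  if (any(bad)) {
    nm <- toupper(gsub("[^A-Za-z].*", "", gsub("^[0-9]+", "", elety[bad])))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    e[bad] <- ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN"),
                     two, one)
  }
  e
}

#' Parse a protein-ligand complex structure
#'
#' Reads a PDB or mmCIF file, resolves alternate locations (highest
#' occupancy wins, ties broken by altloc identifier), selects exactly one
#' ligand, and indexes protein residues in chain order.
#'
#' Ligand candidates are HETATM groups excluding waters and a configurable
#' blocklist of ions, buffer components and glycan units
#' ([default_ligand_blocklist()]). With `ligand = "auto"` the file must
#' contain exactly one candidate; otherwise an "ambiguous ligand" error
#' lists the candidates. A residue-name selector picks that group (first
#' occurrence in file order if several copies exist).
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param ligand `"auto"` or a HETATM residue name.
#' @param blocklist Residue names never considered ligand candidates.
#' @return An object of class `complex_structure` with elements `atoms`
#'   (all resolved atoms), `protein` (ordered residue table, one row per
#'   residue position j = 1..n), `prot_atoms` (protein atoms with residue
#'   position `j`), `ligand` (ligand heavy atoms, rows i = 1..m),
#'   `ligand_name`, and `source_id`.
#' @export
parse_complex <- function(path, ligand = "auto",
                          blocklist = default_ligand_blocklist()) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE),
    error = function(e) stop("format error: cannot parse '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$element <- .guess_element(at$elety, at$elesy)

  # altloc: keep the highest-occupancy conformer per atom slot
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, ][!duplicated(key[ord]), ]
  at <- at[order(as.integer(rownames(at))), ]

  prot_at <- at[at$type == "ATOM" & !(at$element %in% c("H", "D")), ,
                drop = FALSE]
  if (nrow(prot_at) == 0) stop("no polymer chain found in ", path)
  rkey <- paste(prot_at$chain, prot_at$resno, prot_at$insert, sep = "|")
  first <- !duplicated(rkey)
  protein <- data.frame(
    chain = prot_at$chain[first], resno = prot_at$resno[first],
    insert = prot_at$insert[first], resid = prot_at$resid[first],
    stringsAsFactors = FALSE
  )
  protein$j <- seq_len(nrow(protein))
  prot_at$j <- match(rkey, rkey[first])

  het <- at[at$type == "HETATM", , drop = FALSE]
  het <- het[!(toupper(het$resid) %in% .water_names), , drop = FALSE]
  het <- het[!(toupper(het$resid) %in% toupper(blocklist)), , drop = FALSE]
  if (nrow(het) == 0) stop("no ligand candidate in ", path)
  gkey <- paste(het$resid, het$chain, het$resno, het$insert, sep = "|")
  groups <- unique(gkey)
  gnames <- het$resid[match(groups, gkey)]
  if (identical(ligand, "auto")) {
    if (length(groups) > 1) {
      stop("ambiguous ligand: candidates are ",
           paste(unique(paste0(gnames, "/",
                               het$chain[match(groups, gkey)], ":",
                               het$resno[match(groups, gkey)])),
                 collapse = ", "))
    }
    sel <- groups[1]
  } else {
    hit <- which(gnames == ligand)
    if (length(hit) == 0) stop("no ligand candidate named '", ligand, "'")
    sel <- groups[hit[1]]
  }
  lig <- het[gkey == sel & !(het$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(lig) == 0) stop("no ligand candidate: selected group has no heavy atoms")
  lig$i <- seq_len(nrow(lig))

  out <- list(
    atoms = at, protein = protein, prot_atoms = prot_at, ligand = lig,
    ligand_name = lig$resid[1],
    source_id = sub("\\.[^.]*$", "", basename(path))
  )
  class(out) <- "complex_structure"
  stopifnot(all(is.finite(c(out$prot_atoms$x, out$prot_atoms$y,
                            out$prot_atoms$z, out$ligand$x, out$ligand$y,
                            out$ligand$z))))
  out
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("complex_structure:", x$source_id, "\n")
  cat("  protein: ", nrow(x$protein), " residues (n), ",
      nrow(x$prot_atoms), " heavy atoms, chains: ",
      paste(unique(x$protein$chain), collapse = ","), "\n", sep = "")
  cat("  ligand:  ", x$ligand_name, ", ", nrow(x$ligand),
      " heavy atoms (m)\n", sep = "")
  invisible(x)
}

.coords <- function(df) cbind(df$x, df$y, df$z)

# minimum distance from each row of A (k x 3) to the point set B (l x 3)
.min_dist_to_set <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1, min))
}

#' Localize the binding pocket
#'
#' Returns the positions `j` of all protein residues having any atom within
#' `radius` Angstrom of any ligand heavy atom.
#'
#' @param cx A `complex_structure`.
#' @param radius Pocket radius in Angstrom (default 10).
#' @return Sorted integer vector of residue positions (possibly empty).
#' @export
localize_pocket <- function(cx, radius = 10) {
  stopifnot(inherits(cx, "complex_structure"))
  if (!(is.numeric(radius) && radius > 0)) stop("radius must be > 0")
  dmin <- .min_dist_to_set(.coords(cx$prot_atoms), .coords(cx$ligand))
  sort(unique(cx$prot_atoms$j[dmin <= radius]))
}

#' Extract the one-letter protein sequence
#'
#' Maps 3-letter residue names to the one-letter alphabet (common modified
#' residues map to their parent, e.g. MSE to M; unknown names to X), with a
#' bijective index map between sequence positions and structure residues.
#'
#' @param cx A `complex_structure`.
#' @return Object of class `protein_sequence`: `sequence` (string), `codes`
#'   (character vector length n), `index_map` (data.frame pos/chain/resno/
#'   insert/resid).
#' @export
extract_sequence <- function(cx) {
  stopifnot(inherits(cx, "complex_structure"))
  if (nrow(cx$protein) < 1) stop("complex has no protein residues")
  codes <- .aa3to1[toupper(cx$protein$resid)]
  codes[is.na(codes)] <- "X"
  out <- list(
    sequence = paste(codes, collapse = ""),
    codes = unname(codes),
    index_map = data.frame(
      pos = cx$protein$j, chain = cx$protein$chain,
      resno = cx$protein$resno, insert = cx$protein$insert,
      resid = cx$protein$resid, stringsAsFactors = FALSE
    )
  )
  class(out) <- "protein_sequence"
  out
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("protein_sequence (", length(x$codes), " residues)\n", sep = "")
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Serialize a complex back to PDB
#'
#' Writes the resolved atoms (protein as ATOM, selected ligand as HETATM)
#' so that re-parsing yields identical residue and atom counts.
#'
#' @param cx A `complex_structure`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(cx, path) {
  stopifnot(inherits(cx, "complex_structure"))
  p <- cx$prot_atoms; l <- cx$ligand
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(rbind(.coords(p), .coords(l)))),
    type = c(rep("ATOM", nrow(p)), rep("HETATM", nrow(l))),
    resno = c(p$resno, l$resno),
    resid = c(p$resid, l$resid),
    eleno = seq_len(nrow(p) + nrow(l)),
    elety = c(p$elety, l$elety),
    chain = c(p$chain, l$chain),
    o = rep(1, nrow(p) + nrow(l)),
    b = rep(0, nrow(p) + nrow(l)),
    elesy = c(p$element, l$element)
  )
  invisible(path)
}

#' Complex manifest
#'
#' Summary of a parsed complex (identifier, chains, ligand, m, n, pocket
#' residues), suitable for JSON serialization.
#'
#' @param cx A `complex_structure`.
#' @param radius Pocket radius passed to [localize_pocket()].
#' @return Named list.
#' @export
complex_manifest <- function(cx, radius = 10) {
  list(
    source_id = cx$source_id,
    chains = unique(cx$protein$chain),
    ligand = cx$ligand_name,
    m = nrow(cx$ligand),
    n = nrow(cx$protein),
    pocket_radius = radius,
    pocket_residues = localize_pocket(cx, radius)
  )
}
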