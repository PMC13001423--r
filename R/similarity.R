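# Ligand similarity: Tanimoto over extended-connectivity (Morgan)
# fingerprints computed on ChemmineR/OpenBabel-parsed molecular graphs.
# Protein similarity: Needleman-Wunsch global alignment percent identity
# via Biostrings.

.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
  CL = 17, BR = 35, I = 53, SE = 34, SI = 14
)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles SMILES line notation.
#' @return List: `elements` (heavy-atom symbols), `bonds` (data.frame
#'   a, b, order), `charges`.
#' @export
parse_smiles <- function(smiles) {
  # single-atom molecules confuse the SDF round trip; handle them directly
  single <- regmatches(smiles,
    regexec("^\\[?([A-Z][a-z]?)[H0-9+-]*\\]?$", smiles))[[1]]
  if (length(single) == 2 && toupper(single[2]) %in% names(.atomic_numbers)) {
    chg <- if (grepl("\\+", smiles)) 1L else if (grepl("-", smiles)) -1L
           else 0L
    return(list(elements = toupper(single[2]),
                bonds = data.frame(a = integer(), b = integer(),
                                   order = integer()),
                charges = chg))
  }
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) stop("invalid SMILES: ", smiles))
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0) stop("invalid SMILES: ", smiles)
  elements <- toupper(gsub("_.*", "", rownames(ab)))
  if (!all(grepl("^[A-Z]{1,2}$", elements)))
    stop("invalid SMILES: ", smiles)
  bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
  if (!is.null(bb) && !is.matrix(bb)) bb <- matrix(bb, nrow = 1)
  bonds <- if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3)
    data.frame(a = integer(), b = integer(), order = integer())
  else data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                  order = as.integer(bb[, 3]))
  charges <- if (ncol(ab) >= 5) as.integer(ab[, 5]) else
    integer(length(elements))
  heavy <- elements != "H"
  if (!all(heavy)) {
    idx <- which(heavy); remap <- match(seq_along(elements), idx)
    bonds <- bonds[bonds$a %in% idx & bonds$b %in% idx, , drop = FALSE]
    bonds$a <- remap[bonds$a]; bonds$b <- remap[bonds$b]
    elements <- elements[heavy]; charges <- charges[heavy]
  }
  list(elements = elements, bonds = bonds, charges = charges)
}

#' Ligand record: tokens aligned to heavy atoms
#'
#' @param smiles SMILES notation.
#' @param selfies Optional SELFIES notation, carried as an opaque
#'   annotation.
#' @return Object of class `ligand_record` with `smiles`, `selfies`,
#'   `atom_tokens` (element symbols, one per heavy atom), `graph`.
#' @export
ligand_record <- function(smiles, selfies = NULL) {
  g <- parse_smiles(smiles)
  structure(list(smiles = smiles, selfies = selfies,
                 atom_tokens = g$elements, graph = g),
            class = "ligand_record")
}

# ring membership per atom: atoms incident to a non-bridge edge
.in_ring <- function(n_atoms, bonds) {
  inring <- logical(n_atoms)
  if (nrow(bonds) == 0 || n_atoms < 3) return(inring)
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a", "b")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n_atoms)
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  br <- igraph::bridges(g)
  cyc_edges <- setdiff(seq_len(nrow(bonds)), as.integer(br))
  if (length(cyc_edges) > 0)
    inring[unique(unlist(bonds[cyc_edges, c("a", "b")]))] <- TRUE
  inring
}

#' Extended-connectivity (Morgan) fingerprint bit set
#'
#' Iterative neighborhood relabelling: each atom starts from a hash of
#' (atomic number, heavy degree, total bond order, formal charge, ring
#' membership); for `radius` rounds, identifiers are rehashed together
#' with the sorted (bond order, neighbor identifier) pairs. All
#' identifiers from all rounds are folded into `nbits` bits.
#'
#' @param smiles SMILES notation (or a pre-parsed graph from
#'   [parse_smiles()]).
#' @param radius Neighborhood radius (default 2, ECFP4-like).
#' @param nbits Bit-space size (default 2048).
#' @return Sorted integer vector of set bit positions (0-based).
#' @export
ecfp_bits <- function(smiles, radius = 2, nbits = 2048) {
  g <- if (is.character(smiles)) parse_smiles(smiles) else smiles
  na <- length(g$elements)
  z <- .atomic_numbers[g$elements]
  z[is.na(z)] <- 0
  deg <- tabulate(c(g$bonds$a, g$bonds$b), nbins = na)
  val <- numeric(na)
  for (r in seq_len(nrow(g$bonds))) {
    val[g$bonds$a[r]] <- val[g$bonds$a[r]] + g$bonds$order[r]
    val[g$bonds$b[r]] <- val[g$bonds$b[r]] + g$bonds$order[r]
  }
  ring <- .in_ring(na, g$bonds)
  ids <- vapply(seq_len(na), function(a)
    .hash_ints(c(z[a], deg[a], val[a], g$charges[a], ring[a])), integer(1))
  all_ids <- ids
  nbrs <- lapply(seq_len(na), function(a) {
    sel <- g$bonds$a == a | g$bonds$b == a
    data.frame(order = g$bonds$order[sel],
               at = ifelse(g$bonds$a[sel] == a, g$bonds$b[sel],
                           g$bonds$a[sel]))
  })
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(na), function(a) {
      nb <- nbrs[[a]]
      pairs <- cbind(nb$order, ids[nb$at])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      .hash_ints(c(r, ids[a], as.vector(t(pairs))))
    }, integer(1))
    all_ids <- c(all_ids, ids)
  }
  sort(unique(all_ids %% nbits))
}

#' Tanimoto (Jaccard) similarity of two bit sets
#'
#' @param a,b Integer vectors of set bit positions.
#' @return `|a & b| / |a | b|`; 1 when both sets are empty.
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Ligand chemical similarity (Tanimoto over ECFP)
#'
#' @param a,b SMILES strings.
#' @param radius,nbits Fingerprint parameters (default radius 2, 2048
#'   bits).
#' @return Similarity in `[0, 1]`.
#' @export
ligand_similarity <- function(a, b, radius = 2, nbits = 2048) {
  tanimoto(ecfp_bits(a, radius, nbits), ecfp_bits(b, radius, nbits))
}

.aa_submat <- function() {
  letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V", "U", "O", "B", "J",
               "Z", "X", "*")
  m <- diag(1, length(letters))
  dimnames(m) <- list(letters, letters)
  m
}

#' Protein global sequence identity (Needleman-Wunsch)
#'
#' Global alignment with match 1, mismatch 0, linear gap penalty
#' (`gap` per gapped position); identity is the fraction of identical
#' aligned positions over the alignment length (gaps included), in
#' percent.
#'
#' @param a,b Amino-acid sequences (strings).
#' @param gap Per-position gap penalty (positive number; default 1).
#' @return Percent identity in `[0, 100]`.
#' @export
protein_similarity <- function(a, b, gap = 1) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = .aa_submat(),
    gapOpening = 0, gapExtension = gap, type = "global")
  s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  100 * sum(s1 == s2 & s1 != "-") / length(s1)
}
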