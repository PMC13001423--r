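# Synthetic fixtures: toy complexes with planted contacts whose annotation
# round-trips exactly, and embedding corpora with contact-informed latent
# structure for training/recovery experiments.
#
# Toy geometry: residues are placed as small template clusters on a 15 A
# lattice (far beyond every detection window, so nothing interacts by
# accident); each planted contact chooses a residue template whose
# interaction site points up (+z) and parks the partner ligand atom (or a
# benzene-like ring for pi-stacking) directly above it at the target
# distance. Unused ligand atoms are parked 60 A away. Fixture ligands are
# labeled pseudo-atoms, not chemically valid molecules.

.res_templates <- list(
  GLY = data.frame(
    elety = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    x = c(-1.4, 0, 1.3, 1.5), y = c(0.4, 0, 0.5, 0.5),
    z = c(0, 0.2, 0, 1.5)),
  ALA = data.frame(
    elety = c("N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C"),
    x = c(-1.4, 0, 1.3, 1.9, -0.4), y = c(0.4, 0, 0.5, 0.5, -1.2),
    z = c(0, 0, 0, 1.0, 0.8)),
  SER = data.frame(
    elety = c("N", "CA", "C", "O", "CB", "OG"),
    element = c("N", "C", "C", "O", "C", "O"),
    x = c(-1.4, 0, 1.3, 1.9, 0, 0), y = c(0.4, 0, 0.5, 0.5, -0.9, -0.9),
    z = c(0, 0, 0, 1.0, 1.0, 2.4)),
  ASP = data.frame(
    elety = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    element = c("N", "C", "C", "O", "C", "C", "O", "O"),
    x = c(-1.4, 0, 1.3, 1.9, 0, 0, -1.1, 1.1),
    y = c(0.4, 0, 0.5, 0.5, -0.9, -0.9, -0.9, -0.9),
    z = c(0, 0, 0, 1.0, 0.9, 2.2, 2.9, 2.9)),
  LEU = data.frame(
    elety = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
    element = c("N", "C", "C", "O", "C", "C", "C", "C"),
    x = c(-1.4, 0, 1.3, 1.9, 0, 0, 0, 1.3),
    y = c(0.4, 0, 0.5, 0.5, -0.9, -0.9, -0.9, -0.3),
    z = c(0, 0, 0, 1.0, 0.9, 2.0, 3.4, 2.0)),
  PHE = data.frame(
    elety = c("N", "CA", "C", "O", "CB",
              "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    element = c("N", "C", "C", "O", "C", "C", "C", "C", "C", "C", "C"),
    x = c(-1.4, 0, 1.3, 1.9, 0, 1.39, 0.695, -0.695, -1.39, -0.695, 0.695),
    y = c(0.4, 0, 0.5, 0.5, -0.9,
          -0.9, 0.304, 0.304, -0.9, -2.104, -2.104),
    z = c(-0.6, -0.6, -0.6, -1.6, 0.2, 2, 2, 2, 2, 2, 2))
)

.type_residue <- c(hbond = "SER", salt_bridge = "ASP", hydrophobic = "LEU",
                   vdw = "GLY", pipi = "PHE", cation_pi = "PHE")

# interaction site in template-local coordinates
.type_site <- function(type) {
  switch(type,
    hbond = c(0, -0.9, 2.4),          # SER OG
    salt_bridge = c(0, -0.9, 2.9),    # ASP OD centroid
    hydrophobic = c(0, -0.9, 3.4),    # LEU CD1
    vdw = c(1.5, 0.5, 1.5),           # GLY backbone O
    pipi = c(0, -0.9, 2.0),           # PHE ring centroid
    cation_pi = c(0, -0.9, 2.0))
}

.type_lig_element <- c(hbond = "N", salt_bridge = "N", hydrophobic = "C",
                       vdw = "C", pipi = "C", cation_pi = "N")

# distance window a planted contact of this type must respect (the vdw
# fixture pairs a ligand carbon with a backbone oxygen)
.synth_window <- function(type, rules = default_rules()) {
  if (type == "vdw") rule_window(rules, "vdw", "C", "O")
  else rule_window(rules, type)
}

#' Specification of a synthetic planted-contact complex
#'
#' @param n Number of protein residues.
#' @param m Number of ligand heavy atoms.
#' @param contacts data.frame with columns `type`, `i` (ligand atom
#'   index), `j` (residue position), `dist` (target distance, Angstrom,
#'   strictly inside the type's detection window). A `pipi` contact
#'   occupies ligand indices `i..i+5` (a planted 6-ring with atom `i`
#'   closest to the protein ring).
#' @param seed Geometry seed (reserved; the lattice itself is
#'   deterministic).
#' @return List of class `synthetic_complex_spec`.
#' @export
synthetic_complex_spec <- function(n, m, contacts = NULL, seed = 1) {
  if (is.null(contacts))
    contacts <- data.frame(type = character(), i = integer(), j = integer(),
                           dist = numeric())
  structure(list(n = n, m = m, contacts = contacts, seed = seed),
            class = "synthetic_complex_spec")
}

.validate_spec <- function(spec, rules) {
  ct <- spec$contacts
  if (nrow(ct) == 0) return(invisible(TRUE))
  if (!all(ct$type %in% interaction_types()))
    stop("unknown contact type in spec")
  used_i <- integer(); used_j <- integer()
  for (r in seq_len(nrow(ct))) {
    ii <- if (ct$type[r] == "pipi") ct$i[r] + 0:5 else ct$i[r]
    if (any(ii < 1 | ii > spec$m) || ct$j[r] < 1 || ct$j[r] > spec$n)
      stop("planted contact index out of range")
    if (any(ii %in% used_i) || ct$j[r] %in% used_j)
      stop("infeasible geometry: overlapping placements in spec")
    used_i <- c(used_i, ii); used_j <- c(used_j, ct$j[r])
    w <- .synth_window(ct$type[r], rules)
    if (!(ct$dist[r] > w[1] && ct$dist[r] < w[2]))
      stop("planted distance ", ct$dist[r], " not strictly inside the ",
           ct$type[r], " window [", w[1], ", ", w[2], "]")
  }
  invisible(TRUE)
}

#' Ground-truth maps implied by a planted-contact specification
#'
#' Computes the per-type and overall interaction maps analytically from
#' the planted distances via [decay_strength()], without constructing
#' geometry.
#'
#' @param spec A `synthetic_complex_spec` (or compatible list).
#' @param rules A `rule_config`.
#' @return List with `maps`, `overall`, `residue_labels`, `site_pairs`,
#'   matching the layout of [annotate_complex()] output.
#' @export
planted_maps <- function(spec, rules = default_rules()) {
  maps <- stats::setNames(
    lapply(interaction_types(), function(t) matrix(0, spec$m, spec$n)),
    interaction_types())
  ct <- spec$contacts
  for (r in seq_len(nrow(ct))) {
    w <- .synth_window(ct$type[r], rules)
    maps[[ct$type[r]]][ct$i[r], ct$j[r]] <-
      decay_strength(ct$dist[r], w[1], w[2], rules$floor)
  }
  overall <- aggregate_overall(maps, method = rules$aggregation)
  lab <- project_residue_labels(overall)
  c(list(maps = maps, overall = overall), lab)
}

#' Build a synthetic complex with planted contacts
#'
#' Constructs toy geometry realizing exactly the planted contacts: running
#' [annotate_complex()] with the same rules recovers the contact list
#' (type, i, j) exactly, with strengths equal to the decayed target
#' distances.
#'
#' @param spec A `synthetic_complex_spec`.
#' @param rules A `rule_config`.
#' @return List: `cx` (a `complex_structure`), `truth` (ground-truth maps
#'   from [planted_maps()]), `spec`.
#' @export
make_complex <- function(spec, rules = default_rules()) {
  .validate_spec(spec, rules)
  n <- spec$n; m <- spec$m; ct <- spec$contacts
  res_types <- rep("ALA", n)
  if (nrow(ct) > 0) res_types[ct$j] <- .type_residue[ct$type]

  ncol_grid <- ceiling(sqrt(n))
  origin <- function(j) c(((j - 1) %% ncol_grid) * 15,
                          ((j - 1) %/% ncol_grid) * 15, 0)

  prot <- do.call(rbind, lapply(seq_len(n), function(j) {
    tpl <- .res_templates[[res_types[j]]]
    o <- origin(j)
    data.frame(type = "ATOM", elety = tpl$elety, resid = res_types[j],
               chain = "A", resno = j, insert = "", x = tpl$x + o[1],
               y = tpl$y + o[2], z = tpl$z + o[3], o = 1,
               element = tpl$element, j = j, stringsAsFactors = FALSE)
  }))

  # default: park ligand atoms far away, element C
  lx <- (seq_len(m) - 1) * 8
  lig <- data.frame(type = "HETATM", elety = paste0("C", seq_len(m)),
                    resid = "LIG", chain = "X", resno = 900, insert = "",
                    x = lx, y = -30, z = 60, o = 1, element = "C",
                    i = seq_len(m), stringsAsFactors = FALSE)

  for (r in seq_len(nrow(ct))) {
    type <- ct$type[r]; i <- ct$i[r]; j <- ct$j[r]; dtar <- ct$dist[r]
    o <- origin(j); site <- .type_site(type) + o
    el <- .type_lig_element[[type]]
    if (type == "pipi") {
      delta <- 0.35; rr <- 1.39
      tz <- sqrt(dtar^2 - delta^2)
      cen <- site + c(delta, 0, tz)
      th <- (180 - 60 * (0:5)) * pi / 180
      for (k in 0:5) {
        lig$x[i + k] <- cen[1] + rr * cos(th[k + 1])
        lig$y[i + k] <- cen[2] + rr * sin(th[k + 1])
        lig$z[i + k] <- cen[3]
        lig$element[i + k] <- "C"
        lig$elety[i + k] <- paste0("C", i + k)
      }
    } else {
      lig$x[i] <- site[1]; lig$y[i] <- site[2]; lig$z[i] <- site[3] + dtar
      lig$element[i] <- el
      lig$elety[i] <- paste0(el, i)
    }
  }

  protein <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                        resid = res_types, j = seq_len(n),
                        stringsAsFactors = FALSE)
  cx <- structure(list(
    atoms = rbind(prot[, setdiff(names(prot), "j")],
                  stats::setNames(lig[, setdiff(names(lig), "i")],
                                  setdiff(names(prot), "j"))),
    protein = protein, prot_atoms = prot, ligand = lig,
    ligand_name = "LIG",
    source_id = sprintf("synthetic-n%d-m%d-seed%d", n, m, spec$seed)
  ), class = "complex_structure")

  list(cx = cx, truth = planted_maps(spec, rules), spec = spec)
}

#' Specification of a synthetic protein-ligand training pair
#'
#' @param n,m Token counts (protein residues / ligand atoms).
#' @param y Binding label (1 requires at least one planted contact, 0
#'   requires none).
#' @param contacts Planted contacts as in [synthetic_complex_spec()].
#' @param seed Pair seed for embeddings, noise and latent directions.
#' @return List of class `synthetic_pair_spec`.
#' @export
synthetic_pair_spec <- function(n, m, y, contacts = NULL, seed = 1) {
  if (is.null(contacts))
    contacts <- data.frame(type = character(), i = integer(), j = integer(),
                           dist = numeric())
  if (y == 1 && nrow(contacts) == 0)
    stop("positive pair must have at least one planted contact")
  if (y == 0 && nrow(contacts) > 0)
    stop("negative pair must have no planted contacts")
  structure(list(n = n, m = m, y = y, contacts = contacts, seed = seed),
            class = "synthetic_pair_spec")
}

#' Random planted-contact pair specifications
#'
#' Samples balanced positive/negative pair specs: positives carry 1-3
#' planted contacts (uniform over types and map cells, distances uniform
#' strictly inside the type's window), negatives none.
#'
#' @param n_pairs Number of pairs (split evenly between labels).
#' @param n,m Token counts.
#' @param max_contacts Maximum planted contacts per positive pair.
#' @param seed Seed.
#' @param types Contact types to sample from (default: all single-atom
#'   types; `pipi` is excluded here because its 6-atom ring only matters
#'   for geometric fixtures, not embedding corpora).
#' @return List of `synthetic_pair_spec`.
#' @export
sample_pair_specs <- function(n_pairs, n = 30, m = 8, max_contacts = 3,
                              seed = 1,
                              types = c("hbond", "salt_bridge", "vdw",
                                        "hydrophobic", "cation_pi")) {
  .with_seed(.hash_ints(c(seed, 101)), {
    lapply(seq_len(n_pairs), function(k) {
      y <- as.integer(k %% 2 == 1)
      ct <- NULL
      if (y == 1) {
        nc <- sample(seq_len(max_contacts), 1)
        tt <- sample(types, nc, replace = TRUE)
        ii <- sample(m, nc); jj <- sample(n, nc)
        dd <- vapply(tt, function(t) {
          w <- .synth_window(t); stats::runif(1, w[1] + 0.05, w[2] - 0.05)
        }, numeric(1))
        ct <- data.frame(type = tt, i = ii, j = jj, dist = dd)
      }
      synthetic_pair_spec(n, m, y, ct, seed = .hash_ints(c(seed, k)))
    })
  })
}

#' Generate a training corpus from pair specifications
#'
#' For each pair, token embeddings come from the frozen hash encoder;
#' then, for every planted contact, a seeded unit latent direction is
#' added to both the ligand-atom and the protein-residue embedding
#' (strength `beta`), followed by i.i.d. Gaussian noise of scale `sigma`.
#' Interacting tokens thus share a latent direction the attention module
#' can learn to detect. Positives carry their ground-truth maps; negative
#' pairs have no interaction annotation. Pure function of (specs, seed).
#'
#' @param specs List of `synthetic_pair_spec` (at least one of each
#'   label).
#' @param seed Corpus seed.
#' @param h Embedding dimension.
#' @param beta Latent direction strength.
#' @param sigma Noise scale (default 0.1).
#' @param encoder Registered encoder name.
#' @return List of class `crossbind_corpus`; each element has `P`, `D`,
#'   `y`, `maps` (or `NULL`), `spec`, `latents`.
#' @export
make_dataset <- function(specs, seed = 1, h = 64, beta = 1.5, sigma = 0.1,
                         encoder = "hash") {
  ys <- vapply(specs, `[[`, 0, "y")
  if (length(specs) < 2 || length(unique(ys)) < 2)
    stop("corpus must contain both positive and negative pairs")
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  out <- lapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    ps <- .hash_ints(c(seed, sp$seed, k))
    tok <- .with_seed(ps, list(
      prot = sample(aa, sp$n, replace = TRUE),
      lig = sample(c("C", "N", "O"), sp$m, replace = TRUE)))
    E <- encode(tok$prot, tok$lig, h = h, encoder = encoder, seed = ps)
    P <- E$P; D <- E$D
    latents <- list()
    for (r in seq_len(nrow(sp$contacts))) {
      u <- .with_seed(.hash_ints(c(ps, 7, r)), stats::rnorm(h))
      u <- u / sqrt(sum(u^2))
      i <- sp$contacts$i[r]; j <- sp$contacts$j[r]
      D[i, ] <- D[i, ] + beta * u
      P[j, ] <- P[j, ] + beta * u
      latents[[r]] <- u
    }
    if (sigma > 0) {
      noise <- .with_seed(.hash_ints(c(ps, 13)), list(
        P = matrix(stats::rnorm(sp$n * h, sd = sigma), sp$n, h),
        D = matrix(stats::rnorm(sp$m * h, sd = sigma), sp$m, h)))
      P <- P + noise$P; D <- D + noise$D
    }
    maps <- if (sp$y == 1) planted_maps(sp) else NULL
    list(P = P, D = D, y = sp$y, maps = maps, spec = sp, latents = latents)
  })
  structure(out, class = "crossbind_corpus")
}
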