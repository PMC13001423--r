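# Rule-based detection of six non-covalent interaction classes and assembly
# of per-type residue-atom strength maps.
#
# Chemistry perception is deliberately simple and name/element-based (the
# input is a plain coordinate file): protein donors/acceptors are N/O atoms,
# charged groups and aromatic rings come from residue-name templates, and
# ligand nitrogens/oxygens are treated as cation/anion candidates unless the
# caller supplies explicit atom lists. All constants live in `rule_config`.

.backbone_names <- c("N", "CA", "C", "O", "OXT")

.pos_groups <- list(
  ARG = c("NH1", "NH2", "CZ", "NE"),
  LYS = c("NZ"),
  HIS = c("ND1", "NE2")
)
.neg_groups <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)
.aromatic_rings <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

.dist_mat <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

.empty_contacts <- function() {
  data.frame(type = character(), i = integer(), j = integer(),
             d = numeric(), angle = numeric(), strength = numeric(),
             stringsAsFactors = FALSE)
}

.contact_rows <- function(type, i, j, d, rules, angle = NA_real_) {
  if (length(i) == 0) return(.empty_contacts())
  if (type == "vdw") stop(".contact_rows: vdw strengths are pair-specific")
  w <- rule_window(rules, type)
  data.frame(type = type, i = as.integer(i), j = as.integer(j), d = d,
             angle = if (length(angle) == 1) rep(angle, length(i)) else angle,
             strength = decay_strength(d, w[1], w[2], rules$floor),
             stringsAsFactors = FALSE)
}

# keep one contact per (i, j) at minimum distance
.dedup_contacts <- function(ct) {
  if (nrow(ct) == 0) return(ct)
  ord <- order(ct$i, ct$j, ct$d)
  ct <- ct[ord, ]
  ct[!duplicated(ct[, c("i", "j")]), , drop = FALSE]
}

# hydrogens attached (within rules$h_bond_len) to a heavy atom position
.attached_h <- function(cx, rules) {
  h <- cx$atoms[cx$atoms$element %in% c("H", "D"), , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  .coords(h)
}

.hba_angle <- function(donor, h, acceptor) {
  u <- donor - h; v <- acceptor - h
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# plane normal by SVD; returns list(normal, max_dev)
.ring_plane <- function(pts) {
  c0 <- colMeans(pts)
  s <- svd(sweep(pts, 2, c0))
  normal <- s$v[, 3]
  list(centroid = c0, normal = normal,
       max_dev = max(abs(sweep(pts, 2, c0) %*% normal)))
}

#' Detect rings among ligand heavy atoms
#'
#' Bonds are perceived by a heavy-atom distance cutoff, rings of size 5-6
#' are enumerated on the bond graph, and a ring is kept as aromatic-capable
#' when all members are C/N and the ring is near-planar (max out-of-plane
#' deviation 0.15 Angstrom).
#'
#' @param cx A `complex_structure`.
#' @param rules A `rule_config` (supplies `bond_cutoff`).
#' @return List of integer vectors of ligand atom indices (possibly empty).
#' @export
detect_ligand_rings <- function(cx, rules = default_rules()) {
  L <- .coords(cx$ligand)
  m <- nrow(L)
  if (m < 5) return(list())
  D <- .dist_mat(L, L)
  adj <- which(D > 0.4 & D <= rules$bond_cutoff & upper.tri(D), arr.ind = TRUE)
  if (nrow(adj) == 0) return(list())
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  if (igraph::vcount(g) < m) g <- igraph::add_vertices(g, m - igraph::vcount(g))
  rings <- list()
  seen <- character()
  for (e in seq_len(nrow(adj))) {
    u <- adj[e, 1]; v <- adj[e, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v)$vpath[[1]])
    if (length(sp) %in% c(5, 6)) {
      memb <- sort(as.integer(sp))
      key <- paste(memb, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        elems <- cx$ligand$element[memb]
        if (all(elems %in% c("C", "N"))) {
          pl <- .ring_plane(L[memb, , drop = FALSE])
          if (pl$max_dev <= 0.15) rings[[length(rings) + 1]] <- memb
        }
      }
    }
  }
  rings
}

# aromatic rings of pocket residues: list of (j, atoms idx into prot_atoms)
.protein_rings <- function(cx, pocket) {
  out <- list()
  pa <- cx$prot_atoms
  for (j in pocket) {
    resname <- toupper(cx$protein$resid[j])
    tpl <- .aromatic_rings[[resname]]
    if (is.null(tpl)) next
    rows <- which(pa$j == j)
    for (ring in tpl) {
      idx <- rows[match(ring, pa$elety[rows])]
      if (!anyNA(idx)) out[[length(out) + 1]] <- list(j = j, rows = idx)
    }
  }
  out
}

# charged-group centroids of pocket residues: data.frame(j, sign, x, y, z)
.protein_charged <- function(cx, pocket) {
  pa <- cx$prot_atoms
  res <- list()
  for (j in pocket) {
    resname <- toupper(cx$protein$resid[j])
    for (sgn in c(1, -1)) {
      tpl <- if (sgn > 0) .pos_groups[[resname]] else .neg_groups[[resname]]
      if (is.null(tpl)) next
      rows <- which(pa$j == j & pa$elety %in% tpl)
      if (length(rows) == 0) next
      cen <- colMeans(.coords(pa[rows, , drop = FALSE]))
      res[[length(res) + 1]] <- data.frame(
        j = j, sign = sgn, x = cen[1], y = cen[2], z = cen[3])
    }
  }
  if (length(res) == 0) return(NULL)
  do.call(rbind, res)
}

.detect_hbond <- function(cx, rules, pocket) {
  w <- rule_window(rules, "hbond")
  lig <- which(cx$ligand$element %in% c("N", "O"))
  pa <- cx$prot_atoms
  prot <- which(pa$j %in% pocket & pa$element %in% c("N", "O"))
  if (length(lig) == 0 || length(prot) == 0) return(.empty_contacts())
  Lc <- .coords(cx$ligand)[lig, , drop = FALSE]
  Pc <- .coords(pa)[prot, , drop = FALSE]
  D <- .dist_mat(Lc, Pc)
  hit <- which(D >= w[1] & D <= w[2], arr.ind = TRUE)
  if (nrow(hit) == 0) return(.empty_contacts())
  Hc <- .attached_h(cx, rules)
  keep <- logical(nrow(hit)); ang <- rep(NA_real_, nrow(hit))
  for (r in seq_len(nrow(hit))) {
    a <- Lc[hit[r, 1], ]; b <- Pc[hit[r, 2], ]
    if (is.null(Hc)) { keep[r] <- TRUE; next }
    da <- sqrt(colSums((t(Hc) - a)^2)); db <- sqrt(colSums((t(Hc) - b)^2))
    hs <- which(da <= rules$h_bond_len | db <= rules$h_bond_len)
    if (length(hs) == 0) { keep[r] <- TRUE; next }
    angs <- vapply(hs, function(k) {
      if (da[k] <= rules$h_bond_len) .hba_angle(a, Hc[k, ], b)
      else .hba_angle(b, Hc[k, ], a)
    }, numeric(1))
    if (any(angs >= rules$hbond$angle_min)) {
      keep[r] <- TRUE
      ang[r] <- max(angs)
    }
  }
  hit <- hit[keep, , drop = FALSE]
  .contact_rows("hbond", lig[hit[, 1]], pa$j[prot[hit[, 2]]],
                D[cbind(hit[, 1], hit[, 2])], rules, ang[keep])
}

.detect_salt_bridge <- function(cx, rules, pocket,
                                lig_cations = NULL, lig_anions = NULL) {
  w <- rule_window(rules, "salt_bridge")
  grp <- .protein_charged(cx, pocket)
  if (is.null(grp)) return(.empty_contacts())
  if (is.null(lig_cations)) lig_cations <- which(cx$ligand$element == "N")
  if (is.null(lig_anions))  lig_anions  <- which(cx$ligand$element == "O")
  out <- .empty_contacts()
  for (sgn in c(1, -1)) {
    lig <- if (sgn > 0) lig_anions else lig_cations   # opposite charges pair
    g <- grp[grp$sign == sgn, , drop = FALSE]
    if (length(lig) == 0 || nrow(g) == 0) next
    D <- .dist_mat(.coords(cx$ligand)[lig, , drop = FALSE],
                   cbind(g$x, g$y, g$z))
    hit <- which(D >= w[1] & D <= w[2], arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out <- rbind(out, .contact_rows("salt_bridge", lig[hit[, 1]],
                                    g$j[hit[, 2]],
                                    D[cbind(hit[, 1], hit[, 2])], rules))
  }
  out
}

.detect_hydrophobic <- function(cx, rules, pocket) {
  w <- rule_window(rules, "hydrophobic")
  lig <- which(cx$ligand$element == "C")
  pa <- cx$prot_atoms
  prot <- which(pa$j %in% pocket & pa$element == "C" &
                  !(pa$elety %in% .backbone_names))
  if (length(lig) == 0 || length(prot) == 0) return(.empty_contacts())
  D <- .dist_mat(.coords(cx$ligand)[lig, , drop = FALSE],
                 .coords(pa)[prot, , drop = FALSE])
  hit <- which(D >= w[1] & D <= w[2], arr.ind = TRUE)
  .contact_rows("hydrophobic", lig[hit[, 1]], pa$j[prot[hit[, 2]]],
                D[cbind(hit[, 1], hit[, 2])], rules)
}

.detect_vdw <- function(cx, rules, pocket) {
  pa <- cx$prot_atoms
  prot <- which(pa$j %in% pocket)
  if (length(prot) == 0) return(.empty_contacts())
  D <- .dist_mat(.coords(cx$ligand), .coords(pa)[prot, , drop = FALSE])
  S <- outer(vdw_radius(cx$ligand$element),
             vdw_radius(pa$element[prot]), "+")
  hit <- which(D >= S - rules$vdw$slack & D <= S + rules$vdw$slack,
               arr.ind = TRUE)
  if (nrow(hit) == 0) return(.empty_contacts())
  d <- D[hit]; s <- S[hit]
  data.frame(type = "vdw", i = hit[, 1], j = pa$j[prot[hit[, 2]]],
             d = d, angle = NA_real_,
             strength = decay_strength(d, pmax(s - rules$vdw$slack, 0),
                                       s + rules$vdw$slack, rules$floor),
             stringsAsFactors = FALSE)
}

.interplanar_angle <- function(n1, n2) {
  cosang <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

.detect_pipi <- function(cx, rules, pocket) {
  w <- rule_window(rules, "pipi")
  lr <- detect_ligand_rings(cx, rules)
  pr <- .protein_rings(cx, pocket)
  if (length(lr) == 0 || length(pr) == 0)
    return(list(contacts = .empty_contacts(), cover = NULL))
  L <- .coords(cx$ligand); PA <- .coords(cx$prot_atoms)
  out <- .empty_contacts(); cover <- list()
  for (rl in lr) {
    pl_l <- .ring_plane(L[rl, , drop = FALSE])
    for (rp in pr) {
      pl_p <- .ring_plane(PA[rp$rows, , drop = FALSE])
      d <- sqrt(sum((pl_l$centroid - pl_p$centroid)^2))
      if (d < w[1] || d > w[2]) next
      a <- .interplanar_angle(pl_l$normal, pl_p$normal)
      ok <- a <= rules$pipi$parallel_max ||
        (a >= rules$pipi$tshape_min && a <= rules$pipi$tshape_max)
      if (!ok) next
      dd <- sqrt(colSums((t(L[rl, , drop = FALSE]) - pl_p$centroid)^2))
      i <- rl[which.min(dd)]   # nearest ring member, ties -> lowest index
      out <- rbind(out, .contact_rows("pipi", i, rp$j, d, rules, a))
      cover[[length(cover) + 1]] <- data.frame(i = rl, j = rp$j)
    }
  }
  list(contacts = out, cover = if (length(cover)) do.call(rbind, cover))
}

.detect_cation_pi <- function(cx, rules, pocket, lig_cations = NULL) {
  w <- rule_window(rules, "cation_pi")
  out <- .empty_contacts(); cover <- list()
  # ligand cation -> protein aromatic ring
  if (is.null(lig_cations)) lig_cations <- which(cx$ligand$element == "N")
  pr <- .protein_rings(cx, pocket)
  if (length(lig_cations) > 0 && length(pr) > 0) {
    PA <- .coords(cx$prot_atoms)
    for (rp in pr) {
      cen <- colMeans(PA[rp$rows, , drop = FALSE])
      d <- sqrt(colSums((t(.coords(cx$ligand)[lig_cations, , drop = FALSE]) -
                           cen)^2))
      hit <- which(d >= w[1] & d <= w[2])
      if (length(hit))
        out <- rbind(out, .contact_rows("cation_pi", lig_cations[hit],
                                        rp$j, d[hit], rules))
    }
  }
  # protein cation group -> ligand ring
  grp <- .protein_charged(cx, pocket)
  lr <- detect_ligand_rings(cx, rules)
  if (!is.null(grp) && length(lr) > 0) {
    g <- grp[grp$sign > 0, , drop = FALSE]
    L <- .coords(cx$ligand)
    for (rl in lr) {
      pl <- .ring_plane(L[rl, , drop = FALSE])
      if (nrow(g) == 0) next
      d <- sqrt(colSums((t(cbind(g$x, g$y, g$z)) - pl$centroid)^2))
      hit <- which(d >= w[1] & d <= w[2])
      for (k in hit) {
        dd <- sqrt(colSums((t(L[rl, , drop = FALSE]) -
                              as.numeric(cbind(g$x, g$y, g$z)[k, ]))^2))
        i <- rl[which.min(dd)]
        out <- rbind(out, .contact_rows("cation_pi", i, g$j[k], d[k], rules))
        cover[[length(cover) + 1]] <- data.frame(i = rl, j = g$j[k])
      }
    }
  }
  list(contacts = out, cover = if (length(cover)) do.call(rbind, cover))
}

#' Detect contacts of one interaction type
#'
#' Applies the type's chemistry eligibility, distance window and (where
#' defined) angular filter to all ligand-atom / pocket-residue pairs,
#' keeping one contact per (i, j) at the minimum realizing distance.
#'
#' @param cx A `complex_structure`.
#' @param type One of [interaction_types()].
#' @param rules A `rule_config`.
#' @param pocket Residue positions to scan; computed with
#'   [localize_pocket()] at `radius` when `NULL`.
#' @param radius Pocket radius used when `pocket` is `NULL`.
#' @return data.frame with columns type, i, j, d, angle, strength.
#' @export
detect_contacts <- function(cx, type, rules = default_rules(),
                            pocket = NULL, radius = 10) {
  if (!type %in% interaction_types()) stop("unknown interaction type: ", type)
  if (is.null(pocket)) pocket <- localize_pocket(cx, radius)
  ct <- switch(type,
    hbond = .detect_hbond(cx, rules, pocket),
    salt_bridge = .detect_salt_bridge(cx, rules, pocket),
    hydrophobic = .detect_hydrophobic(cx, rules, pocket),
    vdw = .detect_vdw(cx, rules, pocket),
    pipi = .detect_pipi(cx, rules, pocket)$contacts,
    cation_pi = .detect_cation_pi(cx, rules, pocket)$contacts
  )
  .dedup_contacts(ct)
}

#' Build an m x n strength map from contacts
#'
#' @param contacts data.frame with columns i, j, strength.
#' @param m,n Map dimensions (ligand atoms x protein residues).
#' @return m x n numeric matrix, zero where no contact.
#' @export
build_map <- function(contacts, m, n) {
  A <- matrix(0, m, n)
  if (nrow(contacts) > 0) {
    if (any(contacts$i < 1 | contacts$i > m | contacts$j < 1 | contacts$j > n))
      stop("contact index out of range for ", m, " x ", n, " map")
    A[cbind(contacts$i, contacts$j)] <- contacts$strength
  }
  A
}

#' Aggregate per-type maps into the overall interaction map
#'
#' Element-wise maximum by default, preserving the `[1e-6, 1]` range of
#' nonzero entries and strongest-force semantics; `"sum"` adds strengths
#' and clips at 1.
#'
#' @param maps List of equally-shaped numeric matrices.
#' @param method `"max"` or `"sum"`.
#' @return Matrix of the common shape.
#' @export
aggregate_overall <- function(maps, method = c("max", "sum")) {
  method <- match.arg(method)
  dims <- lapply(maps, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("shape mismatch across maps")
  if (method == "max") Reduce(pmax, maps)
  else pmin(Reduce(`+`, maps), 1)
}

#' Residue-level binding-site labels from the overall map
#'
#' @param overall m x n overall interaction map.
#' @return List: `residue_labels` (0/1 integer vector length n, 1 where the
#'   residue's column has any nonzero entry) and `site_pairs` (data.frame
#'   i, j of all nonzero cells).
#' @export
project_residue_labels <- function(overall) {
  nz <- which(overall > 0, arr.ind = TRUE)
  labels <- integer(ncol(overall))
  labels[unique(nz[, 2])] <- 1L
  sp <- data.frame(i = as.integer(nz[, 1]), j = as.integer(nz[, 2]))
  sp <- sp[order(sp$i, sp$j), , drop = FALSE]
  rownames(sp) <- NULL
  list(residue_labels = labels, site_pairs = sp)
}

#' Stratify binding affinity into supervision labels
#'
#' High-confidence negatives are pairs with affinity >= -5 kcal/mol,
#' positives <= -7 kcal/mol; moderate affinities are excluded to reduce
#' label ambiguity.
#'
#' @param affinity Numeric vector, kcal/mol.
#' @return Character vector in {"positive", "negative", "excluded"}.
#' @export
stratify_affinity <- function(affinity) {
  if (any(!is.finite(affinity))) stop("affinity must be finite")
  ifelse(affinity >= -5, "negative",
         ifelse(affinity <= -7, "positive", "excluded"))
}

#' Annotate a complex into an interaction map set
#'
#' Runs all six detectors on the binding pocket, applies
#' specific-over-generic precedence (van der Waals contacts are dropped at
#' cells carrying any specific type; hydrophobic contacts are dropped at
#' cells covered by a ring-mediated pi-pi or cation-pi contact, extended to
#' all atoms of the participating ligand ring), and assembles the per-type
#' maps, the overall map, residue labels and the binding-site pair list.
#'
#' @param cx A `complex_structure`.
#' @param rules A `rule_config`.
#' @param radius Pocket radius (Angstrom).
#' @return Object of class `interaction_maps`: `maps` (named list of six
#'   m x n matrices), `overall`, `residue_labels`, `site_pairs`, `contacts`
#'   (all retained contacts), `m`, `n`, `pocket`, `rules`.
#' @export
annotate_complex <- function(cx, rules = default_rules(), radius = 10) {
  stopifnot(inherits(cx, "complex_structure"))
  pocket <- localize_pocket(cx, radius)
  m <- nrow(cx$ligand); n <- nrow(cx$protein)

  hb <- .dedup_contacts(.detect_hbond(cx, rules, pocket))
  sb <- .dedup_contacts(.detect_salt_bridge(cx, rules, pocket))
  pp <- .detect_pipi(cx, rules, pocket)
  cp <- .detect_cation_pi(cx, rules, pocket)
  ppc <- .dedup_contacts(pp$contacts)
  cpc <- .dedup_contacts(cp$contacts)
  hp <- .dedup_contacts(.detect_hydrophobic(cx, rules, pocket))
  vw <- .dedup_contacts(.detect_vdw(cx, rules, pocket))

  pairkey <- function(df) if (is.null(df) || nrow(df) == 0) character()
    else paste(df$i, df$j)
  ring_cover <- unique(c(pairkey(pp$cover), pairkey(cp$cover)))
  if (nrow(hp) > 0)
    hp <- hp[!(pairkey(hp) %in% c(ring_cover, pairkey(ppc), pairkey(cpc))), ,
             drop = FALSE]
  specific <- unique(c(pairkey(hb), pairkey(sb), pairkey(ppc), pairkey(cpc),
                       pairkey(hp), ring_cover))
  if (nrow(vw) > 0) vw <- vw[!(pairkey(vw) %in% specific), , drop = FALSE]

  bytype <- list(hbond = hb, salt_bridge = sb, vdw = vw,
                 hydrophobic = hp, pipi = ppc, cation_pi = cpc)
  maps <- lapply(bytype, build_map, m = m, n = n)
  overall <- aggregate_overall(maps, method = rules$aggregation)
  lab <- project_residue_labels(overall)
  contacts <- do.call(rbind, bytype)
  rownames(contacts) <- NULL
  out <- list(maps = maps, overall = overall,
              residue_labels = lab$residue_labels,
              site_pairs = lab$site_pairs, contacts = contacts,
              m = m, n = n, pocket = pocket, rules = rules)
  class(out) <- "interaction_maps"
  out
}

#' @export
print.interaction_maps <- function(x, ...) {
  cat("interaction_maps: m =", x$m, "ligand atoms x n =", x$n, "residues\n")
  for (t in names(x$maps)) {
    cat(sprintf("  %-12s %d contacts\n", t, sum(x$maps[[t]] > 0)))
  }
  cat("  binding residues:", sum(x$residue_labels), "\n")
  invisible(x)
}
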