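# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops over all atom pairs (no pocket restriction),
# straight-line re-implementations of the attention formulas, and
# exhaustive alignment enumeration.

.odist <- function(a, b) sqrt(sum((a - b)^2))

.ocoords <- function(df) cbind(df$x, df$y, df$z)

.o_vdw_r <- function(el) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, F = 1.47)
  r <- tab[el]; r[is.na(r)] <- 1.70; unname(r)
}

# cycle detection: connected atom sets of size 5/6 where every member has
# exactly two neighbours within the group
.o_lig_rings <- function(lig) {
  L <- .ocoords(lig); m <- nrow(lig)
  if (m < 5) return(list())
  adj <- matrix(FALSE, m, m)
  for (a in seq_len(m - 1)) for (b in (a + 1):m)
    if (.odist(L[a, ], L[b, ]) <= 1.75) adj[a, b] <- adj[b, a] <- TRUE
  comp <- rep(0L, m); cid <- 0
  for (s in seq_len(m)) {
    if (comp[s] > 0) next
    cid <- cid + 1; queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0)
      comp[nb] <- cid; queue <- c(queue, nb)
    }
  }
  rings <- list()
  for (c0 in seq_len(cid)) {
    memb <- which(comp == c0)
    if (length(memb) %in% c(5, 6) &&
        all(rowSums(adj[memb, memb, drop = FALSE]) == 2) &&
        all(lig$element[memb] %in% c("C", "N")))
      rings[[length(rings) + 1]] <- memb
  }
  rings
}

.o_ring_geom <- function(pts) {
  cen <- colMeans(pts)
  v1 <- pts[1, ] - cen; v2 <- pts[2, ] - cen
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  list(cen = cen, nrm = nrm / sqrt(sum(nrm^2)))
}

.o_prot_rings <- function(cx) {
  tabs <- list(
    PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
               c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
    HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")))
  pa <- cx$prot_atoms
  out <- list()
  for (j in cx$protein$j) {
    for (ring in tabs[[toupper(cx$protein$resid[j])]]) {
      rows <- which(pa$j == j & pa$elety %in% ring)
      if (length(rows) == length(ring))
        out[[length(out) + 1]] <- c(list(j = j),
                                    .o_ring_geom(.ocoords(pa[rows, ])))
    }
  }
  out
}

.o_charged <- function(cx) {
  pos <- list(ARG = c("NH1", "NH2", "CZ", "NE"), LYS = "NZ",
              HIS = c("ND1", "NE2"))
  neg <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  pa <- cx$prot_atoms
  out <- list()
  for (j in cx$protein$j) {
    rn <- toupper(cx$protein$resid[j])
    for (s in c(1, -1)) {
      tpl <- if (s > 0) pos[[rn]] else neg[[rn]]
      if (is.null(tpl)) next
      rows <- which(pa$j == j & pa$elety %in% tpl)
      if (length(rows))
        out[[length(out) + 1]] <- list(j = j, sign = s,
                                       cen = colMeans(.ocoords(pa[rows, ])))
    }
  }
  out
}

# full-complex brute-force contact scan (hydrogen-free fixtures),
# applying the same default constants and the same specific-over-generic
# precedence, written as independent loops
oracle_contacts <- function(cx) {
  pa <- cx$prot_atoms; lig <- cx$ligand
  P <- .ocoords(pa); L <- .ocoords(lig)
  res <- list()
  add <- function(type, i, j, d)
    res[[length(res) + 1]] <<- data.frame(type = type, i = i, j = j, d = d)
  for (i in seq_len(nrow(lig))) for (a in seq_len(nrow(pa))) {
    d <- .odist(L[i, ], P[a, ])
    j <- pa$j[a]
    if (lig$element[i] %in% c("N", "O") && pa$element[a] %in% c("N", "O") &&
        d >= 2.5 && d <= 3.5) add("hbond", i, j, d)
    if (lig$element[i] == "C" && pa$element[a] == "C" &&
        !(pa$elety[a] %in% c("N", "CA", "C", "O", "OXT")) &&
        d >= 3.3 && d <= 4.0) add("hydrophobic", i, j, d)
    s <- .o_vdw_r(lig$element[i]) + .o_vdw_r(pa$element[a])
    if (d >= s - 0.5 && d <= s + 0.5) add("vdw", i, j, d)
  }
  for (g in .o_charged(cx)) {
    want <- if (g$sign > 0) "O" else "N"
    for (i in which(lig$element == want)) {
      d <- .odist(L[i, ], g$cen)
      if (d >= 3.0 && d <= 5.5) add("salt_bridge", i, g$j, d)
    }
  }
  lr <- .o_lig_rings(lig)
  pr <- .o_prot_rings(cx)
  cover <- character()
  for (rp in pr) {
    for (i in which(lig$element == "N")) {
      d <- .odist(L[i, ], rp$cen)
      if (d >= 3.5 && d <= 6.0) add("cation_pi", i, rp$j, d)
    }
    for (rl in lr) {
      gl <- .o_ring_geom(L[rl, , drop = FALSE])
      d <- .odist(gl$cen, rp$cen)
      if (d < 3.5 || d > 5.5) next
      ang <- acos(min(1, abs(sum(gl$nrm * rp$nrm)))) * 180 / pi
      if (!(ang <= 30 || (ang >= 60 && ang <= 90))) next
      dd <- apply(L[rl, , drop = FALSE], 1, .odist, b = rp$cen)
      add("pipi", rl[which.min(dd)], rp$j, d)
      cover <- c(cover, paste(rl, rp$j))
    }
  }
  for (g in .o_charged(cx)) {
    if (g$sign < 0) next
    for (rl in lr) {
      gl <- .o_ring_geom(L[rl, , drop = FALSE])
      d <- .odist(gl$cen, g$cen)
      if (d >= 3.5 && d <= 6.0) {
        dd <- apply(L[rl, , drop = FALSE], 1, .odist, b = g$cen)
        add("cation_pi", rl[which.min(dd)], g$j, d)
        cover <- c(cover, paste(rl, g$j))
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(type = character(), i = integer(), j = integer(),
                      d = numeric()))
  ct <- do.call(rbind, res)
  # dedup: min distance per (type, i, j)
  ct <- ct[order(ct$type, ct$i, ct$j, ct$d), ]
  ct <- ct[!duplicated(ct[, c("type", "i", "j")]), ]
  # precedence
  key <- function(df) paste(df$i, df$j)
  hp <- ct$type == "hydrophobic"
  drop_hp <- hp & key(ct) %in% c(cover,
                                 key(ct[ct$type %in% c("pipi", "cation_pi"), ]))
  ct <- ct[!drop_hp, ]
  vw <- ct$type == "vdw"
  ct <- ct[!(vw & key(ct) %in% c(cover, key(ct[ct$type != "vdw", ]))), ]
  rownames(ct) <- NULL
  ct
}

# straight-line dense re-implementation of the interaction-module forward
# pass (loops and explicit softmax; no shared code)
oracle_forward <- function(P, D, par, h, H) {
  softmax_vec <- function(v) { e <- exp(v - max(v)); e / sum(e) }
  att <- function(Q, K) {
    S <- matrix(0, nrow(Q), nrow(K))
    for (r in seq_len(nrow(Q))) for (c in seq_len(nrow(K)))
      S[r, c] <- sum(Q[r, ] * K[c, ]) / sqrt(h / H)
    t(apply(S, 1, softmax_vec))
  }
  n <- nrow(P); m <- nrow(D); ht <- h / H
  Pcat <- matrix(0, n, h); Dcat <- matrix(0, m, h)
  heads <- list()
  for (t in seq_len(H)) {
    ix <- ((t - 1) * ht + 1):(t * ht)
    Qp <- (P %*% par$Wqp)[, ix, drop = FALSE]
    Kp <- (P %*% par$Wkp)[, ix, drop = FALSE]
    Vp <- (P %*% par$Wvp)[, ix, drop = FALSE]
    Qd <- (D %*% par$Wqd)[, ix, drop = FALSE]
    Kd <- (D %*% par$Wkd)[, ix, drop = FALSE]
    Vd <- (D %*% par$Wvd)[, ix, drop = FALSE]
    A_pd <- att(Qp, Kd); A_dp <- att(Qd, Kp)
    A_pp <- att(Qp, Kp); A_dd <- att(Qd, Kd)
    Pcat[, ix] <- 0.5 * (A_pp %*% Vp + A_pd %*% Vd)
    Dcat[, ix] <- 0.5 * (A_dd %*% Vd + A_dp %*% Vp)
    heads[[t]] <- list(A_pd = A_pd, A_dp = A_dp)
  }
  Pstar <- Pcat %*% par$Wpo; Dstar <- Dcat %*% par$Wdo
  F <- c(colMeans(Dstar), colMeans(Pstar))
  z1 <- pmax(as.vector(F %*% par$W1) + par$b1, 0)
  z2 <- pmax(as.vector(z1 %*% par$W2) + par$b2, 0)
  p <- 1 / (1 + exp(-(sum(z2 * par$w3) + par$b3)))
  list(heads = heads, Pstar = Pstar, Dstar = Dstar, F = F, p = p)
}

# exhaustive global-alignment enumeration (match 1, mismatch 0, gap -1):
# returns the optimal score for sequences of length <= 6
oracle_nw_score <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1, j + 1, score + as.integer(A[i] == B[j]))
    if (i <= length(A)) rec(i + 1, j, score - 1)
    if (j <= length(B)) rec(i, j + 1, score - 1)
  }
  rec(1, 1, 0)
  best
}
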