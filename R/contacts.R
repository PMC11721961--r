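# Residue contact matrices and geometric ligand-receptor interaction
# fingerprints. The fingerprint rules are a documented geometric
# re-implementation of the usual profiler conventions (hydrophobic,
# hydrogen bond, halogen bond, pi-stacking, pi-cation, salt bridge, water
# bridge), not a clone of any particular program.

#' Residue contact matrix of one frame
#'
#' For every residue pair (i < j) of non-water, non-ligand atoms, the
#' minimum heavy-atom distance, reported only when it is at most `cutoff`.
#' Sequence-adjacent pairs are included by default.
#'
#' @param frame a `structure_frame` (>= 2 residues).
#' @param cutoff distance cutoff in Angstrom (default 6.5).
#' @param include_adjacent keep pairs with |i - j| == 1 (default TRUE).
#' @param method `"cells"` (spatial binning, default) or `"brute"` (double
#'   loop); the two must agree exactly.
#' @return data frame with `res_i`, `res_j` (residue numbers, i < j) and
#'   `distance` (Angstrom), ordered by (res_i, res_j).
#' @export
contact_matrix <- function(frame, cutoff = 6.5, include_adjacent = TRUE,
                           method = c("cells", "brute")) {
  method <- match.arg(method)
  sel <- which(frame$elem != "H" & !frame$ligand &
                 !toupper(frame$resname) %in% c("HOH", "WAT"))
  if (length(unique(frame$resno[sel])) < 2)
    stop("need >= 2 residues for a contact matrix")
  xyz <- coords(frame, sel)
  res <- frame$resno[sel]
  out <- if (method == "brute") .contacts_brute(xyz, res, cutoff)
  else .contacts_cells(xyz, res, cutoff)
  if (!include_adjacent)
    out <- out[abs(out$res_i - out$res_j) != 1L, , drop = FALSE]
  out[order(out$res_i, out$res_j), , drop = FALSE]
}

.contacts_brute <- function(xyz, res, cutoff) {
  n <- nrow(xyz)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * xyz %*% t(xyz)
  d <- sqrt(pmax(d2, 0))
  ri <- matrix(res, n, n)
  rj <- t(ri)
  keep <- which(d <= cutoff & ri < rj)
  if (length(keep) == 0)
    return(data.frame(res_i = integer(), res_j = integer(),
                      distance = numeric()))
  key <- paste(ri[keep], rj[keep], sep = "_")
  mins <- tapply(d[keep], key, min)
  parts <- do.call(rbind, strsplit(names(mins), "_"))
  data.frame(res_i = as.integer(parts[, 1]), res_j = as.integer(parts[, 2]),
             distance = as.numeric(mins))
}

.contacts_cells <- function(xyz, res, cutoff) {
  # spatial hash with cell size = cutoff; candidate pairs come only from
  # the same or adjacent cells, then exact distances are taken
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  # map from cell coordinates to member atoms
  ckey <- paste(cell[, 1], cell[, 2], cell[, 3])
  members <- split(seq_len(nrow(xyz)), ckey)
  coords_of <- do.call(rbind, strsplit(names(members), " "))
  storage.mode(coords_of) <- "integer"
  lookup <- new.env(hash = TRUE)
  for (k in seq_along(members)) assign(names(members)[k], members[[k]], lookup)
  best <- new.env(hash = TRUE)
  for (k in seq_along(members)) {
    cc <- coords_of[k, ]
    neigh <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      nm <- paste(cc[1] + dx, cc[2] + dy, cc[3] + dz)
      if (exists(nm, lookup, inherits = FALSE))
        neigh <- c(neigh, get(nm, lookup))
    }
    for (i in members[[k]]) {
      js <- neigh[res[neigh] != res[i]]
      if (length(js) == 0) next
      dd <- sqrt(colSums((t(xyz[js, , drop = FALSE]) - xyz[i, ])^2))
      ok <- which(dd <= cutoff)
      for (q in ok) {
        j <- js[q]
        a <- min(res[i], res[j]); b <- max(res[i], res[j])
        nm <- paste(a, b, sep = "_")
        cur <- if (exists(nm, best, inherits = FALSE))
          get(nm, best) else Inf
        if (dd[q] < cur) assign(nm, dd[q], best)
      }
    }
  }
  nms <- ls(best)
  if (length(nms) == 0)
    return(data.frame(res_i = integer(), res_j = integer(),
                      distance = numeric()))
  parts <- do.call(rbind, strsplit(nms, "_"))
  data.frame(res_i = as.integer(parts[, 1]), res_j = as.integer(parts[, 2]),
             distance = vapply(nms, function(nm) get(nm, best), numeric(1)),
             row.names = NULL)
}

# ---- chemistry helpers for fingerprints ------------------------------------

# heavy-atom bond graph by covalent distance (generic 1.9 A, 2.1 if S/P/Cl/Br/I)
.bond_pairs <- function(xyz, elem) {
  n <- nrow(xyz)
  if (n < 2) return(cbind(integer(0), integer(0)))
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * xyz %*% t(xyz)
  d <- sqrt(pmax(d2, 0))
  big <- elem %in% c("S", "P", "CL", "BR", "I")
  cut <- ifelse(outer(big, big, `|`), 2.1, 1.9)
  cut[elem == "H", ] <- 1.25
  cut[, elem == "H"] <- 1.25
  idx <- which(d > 0.4 & d <= cut & upper.tri(d), arr.ind = TRUE)
  idx
}

# rings of size 5 or 6 in an atom subset, via the bond graph
.find_rings <- function(xyz, elem) {
  heavy <- which(elem != "H")
  if (length(heavy) < 5) return(list())
  bp <- .bond_pairs(xyz[heavy, , drop = FALSE], elem[heavy])
  if (nrow(bp) == 0) return(list())
  g <- igraph::graph_from_edgelist(bp, directed = FALSE)
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(bp))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, bp[k, ]))
    sp <- suppressWarnings(igraph::shortest_paths(g2, bp[k, 1], bp[k, 2])$vpath[[1]])
    len <- length(sp)
    if (len %in% c(5, 6)) {
      ring <- sort(as.integer(sp))
      sig <- paste(ring, collapse = ",")
      if (!sig %in% seen) {
        seen <- c(seen, sig)
        rings[[length(rings) + 1L]] <- heavy[ring]
      }
    }
  }
  # keep roughly planar rings only (aromatic proxy)
  Filter(function(r) .ring_planarity(xyz[r, , drop = FALSE]) < 0.15, rings)
}

# RMS out-of-plane deviation of ring atoms
.ring_planarity <- function(p) {
  p <- sweep(p, 2, colMeans(p))
  sv <- svd(p)
  sqrt(mean((p %*% sv$v[, 3])^2))
}

.ring_normal <- function(p) {
  p <- sweep(p, 2, colMeans(p))
  svd(p)$v[, 3]
}

# positively charged centers of standard residues (Arg guanidinium carbon,
# Lys ammonium nitrogen); ligand cations are N atoms with >= 4 bonds
.protein_cations <- function(frame, xyz, sel) {
  nm <- trimws(frame$atom[sel])
  rn <- toupper(frame$resname[sel])
  sel[(rn == "ARG" & nm %in% c("CZ", "NH1", "NH2")) |
        (rn == "LYS" & nm == "NZ")]
}

.protein_anions <- function(frame, sel) {
  nm <- trimws(frame$atom[sel])
  rn <- toupper(frame$resname[sel])
  sel[(rn == "ASP" & nm %in% c("OD1", "OD2")) |
        (rn == "GLU" & nm %in% c("OE1", "OE2")) | nm == "OXT"]
}

# ligand formal charges by valence heuristics on the bond graph
.ligand_charges <- function(frame, xyz, lig) {
  if (length(lig) == 0) return(list(pos = integer(0), neg = integer(0)))
  sub <- xyz[lig, , drop = FALSE]
  el <- frame$elem[lig]
  bp <- .bond_pairs(sub, el)
  deg <- tabulate(c(bp[, 1], bp[, 2]), nbins = length(lig))
  pos <- lig[el == "N" & deg >= 4]
  # protonated primary amine: N bonded to >= 2 H
  nH <- vapply(seq_along(lig), function(i) {
    nb <- c(bp[bp[, 1] == i, 2], bp[bp[, 2] == i, 1])
    sum(el[nb] == "H")
  }, integer(1))
  pos <- union(pos, lig[el == "N" & nH >= 2])
  # carboxylate oxygens: O (deg 1) bonded to a C that carries two such O
  neg <- integer(0)
  for (i in seq_along(lig)) {
    if (el[i] != "O" || deg[i] != 1) next
    nb <- c(bp[bp[, 1] == i, 2], bp[bp[, 2] == i, 1])
    cpart <- nb[el[nb] == "C"]
    if (length(cpart) != 1) next
    onb <- c(bp[bp[, 1] == cpart, 2], bp[bp[, 2] == cpart, 1])
    if (sum(el[onb] == "O" & deg[onb] == 1) >= 2)
      neg <- c(neg, lig[i])
  }
  list(pos = pos, neg = unique(neg))
}

# aromatic ring atom sets for standard residues, by atom-name template
.protein_rings <- function(frame, sel) {
  out <- list()
  templates <- list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                    TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                    HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
                    HIE = c("CG", "ND1", "CD2", "CE1", "NE2"))
  for (rn in unique(frame$resno[sel])) {
    rows <- sel[frame$resno[sel] == rn]
    tpl <- templates[[toupper(frame$resname[rows[1]])]]
    if (is.null(tpl)) next
    idx <- rows[match(tpl, trimws(frame$atom[rows]))]
    if (any(is.na(idx))) next
    out[[length(out) + 1L]] <- idx
  }
  out
}

#' Default geometric rules for interaction fingerprints
#'
#' Thresholds (Angstrom / degrees) for the seven contact classes. All are
#' plain list entries and can be overridden per call.
#'
#' @return named list of rule parameters.
#' @export
fingerprint_rules <- function() {
  list(hpi_dist = 4.0,          # apolar C...C
       hb_dist = 3.5, hb_angle = 120,
       xb_dist = 3.5, xb_angle = 140,
       pst_dist = 5.5, pst_angle = 30, pst_tshape = c(60, 90),
       pic_dist = 6.0,
       sb_dist = 5.5,
       wb_leg_dist = 3.5)
}

#' Ligand-receptor interaction fingerprint of one frame
#'
#' Binary presence of seven contact classes between the flagged ligand and
#' each protein residue: hydrophobic (HPI), hydrogen bond (HB), halogen
#' bond (XB), pi-stacking (PST), pi-cation (PIC), salt bridge (SB), and
#' water bridge (WB). Geometry rules come from [fingerprint_rules()];
#' aromatic rings are taken from residue templates (protein) and from
#' planar 5/6-cycles of the distance-based bond graph (ligand), charges
#' from residue templates and ligand valence heuristics.
#'
#' @param frame a `structure_frame` with at least one flagged ligand atom.
#' @param rules rule list, see [fingerprint_rules()].
#' @return data frame with `resno`, `class`, `value` (0/1) covering every
#'   protein residue x class combination.
#' @export
interaction_fingerprint <- function(frame, rules = fingerprint_rules()) {
  lig <- which(frame$ligand)
  if (length(lig) == 0) stop("no-ligand: no atoms flagged as ligand")
  xyz <- coords(frame)
  water <- which(toupper(frame$resname) %in% c("HOH", "WAT"))
  prot <- which(!frame$ligand & frame$elem != "H" &
                  !seq_len(nrow(frame)) %in% water)
  residues <- sort(unique(frame$resno[prot]))
  classes <- c("HPI", "HB", "XB", "PST", "PIC", "SB", "WB")
  fp <- matrix(0L, length(residues), length(classes),
               dimnames = list(residues, classes))
  dist1 <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))

  # apolar carbons: C bonded to no N/O (ligand side via bond graph,
  # protein side likewise, computed once on the heavy atoms)
  heavy <- which(frame$elem != "H")
  bp_all <- .bond_pairs(xyz[heavy, , drop = FALSE], frame$elem[heavy])
  apolar <- rep(FALSE, nrow(frame))
  for (hi in seq_along(heavy)) {
    i <- heavy[hi]
    if (frame$elem[i] != "C") next
    nb <- heavy[c(bp_all[bp_all[, 1] == hi, 2], bp_all[bp_all[, 2] == hi, 1])]
    apolar[i] <- !any(frame$elem[nb] %in% c("N", "O"))
  }

  lig_heavy <- lig[frame$elem[lig] != "H"]
  lig_rings <- .find_rings(xyz[lig, , drop = FALSE], frame$elem[lig])
  lig_rings <- lapply(lig_rings, function(r) lig[r])
  lig_q <- .ligand_charges(frame, xyz, lig_heavy)
  prot_rings <- .protein_rings(frame, prot)
  prot_cat <- .protein_cations(frame, xyz, prot)
  prot_an <- .protein_anions(frame, prot)
  lig_pol <- lig[frame$elem[lig] %in% c("N", "O")]
  halogens <- lig[frame$elem[lig] %in% c("F", "CL", "BR", "I")]

  mark <- function(resno, cls) {
    fp[as.character(resno), cls] <<- 1L
  }

  for (rn in residues) {
    ratoms <- prot[frame$resno[prot] == rn]
    # HPI: apolar carbon pair within cutoff
    ra <- ratoms[apolar[ratoms]]
    la <- lig_heavy[apolar[lig_heavy]]
    if (length(ra) > 0 && length(la) > 0) {
      dmin <- min(sqrt(outer(rowSums(xyz[ra, , drop = FALSE]^2),
                             rowSums(xyz[la, , drop = FALSE]^2), `+`) -
                         2 * xyz[ra, , drop = FALSE] %*%
                         t(xyz[la, , drop = FALSE])))
      if (is.finite(dmin) && dmin <= rules$hpi_dist) mark(rn, "HPI")
    }
    # HB: ligand polar atom vs residue polar atom (distance proxy; frames
    # rarely carry polar hydrogens in this pipeline)
    rpol <- ratoms[frame$elem[ratoms] %in% c("N", "O")]
    if (length(rpol) > 0 && length(lig_pol) > 0) {
      for (a in rpol) for (b in lig_pol) {
        if (dist1(a, b) <= rules$hb_dist) { mark(rn, "HB"); break }
      }
    }
    # XB: C-X...acceptor
    if (length(halogens) > 0 && length(rpol) > 0) {
      for (x in halogens) {
        cx <- lig_heavy[frame$elem[lig_heavy] == "C"]
        if (length(cx) == 0) next
        dcx <- sqrt(colSums((t(xyz[cx, , drop = FALSE]) - xyz[x, ])^2))
        cdonor <- cx[which.min(dcx)]
        if (min(dcx) > 2.1) next
        for (a in rpol) {
          if (dist1(x, a) > rules$xb_dist) next
          v1 <- xyz[cdonor, ] - xyz[x, ]
          v2 <- xyz[a, ] - xyz[x, ]
          ang <- acos(pmin(pmax(sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
          if (ang >= rules$xb_angle) { mark(rn, "XB"); break }
        }
      }
    }
    # PST: ring-ring centroid distance + plane angle
    rr <- Filter(function(r) frame$resno[r[1]] == rn, prot_rings)
    if (length(rr) > 0 && length(lig_rings) > 0) {
      for (r1 in rr) for (r2 in lig_rings) {
        c1 <- colMeans(xyz[r1, , drop = FALSE])
        c2 <- colMeans(xyz[r2, , drop = FALSE])
        if (sqrt(sum((c1 - c2)^2)) > rules$pst_dist) next
        n1 <- .ring_normal(xyz[r1, , drop = FALSE])
        n2 <- .ring_normal(xyz[r2, , drop = FALSE])
        ang <- acos(pmin(abs(sum(n1 * n2)), 1)) * 180 / pi
        if (ang <= rules$pst_angle ||
            (ang >= rules$pst_tshape[1] && ang <= rules$pst_tshape[2]))
          mark(rn, "PST")
      }
    }
    # PIC: cation vs aromatic ring centroid, both directions
    cats <- prot_cat[frame$resno[prot_cat] == rn]
    if (length(cats) > 0 && length(lig_rings) > 0) {
      for (ct in cats) for (r2 in lig_rings) {
        c2 <- colMeans(xyz[r2, , drop = FALSE])
        if (sqrt(sum((xyz[ct, ] - c2)^2)) <= rules$pic_dist) mark(rn, "PIC")
      }
    }
    if (length(rr) > 0 && length(lig_q$pos) > 0) {
      for (r1 in rr) for (ct in lig_q$pos) {
        c1 <- colMeans(xyz[r1, , drop = FALSE])
        if (sqrt(sum((xyz[ct, ] - c1)^2)) <= rules$pic_dist) mark(rn, "PIC")
      }
    }
    # SB: opposite charges
    sb_pairs <- rbind(
      if (length(cats) > 0 && length(lig_q$neg) > 0)
        expand.grid(a = cats, b = lig_q$neg),
      if (length(lig_q$pos) > 0) {
        ans <- prot_an[frame$resno[prot_an] == rn]
        if (length(ans) > 0) expand.grid(a = ans, b = lig_q$pos)
      })
    if (!is.null(sb_pairs) && nrow(sb_pairs) > 0) {
      for (k in seq_len(nrow(sb_pairs))) {
        if (dist1(sb_pairs$a[k], sb_pairs$b[k]) <= rules$sb_dist) {
          mark(rn, "SB"); break
        }
      }
    }
    # WB: ligand-water-residue hydrogen-bond chain (distance legs)
    if (length(water) > 0 && length(rpol) > 0 && length(lig_pol) > 0) {
      wox <- water[frame$elem[water] == "O"]
      for (w in wox) {
        leg1 <- any(vapply(lig_pol, function(b)
          dist1(w, b) <= rules$wb_leg_dist, logical(1)))
        if (!leg1) next
        leg2 <- any(vapply(rpol, function(a)
          dist1(w, a) <= rules$wb_leg_dist, logical(1)))
        if (leg2) { mark(rn, "WB"); break }
      }
    }
  }
  data.frame(resno = rep(residues, times = length(classes)),
             class = rep(classes, each = length(residues)),
             value = as.integer(fp))
}

#' High-frequency fingerprint filter
#'
#' Keeps (residue, class) fingerprint bits whose occurrence fraction across
#' frames strictly exceeds the threshold.
#'
#' @param rows list of per-frame fingerprint data frames from
#'   [interaction_fingerprint()] (>= 1).
#' @param threshold strict frequency threshold (default 0.40).
#' @return data frame with `resno`, `class`, `frequency`, sorted by
#'   decreasing frequency.
#' @export
frequency_filter <- function(rows, threshold = 0.40) {
  stopifnot(is.list(rows), length(rows) >= 1)
  all <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ resno + class, data = all, FUN = mean)
  names(agg)[3] <- "frequency"
  out <- agg[agg$frequency > threshold, , drop = FALSE]
  out[order(-out$frequency, out$resno, out$class), , drop = FALSE]
}
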