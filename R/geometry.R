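# Geometric trajectory descriptors: superposition RMSD, radius of gyration
# (total and per-axis), Shrake-Rupley solvent-accessible surface area,
# backbone dihedrals, hydrogen-bond counting, and group-group distances.

#' Optimal-superposition RMSD between two frames
#'
#' Kabsch least-squares fit: the minimum root-mean-square deviation over
#' all rigid rotations and translations of `frame` onto `reference`,
#' computed on the selected atoms (which must map 1:1 between the frames).
#'
#' @param frame,reference `structure_frame` objects.
#' @param selection atom indices used for the fit and the deviation
#'   (default: heavy atoms). Interpreted in both frames, so the two frames
#'   must share their atom ordering.
#' @param fit superpose before measuring (default TRUE); FALSE gives the
#'   raw coordinate RMSD.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame, reference, selection = NULL, fit = TRUE) {
  if (is.null(selection)) selection <- select_atoms(frame, heavy = TRUE)
  if (max(selection) > nrow(frame) || max(selection) > nrow(reference))
    stop("selection error: selections must map 1:1 between the frames")
  a <- coords(frame, selection)
  b <- coords(reference, selection)
  if (nrow(a) != nrow(b)) stop("selection error: selections must map 1:1")
  if (!fit) return(sqrt(mean(rowSums((a - b)^2))))
  if (nrow(a) < 3) stop("selection error: need >= 3 atoms for a fit")
  idx <- seq_len(3L * nrow(a))
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a)),
                           fixed.inds = idx, mobile.inds = idx)
  m <- matrix(fitted, ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums((m - b)^2)))
}

#' Radius of gyration, total or along one lab-frame axis
#'
#' Mass-weighted: \eqn{R_g^2 = \sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}.
#' The per-axis variant uses the displacement component along that axis,
#' so that \eqn{R_g^2 = R_g[X]^2 + R_g[Y]^2 + R_g[Z]^2} holds exactly.
#' Axes are lab-frame; no principal-axis alignment is applied. Atoms with
#' unknown mass count with unit mass.
#'
#' @param frame a `structure_frame`.
#' @param selection atom indices (default all).
#' @param axis `"all"` (default), `"X"`, `"Y"`, or `"Z"`.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame, selection = NULL,
                               axis = c("all", "X", "Y", "Z")) {
  axis <- match.arg(axis)
  if (is.null(selection)) selection <- seq_len(nrow(frame))
  xyz <- coords(frame, selection)
  m <- frame$mass[selection]
  m[is.na(m)] <- 1
  com <- colSums(xyz * m) / sum(m)
  d <- sweep(xyz, 2, com)
  sq <- switch(axis,
               all = rowSums(d^2),
               X = d[, 1]^2, Y = d[, 2]^2, Z = d[, 3]^2)
  sqrt(sum(m * sq) / sum(m))
}

# Bondi van der Waals radii, Angstrom
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: each atom's sphere of radius (vdW + probe) is sampled on
#' a deterministic golden-spiral point set; points not buried inside any
#' neighboring sphere count toward the exposed area.
#'
#' @param frame a `structure_frame`.
#' @param selection atom indices (default: all non-water atoms).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param n_sphere_points quadrature points per atom (default 960).
#' @param radii optional named vector overriding/extending the built-in
#'   Bondi radii (names = element symbols).
#' @return list with `total` (Angstrom^2) and `per_atom` (one value per
#'   selected atom).
#' @export
sasa <- function(frame, selection = NULL, probe_radius = 1.4,
                 n_sphere_points = 960, radii = NULL) {
  if (is.null(selection))
    selection <- which(!toupper(frame$resname) %in% c("HOH", "WAT"))
  xyz <- coords(frame, selection)
  rtab <- .VDW_RADII
  if (!is.null(radii)) rtab[names(radii)] <- radii
  el <- toupper(frame$elem[selection])
  r <- rtab[el]
  if (any(is.na(r)))
    stop("missing-radius: no van der Waals radius for element ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  r <- unname(r) + probe_radius
  n <- nrow(xyz)
  sp <- .sphere_points(n_sphere_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    # exactly coincident duplicates: count the sphere once
    dup <- which(d2 < 1e-12 & seq_len(n) < i)
    if (length(dup) > 0) next
    nbr <- which(d2 >= 1e-12 & d2 < (r[i] + r)^2 & seq_len(n) != i)
    pts <- sweep(sp * r[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nbr) {
      dj <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      exposed <- exposed & dj >= r[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Dihedral angle of four points
#'
#' Signed torsion in degrees, in (-180, 180]; returns NA for degenerate
#' (collinear) configurations.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi dihedrals per residue
#'
#' Standard definitions: \eqn{\phi_i = (C_{i-1}, N_i, CA_i, C_i)} and
#' \eqn{\psi_i = (N_i, CA_i, C_i, N_{i+1})}. Terminal residues and residues
#' missing backbone atoms yield NA, not an error.
#'
#' @param frame a `structure_frame` with N/CA/C backbone atoms.
#' @return data frame with `resno`, `phi`, `psi` (degrees).
#' @export
backbone_dihedrals <- function(frame) {
  prot <- frame[!frame$ligand & !toupper(frame$resname) %in% c("HOH", "WAT"), ]
  res <- sort(unique(prot$resno))
  get <- function(rn, nm) {
    i <- which(prot$resno == rn & trimws(prot$atom) == nm)
    if (length(i) == 0) return(NULL)
    as.numeric(prot[i[1], c("x", "y", "z")])
  }
  phi <- psi <- rep(NA_real_, length(res))
  for (k in seq_along(res)) {
    rn <- res[k]
    N <- get(rn, "N"); CA <- get(rn, "CA"); C <- get(rn, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (k > 1) {
      Cm <- get(res[k - 1], "C")
      if (!is.null(Cm)) phi[k] <- dihedral(Cm, N, CA, C)
    }
    if (k < length(res)) {
      Np <- get(res[k + 1], "N")
      if (!is.null(Np)) psi[k] <- dihedral(N, CA, C, Np)
    }
  }
  data.frame(resno = res, phi = phi, psi = psi)
}

#' Count hydrogen bonds by geometric criteria
#'
#' A donor-acceptor pair counts when the donor-heavy-atom to acceptor
#' distance is at most `dist_cutoff` and the D-H...A angle of some donor
#' hydrogen is at least `angle_cutoff`. Donors/acceptors are N and O atoms;
#' hydrogens are assigned to the nearest heavy atom within 1.25 Angstrom.
#' With `proxy = TRUE` (for hydrogen-free structures) the angle criterion
#' is skipped and the distance alone decides.
#'
#' @param frame a `structure_frame`.
#' @param dist_cutoff donor-acceptor distance cutoff, Angstrom
#'   (default 3.5).
#' @param angle_cutoff D-H...A angle cutoff, degrees (default 120).
#' @param proxy use donor heavy-atom distance only (default: automatic —
#'   TRUE when the frame has no hydrogens).
#' @param exclude_same_residue drop pairs within one residue
#'   (default TRUE).
#' @return list with `count` and `pairs` (data frame of donor/acceptor atom
#'   indices and distances).
#' @export
hbond_count <- function(frame, dist_cutoff = 3.5, angle_cutoff = 120,
                        proxy = NULL, exclude_same_residue = TRUE) {
  xyz <- coords(frame)
  polar <- which(frame$elem %in% c("N", "O"))
  hyd <- which(frame$elem == "H")
  if (is.null(proxy)) proxy <- length(hyd) == 0
  if (length(polar) < 2)
    return(list(count = 0L, pairs = data.frame(donor = integer(),
                                               acceptor = integer(),
                                               distance = numeric())))
  # attach hydrogens to the closest heavy atom within covalent range
  h_owner <- integer(0)
  if (length(hyd) > 0) {
    heavy <- which(frame$elem != "H")
    h_owner <- vapply(hyd, function(h) {
      d2 <- rowSums(sweep(xyz[heavy, , drop = FALSE], 2, xyz[h, ])^2)
      j <- which.min(d2)
      if (d2[j] <= 1.25^2) heavy[j] else NA_integer_
    }, integer(1))
  }
  donors <- if (proxy) polar else
    unique(stats::na.omit(h_owner[frame$elem[h_owner] %in% c("N", "O")]))
  pairs <- list()
  for (d in donors) {
    d2 <- rowSums(sweep(xyz[polar, , drop = FALSE], 2, xyz[d, ])^2)
    cand <- polar[d2 > 1e-6 & d2 <= dist_cutoff^2]
    if (exclude_same_residue)
      cand <- cand[!(frame$resno[cand] == frame$resno[d] &
                       frame$chain[cand] == frame$chain[d])]
    for (a in cand) {
      ok <- proxy
      if (!proxy) {
        hs <- hyd[!is.na(h_owner) & h_owner == d]
        for (h in hs) {
          v1 <- xyz[d, ] - xyz[h, ]
          v2 <- xyz[a, ] - xyz[h, ]
          ang <- acos(pmin(pmax(sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
          if (ang >= angle_cutoff) { ok <- TRUE; break }
        }
      }
      if (ok) pairs[[length(pairs) + 1L]] <-
          data.frame(donor = d, acceptor = a,
                     distance = sqrt(sum((xyz[d, ] - xyz[a, ])^2)))
    }
  }
  if (length(pairs) == 0)
    return(list(count = 0L, pairs = data.frame(donor = integer(),
                                               acceptor = integer(),
                                               distance = numeric())))
  pr <- do.call(rbind, pairs)
  # deduplicate donor<->acceptor double counting in proxy mode
  key <- paste(pmin(pr$donor, pr$acceptor), pmax(pr$donor, pr$acceptor))
  pr <- pr[!duplicated(key), , drop = FALSE]
  list(count = nrow(pr), pairs = pr)
}

#' Distance between two atom groups
#'
#' @param frame a `structure_frame`.
#' @param selection_a,selection_b atom indices (non-empty).
#' @param mode `"com"` (mass-weighted center-of-mass distance, default) or
#'   `"min-heavy-atom"` (minimum distance between heavy atoms).
#' @return distance in Angstrom.
#' @export
group_distance <- function(frame, selection_a, selection_b,
                           mode = c("com", "min-heavy-atom")) {
  mode <- match.arg(mode)
  if (length(selection_a) == 0 || length(selection_b) == 0)
    stop("selection error: empty selection")
  if (mode == "com") {
    com1 <- .group_com(frame, selection_a)
    com2 <- .group_com(frame, selection_b)
    return(sqrt(sum((com1 - com2)^2)))
  }
  a <- selection_a[frame$elem[selection_a] != "H"]
  b <- selection_b[frame$elem[selection_b] != "H"]
  if (length(a) == 0 || length(b) == 0)
    stop("selection error: no heavy atoms in selection")
  xa <- coords(frame, a); xb <- coords(frame, b)
  min(sqrt(outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)))
}

.group_com <- function(frame, sel) {
  xyz <- coords(frame, sel)
  m <- frame$mass[sel]
  m[is.na(m)] <- 1
  colSums(xyz * m) / sum(m)
}
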