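# Structure I/O and geometric descriptors.

make_tripeptide <- function() {
  # 3 glycine-like residues with N, CA, C backbone, roughly extended
  atoms <- expand.grid(name = c("N", "CA", "C"), res = 1:3)
  xyz <- matrix(0, 9, 3)
  for (i in 1:9) xyz[i, ] <- c(1.4 * (i - 1), 0.4 * (i %% 2), 0)
  fr <- toy_frame(xyz, elem = c("N", "C", "C"),
                  atom = as.character(atoms$name), resno = atoms$res)
  fr
}

test_that("multi-model PDB round-trips through write and read", {
  f1 <- make_tripeptide()
  f2 <- f1
  f2$x <- f2$x + 0.5
  path <- tempfile(fileext = ".pdb")
  write_structures(list(f1, f2), path)
  frames <- read_structures(path)
  expect_length(frames, 2)
  expect_equal(nrow(frames[[1]]), nrow(frames[[2]]))
  expect_equal(frames[[1]]$x, f1$x, tolerance = 1e-3)
  expect_equal(frames[[2]]$x, f2$x, tolerance = 1e-3)
  expect_equal(frames[[1]]$resno, f1$resno)
  expect_false(any(frames[[1]]$ligand))
})

test_that("HETATM ligand atoms are flagged; waters are not ligands", {
  prot <- make_tripeptide()
  lig <- toy_frame(cbind(20, 0:1, 0), elem = "C", atom = "C1",
                   resno = 90, resname = "LIG", ligand = TRUE)
  wat <- toy_frame(cbind(30, 0, 0), elem = "O", atom = "O",
                   resno = 95, resname = "HOH")
  path <- tempfile(fileext = ".pdb")
  write_structures(list(rbind(prot, lig, wat)), path)
  fr <- read_structures(path)[[1]]
  expect_equal(sum(fr$ligand), 2)
  expect_false(any(fr$ligand[fr$resname == "HOH"]))
})

test_that("XYZ trajectories parse with frame-count and column validation", {
  path <- tempfile(fileext = ".xyz")
  lines <- character(0)
  for (f in 1:3) {
    lines <- c(lines, "5", sprintf("frame %d", f),
               sprintf("C %.3f %.3f %.3f", 1:5 + f, 0:4, rep(0, 5)))
  }
  writeLines(lines, path)
  frames <- read_structures(path)
  expect_length(frames, 3)
  expect_equal(nrow(frames[[1]]), 5)
  expect_equal(frames[[2]]$x, 1:5 + 2)

  bad <- tempfile(fileext = ".xyz")
  writeLines(c("2", "t", "C 0 0 0", "C 1 1"), bad)
  expect_error(read_structures(bad), "parse error")
  mism <- tempfile(fileext = ".xyz")
  writeLines(c("2", "t", "C 0 0 0", "C 1 1 1", "3", "t",
               "C 0 0 0", "C 1 1 1", "C 2 2 2"), mism)
  expect_error(read_structures(mism), "frame-mismatch")
})

test_that("superposition RMSD is zero under rigid motion and positive otherwise", {
  fr <- make_tripeptide()
  expect_equal(rmsd(fr, fr), 0, tolerance = 1e-8)
  rot <- rotate_frame(fr)
  expect_equal(rmsd(rot, fr), 0, tolerance = 1e-6)
  moved <- fr
  moved$y[5] <- moved$y[5] + 1.2
  expect_gt(rmsd(moved, fr), 0.1)
  expect_error(rmsd(fr, fr[1:5, ], selection = 1:9), "selection")
})

test_that("fitted RMSD matches a rotation-grid search oracle on a 3-atom toy", {
  ref <- toy_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  frame <- toy_frame(rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1, 0)))
  got <- rmsd(frame, ref, selection = 1:3)
  # brute-force: centered coordinates, minimize over sampled z-rotations
  # (the perturbation is in-plane, so in-plane rotations suffice)
  center <- function(m) sweep(m, 2, colMeans(m))
  a <- center(coords(frame)); b <- center(coords(ref))
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = 20001)) {
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    best <- min(best, sqrt(mean(rowSums((a %*% R - b)^2))))
  }
  expect_equal(got, best, tolerance = 1e-3)
})

test_that("radius of gyration matches analytic values and axis decomposition", {
  single <- toy_frame(rbind(c(3, 3, 3)))
  expect_equal(radius_of_gyration(single), 0)
  two <- toy_frame(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(two), 1)
  expect_equal(radius_of_gyration(two, axis = "X"), 1)
  expect_equal(radius_of_gyration(two, axis = "Y"), 0)
  # Rg^2 = sum of per-axis components, on an arbitrary cloud
  set.seed(7)
  cloud <- toy_frame(matrix(rnorm(30), 10, 3),
                     elem = rep(c("C", "N", "O"), length.out = 10))
  rg2 <- radius_of_gyration(cloud)^2
  parts <- sum(vapply(c("X", "Y", "Z"), function(a)
    radius_of_gyration(cloud, axis = a)^2, numeric(1)))
  expect_equal(rg2, parts, tolerance = 1e-12)
})

test_that("SASA: isolated sphere, additivity, full overlap, quadrature", {
  one <- toy_frame(rbind(c(0, 0, 0)), elem = "C")
  s1 <- sasa(one, n_sphere_points = 960)
  expect_equal(s1$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  far <- toy_frame(rbind(c(0, 0, 0), c(50, 0, 0)), elem = "C")
  expect_equal(sasa(far)$total, 2 * s1$total, tolerance = 1e-6)
  overlap <- toy_frame(rbind(c(0, 0, 0), c(0, 0, 0)), elem = "C")
  expect_equal(sasa(overlap)$total, s1$total, tolerance = 1e-6)
  # quadrature convergence: doubling points changes the total < 0.5%
  set.seed(3)
  blob <- toy_frame(matrix(rnorm(24, sd = 2), 8, 3),
                    elem = rep(c("C", "N", "O", "S"), 2))
  t1 <- sasa(blob, n_sphere_points = 480)$total
  t2 <- sasa(blob, n_sphere_points = 960)$total
  expect_lt(abs(t2 - t1) / t2, 0.005)
  expect_error(sasa(toy_frame(rbind(c(0, 0, 0)), elem = "XX")),
               "missing-radius")
})

test_that("dihedrals: constructed planar trans, mirror negation, collinear", {
  # four atoms in a plane with a 180-degree torsion
  p <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(abs(dihedral(p[1, ], p[2, ], p[3, ], p[4, ])), 180)
  q <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  d <- dihedral(q[1, ], q[2, ], q[3, ], q[4, ])
  qm <- q; qm[, 3] <- -qm[, 3]   # mirror through z = 0
  expect_equal(dihedral(qm[1, ], qm[2, ], qm[3, ], qm[4, ]), -d)
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_true(is.na(dihedral(col[1, ], col[2, ], col[3, ], col[4, ])))
})

test_that("backbone phi/psi cover interior residues, NA at termini", {
  fr <- make_tripeptide()
  bd <- backbone_dihedrals(fr)
  expect_equal(bd$resno, 1:3)
  expect_true(is.na(bd$phi[1]))
  expect_true(is.na(bd$psi[3]))
  expect_true(is.finite(bd$phi[2]))
  expect_true(is.finite(bd$psi[2]))
})

test_that("hydrogen-bond counting honors distance and angle criteria", {
  # water dimer: donor O with H pointing at acceptor O 2.9 A away
  dimer <- toy_frame(rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.9, 0, 0)),
                     elem = c("O", "H", "O"), atom = c("O", "H1", "O"),
                     resno = c(1, 1, 2), resname = "HOH")
  expect_equal(hbond_count(dimer)$count, 1)
  stretched <- dimer
  stretched$x[3] <- 4.5
  expect_equal(hbond_count(stretched)$count, 0)
  # bent: H at right angle to the acceptor direction
  bent <- dimer
  bent$x[2] <- 0; bent$y[2] <- 0.96
  expect_equal(hbond_count(bent)$count, 0)
  # proxy mode without hydrogens
  noH <- dimer[c(1, 3), ]
  expect_equal(hbond_count(noH)$count, 1)
})

test_that("group distances: point groups, symmetry, and min <= com", {
  two <- toy_frame(rbind(c(0, 0, 0), c(5, 0, 0)), resno = c(1, 2))
  expect_equal(group_distance(two, 1, 2, "com"), 5)
  expect_equal(group_distance(two, 1, 2, "min-heavy-atom"), 5)
  set.seed(21)
  for (k in 1:25) {
    xyz <- matrix(rnorm(60, sd = 4), 20, 3)
    fr <- toy_frame(xyz, resno = rep(1:2, each = 10))
    a <- which(fr$resno == 1); b <- which(fr$resno == 2)
    # oracle equality against explicit double loops
    brute_min <- min(apply(xyz[a, ], 1, function(p)
      sqrt(colSums((t(xyz[b, ]) - p)^2))))
    expect_equal(group_distance(fr, a, b, "min-heavy-atom"), brute_min,
                 tolerance = 1e-12)
    expect_equal(group_distance(fr, a, b, "com"),
                 sqrt(sum((colMeans(xyz[a, ]) - colMeans(xyz[b, ]))^2)),
                 tolerance = 1e-12)
  }
  expect_error(group_distance(two, integer(0), 2), "selection")
})

test_that("featurize_trajectory is deterministic and rigid-motion stable", {
  traj <- gen_two_state_trajectory(n_frames = 6, seed = 5)
  ft1 <- featurize_trajectory(traj$frames)
  ft2 <- featurize_trajectory(traj$frames)
  expect_identical(ft1, ft2)
  # rotating a frame leaves its descriptors unchanged
  fr <- traj$frames[[2]]
  rot <- rotate_frame(fr)
  expect_equal(rmsd(rot, traj$frames[[1]]), rmsd(fr, traj$frames[[1]]),
               tolerance = 1e-6)
  expect_equal(radius_of_gyration(rot), radius_of_gyration(fr),
               tolerance = 1e-9)
})
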