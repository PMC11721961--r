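# Basin detection, state labeling, minimax pathway search, second-pathway
# discovery, and 1-D profiles.

test_that("find_minima: single well, flat grid, and small-grid guard", {
  x <- seq(-3, 3, length.out = 21)
  v <- outer(x, x, function(a, b) -exp(-(a^2 + b^2)))
  g <- fes_grid(v, cv1 = x, cv2 = x)
  m <- find_minima(g)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$cv1, m$cv2), c(0, 0))
  expect_equal(m$energy, 0)

  flat <- fes_grid(matrix(1, 5, 5), cv1 = 1:5, cv2 = 1:5)
  expect_equal(nrow(find_minima(flat)), 0)
  tiny <- fes_grid(matrix(1:4 + 0, 2, 2), cv1 = 1:2, cv2 = 1:2)
  expect_error(find_minima(tiny), "too-small")
})

test_that("find_minima recovers the constructed double-well centers", {
  pot <- make_double_well(4, 20, asymmetry = 5)
  g <- potential_on_grid(pot, n = 101)
  m <- find_minima(g, energy_cap = 10)
  expect_equal(nrow(m), 2)
  h <- fes_spacing(g)[1]
  for (i in 1:2) {
    d <- sqrt((m$cv1 - pot$minima$cv1[i])^2 + (m$cv2 - pot$minima$cv2[i])^2)
    expect_lte(min(d), sqrt(2) * h + 1e-9)
  }
  # sorted ascending by energy
  expect_true(!is.unsorted(m$energy))
})

test_that("state labeling assigns references, intermediates, and resolves conflicts", {
  m <- data.frame(row = c(1, 2, 3), col = c(1, 2, 3),
                  cv1 = c(0, 5, 10), cv2 = c(0, 0, 0),
                  energy = c(0, 3, 1), label = NA_character_)
  lab <- label_states(m, list(inactive = c(0, 0), active = c(10, 0)))
  expect_equal(lab$label, c("inactive", "intermediate", "active"))
  # both references nearest the same minimum: closer wins, other takes
  # second nearest
  lab2 <- label_states(m, list(inactive = c(0.4, 0), active = c(1, 0)))
  expect_equal(lab2$label[1], "inactive")
  expect_equal(lab2$label[2], "active")
  # equidistant tie: broken by lower free energy
  m3 <- data.frame(row = 1:2, col = 1:2, cv1 = c(-1, 1), cv2 = c(0, 0),
                   energy = c(4, 2), label = NA_character_)
  lab3 <- label_states(m3, list(inactive = c(0, 0), active = c(5, 0)))
  expect_equal(lab3$label[2], "inactive")  # lower energy wins the tie
  expect_error(label_states(m[1, ], list(inactive = c(0, 0),
                                         active = c(1, 0))),
               "labeling-conflict")
})

test_that("labeling is invariant to uniform energy shifts", {
  v <- random_grid(8, 31)
  g1 <- fes_grid(v, cv1 = 1:8, cv2 = 1:8)
  g2 <- fes_grid(v + 11.5, cv1 = 1:8, cv2 = 1:8)   # anchored identically
  refs <- list(inactive = c(2, 2), active = c(7, 7))
  m1 <- find_minima(g1); m2 <- find_minima(g2)
  if (nrow(m1) >= 2) {
    expect_equal(label_states(m1, refs)$label, label_states(m2, refs)$label)
  }
  expect_equal(g1$values, g2$values)
})

test_that("minimax pathway matches the hand-enumerated 3x3 example", {
  v <- rbind(c(0, 10, 2), c(3, 50, 4), c(8, 6, 0))
  g <- fes_grid(v, cv1 = 0:2, cv2 = 0:2)
  p <- mfep(g, c(0, 0), c(2, 2), connectivity = 4)
  expect_equal(p$barrier_forward, 8)
  expect_equal(p$nodes[, "row"], c(0, 1, 2, 2, 2))
  expect_equal(p$nodes[, "col"], c(0, 0, 0, 1, 2))
  expect_error(mfep(g, c(0, 0), c(0, 0)), "must differ")
  expect_error(mfep(g, c(0, 0), c(9, 9)), "outside")
})

test_that("minimax barrier equals independent oracles on random grids", {
  # threshold-connectivity oracle, 8-connected 6x6
  for (sd in 1:40) {
    v <- random_grid(6, sd)
    g <- fes_grid(v, cv1 = 1:6, cv2 = 1:6, anchor = FALSE)
    p <- mfep(g, c(0, 0), c(5, 5))
    expect_equal(max(p$energies), oracle_minimax_threshold(v, c(1, 1), c(6, 6)))
  }
  # exhaustive simple-path enumeration, 4-connected 4x4 and 8-connected 4x4
  for (sd in 1:15) {
    v <- random_grid(4, sd + 300)
    g <- fes_grid(v, cv1 = 1:4, cv2 = 1:4, anchor = FALSE)
    expect_equal(max(mfep(g, c(0, 0), c(3, 3), connectivity = 4)$energies),
                 oracle_minimax(v, c(1, 1), c(4, 4), connectivity = 4))
    expect_equal(max(mfep(g, c(0, 0), c(3, 3))$energies),
                 oracle_minimax(v, c(1, 1), c(4, 4), connectivity = 8))
  }
})

test_that("barrier identities and monotonicity under single-node raises", {
  for (sd in 1:10) {
    v <- random_grid(7, sd + 50)
    g <- fes_grid(v, cv1 = 1:7, cv2 = 1:7)
    p <- mfep(g, c(0, 0), c(6, 6))
    # forward - reverse = F(target) - F(source) exactly
    expect_equal(p$barrier_forward - p$barrier_reverse,
                 g$values[7, 7] - g$values[1, 1])
    expect_gte(p$barrier_forward, 0)
    expect_gte(max(p$energies), max(g$values[1, 1], g$values[7, 7]))
    # raising one interior node never lowers the minimax level
    set.seed(sd)
    r <- sample(2:6, 1); c <- sample(2:6, 1)
    v2 <- v; v2[r, c] <- v2[r, c] + 25
    g2 <- fes_grid(v2, cv1 = 1:7, cv2 = 1:7, anchor = FALSE)
    g1 <- fes_grid(v, cv1 = 1:7, cv2 = 1:7, anchor = FALSE)
    expect_gte(max(mfep(g2, c(0, 0), c(6, 6))$energies),
               max(mfep(g1, c(0, 0), c(6, 6))$energies))
  }
})

test_that("boltzmann-sum mode penalizes long moderate-energy detours", {
  # direct route crosses one 12 kJ/mol node; the detour stays at 8 but is
  # much longer: minimax prefers the detour, the exp-weighted sum does not
  v <- matrix(8, 7, 7)
  v[, 1:3] <- 2
  v[, 5:7] <- 2
  v[4, 4] <- 12
  v[c(1:3, 5:7), 4] <- 40
  g <- fes_grid(v, cv1 = 1:7, cv2 = 1:7, temperature = 310)
  pm <- mfep(g, c(3, 0), c(3, 6), mode = "boltzmann-sum")
  expect_true(any(pm$energies == 12 - min(v)))
  expect_equal(max(pm$energies), 12 - min(v))
})

test_that("second pathway is found on a double-saddle landscape only", {
  gd <- make_double_saddle(4, 20, 30)
  m <- find_minima(gd, energy_cap = 10)
  p1 <- mfep(gd, m[1, ], m[2, ])
  expect_equal(p1$barrier_forward, 20, tolerance = 0.05)
  p2 <- second_path(gd, p1)
  expect_equal(p2$barrier_forward, 30, tolerance = 0.05)
  ts1 <- p1$nodes[which.max(p1$energies), ]
  ts2 <- p2$nodes[which.max(p2$energies), ]
  expect_gt(sqrt(sum((ts1 - ts2)^2)), 4)
  expect_error(second_path(gd, p1, exclusion_radius = 0),
               "exclusion_radius")

  single <- gen_fes(minima = data.frame(cv1 = c(3, 7), cv2 = 5,
                                        energy = c(0, 5)),
                    saddles = data.frame(cv1 = 5, cv2 = 5, energy = 20))
  ms <- find_minima(single, energy_cap = 10)
  ps <- mfep(single, ms[1, ], ms[2, ])
  expect_error(second_path(single, ps), "no-second-path")
})

test_that("1-D profiles accumulate arc length and peak at the barrier", {
  v <- matrix(c(0, 5, 2, 1, 9, 3, 4, 6, 0), 3, 3)
  g <- fes_grid(v, cv1 = c(0, 0.5, 1), cv2 = c(0, 0.5, 1))
  p <- mfep(g, c(0, 0), c(2, 2))
  pr <- profile_1d(p, g)
  expect_equal(pr$arc_length[1], 0)
  expect_true(all(diff(pr$arc_length) > 0))
  expect_equal(max(pr$F), p$barrier_forward + p$energies[1])
  # straight and diagonal step lengths
  seg <- diff(pr$arc_length)
  expect_true(all(abs(seg - 0.5) < 1e-9 | abs(seg - 0.5 * sqrt(2)) < 1e-9))
})
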