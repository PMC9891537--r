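# lattice construction, neighbour averaging, and the tissue-patterning
# simulations (wing vein, dorsoventral boundary)

test_that("trans input is the arithmetic mean over existing neighbours", {
  sp <- ligand_species("Delta", b_L = 0)
  tis <- make_tissue(3, 3, list(sp))
  f <- matrix(0, 3, 3)
  # interior cell (2,2): 4 von Neumann neighbours
  f[1, 2] <- 0; f[3, 2] <- 100; f[2, 1] <- 200; f[2, 3] <- 300
  expect_equal(neighbor_trans_input(tis, 2, 2, list(Delta = f))[["Delta"]],
               150)
  # corner cell (1,1): 2 neighbours only
  f2 <- matrix(0, 3, 3); f2[1, 2] <- 100; f2[2, 1] <- 300
  expect_equal(neighbor_trans_input(tis, 1, 1, list(Delta = f2))[["Delta"]],
               200)
  # uniform field: every cell sees the common level
  fu <- matrix(42, 3, 3)
  for (r in 1:3) for (c in 1:3)
    expect_equal(neighbor_trans_input(tis, r, c, list(Delta = fu))[["Delta"]],
                 42)
  # moore corner has 3 neighbours
  tm <- make_tissue(3, 3, list(sp), topology = "moore")
  f3 <- matrix(0, 3, 3); f3[1, 2] <- 30; f3[2, 1] <- 60; f3[2, 2] <- 90
  expect_equal(neighbor_trans_input(tm, 1, 1, list(Delta = f3))[["Delta"]],
               60)
})

test_that("the ligand production gradient is exponential and symmetric", {
  y <- 1:17
  prof <- gradient_profile(15000, 9, y)
  expect_equal(prof[9], 15000)
  expect_equal(prof[10], 15000 / exp(1), tolerance = 1e-12)
  expect_equal(prof[8], prof[10])
  expect_equal(prof, rev(prof))
})

test_that("a ligand gradient produces two flanking bands of Notch activity", {
  wv <- wing_vein_simulation(rows = 15, cols = 4, y0 = 8)
  Sy <- rowMeans(wv$S)
  maxima <- which(diff(sign(diff(Sy))) == -2) + 1
  expect_equal(length(maxima), 2L)
  expect_true(all(sort(maxima) == c(min(maxima), max(maxima))))
  expect_lt(min(maxima), 8)
  expect_gt(max(maxima), 8)
  # the high-ligand centre is a cis-inhibited trough
  expect_lt(Sy[8], Sy[min(maxima)])
  expect_lt(Sy[8], Sy[max(maxima)])
  # mirror symmetry about the gradient centre on a symmetric grid
  expect_equal(Sy, rev(Sy), tolerance = 1e-5)
  expect_lt(wv$residual, 1e-6 * 200)
})

test_that("shifting the gradient centre shifts the activity pattern", {
  a <- wing_vein_simulation(rows = 15, cols = 4, y0 = 7)
  b <- wing_vein_simulation(rows = 15, cols = 4, y0 = 8)
  Sa <- rowMeans(a$S); Sb <- rowMeans(b$S)
  # compare away from the grid edges: pattern is translated by one row
  expect_equal(Sa[3:12], Sb[4:13], tolerance = 0.02 * max(Sb))
})

test_that("no ligand means a flat, silent activity field", {
  wv <- wing_vein_simulation(rows = 8, cols = 4, L_max = 0)
  expect_equal(max(abs(wv$S)), 0, tolerance = 1e-8)
})

test_that("T1 forms dorsoventral boundary stripes, MI does not", {
  t1 <- dv_boundary_simulation(rows = 12, cols = 6, model = "T1")
  mi <- dv_boundary_simulation(rows = 12, cols = 6, model = "MI")
  Sy <- rowMeans(t1$S)
  boundary_max <- max(t1$S)
  # signal concentrates in the two interface rows (6 and 7)
  expect_equal(sort(order(Sy, decreasing = TRUE)[1:2]), c(6, 7))
  # rows away from the interface are quiet
  expect_lt(max(Sy[c(1:4, 9:12)]), 0.1 * boundary_max)
  # mutual inactivation cannot hold ligand and receptor in the same cells
  expect_lt(max(mi$S), 0.1 * boundary_max)
  expect_lt(t1$residual, 1e-6 * 1000)
})

test_that("boundary signalling holds on Moore and hexagonal lattices too", {
  for (topo in c("moore", "hex")) {
    t1 <- dv_boundary_simulation(rows = 10, cols = 6, model = "T1",
                                 topology = topo)
    Sy <- rowMeans(t1$S)
    expect_equal(sort(order(Sy, decreasing = TRUE)[1:2]), c(5, 6),
                 info = topo)
    expect_lt(max(Sy[c(1:3, 8:10)]), 0.1 * max(t1$S))
  }
})

test_that("reducing Notch production abolishes the boundary stripes", {
  S_max <- vapply(c(1000, 600, 350, 200), function(bn)
    max(dv_boundary_simulation(rows = 12, cols = 6, model = "T1",
                               b_N = bn)$S), numeric(1))
  expect_true(all(diff(S_max) < 0))
  expect_lt(S_max[4], 0.3 * S_max[1])
})

test_that("ectopic ligand stripes induce activity in the responsive compartment", {
  base <- dv_boundary_simulation(rows = 12, cols = 6, model = "T1")
  ect <- dv_boundary_simulation(rows = 12, cols = 6, model = "T1",
    ectopic = list(species = "Delta", center = 3, L_max = 15000))
  # dorsal rows flanking the stripe light up; without the stripe they are dark
  flank <- rowMeans(ect$S)[c(2, 4)]
  expect_gt(min(flank), 10 * max(rowMeans(base$S)[c(2, 4)], 1e-6))
  # ectopic Serrate in the ventral compartment activates ventral neighbours
  ect_s <- dv_boundary_simulation(rows = 12, cols = 6, model = "T1",
    ectopic = list(species = "Serrate", center = 10, L_max = 15000))
  expect_gt(min(rowMeans(ect_s$S)[c(9, 11)]),
            10 * max(rowMeans(base$S)[c(9, 11)], 1e-6))
})

test_that("low-dimerization ectopic ligand spreads ectopic Notch activity", {
  normal <- dv_boundary_simulation(rows = 12, cols = 6, model = "T1",
    ectopic = list(species = "Delta", center = 3, L_max = 15000))
  low_kd <- dv_boundary_simulation(rows = 12, cols = 6, model = "T1",
    ectopic = list(species = "Delta", center = 3, L_max = 15000, k_d = 1e-6))
  # with normal dimerization the stripe cells cis-inhibit themselves;
  # dimer-poor ectopic ligand leaves them active far beyond the boundary
  stripe_row <- 3
  expect_gt(rowMeans(low_kd$S)[stripe_row],
            5 * rowMeans(normal$S)[stripe_row])
  expect_gt(max(low_kd$S[1:4, ]), max(normal$S[1:4, ]))
})

test_that("Fringe gating confines trans-activation to the permitted compartment", {
  # Serrate produced dorsally can only activate ventral Notch: with no other
  # ligand present, dorsal cells must stay silent
  comp <- matrix("ventral", nrow = 8, ncol = 4)
  comp[1:4, ] <- "dorsal"
  b_L <- matrix(0, 8, 4); b_L[1:4, ] <- 200
  ser <- ligand_species("Serrate", b_L = b_L, activates = "ventral")
  tis <- make_tissue(8, 4, list(ser), b_N = 1000, compartment = comp)
  out <- simulate_tissue(tis, model = "T1")
  expect_equal(max(out$S[1:4, ]), 0, tolerance = 1e-6)
  expect_gt(max(out$S[5, ]), 1) # first ventral row sees dorsal Serrate
  # rows deeper in the ventral compartment see no ligand at all
  expect_lt(max(out$S[7:8, ]), 0.01 * max(out$S[5, ]))
})

test_that("the lattice steady state zeroes the whole-tissue system", {
  out <- dv_boundary_simulation(rows = 8, cols = 4, model = "T1")
  expect_lt(out$residual, 1e-6 * 1000)
  tab <- lattice_as_table(out)
  expect_equal(nrow(tab), 8 * 4)
  expect_true(all(c("row", "col", "L_Serrate", "L_Delta", "Lstar_Serrate",
                    "Lstar_Delta", "N", "S") %in% names(tab)))
})
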