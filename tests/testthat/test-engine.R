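# time integration, dose-response sweeps, two-cell systems and the
# cis-inhibition relief dynamics

test_that("integration reproduces pure exponential decay to 1e-6", {
  p <- notch_params(b_L = 0, b_N = 0, k_d = 0, k_t = 0, k_ci = 0, k_ca = 0)
  times <- seq(0, 50, by = 0.5)
  tr <- simulate_cell(rhs_mi, c(L = 100, N = 0, S = 0), times, p = p)
  expect_lt(max(abs(tr$L - 100 * exp(-0.1 * tr$time)) /
                pmax(100 * exp(-0.1 * tr$time), 1e-6)), 1e-6)
  # protein half-life at beta = 0.1/h is about 7 hours
  half <- simulate_cell(rhs_mi, c(L = 100, N = 0, S = 0),
                        c(0, log(2) / 0.1), p = p)
  expect_equal(half$L[2], 50, tolerance = 1e-6)
})

test_that("a zero-length time span returns the initial state only", {
  tr <- simulate_cell(rhs_t1, cell_state(L = 5, N = 7), times = 0)
  expect_equal(nrow(tr), 1L)
  expect_equal(unlist(tr[1, -1]), cell_state(L = 5, N = 7))
})

test_that("long integration lands on the T1 closed-form steady state", {
  p <- notch_params()
  tr <- simulate_cell(rhs_t1, cell_state(), times = c(0, 400, 500), p = p)
  ss <- t1_steady_state(p)
  expect_lt(max(rel_diff(unlist(tr[3, -1])[1:3], ss[1:3])), 1e-4)
})

test_that("normalize_activity scales to a unit maximum", {
  expect_equal(normalize_activity(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_equal(normalize_activity(5), 1)
  v <- c(0.3, 1.7, 0.2)
  expect_equal(normalize_activity(normalize_activity(v)),
               normalize_activity(v))
  expect_error(normalize_activity(c(0, 0)), "all activity values are zero")
})

test_that("cis-ligand production suppresses Notch activity in C1, C2 and C3", {
  p <- notch_params()
  grid <- c(0, 100, 300, 1000, 3000, 10000)
  for (m in c("C1", "C2", "C3")) {
    sw <- production_sweep(p, grid, mode = "cis", cis = m)
    expect_true(all(diff(sw$S) < 0), info = m)
  }
  # no cis ligand: S is the closed-form uninhibited response to L_ext = 1500
  s0 <- production_sweep(p, 0, mode = "cis", cis = "C1")
  N0 <- p$b_N / (p$beta + p$k_t * 1500)
  expect_equal(s0$S, p$k_t * 1500 * N0 / p$beta_S, tolerance = 1e-6)
})

test_that("only dimer-mediated cis-inhibition releases Notch as k_d drops", {
  p <- notch_params()
  kd_grid <- c(0, 1e-7, 1e-6, 1e-5, 1e-4)
  c1 <- dimerization_sweep(p, kd_grid, b_L = 10000, mode = "cis", cis = "C1")
  c2 <- dimerization_sweep(p, kd_grid, b_L = 10000, mode = "cis", cis = "C2")
  S_free <- p$k_t * 1500 * (p$b_N / (p$beta + p$k_t * 1500)) / p$beta_S
  # C1: dimer-deficient ligand cannot cis-inhibit; full recovery at k_d = 0
  expect_equal(c1$S[1], S_free, tolerance = 1e-6)
  expect_gt(c1$S[1], 20 * c1$S[length(kd_grid)])
  # C2: monomers still cis-inhibit; activity stays suppressed
  expect_lt(max(c2$S), 0.1 * S_free)
  # k_d = 0 under C1 equals the mutual-inactivation model with k_ci = 0
  expect_equal(c1$S[1], S_free, tolerance = 1e-6)
})

test_that("trans-ligand production drives Notch activity up (model T1)", {
  p <- notch_params()
  sw <- production_sweep(p, c(100, 300, 1000, 3000, 10000), mode = "trans",
                         trans = "T1")
  expect_true(all(diff(sw$S) > 0))
})

test_that("dimer-deficient trans ligand still trans-activates under T1 but not T2", {
  p <- notch_params()
  kd_grid <- c(1e-7, 1e-6, 1e-5, 1e-4)
  t1 <- dimerization_sweep(p, kd_grid, b_L = 10000, mode = "trans",
                           trans = "T1")
  t2 <- dimerization_sweep(p, kd_grid, b_L = 10000, mode = "trans",
                           trans = "T2")
  # monomer-mediated trans-activation persists as the sender's k_d drops
  expect_gt(t1$S[1], 0.5 * max(t1$S))
  # dimer-mediated trans-activation weakens with the dimer supply (the
  # dimer pool shrinks only slowly with k_d, since k_d L^2 tracks b_L/2
  # until degradation takes over)
  expect_true(all(diff(t2$S) > 0))
  expect_lt(t2$S[1], 0.8 * max(t2$S))
})

test_that("two identical coupled cells stay identical over time", {
  p <- notch_params()
  coupled <- function(y, ext, pp) {
    y1 <- y[1:4]; y2 <- y[5:8]
    c(rhs_t1(y1, external_signal(L_ext = y2[[1]], N_ext = y2[[3]]), pp),
      rhs_t1(y2, external_signal(L_ext = y1[[1]], N_ext = y1[[3]]), pp))
  }
  init <- c(cell_state(L = 10, N = 30), cell_state(L = 10, N = 30))
  tr <- simulate_cell(coupled, init, seq(0, 200, by = 10), p = p,
                      method = "lsoda")
  expect_equal(as.matrix(tr[, 2:5]), as.matrix(tr[, 6:9]),
               ignore_attr = TRUE, tolerance = 1e-10)
  ss <- two_cell_steady_state(p, p)
  expect_equal(ss$cell1, ss$cell2, tolerance = 1e-8)
})

test_that("two-cell activity peaks at intermediate ligand production under T1", {
  p <- notch_params()
  grid <- c(50, 200, 500, 1000, 2000, 5000, 20000, 50000)
  t1 <- two_cell_sweep(p, grid, trans = "T1")
  t3 <- two_cell_sweep(p, grid, trans = "T3")
  peak <- which.max(t1$S_normalized)
  expect_gt(peak, 1)
  expect_lt(peak, length(grid))
  # T1 collapses at high ligand production, T3 does not
  expect_lt(t1$S_normalized[length(grid)], 0.1)
  expect_gt(t3$S_normalized[length(grid)], 0.3)
})

test_that("cis-activation response is non-monotonic only with monomer drive", {
  p <- notch_params()
  grid <- c(10, 50, 200, 500, 1000, 2000, 5000, 20000)
  s1 <- cis_activation_sweep(1, p, grid)
  s2 <- cis_activation_sweep(2, p, grid)
  s3 <- cis_activation_sweep(3, p, grid)
  # scenario 1: interior peak (rise then fall)
  peak <- which.max(s1$S)
  expect_gt(peak, 1)
  expect_lt(peak, length(grid))
  # scenario 2: dimer-driven activation saturates monotonically
  expect_true(all(diff(s2$S) > 0))
  # scenario 3: dimer cis-activation keeps signalling from being shut off by
  # high cis-ligand production; scenario 1 collapses instead
  frac3 <- s3$S[length(grid)] / max(s3$S)
  frac1 <- s1$S[length(grid)] / max(s1$S)
  expect_gt(frac3, 0.25)
  expect_gt(frac3, 8 * frac1)
  # no cis-activation rate, no signal at all
  expect_equal(cis_activation_sweep(1, p, grid, k_ca = 0)$S,
               rep(0, length(grid)))
})

test_that("lower dimer affinity strengthens cis-activation, weakens inhibition", {
  p <- notch_params()
  grid <- c(200, 1000, 5000, 20000)
  base <- cis_activation_sweep(1, p, grid)
  low <- cis_activation_sweep(1, p, grid, k_ci = 6e-5)
  expect_true(all(low$S >= base$S))
  expect_gt(low$S[length(grid)], 5 * base$S[length(grid)])
})

test_that("dimer-loaded cells show delayed Notch activation after ligand shutoff", {
  p <- notch_params()
  tr <- cis_inhibition_dynamics(p, times = seq(0, 150, by = 0.5))
  expect_equal(unlist(tr[1, -1]), cell_state(L = 500, Lstar = 9500))
  # no production: total ligand content can only decay
  total <- tr$L + 2 * tr$Lstar
  expect_true(all(diff(total) <= 1e-8 * total[1]))
  # delayed onset: little signal early, full signal late
  S_final <- tr$S[nrow(tr)]
  expect_lt(tr$S[tr$time == 5], 0.1 * S_final)
  # the exhausted-ligand limit is the b_L = 0 closed form
  p0 <- p; p0$b_L <- 0
  ss <- t1_steady_state(p0, external_signal(L_ext = 1500))
  expect_equal(S_final, ss[["S"]], tolerance = 1e-3)
  expect_equal(ss[["L"]], 0)
  expect_equal(ss[["N"]], p$b_N / (p$beta + p$k_t * 1500))
})

test_that("the Notch response is qualitatively independent of oligomer size", {
  p <- notch_params()
  shape <- function(sw) {
    d <- diff(sw$S_normalized)
    if (all(d <= 0)) "decreasing"
    else if (all(d >= 0)) "increasing"
    else "interior_peak"
  }
  grid_ft <- c(0, 100, 300, 1000, 3000, 10000)
  grid_sc <- c(10, 50, 200, 1000, 5000, 20000)
  shapes_ft <- vapply(2:4, function(n)
    shape(oligomer_sweep("fixed_trans", n, p, grid_ft)), "")
  expect_true(all(shapes_ft == "decreasing"))
  shapes_sc <- vapply(2:4, function(n)
    shape(oligomer_sweep("single_cell", n, p, grid_sc)), "")
  expect_true(all(shapes_sc == "interior_peak"))
  shapes_tc <- vapply(2:4, function(n)
    shape(oligomer_sweep("two_cell", n, p, c(50, 200, 1000, 5000, 20000))), "")
  expect_equal(length(unique(shapes_tc)), 1L)
})

test_that("cytoplasm-confined cis-inhibition suppresses Notch at least as much", {
  p <- notch_params()
  grid <- c(0, 100, 300, 1000, 3000, 10000)
  cyto <- compartment_sweep("fixed_trans", "cytoplasmic", p, grid)
  homog <- compartment_sweep("fixed_trans", "homogeneous", p, grid)
  expect_true(all(cyto$S <= homog$S * (1 + 1e-8)))
  # fast transport drains the cytoplasmic monomer pool
  p_fast <- notch_params(k_r = 1e4)
  ss <- steady_state_numeric(rhs_compartment, p_fast,
                             external_signal(L_ext = 1500),
                             compartment_state())
  expect_lt(ss[["L_c"]], 1)
})
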