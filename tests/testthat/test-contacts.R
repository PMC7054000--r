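test_that("loops_from_snapshot returns ordered bridged pairs", {
  tr <- fake_trajectory(cbind(10L, 120L), cbind(250L, 180L), 300)
  b <- loops_from_snapshot(tr, 1)
  expect_equal(nrow(b), 2L)
  expect_equal(b[1, ], c(left = 10, right = 250))
  expect_equal(b[2, ], c(left = 120, right = 180))
  tr0 <- fake_trajectory(matrix(integer(0), 1, 0), matrix(integer(0), 1, 0), 50)
  expect_equal(nrow(loops_from_snapshot(tr0, 1)), 0L)
})

test_that("effective separations equal whole-lattice Dijkstra distances", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (k in 1:3) {
    n <- 50
    l <- sort(sample.int(n - 10, 3))
    bridges <- cbind(l, l + sample(3:9, 3, replace = TRUE))
    g <- igraph::make_lattice(n)  # backbone, weight 1
    igraph::E(g)$weight <- 1
    g <- igraph::add_edges(g, as.vector(t(bridges)), weight = 0)
    oracle <- igraph::distances(g)
    expect_equal(effective_separation(1:50, bridges), unname(oracle),
                 tolerance = 1e-12)
  }
  # backbone only: separation is |i - j| and contact decays strictly
  s0 <- effective_separation(1:50, matrix(integer(0), 0, 2))
  expect_equal(s0, abs(outer(1:50, 1:50, "-")))
})

test_that("compiled and R contact accumulation agree exactly", {
  p <- sim_params(n_monomers = 100, n_extruders = 2, n_steps = 400,
                  n_replicates = 1, snapshot_stride = 40, seed = 13)
  tr <- run_extrusion(p, make_ctcf_layout("random", 100, n_sites = 4, seed = 5))
  m_c <- contact_map_gaussian(tr, bin_monomers = 2)
  m_r <- contact_map_gaussian(tr, bin_monomers = 2, engine = "r")
  expect_equal(m_c$matrix, m_r$matrix, tolerance = 1e-14)
})

test_that("gaussian map without extruders depends only on distance, decreasing", {
  tr <- fake_trajectory(matrix(integer(0), 1, 0), matrix(integer(0), 1, 0), 100)
  m <- contact_map_gaussian(tr, bin_monomers = 5)
  d1 <- m$matrix[1, ]            # first row over distance
  expect_true(all(diff(d1) < 0))
  # translation invariance along the diagonal
  for (k in 1:15) expect_equal(m$matrix[k, k + 3], m$matrix[k + 1, k + 4])
})

test_that("a permanent bridge maximizes its own contact entry", {
  tr <- fake_trajectory(matrix(10L), matrix(80L), 100)
  m <- contact_map_gaussian(tr, bin_monomers = 1)
  # s_eff(10, 80) = 0: the bridged entry equals the diagonal maximum
  expect_equal(m$matrix[10, 80], m$matrix[10, 10])
  expect_equal(max(m$matrix), m$matrix[10, 80])
  # and exceeds the unbridged control at equal |i - j|
  tr0 <- fake_trajectory(matrix(1L), matrix(2L), 100)
  m0 <- contact_map_gaussian(tr0, bin_monomers = 1)
  expect_gt(m$matrix[10, 80], m0$matrix[10, 80])
})

test_that("both contact modes are symmetric and nonnegative", {
  p <- sim_params(n_monomers = 60, n_extruders = 1, n_steps = 200,
                  n_replicates = 1, snapshot_stride = 100, seed = 3)
  tr <- run_extrusion(p, empty_ctcf(60))
  mg <- contact_map_gaussian(tr, bin_monomers = 3)
  expect_identical(mg$matrix, t(mg$matrix))
  expect_true(all(mg$matrix >= 0))
  mm <- contact_map_md(tr, md_params(steps_per_snapshot = 150L,
                                     equilibrate = 50L, sample_every = 10L),
                       bin_monomers = 3, seed = 7)
  expect_identical(mm$matrix, t(mm$matrix))
  expect_true(all(mm$matrix >= 0))
})

test_that("zero-temperature relaxation decreases bond energy monotonically", {
  prof <- md_relaxation_profile(40, n_steps = 150, seed = 2)
  expect_true(all(diff(prof$bond_msd) <= 1e-12))
  expect_lt(prof$bond_var[150], prof$bond_var[1] / 10)
})

test_that("md mode enriches bridged pairs over unbridged controls", {
  reps <- 40L  # re-anchored snapshots of the same bridge
  tr_b <- fake_trajectory(matrix(10L, reps, 1), matrix(50L, reps, 1), 60)
  tr_0 <- fake_trajectory(matrix(1L, reps, 1), matrix(2L, reps, 1), 60)
  p <- md_params(steps_per_snapshot = 60L, equilibrate = 20L,
                 sample_every = 10L)
  m_b <- contact_map_md(tr_b, p, bin_monomers = 5, seed = 11)
  m_0 <- contact_map_md(tr_0, p, bin_monomers = 5, seed = 11)
  i <- 2L; j <- 10L  # bins containing beads 10 and 50
  expect_gt(m_b$matrix[i, j], m_0$matrix[i, j])
})

test_that("md integration instability is caught with a diagnostic", {
  tr <- fake_trajectory(matrix(5L), matrix(20L), 30)
  p <- md_params(dt = 5, steps_per_snapshot = 50L)
  expect_error(contact_map_md(tr, p, bin_monomers = 3, seed = 1),
               "unstable integration")
})

test_that("gaussian and md modes rank contacts consistently", {
  # persistent convergent loop on a short chain; modest thermal noise
  p <- sim_params(n_monomers = 80, n_extruders = 1, p_dissociate = 0,
                  p_resume = 0, n_steps = 600, n_replicates = 1,
                  snapshot_stride = 60, seed = 5)
  ct <- ctcf_track(80, position = c(15L, 65L), orientation = c("+", "-"),
                   halt_prob = c(1, 1))
  tr <- run_extrusion(p, ct)
  mg <- contact_map_gaussian(tr, bin_monomers = 4)
  mm <- contact_map_md(tr, md_params(steps_per_snapshot = 1500L,
                                     equilibrate = 200L, sample_every = 5L,
                                     temperature = 0.5, capture_radius = 3),
                       bin_monomers = 4, seed = 9)
  ut <- upper.tri(mg$matrix)
  rho <- stats::cor(mg$matrix[ut], mm$matrix[ut], method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("coverage balancing matches hand-computed 3x3 entries", {
  A <- matrix(c(4, 1, 1,
                1, 2, 1,
                1, 1, 2), 3, 3, byrow = TRUE)
  m <- contact_map(A, bin_size = 1000)
  b <- balance(m, "coverage")
  # row sums 6, 4, 4; entry (i, j) / sqrt(rs_i * rs_j)
  expect_equal(b$matrix[1, 1], 4 / 6)
  expect_equal(b$matrix[1, 2], 1 / sqrt(24))
  expect_equal(b$matrix[2, 2], 0.5)
  expect_equal(b$matrix[2, 3], 0.25)
  expect_equal(b$normalized, "coverage")
})

test_that("balancing normalizes rows and preserves symmetry and masks", {
  cmap <- make_toy_contact_map(toy_map_spec(40, tad_blocks = data.frame(
    start_bin = 5, end_bin = 20, intra_weight = 3)))
  # constant map stays constant under both methods
  flat <- contact_map(matrix(2, 10, 10), 1000)
  expect_true(all(abs(balance(flat, "coverage")$matrix -
                      balance(flat, "coverage")$matrix[1, 1]) < 1e-12))
  expect_true(all(abs(balance(flat, "iterative")$matrix -
                      balance(flat, "iterative")$matrix[1, 1]) < 1e-12))
  bi <- balance(cmap, "iterative")
  rs <- rowSums(bi$matrix)
  expect_lt(max(abs(rs - mean(rs))) / mean(rs), 1e-6)
  expect_identical(bi$matrix, t(bi$matrix))
  # masked zero row stays zero
  A <- cmap$matrix; A[3, ] <- 0; A[, 3] <- 0
  bz <- balance(contact_map(A, 1000), "iterative")
  expect_true(all(bz$matrix[3, ] == 0))
  rs2 <- rowSums(bz$matrix)[-3]
  expect_lt(max(abs(rs2 - mean(rs2))) / mean(rs2), 1e-6)
})
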