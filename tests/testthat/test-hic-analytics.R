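test_that("P(s) puts nearest-neighbour-only contacts in the first bin", {
  A <- matrix(0, 30, 30)
  A[cbind(1:29, 2:30)] <- 1
  A <- A + t(A)
  ps <- ps_curve(contact_map(A, 1000))
  nz <- ps[ps$mean_contact > 0, ]
  expect_equal(nrow(nz), 1L)
  expect_lte(nz$dist_lo[1], 1000)
  expect_gt(nz$dist_hi[1], 1000)
})

test_that("P(s) of a power-law map recovers the decay slope", {
  m <- make_toy_contact_map(toy_map_spec(400, bin_size = 1000,
                                         decay_exponent = 1))
  ps <- ps_curve(m, bins_per_decade = 10)
  # fit in the asymptotic range where (1 + s)^-1 ~ s^-1
  sel <- ps$dist_mid >= 2e4 & ps$dist_mid <= 2e5
  fit <- stats::lm(log(mean_contact) ~ log(dist_mid), data = ps[sel, ])
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.05)
})

test_that("detrended P(s) peak sits at a planted loop scale", {
  # strong dots at |i - j| = 60 bins on an ideal-chain background
  dots <- data.frame(bin_i = c(30, 120, 210), bin_j = c(90, 180, 270),
                     amplitude = 3)
  m <- make_toy_contact_map(toy_map_spec(300, bin_size = 1000, dots = dots,
                                         decay_exponent = 1.5))
  peak <- ps_peak(ps_curve(m, bins_per_decade = 10))
  expect_gt(peak, 40000)
  expect_lt(peak, 90000)
})

test_that("insulation of a constant map is flat with no boundaries", {
  m <- contact_map(matrix(1, 60, 60), 10000)
  prof <- insulation(m, window = 50000)
  sc <- prof$score[!is.na(prof$score)]
  expect_true(all(abs(sc) < 1e-12))
  expect_length(attr(prof, "boundaries"), 0L)
})

test_that("two-block maps have their insulation minimum at the block joint", {
  m <- two_block_map(n = 100, split = 51)
  prof <- insulation(m, window = 50000)  # w = 5 bins
  expect_equal(which.min(prof$score), 51L)
  expect_true(51L %in% attr(prof, "boundaries"))
})

test_that("translating the map translates the raw insulation profile", {
  blocks1 <- data.frame(start_bin = c(11, 41), end_bin = c(41, 71),
                        intra_weight = 2)
  blocks2 <- data.frame(start_bin = c(21, 51), end_bin = c(51, 81),
                        intra_weight = 2)
  m1 <- make_toy_contact_map(toy_map_spec(120, bin_size = 10000,
                                          tad_blocks = blocks1,
                                          decay_exponent = 0))
  m2 <- make_toy_contact_map(toy_map_spec(120, bin_size = 10000,
                                          tad_blocks = blocks2,
                                          decay_exponent = 0))
  r1 <- attr(insulation(m1, window = 50000), "score_raw")
  r2 <- attr(insulation(m2, window = 50000), "score_raw")
  # interior bins: the flat background makes the shift exact
  idx <- 30:80
  expect_equal(r2[idx + 10], r1[idx], tolerance = 1e-12)
})

test_that("boundary_profile averages around positions with a random control", {
  m <- two_block_map(n = 100, split = 51)
  prof <- insulation(m, window = 50000)
  bp <- boundary_profile(prof, positions = 51L, flank = 5, n_random = 200,
                         seed = 3)
  expect_equal(nrow(bp), 11L)
  # the boundary trough is deeper than the random-position average
  expect_lt(bp$mean_score[bp$offset == 0], bp$mean_score_random[bp$offset == 0])
  expect_equal(bp$mean_score[bp$offset == 0], min(prof$score, na.rm = TRUE))
})

test_that("APA pileup of planted dots is center-enriched", {
  dots <- data.frame(bin_i = c(30, 25, 40), bin_j = c(70, 75, 85),
                     amplitude = 4)
  m <- make_toy_contact_map(toy_map_spec(120, bin_size = 10000, dots = dots,
                                         decay_exponent = 0.3))
  res <- apa(m, data.frame(bin1 = dots$bin_i, bin2 = dots$bin_j))
  expect_equal(res$n_used, 3L)
  expect_equal(dim(res$pileup), c(21L, 21L))
  corners <- mean(c(res$pileup[1:5, 1:5], res$pileup[1:5, 17:21],
                    res$pileup[17:21, 1:5], res$pileup[17:21, 17:21]))
  expect_gt(res$center, corners)
  expect_gt(res$enrichment, 1.5)
})

test_that("single-loop APA equals that loop's submatrix exactly", {
  m <- make_toy_contact_map(toy_map_spec(120, bin_size = 10000,
                                         decay_exponent = 1))
  res <- apa(m, data.frame(bin1 = 40, bin2 = 90))
  expect_equal(res$pileup, m$matrix[30:50, 80:100])
  expect_equal(res$center, m$matrix[40, 90])
})

test_that("APA on random loops over a featureless background is ~1", {
  m <- make_toy_contact_map(toy_map_spec(200, bin_size = 10000,
                                         decay_exponent = 0))
  set.seed(7)
  b1 <- sample(15:90, 25, replace = TRUE)
  res <- apa(m, data.frame(bin1 = b1, bin2 = b1 + sample(25:80, 25, TRUE)))
  expect_gt(res$n_used, 10L)
  expect_equal(res$enrichment, 1, tolerance = 0.2)
})

test_that("APA skips loops too near the diagonal or edges, and can reject all", {
  m <- make_toy_contact_map(toy_map_spec(60, decay_exponent = 1))
  res <- apa(m, data.frame(bin1 = c(5, 20, 25), bin2 = c(55, 25, 50)))
  expect_equal(res$n_skipped, 2L)  # edge-adjacent and near-diagonal
  expect_equal(res$n_used, 1L)
  expect_error(apa(m, data.frame(bin1 = 20, bin2 = 25)), "no usable loops")
})

test_that("TAD pileups aggregate size classes on their own windows", {
  # identical synthetic TADs: pileup equals any single instance
  m <- make_toy_contact_map(toy_map_spec(
    200, bin_size = 10000,
    tad_blocks = data.frame(start_bin = c(41, 141), end_bin = c(61, 161),
                            intra_weight = 2),
    decay_exponent = 1))
  tads <- data.frame(start = c(400000, 1400000), end = c(600000, 1600000))
  res <- tad_pileup(m, tads, size_classes = c(100000, 300000))
  expect_length(res, 1L)
  pk <- res[[1]]
  expect_equal(pk$n, 2L)
  w <- (nrow(pk$pileup) - 1L) / 2
  c1 <- 51  # center bin of the first TAD (midpoint 500 kb falls in bin 51)
  expect_equal(pk$pileup / 2, m$matrix[(c1 - w):(c1 + w), (c1 - w):(c1 + w)],
               tolerance = 1e-12)
  # within-TAD mean exceeds cross-boundary mean
  half <- w %/% 2
  within <- mean(pk$pileup[(w - half):(w + half), (w - half):(w + half)])
  cross <- mean(pk$pileup[1:half, (2 * w - half):(2 * w + 1)])
  expect_gt(within, cross)
})

test_that("each TAD lands in exactly one size class", {
  m <- make_toy_contact_map(toy_map_spec(200, bin_size = 10000,
                                         decay_exponent = 1))
  tads <- data.frame(start = c(500000, 900000, 1300000),
                     end = c(650000, 1150000, 1700000))
  classes <- c(100000, 200000, 300000, 500000)
  res <- suppressWarnings(tad_pileup(m, tads, classes))
  expect_equal(sum(vapply(res, `[[`, numeric(1), "n")), 3)
  lens <- tads$end - tads$start
  for (i in seq_along(lens)) {
    inside <- vapply(res, function(r) lens[i] >= r$class[1] & lens[i] < r$class[2],
                     logical(1))
    expect_equal(sum(inside), 1L)
  }
})
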