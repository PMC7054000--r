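test_that("loop lengths are anchor-midpoint distances and ECDF is standard", {
  l <- loop_list("chr1", c(100, 100), c(200, 200), c(1100, 5100), c(1200, 5200))
  expect_equal(loop_lengths(l), c(1000, 5000))
  # lengths 1, 2, 3 -> ECDF(2) = 2/3
  l3 <- loop_list("chr1", c(0, 0, 0), c(2, 2, 2), c(1, 2, 3), c(3, 4, 5))
  e <- loop_length_ecdf(l3)
  expect_equal(attr(e, "fun")(2), 2 / 3)
  expect_equal(e$ecdf, c(1, 2, 3) / 3)
  expect_true(all(diff(e$length) >= 0))
  expect_error(loop_list("chr1", 10, 5, 20, 30), "start < end")
  expect_error(loop_list("chr1", 100, 200, 10, 90), "upstream")
})

test_that("anchors below 15 kb are tested at exactly 15 kb", {
  # 5 kb anchor at [100000, 105000); a peak 3 kb beyond its edge lies inside
  # the symmetric 15 kb expansion [95000, 110000) but outside the raw anchor
  l <- loop_list("chr1", 100000, 105000, 400000, 405000)
  peaks <- data.frame(chrom = "chr1", start = c(108000, 390000),
                      end = c(108500, 390500))
  occ <- ctcf_occupancy(l, peaks, chrom_sizes = c(chr1 = 1e6), seed = 2)
  expect_equal(occ$observed, 1L)  # anchor1 via expansion; anchor2 misses
  expect_equal(occ$n_anchors, 2L)
})

test_that("anchor-centered peaks give large fold enrichment", {
  set.seed(10)
  mid1 <- sort(sample(seq(50000, 4.5e6, by = 1000), 30))
  l <- loop_list("chr1", mid1 - 2000, mid1 + 2000,
                 mid1 + 200000 - 2000, mid1 + 200000 + 2000)
  centers <- c(mid1, mid1 + 200000)
  peaks <- data.frame(chrom = "chr1", start = centers - 250,
                      end = centers + 250)
  occ <- ctcf_occupancy(l, peaks, chrom_sizes = c(chr1 = 5e6), seed = 4)
  expect_equal(occ$observed, 60L)
  expect_gt(occ$fold, 3)
})

test_that("dense uniform peaks give fold enrichment near 1", {
  set.seed(11)
  mid1 <- sort(sample(seq(1e5, 4e6, by = 1000), 40))
  l <- loop_list("chr1", mid1 - 5000, mid1 + 5000,
                 mid1 + 300000 - 5000, mid1 + 300000 + 5000)
  starts <- seq(0, 5e6 - 20000, by = 20000)
  peaks <- data.frame(chrom = "chr1", start = starts, end = starts + 10000)
  occ <- ctcf_occupancy(l, peaks, chrom_sizes = c(chr1 = 5e6),
                        n_controls = 10, seed = 6)
  expect_gt(occ$fold, 0.8)
  expect_lt(occ$fold, 1.25)
})

test_that("occupancy fold is invariant to a global coordinate shift", {
  set.seed(12)
  mid1 <- sort(sample(seq(2e5, 3e6, by = 1000), 20))
  mk <- function(off) {
    list(loops = loop_list("chr1", mid1 - 3000 + off, mid1 + 3000 + off,
                           mid1 + 250000 - 3000 + off, mid1 + 250000 + 3000 + off),
         peaks = data.frame(chrom = "chr1", start = c(mid1, mid1 + 7e5) - 400 + off,
                            end = c(mid1, mid1 + 7e5) + 400 + off))
  }
  a <- mk(0); b <- mk(50000)
  oa <- ctcf_occupancy(a$loops, a$peaks, c(chr1 = 4e6), n_controls = 50, seed = 3)
  ob <- ctcf_occupancy(b$loops, b$peaks, c(chr1 = 4e6 + 50000), n_controls = 50,
                       seed = 3)
  expect_equal(oa$observed, ob$observed)
  expect_equal(oa$fold, ob$fold, tolerance = 0.5)
})

test_that("convergence classification follows the ordered orientations", {
  mk_loop <- function() loop_list("chr1", 10000, 12000, 200000, 202000)
  smc3 <- data.frame(chrom = "chr1", start = c(10500, 200500),
                     end = c(11500, 201500))
  motif <- function(s1, s2) data.frame(
    chrom = "chr1", start = c(10800, 200800), end = c(10820, 200820),
    strand = c(s1, s2))
  cc <- classify_convergence(mk_loop(), motif("+", "-"), smc3)
  expect_equal(unname(cc$proportions["convergent"]), 1)
  expect_equal(sum(cc$proportions), 1)
  cc2 <- classify_convergence(mk_loop(), motif("-", "+"), smc3)
  expect_equal(unname(cc2$proportions["divergent"]), 1)
  cc3 <- classify_convergence(mk_loop(), motif("+", "+"), smc3)
  expect_equal(unname(cc3$proportions["tandem"]), 1)
  # two opposite-sign motifs in one anchor -> ambiguous, excluded
  amb <- rbind(motif("+", "-"),
               data.frame(chrom = "chr1", start = 10900, end = 10920,
                          strand = "-"))
  expect_error(classify_convergence(mk_loop(), amb, smc3), "no eligible")
  # missing SMC3 at one anchor -> excluded
  expect_error(classify_convergence(mk_loop(), motif("+", "-"), smc3[1, ]),
               "no eligible")
})

test_that("random orientations give proportions (0.25, 0.5, 0.25)", {
  set.seed(20)
  n <- 4000
  mid1 <- seq(50000, by = 40000, length.out = n)
  l <- loop_list("chr1", mid1 - 1000, mid1 + 1000,
                 mid1 + 15000 - 1000, mid1 + 15000 + 1000)
  centers <- c(mid1, mid1 + 15000)
  smc3 <- data.frame(chrom = "chr1", start = centers - 100, end = centers + 100)
  motifs <- data.frame(chrom = "chr1", start = centers - 10, end = centers + 10,
                       strand = sample(c("+", "-"), 2 * n, replace = TRUE))
  cc <- classify_convergence(l, motifs, smc3, min_width = 2000)
  expect_equal(cc$n_eligible, n)
  tol <- 4 * sqrt(0.25 * 0.75 / n)
  expect_equal(unname(cc$proportions["convergent"]), 0.25, tolerance = tol / 0.25)
  expect_equal(unname(cc$proportions["tandem"]), 0.5, tolerance = tol / 0.5)
  expect_equal(unname(cc$proportions["divergent"]), 0.25, tolerance = tol / 0.25)
  expect_equal(sum(cc$proportions), 1, tolerance = 1e-12)
})

test_that("union overlap merges transitive runs with membership labels", {
  res <- interval_union_overlap(list(
    A = data.frame(chrom = "chr1", start = 0, end = 10),
    B = data.frame(chrom = "chr1", start = 5, end = 15)))
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 0)
  expect_equal(res$end, 15)
  expect_equal(res$membership, "A,B")
  # disjoint sets pass through as singletons
  res2 <- interval_union_overlap(list(
    A = data.frame(chrom = "chr1", start = 0, end = 10),
    B = data.frame(chrom = "chr1", start = 20, end = 30)))
  expect_equal(res2$membership, c("A", "B"))
  expect_error(interval_union_overlap(list(
    A = data.frame(chrom = "chr1", start = 10, end = 5))), "row 1")
})

test_that("union overlap matches the quadratic sweep on random sets", {
  set.seed(33)
  for (rep in 1:3) {
    sets <- list(A = random_intervals(200), B = random_intervals(200),
                 C = random_intervals(200))
    fast <- interval_union_overlap(sets)
    slow <- brute_union_overlap(sets)
    expect_equal(fast$start, slow$start)
    expect_equal(fast$end, slow$end)
    expect_equal(fast$membership, slow$membership)
    expect_equal(fast$n_sets, slow$n_sets)
  }
})

test_that("union overlap is idempotent on its own output", {
  set.seed(34)
  sets <- list(A = random_intervals(100), B = random_intervals(100))
  merged <- interval_union_overlap(sets)
  again <- interval_union_overlap(list(M = merged[, c("chrom", "start", "end")]))
  expect_equal(again$start, merged$start)
  expect_equal(again$end, merged$end)
})
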