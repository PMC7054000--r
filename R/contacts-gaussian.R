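#' Effective contour separations given a set of bridges
#'
#' Shortest-path distance between lattice coordinates on the graph whose
#' edges are backbone steps of weight 1 and bridged (looped) monomer pairs
#' of weight 0. A shortest path is a backbone run, optionally entering the
#' bridge network at one endpoint and leaving at another, so distances
#' follow from all-pairs shortest paths among the bridge endpoints alone
#' (Floyd-Warshall on at most `2 * n_bridges` nodes) — exact, and verified
#' against a whole-lattice Dijkstra in the test suite.
#'
#' @param x Numeric vector of query coordinates (monomer units).
#' @param bridges Two-column matrix of bridged monomer pairs (may have zero
#'   rows).
#' @return A symmetric `length(x)` x `length(x)` matrix of effective
#'   separations.
#' @export
effective_separation <- function(x, bridges) {
  base <- abs(outer(x, x, "-"))
  if (is.null(bridges) || nrow(bridges) == 0L) return(base)
  ep <- as.numeric(t(bridges))          # endpoints, bridge k at 2k-1, 2k
  m <- length(ep)
  D <- abs(outer(ep, ep, "-"))
  for (k in seq_len(nrow(bridges))) D[2L * k - 1L, 2L * k] <- D[2L * k, 2L * k - 1L] <- 0
  for (k in seq_len(m)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  A <- abs(outer(x, ep, "-"))           # |x_i - endpoint_u|
  # min-plus product: Tm[i, v] = min_u A[i, u] + D[u, v]
  Tm <- A
  for (v in seq_len(m)) {
    cand <- A + rep(D[, v], each = nrow(A))
    Tm[, v] <- do.call(pmin, lapply(seq_len(m), function(u) cand[, u]))
  }
  s <- base
  for (v in seq_len(m)) s <- pmin(s, outer(Tm[, v], A[, v], "+"))
  s
}

#' Analytic loop-free background contact map
#'
#' The contact map the gaussian mode produces for a chain with no extruders:
#' `n_snapshots * (1 + s / capture_scale)^(-exponent)` over bin-center
#' separations `s`. Used as the reference when isolating loop-attributable
#' contact mass (see [ps_excess()]).
#'
#' @param n_monomers Lattice length.
#' @param bin_monomers Monomers per map bin.
#' @param n_snapshots Snapshot count the background should be scaled to.
#' @param capture_scale,exponent Contact kernel parameters, as in
#'   [contact_map_gaussian()].
#' @return A raw [contact_map].
#' @export
background_contact_map <- function(n_monomers, bin_monomers = 5L,
                                   n_snapshots = 1L, capture_scale = 1,
                                   exponent = 1.5) {
  nb <- n_monomers %/% bin_monomers
  centers <- (seq_len(nb) - 0.5) * bin_monomers + 0.5
  s <- abs(outer(centers, centers, "-"))
  contact_map(n_snapshots * (1 + s / capture_scale)^(-exponent),
              bin_size = bin_monomers * 1000, normalized = "raw")
}

#' Contact map from a trajectory via ideal-chain return probabilities
#'
#' For every snapshot, treats each extruder as a zero-length bridge between
#' its two ends, computes effective contour separations `s_eff` between bin
#' centers by shortest path, and accumulates contact weight
#' `(1 + s_eff / capture_scale)^(-3/2)` — the return probability scaling of
#' an ideal chain. Snapshots and replicates are summed.
#'
#' @param trajectory An `extrusion_trajectory`.
#' @param capture_scale Contour-length scale of the contact kernel,
#'   monomers.
#' @param bin_monomers Monomers per map bin (1 monomer = 1 kb).
#' @param exponent Contact decay exponent (default 3/2, ideal chain).
#' @param engine `"cpp"` (compiled accumulation, default) or `"r"` (via
#'   [effective_separation()]; identical results, used for cross-checks).
#' @return A raw [contact_map] with `bin_size = bin_monomers * 1000` bp.
#' @export
contact_map_gaussian <- function(trajectory, capture_scale = 1,
                                 bin_monomers = 5L, exponent = 1.5,
                                 engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(trajectory, "extrusion_trajectory"),
            capture_scale > 0, exponent > 0)
  n_mon <- trajectory$params$n_monomers
  nb <- n_mon %/% bin_monomers
  if (nb < 2L) stop("fewer than 2 bins; decrease bin_monomers")
  centers <- (seq_len(nb) - 0.5) * bin_monomers + 0.5  # monomer midpoints
  n_snap <- nrow(trajectory$left)
  if (n_snap < 1L) stop("trajectory has no snapshots")
  if (engine == "cpp") {
    acc <- accumulate_gaussian_contacts_cpp(centers, trajectory$left,
                                            trajectory$right, capture_scale,
                                            exponent)
  } else {
    acc <- matrix(0, nb, nb)
    for (i in seq_len(n_snap)) {
      s_eff <- effective_separation(centers, loops_from_snapshot(trajectory, i))
      acc <- acc + (1 + s_eff / capture_scale)^(-exponent)
    }
  }
  contact_map(acc, bin_size = bin_monomers * 1000, normalized = "raw")
}
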