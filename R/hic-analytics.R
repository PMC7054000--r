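#' Contact probability versus genomic distance, P(s)
#'
#' Mean contact frequency in logarithmically increasing genomic-distance
#' bins, the standard P(s) summary of a contact map.
#'
#' @param map A [contact_map] with at least 2 bins.
#' @param bins_per_decade Number of log-spaced distance bins per decade.
#' @param normalize If TRUE, scale the means so they sum to 1.
#' @return A data frame with columns `dist_lo`, `dist_hi` (bp, half-open),
#'   `dist_mid` (geometric midpoint), `mean_contact`, `n_pairs`.
#' @export
ps_curve <- function(map, bins_per_decade = 10L, normalize = FALSE) {
  stopifnot(inherits(map, "contact_map"))
  A <- map$matrix
  n <- nrow(A)
  if (n < 2L) stop("contact map must have at least 2 bins")
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  off <- s > 0
  d_bp <- s[off] * map$bin_size
  v <- A[off]
  lo <- log10(map$bin_size)
  hi <- log10((n - 1) * map$bin_size)
  breaks <- 10^seq(lo, hi + 1 / bins_per_decade, by = 1 / bins_per_decade)
  idx <- findInterval(d_bp, breaks, rightmost.closed = FALSE)
  mc <- tapply(v, idx, mean)
  np <- tapply(v, idx, length)
  k <- as.integer(names(mc))
  out <- data.frame(dist_lo = breaks[k], dist_hi = breaks[k + 1L],
                    dist_mid = sqrt(breaks[k] * breaks[k + 1L]),
                    mean_contact = as.numeric(mc),
                    n_pairs = as.integer(np))
  if (normalize) out$mean_contact <- out$mean_contact / sum(out$mean_contact)
  out
}

#' Peak position of a detrended P(s) curve
#'
#' Raw P(s) decreases monotonically, so the characteristic interaction scale
#' is located on a detrended curve. Two detrends are supported: dividing by
#' a `reference` P(s) computed on matching distance bins (e.g. from a
#' loop-free map of the same model, giving the exact enrichment profile), or
#' multiplying by `s^alpha` with the ideal-chain exponent `alpha = 3/2`.
#'
#' @param ps A data frame from [ps_curve()].
#' @param reference Optional P(s) data frame on identical distance bins,
#'   used as the denominator.
#' @param detrend_exponent Detrending exponent alpha when no reference is
#'   given.
#' @return Peak distance in bp (the `dist_mid` of the maximizing bin).
#' @export
ps_peak <- function(ps, reference = NULL, detrend_exponent = 1.5) {
  stopifnot(is.data.frame(ps), nrow(ps) >= 1)
  if (!is.null(reference)) {
    if (nrow(reference) != nrow(ps) ||
        any(abs(reference$dist_mid - ps$dist_mid) > 1e-6 * ps$dist_mid))
      stop("reference P(s) must be computed on identical distance bins")
    return(ps$dist_mid[which.max(ps$mean_contact / reference$mean_contact)])
  }
  ps$dist_mid[which.max(ps$mean_contact * ps$dist_mid^detrend_exponent)]
}

#' Loop-attributable contact mass by distance, and its characteristic scale
#'
#' Raw P(s) of this package's contact model has no interior peak: the
#' loop-free background falls off smoothly and loop enrichment grows
#' monotonically with separation, so the informative quantity is the contact
#' mass in excess of the background per log-spaced distance bin.
#' `ps_excess()` subtracts a reference P(s) (typically from
#' [background_contact_map()] at the matching snapshot count) and multiplies
#' by the pair count per bin. `loop_contact_scale()` summarizes where that
#' excess sits: the discrete argmax bin and the excess-weighted geometric
#' mean distance, a robust estimator of the characteristic loop scale that
#' shifts with extruder lifetime.
#'
#' @param ps P(s) data frame from [ps_curve()] on a raw map.
#' @param reference P(s) data frame of the matching loop-free background on
#'   identical distance bins.
#' @param scale Multiplier applied to the reference (1 when the reference
#'   was already built at the map's snapshot count).
#' @return `ps_excess()`: the `ps` table with an `excess` column (per-bin
#'   total contact mass above background). `loop_contact_scale()`: a list
#'   with `peak_bp` (argmax bin midpoint) and `scale_bp` (excess-weighted
#'   geometric mean distance).
#' @export
ps_excess <- function(ps, reference, scale = 1) {
  stopifnot(is.data.frame(ps), is.data.frame(reference))
  if (nrow(reference) != nrow(ps) ||
      any(abs(reference$dist_mid - ps$dist_mid) > 1e-6 * ps$dist_mid))
    stop("reference P(s) must be computed on identical distance bins")
  ps$excess <- (ps$mean_contact - scale * reference$mean_contact) * ps$n_pairs
  ps
}

#' @rdname ps_excess
#' @export
loop_contact_scale <- function(ps, reference, scale = 1) {
  ex <- ps_excess(ps, reference, scale)
  w <- pmax(ex$excess, 0)
  if (sum(w) <= 0) stop("no contact mass above background")
  list(peak_bp = ex$dist_mid[which.max(ex$excess)],
       scale_bp = exp(sum(w * log(ex$dist_mid)) / sum(w)))
}

#' Cross-window insulation profile of a contact map
#'
#' For each bin `i` with a full window on both sides, the raw insulation is
#' the mean of the `w x w` submatrix spanning `[i - w, i) x [i, i + w)`
#' (`w = window / resolution` bins), i.e. the contacts crossing the
#' boundary between bins `i - 1` and `i`. Scores are reported as log2 of the
#' raw value over the map-wide mean of raw values; boundaries are local
#' minima whose depth below the surrounding maximum within `w` bins exceeds
#' `prominence`. Edge bins without a full window are masked (NA).
#'
#' @param map A [contact_map]; its `bin_size` must equal `resolution`.
#' @param resolution Bin size in bp (default: the map's).
#' @param window Window size in bp; a multiple of `resolution`, at least
#'   `2 * resolution`.
#' @param max_dist Maximum interaction distance considered, bp (entries
#'   farther apart are excluded from the window mean).
#' @param prominence Minimum depth (in log2 units) below the local maximum
#'   for a boundary call.
#' @return An `insulation_profile`: data frame with columns `bin`, `start`,
#'   `end` (bp), `score` (log2, NA where masked); attributes `resolution`,
#'   `window`, `boundaries` (bin indices).
#' @export
insulation <- function(map, resolution = map$bin_size, window = 15000,
                       max_dist = 2e6, prominence = 0.2) {
  stopifnot(inherits(map, "contact_map"))
  if (resolution != map$bin_size)
    stop("resolution must equal the map's bin_size; rebin the map first")
  w <- window / resolution
  if (w != round(w)) stop("window must be a multiple of resolution")
  w <- as.integer(w)
  if (w < 2L) stop("window must be at least 2 * resolution")
  A <- map$matrix
  n <- nrow(A)
  if (n < 2L * w + 1L) stop("map too small for this window")
  maxbins <- floor(max_dist / resolution)
  score_raw <- rep(NA_real_, n)
  for (i in (w + 1L):(n - w + 1L)) {
    rows <- (i - w):(i - 1L); cols <- i:(i + w - 1L)
    sub <- A[rows, cols, drop = FALSE]
    d <- abs(outer(rows, cols, "-"))
    score_raw[i] <- mean(sub[d <= maxbins])
  }
  ok <- which(is.finite(score_raw) & score_raw > 0)
  if (length(ok) == 0L) stop("no defined insulation scores")
  score <- rep(NA_real_, n)
  score[ok] <- log2(score_raw[ok] / mean(score_raw[ok]))
  bd <- integer(0)
  for (i in ok) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    nb <- score[lo:hi]
    if (all(is.na(nb))) next
    if (!is.na(score[i]) && score[i] == min(nb, na.rm = TRUE) &&
        max(nb, na.rm = TRUE) - score[i] >= prominence &&
        sum(nb == score[i], na.rm = TRUE) == 1L)
      bd <- c(bd, i)
  }
  out <- data.frame(bin = seq_len(n),
                    start = map$origin + (seq_len(n) - 1L) * resolution,
                    end = map$origin + seq_len(n) * resolution,
                    score = score)
  attr(out, "resolution") <- resolution
  attr(out, "window") <- window
  attr(out, "boundaries") <- bd
  attr(out, "score_raw") <- score_raw
  class(out) <- c("insulation_profile", "data.frame")
  out
}

#' Average insulation profile around positions, with a random control
#'
#' Averages the insulation score in a window of `flank` bins around the
#' supplied bin positions, and around `n_random` uniformly drawn control
#' positions — the dashed "random positions" control of boundary-averaged
#' insulation plots.
#'
#' @param profile An `insulation_profile` from [insulation()].
#' @param positions Bin indices (e.g. boundary calls).
#' @param flank Bins of context on each side.
#' @param n_random Number of random control positions.
#' @param seed Integer seed for the control draw.
#' @return A data frame with columns `offset` (bins), `mean_score`,
#'   `mean_score_random`.
#' @export
boundary_profile <- function(profile, positions = attr(profile, "boundaries"),
                             flank = 10L, n_random = 100L, seed = 1L) {
  stopifnot(inherits(profile, "insulation_profile"), length(positions) > 0)
  n <- nrow(profile)
  stack <- function(pos) {
    keep <- pos[pos - flank >= 1L & pos + flank <= n]
    if (length(keep) == 0L) return(rep(NA_real_, 2L * flank + 1L))
    m <- vapply(keep, function(p) profile$score[(p - flank):(p + flank)],
                numeric(2L * flank + 1L))
    rowMeans(m, na.rm = TRUE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  rnd <- sample((flank + 1L):(n - flank), n_random, replace = TRUE)
  data.frame(offset = -flank:flank,
             mean_score = stack(positions),
             mean_score_random = stack(rnd))
}

#' Aggregate peak analysis (APA) of loops
#'
#' Sums fixed-size submatrices of a (balanced) contact map centered on each
#' loop's (anchor1 midpoint bin, anchor2 midpoint bin): with the default
#' `window_bins = 10` on a 10 kb map these are the classic 210 kb x 210 kb
#' (21 x 21 bin) squares. Loops closer than the window to the matrix edge or
#' to the diagonal are skipped and counted. Reports the pileup, the center
#' value (total contacts at the loop set's center), and the enrichment of
#' the center over the mean of the four corner blocks.
#'
#' @param map A [contact_map]; balanced input is expected for interpretable
#'   enrichments.
#' @param loops A [loop_list], or a data frame / matrix with columns
#'   `bin1`, `bin2` of anchor-midpoint bin indices.
#' @param window_bins Half-width of the pileup in bins (pileup is
#'   `2 * window_bins + 1` square).
#' @param corner_bins Side length of the corner blocks used for the
#'   enrichment denominator.
#' @return A list with `pileup` (matrix), `center` (its central value),
#'   `enrichment` (center / mean of the four corner blocks), `n_used`,
#'   `n_skipped`.
#' @export
apa <- function(map, loops, window_bins = 10L, corner_bins = 5L) {
  stopifnot(inherits(map, "contact_map"))
  bins <- .loop_bins(map, loops)
  w <- as.integer(window_bins)
  n <- nrow(map$matrix)
  sz <- 2L * w + 1L
  pile <- matrix(0, sz, sz)
  used <- 0L; skipped <- 0L
  for (k in seq_len(nrow(bins))) {
    i <- bins[k, 1]; j <- bins[k, 2]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    if (i - w < 1L || j + w > n || (j - i) <= 2L * w) { skipped <- skipped + 1L; next }
    pile <- pile + map$matrix[(i - w):(i + w), (j - w):(j + w)]
    used <- used + 1L
  }
  if (used == 0L) stop("no usable loops for APA (all skipped)")
  cb <- as.integer(corner_bins)
  corners <- c(pile[1:cb, 1:cb], pile[1:cb, (sz - cb + 1L):sz],
               pile[(sz - cb + 1L):sz, 1:cb],
               pile[(sz - cb + 1L):sz, (sz - cb + 1L):sz])
  center <- pile[w + 1L, w + 1L]
  list(pileup = pile, center = center,
       enrichment = center / mean(corners),
       n_used = used, n_skipped = skipped)
}

# loops -> two-column matrix of anchor-midpoint bin indices on `map`
.loop_bins <- function(map, loops) {
  if (inherits(loops, "loop_list")) {
    mid1 <- (loops$start1 + loops$end1) / 2
    mid2 <- (loops$start2 + loops$end2) / 2
    cbind(floor((mid1 - map$origin) / map$bin_size) + 1L,
          floor((mid2 - map$origin) / map$bin_size) + 1L)
  } else {
    m <- as.matrix(as.data.frame(loops)[, c("bin1", "bin2")])
    storage.mode(m) <- "integer"
    m
  }
}

#' Size-classified aggregate TAD pileups
#'
#' Groups TADs by length into the supplied size classes and, for each class,
#' sums fixed-size submatrices of a coverage-normalized map centered on the
#' TAD centers (window scaled to the class upper bound, so same-class TADs
#' are aggregated at a common size).
#'
#' @param map A [contact_map].
#' @param tads A data frame with columns `start`, `end` (bp).
#' @param size_classes Numeric breaks (bp) defining left-closed,
#'   right-open length classes.
#' @param flank_factor Window half-width = `flank_factor *` class upper
#'   bound (in bins, rounded up).
#' @return A list per non-empty class: `pileup`, `n`, `class` (bp range).
#'   Empty classes are omitted with a warning.
#' @export
tad_pileup <- function(map, tads, size_classes, flank_factor = 0.75) {
  stopifnot(inherits(map, "contact_map"), length(size_classes) >= 2)
  tads <- as.data.frame(tads)
  len <- tads$end - tads$start
  cls <- findInterval(len, size_classes, rightmost.closed = FALSE)
  cls[len >= size_classes[length(size_classes)] | cls == 0L] <- NA
  n <- nrow(map$matrix)
  out <- list()
  for (k in seq_len(length(size_classes) - 1L)) {
    idx <- which(!is.na(cls) & cls == k)
    if (length(idx) == 0L) {
      warning(sprintf("no TADs in class [%g, %g); omitted",
                      size_classes[k], size_classes[k + 1L]))
      next
    }
    w <- as.integer(ceiling(flank_factor * size_classes[k + 1L] / map$bin_size))
    sz <- 2L * w + 1L
    pile <- matrix(0, sz, sz); used <- 0L
    for (i in idx) {
      cbin <- floor(((tads$start[i] + tads$end[i]) / 2 - map$origin) /
                      map$bin_size) + 1L
      if (cbin - w < 1L || cbin + w > n) next
      pile <- pile + map$matrix[(cbin - w):(cbin + w), (cbin - w):(cbin + w)]
      used <- used + 1L
    }
    if (used == 0L) {
      warning(sprintf("class [%g, %g): all TADs too close to the map edge; omitted",
                      size_classes[k], size_classes[k + 1L]))
      next
    }
    out[[sprintf("[%g,%g)", size_classes[k], size_classes[k + 1L])]] <-
      list(pileup = pile, n = used,
           class = c(size_classes[k], size_classes[k + 1L]))
  }
  if (length(out) == 0L) stop("no size class contained a usable TAD")
  out
}
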