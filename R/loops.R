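#' Chromatin loop list
#'
#' Paired genomic intervals (0-based half-open) giving the two anchors of
#' each loop, anchor1 upstream of anchor2 on the same chromosome. Loop
#' length is the distance between anchor midpoints.
#'
#' @param chrom Chromosome per loop.
#' @param start1,end1 Anchor-1 interval, bp.
#' @param start2,end2 Anchor-2 interval, bp.
#' @return A `loop_list` data frame.
#' @export
loop_list <- function(chrom, start1, end1, start2, end2) {
  out <- data.frame(chrom = as.character(chrom),
                    start1 = as.numeric(start1), end1 = as.numeric(end1),
                    start2 = as.numeric(start2), end2 = as.numeric(end2),
                    stringsAsFactors = FALSE)
  if (any(out$start1 >= out$end1) || any(out$start2 >= out$end2))
    stop("anchor intervals must have start < end")
  if (any((out$start1 + out$end1) / 2 >= (out$start2 + out$end2) / 2))
    stop("anchor1 must lie upstream of anchor2 (midpoint order)")
  class(out) <- c("loop_list", "data.frame")
  out
}

#' Loop lengths (anchor-midpoint distances)
#'
#' @param loops A [loop_list].
#' @return Numeric vector of lengths, bp.
#' @export
loop_lengths <- function(loops) {
  stopifnot(inherits(loops, "loop_list"))
  (loops$start2 + loops$end2) / 2 - (loops$start1 + loops$end1) / 2
}

#' Empirical cumulative distribution of loop lengths
#'
#' @param loops A [loop_list] with at least one loop.
#' @return A data frame with columns `length` (sorted, bp) and `ecdf`
#'   (monotone from 1/n to 1); attribute `fun` holds the [stats::ecdf()]
#'   step function.
#' @export
loop_length_ecdf <- function(loops) {
  len <- loop_lengths(loops)
  if (length(len) == 0L) stop("no loops")
  f <- stats::ecdf(len)
  len <- sort(len)
  out <- data.frame(length = len, ecdf = f(len))
  attr(out, "fun") <- f
  out
}

# anchors of a loop_list as a GRanges, anchors <min_width expanded
# symmetrically about their midpoints
.anchor_granges <- function(loops, min_width = 15000) {
  st <- c(loops$start1, loops$start2)
  en <- c(loops$end1, loops$end2)
  w <- en - st
  grow <- w < min_width
  mid <- (st + en) / 2
  st[grow] <- round(mid[grow] - min_width / 2)
  en[grow] <- st[grow] + min_width
  st <- pmax(st, 0)
  GenomicRanges::GRanges(rep(loops$chrom, 2L),
                         IRanges::IRanges(start = st + 1L, end = en))
}

.intervals_granges <- function(x) {
  x <- as.data.frame(x)
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(start = x$start + 1L,
                                                   end = x$end))
}

#' CTCF occupancy of loop anchors with translational controls
#'
#' Expands loop anchors smaller than `min_width` (15 kb) symmetrically to
#' `min_width`, counts anchors overlapping at least one peak, and compares
#' with the mean overlap of `n_controls` random translational controls:
#' every control anchor keeps its width and chromosome but is re-placed
#' uniformly in `[0, chrom_length - width)`.
#'
#' @param loops A [loop_list].
#' @param peaks Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param chrom_sizes Named numeric vector of chromosome lengths, bp.
#' @param n_controls Number of random controls (default 10).
#' @param min_width Minimum tested anchor width, bp.
#' @param seed Base seed; control k uses `seed + k`.
#' @return A list with `observed` (anchors overlapping >= 1 peak),
#'   `expected` (mean over controls), `fold` (observed / expected; `Inf`
#'   with `infinite_fold = TRUE` when expected is 0), `n_anchors`.
#' @export
ctcf_occupancy <- function(loops, peaks, chrom_sizes, n_controls = 10L,
                           min_width = 15000, seed = 1L) {
  stopifnot(inherits(loops, "loop_list"), n_controls >= 1)
  anchors <- .anchor_granges(loops, min_width)
  pk <- .intervals_granges(peaks)
  observed <- sum(GenomicRanges::countOverlaps(anchors, pk) > 0)
  widths <- GenomicRanges::width(anchors)
  chroms <- as.character(GenomicRanges::seqnames(anchors))
  if (!all(chroms %in% names(chrom_sizes)))
    stop("chrom_sizes must name every loop chromosome")
  lens <- unname(chrom_sizes[chroms])
  if (any(lens < widths)) stop("an anchor is wider than its chromosome")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  ctrl <- vapply(seq_len(n_controls), function(k) {
    set.seed(as.integer(seed) + k)
    st <- floor(stats::runif(length(widths), 0, lens - widths + 1))
    g <- GenomicRanges::GRanges(chroms,
                                IRanges::IRanges(start = st + 1L,
                                                 width = widths))
    sum(GenomicRanges::countOverlaps(g, pk) > 0)
  }, numeric(1))
  expected <- mean(ctrl)
  list(observed = observed, expected = expected,
       fold = if (expected > 0) observed / expected else Inf,
       infinite_fold = expected == 0,
       n_anchors = length(anchors))
}

#' Classify loops by CTCF motif convergence
#'
#' A loop is eligible when each anchor overlaps at least one SMC3 peak and
#' exactly one oriented CTCF motif (anchors with zero or multiple motifs are
#' excluded as ambiguous). Eligible loops are classified from the ordered
#' motif orientations: `(+,-)` convergent, `(-,+)` divergent, equal
#' orientations tandem. The random expectation with unbiased orientations is
#' (0.25, 0.5, 0.25).
#'
#' @param loops A [loop_list].
#' @param ctcf_motifs Data frame with columns `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`).
#' @param smc3_peaks Data frame with columns `chrom`, `start`, `end`.
#' @param min_width Anchor expansion floor, bp (as in [ctcf_occupancy()]).
#' @return A list with `proportions` (named: convergent, tandem, divergent;
#'   sums to 1), `counts`, `n_eligible`, `expected = c(0.25, 0.5, 0.25)`.
#' @export
classify_convergence <- function(loops, ctcf_motifs, smc3_peaks,
                                 min_width = 15000) {
  stopifnot(inherits(loops, "loop_list"))
  ctcf_motifs <- as.data.frame(ctcf_motifs)
  if (!all(ctcf_motifs$strand %in% c("+", "-")))
    stop("ctcf_motifs must carry '+'/'-' orientations")
  anchors <- .anchor_granges(loops, min_width)
  nl <- nrow(loops)
  mg <- .intervals_granges(ctcf_motifs)
  sg <- .intervals_granges(smc3_peaks)
  smc_ok <- GenomicRanges::countOverlaps(anchors, sg) > 0
  hits <- GenomicRanges::findOverlaps(anchors, mg)
  n_motif <- tabulate(S4Vectors::queryHits(hits), nbins = 2L * nl)
  motif_strand <- rep(NA_character_, 2L * nl)
  one <- which(n_motif == 1L)
  if (length(one) > 0) {
    h1 <- hits[S4Vectors::queryHits(hits) %in% one]
    motif_strand[S4Vectors::queryHits(h1)] <-
      ctcf_motifs$strand[S4Vectors::subjectHits(h1)]
  }
  a1 <- seq_len(nl); a2 <- nl + seq_len(nl)
  eligible <- smc_ok[a1] & smc_ok[a2] & n_motif[a1] == 1L & n_motif[a2] == 1L
  if (!any(eligible)) stop("no eligible loops (SMC3 + unambiguous CTCF at both anchors)")
  s1 <- motif_strand[a1][eligible]; s2 <- motif_strand[a2][eligible]
  cls <- ifelse(s1 == "+" & s2 == "-", "convergent",
                ifelse(s1 == "-" & s2 == "+", "divergent", "tandem"))
  counts <- c(convergent = sum(cls == "convergent"),
              tandem = sum(cls == "tandem"),
              divergent = sum(cls == "divergent"))
  list(proportions = counts / sum(counts), counts = counts,
       n_eligible = sum(eligible),
       expected = c(convergent = 0.25, tandem = 0.5, divergent = 0.25))
}

#' Union overlap of interval sets
#'
#' Merges every run of transitively overlapping intervals across the input
#' sets into one union site labeled with its set-membership pattern — the
#' inclusive ("union") overlap display used for peak comparisons, supporting
#' Venn-style counts.
#'
#' @param interval_sets Named list of data frames with columns `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return A data frame with columns `chrom`, `start`, `end`, `membership`
#'   (comma-separated set names) and `n_sets`; attribute `counts` tabulates
#'   membership patterns.
#' @export
interval_union_overlap <- function(interval_sets) {
  stopifnot(is.list(interval_sets), length(interval_sets) >= 1)
  if (is.null(names(interval_sets)) || any(names(interval_sets) == ""))
    names(interval_sets) <- paste0("set", seq_along(interval_sets))
  for (nm in names(interval_sets)) {
    x <- as.data.frame(interval_sets[[nm]])
    bad <- which(x$start >= x$end | x$start < 0)
    if (length(bad) > 0)
      stop(sprintf("malformed interval in set '%s' at row %d (start >= end or negative)",
                   nm, bad[1]))
  }
  gr <- lapply(interval_sets, .intervals_granges)
  all_gr <- do.call(c, unname(gr))
  # min.gapwidth = 0: merge only truly overlapping intervals, not ones that
  # merely touch at a shared half-open endpoint
  merged <- GenomicRanges::reduce(all_gr, min.gapwidth = 0L)
  member <- vapply(seq_along(merged), function(i) "", character(1))
  memb_mat <- vapply(gr, function(g)
    GenomicRanges::countOverlaps(merged, g) > 0, logical(length(merged)))
  memb_mat <- matrix(memb_mat, nrow = length(merged),
                     dimnames = list(NULL, names(interval_sets)))
  member <- apply(memb_mat, 1, function(r)
    paste(names(interval_sets)[r], collapse = ","))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged) - 1L,
                    end = GenomicRanges::end(merged),
                    membership = member,
                    n_sets = rowSums(memb_mat),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- table(out$membership)
  out
}
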