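#' Contact map container
#'
#' A dense symmetric nonnegative matrix with bin-size metadata — the unit of
#' all Hi-C-style analytics in this package.
#'
#' @param matrix Square numeric matrix, symmetric within 1e-9, entries >= 0.
#' @param bin_size Bin size in bp.
#' @param origin Genomic/lattice offset of the first bin, bp.
#' @param normalized One of `"raw"`, `"coverage"`, `"balanced"`.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(matrix, bin_size, origin = 0,
                        normalized = c("raw", "coverage", "balanced")) {
  normalized <- match.arg(normalized)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("contact map must be square")
  if (any(!is.finite(matrix))) stop("contact map entries must be finite")
  if (any(matrix < 0)) stop("contact map entries must be nonnegative")
  if (max(abs(matrix - t(matrix))) > 1e-9 * max(1, max(abs(matrix))))
    stop("contact map must be symmetric (within 1e-9 relative)")
  matrix <- (matrix + t(matrix)) / 2  # exact symmetry
  structure(list(matrix = matrix, bin_size = as.numeric(bin_size),
                 origin = as.numeric(origin), normalized = normalized),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact map: %d x %d bins of %g bp (origin %g bp, %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_size, x$origin,
              x$normalized))
  invisible(x)
}

#' @export
dim.contact_map <- function(x) dim(x$matrix)

#' Balance a contact map
#'
#' `"coverage"` divides entry (i, j) by `sqrt(rowsum_i * rowsum_j)`
#' (vanilla-coverage normalization). `"iterative"` alternates symmetric
#' row/column scaling until the unmasked row sums agree to a relative
#' deviation below `tol` (a simple iterative-correction stand-in for
#' Knight-Ruiz balancing). Rows with zero total signal are masked and
#' returned as zeros.
#'
#' @param map A [contact_map].
#' @param method `"coverage"` or `"iterative"`.
#' @param tol Relative row-sum tolerance for the iterative method.
#' @param max_iter Iteration cap for the iterative method.
#' @return A balanced [contact_map] (`normalized` set accordingly).
#' @export
balance <- function(map, method = c("coverage", "iterative"), tol = 1e-6,
                    max_iter = 200L) {
  method <- match.arg(method)
  stopifnot(inherits(map, "contact_map"))
  A <- map$matrix
  rs <- rowSums(A)
  keep <- rs > 0
  if (!any(keep)) stop("contact map has no signal to balance")
  B <- A
  if (method == "coverage") {
    s <- sqrt(rs[keep])
    B[keep, keep] <- A[keep, keep] / outer(s, s)
    B[!keep, ] <- 0; B[, !keep] <- 0
    out <- contact_map(B, map$bin_size, map$origin, "coverage")
  } else {
    M <- A[keep, keep, drop = FALSE]
    for (it in seq_len(max_iter)) {
      b <- rowSums(M)
      dev <- max(abs(b - mean(b))) / mean(b)
      if (dev < tol) break
      s <- sqrt(b / mean(b))
      M <- M / outer(s, s)
    }
    B[keep, keep] <- M
    B[!keep, ] <- 0; B[, !keep] <- 0
    out <- contact_map(B, map$bin_size, map$origin, "balanced")
  }
  out
}

#' Extract bridged monomer pairs from a trajectory snapshot
#'
#' @param trajectory An `extrusion_trajectory`.
#' @param i Snapshot row index.
#' @return A two-column integer matrix (left, right), one row per extruder,
#'   ordered by left position; zero rows when the snapshot holds no
#'   extruders.
#' @export
loops_from_snapshot <- function(trajectory, i) {
  stopifnot(inherits(trajectory, "extrusion_trajectory"),
            i >= 1, i <= nrow(trajectory$left))
  m <- cbind(left = trajectory$left[i, ], right = trajectory$right[i, ])
  m[order(m[, 1]), , drop = FALSE]
}
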