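#' Oriented CTCF site track on a monomer lattice
#'
#' A `ctcf_track` holds the oriented CTCF binding sites that halt loop
#' extruders: for each site a monomer position (1-based), a motif
#' orientation (`"+"` points toward increasing coordinates), and a halting
#' probability in \[0, 1\] applied when an extruder end steps onto the site.
#'
#' @param n_monomers Number of monomers on the lattice (1 monomer = 1 kb).
#' @param position Integer vector of site positions in `1..n_monomers`,
#'   strictly increasing, no duplicates.
#' @param orientation Character vector of `"+"`/`"-"` motif orientations.
#' @param halt_prob Numeric vector of halting probabilities in \[0, 1\].
#'
#' @return An object of class `ctcf_track`: a data frame with columns
#'   `position`, `orientation`, `halt_prob` and attribute `n_monomers`.
#' @export
ctcf_track <- function(n_monomers, position = integer(), orientation = character(),
                       halt_prob = numeric()) {
  n_monomers <- as.integer(n_monomers)
  stopifnot(length(n_monomers) == 1L, n_monomers >= 1L)
  position <- as.integer(position)
  if (length(position) != length(orientation) || length(position) != length(halt_prob))
    stop("position, orientation and halt_prob must have equal length")
  if (any(position < 1L | position > n_monomers))
    stop("site positions must lie in 1..n_monomers")
  if (is.unsorted(position, strictly = TRUE))
    stop("site positions must be strictly increasing (no duplicates)")
  if (!all(orientation %in% c("+", "-")))
    stop("orientation must be '+' or '-'")
  if (any(halt_prob < 0 | halt_prob > 1))
    stop("halt_prob must be in [0, 1]")
  out <- data.frame(position = position, orientation = orientation,
                    halt_prob = as.numeric(halt_prob), stringsAsFactors = FALSE)
  attr(out, "n_monomers") <- n_monomers
  class(out) <- c("ctcf_track", "data.frame")
  out
}

#' @export
print.ctcf_track <- function(x, ...) {
  cat(sprintf("CTCF site track: %d sites on %d monomers\n",
              nrow(x), attr(x, "n_monomers")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Generate a CTCF site layout
#'
#' Two layouts are available. `"simplified_fig6a"` is the minimal
#' three-convergent-pair configuration used to probe the relationship
#' between extruder lifetime and loop size: six sites on a 1000-monomer
#' polymer, the two outermost with halting probability 0.9 and the inner
#' four with 0.4. `"random"` draws site positions uniformly without
#' replacement, orientations Bernoulli(0.5) and halting probabilities
#' Uniform(0, 1).
#'
#' Positions for the simplified layout are a package convention (the layout
#' is specified only as "three pairs of convergent CTCF sites"): monomers
#' 100, 263, 426, 575, 738, 901 with orientations `+,-,+,-,+,-`, so adjacent
#' pairs (1,2), (3,4), (5,6) are convergent and near-evenly spaced.
#'
#' @param kind `"simplified_fig6a"` or `"random"`.
#' @param n_monomers Lattice size; the simplified layout requires 1000.
#' @param n_sites Number of sites for `kind = "random"`.
#' @param seed Integer seed (used by `kind = "random"`).
#' @return A [ctcf_track].
#' @examples
#' make_ctcf_layout("simplified_fig6a")
#' make_ctcf_layout("random", n_monomers = 100, n_sites = 8, seed = 1)
#' @export
make_ctcf_layout <- function(kind = c("simplified_fig6a", "random"),
                             n_monomers = 1000L, n_sites = 6L, seed = 1L) {
  kind <- match.arg(kind)
  n_monomers <- as.integer(n_monomers)
  if (kind == "simplified_fig6a") {
    if (n_monomers < 1000L)
      stop("the simplified layout is defined on a 1000-monomer polymer; n_monomers must be >= 1000")
    return(ctcf_track(
      n_monomers  = n_monomers,
      position    = c(100L, 263L, 426L, 575L, 738L, 901L),
      orientation = c("+", "-", "+", "-", "+", "-"),
      halt_prob   = c(0.9, 0.4, 0.4, 0.4, 0.4, 0.9)
    ))
  }
  n_sites <- as.integer(n_sites)
  if (n_monomers < n_sites)
    stop(sprintf("n_monomers = %d is too small for %d sites", n_monomers, n_sites))
  if (n_monomers < 10L) stop("n_monomers must be >= 10")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  pos <- sort(sample.int(n_monomers, n_sites, replace = FALSE))
  ori <- ifelse(stats::runif(n_sites) < 0.5, "+", "-")
  hp  <- stats::runif(n_sites)
  ctcf_track(n_monomers, pos, ori, hp)
}

#' Convert a ChIP-seq-like signal into per-monomer halting probabilities
#'
#' Mirrors the normalization used to derive halting probabilities from CTCF
#' ChIP-seq coverage: the nonnegative per-monomer signal is divided by its
#' maximum, giving probabilities in \[0, 1\] with max exactly 1.
#'
#' @param signal Nonnegative numeric vector, at least one positive value.
#' @return Numeric vector of the same length in \[0, 1\].
#' @examples
#' chip_to_halt_prob(c(0, 5, 10))
#' @export
chip_to_halt_prob <- function(signal) {
  signal <- as.numeric(signal)
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("signal must be finite and nonnegative")
  m <- max(signal)
  if (m <= 0) stop("signal is all zero; cannot normalize to probabilities")
  signal / m
}

# Save/restore .Random.seed so seeded generators do not perturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
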