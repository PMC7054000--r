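#' Specification of a synthetic iFRAP trace
#'
#' Describes a ground-truth exponential decay model from which
#' [simulate_frap_trace()] draws noisy traces. The post-bleach difference
#' signal follows `f(t) = exp(-koff1 * t)` (single) or
#' `f(t) = a * exp(-koff1 * t) + (1 - a) * exp(-koff2 * t)` (double), where
#' `a` is the dynamic (fast) fraction and `1 - a` the stable fraction.
#'
#' @param model `"single"` or `"double"`.
#' @param a Dynamic fraction in \[0, 1\] (double model only; single implies 1).
#' @param koff1 Fast dissociation rate, 1/min.
#' @param koff2 Slow dissociation rate, 1/min; must satisfy `koff2 < koff1`.
#' @param noise_sd Additive Gaussian noise sd in normalized intensity units.
#'   Default 0.02, a typical confocal noise level for normalized traces.
#' @param n_timepoints Number of post-bleach frames.
#' @param dt Frame interval, minutes.
#' @param n_prebleach Number of pre-bleach frames (value 1 plus noise).
#' @param seed Integer seed.
#' @return A `frap_sim_spec` list.
#' @export
frap_sim_spec <- function(model = c("single", "double"), a = 1, koff1,
                          koff2 = NA_real_, noise_sd = 0.02,
                          n_timepoints = 60L, dt = 1, n_prebleach = 2L,
                          seed = 1L) {
  model <- match.arg(model)
  stopifnot(is.numeric(koff1), koff1 > 0, noise_sd >= 0,
            n_timepoints >= 2, dt > 0, n_prebleach >= 1)
  if (a < 0 || a > 1) stop("a must be in [0, 1]")
  if (model == "double") {
    if (!is.finite(koff2) || koff2 <= 0) stop("double model requires koff2 > 0")
    if (koff2 >= koff1) stop("double model requires koff1 > koff2 (fast vs slow)")
  }
  structure(list(model = model, a = a, koff1 = koff1, koff2 = koff2,
                 noise_sd = noise_sd, n_timepoints = as.integer(n_timepoints),
                 dt = dt, n_prebleach = as.integer(n_prebleach),
                 seed = as.integer(seed)),
            class = "frap_sim_spec")
}

#' Evaluate the ground-truth decay model of a spec
#'
#' @param spec A [frap_sim_spec].
#' @param t Time in minutes from the first post-bleach frame.
#' @return `f(t)` of the spec's model, noise-free.
#' @export
frap_model_value <- function(spec, t) {
  if (spec$model == "single") exp(-spec$koff1 * t)
  else spec$a * exp(-spec$koff1 * t) + (1 - spec$a) * exp(-spec$koff2 * t)
}

#' Simulate a normalized iFRAP trace
#'
#' Produces `n_prebleach` frames at value 1 followed by the post-bleach
#' difference signal (unbleached minus bleached, normalized so the first
#' post-bleach frame is 1) of the spec's decay model, with i.i.d. Gaussian
#' noise of sd `noise_sd` added to every frame. The ground-truth spec is
#' attached for parameter-recovery studies.
#'
#' @param spec A [frap_sim_spec].
#' @return A [frap_trace] with attribute `truth = spec`.
#' @examples
#' sp <- frap_sim_spec("single", koff1 = 1/13, noise_sd = 0)
#' tr <- simulate_frap_trace(sp)
#' @export
simulate_frap_trace <- function(spec) {
  stopifnot(inherits(spec, "frap_sim_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  t_pre  <- -rev(seq_len(spec$n_prebleach)) * spec$dt
  t_post <- (seq_len(spec$n_timepoints) - 1L) * spec$dt
  f <- c(rep(1, spec$n_prebleach), frap_model_value(spec, t_post))
  sig <- f + stats::rnorm(length(f), sd = spec$noise_sd)
  tr <- frap_trace(time_min = c(t_pre, t_post), signal = sig,
                   n_prebleach = spec$n_prebleach)
  attr(tr, "truth") <- spec
  tr
}

#' Specification of a toy contact map
#'
#' Describes a synthetic Hi-C-like map: a translation-invariant power-law
#' background `(1 + s)^(-decay_exponent)` over bin separation `s`, plus
#' block-TAD enrichments and planted corner dots (3x3 Gaussian bumps),
#' mirrored below the diagonal. Dots placed at identical coordinates have
#' their amplitudes summed.
#'
#' @param n_bins Matrix dimension.
#' @param bin_size Bin size in bp.
#' @param tad_blocks Data frame with columns `start_bin`, `end_bin`
#'   (1-based, inclusive start, exclusive end) and `intra_weight` (> 0),
#'   or NULL.
#' @param dots Data frame with columns `bin_i`, `bin_j` (`bin_i < bin_j`)
#'   and `amplitude` (> 0), or NULL.
#' @param decay_exponent Background decay exponent (default 1, qualitatively
#'   matching interphase contact-frequency decay over bins).
#' @param seed Integer seed (reserved for noisy variants; the default map is
#'   deterministic).
#' @return A `toy_map_spec` list.
#' @export
toy_map_spec <- function(n_bins, bin_size = 10000L, tad_blocks = NULL,
                         dots = NULL, decay_exponent = 1, seed = 1L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2, bin_size >= 1, decay_exponent >= 0)
  if (!is.null(tad_blocks)) {
    tad_blocks <- as.data.frame(tad_blocks)
    stopifnot(all(c("start_bin", "end_bin", "intra_weight") %in% names(tad_blocks)))
    if (any(tad_blocks$start_bin < 1 | tad_blocks$end_bin > n_bins + 1L |
            tad_blocks$start_bin >= tad_blocks$end_bin))
      stop("tad_blocks must lie within the matrix with start_bin < end_bin")
    if (any(tad_blocks$intra_weight <= 0)) stop("intra_weight must be > 0")
  }
  if (!is.null(dots)) {
    dots <- as.data.frame(dots)
    stopifnot(all(c("bin_i", "bin_j", "amplitude") %in% names(dots)))
    if (any(dots$bin_i >= dots$bin_j)) stop("dots must lie above the diagonal (bin_i < bin_j)")
    if (any(dots$bin_i < 1 | dots$bin_j > n_bins)) stop("dots outside the matrix")
    if (any(dots$amplitude <= 0)) stop("dot amplitudes must be > 0")
  }
  structure(list(n_bins = n_bins, bin_size = as.integer(bin_size),
                 tad_blocks = tad_blocks, dots = dots,
                 decay_exponent = decay_exponent, seed = as.integer(seed)),
            class = "toy_map_spec")
}

#' Build a toy contact map with block TADs and planted dots
#'
#' @param spec A [toy_map_spec].
#' @return A [contact_map] (symmetric, nonnegative).
#' @examples
#' sp <- toy_map_spec(100, tad_blocks = data.frame(
#'   start_bin = c(1, 51), end_bin = c(51, 101), intra_weight = c(2, 2)))
#' m <- make_toy_contact_map(sp)
#' @export
make_toy_contact_map <- function(spec) {
  stopifnot(inherits(spec, "toy_map_spec"))
  n <- spec$n_bins
  idx <- seq_len(n)
  s <- abs(outer(idx, idx, "-"))
  mat <- (1 + s)^(-spec$decay_exponent)
  if (!is.null(spec$tad_blocks)) {
    for (k in seq_len(nrow(spec$tad_blocks))) {
      b <- spec$tad_blocks[k, ]
      rng <- b$start_bin:(b$end_bin - 1L)
      mat[rng, rng] <- mat[rng, rng] + b$intra_weight
    }
  }
  if (!is.null(spec$dots)) {
    # 3x3 Gaussian bump, peak = amplitude
    off <- -1:1
    kern <- exp(-(outer(off^2, off^2, "+")) / 2)
    for (k in seq_len(nrow(spec$dots))) {
      d <- spec$dots[k, ]
      ri <- d$bin_i + off; cj <- d$bin_j + off
      ok_r <- ri >= 1 & ri <= n; ok_c <- cj >= 1 & cj <= n
      bump <- d$amplitude * kern[ok_r, ok_c, drop = FALSE]
      mat[ri[ok_r], cj[ok_c]] <- mat[ri[ok_r], cj[ok_c]] + bump
      mat[cj[ok_c], ri[ok_r]] <- mat[cj[ok_c], ri[ok_r]] + t(bump)
    }
  }
  contact_map(mat, bin_size = spec$bin_size)
}
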