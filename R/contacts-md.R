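#' Parameters of the bead-spring Langevin contact-map mode
#'
#' Controls the small overdamped-Langevin polymer model used as a physical
#' cross-check of the ideal-chain contact approximation. The chain has
#' harmonic backbone bonds (rest length `bond_length`, stiffness
#' `k_backbone`), a soft harmonic excluded-volume repulsion below
#' `ev_sigma`, and harmonic bonds of stiffness `k_bridge` between the
#' bridged monomer pairs of the current snapshot.
#'
#' @param dt Integration step (overdamped units; displacement per unit
#'   force).
#' @param temperature Thermal noise scale; 0 gives pure gradient flow.
#' @param k_backbone,k_bridge Harmonic bond stiffnesses.
#' @param bond_length Backbone rest length (bead diameters).
#' @param ev_epsilon,ev_sigma Excluded-volume strength and range; epsilon 0
#'   disables it.
#' @param capture_radius 3D distance below which a contact is counted
#'   (default 2 bead diameters).
#' @param f_cap Per-bead force cap: force vectors longer than this are
#'   rescaled, so freshly imposed long-range bridge bonds pull at constant
#'   speed instead of destabilizing the integrator.
#' @param steps_per_snapshot Integration steps run under each snapshot's
#'   bridge set.
#' @param sample_every Count contacts every this many steps.
#' @param equilibrate Steps run before the first contact count of each
#'   snapshot block.
#' @param max_step Stability guard: integration aborts if any bead moves
#'   further than this in one step.
#' @return An `md_params` list.
#' @export
md_params <- function(dt = 0.01, temperature = 1, k_backbone = 20,
                      k_bridge = 20, bond_length = 1, ev_epsilon = 2,
                      ev_sigma = 1, capture_radius = 2, f_cap = 20,
                      steps_per_snapshot = 200L, sample_every = 20L,
                      equilibrate = 100L, max_step = 1.5) {
  stopifnot(dt > 0, temperature >= 0, k_backbone > 0, k_bridge >= 0,
            bond_length > 0, ev_epsilon >= 0, ev_sigma > 0,
            capture_radius > 0, f_cap > 0, steps_per_snapshot >= 1,
            sample_every >= 1, max_step > 0)
  structure(list(dt = dt, temperature = temperature,
                 k_backbone = k_backbone, k_bridge = k_bridge,
                 bond_length = bond_length, ev_epsilon = ev_epsilon,
                 ev_sigma = ev_sigma, capture_radius = capture_radius,
                 f_cap = f_cap,
                 steps_per_snapshot = as.integer(steps_per_snapshot),
                 sample_every = as.integer(sample_every),
                 equilibrate = as.integer(equilibrate), max_step = max_step),
            class = "md_params")
}

# Total force on every bead: harmonic backbone + soft excluded volume +
# harmonic bridges. X is n x 3.
.md_forces <- function(X, bridges, p) {
  n <- nrow(X)
  FF <- matrix(0, n, 3)
  # backbone bonds i -- i+1
  d <- X[-1, , drop = FALSE] - X[-n, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  len[len < 1e-12] <- 1e-12
  fmag <- p$k_backbone * (len - p$bond_length) / len
  fb <- d * fmag
  FF[-n, ] <- FF[-n, ] + fb
  FF[-1, ] <- FF[-1, ] - fb
  # soft excluded volume: U = eps * (1 - r / sigma)^2 for r < sigma
  if (p$ev_epsilon > 0) {
    dx <- outer(X[, 1], X[, 1], "-")
    dy <- outer(X[, 2], X[, 2], "-")
    dz <- outer(X[, 3], X[, 3], "-")
    r <- sqrt(dx^2 + dy^2 + dz^2)
    diag(r) <- Inf
    w <- which(r < p$ev_sigma, arr.ind = TRUE)
    if (nrow(w) > 0) {
      rr <- r[w]
      fm <- 2 * p$ev_epsilon * (1 - rr / p$ev_sigma) / (p$ev_sigma * rr)
      FF[, 1] <- FF[, 1] + rowsum_into(dx[w] * fm, w[, 1], n)
      FF[, 2] <- FF[, 2] + rowsum_into(dy[w] * fm, w[, 1], n)
      FF[, 3] <- FF[, 3] + rowsum_into(dz[w] * fm, w[, 1], n)
    }
  }
  # bridge bonds (rest length 0 scale: pull to bond_length)
  if (!is.null(bridges) && nrow(bridges) > 0 && p$k_bridge > 0) {
    for (k in seq_len(nrow(bridges))) {
      i <- bridges[k, 1]; j <- bridges[k, 2]
      d <- X[j, ] - X[i, ]
      len <- sqrt(sum(d^2)); if (len < 1e-12) len <- 1e-12
      f <- p$k_bridge * (len - p$bond_length) * d / len
      FF[i, ] <- FF[i, ] + f
      FF[j, ] <- FF[j, ] - f
    }
  }
  # per-bead force cap: rescale vectors longer than f_cap
  nrm <- sqrt(rowSums(FF^2))
  over <- nrm > p$f_cap
  if (any(over)) FF[over, ] <- FF[over, , drop = FALSE] * (p$f_cap / nrm[over])
  FF
}

# sum values into bins 1..n (positive direction only; pair (i,j) appears in
# both orientations of the which() output, so each bead accumulates its own
# half)
rowsum_into <- function(v, idx, n) {
  out <- numeric(n)
  t <- tapply(v, idx, sum)
  out[as.integer(names(t))] <- t
  out
}

#' Contact map from a trajectory via a bead-spring Langevin polymer
#'
#' Integrates an overdamped Langevin bead-spring chain (one bead per
#' monomer) under each snapshot's bridge set and counts 3D contacts below
#' the capture radius, aggregated over snapshots. Intended for small systems
#' (<= 2000 beads) as a physical cross-check of [contact_map_gaussian()].
#'
#' @param trajectory An `extrusion_trajectory`.
#' @param params An [md_params].
#' @param bin_monomers Monomers per map bin.
#' @param snapshots Indices of snapshot rows to use (default: all).
#' @param seed Integer seed for the thermal noise.
#' @return A raw [contact_map].
#' @export
contact_map_md <- function(trajectory, params = md_params(),
                           bin_monomers = 5L, snapshots = NULL, seed = 1L) {
  stopifnot(inherits(trajectory, "extrusion_trajectory"),
            inherits(params, "md_params"))
  n <- trajectory$params$n_monomers
  if (n > 2000L) stop("md mode is restricted to <= 2000 beads")
  nb <- n %/% bin_monomers
  if (nb < 2L) stop("fewer than 2 bins; decrease bin_monomers")
  if (is.null(snapshots)) snapshots <- seq_len(nrow(trajectory$left))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  # initial conformation: compact random walk
  X <- apply(matrix(stats::rnorm(3 * n, sd = params$bond_length / sqrt(3)),
                    n, 3), 2, cumsum)
  acc <- matrix(0, nb, nb)
  noise_sd <- sqrt(2 * params$temperature * params$dt)
  bead_bin <- pmin((seq_len(n) - 1L) %/% bin_monomers + 1L, nb)
  for (si in snapshots) {
    bridges <- loops_from_snapshot(trajectory, si)
    for (s in seq_len(params$steps_per_snapshot)) {
      FF <- .md_forces(X, bridges, params)
      dX <- params$dt * FF
      if (noise_sd > 0) dX <- dX + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
      if (any(!is.finite(dX)) || max(abs(dX)) > params$max_step)
        stop(sprintf(
          "unstable integration at snapshot %d step %d (max displacement %.3g > %.3g); reduce dt",
          si, s, suppressWarnings(max(abs(dX))), params$max_step))
      X <- X + dX
      if (s > params$equilibrate && s %% params$sample_every == 0L) {
        D <- as.matrix(stats::dist(X))
        hit <- which(D < params$capture_radius & upper.tri(D), arr.ind = TRUE)
        if (nrow(hit) > 0) {
          bi <- bead_bin[hit[, 1]]; bj <- bead_bin[hit[, 2]]
          for (k in seq_along(bi)) {
            acc[bi[k], bj[k]] <- acc[bi[k], bj[k]] + 1
            if (bi[k] != bj[k]) acc[bj[k], bi[k]] <- acc[bj[k], bi[k]] + 1
          }
        }
      }
    }
  }
  contact_map(acc, bin_size = bin_monomers * 1000, normalized = "raw")
}

#' Relax a bead-spring chain by gradient flow (zero temperature)
#'
#' Utility used to study integrator stability: runs the backbone-only chain
#' at zero temperature and tracks the chain toward equal bond lengths. The
#' bond energy (mean squared deviation of bond lengths from the rest
#' length) is the Lyapunov function of the gradient flow and must decrease
#' monotonically for a stable step size; the bond-length variance is
#' reported alongside.
#'
#' @param n Number of beads.
#' @param n_steps Integration steps.
#' @param params An [md_params] (temperature and excluded volume are
#'   ignored; set to 0).
#' @param seed Seed for the initial conformation.
#' @return A data frame with columns `step`, `bond_msd` (mean squared
#'   deviation from the rest length) and `bond_var`.
#' @export
md_relaxation_profile <- function(n, n_steps = 200L, params = md_params(),
                                  seed = 1L) {
  p <- params
  p$temperature <- 0; p$ev_epsilon <- 0
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  X <- apply(matrix(stats::rnorm(3 * n, sd = 2 * p$bond_length), n, 3), 2, cumsum)
  msd <- vvar <- numeric(n_steps)
  none <- matrix(integer(0), 0, 2)
  for (s in seq_len(n_steps)) {
    X <- X + p$dt * .md_forces(X, none, p)
    len <- sqrt(rowSums((X[-1, , drop = FALSE] - X[-n, , drop = FALSE])^2))
    msd[s] <- mean((len - p$bond_length)^2)
    vvar[s] <- stats::var(len)
  }
  data.frame(step = seq_len(n_steps), bond_msd = msd, bond_var = vvar)
}
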