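#' Loop-extrusion simulation parameters
#'
#' Parameters of the discrete-time stochastic extrusion model. One time step
#' moves each free extruder end one monomer outward (1 monomer = 1 kb). Each
#' bound extruder dissociates with per-step probability
#' `p_dissociate / lifetime_multiplier` (wild type 0.0002, i.e. a mean
#' lifetime of 5000 steps) and is instantly reloaded at a random free
#' position, keeping the extruder count constant. A halted end resumes with
#' per-step probability `p_resume` (0.0005 in the chromosome-region model,
#' a halted lifetime of ~2000 steps; 0.0001 in the simplified layout).
#'
#' @param n_monomers Lattice length (2000 for the chr9 region model, 1000
#'   for the simplified layout).
#' @param n_extruders Number of simultaneously bound extruders (default 3).
#' @param p_dissociate Per-step dissociation probability at multiplier 1.
#' @param p_resume Per-step resumption probability for a halted end.
#' @param lifetime_multiplier Scales the mean extruder lifetime: 1 for wild
#'   type, 0.5 for the STAG1-RNAi regime (shorter-lived extruders), 5 for
#'   the STAG2-RNAi regime (longer-lived extruders).
#' @param n_steps Steps per replicate (desk-scale default 50000; the full
#'   study scale is 850000).
#' @param n_replicates Independent replicates aggregated downstream
#'   (desk-scale default 24; full scale 480).
#' @param snapshot_stride Record extruder positions every this many steps.
#' @param orientation_blind If TRUE, CTCF halting ignores motif orientation;
#'   by default an end only halts at motifs pointing toward the loop
#'   interior (convergent blocking).
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_monomers = 1000L, n_extruders = 3L,
                       p_dissociate = 2e-4, p_resume = 1e-4,
                       lifetime_multiplier = 1, n_steps = 50000L,
                       n_replicates = 24L, snapshot_stride = 100L,
                       orientation_blind = FALSE, seed = 1L) {
  p_eff <- p_dissociate / lifetime_multiplier
  stopifnot(n_monomers >= 2, n_extruders >= 1,
            p_dissociate >= 0, p_dissociate <= 1,
            p_resume >= 0, p_resume <= 1,
            lifetime_multiplier > 0,
            p_eff >= 0, p_eff <= 1,
            n_steps >= 1, n_replicates >= 1, snapshot_stride >= 1)
  structure(list(n_monomers = as.integer(n_monomers),
                 n_extruders = as.integer(n_extruders),
                 p_dissociate = p_dissociate, p_resume = p_resume,
                 lifetime_multiplier = lifetime_multiplier,
                 n_steps = as.integer(n_steps),
                 n_replicates = as.integer(n_replicates),
                 snapshot_stride = as.integer(snapshot_stride),
                 orientation_blind = isTRUE(orientation_blind),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Lifetime multiplier for a depletion condition
#'
#' Maps the experimental condition to the extruder-lifetime multiplier used
#' in simulations: depleting STAG2 leaves the long-lived STAG1 form of
#' cohesin (5-fold longer lifetimes); depleting STAG1 leaves the short-lived
#' STAG2 form (2-fold shorter).
#'
#' @param condition One of `"wt"`, `"stag1_rnai"`, `"stag2_rnai"`.
#' @return A numeric multiplier.
#' @export
condition_multiplier <- function(condition = c("wt", "stag1_rnai", "stag2_rnai")) {
  condition <- match.arg(condition)
  c(wt = 1, stag1_rnai = 0.5, stag2_rnai = 5)[[condition]]
}

# Per-monomer halting probabilities seen by each end. A left end extrudes
# leftward with the loop interior to its right, so it is blocked by '+'
# motifs (pointing rightward, toward the interior); a right end by '-'
# motifs. orientation_blind exposes every site to both ends.
.halt_arrays <- function(params, ctcf) {
  stopifnot(inherits(ctcf, "ctcf_track"))
  if (attr(ctcf, "n_monomers") != params$n_monomers)
    stop("ctcf track and params disagree on n_monomers")
  hp_left <- hp_right <- numeric(params$n_monomers)
  if (nrow(ctcf) > 0) {
    if (params$orientation_blind) {
      hp_left[ctcf$position] <- ctcf$halt_prob
      hp_right[ctcf$position] <- ctcf$halt_prob
    } else {
      plus <- ctcf$orientation == "+"
      hp_left[ctcf$position[plus]] <- ctcf$halt_prob[plus]
      hp_right[ctcf$position[!plus]] <- ctcf$halt_prob[!plus]
    }
  }
  list(left = hp_left, right = hp_right)
}
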