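#' Initialize a simulation state
#'
#' Loads `n_extruders` extruders at uniformly random non-overlapping
#' positions, each occupying two adjacent monomers (`left = p`,
#' `right = p + 1`), with no end halted.
#'
#' @param params A [sim_params].
#' @param ctcf A [ctcf_track] on the same lattice.
#' @param seed Integer seed.
#' @return A `sim_state` list with integer vectors `left`, `right`, logical
#'   `lhalt`, `rhalt`, integer `age`, `lhalt_age`, `rhalt_age`, and empty
#'   event records.
#' @export
init_state <- function(params, ctcf, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  .halt_arrays(params, ctcf)  # validates lattice agreement
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  st <- .empty_state(params$n_extruders)
  occ <- logical(params$n_monomers)
  for (e in seq_len(params$n_extruders)) {
    free <- which(!occ[-params$n_monomers] & !occ[-1])
    if (length(free) == 0L)
      stop(sprintf("lattice too crowded: cannot place extruder %d of %d on %d monomers",
                   e, params$n_extruders, params$n_monomers))
    p <- free[sample.int(length(free), 1L)]
    st$left[e] <- p; st$right[e] <- p + 1L
    occ[p] <- occ[p + 1L] <- TRUE
  }
  st
}

.empty_state <- function(n) {
  structure(list(left = integer(n), right = integer(n),
                 lhalt = logical(n), rhalt = logical(n),
                 age = integer(n), lhalt_age = integer(n),
                 rhalt_age = integer(n),
                 lifetimes = numeric(0), halt_durations = numeric(0),
                 counts = c(loads = 0L, dissociations = 0L,
                            halts = 0L, resumes = 0L)),
            class = "sim_state")
}

#' Advance the extrusion state by one time step (reference implementation)
#'
#' One synchronous update in four stages: (1) ages increment and each
#' extruder dissociates with probability
#' `p_dissociate / lifetime_multiplier`, recording its completed lifetime
#' and instantly reloading at a random free position; (2) each halted end
#' resumes with probability `p_resume`, recording the halted-episode
#' duration; (3) each non-halted end attempts to move one monomer outward —
#' moves off the lattice or onto a monomer occupied by another extruder end
#' are blocked (the end stays put, not halted), and a move onto a CTCF site
#' whose motif points toward the loop interior halts the end with that
#' site's halting probability. Halt tests occur only on moves onto a site,
#' so a resumed end steps off its halting site without re-testing it.
#'
#' This pure-R stepper defines the model semantics; [run_extrusion()] runs
#' the same update in compiled code. Conflicting moves are resolved
#' sequentially in extruder index order, left end before right.
#'
#' @param state A `sim_state` from [init_state()].
#' @param params A [sim_params].
#' @param ctcf A [ctcf_track].
#' @return The updated `sim_state`, with completed lifetimes, halted-episode
#'   durations and event counts accumulated in place.
#' @export
extrusion_step <- function(state, params, ctcf) {
  hp <- .halt_arrays(params, ctcf)
  n_mon <- params$n_monomers
  p_diss <- params$p_dissociate / params$lifetime_multiplier
  occ <- logical(n_mon)
  occ[c(state$left, state$right)] <- TRUE

  # stage 1: dissociation + instant reload
  for (e in seq_along(state$left)) {
    state$age[e] <- state$age[e] + 1L
    if (stats::runif(1) < p_diss) {
      state$lifetimes <- c(state$lifetimes, state$age[e])
      state$counts[["dissociations"]] <- state$counts[["dissociations"]] + 1L
      occ[c(state$left[e], state$right[e])] <- FALSE
      free <- which(!occ[-n_mon] & !occ[-1])
      if (length(free) == 0L) stop("no free position to reload an extruder")
      p <- free[sample.int(length(free), 1L)]
      state$left[e] <- p; state$right[e] <- p + 1L
      occ[c(p, p + 1L)] <- TRUE
      state$lhalt[e] <- state$rhalt[e] <- FALSE
      state$age[e] <- 0L
      state$counts[["loads"]] <- state$counts[["loads"]] + 1L
    }
  }

  # stage 2: resumption of halted ends
  for (e in seq_along(state$left)) {
    if (state$lhalt[e]) {
      state$lhalt_age[e] <- state$lhalt_age[e] + 1L
      if (stats::runif(1) < params$p_resume) {
        state$halt_durations <- c(state$halt_durations, state$lhalt_age[e])
        state$lhalt[e] <- FALSE
        state$counts[["resumes"]] <- state$counts[["resumes"]] + 1L
      }
    }
    if (state$rhalt[e]) {
      state$rhalt_age[e] <- state$rhalt_age[e] + 1L
      if (stats::runif(1) < params$p_resume) {
        state$halt_durations <- c(state$halt_durations, state$rhalt_age[e])
        state$rhalt[e] <- FALSE
        state$counts[["resumes"]] <- state$counts[["resumes"]] + 1L
      }
    }
  }

  # stage 3: outward movement with blocking and CTCF halting
  for (e in seq_along(state$left)) {
    if (!state$lhalt[e]) {
      tgt <- state$left[e] - 1L
      if (tgt >= 1L && !occ[tgt]) {
        occ[state$left[e]] <- FALSE; occ[tgt] <- TRUE
        state$left[e] <- tgt
        h <- hp$left[tgt]
        if (h > 0 && stats::runif(1) < h) {
          state$lhalt[e] <- TRUE; state$lhalt_age[e] <- 0L
          state$counts[["halts"]] <- state$counts[["halts"]] + 1L
        }
      }
    }
    if (!state$rhalt[e]) {
      tgt <- state$right[e] + 1L
      if (tgt <= n_mon && !occ[tgt]) {
        occ[state$right[e]] <- FALSE; occ[tgt] <- TRUE
        state$right[e] <- tgt
        h <- hp$right[tgt]
        if (h > 0 && stats::runif(1) < h) {
          state$rhalt[e] <- TRUE; state$rhalt_age[e] <- 0L
          state$counts[["halts"]] <- state$counts[["halts"]] + 1L
        }
      }
    }
  }
  state
}

#' Run a loop-extrusion simulation
#'
#' Iterates the extrusion update for `n_steps` over `n_replicates`
#' independent replicates (replicate `r` is seeded with `seed + r - 1`),
#' recording extruder positions every `snapshot_stride` steps together with
#' all completed lifetimes, halted-episode durations and event counts.
#'
#' @param params A [sim_params].
#' @param ctcf A [ctcf_track].
#' @param engine `"cpp"` (compiled, default) or `"r"` (the reference
#'   stepper; only sensible for tiny runs).
#' @return An `extrusion_trajectory`: list with snapshot matrices `left`,
#'   `right` (rows = snapshots stacked over replicates, columns =
#'   extruders), logical matrices `lhalt`, `rhalt`, integer vectors
#'   `replicate` and `step` per snapshot row, numeric `lifetimes` and
#'   `halt_durations`, a `counts` vector, and the `params`/`ctcf` used.
#' @examples
#' p <- sim_params(n_monomers = 200, n_steps = 500, n_replicates = 2,
#'                 snapshot_stride = 50)
#' tr <- run_extrusion(p, make_ctcf_layout("random", 200, n_sites = 4, seed = 2))
#' @export
run_extrusion <- function(params, ctcf, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "sim_params"))
  hp <- .halt_arrays(params, ctcf)
  n_snap <- params$n_steps %/% params$snapshot_stride
  if (n_snap < 1L) stop("n_steps must be at least snapshot_stride")
  nr <- params$n_replicates
  left <- right <- matrix(0L, n_snap * nr, params$n_extruders)
  lhalt <- rhalt <- matrix(FALSE, n_snap * nr, params$n_extruders)
  lifetimes <- halt_durations <- numeric(0)
  counts <- c(loads = 0L, dissociations = 0L, halts = 0L, resumes = 0L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (r in seq_len(nr)) {
    set.seed(params$seed + r - 1L)
    st <- init_state(params, ctcf, seed = params$seed + r - 1L)
    rows <- (r - 1L) * n_snap + seq_len(n_snap)
    if (engine == "cpp") {
      res <- run_extrusion_cpp(params$n_monomers, params$n_extruders,
                               params$p_dissociate / params$lifetime_multiplier,
                               params$p_resume, params$n_steps,
                               params$snapshot_stride,
                               hp$left, hp$right,
                               st$left, st$right)
      left[rows, ] <- res$left; right[rows, ] <- res$right
      lhalt[rows, ] <- res$lhalt; rhalt[rows, ] <- res$rhalt
      lifetimes <- c(lifetimes, res$lifetimes)
      halt_durations <- c(halt_durations, res$halt_durations)
      counts <- counts + res$counts
    } else {
      for (s in seq_len(params$n_steps)) {
        st <- extrusion_step(st, params, ctcf)
        if (s %% params$snapshot_stride == 0L) {
          i <- rows[s %/% params$snapshot_stride]
          left[i, ] <- st$left; right[i, ] <- st$right
          lhalt[i, ] <- st$lhalt; rhalt[i, ] <- st$rhalt
        }
      }
      lifetimes <- c(lifetimes, st$lifetimes)
      halt_durations <- c(halt_durations, st$halt_durations)
      counts <- counts + st$counts
    }
  }
  structure(list(left = left, right = right, lhalt = lhalt, rhalt = rhalt,
                 replicate = rep(seq_len(nr), each = n_snap),
                 step = rep(seq_len(n_snap) * params$snapshot_stride, nr),
                 lifetimes = lifetimes, halt_durations = halt_durations,
                 counts = counts, params = params, ctcf = ctcf),
            class = "extrusion_trajectory")
}

#' @export
print.extrusion_trajectory <- function(x, ...) {
  cat(sprintf(
    "extrusion trajectory: %d extruders, %d snapshots (%d replicates x %d steps)\n",
    x$params$n_extruders, nrow(x$left), x$params$n_replicates, x$params$n_steps))
  cat(sprintf("  completed lifetimes: %d (mean %.1f); halted episodes: %d (mean %.1f)\n",
              length(x$lifetimes), mean(x$lifetimes),
              length(x$halt_durations), mean(x$halt_durations)))
  invisible(x)
}

#' Summaries of extruder lifetimes and halted-episode durations
#'
#' @param trajectory An `extrusion_trajectory` with at least 30 completed
#'   lifetimes.
#' @return A list with components `lifetime` and `halted`, each holding
#'   `mean`, `sd`, `n`, `se` and a 95% confidence interval `ci` for the
#'   mean (NA when no events of that kind completed).
#' @export
extruder_lifetime_stats <- function(trajectory) {
  stopifnot(inherits(trajectory, "extrusion_trajectory"))
  if (length(trajectory$lifetimes) < 30)
    stop(sprintf("too few completed lifetimes (%d < 30) for stable summaries",
                 length(trajectory$lifetimes)))
  summ <- function(x) {
    if (length(x) == 0)
      return(list(mean = NA_real_, sd = NA_real_, n = 0L, se = NA_real_,
                  ci = c(NA_real_, NA_real_)))
    m <- mean(x); s <- stats::sd(x); n <- length(x); se <- s / sqrt(n)
    list(mean = m, sd = s, n = n, se = se,
         ci = m + c(-1, 1) * stats::qt(0.975, n - 1) * se)
  }
  list(lifetime = summ(trajectory$lifetimes),
       halted = summ(trajectory$halt_durations))
}
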