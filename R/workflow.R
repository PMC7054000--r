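#' Workflow configuration
#'
#' Validated configuration for the wild-type / STAG1-RNAi / STAG2-RNAi
#' comparison workflow. Unknown keys are rejected.
#'
#' @param layout `"simplified_fig6a"` or `"random"` CTCF layout.
#' @param conditions Subset of `c("wt", "stag1_rnai", "stag2_rnai")`.
#' @param n_monomers,n_extruders,p_dissociate,p_resume,n_steps,n_replicates,snapshot_stride
#'   Simulation parameters; see [sim_params()].
#' @param bin_monomers Contact-map bin width, monomers.
#' @param insulation_window Insulation window, bp.
#' @param seed Base seed.
#' @return A `run_config` list.
#' @export
run_config <- function(layout = "simplified_fig6a",
                       conditions = c("wt", "stag1_rnai", "stag2_rnai"),
                       n_monomers = 1000L, n_extruders = 3L,
                       p_dissociate = 2e-4, p_resume = 1e-4,
                       n_steps = 50000L, n_replicates = 24L,
                       snapshot_stride = 100L, bin_monomers = 5L,
                       insulation_window = 15000, seed = 1L) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  cfg <- list(layout = layout, conditions = conditions,
              n_monomers = as.integer(n_monomers),
              n_extruders = as.integer(n_extruders),
              p_dissociate = p_dissociate, p_resume = p_resume,
              n_steps = as.integer(n_steps),
              n_replicates = as.integer(n_replicates),
              snapshot_stride = as.integer(snapshot_stride),
              bin_monomers = as.integer(bin_monomers),
              insulation_window = insulation_window,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a workflow configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the condition-comparison workflow
#'
#' For each condition, simulates extrusion with the condition's lifetime
#' multiplier (see [condition_multiplier()]), aggregates replicate
#' trajectories into a balanced contact map, and computes P(s) curves with
#' characteristic loop-contact scales, insulation profiles and loop-length
#' samples.
#' Writes per-condition contact maps (`.rds` and text dump), P(s) tables and
#' insulation bedGraphs, a pooled loop-length ECDF comparison, and a JSON
#' summary recording seeds, parameters and package version. Outputs are
#' reproducible from (config, seed).
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with per-condition results (`trajectory`
#'   summaries, `map`, `ps`, `loop_scale_bp`, `insulation`) and the summary
#'   path.
#' @export
run_workflow <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  ctcf <- if (config$layout == "simplified_fig6a")
    make_ctcf_layout("simplified_fig6a", config$n_monomers)
  else
    make_ctcf_layout("random", config$n_monomers, seed = config$seed)
  results <- list()
  ecdf_rows <- list()
  summary <- list(package_version = as.character(utils::packageVersion("cohesim")),
                  seed = config$seed, config = unclass(config),
                  conditions = list())
  for (cond in config$conditions) {
    mult <- condition_multiplier(cond)
    say("[%s] simulating %d replicates x %d steps (lifetime multiplier %g, seed %d)",
        cond, config$n_replicates, config$n_steps, mult, config$seed)
    params <- sim_params(n_monomers = config$n_monomers,
                         n_extruders = config$n_extruders,
                         p_dissociate = config$p_dissociate,
                         p_resume = config$p_resume,
                         lifetime_multiplier = mult,
                         n_steps = config$n_steps,
                         n_replicates = config$n_replicates,
                         snapshot_stride = config$snapshot_stride,
                         seed = config$seed)
    traj <- run_extrusion(params, ctcf)
    raw <- contact_map_gaussian(traj, bin_monomers = config$bin_monomers)
    ref <- ps_curve(background_contact_map(config$n_monomers,
                                           config$bin_monomers,
                                           n_snapshots = nrow(traj$left)))
    scale_bp <- loop_contact_scale(ps_curve(raw), ref)$scale_bp
    map <- balance(raw, "coverage")
    ps <- ps_curve(map)
    ins <- insulation(map, window = config$insulation_window)
    lens <- 1000 * as.numeric(traj$right - traj$left)  # bp (1 monomer = 1 kb)
    write_contact_map(map, file.path(out_dir, paste0("map_", cond, ".rds")))
    write_contact_map(map, file.path(out_dir, paste0("map_", cond, ".txt")),
                      format = "txt")
    utils::write.csv(ps, file.path(out_dir, paste0("ps_", cond, ".csv")),
                     row.names = FALSE)
    write_bedgraph(ins, file.path(out_dir, paste0("insulation_", cond, ".bedGraph")))
    ecdf_rows[[cond]] <- data.frame(condition = cond, loop_length_bp = lens)
    results[[cond]] <- list(map = map, ps = ps, loop_scale_bp = scale_bp,
                            insulation = ins,
                            lifetimes = traj$lifetimes,
                            counts = traj$counts)
    summary$conditions[[cond]] <- list(
      lifetime_multiplier = mult,
      n_completed_lifetimes = length(traj$lifetimes),
      mean_lifetime_steps = mean(traj$lifetimes),
      loop_scale_bp = scale_bp,
      median_loop_length_bp = stats::median(lens))
    say("[%s] loop contact scale %g bp; median loop %g bp", cond, scale_bp,
        stats::median(lens))
  }
  ecdf_df <- do.call(rbind, ecdf_rows)
  utils::write.csv(ecdf_df, file.path(out_dir, "loop_lengths.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("workflow complete: %s", out_dir)
  invisible(c(results, list(summary_path = file.path(out_dir, "summary.json"))))
}
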