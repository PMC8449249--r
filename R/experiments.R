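# Scenario orchestration: full coupled simulations, the (Tp, b*, Fr)
# hypothesis sweep, the replicate-stability study, in-silico Hypoxyprobe
# labeling and the heterogeneous-oxygen scenario.

#' Configuration of a coupled tumor scenario
#'
#' @param domain_um square domain side, um (default 3000)
#' @param init_radius_um initial packed-disc tumor radius, um (must be
#'   below half the domain)
#' @param Tp phenotypic persistence time, minutes; \code{Inf} = permanent
#' @param b_star responder migration bias
#' @param Fr responder fraction in [0, 1]
#' @param end_time_hr simulated time, hours
#' @param snapshot_interval_hr interval between stored snapshots, hours
#' @param heterogeneous_sources number of randomly placed oxygen source
#'   voxels replacing the boundary condition; 0 keeps the radial
#'   far-field boundary
#' @param pressure_feedback suppress division and negate the migration
#'   stimulus above the pressure threshold (used with heterogeneous
#'   sources)
#' @param seed integer seed; the run is fully deterministic given it
#' @param params a [phenotype_params()]
#' @param spacing_um oxygen voxel spacing, um
#' @param sigma_bar far-field pO2, mmHg
#' @param uptake_viable per-cell oxygen uptake, 1/min
#' @param uptake_necrotic_frac necrotic uptake fraction of viable
#' @param D,lambda_bg oxygen diffusion coefficient (um^2/min) and
#'   background decay (1/min)
#' @param repulsion,adhesion,adhesion_factor mechanics coefficients
#' @param pressure_threshold dimensionless pressure threshold
#' @param dt_phenotype,dt_mechanics,dt_diffusion time-step hierarchy,
#'   minutes
#' @param max_cells safety cap on the population size
#' @return an object of class \code{scenario_config}
#' @export
scenario_config <- function(domain_um = 3000, init_radius_um = 250,
                            Tp = 3000, b_star = 0.5, Fr = 0.5,
                            end_time_hr = 130, snapshot_interval_hr = 10,
                            heterogeneous_sources = 0,
                            pressure_feedback = FALSE, seed = 1L,
                            params = phenotype_params(Tp = Tp, Fr = Fr,
                                                      b_star = b_star),
                            spacing_um = 20, sigma_bar = 45,
                            uptake_viable = .hypoxfate_defaults$uptake_viable,
                            uptake_necrotic_frac = .hypoxfate_defaults$uptake_necrotic_frac,
                            D = 1e5, lambda_bg = 0.1,
                            repulsion = 10, adhesion = 0.4,
                            adhesion_factor = 1.25,
                            pressure_threshold = 10,
                            dt_phenotype = 6, dt_mechanics = 0.1,
                            dt_diffusion = 1, max_cells = 200000) {
  if (init_radius_um >= domain_um / 2)
    stop("initial tumor radius must be below half the domain")
  structure(as.list(environment()), class = "scenario_config")
}

#' Run one coupled tumor scenario
#'
#' Full simulation of oxygen diffusion, phenotype switching with
#' permanent fate mapping, fluorescence, the Ki67 cycle, necrosis with
#' lysis, adhesion-repulsion mechanics and gradient-biased motility, to
#' the configured end time.  Snapshots (per-cell tables plus the oxygen
#' field) are stored at the configured interval; the run is
#' seed-deterministic.
#'
#' @param config a [scenario_config()]
#' @return an object of class \code{simulation_result}: list of
#'   \code{snapshots} (data frames with an attached \code{sigma_field}),
#'   \code{counts} time series, division/lysis totals, the final field
#'   and the \code{config}
#' @export
run_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  field <- init_field(config$domain_um, config$spacing_um, config$sigma_bar,
                      config$D, config$lambda_bg)
  if (config$heterogeneous_sources > 0)
    field <- place_oxygen_sources(field, config$heterogeneous_sources,
                                  seed = config$seed)
  p <- config$params
  pos <- hex_disc(config$domain_um / 2, config$domain_um / 2,
                  config$init_radius_um, p$cell_radius)
  Tp_min <- if (is.finite(p$Tp)) p$Tp else -1
  par <- list(domain_um = config$domain_um, spacing_um = config$spacing_um,
              sigma_far = config$sigma_bar, D = config$D,
              lambda_bg = config$lambda_bg,
              uptake_viable = config$uptake_viable,
              uptake_necrotic_frac = config$uptake_necrotic_frac,
              sigma_H = p$sigma_H, sigma_T = p$sigma_T, Tp_min = Tp_min,
              Fr = p$Fr, b_star = p$b_star,
              s_dsred = p$preset_dsred$s, b_dsred = p$preset_dsred$b,
              s_gfp = p$preset_gfp_nonresponder$s,
              b_gfp = p$preset_gfp_nonresponder$b,
              tau = p$preset_dsred$tau, cell_radius = p$cell_radius,
              repulsion = config$repulsion, adhesion = config$adhesion,
              adhesion_factor = config$adhesion_factor,
              alpha0 = p$alpha0, beta0 = p$beta0, alpha1 = p$alpha1,
              beta1 = p$beta1, ki67_entry_rate = p$ki67_entry_rate,
              ki67_duration = p$ki67_duration, lysis_time = p$lysis_time,
              pressure_feedback = config$pressure_feedback,
              pressure_threshold = config$pressure_threshold,
              dt_phenotype = config$dt_phenotype,
              dt_mechanics = config$dt_mechanics,
              dt_diffusion = config$dt_diffusion,
              end_time_min = config$end_time_hr * 60,
              snapshot_interval_min = config$snapshot_interval_hr * 60,
              max_cells = as.integer(config$max_cells))
  raw <- run_engine_cpp(pos$x, pos$y, field$sigma, field$dirichlet, par)
  snaps <- lapply(raw$snapshots, function(s) {
    df <- data.frame(time_min = s$time_min, x_um = s$x_um, y_um = s$y_um,
                     state = s$state, switched = s$switched,
                     DsRed = s$DsRed, GFP = s$GFP, Ki67 = s$Ki67,
                     responder = s$responder, reverted = s$reverted,
                     persistence_clock_min = s$persistence_clock_min,
                     sigma_local = s$sigma_local, pressure = s$pressure)
    attr(df, "sigma_field") <- s$sigma_field
    df
  })
  structure(list(snapshots = snaps, counts = raw$counts,
                 total_divisions = raw$total_divisions,
                 total_lysed = raw$total_lysed,
                 sigma_final = raw$sigma_final, config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf(
    "simulation_result: %d snapshots to t = %g min; final %d cells (%d necrotic, %d GFP-switched)\n",
    length(x$snapshots), last$time_min[1], nrow(last),
    sum(last$state == 3), sum(last$switched == 1)))
  invisible(x)
}

#' Final snapshot of a simulation result
#' @param result a \code{simulation_result}
#' @return the last snapshot data frame
#' @export
final_snapshot <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  result$snapshots[[length(result$snapshots)]]
}

#' Render and classify a simulation snapshot
#'
#' @param snapshot a snapshot data frame from [run_scenario()]
#' @param domain_um domain side, um
#' @param thresholds a [morphometric_thresholds()]
#' @param resolution image side in px (default keeps 3 um/px)
#' @param cell_radius cell radius, um
#' @return a \code{morphometric_report}
#' @export
classify_snapshot <- function(snapshot, domain_um,
                              thresholds = morphometric_thresholds(),
                              resolution = round(domain_um / 3),
                              cell_radius = 8.412) {
  img <- render_snapshot(snapshot, domain_um, resolution, cell_radius)
  classify(img, thresholds)
}

#' Sweep the (Tp, b*, Fr) hypothesis space
#'
#' Runs one scenario per grid point and replicate, classifies the final
#' snapshot and tabulates the result.  Replicate seeds are consecutive
#' integers from the base config seed.  Failures of individual runs are
#' recorded per row and the sweep continues.
#'
#' @param Tp_grid,b_star_grid,Fr_grid parameter grids (minutes /
#'   dimensionless / fraction); \code{Inf} allowed in \code{Tp_grid}
#' @param replicates replicates per grid point
#' @param base_config a [scenario_config()] supplying everything else
#' @return data frame of class \code{sweep_result}: one row per grid
#'   point and replicate with the Boolean classification, measured
#'   quantities, tumor radius, necrotic fraction and cell counts
#' @export
sweep <- function(Tp_grid, b_star_grid, Fr_grid, replicates = 1,
                  base_config = scenario_config()) {
  grid <- expand.grid(Tp = Tp_grid, b_star = b_star_grid, Fr = Fr_grid,
                      replicate = seq_len(replicates))
  if (nrow(grid) == 0) stop("empty sweep grid")
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    cfg <- base_config
    cfg$Tp <- g$Tp; cfg$b_star <- g$b_star; cfg$Fr <- g$Fr
    cfg$params <- phenotype_params(Tp = g$Tp, Fr = g$Fr, b_star = g$b_star)
    cfg$seed <- base_config$seed + g$replicate - 1L
    rows[[k]] <- tryCatch({
      res <- run_scenario(cfg)
      snap <- final_snapshot(res)
      rep_ <- classify_snapshot(snap, cfg$domain_um)
      viable <- snap$state != 3
      ctr <- cfg$domain_um / 2
      r <- sqrt((snap$x_um - ctr)^2 + (snap$y_um - ctr)^2)
      data.frame(Tp = g$Tp, b_star = g$b_star, Fr = g$Fr,
                 seed = cfg$seed, plume = rep_$plume, escape = rep_$escape,
                 necrotic_core = rep_$necrotic_core, d_max_px = rep_$d_max,
                 A_px2 = rep_$A, F_N = rep_$F_N,
                 tumor_radius_um = if (any(viable)) max(r[viable]) else 0,
                 n_viable = sum(viable), n_necrotic = sum(!viable),
                 n_switched = sum(snap$switched == 1), error = NA_character_)
    }, error = function(e) {
      data.frame(Tp = g$Tp, b_star = g$b_star, Fr = g$Fr,
                 seed = base_config$seed + g$replicate - 1L,
                 plume = NA, escape = NA, necrotic_core = NA,
                 d_max_px = NA_real_, A_px2 = NA_real_, F_N = NA_real_,
                 tumor_radius_um = NA_real_, n_viable = NA_integer_,
                 n_necrotic = NA_integer_, n_switched = NA_integer_,
                 error = conditionMessage(e))
    })
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Replicate-stability study of the Boolean classification
#'
#' Runs \code{n_replicates} seeded replicates of one scenario and counts
#' how many classify positive for plume, escape and necrotic core at the
#' end time.
#'
#' @param config a [scenario_config()]
#' @param n_replicates number of replicates (>= 1)
#' @return list: \code{counts} (named integer vector plume/escape/
#'   necrotic_core), \code{n}, and the per-replicate \code{table}
#' @export
replicate_stability <- function(config = scenario_config(), n_replicates = 20) {
  if (n_replicates < 1) stop("`n_replicates` must be at least 1")
  tab <- sweep(config$Tp, config$b_star, config$Fr,
               replicates = n_replicates, base_config = config)
  ok <- !is.na(tab$plume)
  list(counts = c(plume = sum(tab$plume[ok]),
                  escape = sum(tab$escape[ok]),
                  necrotic_core = sum(tab$necrotic_core[ok])),
       n = n_replicates, table = tab)
}

#' In-silico Hypoxyprobe labeling of a snapshot
#'
#' Marks viable cells whose local pO2 is below the hypoxia threshold at
#' snapshot time, emulating a pimonidazole stain: currently hypoxic
#' cells are positive; reoxygenated (post-hypoxic, GFP-positive) cells
#' are negative.
#'
#' @param snapshot a snapshot data frame with \code{sigma_local}
#' @param sigma_H hypoxia threshold, mmHg
#' @return logical vector, one element per cell
#' @export
label_hypoxyprobe <- function(snapshot, sigma_H = 10) {
  if (!"sigma_local" %in% names(snapshot))
    stop("snapshot must carry per-cell sigma_local")
  snapshot$state != 3 & snapshot$sigma_local < sigma_H
}

#' Write a snapshot as per-cell CSV
#'
#' @param snapshot a snapshot data frame
#' @param path file path
#' @export
write_snapshot <- function(snapshot, path) {
  utils::write.csv(snapshot, path, row.names = FALSE)
  invisible(path)
}
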