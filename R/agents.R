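# Cell agents: oxygen-dependent phenotype switching with permanent fate
# mapping, the two-ODE DsRed/GFP fluorescence switch, the oxygen-scaled
# Ki67 cycle, necrosis, and adhesion-repulsion mechanics with a pressure
# readout.  These R functions define the per-cell update rules at
# unit-test granularity; run_scenario() executes the same rules in the
# compiled engine.

#' Phenotype and rate parameters of the tumor agents
#'
#' @param sigma_H hypoxia threshold, mmHg: below it a normoxic cell
#'   switches permanently to GFP expression and to the migratory preset
#' @param sigma_T necrosis threshold, mmHg (must be < \code{sigma_H})
#' @param sigma_bar far-field pO2, mmHg (scales the Ki67 entry rate)
#' @param Tp phenotypic persistence time, minutes; \code{Inf} means the
#'   migratory phenotype is kept permanently after reoxygenation
#' @param Fr responder fraction in [0, 1]
#' @param b_star migration bias of GFP responders
#' @param preset_dsred,preset_gfp_nonresponder,preset_gfp_responder
#'   [motility_params()] presets for the three behavioral classes
#' @param alpha0,beta0,alpha1,beta1 protein production/degradation rates
#'   of the fluorescence ODEs, 1/min
#' @param ki67_entry_rate Ki67- to Ki67+ base transition rate at
#'   \code{sigma = sigma_bar}, 1/min.  The default gives a steady Ki67+
#'   fraction of 52.5 percent (the midpoint of the observed 50--55
#'   percent range) together with the default phase duration.
#' @param ki67_duration fixed Ki67+ phase duration ending in division,
#'   minutes (default 930 = 15.5 hr)
#' @param lysis_time time a necrotic cell persists as a mechanical
#'   obstacle before removal, minutes (default 1440 = 24 hr)
#' @param cell_radius cell radius, um
#' @return an object of class \code{phenotype_params}
#' @export
phenotype_params <- function(sigma_H = 10, sigma_T = 5, sigma_bar = 45,
                             Tp = 3000, Fr = 0.5, b_star = 0.5,
                             preset_dsred = motility_params(15, 0.28, 0.1791),
                             preset_gfp_nonresponder = motility_params(15, 0.38, 0.1718),
                             preset_gfp_responder = motility_params(15, 0.38, b_star),
                             alpha0 = 0.002, beta0 = 0.002,
                             alpha1 = 0.002, beta1 = 0.002,
                             ki67_entry_rate = 1 / 838,
                             ki67_duration = 930, lysis_time = 1440,
                             cell_radius = 8.412) {
  if (sigma_T >= sigma_H) stop("`sigma_T` must be below `sigma_H`")
  if (Fr < 0 || Fr > 1) stop("`Fr` must lie in [0, 1]")
  structure(list(sigma_H = sigma_H, sigma_T = sigma_T, sigma_bar = sigma_bar,
                 Tp = Tp, Fr = Fr, b_star = b_star,
                 preset_dsred = preset_dsred,
                 preset_gfp_nonresponder = preset_gfp_nonresponder,
                 preset_gfp_responder = preset_gfp_responder,
                 alpha0 = alpha0, beta0 = beta0, alpha1 = alpha1,
                 beta1 = beta1, ki67_entry_rate = ki67_entry_rate,
                 ki67_duration = ki67_duration, lysis_time = lysis_time,
                 cell_radius = cell_radius),
            class = "phenotype_params")
}

#' A single cell agent
#'
#' @param position numeric 2-vector, um
#' @param params a [phenotype_params()]
#' @return an object of class \code{cell}: a list with position, radius,
#'   phenotype state (\code{"normoxic"}, \code{"hypoxic"},
#'   \code{"post_hypoxic"} or \code{"necrotic"}), gene pair \code{G},
#'   fluorescence \code{DsRed}/\code{GFP}, cycle state and clock,
#'   persistence clock, responder/reverted flags, motility preset,
#'   velocity and pressure
#' @export
new_cell <- function(position = c(0, 0), params = phenotype_params()) {
  structure(list(position = position, radius = params$cell_radius,
                 state = "normoxic", G = c(1L, 0L),
                 DsRed = 1, GFP = 0,
                 cycle_state = "Ki67-", cycle_clock = 0,
                 persistence_clock = 0, responder = FALSE,
                 responder_drawn = FALSE, reverted = FALSE,
                 motility = params$preset_dsred,
                 velocity = c(0, 0), pressure = 0),
            class = "cell")
}

#' One integration step of the fluorescence ODE pair
#'
#' The normalized protein pair obeys
#' \deqn{d[DsRed]/dt = \alpha_0 G_0 (1 - [DsRed]) - \beta_0 [DsRed](1 - G_0)}
#' \deqn{d[GFP]/dt   = \alpha_1 G_1 (1 - [GFP])   - \beta_1 [GFP](1 - G_1)}
#' With binary gene states each equation is linear, so the step uses the
#' exact exponential solution; values are clamped to [0, 1] against
#' round-off only.
#'
#' @param cell a \code{cell}
#' @param dt step, minutes (> 0)
#' @param params a [phenotype_params()]
#' @return the updated \code{cell}
#' @export
update_fluorescence <- function(cell, dt, params = phenotype_params()) {
  if (dt <= 0) stop("`dt` must be positive")
  if (cell$G[2] == 1L) { # G = (0, 1): switched
    cell$DsRed <- cell$DsRed * exp(-params$beta0 * dt)
    cell$GFP <- 1 - (1 - cell$GFP) * exp(-params$alpha1 * dt)
  } else {               # G = (1, 0)
    cell$DsRed <- 1 - (1 - cell$DsRed) * exp(-params$alpha0 * dt)
    cell$GFP <- cell$GFP * exp(-params$beta1 * dt)
  }
  cell$DsRed <- min(1, max(0, cell$DsRed))
  cell$GFP <- min(1, max(0, cell$GFP))
  cell
}

#' Oxygen-dependent phenotype update
#'
#' Below \code{sigma_H} a normoxic cell switches state to hypoxic, sets
#' its gene pair permanently to (0, 1), draws its responder flag once
#' (Bernoulli \code{Fr}) and adopts the GFP responder or non-responder
#' motility preset.  Below \code{sigma_T} the cell becomes necrotic
#' (absorbing; motility zeroed, cycle halted).  A hypoxic cell that finds
#' itself at \code{sigma >= sigma_H} becomes post-hypoxic and accumulates
#' its persistence clock; once the clock reaches \code{Tp} the motility
#' reverts to the DsRed preset.  Re-entering hypoxia resets the clock and
#' restores the hypoxic motility.
#'
#' @param cell a \code{cell} (not necrotic)
#' @param sigma_local local pO2, mmHg
#' @param params a [phenotype_params()]
#' @param dt step, minutes
#' @return the updated \code{cell}
#' @export
update_phenotype <- function(cell, sigma_local, params, dt) {
  if (cell$state == "necrotic") stop("cell is necrotic (absorbing state)")
  if (sigma_local < params$sigma_T) {
    cell$state <- "necrotic"
    cell$G <- c(0L, 1L)
    cell$motility$s <- 0
    cell$cycle_state <- "Ki67-"
    return(cell)
  }
  gfp_preset <- function(cell) {
    if (cell$responder) params$preset_gfp_responder
    else params$preset_gfp_nonresponder
  }
  if (sigma_local < params$sigma_H) {
    if (cell$G[2] == 0L) { # first hypoxic exposure: permanent switch
      cell$G <- c(0L, 1L)
      if (!cell$responder_drawn) {
        cell$responder <- stats::runif(1) < params$Fr
        cell$responder_drawn <- TRUE
      }
    }
    if (cell$state != "hypoxic") {
      cell$state <- "hypoxic"
      cell$persistence_clock <- 0
      cell$reverted <- FALSE
    }
    cell$motility <- gfp_preset(cell)
  } else {
    if (cell$state == "hypoxic") {
      cell$state <- "post_hypoxic"
      cell$persistence_clock <- 0
    } else if (cell$state == "post_hypoxic") {
      cell$persistence_clock <- cell$persistence_clock + dt
    }
    if (cell$state == "post_hypoxic" && is.finite(params$Tp) &&
        cell$persistence_clock >= params$Tp) {
      cell$reverted <- TRUE
    }
    cell$motility <- if (cell$state == "post_hypoxic" && !cell$reverted)
      gfp_preset(cell) else params$preset_dsred
  }
  cell
}

#' Oxygen-scaled Ki67 cycle update
#'
#' A Ki67- cell enters Ki67+ at rate
#' \code{ki67_entry_rate * min(sigma_local / sigma_bar, 1)}; a Ki67+ cell
#' progresses for the fixed phase duration and then divides, the daughter
#' inheriting the gene pair, responder flag, protein concentrations and
#' motility preset, placed one cell radius away in a random direction.
#' Division is suppressed while \code{suppress} is \code{TRUE} (the
#' pressure feedback); the mother then holds at the end of the phase.
#'
#' @param cell a viable \code{cell}
#' @param sigma_local local pO2, mmHg
#' @param params a [phenotype_params()]
#' @param dt step, minutes
#' @param suppress block division this step (default \code{FALSE})
#' @return the updated \code{cell}, or a list \code{list(mother,
#'   daughter)} when a division occurred
#' @export
update_cycle <- function(cell, sigma_local, params, dt, suppress = FALSE) {
  if (cell$state == "necrotic") stop("cell is necrotic")
  if (cell$cycle_state == "Ki67-") {
    rate <- params$ki67_entry_rate * min(max(sigma_local, 0) / params$sigma_bar, 1)
    if (stats::runif(1) < -expm1(-rate * dt)) {
      cell$cycle_state <- "Ki67+"
      cell$cycle_clock <- 0
    }
    return(cell)
  }
  cell$cycle_clock <- cell$cycle_clock + dt
  if (cell$cycle_clock < params$ki67_duration || suppress) return(cell)
  th <- stats::runif(1, 0, 2 * pi)
  daughter <- cell
  daughter$position <- cell$position + cell$radius * c(cos(th), sin(th))
  cell$cycle_state <- "Ki67-"; cell$cycle_clock <- 0
  daughter$cycle_state <- "Ki67-"; daughter$cycle_clock <- 0
  list(mother = cell, daughter = daughter)
}

#' Pairwise adhesion-repulsion mechanics step
#'
#' Quadratic overlap repulsion inside the summed radius and quadratic
#' adhesion inside \code{adhesion_factor} times the summed radius.  The
#' velocity of each cell is the pairwise force term plus its motility
#' term \code{s * direction}; positions advance by forward Euler.  A
#' dimensionless scalar pressure accumulates from repulsive overlaps,
#' normalized so one neighbor at the equilibrium spacing contributes 1.
#'
#' @param cells data frame with columns \code{x}, \code{y}, and
#'   optionally \code{vx_mot}, \code{vy_mot} (motility velocity, um/min)
#' @param dt mechanics step, minutes
#' @param cell_radius cell radius, um
#' @param repulsion,adhesion force coefficients, um/min
#' @param adhesion_factor interaction radius as a multiple of the summed
#'   radius
#' @return the data frame with updated positions and columns \code{vx},
#'   \code{vy} (total velocity) and \code{pressure}
#' @export
update_mechanics <- function(cells, dt = 0.1, cell_radius = 8.412,
                             repulsion = 10, adhesion = 0.4,
                             adhesion_factor = 1.25) {
  n <- nrow(cells)
  vx <- if ("vx_mot" %in% names(cells)) cells$vx_mot else numeric(n)
  vy <- if ("vy_mot" %in% names(cells)) cells$vy_mot else numeric(n)
  pressure <- numeric(n)
  Rsum <- 2 * cell_radius
  r_int <- adhesion_factor * Rsum
  x_eq <- (sqrt(repulsion) - sqrt(adhesion)) /
    (sqrt(repulsion) - sqrt(adhesion) / adhesion_factor)
  p_norm <- (1 - x_eq)^2
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dx <- cells$x[j] - cells$x[i]; dy <- cells$y[j] - cells$y[i]
      d <- sqrt(dx^2 + dy^2)
      if (d >= r_int || d < 1e-12) next
      ex <- dx / d; ey <- dy / d
      f <- 0
      if (d < Rsum) {
        o <- 1 - d / Rsum
        f <- f - repulsion * o^2
        pr <- o^2 / p_norm
        pressure[i] <- pressure[i] + pr
        pressure[j] <- pressure[j] + pr
      }
      f <- f + adhesion * (1 - d / r_int)^2
      vx[i] <- vx[i] + f * ex; vy[i] <- vy[i] + f * ey
      vx[j] <- vx[j] - f * ex; vy[j] <- vy[j] - f * ey
    }
  }
  cells$x <- cells$x + vx * dt
  cells$y <- cells$y + vy * dt
  cells$vx <- vx; cells$vy <- vy
  cells$pressure <- pressure
  cells
}

#' Pressure feedback on proliferation and migration direction
#'
#' Above the pressure threshold, division is suppressed for the step and
#' the migration bias direction is negated (stimulus away from the dense
#' region).  Used in heterogeneous-oxygen scenarios; no effect at or
#' below the threshold.
#'
#' @param cell a \code{cell} with its \code{pressure} computed this step
#' @param threshold dimensionless pressure threshold (default 10)
#' @return the \code{cell} with logical \code{division_blocked} set and,
#'   when triggered, its motility direction negated
#' @export
apply_pressure_feedback <- function(cell, threshold = 10) {
  if (cell$pressure > threshold) {
    cell$division_blocked <- TRUE
    cell$motility$d <- -cell$motility$d
  } else {
    cell$division_blocked <- FALSE
  }
  cell
}
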