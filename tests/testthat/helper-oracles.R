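# Shared helpers and independent oracles used across the test files.

# Independent fixed-step biased persistent random walk, coded with plain
# per-step Bernoulli turns (no event skipping).  Returns displacement of
# each cell from the origin at `duration`.
oracle_bprw_final_disp <- function(n_cells, s, b, d = c(1, 0), tau = 15,
                                   dt = 0.5, duration = 900) {
  nsteps <- round(duration / dt)
  dirs <- matrix(0, n_cells, 2)
  th <- runif(n_cells, 0, 2 * pi)
  # initial directions via the same biased rule
  v1 <- (1 - b) * cos(th) + b * d[1]
  v2 <- (1 - b) * sin(th) + b * d[2]
  nv <- sqrt(v1^2 + v2^2)
  dirs[, 1] <- v1 / nv; dirs[, 2] <- v2 / nv
  x <- numeric(n_cells); y <- numeric(n_cells)
  p <- dt / tau
  for (k in seq_len(nsteps)) {
    turn <- runif(n_cells) < p
    if (any(turn)) {
      m <- sum(turn)
      th <- runif(m, 0, 2 * pi)
      v1 <- (1 - b) * cos(th) + b * d[1]
      v2 <- (1 - b) * sin(th) + b * d[2]
      nv <- sqrt(v1^2 + v2^2)
      dirs[turn, 1] <- v1 / nv; dirs[turn, 2] <- v2 / nv
    }
    x <- x + s * dt * dirs[, 1]
    y <- y + s * dt * dirs[, 2]
  }
  sqrt(x^2 + y^2)
}

# hand-buildable track cohort
make_cohort <- function(time_min, xs, ys) {
  structure(list(time_min = time_min,
                 x = do.call(rbind, xs), y = do.call(rbind, ys)),
            class = "track_cohort")
}

# a 1D slab oxygen field: Dirichlet on the left/right columns only,
# uniform volumetric uptake lambda added via a fake cell-free field
slab_field <- function(nx = 101, ny = 11, h = 20, sigma_bar = 45,
                       lambda = 0.01, D = 1e5) {
  f <- init_field(nx * h, h, sigma_bar, D = D, lambda_bg = lambda)
  # rebuild mask: keep only left/right Dirichlet columns, shrink rows
  f$sigma <- matrix(sigma_bar, ny, nx)
  dir <- matrix(0L, ny, nx)
  dir[, 1] <- 1L; dir[, nx] <- 1L
  f$dirichlet <- dir
  f
}

# closed-form steady profile of D u'' = lambda u with u = sigma_bar at
# the two Dirichlet voxel centers
slab_closed_form <- function(x, x_left, x_right, sigma_bar, D, lambda) {
  l <- sqrt(D / lambda)
  mid <- (x_left + x_right) / 2
  sigma_bar * cosh((x - mid) / l) / cosh((x_right - mid) / l)
}
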