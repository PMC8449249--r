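# Oxygen microenvironment: a discretized pO2 field sigma on a regular 2D
# mesh with a far-field (Dirichlet) value sigma_bar, linear background
# decay and per-cell uptake, solved by an implicit operator-split scheme.

#' Initialize an oxygen field
#'
#' Creates a uniform pO2 field at the far-field value \code{sigma_bar}
#' on a square domain, with the outer boundary ring marked Dirichlet
#' (pinned to \code{sigma_bar}).
#'
#' @param domain_um side length of the square domain, um
#' @param spacing_um voxel spacing, um; must divide \code{domain_um}
#' @param sigma_bar far-field pO2, mmHg (default 45, the midpoint of the
#'   measured 43--46 mmHg peripheral range)
#' @param D oxygen diffusion coefficient, um^2/min
#' @param lambda_bg background decay rate, 1/min
#' @return an object of class \code{oxygen_field}: list with matrix
#'   \code{sigma} (rows = y, cols = x; voxel centers at
#'   \code{(j - 0.5) * spacing}), integer matrix \code{dirichlet},
#'   and the scalars above
#' @export
init_field <- function(domain_um, spacing_um, sigma_bar = 45,
                       D = 1e5, lambda_bg = 0.1) {
  if (spacing_um <= 0) stop("`spacing_um` must be positive")
  n <- domain_um / spacing_um
  if (abs(n - round(n)) > 1e-9) stop("`spacing_um` must divide `domain_um`")
  n <- as.integer(round(n))
  sigma <- matrix(sigma_bar, n, n)
  dir <- matrix(0L, n, n)
  dir[1, ] <- 1L; dir[n, ] <- 1L; dir[, 1] <- 1L; dir[, n] <- 1L
  structure(list(sigma = sigma, dirichlet = dir, spacing = spacing_um,
                 sigma_bar = sigma_bar, D = D, lambda_bg = lambda_bg),
            class = "oxygen_field")
}

#' @export
print.oxygen_field <- function(x, ...) {
  cat(sprintf("oxygen_field: %dx%d voxels at %g um, sigma in [%.2f, %.2f] mmHg (far-field %g)\n",
              nrow(x$sigma), ncol(x$sigma), x$spacing,
              min(x$sigma), max(x$sigma), x$sigma_bar))
  invisible(x)
}

# total linear uptake map (1/min) from background decay plus cells
.uptake_map <- function(field, cells = NULL, cell_radius = 8.412,
                        uptake_viable = .hypoxfate_defaults$uptake_viable,
                        uptake_necrotic_frac = .hypoxfate_defaults$uptake_necrotic_frac) {
  lam <- matrix(field$lambda_bg, nrow(field$sigma), ncol(field$sigma))
  if (!is.null(cells) && nrow(cells) > 0) {
    h <- field$spacing
    frac <- pi * cell_radius^2 / h^2 # cell cross-section per voxel area
    j <- pmin(ncol(lam), pmax(1L, as.integer(cells$x_um %/% h) + 1L))
    i <- pmin(nrow(lam), pmax(1L, as.integer(cells$y_um %/% h) + 1L))
    u <- ifelse(!is.null(cells$state) & cells$state == "necrotic",
                uptake_viable * uptake_necrotic_frac, uptake_viable) * frac
    for (k in seq_along(i)) lam[i[k], j[k]] <- lam[i[k], j[k]] + u[k]
  }
  lam
}

#' Advance the oxygen field by one implicit diffusion-decay-uptake step
#'
#' One operator-split step: implicit linear reaction (background decay
#' plus per-cell uptake in the voxel containing each cell), then implicit
#' one-dimensional diffusion sweeps along x and y (Thomas solves).  The
#' scheme is unconditionally stable and satisfies the discrete maximum
#' principle; Dirichlet voxels hold \code{sigma_bar} exactly.
#'
#' @param field an \code{oxygen_field}
#' @param cells optional data frame with columns \code{x_um},
#'   \code{y_um} and optionally \code{state} (\code{"necrotic"} cells
#'   consume at a reduced rate)
#' @param dt time step, minutes
#' @param uptake_viable per-cell uptake rate, 1/min
#' @param uptake_necrotic_frac necrotic uptake as a fraction of viable
#' @param cell_radius cell radius, um
#' @return the updated \code{oxygen_field}
#' @export
step_diffusion <- function(field, cells = NULL, dt = 0.01,
                           uptake_viable = .hypoxfate_defaults$uptake_viable,
                           uptake_necrotic_frac = .hypoxfate_defaults$uptake_necrotic_frac,
                           cell_radius = 8.412) {
  stopifnot(inherits(field, "oxygen_field"))
  if (anyNA(field$sigma))
    stop("numerical failure: NaN in oxygen field before stepping")
  lam <- .uptake_map(field, cells, cell_radius, uptake_viable,
                     uptake_necrotic_frac)
  field$sigma <- diffusion_step_cpp(field$sigma, field$dirichlet,
                                    field$sigma_bar, lam, field$D,
                                    field$spacing, dt)
  field
}

#' Solve the oxygen field to steady state
#'
#' Computes the discrete steady state of the reaction-diffusion equation
#' (diffusion balancing background decay and cellular uptake, Dirichlet
#' voxels pinned) by red-black successive over-relaxation, warm-started
#' from the field's current values.
#'
#' @inheritParams step_diffusion
#' @param tol convergence tolerance on the per-sweep maximum change, mmHg
#' @param max_sweeps iteration cap
#' @export
solve_steady <- function(field, cells = NULL, tol = 1e-6,
                         max_sweeps = 20000,
                         uptake_viable = .hypoxfate_defaults$uptake_viable,
                         uptake_necrotic_frac = .hypoxfate_defaults$uptake_necrotic_frac,
                         cell_radius = 8.412) {
  stopifnot(inherits(field, "oxygen_field"))
  lam <- .uptake_map(field, cells, cell_radius, uptake_viable,
                     uptake_necrotic_frac)
  field$sigma <- steady_solve_cpp(field$sigma, field$dirichlet,
                                  field$sigma_bar, lam, field$D,
                                  field$spacing, tol, max_sweeps, 1.9)
  field
}

#' Bilinearly interpolated oxygen gradient at a point
#'
#' Central-difference gradient of the containing voxel, bilinearly
#' interpolated between voxel centers.
#'
#' @param field an \code{oxygen_field}
#' @param position numeric 2-vector (x, y) in um; must lie inside the
#'   domain
#' @return numeric 2-vector, mmHg/um
#' @export
gradient_at <- function(field, position) {
  stopifnot(inherits(field, "oxygen_field"))
  h <- field$spacing
  L <- ncol(field$sigma) * h
  if (any(position < 0) || position[1] > L || position[2] > nrow(field$sigma) * h)
    stop("position outside domain")
  s <- field$sigma
  n <- nrow(s); m <- ncol(s)
  gx <- matrix(0, n, m); gy <- matrix(0, n, m)
  for (j in seq_len(m)) {
    jm <- max(1, j - 1); jp <- min(m, j + 1)
    gx[, j] <- (s[, jp] - s[, jm]) / ((jp - jm) * h)
  }
  for (i in seq_len(n)) {
    im <- max(1, i - 1); ip <- min(n, i + 1)
    gy[i, ] <- (s[ip, ] - s[im, ]) / ((ip - im) * h)
  }
  c(.bilinear_r(gx, position[1], position[2], h),
    .bilinear_r(gy, position[1], position[2], h))
}

.bilinear_r <- function(f, x, y, h) {
  nx <- ncol(f); ny <- nrow(f)
  gx <- x / h - 0.5; gy <- y / h - 0.5
  j0 <- floor(gx); i0 <- floor(gy)
  fx <- gx - j0; fy <- gy - i0
  j0 <- j0 + 1; i0 <- i0 + 1 # 1-based
  if (j0 < 1) { j0 <- 1; fx <- 0 }
  if (i0 < 1) { i0 <- 1; fy <- 0 }
  j1 <- min(j0 + 1, nx); i1 <- min(i0 + 1, ny)
  if (j0 > nx) { j0 <- j1 <- nx; fx <- 0 }
  if (i0 > ny) { i0 <- i1 <- ny; fy <- 0 }
  f[i0, j0] * (1 - fx) * (1 - fy) + f[i0, j1] * fx * (1 - fy) +
    f[i1, j0] * (1 - fx) * fy + f[i1, j1] * fx * fy
}

#' Replace the boundary condition by randomly placed oxygen sources
#'
#' Clears the Dirichlet mask and pins \code{n_sources} randomly chosen
#' voxels to \code{sigma_bar}, emulating a heterogeneous vascular supply.
#'
#' @param field an \code{oxygen_field}
#' @param n_sources number of source voxels (>= 1)
#' @param seed integer seed
#' @param keep_boundary keep the outer Dirichlet ring as well (default
#'   \code{FALSE})
#' @return the modified \code{oxygen_field}
#' @export
place_oxygen_sources <- function(field, n_sources, seed = 1L,
                                 keep_boundary = FALSE) {
  stopifnot(inherits(field, "oxygen_field"))
  if (n_sources < 1) stop("`n_sources` must be at least 1")
  set.seed(seed)
  n <- nrow(field$sigma); m <- ncol(field$sigma)
  dir <- if (keep_boundary) field$dirichlet else matrix(0L, n, m)
  idx <- sample.int(n * m, n_sources)
  dir[idx] <- 1L
  field$dirichlet <- dir
  field$sigma[idx] <- field$sigma_bar
  field
}

#' Write an oxygen field snapshot
#'
#' Either delimited grid text (tab-separated voxel values, one row per
#' grid row; lossless) or a single-channel grey PNG with values scaled
#' by \code{sigma_bar}.
#'
#' @param field an \code{oxygen_field}
#' @param path file path
#' @param format \code{"text"} or \code{"png"}
#' @export
write_field <- function(field, path, format = c("text", "png")) {
  format <- match.arg(format)
  if (format == "text") {
    utils::write.table(field$sigma, path, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  } else {
    scaled <- pmin(1, pmax(0, field$sigma / field$sigma_bar))
    png::writePNG(scaled, path)
  }
  invisible(path)
}

#' Steady oxygen profile across a packed tumor disc
#'
#' Places a packed disc of viable cells of the given radius at the domain
#' center, solves the field to steady state, converts cells below the
#' necrosis threshold to necrotic (reduced uptake), and iterates this
#' fixed point until the viable/necrotic partition stabilizes.  Returns
#' the radial profile and the pO2 at the innermost viable cell layer --
#' the quantity the in-vivo microprobe reads at the perinecrotic edge.
#'
#' @param domain_um domain side, um
#' @param tumor_radius_um packed disc radius, um
#' @param spacing_um voxel spacing, um
#' @param sigma_bar far-field pO2, mmHg
#' @param sigma_T necrosis threshold, mmHg
#' @param cell_radius cell radius, um
#' @param uptake_viable per-cell uptake rate, 1/min
#' @param uptake_necrotic_frac necrotic uptake fraction
#' @return list: \code{field}, \code{cells} (with final states),
#'   \code{profile} (data frame radius_um, sigma),
#'   \code{sigma_interface} (pO2 at the innermost viable layer, mmHg),
#'   \code{necrotic_radius_um}
#' @export
steady_tumor_profile <- function(domain_um = 3000, tumor_radius_um = 250,
                                 spacing_um = 20, sigma_bar = 45,
                                 sigma_T = 5, cell_radius = 8.412,
                                 uptake_viable = .hypoxfate_defaults$uptake_viable,
                                 uptake_necrotic_frac = .hypoxfate_defaults$uptake_necrotic_frac) {
  field <- init_field(domain_um, spacing_um, sigma_bar)
  pos <- hex_disc(domain_um / 2, domain_um / 2, tumor_radius_um, cell_radius)
  cells <- data.frame(x_um = pos$x, y_um = pos$y,
                      state = rep("viable", nrow(pos)),
                      stringsAsFactors = FALSE)
  for (it in 1:50) {
    field <- solve_steady(field, cells, uptake_viable = uptake_viable,
                          uptake_necrotic_frac = uptake_necrotic_frac,
                          cell_radius = cell_radius)
    sl <- vapply(seq_len(nrow(cells)), function(k)
      .bilinear_r(field$sigma, cells$x_um[k], cells$y_um[k], field$spacing),
      numeric(1))
    newly <- cells$state == "viable" & sl < sigma_T
    if (!any(newly)) break
    cells$state[newly] <- "necrotic"
  }
  sl <- vapply(seq_len(nrow(cells)), function(k)
    .bilinear_r(field$sigma, cells$x_um[k], cells$y_um[k], field$spacing),
    numeric(1))
  r <- sqrt((cells$x_um - domain_um / 2)^2 + (cells$y_um - domain_um / 2)^2)
  viable <- cells$state == "viable"
  necrotic_radius <- if (any(!viable)) max(r[!viable]) else 0
  # innermost viable cell layer: viable cells within one cell diameter of
  # the innermost viable radius
  rin <- min(r[viable])
  inner <- viable & r <= rin + 2 * cell_radius
  list(field = field, cells = transform(cells, sigma = sl, r_um = r),
       profile = data.frame(radius_um = r, sigma = sl)[order(r), ],
       sigma_interface = mean(sl[inner]),
       necrotic_radius_um = necrotic_radius)
}

#' Hexagonally packed disc of cell positions
#'
#' Positions on a hexagonal lattice at the adhesion-repulsion equilibrium
#' spacing, inside a disc.
#'
#' @param cx,cy disc center, um
#' @param radius disc radius, um
#' @param cell_radius cell radius, um
#' @param spacing_factor lattice spacing as a multiple of the cell
#'   diameter (default 0.9526, the equilibrium of the default
#'   adhesion-repulsion pair)
#' @return data frame with columns \code{x}, \code{y}
#' @export
hex_disc <- function(cx, cy, radius, cell_radius = 8.412,
                     spacing_factor = 0.9526) {
  a <- 2 * cell_radius * spacing_factor
  ny <- ceiling(radius / (a * sqrt(3) / 2)) + 1
  pts <- list()
  for (row in -ny:ny) {
    yy <- row * a * sqrt(3) / 2
    off <- if (row %% 2 == 0) 0 else a / 2
    nxr <- ceiling(radius / a) + 1
    xs <- (-nxr:nxr) * a + off
    keep <- xs^2 + yy^2 <= radius^2
    if (any(keep)) pts[[length(pts) + 1]] <- cbind(xs[keep] + cx, yy + cy)
  }
  m <- do.call(rbind, pts)
  data.frame(x = m[, 1], y = m[, 2])
}
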