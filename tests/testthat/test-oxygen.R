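test_that("field initialization is uniform with a Dirichlet boundary ring", {
  f <- init_field(3000, 20, 45)
  expect_equal(dim(f$sigma), c(150, 150))
  expect_true(all(f$sigma == 45))
  expect_equal(sum(f$dirichlet), 4 * 150 - 4)
  expect_error(init_field(3000, -5), "positive")
  expect_error(init_field(3000, 17), "divide")
  # zero far-field is stable under stepping with no cells
  f0 <- init_field(1000, 20, 0)
  f0s <- step_diffusion(f0, dt = 0.5)
  expect_true(all(f0s$sigma == 0))
  # gradient of a fresh uniform field vanishes
  expect_equal(gradient_at(f, c(1500, 1500)), c(0, 0))
  expect_equal(gradient_at(f, c(312, 1788)), c(0, 0))
})

test_that("1D steady state matches the closed-form solution within 1 percent", {
  lambda <- 0.01; D <- 1e5; h <- 20; nx <- 101
  f <- slab_field(nx = nx, ny = 11, h = h, sigma_bar = 45,
                  lambda = lambda, D = D)
  f <- solve_steady(f, tol = 1e-9)
  mid <- f$sigma[6, ]
  xc <- (seq_len(nx) - 0.5) * h
  exact <- slab_closed_form(xc, xc[1], xc[nx], 45, D, lambda)
  expect_lt(max(abs(mid - exact) / exact), 0.01)
  # no variation across the slab
  expect_lt(max(apply(f$sigma, 2, stats::sd)), 1e-6)
})

test_that("stepping obeys the discrete maximum principle", {
  set.seed(11)
  for (k in 1:50) {
    n <- sample(8:24, 1)
    f <- init_field(n * 20, 20, sigma_bar = runif(1, 10, 60))
    f$sigma <- matrix(runif(n * n, 0, f$sigma_bar), n, n)
    cells <- data.frame(
      x_um = runif(5, 0, n * 20), y_um = runif(5, 0, n * 20),
      state = sample(c("viable", "necrotic"), 5, replace = TRUE))
    dt <- 10^runif(1, -2, 1)
    g <- step_diffusion(f, cells, dt = dt, uptake_viable = runif(1, 0, 20))
    expect_lte(max(g$sigma), max(max(f$sigma), f$sigma_bar) + 1e-9)
    expect_gte(min(g$sigma), 0)
  }
})

test_that("a cell-free field relaxes monotonically to the far-field value", {
  f <- init_field(1000, 20, 45, lambda_bg = 0) # no sinks at all
  f$sigma <- matrix(5, 50, 50)
  f$sigma[f$dirichlet == 1L] <- 45
  prev <- f$sigma
  for (k in 1:30) {
    f <- step_diffusion(f, dt = 5)
    expect_true(all(f$sigma >= prev - 1e-9))
    prev <- f$sigma
  }
  f <- solve_steady(f)
  expect_lt(max(abs(f$sigma - 45)), 1e-3)
})

test_that("gradients are exact on linear fields and match a finite-difference oracle", {
  f <- init_field(1000, 20, 45)
  n <- nrow(f$sigma)
  xc <- (seq_len(n) - 0.5) * 20
  a <- 0.03
  f$sigma <- matrix(rep(a * xc, each = n), n, n) # sigma = a * x
  for (p in list(c(500, 500), c(130, 700), c(850, 220)))
    expect_equal(gradient_at(f, p), c(a, 0), tolerance = 1e-9)
  expect_error(gradient_at(f, c(-5, 100)), "outside")

  # radial steady field: at voxel centers the gradient must equal an
  # independently coded central-difference stencil, and point outward
  # from the oxygen sink
  f2 <- init_field(1000, 20, 45)
  cells <- expand.grid(x_um = seq(420, 580, 20), y_um = seq(420, 580, 20))
  cells$state <- "viable"
  f2 <- solve_steady(f2, cells)
  s <- f2$sigma
  set.seed(12)
  for (k in 1:20) {
    i <- sample(5:46, 1); j <- sample(5:46, 1) # interior voxel (row, col)
    p <- c((j - 0.5) * 20, (i - 0.5) * 20)
    g <- gradient_at(f2, p)
    oracle <- c((s[i, j + 1] - s[i, j - 1]) / 40,
                (s[i + 1, j] - s[i - 1, j]) / 40)
    expect_equal(g, oracle, tolerance = 1e-9)
    # gradient points away from the central sink (toward higher oxygen)
    away <- p - c(500, 500)
    if (sqrt(sum(away^2)) > 120 && sqrt(sum(g^2)) > 1e-6)
      expect_gt(sum(g * away), 0)
  }
})

test_that("a packed viable disc depresses central oxygen monotonically inward", {
  pr <- steady_tumor_profile(domain_um = 2000, tumor_radius_um = 250)
  cells <- pr$cells
  # binned radial means decrease toward the center
  bins <- cut(cells$r_um, seq(0, 260, 40))
  m <- tapply(cells$sigma, bins, mean)
  m <- m[!is.na(m)]
  expect_true(all(diff(m) > 0))
  expect_lt(min(cells$sigma), 10)
  expect_gt(max(cells$sigma), min(cells$sigma) + 5)
})

test_that("random oxygen sources are seeded reproducibly and shape the field", {
  f <- init_field(1000, 20, 45)
  a <- place_oxygen_sources(f, 5, seed = 7)
  b <- place_oxygen_sources(f, 5, seed = 7)
  expect_identical(a$dirichlet, b$dirichlet)
  expect_error(place_oxygen_sources(f, 0), "at least 1")
  # single center source: steady field decreases radially away from it
  f1 <- init_field(1000, 20, 45)
  f1$dirichlet <- matrix(0L, 50, 50)
  f1$dirichlet[25, 25] <- 1L
  f1$sigma <- matrix(0, 50, 50); f1$sigma[25, 25] <- 45
  f1 <- solve_steady(f1)
  xc <- (seq_len(50) - 0.5) * 20
  center <- xc[25]
  row_vals <- f1$sigma[25, 25:40]
  expect_true(all(diff(row_vals) < 0))
})
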