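pp <- phenotype_params()

test_that("fluorescence integration matches the closed forms to 1e-6 relative error", {
  # G = (1, 0) with DsRed = 1, GFP = 0 is a fixed point
  cell <- new_cell()
  out <- update_fluorescence(cell, dt = 123, pp)
  expect_equal(out$DsRed, 1); expect_equal(out$GFP, 0)

  # switched cell: GFP(t) = 1 - exp(-alpha1 t); at t = 1/alpha1 it is 0.6321
  cell$G <- c(0L, 1L)
  t_target <- 1 / pp$alpha1
  n_steps <- 50
  c2 <- cell
  for (k in seq_len(n_steps)) c2 <- update_fluorescence(c2, t_target / n_steps, pp)
  expect_equal(c2$GFP, 1 - exp(-1), tolerance = 1e-6)
  expect_lt(abs(c2$GFP - 0.6321) / 0.6321, 1e-3)

  # DsRed halves at t = ln 2 / beta0
  t_half <- log(2) / pp$beta0
  c3 <- cell
  for (k in 1:40) c3 <- update_fluorescence(c3, t_half / 40, pp)
  expect_equal(c3$DsRed, 0.5, tolerance = 1e-6)
  expect_error(update_fluorescence(cell, dt = 0), "positive")
})

test_that("hypoxic switching is permanent and thresholded", {
  set.seed(21)
  cell <- new_cell(params = pp)
  # just below sigma_H: switch to hypoxic, G becomes (0, 1)
  c1 <- update_phenotype(cell, pp$sigma_H - 0.1, pp, dt = 6)
  expect_equal(c1$state, "hypoxic")
  expect_equal(c1$G, c(0L, 1L))
  # reoxygenation never restores (1, 0)
  c2 <- c1
  for (k in 1:200) c2 <- update_phenotype(c2, 45, pp, dt = 6)
  expect_equal(c2$G, c(0L, 1L))
  expect_equal(c2$state, "post_hypoxic")
  # at/above sigma_H nothing switches
  c3 <- update_phenotype(cell, pp$sigma_H + 0.1, pp, dt = 6)
  expect_equal(c3$state, "normoxic")
  expect_equal(c3$G, c(1L, 0L))
})

test_that("necrosis is absorbing and zeroes motility", {
  set.seed(22)
  cell <- new_cell(params = pp)
  cn <- update_phenotype(cell, pp$sigma_T - 1, pp, dt = 6)
  expect_equal(cn$state, "necrotic")
  expect_equal(cn$motility$s, 0)
  expect_error(update_phenotype(cn, 45, pp, dt = 6), "necrotic")
  expect_error(update_cycle(cn, 45, pp, dt = 6), "necrotic")
})

test_that("responder flag follows Fr and is drawn once", {
  pp0 <- phenotype_params(Fr = 0)
  set.seed(23)
  for (k in 1:50) {
    c1 <- update_phenotype(new_cell(params = pp0), 5.5, pp0, dt = 6)
    expect_false(c1$responder)
  }
  ppf <- phenotype_params(Fr = 0.5)
  set.seed(24)
  n <- 400
  resp <- vapply(seq_len(n), function(k)
    update_phenotype(new_cell(params = ppf), 5.5, ppf, dt = 6)$responder,
    logical(1))
  ci <- stats::binom.test(sum(resp), n, 0.5)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
  # once drawn, re-exposure does not re-draw
  set.seed(25)
  c1 <- update_phenotype(new_cell(params = ppf), 5.5, ppf, dt = 6)
  flag <- c1$responder
  c1 <- update_phenotype(c1, 45, ppf, dt = 6)
  c1 <- update_phenotype(c1, 5.5, ppf, dt = 6)
  expect_equal(c1$responder, flag)
})

test_that("phenotypic persistence reverts motility after Tp and resets on re-entry", {
  set.seed(26)
  ppt <- phenotype_params(Tp = 60, Fr = 1, b_star = 0.5)
  c1 <- update_phenotype(new_cell(params = ppt), 5, ppt, dt = 6)
  expect_equal(c1$motility$b, 0.5) # responder preset while hypoxic
  # leave hypoxia: keeps migratory preset until the clock reaches Tp
  c1 <- update_phenotype(c1, 45, ppt, dt = 6)
  expect_equal(c1$motility$b, 0.5)
  for (k in 1:10) c1 <- update_phenotype(c1, 45, ppt, dt = 6)
  expect_true(c1$reverted)
  expect_equal(c1$motility$b, ppt$preset_dsred$b)
  expect_equal(c1$motility$s, ppt$preset_dsred$s)
  # re-entering hypoxia restores the migratory phenotype and resets the clock
  c1 <- update_phenotype(c1, 5, ppt, dt = 6)
  expect_false(c1$reverted)
  expect_equal(c1$motility$b, 0.5)
  expect_equal(c1$persistence_clock, 0)

  # Tp = 0: migratory phenotype dropped the same step the cell leaves hypoxia
  pp0 <- phenotype_params(Tp = 0, Fr = 1, b_star = 0.5)
  c2 <- update_phenotype(new_cell(params = pp0), 5, pp0, dt = 6)
  c2 <- update_phenotype(c2, 45, pp0, dt = 6)
  expect_equal(c2$motility$b, pp0$preset_dsred$b)

  # Tp = Inf: never reverts
  ppi <- phenotype_params(Tp = Inf, Fr = 1, b_star = 0.5)
  c3 <- update_phenotype(new_cell(params = ppi), 5, ppi, dt = 6)
  for (k in 1:500) c3 <- update_phenotype(c3, 45, ppi, dt = 6)
  expect_false(c3$reverted)
  expect_equal(c3$motility$b, 0.5)
})

test_that("cycle entry scales with oxygen and divisions inherit state", {
  set.seed(27)
  cell <- new_cell(params = pp)
  # sigma = 0: entry rate 0, no transitions ever
  for (k in 1:200) {
    cell <- update_cycle(cell, 0, pp, dt = 6)
    expect_equal(cell$cycle_state, "Ki67-")
  }
  # division: exactly two viable cells, daughter inherits the gene pair
  set.seed(28)
  mother <- new_cell(params = pp)
  mother$G <- c(0L, 1L); mother$responder <- TRUE; mother$GFP <- 0.7
  mother$cycle_state <- "Ki67+"; mother$cycle_clock <- pp$ki67_duration - 1
  out <- update_cycle(mother, 45, pp, dt = 6)
  expect_named(out, c("mother", "daughter"))
  expect_equal(out$daughter$G, c(0L, 1L))
  expect_true(out$daughter$responder)
  expect_equal(out$daughter$GFP, 0.7)
  expect_equal(out$mother$cycle_state, "Ki67-")
  expect_equal(out$daughter$cycle_state, "Ki67-")
  d <- sqrt(sum((out$daughter$position - out$mother$position)^2))
  expect_equal(d, mother$radius, tolerance = 1e-9)
  # suppression holds the mother at the end of the phase
  held <- update_cycle(mother, 45, pp, dt = 6, suppress = TRUE)
  expect_equal(held$cycle_state, "Ki67+")
})

test_that("pairwise mechanics are symmetric and match a hand-coded oracle", {
  # isolated cell: stationary, zero pressure
  one <- update_mechanics(data.frame(x = 50, y = 50))
  expect_equal(one$x, 50); expect_equal(one$pressure, 0)

  # two overlapping equal cells move apart symmetrically
  two <- update_mechanics(data.frame(x = c(50, 60), y = c(40, 40)))
  expect_equal(two$x[1] - 50, -(two$x[2] - 60), tolerance = 1e-12)
  expect_lt(two$x[1], 50)
  expect_equal(two$y, c(40, 40))
  expect_gt(two$pressure[1], 0)
  expect_equal(two$pressure[1], two$pressure[2])

  # collinear 3-cell configuration against an independent pairwise oracle
  xs <- c(0, 14, 31); R <- 2 * 8.412; rint <- 1.25 * R
  pair_force <- function(d) {
    f <- 0
    if (d < R) f <- f - 10 * (1 - d / R)^2
    if (d < rint) f <- f + 0.4 * (1 - d / rint)^2
    f
  }
  # velocity of cell i along +x: sum over j of f(d_ij) * sign(x_j - x_i)
  v_expect <- vapply(1:3, function(i) {
    sum(vapply(setdiff(1:3, i), function(j) {
      d <- abs(xs[j] - xs[i])
      if (d >= rint) 0 else pair_force(d) * sign(xs[j] - xs[i])
    }, numeric(1)))
  }, numeric(1))
  three <- update_mechanics(data.frame(x = xs, y = c(0, 0, 0)), dt = 0.1)
  expect_equal(three$vx, v_expect, tolerance = 1e-9)
  expect_equal(three$x, xs + v_expect * 0.1, tolerance = 1e-9)
})

test_that("pressure feedback blocks division and negates the bias direction", {
  cell <- new_cell(params = pp)
  cell$motility$d <- c(1, 0)
  cell$pressure <- 0
  out <- apply_pressure_feedback(cell, threshold = 10)
  expect_false(out$division_blocked)
  expect_equal(out$motility$d, c(1, 0))
  cell$pressure <- 10.1
  out2 <- apply_pressure_feedback(cell, threshold = 10)
  expect_true(out2$division_blocked)
  expect_equal(out2$motility$d, c(-1, 0))
})
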