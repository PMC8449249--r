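# rotate a labeled image by 90 degrees (exact on the pixel grid)
rot90_image <- function(img) {
  r90 <- function(m) t(m)[, nrow(m):1]
  labeled_image(r90(img$red), r90(img$green), r90(img$necrotic),
                px_scale = img$px_scale)
}

test_that("a plain red disc classifies negative on all three tests", {
  img <- generate_fixture_image(resolution = 600, tumor_axes = c(150, 150))
  expect_equal(sum(img$green), 0)
  expect_equal(sum(img$necrotic), 0)
  rep <- classify(img)
  expect_false(rep$plume); expect_false(rep$escape); expect_false(rep$necrotic_core)
  expect_equal(rep$d_max, 0)
  expect_equal(rep$A, 0)
  expect_equal(rep$F_N, 0)
})

test_that("a green annulus is no plume; a radial finger is", {
  ann <- generate_fixture_image(resolution = 600, tumor_axes = c(160, 160),
                                annulus = c(90, 140))
  p <- detect_plumes(ann)
  expect_false(p$plume)
  expect_lt(p$d_max, 30)

  fing <- generate_fixture_image(resolution = 600, tumor_axes = c(160, 160),
                                 annulus = c(90, 140),
                                 fingers = list(count = 1, length_px = 150,
                                                width_px = 24))
  pf <- detect_plumes(fing)
  expect_true(pf$plume)
  expect_gt(pf$d_max, 60)
})

test_that("empty green channel yields (FALSE, 0)", {
  img <- generate_fixture_image(resolution = 300, tumor_axes = c(80, 80))
  expect_equal(detect_plumes(img), list(plume = FALSE, d_max = 0, ellipse = NULL))
})

test_that("escape follows the summed outside-green area against eps_S", {
  base <- list(resolution = 600, tumor_axes = c(120, 120))
  inside <- generate_fixture_image(resolution = 600, tumor_axes = c(120, 120),
                                   annulus = c(60, 100))
  e0 <- detect_escape(inside)
  expect_false(e0$escape); expect_equal(e0$A, 0)

  big <- generate_fixture_image(resolution = 600, tumor_axes = c(120, 120),
                                blobs = 25)
  eb <- detect_escape(big)
  expect_true(eb$escape)
  expect_gt(eb$A, 20); expect_lt(eb$A, 40)

  small <- generate_fixture_image(resolution = 600, tumor_axes = c(120, 120),
                                  blobs = 10)
  es <- detect_escape(small)
  expect_false(es$escape)
  expect_lte(es$A, 20)

  empty <- labeled_image(matrix(FALSE, 50, 50), matrix(FALSE, 50, 50),
                         matrix(FALSE, 50, 50))
  expect_error(detect_escape(empty), "empty tumor")
})

test_that("necrotic core uses a strict area-fraction inequality", {
  m <- function(n_necro) {
    red <- matrix(FALSE, 100, 100); red[1:100, 1:94] <- TRUE
    necro <- matrix(FALSE, 100, 100)
    if (n_necro > 0) necro[seq_len(n_necro)] <- TRUE
    red[necro] <- FALSE
    total <- sum(red) + sum(necro)
    list(img = labeled_image(red, matrix(FALSE, 100, 100), necro),
         F_N = sum(necro) / total)
  }
  z <- m(0)
  expect_false(detect_necrotic_core(z$img)$necrotic_core)
  # exactly at the threshold: fraction 564/9400 = 0.06, strict rule says no
  at <- m(564)
  expect_equal(at$F_N, 0.06)
  expect_false(detect_necrotic_core(at$img)$necrotic_core)
  above <- m(658) # 0.07
  expect_equal(above$F_N, 0.07)
  expect_true(detect_necrotic_core(above$img)$necrotic_core)
})

test_that("a requested necrotic fraction is realized within a pixel quantum", {
  img <- generate_fixture_image(resolution = 600, tumor_axes = c(150, 150),
                                necrotic_fraction = 0.07)
  measured <- detect_necrotic_core(img)$F_N
  expect_lt(abs(measured - 0.07), 0.005)
  expect_true(detect_necrotic_core(img)$necrotic_core)
})

test_that("the composite classifier is deterministic and detects all three features", {
  img <- generate_fixture_image(resolution = 600, tumor_axes = c(160, 160),
                                annulus = c(90, 140),
                                fingers = list(count = 1, length_px = 150,
                                               width_px = 24),
                                blobs = 25, necrotic_fraction = 0.10)
  r1 <- classify(img)
  expect_true(r1$plume); expect_true(r1$escape); expect_true(r1$necrotic_core)
  r2 <- classify(img)
  expect_identical(r1[c("plume", "escape", "necrotic_core", "d_max", "A", "F_N")],
                   r2[c("plume", "escape", "necrotic_core", "d_max", "A", "F_N")])
})

test_that("classification is invariant under 90-degree rotation", {
  fixtures <- list(
    generate_fixture_image(resolution = 600, tumor_axes = c(160, 160),
                           annulus = c(90, 140)),
    generate_fixture_image(resolution = 600, tumor_axes = c(160, 160),
                           annulus = c(90, 140),
                           fingers = list(count = 1, length_px = 150,
                                          width_px = 24)),
    generate_fixture_image(resolution = 600, tumor_axes = c(120, 120),
                           blobs = 25, necrotic_fraction = 0.08))
  for (img in fixtures) {
    a <- classify(img)
    b <- classify(rot90_image(img))
    expect_equal(a$plume, b$plume)
    expect_equal(a$escape, b$escape)
    expect_equal(a$necrotic_core, b$necrotic_core)
  }
})

test_that("raising thresholds never turns a negative into a positive", {
  img <- generate_fixture_image(resolution = 600, tumor_axes = c(160, 160),
                                annulus = c(90, 140),
                                fingers = list(count = 1, length_px = 150,
                                               width_px = 24),
                                blobs = 25, necrotic_fraction = 0.10)
  strict <- classify(img, morphometric_thresholds(eps_P = 500, eps_S = 1e6,
                                                  eps_N = 0.5))
  expect_false(strict$plume); expect_false(strict$escape)
  expect_false(strict$necrotic_core)
})

test_that("rendering draws discs with correct area bookkeeping", {
  empty <- render_snapshot(data.frame(x_um = numeric(0), y_um = numeric(0),
                                      state = integer(0), switched = integer(0)),
                           domain_um = 600, resolution = 200)
  expect_equal(sum(empty$red) + sum(empty$green) + sum(empty$necrotic), 0)

  one <- render_snapshot(data.frame(x_um = 300, y_um = 300, state = 0,
                                    switched = 0),
                         domain_um = 600, resolution = 200)
  expect_gt(sum(one$red), 0)
  expect_equal(sum(one$green), 0)
  ctr <- which(one$red, arr.ind = TRUE)
  expect_equal(mean(ctr[, 1]), 100.5, tolerance = 1)
  expect_equal(mean(ctr[, 2]), 100.5, tolerance = 1)

  # n non-overlapping green cells cover ~ n * pi * (r / px)^2 pixels
  xs <- seq(100, 500, by = 100)
  grid <- expand.grid(x_um = xs, y_um = xs)
  cells <- data.frame(x_um = grid$x_um, y_um = grid$y_um, state = 0, switched = 1)
  img <- render_snapshot(cells, domain_um = 600, resolution = 600)
  expected <- nrow(cells) * pi * 8.412^2 # at 1 um/px
  expect_lt(abs(sum(img$green) - expected) / expected, 0.1)
  expect_error(render_snapshot(cells, 600, resolution = 50), "at least 100")
})

test_that("labeled images round-trip through PNG", {
  img <- generate_fixture_image(resolution = 300, tumor_axes = c(80, 80),
                                annulus = c(40, 70), necrotic_fraction = 0.05)
  path <- tempfile(fileext = ".png")
  write_labeled_image(img, path)
  back <- read_labeled_image(path, px_scale = img$px_scale)
  expect_identical(back$red, img$red)
  expect_identical(back$green, img$green)
  expect_identical(back$necrotic, img$necrotic)
  unlink(path)
})

test_that("congruence of channel masks is enforced", {
  expect_error(labeled_image(matrix(FALSE, 10, 10), matrix(FALSE, 5, 5),
                             matrix(FALSE, 10, 10)), "congruent")
})
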