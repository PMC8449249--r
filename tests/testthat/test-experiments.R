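# Short coupled runs on a reduced domain keep these tests fast; the
# acceptance suite exercises the full study conditions.
tiny_config <- function(...) {
  args <- list(domain_um = 1000, init_radius_um = 150, end_time_hr = 4,
               snapshot_interval_hr = 2, seed = 5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}

test_that("scenarios are seed-deterministic", {
  a <- run_scenario(tiny_config())
  b <- run_scenario(tiny_config())
  expect_identical(final_snapshot(a)$x_um, final_snapshot(b)$x_um)
  expect_identical(a$counts, b$counts)
  c_ <- run_scenario(tiny_config(seed = 6))
  expect_false(identical(final_snapshot(a)$x_um, final_snapshot(c_)$x_um))
})

test_that("cell counts change only through division and lysis", {
  res <- run_scenario(tiny_config(end_time_hr = 8))
  ct <- res$counts
  n <- ct$n_viable + ct$n_necrotic
  n0 <- nrow(hex_disc(500, 500, 150))
  expect_equal(n, n0 + cumsum(ct$divisions) - cumsum(ct$lysed))
  expect_equal(res$total_divisions, sum(ct$divisions))
})

test_that("fate switching is irreversible and necrosis absorbing at population level", {
  res <- run_scenario(tiny_config(end_time_hr = 10, uptake_viable = 12))
  ct <- res$counts
  expect_true(all(diff(ct$n_switched) >= 0))
  # cumulative necrotic count (current + lysed) never decreases
  cum_necro <- ct$n_necrotic + cumsum(ct$lysed)
  expect_true(all(diff(cum_necro) >= 0))
  snap <- final_snapshot(res)
  # DsRed decays and GFP rises in switched cells only
  sw <- snap$switched == 1
  if (any(sw)) expect_true(all(snap$GFP[sw] >= 0 & snap$DsRed[sw] <= 1))
  expect_true(all(snap$DsRed[!sw] > 0.99))
})

test_that("responder flags appear at the configured fraction among switched cells", {
  res <- run_scenario(tiny_config(end_time_hr = 12, Fr = 0.5,
                                  uptake_viable = 12))
  snap <- final_snapshot(res)
  sw <- snap$switched == 1
  expect_gt(sum(sw), 50)
  ci <- stats::binom.test(sum(snap$responder[sw]), sum(sw), 0.5)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
  res0 <- run_scenario(tiny_config(end_time_hr = 8, Fr = 0,
                                   uptake_viable = 12))
  expect_equal(sum(final_snapshot(res0)$responder), 0)
})

test_that("a 1x1x1 sweep gives a single deterministic row", {
  cfg <- tiny_config(end_time_hr = 2)
  tab <- sweep(3000, 0.5, 1, replicates = 1, base_config = cfg)
  expect_equal(nrow(tab), 1)
  expect_true(is.na(tab$error))
  tab2 <- sweep(3000, 0.5, 1, replicates = 1, base_config = cfg)
  expect_equal(tab$n_viable, tab2$n_viable)
  expect_error(sweep(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("replicate_stability counts positives over seeded replicates", {
  cfg <- tiny_config(end_time_hr = 2)
  st <- replicate_stability(cfg, n_replicates = 2)
  expect_equal(st$n, 2)
  expect_named(st$counts, c("plume", "escape", "necrotic_core"))
  expect_equal(nrow(st$table), 2)
  expect_equal(st$table$seed, c(cfg$seed, cfg$seed + 1L))
  expect_error(replicate_stability(cfg, 0), "at least 1")
})

test_that("Hypoxyprobe labeling marks exactly the currently hypoxic viable cells", {
  snap <- data.frame(state = c(0, 1, 2, 3, 0),
                     switched = c(0, 1, 1, 1, 0),
                     sigma_local = c(45, 8, 20, 2, 9.5))
  hp <- label_hypoxyprobe(snap, sigma_H = 10)
  # normoxic well-oxygenated: negative; currently hypoxic GFP+: positive;
  # reoxygenated GFP+ (plume): negative; necrotic: negative
  expect_equal(hp, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_error(label_hypoxyprobe(data.frame(state = 1)), "sigma_local")
})

test_that("snapshots carry the local oxygen seen by each cell", {
  res <- run_scenario(tiny_config(end_time_hr = 2))
  snap <- final_snapshot(res)
  expect_true(all(snap$sigma_local <= 45 + 1e-9))
  expect_true(all(snap$sigma_local >= 0))
  # interior cells see less oxygen than the domain far field
  expect_lt(min(snap$sigma_local), 45)
  path <- tempfile(fileext = ".csv")
  write_snapshot(snap, path)
  expect_true(file.exists(path))
  expect_match(readLines(path, n = 1), "sigma_local")
  unlink(path)
})

test_that("heterogeneous sources with pressure feedback run and stay physical", {
  cfg <- tiny_config(end_time_hr = 4, heterogeneous_sources = 6,
                     pressure_feedback = TRUE)
  res <- run_scenario(cfg)
  snap <- final_snapshot(res)
  expect_true(all(is.finite(snap$x_um)))
  expect_true(all(snap$x_um >= 0 & snap$x_um <= 1000))
  # replicate determinism under the heterogeneous boundary condition
  res2 <- run_scenario(cfg)
  expect_identical(final_snapshot(res2)$x_um, snap$x_um)
})
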