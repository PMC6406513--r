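g <- make_grid(41)

test_that("population integrals are additive over complementary masks", {
  expect_equal(population(matrix(2.5, 41, 41), g), 2.5)
  set.seed(5)
  w <- matrix(runif(41 * 41), 41, 41)
  mask <- matrix(runif(41 * 41) > 0.5, 41, 41)
  expect_equal(population(w, g, mask) + population(w, g, !mask),
               population(w, g))
})

test_that("tumor volume follows the equivalent-diameter sphere formula", {
  f0 <- list(x = matrix(0, 41, 41), y = matrix(0, 41, 41))
  expect_identical(tumor_volume(f0, g, L = 10), 0)

  rho <- 0.2
  f <- list(x = make_initial_tumor(g, radius = rho, peak = 0.5, taper = 1e-9),
            y = matrix(0, 41, 41))
  V <- tumor_volume(f, g, L = 10, threshold_fraction = 0.1)
  V_exact <- (4 * pi / 3) * (10 * rho)^3
  # support area quantizes to whole cells: allow one-cell-ring slack
  slack <- (4 * pi / 3) * ((10 * (rho + g$hx))^3 - (10 * rho)^3)
  expect_lt(abs(V - V_exact), slack)
  # threshold above the plateau empties the support
  expect_identical(tumor_volume(f, g, L = 10, threshold_fraction = 0.9), 0)
  # monotone non-increasing in the threshold
  ths <- c(0.05, 0.1, 0.2, 0.4, 0.6)
  Vs <- vapply(ths, function(t) tumor_volume(f, g, 10, t), numeric(1))
  expect_true(all(diff(Vs) <= 0))
})

test_that("adherent population is an inside-facing shell integral", {
  spec <- cspg_ring_spec()
  expect_identical(adherent_population(matrix(1, 41, 41), g, NULL), 0)
  w <- matrix(1, 41, 41)
  shell2 <- adherent_population(w, g, spec, width = 2)
  expect_gt(shell2, 0)
  # saturating the width recovers everything enclosed by the barrier
  X <- outer(g$x, rep(1, 41)); Y <- outer(rep(1, 41), g$y)
  enclosed <- sqrt((X - 0.5)^2 + (Y - 0.5)^2) < spec$r_inner
  wide <- adherent_population(w, g, spec, width = 1000)
  expect_equal(wide, population(w, g, enclosed), tolerance = 1e-12)
  expect_gt(wide, shell2)
})

test_that("intracellular maps compose the lookup with the classifier", {
  tab <- fixture_qss_table()
  th <- classifier_thresholds()
  Bf <- matrix(c(0, 0, 1, 1), 2, 2)
  vf <- matrix(c(0, 0, 0, 1), 2, 2)
  maps <- intracellular_maps(Bf, vf, tab, th)
  expect_identical(maps$region[1, 1], "ANTI_APOPTOTIC")
  expect_identical(maps$region[1, 2], "APOPTOTIC")
  expect_identical(maps$region[2, 2], "NECROPTOTIC")
  # label agrees cell-by-cell with classify(lookup(B, v))
  lab <- classify_state(maps$F, maps$A, maps$R, th)
  expect_identical(as.character(lab), as.character(maps$region))
  # averaging a uniform map returns the cell value
  u <- intracellular_maps(matrix(0.3, 3, 3), matrix(0, 3, 3), tab, th)
  expect_equal(unname(u$means["F"]), u$F[1, 1])
})

test_that("snapshot metrics are internally consistent", {
  tab <- fixture_qss_table()
  r <- fixture_run("combo-nx31", preset("fig6-combo", nx = 31,
                                        t_end_day = 2))
  m <- r$metrics
  expect_equal(m$alive, m$uninfected + m$infected, tolerance = 1e-12)
  q <- m$x_Q1 + m$x_Q2 + m$x_Q3 + m$x_Q4
  expect_equal(q, m$uninfected, tolerance = 1e-8)
  expect_equal(m$x_omega_plus + m$x_omega_minus, m$uninfected,
               tolerance = 1e-8)
})

test_that("result containers round-trip losslessly and fail loudly", {
  tab <- fixture_qss_table()
  scn <- scenario("OV", nx = 21, t_end_day = 0.5,
                  snapshot_days = c(0, 0.5))
  r <- run_scenario(scn, table = tab)
  dir <- file.path(tempdir(), "btzov-container-test")
  unlink(dir, recursive = TRUE)
  write_results(r, dir)
  back <- read_results(dir)
  expect_equal(back$metrics$alive, r$metrics$alive, tolerance = 1e-12)
  for (i in seq_along(r$snapshots))
    for (nm in names(r$snapshots[[i]]))
      expect_equal(back$snapshots[[i]][[nm]], r$snapshots[[i]][[nm]],
                   tolerance = 1e-12)
  expect_error(write_results(r, dir), "already exists")

  # truncation and version mismatch are explicit errors
  unlink(file.path(dir, "fields", "snap002_v.csv"))
  expect_error(read_results(dir), "truncated")
  man <- file.path(dir, "manifest.json")
  txt <- sub('"version": 1', '"version": 99', readLines(man))
  writeLines(txt, man)
  expect_error(read_results(dir), "format/version")
  unlink(dir, recursive = TRUE)
})

test_that("identical configurations reproduce identical metrics", {
  tab <- fixture_qss_table()
  scn <- scenario("OV+BTZ", nx = 21, t_end_day = 0.5,
                  snapshot_days = c(0, 0.5))
  r1 <- run_scenario(scn, table = tab)
  r2 <- run_scenario(scn, table = tab)
  expect_identical(r1$metrics, r2$metrics)
})
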