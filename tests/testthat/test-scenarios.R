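g41 <- make_grid(41)

test_that("the initial tumor profile has the right mass and superposes", {
  expect_identical(make_initial_tumor(g41, peak = 0),
                   matrix(0, 41, 41))
  g <- make_grid(101)
  w <- make_initial_tumor(g, center = c(0.5, 0.5), radius = 0.1,
                          peak = 0.5, taper = 0.02)
  mass <- population(w, g)
  # radial quadrature of the stated profile: plateau + cosine-taper ring
  ring <- integrate(function(s)
    2 * pi * s * 0.5 * (1 + cos(pi * (s - 0.1) / 0.02)), 0.1, 0.12,
    rel.tol = 1e-10)$value
  exact <- 0.5 * (pi * 0.1^2 + ring)
  expect_lt(abs(mass - exact) / exact, 0.05)
  w1 <- make_initial_tumor(g41, center = c(0.7, 0.7), radius = 0.08)
  w2 <- make_initial_tumor(g41, center = c(0.25, 0.25), radius = 0.06,
                           peak = 0.3)
  expect_equal(population(w1 + w2, g41), population(w1, g41) +
                 population(w2, g41))
  expect_error(make_initial_tumor(g41, center = c(0.95, 0.5), radius = 0.1),
               "boundary")
})

test_that("OV boluses add exactly their dose and commute", {
  v <- matrix(0, 41, 41)
  expect_identical(apply_ov_bolus(v, g41, c(0.3, 0.3), dose = 0), v)
  v1 <- apply_ov_bolus(v, g41, c(0.3, 0.3), dose = 2.5, spread = 0.03)
  expect_lt(abs(population(v1, g41) - 2.5) / 2.5, 1e-8)
  # near-boundary truncation is renormalized
  v2 <- apply_ov_bolus(v, g41, c(0.02, 0.5), dose = 1, spread = 0.05)
  expect_lt(abs(population(v2, g41) - 1), 1e-8)
  a <- apply_ov_bolus(apply_ov_bolus(v, g41, c(0.3, 0.3), 1), g41,
                      c(0.7, 0.7), 2)
  b <- apply_ov_bolus(apply_ov_bolus(v, g41, c(0.7, 0.7), 2), g41,
                      c(0.3, 0.3), 1)
  expect_equal(a, b)
  expect_error(apply_ov_bolus(v, g41, c(1.2, 0.5), 1), "unit square")
})

test_that("the BTZ source covers its discs at the requested rate", {
  zero_src <- btz_source_map(g41, NULL, IB = 0)
  expect_identical(zero_src(5), matrix(0, 41, 41))
  expect_error(btz_source_map(g41, NULL, IB = 0.1), "site")

  src <- btz_source_map(g41, c(0.5, 0.5), IB = 0.18, radius = 0.1,
                        window = c(0, 48))
  m <- src(0)
  expect_identical(max(m), 0.18)
  total <- sum(m) * g41$hx * g41$hy
  expect_gt(total, 0.18 * pi * 0.1^2 * 0.9)
  expect_lt(total, 0.18 * pi * (0.1 + 3 * g41$hx)^2)
  expect_identical(src(100), matrix(0, 41, 41))   # window closed

  # the printed dose ladder maps to the supply rates used by the presets
  ladder <- c(0, 3.3e-2, 7.7e-2, 1.8e-1, 3.3e-1)
  for (IB in ladder[-1]) {
    s <- btz_source_map(g41, c(0.5, 0.5), IB = IB)
    expect_identical(max(s(0)), IB)
  }
})

test_that("resection removes the cell fields only, with exact bookkeeping", {
  f <- list(x = make_initial_tumor(g41), y = matrix(0.1, 41, 41),
            n = matrix(0.05, 41, 41), v = matrix(1, 41, 41),
            B = matrix(0.4, 41, 41))
  pre <- population(f$x, g41)
  out <- apply_resection(f, g41, center = c(0.5, 0.5), radius = 0.8)
  expect_true(all(out$x == 0) && all(out$y == 0) && all(out$n == 0))
  expect_identical(out$v, f$v)
  expect_identical(out$B, f$B)
  expect_equal(attr(out, "removed"), pre)

  far <- apply_resection(f, g41, center = c(0.9, 0.9), radius = 0.05)
  expect_identical(far$x, f$x)
})

test_that("region masks partition the domain", {
  reg <- region_maps(g41, cspg_ring_spec(gap = TRUE))
  expect_true(all(reg$Q1 + reg$Q2 + reg$Q3 + reg$Q4 == 1))
  expect_true(all(reg$omega_plus + reg$omega_minus == 1))
  expect_true(all(reg$inside + reg$outside == 1))
  expect_true(all(reg$omega_i[reg$inside] == FALSE))
  # the invasion area sits in the gap quadrant
  expect_true(all(which(reg$omega_i, arr.ind = TRUE) > 21 - 8))
})

test_that("an open ring has strictly fewer barrier faces than a closed one", {
  closed <- make_cspg_masks(cspg_ring_spec(), g41)
  open <- make_cspg_masks(cspg_ring_spec(gap = TRUE), g41)
  nfaces <- function(m) sum(m$barrier$fx) + sum(m$barrier$fy)
  expect_gt(nfaces(closed), nfaces(open))
  expect_gt(nfaces(open), 0)
  none <- make_cspg_masks(NULL, g41)
  expect_identical(nfaces(none), 0L)
})

test_that("every preset builds a valid scenario", {
  names <- c("default", "fig6-pbs", "fig6-btz", "fig6-ov", "fig6-combo",
             "fig8-periphery", "fig8-periphery-center", "fig8-combo",
             "fig9-ov", "fig9-combo", "fig10-closed", "fig10-open",
             "fig11-control", "fig11-ov", "fig11-combo", "fig12-resection")
  for (nm in names) {
    scn <- preset(nm, nx = 31, t_end_day = 2)
    expect_s3_class(scn, "scenario")
    expect_true(all(scn$ov_sites >= 0 & scn$ov_sites <= 1))
    expect_gt(scn$t_end_day, 0)
  }
  sweep <- preset("fig12-sweep", nx = 31, t_end_day = 2)
  expect_length(sweep, 9)
  combos <- t(vapply(sweep, function(s) c(s$f_D1, s$f_Dv), numeric(2)))
  expect_identical(nrow(unique(combos)), 9L)
  expect_error(preset("fig99"), "unknown preset")
})

test_that("upper half-domain heterogeneity slows growth there", {
  tab <- fixture_qss_table()
  scn <- scenario("PBS", nx = 31, t_end_day = 4, omega_plus_factor = 0.01,
                  snapshot_days = c(0, 4))
  r <- run_scenario(scn, table = tab)
  m <- r$metrics[nrow(r$metrics), ]
  expect_lt(m$x_omega_plus, m$x_omega_minus)
})

test_that("treating the invasion area suppresses escape, more so with BTZ", {
  tab <- fixture_qss_table()
  ctl <- fixture_run("fig11-control",
                     preset("fig11-control", nx = 51, t_end_day = 10))
  ov <- fixture_run("fig11-ov", preset("fig11-ov", nx = 51, t_end_day = 10))
  combo <- fixture_run("fig11-combo",
                       preset("fig11-combo", nx = 51, t_end_day = 10))
  x_ctl <- final_metric(ctl, "x_omega_i")
  x_ov <- final_metric(ov, "x_omega_i")
  x_combo <- final_metric(combo, "x_omega_i")
  expect_lt(x_ov, x_ctl)
  expect_lt(x_combo, x_ov)
})

test_that("resection followed by combination therapy runs end to end", {
  tab <- fixture_qss_table()
  r <- run_scenario(preset("fig12-resection", nx = 31, t_end_day = 2),
                    table = tab)
  m0 <- r$metrics[1, ]; m1 <- r$metrics[nrow(r$metrics), ]
  # the resected core leaves a ring: center stays empty early on
  expect_lt(r$snapshots[[1]]$x[16, 16], 1e-12)
  expect_gt(m0$uninfected, 0)
  expect_true(all(is.finite(unlist(m1))))
})
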