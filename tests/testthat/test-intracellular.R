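p_def <- intracellular_params()
sc_def <- reference_scales()

test_that("oHSV switch is a saturating ratio with the right landmarks", {
  expect_identical(ohsv_switch(0, 1), 0)
  expect_identical(ohsv_switch(2.5, 2.5), 0.5)
  expect_gt(ohsv_switch(1e6 * 0.3, 0.3), 1 - 1e-6)
  v <- seq(0, 10, by = 0.5)
  expect_true(all(diff(ohsv_switch(v, 0.7)) > 0))
  expect_error(ohsv_switch(-1, 1), "non-negative")
  expect_error(ohsv_switch(1, 0), "strictly positive")
})

test_that("rhs at the origin equals the summed constitutive inputs", {
  d <- intracellular_rhs(c(0, 0, 0, 0), B = 0, ohsv = 0, p_def)
  # Hill repressions are at their maxima when the repressor is absent
  expect_equal(unname(d),
               c(p_def$k1, p_def$c1 + p_def$k3, p_def$c2 + p_def$k7,
                 p_def$k10))
  expect_equal(unname(d), c(0.208, 0.7274, 0.011893, 0.52), tolerance = 1e-12)
})

test_that("virus drive attenuates the BTZ arm and needs F to act on RIP1", {
  d <- intracellular_rhs(c(0, 0, 0, 0), B = 0, ohsv = 1, p_def)
  expect_identical(d[["R"]], p_def$k10)   # k11 term dies with F = 0
  # at B > 0 the oHSV factor strictly reduces the IkB drive
  d0 <- intracellular_rhs(c(0, 0, 0, 0), B = 1, ohsv = 0, p_def)
  d1 <- intracellular_rhs(c(0, 0, 0, 0), B = 1, ohsv = 1, p_def)
  expect_lt(d1[["S"]], d0[["S"]])
  expect_error(intracellular_rhs(c(-1, 0, 0, 0), 0, 0, p_def),
               "non-negative")
})

test_that("steady states satisfy the residual bound across the B range", {
  for (B in c(0, 0.3, 0.7, 1.2)) {
    for (ov in c(FALSE, TRUE)) {
      s <- steady_state(B, ov, p_def, sc_def)
      expect_lt(s$residual, 1e-8)
      res <- intracellular_rhs(s$raw, B, as.numeric(ov), p_def)
      expect_lt(max(abs(res)), 1e-8)
    }
  }
})

test_that("root-finding agrees with long-time integration to 3 significant figures", {
  for (B in c(0, 0.25, 0.5, 0.75, 1)) {
    for (ov in c(FALSE, TRUE)) {
      s <- steady_state(B, ov, p_def, sc_def)
      tr <- intracellular_integrate(c(0, 0, 0.2, 5), B, as.numeric(ov),
                                    c(0, 2000), p_def, sc_def,
                                    report_dt = 100)
      endpoint <- unlist(tr[nrow(tr), c("S", "F", "A", "R")])
      expect_equal(unname(endpoint), unname(s$scaled), tolerance = 5e-4)
    }
  }
})

test_that("returned fixed points are linearly stable", {
  for (B in c(0, 1)) {
    s <- steady_state(B, FALSE, p_def, sc_def)
    # numerical Jacobian at the fixed point
    J <- matrix(0, 4, 4)
    h <- 1e-6
    for (j in 1:4) {
      e <- rep(0, 4); e[j] <- h
      J[, j] <- (intracellular_rhs(s$raw + e, B, 0, p_def) -
                   intracellular_rhs(pmax(s$raw - e, 0), B, 0, p_def)) /
        (2 * h)
    }
    expect_true(all(Re(eigen(J)$values) < 0))
  }
})

test_that("the IkB/NF-kB pair is decoupled from Bax and RIP1 initial data", {
  # fixed-step integration so the step sequence cannot depend on A, R
  tt <- c(0, 100)
  a <- intracellular_integrate(c(0.01, 0.3, 0.2, 1.0), 0.4, 0, tt,
                               p_def, sc_def, report_dt = 0.25,
                               method = "rk4")
  b <- intracellular_integrate(c(0.01, 0.3, 0.55, 3.7), 0.4, 0, tt,
                               p_def, sc_def, report_dt = 0.25,
                               method = "rk4")
  expect_lt(max(abs(a$S - b$S)), 1e-10)
  expect_lt(max(abs(a$F - b$F)), 1e-10)
})

test_that("RIP1 relaxes to k10/mu_r along the closed form when k11 = 0", {
  p0 <- intracellular_params(k11 = 1e-12)   # constructor requires > 0
  p0$k11 <- 0
  R0 <- 2.5
  tr <- intracellular_integrate(c(0, 0, 0, R0), 0.5, 1, c(0, 60), p0,
                                sc_def, report_dt = 0.5)
  raw <- attr(tr, "raw")
  Rinf <- p0$k10 / p0$mu_r
  expected <- Rinf + (R0 - Rinf) * exp(-p0$mu_r * tr$time)
  expect_equal(raw[, "R"], expected, tolerance = 1e-6)
})

test_that("trajectories stay non-negative from non-negative starts", {
  set.seed(42)
  for (i in 1:5) {
    s0 <- runif(4, 0, 5)
    tr <- intracellular_integrate(s0, runif(1, 0, 1.2), runif(1), c(0, 300),
                                  p_def, sc_def, report_dt = 1)
    expect_gt(min(as.matrix(tr[, c("S", "F", "A", "R")])), -1e-9)
  }
})

test_that("zero-length integration returns the initial state only", {
  tr <- intracellular_integrate(c(0.05, 0.25, 0.01, 3.5), 0.3, 0, c(5, 5),
                                p_def, sc_def)
  expect_identical(nrow(tr), 1L)
  expect_equal(unlist(tr[1, c("S", "F", "A", "R")]),
               c(S = 1, F = 0.5, A = 0.1, R = 0.7))
})
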