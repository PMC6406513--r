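p_def <- intracellular_params()
sc_def <- reference_scales()

test_that("cell-death classifier follows the strict threshold definitions", {
  th <- classifier_thresholds()
  expect_identical(as.character(classify_state(2, 1, 1, th)),
                   "ANTI_APOPTOTIC")
  expect_identical(as.character(classify_state(1, 2, 1, th)), "APOPTOTIC")
  expect_identical(as.character(classify_state(2, 1, 2, th)), "NECROPTOTIC")
  # boundary points fail every strict inequality
  expect_identical(as.character(classify_state(1.7, 1.7, 1.7, th)),
                   "UNCLASSIFIED")
  # high F, high A is not a defined region either
  expect_identical(as.character(classify_state(2, 2, 1, th)),
                   "UNCLASSIFIED")
})

test_that("the three regions are pairwise disjoint for arbitrary thresholds", {
  set.seed(7)
  for (i in 1:20) {
    th <- classifier_thresholds(thF = runif(1, 0.5, 3),
                                thA = runif(1, 0.5, 3),
                                thR = runif(1, 0.5, 3))
    F <- runif(200, 0, 6); A <- runif(200, 0, 6); R <- runif(200, 0, 6)
    lab <- classify_state(F, A, R, th)
    in_t <- F > th$thF & A < th$thA & R < th$thR
    in_a <- F < th$thF & A > th$thA & R < th$thR
    in_n <- F > th$thF & A < th$thA & R > th$thR
    expect_false(any(in_t & in_a) || any(in_t & in_n) || any(in_a & in_n))
    expect_identical(unname(as.integer(table(lab)[1:3])),
                     c(sum(in_t), sum(in_a), sum(in_n)))
  }
})

test_that("a degenerate single-point scan equals the direct steady state", {
  sc1 <- bifurcation_scan(0, FALSE, p_def, sc_def)
  s <- steady_state(0, FALSE, p_def, sc_def)
  expect_equal(unlist(sc1[1, c("Ss", "Fs", "As", "Rs")]), s$scaled,
               tolerance = 1e-10)
  expect_error(bifurcation_scan(c(0.5, 0.1)), "sorted")
})

test_that("the scan shows the NF-kB off-switch and the Bax on-switch", {
  Bg <- seq(0, 1.5, length.out = 61)
  cv <- bifurcation_scan(Bg, FALSE, p_def, sc_def)
  expect_gt(cv$Fs[1], cv$As[1])               # anti-apoptotic at low B
  expect_lt(cv$Fs[61], cv$As[61])             # apoptotic at high B
  expect_true(all(diff(cv$Fs) < 1e-9))        # Fs non-increasing
  expect_true(all(diff(cv$As) > -1e-9))       # As non-decreasing
  # curve endpoints agree with direct solves
  e <- steady_state(1.5, FALSE, p_def, sc_def)
  expect_equal(unlist(cv[61, c("Ss", "Fs", "As", "Rs")]), e$scaled,
               tolerance = 1e-8)
})

test_that("the with-OV branch elevates RIP1 at high BTZ", {
  Bg <- c(0.8, 1.0, 1.2)
  off <- bifurcation_scan(Bg, FALSE, p_def, sc_def)
  on <- bifurcation_scan(Bg, TRUE, p_def, sc_def)
  expect_true(all(on$Rs > off$Rs + 1))
})

test_that("crossover shifts to smaller B when the Bax inputs are amplified", {
  b0 <- crossover(p_def, sc_def)
  expect_gt(b0, 0); expect_lt(b0, 1.5)
  # at the crossover the two curves actually intersect
  s <- steady_state(b0, FALSE, p_def, sc_def)
  expect_lt(abs(s$scaled[["Fs"]] - s$scaled[["As"]]), 1e-2)
  p_hot <- intracellular_params(c2 = p_def$c2 * 10, k7 = p_def$k7 * 10)
  expect_lt(crossover(p_hot, sc_def), b0)
})

test_that("the periodic BTZ schedule hits its printed landmarks", {
  expect_equal(periodic_btz(0), 0.7)
  expect_equal(periodic_btz(250), 0.2)
  expect_equal(periodic_btz(125), 0.45)
  expect_error(periodic_btz(-1), "non-negative")
})

test_that("a constant mid-range drive yields no decreasing-phase exit", {
  expect_error(hysteresis_exit(p_def, sc_def, forcing = function(t)
    rep(0.45, length(t))), "no downward")
})

test_that("qss lookup interpolates the scan and clamps beyond the table", {
  tab <- fixture_qss_table()
  B <- c(0, 0.31, 0.77, 1.0)
  lk <- qss_lookup(B, FALSE, tab)
  direct <- t(vapply(B, function(b)
    steady_state(b, FALSE, p_def, sc_def)$scaled, numeric(4)))
  expect_equal(unname(lk), unname(direct), tolerance = 1e-3)
  expect_warning(qss_lookup(max(tab$B) + 5, FALSE, tab), "clamped")
})
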