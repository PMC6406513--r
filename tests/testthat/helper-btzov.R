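# shared fixtures, built once per test run and memoized

.fixtures <- new.env(parent = emptyenv())

# steady-state lookup table at default parameters (a few seconds to build)
fixture_qss_table <- function() {
  if (is.null(.fixtures$tab)) .fixtures$tab <- qss_table()
  .fixtures$tab
}

# memoized scenario runs keyed by preset name / configuration label
fixture_run <- function(key, scn_fun, ...) {
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- run_scenario(scn_fun, table = fixture_qss_table(),
                                     ...)
  .fixtures[[key]]
}

final_alive <- function(res) res$metrics[nrow(res$metrics), "alive"]
final_metric <- function(res, col) res$metrics[nrow(res$metrics), col]

# uniform diffusivity face maps for a grid
uniform_dmaps <- function(grid, rp) {
  mk <- function(D) face_diffusivities(matrix(D, grid$nx, grid$ny))
  list(x = mk(rp$D1), y = mk(rp$D2), v = mk(rp$Dv), B = mk(rp$DB))
}

# lumped reaction ODE oracle for the five-field system (no transport),
# integrated independently with deSolve at tight tolerance
lumped_ode_oracle <- function(state0, t_end, rp, tab,
                              th = classifier_thresholds(), srcB = 0) {
  rhs <- function(t, s, parms) {
    x <- s[1]; y <- s[2]; n <- s[3]; v <- s[4]; B <- s[5]
    lk <- qss_lookup(B, v / (rp$k_ohsv + v) >= 0.5, tab)
    Ia <- as.numeric(lk[, "Fs"] < th$thF & lk[, "As"] > th$thA &
                       lk[, "Rs"] < th$thR)
    In <- as.numeric(lk[, "Fs"] > th$thF & lk[, "As"] < th$thA &
                       lk[, "Rs"] > th$thR)
    inf <- (rp$beta + rp$beta3B * B * In) * v
    list(c(rp$lambda * x * (1 - x) - inf * x - rp$beta1 * x * B * Ia,
           inf * x - rp$delta * y,
           rp$delta * y - rp$mu * n,
           rp$b * rp$delta * y * (1 + rp$alpha1B * B) - rp$gamma * v,
           srcB - (rp$mu1x * x + rp$mu2x * y) * B / (rp$kBn + B) -
             rp$muB * B))
  }
  sol <- deSolve::ode(state0, c(0, t_end), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  sol[2, 2:6]
}
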