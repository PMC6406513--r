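#' Dimensionless tissue-model rate groups
#'
#' Converts the dimensional tissue constants to the dimensionless groups
#' used by the solver: fields are scaled by their reference values, space by
#' the physical domain edge `L` (mm) so the computation lives on the unit
#' square, and time stays in hours. Diffusivities may additionally be
#' scaled by per-field multipliers, the calibration knobs used for the
#' tissue-heterogeneity and motility sweeps.
#'
#' The proliferation rate is converted from its tabulated per-day magnitude
#' to per-hour here (see the methods vignette), and the necroptotic-transfer
#' coefficient pairs with the BTZ concentration, the only reading that
#' closes dimensionally.
#'
#' @param sp a [spatial_params()] object.
#' @param ip an [intracellular_params()] object (for the oHSV switch
#'   half-saturation).
#' @param scales a [reference_scales()] object.
#' @param L physical edge length of the square domain (mm).
#' @param f_D1,f_D2,f_Dv,f_DB diffusivity multipliers relative to the
#'   tabulated motilities; the defaults are the package's reference
#'   diffusivities (calibrated once, see the methods vignette).
#' @return A list of dimensionless rate groups (class `"spatial_rates"`).
#' @export
spatial_rates <- function(sp = spatial_params(), ip = intracellular_params(),
                          scales = reference_scales(), L = 10,
                          f_D1 = 500, f_D2 = 500, f_Dv = 0.02, f_DB = 1) {
  stopifnot(L > 0)
  structure(list(
    D1 = f_D1 * sp$D1 / L^2, D2 = f_D2 * sp$D2 / L^2,
    Dv = f_Dv * sp$Dv / L^2, DB = f_DB * sp$DB / L^2,
    lambda = sp$lambda / 10,
    beta = sp$beta * scales$v_star,       # infection, 1/h per unit v
    beta1 = sp$beta1 * scales$B_star,     # BTZ apoptosis, 1/h per unit B
    beta3B = sp$beta3 * scales$B_star,    # necroptotic transfer per unit B
    b = sp$b,
    alpha1B = sp$alpha1 * scales$B_star,  # burst enhancement per unit B
    IBn = sp$IB / scales$B_star,          # supply, 1/h in units of B*
    delta = sp$delta, mu = sp$mu, gamma = sp$gamma,
    mu1x = sp$mu1 * scales$x_star, mu2x = sp$mu2 * scales$y_star,
    muB = sp$muB, kBn = sp$kB / scales$B_star,
    k_ohsv = ip$k_ohsv / scales$v_star,
    L = L), class = "spatial_rates")
}

#' Cell-death indicator fields
#'
#' Evaluates the per-cell apoptosis and necroptosis indicators from the
#' local BTZ and virus fields. In `"qss"` mode the scaled (F, A, R) levels
#' are interpolated from precomputed steady-state tables, using the
#' with-OV branch wherever the smooth oHSV switch is at or above one half
#' (virus at or above its half-saturation); in `"ode"` mode the caller
#' supplies per-cell intracellular states advanced alongside the PDE. The
#' two indicators are disjoint by construction of the classifier.
#'
#' @param B_field,v_field dimensionless field matrices.
#' @param table a [qss_table()] object (required for `"qss"` mode).
#' @param th a [classifier_thresholds()] object.
#' @param k_ohsv dimensionless half-saturation of the oHSV switch.
#' @param mode `"qss"` or `"ode"`.
#' @param states for `"ode"` mode, a list of scaled state matrices
#'   `S`, `F`, `A`, `R`.
#' @return A list with 0/1 matrices `I_apop`, `I_necrop` and the factor
#'   matrix attribute removed for speed.
#' @export
indicators <- function(B_field, v_field, table = NULL,
                       th = classifier_thresholds(), k_ohsv = 0.01,
                       mode = c("qss", "ode"), states = NULL) {
  mode <- match.arg(mode)
  if (any(B_field < 0) || any(v_field < 0))
    stop("indicators: fields must be non-negative")
  d <- dim(B_field)
  if (mode == "qss") {
    if (is.null(table)) stop("indicators: 'table' required in qss mode")
    ov <- ohsv_switch(as.vector(v_field), k_ohsv) >= 0.5
    sfar <- qss_lookup(as.vector(B_field), ov, table)
    F <- sfar[, "Fs"]; A <- sfar[, "As"]; R <- sfar[, "Rs"]
  } else {
    if (is.null(states)) stop("indicators: 'states' required in ode mode")
    F <- as.vector(states$F); A <- as.vector(states$A)
    R <- as.vector(states$R)
  }
  ia <- as.numeric(F < th$thF & A > th$thA & R < th$thR)
  inx <- as.numeric(F > th$thF & A < th$thA & R > th$thR)
  list(I_apop = matrix(ia, d[1], d[2]), I_necrop = matrix(inx, d[1], d[2]))
}

# phi1(z) = (e^z - 1)/z, accurate near zero
.phi1 <- function(z) {
  out <- z
  small <- abs(z) < 1e-5
  out[small] <- 1 + z[small] / 2 + z[small]^2 / 6
  out[!small] <- (exp(z[!small]) - 1) / z[!small]
  out
}

# per-cell linear rate a and production P of each field at a given state
.reaction_coeffs <- function(fs, ind, rp, srcB) {
  inf_rate <- (rp$beta + rp$beta3B * fs$B * ind$I_necrop) * fs$v
  list(
    a_x = rp$lambda * (1 - fs$x) - inf_rate - rp$beta1 * fs$B * ind$I_apop,
    P_y = inf_rate * fs$x, a_y = -rp$delta,
    P_n = rp$delta * fs$y, a_n = -rp$mu,
    P_v = rp$b * rp$delta * fs$y * (1 + rp$alpha1B * fs$B), a_v = -rp$gamma,
    P_B = srcB,
    a_B = -((rp$mu1x * fs$x + rp$mu2x * fs$y) / (rp$kBn + fs$B) + rp$muB))
}

.etd_apply <- function(fs, co, dt) {
  upd <- function(w, a, P) {
    z <- a * dt
    w * exp(z) + P * dt * .phi1(z)
  }
  list(x = upd(fs$x, co$a_x, 0),
       y = upd(fs$y, co$a_y, co$P_y),
       n = upd(fs$n, co$a_n, co$P_n),
       v = upd(fs$v, co$a_v, co$P_v),
       B = upd(fs$B, co$a_B, co$P_B))
}

#' One local reaction update
#'
#' Advances the five fields by `dt` under the reaction (non-transport)
#' terms only, cell by cell, using a second-order exponential Heun scheme:
#' each field is written as \eqn{dw/dt = a(w) w + P(w)} with its loss folded
#' into `a` and its production into `P`, updated exactly for frozen
#' coefficients and corrected with a trapezoidal coefficient average. The
#' scheme is unconditionally positive and reproduces pure exponential decay
#' and constant-production relaxation exactly, which makes the stiff
#' necroptotic-transfer term harmless. Indicator fields are frozen over the
#' update.
#'
#' @param fields a [field_set()] (or plain list of the five matrices).
#' @param ind indicator list from [indicators()].
#' @param rp a [spatial_rates()] object.
#' @param dt time step (h).
#' @param srcB dimensionless BTZ source matrix (or scalar 0).
#' @return The advanced field list.
#' @export
react_step <- function(fields, ind, rp, dt, srcB = 0) {
  co0 <- .reaction_coeffs(fields, ind, rp, srcB)
  w1 <- .etd_apply(fields, co0, dt)
  co1 <- .reaction_coeffs(w1, ind, rp, srcB)
  avg <- function(u, v) (u + v) / 2
  co <- list(a_x = avg(co0$a_x, co1$a_x),
             P_y = avg(co0$P_y, co1$P_y), a_y = co0$a_y,
             P_n = avg(co0$P_n, co1$P_n), a_n = co0$a_n,
             P_v = avg(co0$P_v, co1$P_v), a_v = co0$a_v,
             P_B = avg(co0$P_B, co1$P_B), a_B = avg(co0$a_B, co1$a_B))
  .etd_apply(fields, co, dt)
}
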