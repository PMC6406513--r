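#' One operator-split PDE step
#'
#' Advances the five-field system by `dt` using Strang splitting: a half
#' reaction update, a full Peaceman-Rachford ADI diffusion step for each
#' mobile field (dead cells do not move), then the second half reaction
#' update. Cell-death indicator fields are evaluated once from the BTZ and
#' virus fields at the start of the step and frozen across it.
#'
#' @param fields list of the five dimensionless field matrices.
#' @param dmaps list of face-diffusivity structures for `x`, `y`, `v`, `B`
#'   (see [face_diffusivities()]).
#' @param rp a [spatial_rates()] object.
#' @param ind indicator list from [indicators()].
#' @param dt time step (h).
#' @param grid a [make_grid()] object.
#' @param srcB BTZ source matrix (or 0).
#' @return The advanced field list.
#' @export
pde_step <- function(fields, dmaps, rp, ind, dt, grid, srcB = 0) {
  f <- react_step(fields, ind, rp, dt / 2, srcB)
  f$x <- diffuse_step(f$x, dmaps$x, dt, grid)
  f$y <- diffuse_step(f$y, dmaps$y, dt, grid)
  f$v <- diffuse_step(f$v, dmaps$v, dt, grid)
  f$B <- diffuse_step(f$B, dmaps$B, dt, grid)
  react_step(f, ind, rp, dt / 2, srcB)
}

# clip tiny diffusion undershoots, tracking removed mass per field
.clip_fields <- function(f, clip_env) {
  for (nm in names(f)) {
    w <- f[[nm]]
    neg <- w < 0
    if (any(neg)) {
      lost <- -sum(w[neg])
      if (min(w) < -1e-8)
        clip_env$overshoot <- max(clip_env$overshoot, -min(w))
      clip_env$clipped[nm] <- clip_env$clipped[nm] + lost
      w[neg] <- 0
      f[[nm]] <- w
    }
    clip_env$total[nm] <- max(clip_env$total[nm], sum(w))
  }
  f
}

#' Adaptive advance of the coupled system
#'
#' Integrates the five-field system from `t0` to `t1` with step-doubling
#' error control: each accepted macro step compares one full step against
#' two half steps; the relative discrepancy (per field, max norm) is kept
#' below `tol`, rejected steps halve `dt`, and accepted steps grow it by at
#' most a factor two. The two-half-step solution is kept. Negative
#' undershoots from the ADI sweeps are clipped to zero; the run aborts if
#' the cumulative clipped mass of any field exceeds 1e-6 of its running
#' total, or if `dt` underflows `dt_min`.
#'
#' @param fields initial field list.
#' @param t0,t1 time interval (h).
#' @param dmaps,rp,grid as in [pde_step()].
#' @param table a [qss_table()] for the indicator lookup (qss mode), or
#'   `NULL` with `ind_mode = "ode"` and `cellstates` supplied.
#' @param th a [classifier_thresholds()] object.
#' @param srcB_fun function of time (h) returning the BTZ source matrix.
#' @param dt0 initial step (h).
#' @param tol target local relative error per macro step.
#' @param dt_min abort threshold for the step size.
#' @param ind_mode `"qss"` or `"ode"`.
#' @param cellstates for `"ode"` mode: list of scaled intracellular state
#'   matrices `S`, `F`, `A`, `R`, advanced alongside the PDE.
#' @param p intracellular parameters (used by `"ode"` mode).
#' @return A list `fields`, `dt` (last accepted), `stats` (steps, rejects,
#'   clipped mass), and `cellstates` (when in `"ode"` mode).
#' @export
advance <- function(fields, t0, t1, dmaps, rp, grid, table,
                    th = classifier_thresholds(), srcB_fun = function(t) 0,
                    dt0 = 0.1, tol = 1e-5, dt_min = 1e-8,
                    ind_mode = c("qss", "ode"), cellstates = NULL,
                    p = intracellular_params()) {
  ind_mode <- match.arg(ind_mode)
  clip_env <- new.env()
  clip_env$clipped <- c(x = 0, y = 0, n = 0, v = 0, B = 0)
  clip_env$total <- c(x = 1e-300, y = 1e-300, n = 1e-300, v = 1e-300,
                      B = 1e-300)
  clip_env$overshoot <- 0
  t <- t0; dt <- dt0
  nstep <- 0L; nreject <- 0L
  get_ind <- function(f) {
    if (ind_mode == "qss")
      indicators(f$B, f$v, table, th, rp$k_ohsv, mode = "qss")
    else
      indicators(f$B, f$v, NULL, th, rp$k_ohsv, mode = "ode",
                 states = cellstates)
  }
  while (t < t1 - 1e-12) {
    dt <- min(dt, t1 - t)
    srcB <- srcB_fun(t)
    ind <- get_ind(fields)
    coarse <- pde_step(fields, dmaps, rp, ind, dt, grid, srcB)
    half <- pde_step(fields, dmaps, rp, ind, dt / 2, grid, srcB)
    ind2 <- get_ind(half)
    fine <- pde_step(half, dmaps, rp, ind2, dt / 2, grid,
                     srcB_fun(t + dt / 2))
    err <- 0
    for (nm in names(fields)) {
      sc <- max(abs(fine[[nm]]), 1e-8)
      err <- max(err, max(abs(coarse[[nm]] - fine[[nm]])) / sc)
    }
    if (is.finite(err) && err <= tol) {
      fields <- .clip_fields(fine, clip_env)
      if (ind_mode == "ode")
        cellstates <- advance_cellstates(cellstates, fields$B, fields$v,
                                         dt, p, rp$k_ohsv)
      t <- t + dt
      nstep <- nstep + 1L
      dt <- dt * min(2, max(0.3, 0.9 * (tol / max(err, 1e-16))^(1 / 3)))
    } else {
      dt <- dt / 2
      nreject <- nreject + 1L
      if (dt < dt_min)
        stop(sprintf(
          "advance: time step underflow (dt = %.3g h) at t = %.4f h", dt, t))
    }
    frac <- clip_env$clipped / clip_env$total
    if (any(frac > 1e-6))
      stop("advance: cumulative clipped negative mass exceeds 1e-6 of the ",
           paste(names(which(frac > 1e-6)), collapse = ", "), " total")
  }
  list(fields = fields, dt = dt,
       stats = list(steps = nstep, rejects = nreject,
                    clipped = clip_env$clipped),
       cellstates = cellstates)
}

#' Advance per-cell intracellular states (ode coupling mode)
#'
#' Fourth-order Runge-Kutta update of the scaled per-cell (S, F, A, R)
#' states under the local BTZ level and smooth oHSV drive, substepped to at
#' most 0.25 h, used when the quasi-steady-state indicator coupling is
#' replaced by explicit intracellular dynamics.
#'
#' @param states list of scaled state matrices `S`, `F`, `A`, `R`.
#' @param B_field,v_field dimensionless local drivers.
#' @param dt macro step (h).
#' @param p an [intracellular_params()] object.
#' @param k_ohsv dimensionless oHSV half-saturation.
#' @param scales a [reference_scales()] object.
#' @return The advanced state list.
#' @export
advance_cellstates <- function(states, B_field, v_field, dt,
                               p = intracellular_params(), k_ohsv = 0.01,
                               scales = reference_scales()) {
  ohsv <- ohsv_switch(v_field, k_ohsv)
  sc <- c(scales$S_star, scales$F_star, scales$A_star, scales$R_star)
  drive <- p$kSB * B_field * p$k12 / (p$k12 + p$k13 * ohsv)
  deriv <- function(st) {
    S <- st$S * sc[1]; F <- st$F * sc[2]; A <- st$A * sc[3]
    R <- st$R * sc[4]
    list(S = (drive + p$k1 * p$k2^2 / (p$k2^2 + p$k5 * F^2) - p$mu_s * S) / sc[1],
         F = (p$c1 + p$k3 * p$k4^2 / (p$k4^2 + p$k6 * S^2) - p$mu_f * F) / sc[2],
         A = (p$c2 + p$k7 * p$k8^2 / (p$k8^2 + p$k9 * F^2) - p$mu_a * A) / sc[3],
         R = (p$k10 + p$k11 * ohsv * F - p$mu_r * R) / sc[4])
  }
  nsub <- max(1L, ceiling(dt / 0.25))
  h <- dt / nsub
  lin <- function(a, b, f) Map(function(u, v) u + f * v, a, b)
  for (s in seq_len(nsub)) {
    k1 <- deriv(states)
    k2 <- deriv(lin(states, k1, h / 2))
    k3 <- deriv(lin(states, k2, h / 2))
    k4 <- deriv(lin(states, k3, h))
    states <- Map(function(w, a, b, c2, d)
      pmax(w + h / 6 * (a + 2 * b + 2 * c2 + d), 0),
      states, k1, k2, k3, k4)
  }
  states
}
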