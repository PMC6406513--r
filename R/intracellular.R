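#' Smooth oHSV switch
#'
#' Saturating virus sensor `v / (k + v)` mapping a virus density to the
#' dimensionless oHSV drive in \[0, 1) used by the intracellular equations.
#'
#' @param v virus density (non-negative, any units consistent with `k`).
#' @param k half-saturation density (strictly positive).
#' @return `v / (k + v)`, vectorized over `v`.
#' @export
#' @examples
#' ohsv_switch(0, 1)    # 0
#' ohsv_switch(1, 1)    # 0.5
ohsv_switch <- function(v, k) {
  if (any(v < 0)) stop("ohsv_switch: 'v' must be non-negative")
  if (any(k <= 0)) stop("ohsv_switch: 'k' must be strictly positive")
  v / (k + v)
}

#' Time derivatives of the intracellular system
#'
#' Evaluates the right-hand side of the four coupled equations for IkB (S),
#' NF-kB--Bcl2 (F), Bax (A) and RIP1 (R) in dimensional units (µM/h):
#' \deqn{dS/dt = kSB B k12/(k12 + k13 [oHSV]) + k1 k2^2/(k2^2 + k5 F^2) - \mu_s S}
#' \deqn{dF/dt = c1 + k3 k4^2/(k4^2 + k6 S^2) - \mu_f F}
#' \deqn{dA/dt = c2 + k7 k8^2/(k8^2 + k9 F^2) - \mu_a A}
#' \deqn{dR/dt = k10 + k11 [oHSV] F - \mu_r R}
#' The BTZ drive on IkB is attenuated by the virus through the
#' `k12/(k12 + k13 [oHSV])` factor; all repressive Hill terms are quadratic.
#'
#' @param state numeric length-4 vector `(S, F, A, R)` in µM, non-negative.
#' @param B dimensionless BTZ level (non-negative).
#' @param ohsv dimensionless oHSV drive in \[0, 1\].
#' @param p an [intracellular_params()] object.
#' @return Named numeric length-4 vector of derivatives (µM/h).
#' @export
intracellular_rhs <- function(state, B, ohsv, p = intracellular_params()) {
  if (length(state) != 4L || any(!is.finite(state)))
    stop("intracellular_rhs: 'state' must be four finite numbers")
  if (any(state < 0)) stop("intracellular_rhs: 'state' must be non-negative")
  if (B < 0) stop("intracellular_rhs: 'B' must be non-negative")
  if (ohsv < 0 || ohsv > 1) stop("intracellular_rhs: 'ohsv' must lie in [0, 1]")
  S <- state[[1]]; F <- state[[2]]; A <- state[[3]]; R <- state[[4]]
  dS <- p$kSB * B * p$k12 / (p$k12 + p$k13 * ohsv) +
    p$k1 * p$k2^2 / (p$k2^2 + p$k5 * F^2) - p$mu_s * S
  dF <- p$c1 + p$k3 * p$k4^2 / (p$k4^2 + p$k6 * S^2) - p$mu_f * F
  dA <- p$c2 + p$k7 * p$k8^2 / (p$k8^2 + p$k9 * F^2) - p$mu_a * A
  dR <- p$k10 + p$k11 * ohsv * F - p$mu_r * R
  c(S = dS, F = dF, A = dA, R = dR)
}

#' Integrate the intracellular system
#'
#' Stiff-capable integration (lsoda, relative tolerance 1e-8, absolute
#' 1e-10 µM) of the four-variable system under constant or time-varying BTZ
#' and oHSV drives. States are reported scaled by the reference
#' concentrations (S/S*, F/F*, A/A*, R/R*).
#'
#' @param state0 initial raw state `(S, F, A, R)` in µM.
#' @param B constant dimensionless BTZ level, or a function of time (h).
#' @param ohsv constant oHSV drive in \[0, 1\], or a function of time.
#' @param t_span length-2 numeric, time interval in hours.
#' @param p an [intracellular_params()] object.
#' @param scales a [reference_scales()] object.
#' @param report_dt reporting step (h); the trajectory is dense enough for
#'   event detection at the default 1 h or finer.
#' @param method integrator passed to [deSolve::ode()]; the default
#'   `"lsoda"` is stiff-capable, `"rk4"` gives fixed reporting-step
#'   Runge-Kutta (useful when runs must be comparable step by step).
#' @return A data.frame with columns `time`, `S`, `F`, `A`, `R` (scaled),
#'   with the raw µM trajectory in attribute `"raw"`.
#' @export
intracellular_integrate <- function(state0, B, ohsv = 0,
                                    t_span = c(0, 2000),
                                    p = intracellular_params(),
                                    scales = reference_scales(),
                                    report_dt = 1, method = "lsoda") {
  stopifnot(length(t_span) == 2L, all(is.finite(t_span)),
            t_span[2] >= t_span[1])
  Bf <- if (is.function(B)) B else function(t) B
  Of <- if (is.function(ohsv)) ohsv else function(t) ohsv
  sc <- c(scales$S_star, scales$F_star, scales$A_star, scales$R_star)
  if (t_span[2] == t_span[1]) {
    out <- data.frame(time = t_span[1], S = state0[1] / sc[1],
                      F = state0[2] / sc[2], A = state0[3] / sc[3],
                      R = state0[4] / sc[4])
    attr(out, "raw") <- matrix(state0, nrow = 1,
                               dimnames = list(NULL, c("S", "F", "A", "R")))
    return(out)
  }
  times <- seq(t_span[1], t_span[2], by = min(report_dt, diff(t_span)))
  if (times[length(times)] < t_span[2]) times <- c(times, t_span[2])
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    list(intracellular_rhs(y, Bf(t), Of(t), p))
  }
  sol <- deSolve::ode(y = as.numeric(state0), times = times, func = deriv,
                      parms = NULL, method = method,
                      rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("intracellular_integrate: integrator failed near t = ",
         sol[nrow(sol), 1], " h")
  raw <- unname(sol[, 2:5, drop = FALSE])
  colnames(raw) <- c("S", "F", "A", "R")
  out <- data.frame(time = sol[, 1],
                    S = raw[, 1] / sc[1], F = raw[, 2] / sc[2],
                    A = raw[, 3] / sc[3], R = raw[, 4] / sc[4])
  attr(out, "raw") <- raw
  out
}

# scalar reduction of the steady-state system: S, A, R are explicit in F,
# so fixed points are roots of gF(F) = rhs_F(S(F)) / mu_f - F.
.ss_reduced <- function(B, ohsv, p) {
  b0 <- p$kSB * B * p$k12 / (p$k12 + p$k13 * ohsv)
  Sof <- function(F) (b0 + p$k1 * p$k2^2 / (p$k2^2 + p$k5 * F^2)) / p$mu_s
  gF <- function(F) {
    S <- Sof(F)
    (p$c1 + p$k3 * p$k4^2 / (p$k4^2 + p$k6 * S^2)) / p$mu_f - F
  }
  list(gF = gF, Sof = Sof,
       Aof = function(F) (p$c2 + p$k7 * p$k8^2 / (p$k8^2 + p$k9 * F^2)) / p$mu_a,
       Rof = function(F) (p$k10 + p$k11 * ohsv * F) / p$mu_r)
}

#' Steady state of the intracellular system
#'
#' Finds fixed points of the four-variable system at a given BTZ level. The
#' algebraic system reduces exactly to a scalar equation in F (S, A and R
#' are explicit functions of F), which is solved by bracketed root-finding
#' over a sign-change scan; all roots found are surfaced, and the returned
#' point satisfies a componentwise residual below 1e-8 µM/h.
#'
#' @param B dimensionless BTZ level (non-negative).
#' @param ov_flag logical; `TRUE` sets the binary oHSV drive to 1, `FALSE`
#'   to 0 (the two-state switch used in steady-state analysis).
#' @param p an [intracellular_params()] object.
#' @param scales a [reference_scales()] object.
#' @param init optional raw seed state; when several roots coexist the one
#'   nearest the seed's F component is returned.
#' @return A list of class `"ss_point"` with elements `raw` (named µM
#'   state), `scaled` (named `(Ss, Fs, As, Rs)`), `B`, `ov_flag`,
#'   `residual`, and `roots` (matrix of all raw fixed points found).
#' @export
#' @examples
#' s <- steady_state(0, FALSE)
#' s$scaled[c("Fs", "As", "Rs")]
steady_state <- function(B, ov_flag = FALSE, p = intracellular_params(),
                         scales = reference_scales(), init = NULL) {
  if (B < 0) stop("steady_state: 'B' must be non-negative")
  ohsv <- as.numeric(isTRUE(ov_flag))
  red <- .ss_reduced(B, ohsv, p)
  Fmax <- (p$c1 + p$k3) / p$mu_f      # supremum of the F nullcline
  grid <- seq(0, Fmax * 1.05, length.out = 513)
  gv <- vapply(grid, red$gF, numeric(1))
  idx <- which(gv[-1] * gv[-length(gv)] <= 0 & is.finite(gv[-1]))
  if (!length(idx)) {
    # fallback: long-time integration then a local bracket around it
    s0 <- if (is.null(init)) c(0, 0.2, 0.02, 3.5) else init
    tr <- intracellular_integrate(s0, B, ohsv, c(0, 5000), p, scales,
                                  report_dt = 50)
    Fend <- attr(tr, "raw")[nrow(tr), "F"]
    lo <- max(0, Fend * 0.5); hi <- Fend * 2 + 1e-6
    if (red$gF(lo) * red$gF(hi) > 0)
      stop("steady_state: no fixed point located for B = ", B)
    idx <- NULL
    roots <- uniroot(red$gF, c(lo, hi), tol = 1e-13)$root
  } else {
    roots <- vapply(idx, function(i)
      uniroot(red$gF, grid[c(i, i + 1)], tol = 1e-13)$root, numeric(1))
    roots <- sort(unique(round(roots, 12)))
  }
  Fr <- if (length(roots) > 1L && !is.null(init)) {
    roots[which.min(abs(roots - init[2]))]
  } else roots[1]
  raw <- c(S = red$Sof(Fr), F = Fr, A = red$Aof(Fr), R = red$Rof(Fr))
  res <- intracellular_rhs(raw, B, ohsv, p)
  if (max(abs(res)) > 1e-8)
    stop("steady_state: residual ", max(abs(res)), " exceeds 1e-8 uM/h")
  scaled <- c(Ss = raw[["S"]] / scales$S_star, Fs = raw[["F"]] / scales$F_star,
              As = raw[["A"]] / scales$A_star, Rs = raw[["R"]] / scales$R_star)
  allroots <- t(vapply(roots, function(Fk)
    c(S = red$Sof(Fk), F = Fk, A = red$Aof(Fk), R = red$Rof(Fk)),
    numeric(4)))
  structure(list(raw = raw, scaled = scaled, B = B,
                 ov_flag = isTRUE(ov_flag), residual = max(abs(res)),
                 roots = allroots),
            class = "ss_point")
}

#' @export
print.ss_point <- function(x, ...) {
  cat(sprintf("Intracellular steady state at B = %g (%s OV)\n", x$B,
              if (x$ov_flag) "with" else "without"))
  cat(sprintf("  scaled (Fs, As, Rs) = (%.3f, %.3f, %.3f)   residual %.2e uM/h\n",
              x$scaled[["Fs"]], x$scaled[["As"]], x$scaled[["Rs"]],
              x$residual))
  if (nrow(x$roots) > 1L)
    cat("  note:", nrow(x$roots), "coexisting fixed points found\n")
  invisible(x)
}

#' Periodic BTZ forcing
#'
#' The reference periodic BTZ schedule `B(t) = 0.25 cos(pi t / 250) + 0.45`
#' (t in hours, period 500 h) used to probe transitions between the
#' anti-apoptotic and apoptotic states.
#'
#' @param t time in hours (non-negative), vectorized.
#' @return Dimensionless BTZ level in \[0.2, 0.7\].
#' @export
periodic_btz <- function(t) {
  if (any(t < 0)) stop("periodic_btz: 't' must be non-negative")
  0.25 * cos(pi * t / 250) + 0.45
}

#' Hysteresis-loop exit under periodic BTZ forcing
#'
#' Integrates the system under a periodic BTZ schedule from a state on the
#' apoptotic (high-Bax) branch and returns the BTZ level at which the scaled
#' Bax trajectory first drops through `thA` while B is decreasing, i.e. the
#' point where the solution leaves the upper branch of the response loop.
#'
#' @param p an [intracellular_params()] object.
#' @param scales a [reference_scales()] object.
#' @param forcing BTZ schedule, a function of time in hours.
#' @param state0_scaled initial `(S, F, A, R)` in scaled units; the default
#'   is the reference loop start (S, F, A, R) = (0, 0.5, 4.5, 0.7) at
#'   B(0) = 0.7.
#' @param thA scaled Bax threshold crossed at exit.
#' @param period forcing period in hours; the search covers one full period.
#' @return A list with `B_exit`, `t_exit` (h) and the dense trajectory.
#' @export
hysteresis_exit <- function(p = intracellular_params(),
                            scales = reference_scales(),
                            forcing = periodic_btz,
                            state0_scaled = c(S = 0, F = 0.5, A = 4.5, R = 0.7),
                            thA = classifier_thresholds()$thA,
                            period = 500) {
  raw0 <- state0_scaled * c(scales$S_star, scales$F_star, scales$A_star,
                            scales$R_star)
  tr <- intracellular_integrate(raw0, forcing, 0, c(0, period), p, scales,
                                report_dt = 0.1)
  tt <- tr$time; A <- tr$A
  eps <- 1e-6
  dB <- (forcing(pmax(tt, eps) + eps) - forcing(pmax(tt - eps, 0))) / (2 * eps)
  cross <- which(A[-length(A)] > thA & A[-1] <= thA & dB[-1] < 0)
  if (!length(cross))
    stop("hysteresis_exit: no downward Bax crossing of thA = ", thA,
         " within one period")
  i <- cross[1]
  Afun <- approxfun(tt[seq(max(1, i - 3), min(length(tt), i + 4))],
                    A[seq(max(1, i - 3), min(length(tt), i + 4))])
  t_exit <- uniroot(function(t) Afun(t) - thA, c(tt[i], tt[i + 1]),
                    tol = 1e-10)$root
  list(B_exit = forcing(t_exit), t_exit = t_exit, trajectory = tr)
}
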