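#' Classify a cell state by its (F, A, R) levels
#'
#' Partitions scaled (NF-kB--Bcl2, Bax, RIP1) triples into the
#' anti-apoptotic region (F above threshold, A and R below), the apoptotic
#' region (A above, F and R below) and the necroptotic region (F and R
#' above, A below). All inequalities are strict; triples satisfying none of
#' the three definitions (including boundary points) are `UNCLASSIFIED`.
#'
#' @param F,A,R scaled levels; finite numerics, recycled to equal length.
#' @param th a [classifier_thresholds()] object.
#' @return A factor with levels `ANTI_APOPTOTIC`, `APOPTOTIC`,
#'   `NECROPTOTIC`, `UNCLASSIFIED`.
#' @export
#' @examples
#' classify_state(2, 1, 1)   # ANTI_APOPTOTIC
#' classify_state(1, 2, 1)   # APOPTOTIC
classify_state <- function(F, A, R, th = classifier_thresholds()) {
  n <- max(length(F), length(A), length(R))
  F <- rep_len(F, n); A <- rep_len(A, n); R <- rep_len(R, n)
  if (any(!is.finite(c(F, A, R))))
    stop("classify_state: inputs must be finite")
  lab <- rep("UNCLASSIFIED", n)
  lab[F > th$thF & A < th$thA & R < th$thR] <- "ANTI_APOPTOTIC"
  lab[F < th$thF & A > th$thA & R < th$thR] <- "APOPTOTIC"
  lab[F > th$thF & A < th$thA & R > th$thR] <- "NECROPTOTIC"
  factor(lab, levels = c("ANTI_APOPTOTIC", "APOPTOTIC", "NECROPTOTIC",
                         "UNCLASSIFIED"))
}

#' Steady-state response curves over the BTZ level
#'
#' Computes the scaled steady-state levels (Fs, As, Rs) on a grid of BTZ
#' values by continuation: each solve is seeded from the previous grid
#' point's solution, with the scan start seeded from scratch. The resulting
#' response curves form the effective on-off switch of the cell-death
#' program over B.
#'
#' @param B_grid sorted non-negative BTZ levels.
#' @param ov_flag logical, binary oHSV drive for the whole scan.
#' @param p an [intracellular_params()] object.
#' @param scales a [reference_scales()] object.
#' @param th a [classifier_thresholds()] object (used to label each point).
#' @return A data.frame of class `"bifurcation_curve"` with columns `B`,
#'   `Ss`, `Fs`, `As`, `Rs`, `region`, and attribute `ov_flag`.
#' @export
bifurcation_scan <- function(B_grid, ov_flag = FALSE,
                             p = intracellular_params(),
                             scales = reference_scales(),
                             th = classifier_thresholds()) {
  if (is.unsorted(B_grid)) stop("bifurcation_scan: 'B_grid' must be sorted")
  if (any(B_grid < 0)) stop("bifurcation_scan: 'B_grid' must be non-negative")
  n <- length(B_grid)
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("Ss", "Fs", "As", "Rs")))
  seed <- NULL
  for (i in seq_len(n)) {
    s <- tryCatch(steady_state(B_grid[i], ov_flag, p, scales, init = seed),
                  error = function(e)
                    stop("bifurcation_scan: failure at B = ", B_grid[i],
                         ": ", conditionMessage(e)))
    out[i, ] <- s$scaled
    seed <- s$raw
  }
  df <- data.frame(B = B_grid, out)
  df$region <- classify_state(df$Fs, df$As, df$Rs, th)
  structure(df, class = c("bifurcation_curve", "data.frame"),
            ov_flag = isTRUE(ov_flag))
}

#' @export
print.bifurcation_curve <- function(x, ...) {
  cat(sprintf("Bifurcation scan over B in [%g, %g] (%d points, %s OV)\n",
              min(x$B), max(x$B), nrow(x),
              if (attr(x, "ov_flag")) "with" else "without"))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
plot.bifurcation_curve <- function(x, ...) {
  matplot(x$B, cbind(x$Fs, x$As, x$Rs), type = "l", lty = 1, lwd = 2,
          col = c("blue", "red", "darkgreen"), xlab = "BTZ level B",
          ylab = "scaled steady state", ...)
  legend("right", c("Fs (NF-kB)", "As (Bax)", "Rs (RIP1)"),
         col = c("blue", "red", "darkgreen"), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' BTZ crossover of the NF-kB and Bax response curves
#'
#' Locates the BTZ level at which the scaled steady-state NF-kB--Bcl2 and
#' Bax curves intersect in the absence of OV, by a continuation scan to
#' bracket the sign change of Fs(B) - As(B) followed by bisection.
#'
#' @param p an [intracellular_params()] object.
#' @param scales a [reference_scales()] object.
#' @param interval search interval for B.
#' @param tol bisection tolerance on B.
#' @return The crossover BTZ level (numeric scalar).
#' @export
crossover <- function(p = intracellular_params(),
                      scales = reference_scales(),
                      interval = c(0, 1.5), tol = 1e-4) {
  h <- function(B) {
    s <- steady_state(B, FALSE, p, scales)
    s$scaled[["Fs"]] - s$scaled[["As"]]
  }
  Bs <- seq(interval[1], interval[2], length.out = 31)
  hv <- vapply(Bs, h, numeric(1))
  i <- which(hv[-1] * hv[-length(hv)] <= 0)[1]
  if (is.na(i))
    stop("crossover: Fs(B) - As(B) does not change sign on [",
         interval[1], ", ", interval[2], "]")
  uniroot(h, Bs[c(i, i + 1)], tol = tol)$root
}

#' Quasi-steady-state lookup tables
#'
#' Precomputes the steady-state response curves with and without the binary
#' oHSV drive on a B grid, for fast per-cell interpolation in the spatial
#' model (the intracellular relaxation is fast relative to the tissue
#' timescale, so the cell-death indicators are evaluated at the local
#' steady state).
#'
#' @param p an [intracellular_params()] object.
#' @param scales a [reference_scales()] object.
#' @param B_max upper end of the tabulated BTZ range.
#' @param nB number of grid points.
#' @return A list of class `"qss_table"` with components `B`, `off`, `on`
#'   (each a matrix of scaled `Ss`, `Fs`, `As`, `Rs` per B).
#' @export
qss_table <- function(p = intracellular_params(),
                      scales = reference_scales(), B_max = 10, nB = 401) {
  Bg <- seq(0, B_max, length.out = nB)
  off <- bifurcation_scan(Bg, FALSE, p, scales)
  on <- bifurcation_scan(Bg, TRUE, p, scales)
  structure(list(B = Bg,
                 off = as.matrix(off[, c("Ss", "Fs", "As", "Rs")]),
                 on = as.matrix(on[, c("Ss", "Fs", "As", "Rs")])),
            class = "qss_table")
}

#' Interpolate scaled steady states from a lookup table
#'
#' @param B numeric vector of dimensionless BTZ levels; values beyond the
#'   tabulated range are clamped with a warning.
#' @param ov logical vector (recycled): use the with-OV branch per entry.
#' @param table a [qss_table()] object.
#' @return A matrix with columns `Ss`, `Fs`, `As`, `Rs`.
#' @export
qss_lookup <- function(B, ov, table) {
  n <- length(B)
  ov <- rep_len(as.logical(ov), n)
  rng <- range(table$B)
  if (any(B < rng[1] - 1e-12 | B > rng[2] + 1e-12))
    warning("qss_lookup: BTZ values outside table range [", rng[1], ", ",
            rng[2], "] clamped")
  Bc <- pmin(pmax(B, rng[1]), rng[2])
  out <- matrix(NA_real_, n, 4, dimnames = list(NULL,
                                                c("Ss", "Fs", "As", "Rs")))
  for (j in 1:4) {
    f_off <- approx(table$B, table$off[, j], xout = Bc, rule = 2)$y
    f_on <- approx(table$B, table$on[, j], xout = Bc, rule = 2)$y
    out[, j] <- ifelse(ov, f_on, f_off)
  }
  out
}
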