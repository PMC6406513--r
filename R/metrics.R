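#' Population integral of a field
#'
#' Trapezoid-rule integral of a field over the whole domain or a masked
#' region (boundary nodes own half cells, so a uniform field integrates to
#' exactly its value), in units of the field's reference scale times
#' domain area. This is the same measure the diffusion stencil conserves.
#'
#' @param field matrix conformal with `grid`.
#' @param grid a [make_grid()] object.
#' @param mask optional logical matrix selecting cells.
#' @return Numeric scalar.
#' @export
population <- function(field, grid, mask = NULL) {
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(field)))
    field <- field * mask
  }
  sum(field * .quad_weights(grid))
}

#' Spherical-equivalent tumor volume
#'
#' Thresholds the alive-cell density (uninfected + infected) at a fraction
#' of carrying capacity, takes the equivalent-area radius of the support
#' `r = L * sqrt(area / pi)`, and reports the volume of the sphere with
#' diameter `2r`: `V = (4 pi / 3) r^3`. The equivalent-area definition is
#' robust to ring-shaped late-time patterns that a maximum-extent diameter
#' would overstate.
#'
#' @param fields field list with `x` and `y`.
#' @param grid a [make_grid()] object.
#' @param L physical domain edge (mm).
#' @param threshold_fraction support threshold in (0, 1).
#' @return Volume in mm^3 (0 for empty support).
#' @export
tumor_volume <- function(fields, grid, L = 10, threshold_fraction = 0.1) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  support <- (fields$x + fields$y) >= threshold_fraction
  area <- sum(.quad_weights(grid)[support])
  if (area == 0) return(0)
  r <- L * sqrt(area / pi)
  (4 * pi / 3) * r^3
}

#' Population adhered to the CSPG barrier
#'
#' Integral of the uninfected-cell field over the inside-facing shell of
#' grid nodes within `width` cells of the barrier band, a proxy for tumor
#' cells strongly adhered to the barrier.
#'
#' @param x_field uninfected-cell matrix.
#' @param grid a [make_grid()] object.
#' @param spec a [cspg_ring_spec()] or `NULL` (returns 0).
#' @param width shell width in grid cells (>= 1).
#' @return Numeric scalar.
#' @export
adherent_population <- function(x_field, grid, spec, width = 2) {
  if (is.null(spec)) return(0)
  stopifnot(width >= 1)
  X <- outer(grid$x, rep(1, grid$ny))
  Y <- outer(rep(1, grid$nx), grid$y)
  r <- sqrt((X - spec$center[1])^2 + (Y - spec$center[2])^2)
  shell <- r < spec$r_inner & r >= spec$r_inner - width * grid$hx
  population(x_field, grid, shell)
}

#' Per-cell intracellular maps
#'
#' Applies the quasi-steady-state lookup to the local BTZ and virus fields,
#' returning the scaled (S, F, A, R) maps, the cell-death region label per
#' cell, and domain-averaged levels for bar-chart-style summaries.
#'
#' @param B_field,v_field dimensionless field matrices.
#' @param table a [qss_table()] object.
#' @param th a [classifier_thresholds()] object.
#' @param k_ohsv dimensionless oHSV half-saturation.
#' @return A list with matrices `S`, `F`, `A`, `R`, factor matrix `region`
#'   (as a character matrix), and named vector `means`.
#' @export
intracellular_maps <- function(B_field, v_field, table,
                               th = classifier_thresholds(),
                               k_ohsv = 0.01) {
  d <- dim(B_field)
  ov <- ohsv_switch(as.vector(v_field), k_ohsv) >= 0.5
  sfar <- qss_lookup(as.vector(B_field), ov, table)
  lab <- classify_state(sfar[, "Fs"], sfar[, "As"], sfar[, "Rs"], th)
  out <- list(S = matrix(sfar[, "Ss"], d[1], d[2]),
              F = matrix(sfar[, "Fs"], d[1], d[2]),
              A = matrix(sfar[, "As"], d[1], d[2]),
              R = matrix(sfar[, "Rs"], d[1], d[2]),
              region = matrix(as.character(lab), d[1], d[2]))
  out$means <- c(S = mean(out$S), F = mean(out$F), A = mean(out$A),
                 R = mean(out$R))
  out
}

#' Snapshot metrics
#'
#' Summary quantities of one field snapshot: total, uninfected, infected,
#' dead and alive population integrals, virus and BTZ totals, tumor volume,
#' and per-region populations of the uninfected field where region masks
#' exist (quadrants, half-domains, inside/outside the ring, invasion area).
#'
#' @param fields field list.
#' @param grid a [make_grid()] object.
#' @param regions region mask list from [region_maps()].
#' @param t_day snapshot time in days.
#' @param L physical domain edge (mm).
#' @return One-row data.frame.
#' @export
compute_metrics <- function(fields, grid, regions = NULL, t_day = NA_real_,
                            L = 10) {
  pop <- function(f, m = NULL) population(f, grid, m)
  out <- data.frame(time_day = t_day,
                    uninfected = pop(fields$x), infected = pop(fields$y),
                    dead = pop(fields$n), virus = pop(fields$v),
                    btz = pop(fields$B))
  out$alive <- out$uninfected + out$infected
  out$total <- out$alive + out$dead
  out$volume_mm3 <- tumor_volume(fields, grid, L)
  if (!is.null(regions)) {
    for (q in c("Q1", "Q2", "Q3", "Q4"))
      out[[paste0("x_", q)]] <- pop(fields$x, regions[[q]])
    out$x_omega_plus <- pop(fields$x, regions$omega_plus)
    out$x_omega_minus <- pop(fields$x, regions$omega_minus)
    if (!is.null(regions$inside)) {
      out$x_inside <- pop(fields$x, regions$inside)
      out$x_outside <- pop(fields$x, regions$outside)
      out$x_omega_i <- pop(fields$x, regions$omega_i)
      out$y_omega_i <- pop(fields$y, regions$omega_i)
      out$v_omega_i <- pop(fields$v, regions$omega_i)
    }
  }
  out
}
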