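#' CSPG ring specification
#'
#' Geometry of an annular chondroitin-sulfate-proteoglycan barrier around
#' the tumor, optionally with an open sector (gap). The barrier acts by
#' zeroing the tumor-cell diffusivity on grid faces inside the band.
#'
#' @param center ring center in domain coordinates.
#' @param r_inner,r_outer annulus radii, `0 < r_inner < r_outer`.
#' @param gap logical, whether the ring has an open sector.
#' @param gap_quadrant quadrant (1-4) holding the gap; the gap is centered
#'   on the quadrant bisector.
#' @param gap_width_deg angular width of the gap in degrees, in (0, 90].
#' @return A list of class `"cspg_ring_spec"`.
#' @export
cspg_ring_spec <- function(center = c(0.5, 0.5), r_inner = 0.2,
                           r_outer = 0.25, gap = FALSE, gap_quadrant = 1,
                           gap_width_deg = 45) {
  stopifnot(r_inner > 0, r_outer > r_inner,
            gap_quadrant %in% 1:4)
  if (gap && (gap_width_deg <= 0 || gap_width_deg > 90))
    stop("cspg_ring_spec: gap width must lie in (0, 90] degrees")
  structure(list(center = center, r_inner = r_inner, r_outer = r_outer,
                 gap = isTRUE(gap), gap_quadrant = gap_quadrant,
                 gap_width_deg = gap_width_deg),
            class = "cspg_ring_spec")
}

# angle of the gap-quadrant bisector (radians)
.gap_center_angle <- function(q) c(pi / 4, 3 * pi / 4, 5 * pi / 4,
                                   7 * pi / 4)[q]

# smallest absolute angular distance
.ang_dist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

#' Build CSPG barrier face masks and region maps
#'
#' Marks every grid face whose midpoint lies inside the annulus band as a
#' barrier face (zero tumor-cell diffusivity), except faces inside the open
#' sector when the ring has a gap, and derives the standard region masks
#' (inside/outside the ring mid-line, quadrants, upper/lower halves, and
#' the invasion area beyond the gap).
#'
#' @param spec a [cspg_ring_spec()] object, or `NULL` for no barrier.
#' @param grid a [make_grid()] object.
#' @return A list with `barrier` (logical face masks `fx`, `fy`), `band`
#'   (node mask of the annulus), and `regions` (see [region_maps()]).
#' @export
make_cspg_masks <- function(spec, grid) {
  reg <- region_maps(grid, spec)
  if (is.null(spec)) {
    return(list(barrier = list(fx = matrix(FALSE, grid$nx - 1, grid$ny),
                               fy = matrix(FALSE, grid$nx, grid$ny - 1)),
                band = matrix(FALSE, grid$nx, grid$ny), regions = reg))
  }
  in_band <- function(px, py) {
    r <- sqrt((px - spec$center[1])^2 + (py - spec$center[2])^2)
    ok <- r >= spec$r_inner & r <= spec$r_outer
    if (spec$gap) {
      th <- atan2(py - spec$center[2], px - spec$center[1])
      half <- spec$gap_width_deg * pi / 360
      ok <- ok & .ang_dist(th, .gap_center_angle(spec$gap_quadrant)) > half
    }
    ok
  }
  # face midpoints
  mx_x <- outer((grid$x[-grid$nx] + grid$x[-1]) / 2, rep(1, grid$ny))
  mx_y <- outer(rep(1, grid$nx - 1), grid$y)
  my_x <- outer(grid$x, rep(1, grid$ny - 1))
  my_y <- outer(rep(1, grid$nx), (grid$y[-grid$ny] + grid$y[-1]) / 2)
  node_x <- outer(grid$x, rep(1, grid$ny))
  node_y <- outer(rep(1, grid$nx), grid$y)
  band <- matrix(in_band(node_x, node_y), grid$nx, grid$ny)
  list(barrier = list(fx = matrix(in_band(mx_x, mx_y), grid$nx - 1, grid$ny),
                      fy = matrix(in_band(my_x, my_y), grid$nx, grid$ny - 1)),
       band = band, regions = reg)
}

#' Region masks of the computational domain
#'
#' Node masks for the four quadrants about the domain center, the upper and
#' lower half-domains, and -- when a ring is present -- the inside/outside
#' split at the annulus mid-line plus the invasion area beyond the gap (a
#' sector twice the gap's angular width, radially outside the ring).
#'
#' @param grid a [make_grid()] object.
#' @param spec optional [cspg_ring_spec()].
#' @param center domain center for quadrant definitions.
#' @return A list of logical node matrices `Q1`..`Q4`, `omega_plus`,
#'   `omega_minus`, and (with a ring) `inside`, `outside`, `omega_i`.
#' @export
region_maps <- function(grid, spec = NULL, center = c(0.5, 0.5)) {
  X <- outer(grid$x, rep(1, grid$ny))
  Y <- outer(rep(1, grid$nx), grid$y)
  out <- list(Q1 = X >= center[1] & Y >= center[2],
              Q2 = X < center[1] & Y >= center[2],
              Q3 = X < center[1] & Y < center[2],
              Q4 = X >= center[1] & Y < center[2],
              omega_plus = Y > 0.5)
  out$omega_minus <- !out$omega_plus
  if (!is.null(spec)) {
    r <- sqrt((X - spec$center[1])^2 + (Y - spec$center[2])^2)
    rmid <- (spec$r_inner + spec$r_outer) / 2
    out$inside <- r < rmid
    out$outside <- !out$inside
    th <- atan2(Y - spec$center[2], X - spec$center[1])
    half <- min(spec$gap_width_deg * pi / 180, pi / 2)  # twice the gap half-width
    out$omega_i <- r > spec$r_outer &
      .ang_dist(th, .gap_center_angle(spec$gap_quadrant)) <= half
  }
  out
}

#' Smooth initial tumor profile
#'
#' Compact disc of uninfected cells: `peak` (as a fraction of carrying
#' capacity) inside radius `radius`, cosine-tapered to zero over one taper
#' width, zero outside. The support must lie inside the domain.
#'
#' @param grid a [make_grid()] object.
#' @param center disc center.
#' @param radius disc radius (> 0).
#' @param peak plateau height as a fraction of carrying capacity, in (0, 1]
#'   (0 gives an empty field).
#' @param taper taper width.
#' @return Dimensionless uninfected-cell matrix.
#' @export
make_initial_tumor <- function(grid, center = c(0.5, 0.5), radius = 0.1,
                               peak = 0.5, taper = 0.02) {
  stopifnot(radius > 0, peak >= 0, peak <= 1, taper >= 0)
  if (peak == 0) return(matrix(0, grid$nx, grid$ny))
  ext <- radius + taper
  if (any(center - ext < 0) || any(center + ext > 1))
    stop("make_initial_tumor: profile support crosses the domain boundary")
  X <- outer(grid$x, rep(1, grid$ny))
  Y <- outer(rep(1, grid$nx), grid$y)
  d <- sqrt((X - center[1])^2 + (Y - center[2])^2)
  w <- matrix(0, grid$nx, grid$ny)
  w[d <= radius] <- peak
  edge <- d > radius & d < radius + taper
  w[edge] <- peak * 0.5 * (1 + cos(pi * (d[edge] - radius) / taper))
  w
}

#' Add an OV bolus to the virus field
#'
#' Adds a normalized Gaussian of total integral `dose` (in units of the
#' reference virus density times domain area) centered at `site`. The
#' kernel is truncated at the boundary and renormalized so the added
#' integral equals `dose` exactly.
#'
#' @param v_field dimensionless virus matrix.
#' @param grid a [make_grid()] object.
#' @param site injection site inside the domain.
#' @param dose non-negative total dose.
#' @param spread Gaussian standard deviation.
#' @return The updated virus matrix.
#' @export
apply_ov_bolus <- function(v_field, grid, site, dose, spread = 0.02) {
  if (dose < 0) stop("apply_ov_bolus: 'dose' must be non-negative")
  if (any(site < 0) || any(site > 1))
    stop("apply_ov_bolus: 'site' must lie inside the unit square")
  if (dose == 0) return(v_field)
  X <- outer(grid$x, rep(1, grid$ny))
  Y <- outer(rep(1, grid$nx), grid$y)
  G <- exp(-((X - site[1])^2 + (Y - site[2])^2) / (2 * spread^2))
  v_field + G * dose / sum(G * .quad_weights(grid))
}

#' BTZ source map
#'
#' Constant-rate BTZ supply on a union of site discs, active during a time
#' window: the dimensionless source equals `IB` (in units of the BTZ
#' reference per hour) on the discs and zero elsewhere and outside the
#' window.
#'
#' @param grid a [make_grid()] object.
#' @param sites matrix (or 2-vector) of disc centers; required when
#'   `IB > 0`.
#' @param IB dimensionless supply rate.
#' @param radius disc radius.
#' @param window length-2 active time window in hours.
#' @param taper cosine taper width at the disc edge (keeps the source free
#'   of grid-scale jumps and resolution-independent; the supply rate still
#'   equals `IB` on the disc proper).
#' @return A function of time (h) returning the source matrix.
#' @export
btz_source_map <- function(grid, sites, IB, radius = 0.1,
                           window = c(0, Inf), taper = 0.04) {
  if (IB < 0) stop("btz_source_map: 'IB' must be non-negative")
  zero <- matrix(0, grid$nx, grid$ny)
  if (IB == 0) return(function(t) zero)
  if (is.null(sites) || length(sites) == 0)
    stop("btz_source_map: positive 'IB' requires at least one site")
  if (is.null(dim(sites))) sites <- matrix(sites, ncol = 2)
  X <- outer(grid$x, rep(1, grid$ny))
  Y <- outer(rep(1, grid$nx), grid$y)
  src <- zero
  for (s in seq_len(nrow(sites))) {
    d <- sqrt((X - sites[s, 1])^2 + (Y - sites[s, 2])^2)
    w <- matrix(0, grid$nx, grid$ny)
    w[d <= radius] <- 1
    edge <- d > radius & d < radius + taper
    w[edge] <- 0.5 * (1 + cos(pi * (d[edge] - radius) / taper))
    src <- pmax(src, IB * w)
  }
  function(t) if (t >= window[1] && t < window[2]) src else zero
}

#' Surgical resection
#'
#' Removes all cell populations (uninfected, infected, dead) inside a disc;
#' the virus and BTZ fields are untouched.
#'
#' @param fields field list.
#' @param grid a [make_grid()] object.
#' @param center,radius resection disc, inside the domain.
#' @return The updated field list, with the removed uninfected mass in
#'   attribute `"removed"`.
#' @export
apply_resection <- function(fields, grid, center = c(0.5, 0.5),
                            radius = 0.12) {
  if (any(center < 0) || any(center > 1))
    stop("apply_resection: disc center must lie inside the domain")
  X <- outer(grid$x, rep(1, grid$ny))
  Y <- outer(rep(1, grid$nx), grid$y)
  disc <- (X - center[1])^2 + (Y - center[2])^2 <= radius^2
  removed <- sum(fields$x[disc]) * grid$hx * grid$hy
  for (nm in c("x", "y", "n")) fields[[nm]][disc] <- 0
  attr(fields, "removed") <- removed
  fields
}

# six equally spaced sites on a circle around the tumor periphery
.periphery_sites <- function(center = c(0.5, 0.5), radius = 0.13, n = 6) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' Construct a therapy scenario
#'
#' Bundles everything one in-silico experiment needs: grid resolution and
#' physical size, the initial tumor, the therapy arm, OV bolus sites and
#' schedule, the BTZ source, optional CSPG ring / half-domain heterogeneity
#' / resection, diffusivity multipliers and the time horizon.
#'
#' @param arm one of `"PBS"`, `"BTZ"`, `"OV"`, `"OV+BTZ"`.
#' @param nx grid nodes per side.
#' @param L physical domain edge (mm).
#' @param tumor list with `center`, `radius`, `peak`, `taper`.
#' @param ov_sites matrix of OV injection sites (used by OV arms).
#' @param ov_dose,ov_spread bolus dose and spread per site.
#' @param ov_time_day bolus time(s) in days (recycled over sites).
#' @param btz_sites BTZ source disc centers (defaults to the OV sites).
#' @param btz_IB dimensionless BTZ supply rate (used by BTZ arms).
#' @param btz_radius source disc radius.
#' @param btz_window_days active window of the BTZ source, days.
#' @param cspg optional [cspg_ring_spec()].
#' @param omega_plus_factor optional diffusivity reduction factor applied
#'   to all mobile fields in the upper half-domain (e.g. 0.01).
#' @param resection optional list `center`, `radius` applied at t = 0.
#' @param f_D1,f_D2,f_Dv,f_DB diffusivity multipliers relative to the
#'   package reference diffusivities.
#' @param t_end_day time horizon in days (> 0).
#' @param snapshot_days snapshot times (days); defaults to every half day
#'   plus the standard figure time points up to `t_end_day`.
#' @return A validated list of class `"scenario"`.
#' @export
scenario <- function(arm = c("PBS", "BTZ", "OV", "OV+BTZ"), nx = 51, L = 10,
                     tumor = list(center = c(0.5, 0.5), radius = 0.1,
                                  peak = 0.5, taper = 0.02),
                     ov_sites = .periphery_sites(), ov_dose = 1,
                     ov_spread = 0.02, ov_time_day = 0,
                     btz_sites = NULL, btz_IB = 0.18, btz_radius = 0.05,
                     btz_window_days = c(0, Inf), cspg = NULL,
                     omega_plus_factor = NULL, resection = NULL,
                     f_D1 = 1, f_D2 = 1, f_Dv = 1, f_DB = 1,
                     t_end_day = 10, snapshot_days = NULL) {
  arm <- match.arg(arm)
  stopifnot(t_end_day > 0, ov_dose >= 0, btz_IB >= 0, nx >= 11)
  if (is.null(dim(ov_sites))) ov_sites <- matrix(ov_sites, ncol = 2)
  if (any(ov_sites < 0) || any(ov_sites > 1))
    stop("scenario: OV sites must lie inside the unit square")
  if (is.null(btz_sites)) btz_sites <- ov_sites
  if (is.null(dim(btz_sites))) btz_sites <- matrix(btz_sites, ncol = 2)
  if (is.null(snapshot_days))
    snapshot_days <- sort(unique(c(seq(0, t_end_day, by = 0.5),
                                   c(0, 5, 8, 10), t_end_day)))
  snapshot_days <- sort(unique(snapshot_days[snapshot_days <= t_end_day]))
  structure(list(arm = arm, nx = as.integer(nx), L = L, tumor = tumor,
                 ov_sites = ov_sites, ov_dose = ov_dose,
                 ov_spread = ov_spread,
                 ov_time_day = rep_len(ov_time_day, nrow(ov_sites)),
                 btz_sites = btz_sites, btz_IB = btz_IB,
                 btz_radius = btz_radius,
                 btz_window_days = btz_window_days, cspg = cspg,
                 omega_plus_factor = omega_plus_factor,
                 resection = resection,
                 f_D1 = f_D1, f_D2 = f_D2, f_Dv = f_Dv, f_DB = f_DB,
                 t_end_day = t_end_day, snapshot_days = snapshot_days),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Therapy scenario: arm %s, %d x %d grid, %g mm domain, %g days\n",
              x$arm, x$nx, x$nx, x$L, x$t_end_day))
  if (x$arm %in% c("OV", "OV+BTZ"))
    cat(sprintf("  OV: %d bolus site(s), dose %g each\n", nrow(x$ov_sites),
                x$ov_dose))
  if (x$arm %in% c("BTZ", "OV+BTZ"))
    cat(sprintf("  BTZ: IB = %g at %d site disc(s)\n", x$btz_IB,
                nrow(x$btz_sites)))
  if (!is.null(x$cspg))
    cat(sprintf("  CSPG ring [%g, %g]%s\n", x$cspg$r_inner, x$cspg$r_outer,
                if (x$cspg$gap) sprintf(" with %g deg gap in Q%d",
                                        x$cspg$gap_width_deg,
                                        x$cspg$gap_quadrant) else ""))
  if (!is.null(x$omega_plus_factor))
    cat(sprintf("  upper half-domain diffusivities x %g\n",
                x$omega_plus_factor))
  if (!is.null(x$resection))
    cat(sprintf("  resection disc r = %g at t = 0\n", x$resection$radius))
  invisible(x)
}

#' Named scenario presets
#'
#' Prebuilt configurations of the model's in-silico experiments: the four
#' therapy arms, periphery vs periphery+center injection patterns, the
#' 100-fold-reduced upper half-domain, closed and open CSPG rings with
#' interior injection, anti-invasion treatment of the invasion area, and
#' the resection scenario with its 3 x 3 motility sweep.
#'
#' @param name preset name; see Details. `"fig12-sweep"` returns a list of
#'   nine scenarios, all other names a single [scenario()].
#' @param nx grid resolution override.
#' @param t_end_day time-horizon override.
#' @details Available presets: `default`, `fig6-pbs`, `fig6-btz`,
#'   `fig6-ov`, `fig6-combo`, `fig8-periphery`, `fig8-periphery-center`,
#'   `fig8-combo`, `fig9-ov`, `fig9-combo`, `fig10-closed`, `fig10-open`,
#'   `fig11-control`, `fig11-ov`, `fig11-combo`, `fig12-resection`,
#'   `fig12-sweep`.
#' @return A `scenario` (or list of scenarios for the sweep).
#' @export
preset <- function(name, nx = 51, t_end_day = 10) {
  periph <- .periphery_sites()
  periph_center <- rbind(periph, c(0.5, 0.5))
  ring_closed <- cspg_ring_spec()
  ring_open <- cspg_ring_spec(gap = TRUE)
  interior6 <- .periphery_sites(radius = 0.13, n = 6)
  invasion_sites <- matrix(c(0.5 + 0.33 * cos(pi / 4),
                             0.5 + 0.33 * sin(pi / 4)), ncol = 2)
  base <- function(...) scenario(..., nx = nx, t_end_day = t_end_day)
  switch(name,
    "default" = ,
    "fig6-combo" = base("OV+BTZ", ov_sites = periph_center),
    "fig6-pbs" = base("PBS"),
    "fig6-btz" = base("BTZ", btz_sites = periph_center),
    "fig6-ov" = base("OV", ov_sites = periph_center),
    "fig8-periphery" = base("OV", ov_sites = periph),
    "fig8-periphery-center" = base("OV", ov_sites = periph_center),
    "fig8-combo" = base("OV+BTZ", ov_sites = periph_center),
    "fig9-ov" = base("OV", ov_sites = periph_center,
                     omega_plus_factor = 0.01),
    "fig9-combo" = base("OV+BTZ", ov_sites = periph_center,
                        omega_plus_factor = 0.01),
    "fig10-closed" = base("OV+BTZ", ov_sites = interior6,
                          cspg = ring_closed),
    "fig10-open" = base("OV+BTZ", ov_sites = interior6, cspg = ring_open),
    "fig11-control" = base("OV+BTZ", ov_sites = interior6,
                           cspg = ring_open),
    "fig11-ov" = base("OV+BTZ", ov_sites = rbind(interior6, invasion_sites),
                      btz_sites = interior6, cspg = ring_open),
    "fig11-combo" = base("OV+BTZ",
                         ov_sites = rbind(interior6, invasion_sites),
                         btz_sites = rbind(interior6, invasion_sites),
                         cspg = ring_open),
    "fig12-resection" = base("OV+BTZ", ov_sites = interior6,
                             cspg = ring_open,
                             resection = list(center = c(0.5, 0.5),
                                              radius = 0.08)),
    "fig12-sweep" = {
      combos <- expand.grid(f_D1 = c(0.1, 1, 10), f_Dv = c(0.1, 1, 10))
      lapply(seq_len(nrow(combos)), function(i)
        base("OV+BTZ", ov_sites = interior6, cspg = ring_open,
             resection = list(center = c(0.5, 0.5), radius = 0.12),
             f_D1 = combos$f_D1[i], f_Dv = combos$f_Dv[i],
             f_DB = combos$f_Dv[i]))
    },
    stop("preset: unknown preset '", name, "'"))
}
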