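#' Run a therapy scenario
#'
#' Executes a full in-silico experiment: builds the grid, diffusivity maps
#' (including half-domain heterogeneity and CSPG barrier faces), initial
#' tumor and BTZ source, applies scheduled OV boluses and optional
#' resection, advances the coupled system with the adaptive operator-split
#' solver, and records field snapshots plus a metric time series.
#'
#' @param scn a [scenario()] or [preset()] object.
#' @param params full parameter set from [default_params()] or
#'   [load_params()].
#' @param ind_mode indicator coupling: `"qss"` (default, steady-state
#'   lookup) or `"ode"` (per-cell intracellular dynamics).
#' @param tol adaptive-stepper local error target.
#' @param table optional precomputed [qss_table()] (built on demand).
#' @param verbose print progress per snapshot interval.
#' @return A list of class `"sim_result"`: `scenario`, `times_day`,
#'   `snapshots` (field lists per snapshot), `metrics` (data.frame),
#'   `regions`, `grid`, `stats`.
#' @export
run_scenario <- function(scn, params = default_params(),
                         ind_mode = c("qss", "ode"), tol = 1e-5,
                         table = NULL, verbose = FALSE) {
  ind_mode <- match.arg(ind_mode)
  stopifnot(inherits(scn, "scenario"))
  grid <- make_grid(scn$nx)
  rp <- spatial_rates(params$spatial, params$intracellular, params$scales,
                      L = scn$L, f_D1 = 500 * scn$f_D1,
                      f_D2 = 500 * scn$f_D2, f_Dv = 0.02 * scn$f_Dv,
                      f_DB = scn$f_DB)
  masks <- make_cspg_masks(scn$cspg, grid)

  node_map <- function(D) {
    m <- matrix(D, grid$nx, grid$ny)
    if (!is.null(scn$omega_plus_factor))
      m[masks$regions$omega_plus] <- m[masks$regions$omega_plus] *
        scn$omega_plus_factor
    m
  }
  with_barrier <- function(f) {
    f$fx[masks$barrier$fx] <- 0
    f$fy[masks$barrier$fy] <- 0
    f
  }
  dmaps <- list(x = with_barrier(face_diffusivities(node_map(rp$D1))),
                y = with_barrier(face_diffusivities(node_map(rp$D2))),
                v = face_diffusivities(node_map(rp$Dv)),
                B = face_diffusivities(node_map(rp$DB)))

  fields <- list(x = make_initial_tumor(grid, scn$tumor$center,
                                        scn$tumor$radius, scn$tumor$peak,
                                        scn$tumor$taper),
                 y = matrix(0, grid$nx, grid$ny),
                 n = matrix(0, grid$nx, grid$ny),
                 v = matrix(0, grid$nx, grid$ny),
                 B = matrix(0, grid$nx, grid$ny))
  if (!is.null(scn$resection))
    fields <- apply_resection(fields, grid, scn$resection$center,
                              scn$resection$radius)

  use_ov <- scn$arm %in% c("OV", "OV+BTZ")
  use_btz <- scn$arm %in% c("BTZ", "OV+BTZ") && scn$btz_IB > 0
  srcB_fun <- if (use_btz)
    btz_source_map(grid, scn$btz_sites, scn$btz_IB, scn$btz_radius,
                   window = scn$btz_window_days * 24)
  else function(t) matrix(0, grid$nx, grid$ny)

  if (is.null(table) && ind_mode == "qss")
    table <- qss_table(params$intracellular, params$scales)
  th <- params$thresholds

  cellstates <- NULL
  if (ind_mode == "ode") {
    s0 <- steady_state(0, FALSE, params$intracellular, params$scales)
    cellstates <- lapply(as.list(s0$scaled), function(v)
      matrix(v, grid$nx, grid$ny))
    names(cellstates) <- c("S", "F", "A", "R")
  }

  bolus_times <- if (use_ov) scn$ov_time_day * 24 else numeric(0)
  apply_boluses_at <- function(fields, t_day) {
    if (!use_ov) return(fields)
    sel <- which(abs(scn$ov_time_day - t_day) < 1e-9)
    for (s in sel)
      fields$v <- apply_ov_bolus(fields$v, grid, scn$ov_sites[s, ],
                                 scn$ov_dose, scn$ov_spread)
    fields
  }

  snap_times <- scn$snapshot_days * 24
  event_times <- sort(unique(c(0, snap_times, bolus_times,
                               scn$t_end_day * 24)))
  event_times <- event_times[event_times <= scn$t_end_day * 24 + 1e-9]

  snapshots <- list()
  metrics <- list()
  record <- function(fields, t_h) {
    i <- length(snapshots) + 1L
    snapshots[[i]] <<- fields
    metrics[[i]] <<- compute_metrics(fields, grid, masks$regions,
                                     t_day = t_h / 24, L = scn$L)
  }

  fields <- apply_boluses_at(fields, 0)
  if (0 %in% scn$snapshot_days) record(fields, 0)
  dt <- 0.05
  stats <- list(steps = 0L, rejects = 0L,
                clipped = c(x = 0, y = 0, n = 0, v = 0, B = 0))
  for (k in seq_len(length(event_times) - 1)) {
    t0 <- event_times[k]; t1 <- event_times[k + 1]
    if (t1 <= t0) next
    res <- advance(fields, t0, t1, dmaps, rp, grid, table, th, srcB_fun,
                   dt0 = dt, tol = tol, ind_mode = ind_mode,
                   cellstates = cellstates, p = params$intracellular)
    fields <- res$fields; dt <- res$dt; cellstates <- res$cellstates
    stats$steps <- stats$steps + res$stats$steps
    stats$rejects <- stats$rejects + res$stats$rejects
    stats$clipped <- stats$clipped + res$stats$clipped
    fields <- apply_boluses_at(fields, t1 / 24)
    if (any(abs(snap_times - t1) < 1e-9)) record(fields, t1)
    if (verbose)
      message(sprintf("t = %5.2f d  steps %d  dt = %.3g h", t1 / 24,
                      stats$steps, dt))
  }
  metrics <- do.call(rbind, metrics)
  structure(list(scenario = scn,
                 times_day = scn$snapshot_days,
                 snapshots = snapshots, metrics = metrics,
                 regions = masks$regions, barrier = masks$barrier,
                 band = masks$band, grid = grid, stats = stats),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulation result: arm %s, %d snapshots over %g days (%d steps)\n",
              x$scenario$arm, length(x$snapshots),
              x$scenario$t_end_day, x$stats$steps))
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("  final alive %.4f  dead %.4f  virus %.4g  BTZ %.4g  volume %.1f mm^3\n",
              last$alive, last$dead, last$virus, last$btz, last$volume_mm3))
  invisible(x)
}

#' @export
summary.sim_result <- function(object, ...) {
  cat("Metric time series:\n")
  print(object$metrics, row.names = FALSE, digits = 4)
  invisible(object$metrics)
}

#' @export
plot.sim_result <- function(x, what = c("metrics", "fields"),
                            time_day = NULL, ...) {
  what <- match.arg(what)
  if (what == "metrics") {
    m <- x$metrics
    matplot(m$time_day, cbind(m$uninfected, m$infected, m$dead), type = "l",
            lty = 1, lwd = 2, col = c("black", "red", "gray"),
            xlab = "time (days)", ylab = "population integral", ...)
    legend("topleft", c("uninfected", "infected", "dead"),
           col = c("black", "red", "gray"), lty = 1, lwd = 2, bty = "n")
  } else {
    if (is.null(time_day)) time_day <- max(x$times_day)
    i <- which.min(abs(x$times_day - time_day))
    f <- x$snapshots[[i]]
    op <- par(mfrow = c(2, 2), mar = c(2, 2, 2, 1))
    on.exit(par(op))
    for (nm in c("x", "y", "v", "B")) {
      image(x$grid$x, x$grid$y, f[[nm]], col = hcl.colors(64, "viridis"),
            main = sprintf("%s, t = %g d", nm, x$times_day[i]),
            xlab = "", ylab = "")
    }
  }
  invisible(x)
}
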