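#' Write a simulation result to a directory container
#'
#' Serializes a [run_scenario()] result losslessly to a plain-text
#' directory container: a JSON manifest (format version, scenario
#' configuration, snapshot times, grid), the metric time series as CSV, and
#' one CSV per field per snapshot. Floating-point values round-trip at full
#' double precision.
#'
#' @param result a `sim_result` object.
#' @param path directory to create (must not already contain a manifest
#'   unless `overwrite = TRUE`).
#' @param overwrite replace an existing container.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, overwrite = FALSE) {
  stopifnot(inherits(result, "sim_result"))
  manifest_path <- file.path(path, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("write_results: container already exists at ", path)
  dir.create(file.path(path, "fields"), recursive = TRUE,
             showWarnings = FALSE)
  scn <- result$scenario
  manifest <- list(
    format = "btzov-container", version = 1L,
    nx = result$grid$nx, ny = result$grid$ny,
    times_day = result$times_day,
    arm = scn$arm, L = scn$L,
    scenario = .scenario_to_list(scn))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  data.table::fwrite(result$metrics, file.path(path, "metrics.csv"))
  for (i in seq_along(result$snapshots))
    for (nm in names(result$snapshots[[i]]))
      data.table::fwrite(
        data.table::as.data.table(result$snapshots[[i]][[nm]]),
        file.path(path, "fields", sprintf("snap%03d_%s.csv", i, nm)))
  invisible(path)
}

.scenario_to_list <- function(scn) {
  out <- unclass(scn)
  out$ov_sites <- as.data.frame(out$ov_sites)
  out$btz_sites <- as.data.frame(out$btz_sites)
  if (!is.null(out$cspg)) out$cspg <- unclass(out$cspg)
  out
}

#' Read a simulation result container
#'
#' Inverse of [write_results()]: reconstructs snapshots and metrics from a
#' directory container. An unknown or missing format version raises an
#' explicit error, as do truncated containers.
#'
#' @param path container directory.
#' @return A list of class `"sim_result"` (without the derived region
#'   masks, which are rebuilt from the scenario on demand).
#' @export
read_results <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path))
    stop("read_results: no manifest found at ", path)
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  if (is.null(man$format) || man$format != "btzov-container" ||
      is.null(man$version) || man$version != 1L)
    stop("read_results: unsupported container format/version")
  metrics <- as.data.frame(data.table::fread(file.path(path, "metrics.csv")))
  nsnap <- length(man$times_day)
  snapshots <- vector("list", nsnap)
  for (i in seq_len(nsnap)) {
    snapshots[[i]] <- lapply(
      stats::setNames(nm = c("x", "y", "n", "v", "B")),
      function(nm) {
        f <- file.path(path, "fields", sprintf("snap%03d_%s.csv", i, nm))
        if (!file.exists(f))
          stop("read_results: container truncated, missing ", basename(f))
        m <- as.matrix(data.table::fread(f))
        dimnames(m) <- NULL
        m
      })
  }
  grid <- make_grid(man$nx, man$ny)
  structure(list(scenario = man$scenario, times_day = man$times_day,
                 snapshots = snapshots, metrics = metrics, grid = grid),
            class = "sim_result")
}
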