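#' Intracellular rate constants
#'
#' Constructor for the rate and Hill constants of the four-variable
#' IkB--NF-kB--Bax--RIP1 system. Defaults are the published parameter set for
#' the intracellular dynamics; all values are strictly positive. Units are
#' micromolar and hours throughout; the BTZ level `B` and the virus switch
#' `[oHSV]` enter the equations as dimensionless drivers.
#'
#' @param kSB BTZ signal scaling on IkB production (1/h µM).
#' @param k12,k13 half-saturation and attenuation strength of the oHSV
#'   suppression of the BTZ signal (µM). `k12` equals the BTZ reference
#'   concentration expressed in µM.
#' @param c1,c2 constitutive inputs to the NF-kB--Bcl2 complex and Bax
#'   (1/h µM).
#' @param k10 constitutive input to RIP1 (1/h µM).
#' @param k11 oHSV-dependent RIP1 activation rate (1/h).
#' @param k1,k3,k7 maximal Hill production rates of IkB, NF-kB--Bcl2 and Bax
#'   (1/h µM).
#' @param k5,k6,k9 inhibition strengths in the quadratic Hill terms (1/µM^2).
#' @param k2,k4,k8 Hill half-saturation parameters (dimensionless, enter
#'   squared).
#' @param mu_s,mu_f,mu_a,mu_r first-order decay rates (1/h).
#' @param k_ohsv half-saturation virus density of the smooth oHSV switch
#'   (virus/mm^3); default is 1 percent of the reference virus density.
#' @return A named list of class `"intracellular_params"`.
#' @seealso [spatial_params()], [reference_scales()], [classifier_thresholds()]
#' @export
#' @examples
#' p <- intracellular_params()
#' p$k5
intracellular_params <- function(kSB = 1.0e-1, k12 = 2.6e-2, k13 = 7.8e-1,
                                 c1 = 3.64e-2, c2 = 3.43e-4,
                                 k10 = 5.2e-1, k11 = 1.35,
                                 k1 = 2.08e-1, k3 = 6.91e-1, k7 = 1.155e-2,
                                 k5 = 8.8, k6 = 400, k9 = 4.0,
                                 k2 = 1.0, k4 = 1.0, k8 = 1.0,
                                 mu_s = 1.0397, mu_f = 3.151e-1,
                                 mu_a = 2.17e-2, mu_r = 1.444e-1,
                                 k_ohsv = 0.01 * 2.2e8) {
  p <- list(kSB = kSB, k12 = k12, k13 = k13, c1 = c1, c2 = c2,
            k10 = k10, k11 = k11, k1 = k1, k3 = k3, k7 = k7,
            k5 = k5, k6 = k6, k9 = k9, k2 = k2, k4 = k4, k8 = k8,
            mu_s = mu_s, mu_f = mu_f, mu_a = mu_a, mu_r = mu_r,
            k_ohsv = k_ohsv)
  .check_numeric_fields(p, positive = TRUE, what = "intracellular_params")
  structure(p, class = "intracellular_params")
}

#' Reference concentration and density scales
#'
#' Reference values used to report intracellular outputs in dimensionless
#' form (S/S*, F/F*, A/A*, R/R*) and to nondimensionalize the tissue-level
#' fields (x/x*, y/y*, n/n*, v/v*, B/B*).
#'
#' @param S_star,F_star,A_star,R_star intracellular reference concentrations
#'   (µM).
#' @param x_star,y_star,n_star cell density scales (cells/mm^3).
#' @param v_star virus density scale (virus/mm^3).
#' @param B_star BTZ concentration scale (g/mm^3).
#' @return A named list of class `"reference_scales"`.
#' @export
reference_scales <- function(S_star = 0.05, F_star = 0.5, A_star = 0.1,
                             R_star = 5.0, x_star = 1e6, y_star = 1e6,
                             n_star = 1e6, v_star = 2.2e8, B_star = 1.0e-11) {
  p <- list(S_star = S_star, F_star = F_star, A_star = A_star,
            R_star = R_star, x_star = x_star, y_star = y_star,
            n_star = n_star, v_star = v_star, B_star = B_star)
  .check_numeric_fields(p, positive = TRUE, what = "reference_scales")
  structure(p, class = "reference_scales")
}

#' Tissue-level rate constants
#'
#' Constructor for the dimensional constants of the five-field
#' reaction-diffusion system: random motilities, proliferation, infection,
#' lysis, burst, clearance and BTZ supply/consumption. Defaults are the
#' published parameter set for the distributed variables. All fields must be
#' non-negative and the carrying capacity `x0` strictly positive.
#'
#' @param D1,D2,Dv,DB random motilities / diffusion coefficients of
#'   uninfected cells, infected cells, virus and BTZ (mm^2/h).
#' @param lambda proliferation rate of uninfected cells (1/h).
#' @param x0 carrying capacity (cells/mm^3).
#' @param beta virus infection rate (mm^3/(h virus)).
#' @param beta1 BTZ-induced apoptosis rate (mm^3/(g h)).
#' @param beta3 necroptosis rate in the presence of OVs (mm^3/(g h)); the
#'   coefficient pairs with the BTZ concentration, the only dimensionally
#'   consistent reading (see the methods vignette).
#' @param b burst size of lysed infected cells (dimensionless).
#' @param alpha1 BTZ enhancement of viral replication (mm^3/g).
#' @param IB BTZ supply rate (g/(mm^3 h)).
#' @param delta infected-cell lysis rate (1/h).
#' @param mu removal rate of dead cells (1/h).
#' @param gamma clearance rate of free virus (1/h).
#' @param mu1,mu2 BTZ consumption rates by uninfected/infected cells (1/h).
#' @param muB BTZ decay rate (1/h).
#' @param kB half-saturation of BTZ consumption (g/mm^3).
#' @return A named list of class `"spatial_params"`.
#' @export
spatial_params <- function(D1 = 3.6e-6, D2 = 3.6e-9, Dv = 3.89e-2,
                           DB = 2.5e-2, lambda = 4.2e-1, x0 = 1e6,
                           beta = 2.43e-11, beta1 = 8.0e8, beta3 = 1.37e3,
                           b = 1.1364e1, alpha1 = 1e11, IB = 1.8e-12,
                           delta = 8.2e-2, mu = 1.04e-1, gamma = 1.8e-3,
                           mu1 = 2.075e-9, mu2 = 2.075e-9, muB = 3.47e-2,
                           kB = 1.0e-11) {
  p <- list(D1 = D1, D2 = D2, Dv = Dv, DB = DB, lambda = lambda, x0 = x0,
            beta = beta, beta1 = beta1, beta3 = beta3, b = b,
            alpha1 = alpha1, IB = IB, delta = delta, mu = mu, gamma = gamma,
            mu1 = mu1, mu2 = mu2, muB = muB, kB = kB)
  .check_numeric_fields(p, positive = FALSE, what = "spatial_params")
  if (p$x0 <= 0) stop("spatial_params: 'x0' must be strictly positive")
  structure(p, class = "spatial_params")
}

#' Cell-death classifier thresholds
#'
#' Thresholds on the scaled steady-state levels of NF-kB--Bcl2 (`thF`), Bax
#' (`thA`) and RIP1 (`thR`) defining the anti-apoptotic, apoptotic and
#' necroptotic regions of (F, A, R) space. The defaults place all three at
#' the NF-kB expression level at the BTZ crossover.
#'
#' @param thF,thA,thR strictly positive thresholds in units of the
#'   respective reference scales.
#' @return A named list of class `"classifier_thresholds"`.
#' @export
classifier_thresholds <- function(thF = 1.7, thA = 1.7, thR = 1.7) {
  p <- list(thF = thF, thA = thA, thR = thR)
  .check_numeric_fields(p, positive = TRUE, what = "classifier_thresholds")
  structure(p, class = "classifier_thresholds")
}

#' Full default parameter set
#'
#' @return A list with components `intracellular`, `spatial`, `scales` and
#'   `thresholds`, each a validated constructor default.
#' @export
default_params <- function() {
  list(intracellular = intracellular_params(),
       spatial = spatial_params(),
       scales = reference_scales(),
       thresholds = classifier_thresholds())
}

.check_numeric_fields <- function(p, positive, what) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("%s: '%s' must be a finite numeric scalar", what, nm))
    if (positive && v <= 0)
      stop(sprintf("%s: '%s' must be strictly positive (got %g)", what, nm, v))
    if (!positive && v < 0)
      stop(sprintf("%s: '%s' must be non-negative (got %g)", what, nm, v))
  }
  invisible(TRUE)
}

# flat key -> component lookup used by load_params/save_params
.param_groups <- function() {
  list(intracellular = names(intracellular_params()),
       spatial = names(spatial_params()),
       scales = names(reference_scales()),
       thresholds = names(classifier_thresholds()))
}

#' Load a parameter set from a configuration document
#'
#' Reads a flat key-value document (JSON or YAML, decided by the file
#' extension, or an already-parsed named list) and returns the four
#' parameter objects with any omitted keys at their defaults. Unknown keys
#' are rejected by name; values violating a positivity invariant are
#' rejected by the constructors.
#'
#' @param source path to a `.json`/`.yaml`/`.yml` file, or a named list.
#' @return A list as returned by [default_params()].
#' @export
#' @examples
#' p <- load_params(list(k5 = 8.8))
#' p$intracellular$k5
load_params <- function(source) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("load_params: no such file: ", source)
    ext <- tolower(tools::file_ext(source))
    doc <- switch(ext,
      json = jsonlite::fromJSON(source, simplifyVector = TRUE),
      yaml = ,
      yml  = yaml::read_yaml(source),
      stop("load_params: unsupported extension '", ext,
           "' (use .json, .yaml or .yml)"))
  } else if (is.list(source)) {
    doc <- source
  } else {
    stop("load_params: 'source' must be a file path or a named list")
  }
  doc <- as.list(doc)
  if (length(doc) && (is.null(names(doc)) || any(!nzchar(names(doc)))))
    stop("load_params: document entries must all be named")
  groups <- .param_groups()
  known <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("load_params: unknown key(s): ", paste(unknown, collapse = ", "))
  bad <- names(doc)[!vapply(doc, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad))
    stop("load_params: non-numeric value for key(s): ",
         paste(bad, collapse = ", "))
  doc <- lapply(doc, as.numeric)
  pick <- function(keys) doc[intersect(names(doc), keys)]
  list(intracellular = do.call(intracellular_params, pick(groups$intracellular)),
       spatial = do.call(spatial_params, pick(groups$spatial)),
       scales = do.call(reference_scales, pick(groups$scales)),
       thresholds = do.call(classifier_thresholds, pick(groups$thresholds)))
}

#' Save a parameter set to a configuration document
#'
#' Writes the flattened key-value form of a parameter set at full double
#' precision, so that `load_params(save_params(p, f))` round-trips
#' bit-exactly. The format is chosen by extension (JSON or YAML).
#'
#' @param params a list as returned by [default_params()] or [load_params()].
#' @param path output file path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  stopifnot(is.list(params),
            all(c("intracellular", "spatial", "scales", "thresholds")
                %in% names(params)))
  flat <- c(unclass(params$intracellular), unclass(params$spatial),
            unclass(params$scales), unclass(params$thresholds))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    # full round-trip precision: 17 significant digits
    txt <- paste0("{\n", paste(sprintf("  \"%s\": %.17g", names(flat),
                                       unlist(flat)), collapse = ",\n"),
                  "\n}\n")
    writeLines(txt, path)
  } else if (ext %in% c("yaml", "yml")) {
    # exponential form with a decimal point: YAML floats require one
    txt <- paste(sprintf("%s: %.17e", names(flat), unlist(flat)),
                 collapse = "\n")
    writeLines(txt, path)
  } else {
    stop("save_params: unsupported extension '", ext, "'")
  }
  invisible(path)
}

#' @export
print.intracellular_params <- function(x, ...) {
  cat("Intracellular rate constants (uM, h):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.spatial_params <- function(x, ...) {
  cat("Tissue-level rate constants (mm, h, dimensional):\n")
  print(unlist(unclass(x)))
  invisible(x)
}
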