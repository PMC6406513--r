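#' Uniform grid on the unit square
#'
#' Node-centered regular grid on \eqn{\Omega = [0,1]^2} with spacings
#' `hx = 1/(nx-1)`, `hy = 1/(ny-1)` (default 0.01). Field matrices are
#' indexed `[i, j]` with `i` along x and `j` along y.
#'
#' @param nx,ny number of nodes per side (at least 3).
#' @return A list of class `"pde_grid"` with `nx`, `ny`, `hx`, `hy` and the
#'   node coordinate vectors `x`, `y`.
#' @export
make_grid <- function(nx = 101, ny = nx) {
  stopifnot(nx >= 3, ny >= 3)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 hx = 1 / (nx - 1), hy = 1 / (ny - 1),
                 x = seq(0, 1, length.out = nx),
                 y = seq(0, 1, length.out = ny)),
            class = "pde_grid")
}

#' Five-field state container
#'
#' Bundles the five dimensionless field matrices of the tissue model on a
#' shared grid: uninfected cells `x`, infected cells `y`, dead cells `n`,
#' free virus `v` and BTZ `B` (each scaled by its reference value).
#'
#' @param grid a [make_grid()] object.
#' @param x,y,n,v,B matrices conformal with the grid, or scalars.
#' @return A list of class `"field_set"` with the grid in attribute
#'   `"grid"`.
#' @export
field_set <- function(grid, x = 0, y = 0, n = 0, v = 0, B = 0) {
  expand <- function(m) {
    if (length(m) == 1L) m <- matrix(m, grid$nx, grid$ny)
    stopifnot(is.matrix(m), nrow(m) == grid$nx, ncol(m) == grid$ny)
    if (any(!is.finite(m)) || any(m < 0))
      stop("field_set: fields must be finite and non-negative")
    m
  }
  structure(list(x = expand(x), y = expand(y), n = expand(n),
                 v = expand(v), B = expand(B)),
            class = "field_set", grid = grid)
}

# harmonic-mean face diffusivities from a node diffusivity matrix;
# returns list(fx = (nx-1) x ny, fy = nx x (ny-1))
#' Harmonic-mean face diffusivities
#'
#' Converts a node diffusivity matrix to face diffusivities (harmonic mean
#' of adjacent nodes; zero propagates as a hard barrier face).
#'
#' @param D node diffusivity matrix, or an existing face list (returned
#'   unchanged).
#' @param grid unused, kept for signature stability.
#' @return A list with face matrices `fx` ((nx-1) x ny) and `fy`
#'   (nx x (ny-1)).
#' @export
face_diffusivities <- function(D, grid = NULL) {
  if (is.list(D)) return(D)           # already face form
  a <- D[-nrow(D), , drop = FALSE]; b <- D[-1, , drop = FALSE]
  s <- a + b
  fx <- ifelse(s > 0, 2 * a * b / pmax(s, .Machine$double.xmin), 0)
  a <- D[, -ncol(D), drop = FALSE]; b <- D[, -1, drop = FALSE]
  s <- a + b
  fy <- ifelse(s > 0, 2 * a * b / pmax(s, .Machine$double.xmin), 0)
  list(fx = fx, fy = fy)
}

# trapezoid quadrature weights of the node-centered grid: boundary nodes
# own half cells, so the weights sum exactly to the domain area
.quad_weights <- function(grid) {
  wx <- rep(grid$hx, grid$nx); wx[c(1, grid$nx)] <- grid$hx / 2
  wy <- rep(grid$hy, grid$ny); wy[c(1, grid$ny)] <- grid$hy / 2
  outer(wx, wy)
}

# apply the discrete flux-form diffusion operator along x:  (A_x w)
# fx: (nx-1) x ny face diffusivities, zero-flux boundaries; boundary nodes
# are half-width finite volumes so the trapezoid measure is conserved
.op_x <- function(W, fx, hx) {
  nx <- nrow(W)
  flux <- fx * (W[-1, , drop = FALSE] - W[-nx, , drop = FALSE])  # faces
  out <- matrix(0, nx, ncol(W))
  out[-nx, ] <- flux
  out[-1, ] <- out[-1, , drop = FALSE] - flux
  out[1, ] <- 2 * out[1, ]
  out[nx, ] <- 2 * out[nx, ]
  out / hx^2
}

.op_y <- function(W, fy, hy) t(.op_x(t(W), t(fy), hy))

# batched Thomas solve of (I - r * A_x) W = D along the first dimension,
# vectorized over columns; sub/sup diagonals derive from face values.
.solve_x <- function(D, fx, hx, r) {
  nx <- nrow(D); ny <- ncol(D)
  s <- r / hx^2
  vol <- rep(1, nx); vol[c(1, nx)] <- 2     # half-cell boundary volumes
  low <- rbind(matrix(0, 1, ny), -s * vol[-1] * fx)     # a[i] couples i-1
  up <- rbind(-s * vol[-nx] * fx, matrix(0, 1, ny))     # c[i] couples i+1
  diagm <- matrix(1, nx, ny)
  diagm[-nx, ] <- diagm[-nx, , drop = FALSE] + s * vol[-nx] * fx
  diagm[-1, ] <- diagm[-1, , drop = FALSE] + s * vol[-1] * fx
  # forward elimination
  cp <- up; dp <- D; bp <- diagm
  for (i in 2:nx) {
    m <- low[i, ] / bp[i - 1, ]
    bp[i, ] <- bp[i, ] - m * cp[i - 1, ]
    dp[i, ] <- dp[i, ] - m * dp[i - 1, ]
  }
  if (any(abs(bp) < .Machine$double.xmin))
    stop("diffuse_step: singular tridiagonal system")
  W <- matrix(0, nx, ny)
  W[nx, ] <- dp[nx, ] / bp[nx, ]
  for (i in (nx - 1):1)
    W[i, ] <- (dp[i, ] - cp[i, ] * W[i + 1, ]) / bp[i, ]
  W
}

.solve_y <- function(D, fy, hy, r) t(.solve_x(t(D), t(fy), hy, r))

#' One ADI diffusion step
#'
#' Advances a single field by `dt` under \eqn{\partial_t w = \nabla\cdot(D
#' \nabla w)} with homogeneous Neumann (no-flux) boundaries, using the
#' Peaceman-Rachford alternating-direction-implicit pair (an implicit
#' half-sweep in x against an explicit half-sweep in y, then the reverse).
#' Face diffusivities are harmonic means of adjacent node values; zero
#' faces act as hard reflecting barriers. The flux-form stencil conserves
#' the discrete total exactly and the scheme is unconditionally stable for
#' pure diffusion.
#'
#' @param field matrix conformal with `grid`.
#' @param D_map node diffusivity matrix, or a list `fx`, `fy` of face
#'   diffusivities (as produced internally for barrier masks).
#' @param dt time step (h), strictly positive.
#' @param grid a [make_grid()] object.
#' @return The advanced field matrix.
#' @export
diffuse_step <- function(field, D_map, dt, grid) {
  stopifnot(dt > 0)
  f <- face_diffusivities(D_map)
  r <- dt / 2
  W1 <- .solve_x(field + r * .op_y(field, f$fy, grid$hy), f$fx, grid$hx, r)
  .solve_y(W1 + r * .op_x(W1, f$fx, grid$hx), f$fy, grid$hy, r)
}
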