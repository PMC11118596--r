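#' Tissue energy
#'
#' Dimensionless two-type energy of a tessellated configuration,
#' \deqn{e = \sum_{res} \tfrac12 (a - a_{0})^2 + \tfrac{\bar\Gamma_r}{2}(p - p_{0})^2
#'       + \sum_{mut} \tfrac{\bar K}{2}(a - a_{0})^2 + \tfrac{\bar\Gamma_m}{2}(p - p_{0})^2,}
#' each cell using its own type's preferred values and elasticities (the
#' resident area elasticity is the energy unit, \eqn{\bar K_r = 1}).
#'
#' @param tess a [build_tessellation()] result.
#' @param params an [spv_params()] pair (or a single [type_params()]).
#' @param labels character type labels, one per cell.
#' @return list with `total`, `area_part`, `perimeter_part` and `per_cell`.
#' @export
tissue_energy <- function(tess, params, labels) {
  if (length(labels) != tess$n)
    stop("labels length does not match the tessellation")
  pm <- par_matrix(params)
  t_ <- as_type_int(labels) + 1L
  da <- tess$areas - pm["a0", t_]
  dp <- tess$perimeters - pm["p0", t_]
  wa <- 0.5 * pm["k", t_] * da^2
  wp <- 0.5 * pm["gamma", t_] * dp^2
  list(total = sum(wa) + sum(wp), area_part = sum(wa),
       perimeter_part = sum(wp), per_cell = wa + wp)
}

#' Forces on the cell centers
#'
#' Minus the exact gradient of the tissue energy with respect to every cell
#' center, accounting for the motion of all Voronoi vertices the center
#' generates (each vertex is the circumcenter of its three generators, so a
#' center moves its own polygon and its Voronoi neighbors' polygons). The net
#' force is zero by translation invariance on the torus.
#'
#' @param state a [tissue_state()].
#' @param box a [tissue_box()].
#' @param params an [spv_params()] pair (or single [type_params()]).
#' @return N x 2 matrix of forces, with the total energy as attribute
#'   `"energy"`.
#' @seealso [tissue_forces_fd()] for the finite-difference oracle.
#' @export
tissue_forces <- function(state, box, params) {
  r <- .cpp_forces(state$positions[, 1], state$positions[, 2], box$side,
                   as_type_int(state$types), par_matrix(params))
  structure(r$forces, energy = r$energy)
}

#' Finite-difference forces (oracle)
#'
#' Central-difference gradient of the energy, one tessellation per
#' perturbation. O(N) times more expensive than [tissue_forces()]; intended as
#' an independent check of the analytic geometry calculus, not for production
#' runs.
#'
#' @inheritParams tissue_forces
#' @param h central-difference step.
#' @return N x 2 matrix of forces.
#' @export
tissue_forces_fd <- function(state, box, params, h = 1e-6) {
  pm <- par_matrix(params)
  ty <- as_type_int(state$types)
  x <- state$positions[, 1]; y <- state$positions[, 2]
  e_of <- function(x, y) .cpp_energy(x, y, box$side, ty, pm)$total
  n <- length(x)
  f <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    xp <- x; xm <- x; xp[i] <- x[i] + h; xm[i] <- x[i] - h
    f[i, 1] <- -(e_of(xp, y) - e_of(xm, y)) / (2 * h)
    yp <- y; ym <- y; yp[i] <- y[i] + h; ym[i] <- y[i] - h
    f[i, 2] <- -(e_of(x, yp) - e_of(x, ym)) / (2 * h)
  }
  f
}

#' Per-cell hydrostatic pressure
#'
#' Signed dimensionless pressure of each cell,
#' \deqn{\mathcal{P} = -\bar K (a - a_0) - \frac{\bar\Gamma p}{2a}(p - p_0),}
#' using the cell's own type's parameters. Positive pressure means the cell is
#' compressed below its preferred geometry.
#'
#' @inheritParams tissue_energy
#' @return numeric vector of per-cell pressures.
#' @export
cell_pressure <- function(tess, params, labels) {
  if (length(labels) != tess$n)
    stop("labels length does not match the tessellation")
  pm <- par_matrix(params)
  t_ <- as_type_int(labels) + 1L
  a <- tess$areas; p <- tess$perimeters
  unname(-pm["k", t_] * (a - pm["a0", t_]) -
           pm["gamma", t_] * p / (2 * a) * (p - pm["p0", t_]))
}
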