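#' Simulate the tissue
#'
#' Advances the configuration by the overdamped active equations of motion
#' (forward Euler for positions, Euler--Maruyama for the polarization angles),
#' optionally coupled to the stochastic birth-death process. One Voronoi
#' tessellation and one analytic force evaluation are performed per step;
#' birth/death rates are frozen at each step's geometry and events are sampled
#' within the step interval (a warning is raised if `total_rate * dt` exceeds
#' 0.1, where that approximation degrades).
#'
#' All randomness flows through R's RNG: call `set.seed()` (or pass `seed`)
#' for bitwise-reproducible trajectories.
#'
#' @param state a [tissue_state()].
#' @param box a [tissue_box()].
#' @param params an [spv_params()] pair (or single [type_params()]).
#' @param n_steps number of time steps.
#' @param dt time step (default 0.01, so 1 time unit = 100 steps).
#' @param record_every record observables every this many steps.
#' @param coupling growth coupling: `"none"` (no birth/death), `"area"`
#'   (density regulation, requires `beta = 0`), `"general_beta"` (area plus
#'   beta-weighted perimeter stimulus), or `"pressure"` (rates driven by the
#'   deviation of the cell pressure from the homeostatic pressure `ph`).
#' @param ph homeostatic pressures, a [calibrate_homeostatic_pressure()]
#'   result (required for `coupling = "pressure"`).
#' @param div_offset division offset as a fraction of the parent cell's linear
#'   size: children are placed at the parent center +/- `div_offset *
#'   sqrt(a_parent)` along a uniformly random direction.
#' @param record_cells also record per-cell areas/perimeters at every recorded
#'   frame (used by [estimate_c()]).
#' @param seed optional seed applied before the run.
#' @param quiet suppress rate warnings.
#' @return an object of class `spv_run`: list with the final `state`,
#'   `observables` (one row per recorded frame: time, N, mutant count and
#'   fraction, energy, per-type mean area/perimeter/pressure/growth rate),
#'   `events` (the birth/death log) and optionally `cell_records`.
#' @export
simulate_tissue <- function(state, box, params, n_steps, dt = 0.01,
                            record_every = 100L,
                            coupling = c("none", "area", "pressure",
                                         "general_beta"),
                            ph = NULL, div_offset = 0.05,
                            record_cells = FALSE, seed = NULL, quiet = FALSE) {
  coupling <- match.arg(coupling)
  if (!is.null(seed)) set.seed(seed)
  pm <- par_matrix(params)
  if (coupling == "area" && any(pm["beta", ] != 0))
    stop("coupling = 'area' requires beta = 0; use coupling = 'general_beta'")
  code <- switch(coupling, none = 0L, area = 1L, general_beta = 1L, pressure = 2L)
  phv <- c(0, 0)
  if (coupling == "pressure") {
    if (!inherits(ph, "pressure_coupling"))
      stop("pressure coupling requires a calibrated homeostatic pressure; ",
           "see calibrate_homeostatic_pressure()")
    phv <- ph$ph
  }
  r <- .cpp_simulate(state$positions[, 1], state$positions[, 2], state$angles,
                     as_type_int(state$types), state$ids, box$side, pm,
                     dt, as.integer(n_steps), as.integer(record_every),
                     code, phv, div_offset, state$time, state$next_id,
                     record_cells, quiet)
  out_state <- tissue_state(cbind(r$x, r$y), box, angles = r$theta,
                            types = type_codes[r$type + 1L], time = r$time,
                            ids = r$id)
  out_state$next_id <- r$next_id
  structure(list(state = out_state, observables = r$observables,
                 events = r$events, cell_records = r$cell_records),
            class = "spv_run")
}

#' @export
print.spv_run <- function(x, ...) {
  o <- x$observables
  cat(sprintf("<spv_run> t = %.4g .. %.4g, N = %d .. %d, %d events\n",
              o$time[1], o$time[nrow(o)], o$n[1], o$n[nrow(o)],
              nrow(x$events)))
  invisible(x)
}

#' Advance the tissue by one time step
#'
#' Single forward-Euler step of the equations of motion (no birth/death).
#' Warns if the largest displacement `dt * mu * |F|` exceeds 5% of the mean
#' cell spacing, the usual sign that `dt` is too large for stable integration.
#'
#' @inheritParams simulate_tissue
#' @return the advanced [tissue_state()].
#' @export
step_tissue <- function(state, box, params, dt = 0.01) {
  f <- tissue_forces(state, box, params)
  pm <- par_matrix(params)
  mu <- pm["mobility", as_type_int(state$types) + 1L]
  disp <- dt * mu * sqrt(rowSums(f^2))
  spacing <- box$side / sqrt(n_cells(state))
  if (max(disp) > 0.05 * spacing)
    warning(sprintf("dt * mu * |F| = %.3g exceeds 5%% of the mean cell spacing %.3g; consider a smaller dt",
                    max(disp), spacing))
  simulate_tissue(state, box, params, n_steps = 1L, dt = dt,
                  record_every = 1L, coupling = "none", quiet = TRUE)$state
}

#' Relax a tissue to a nearby energy minimum
#'
#' Gradient-descent burn-in: applies [simulate_tissue()] with self-propulsion
#' and angular noise switched off (`v0 = 0`, `D_r = 0`). Used to initialize
#' experiments and to calibrate the homeostatic pressure.
#'
#' @inheritParams simulate_tissue
#' @param n_steps number of descent steps.
#' @return the relaxed [tissue_state()].
#' @export
relax_tissue <- function(state, box, params, n_steps = 500L, dt = 0.01) {
  if (inherits(params, "type_params")) params <- spv_params(params, params)
  quiet_pair <- spv_params(
    resident = utils::modifyList(unclass(params$resident), list(v0 = 0, d_r = 0)),
    mutant = utils::modifyList(unclass(params$mutant), list(v0 = 0, d_r = 0)))
  simulate_tissue(state, box, quiet_pair, n_steps = n_steps, dt = dt,
                  record_every = max(1L, as.integer(n_steps)),
                  coupling = "none", quiet = TRUE)$state
}
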