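#' Birth and death rates under area coupling
#'
#' Mechanics-regulated rates with stimulus \eqn{x_i = (a_i - a_0) + \beta (p_i - p_0)}:
#' \deqn{r^b_i = r^{b0} + \lambda \max(0, x_i), \qquad
#'       r^d_i = r^{d0} - \lambda \min(0, x_i),}
#' each cell using its own type's parameters. The min/max clipping keeps both
#' rates non-negative while the net growth rate is exactly
#' \eqn{g_i = (r^{b0}-r^{d0}) + \lambda x_i}. With `beta = 0` (density
#' regulation) and symmetric basal rates, the population mean obeys the exact
#' identity \eqn{\langle g \rangle = \lambda (N_0/N - a_0)} because the cell
#' areas partition the box.
#'
#' @param tess a [build_tessellation()] result.
#' @param params an [spv_params()] pair (or single [type_params()]).
#' @param labels character type labels, one per cell.
#' @return an object of class `growth_rates`: list with per-cell `birth`,
#'   `death` and net `growth` rates.
#' @export
rates_area <- function(tess, params, labels) {
  pm <- par_matrix(params)
  t_ <- as_type_int(labels) + 1L
  x <- (tess$areas - pm["a0", t_]) +
    pm["beta", t_] * (tess$perimeters - pm["p0", t_])
  clip_rates(x, pm, t_)
}

#' Birth and death rates under pressure coupling
#'
#' Same clipped linear response as [rates_area()], with the stimulus replaced
#' by the deviation of the cell's hydrostatic pressure from the calibrated
#' homeostatic pressure of its type:
#' \eqn{x_i = \mathcal{P}_i - \mathcal{P}^h}.
#'
#' @inheritParams rates_area
#' @param coupling a [calibrate_homeostatic_pressure()] result.
#' @return a `growth_rates` object.
#' @export
rates_pressure <- function(tess, params, labels, coupling) {
  if (!inherits(coupling, "pressure_coupling"))
    stop("rates_pressure needs a calibrated 'pressure_coupling' object")
  pm <- par_matrix(params)
  t_ <- as_type_int(labels) + 1L
  x <- cell_pressure(tess, params, labels) - coupling$ph[t_]
  clip_rates(x, pm, t_)
}

clip_rates <- function(x, pm, t_) {
  lam <- pm["lam", t_]
  structure(list(birth = unname(pm["rb0", t_] + lam * pmax(0, x)),
                 death = unname(pm["rd0", t_] - lam * pmin(0, x)),
                 growth = unname((pm["rb0", t_] - pm["rd0", t_]) + lam * x)),
            class = "growth_rates")
}

#' Calibrate the homeostatic pressure
#'
#' Relaxes a copy of the tissue and returns the per-type population-mean
#' pressure, the unique homeostatic value at which the mean growth rate of the
#' initial configuration vanishes so the cell number is maintained on average.
#' In a solid-like tissue relaxed from a random start, the calibrated value is
#' negative: a residual pre-stress that gradient descent cannot relax.
#'
#' @inheritParams simulate_tissue
#' @param n_relax gradient-descent steps before measuring.
#' @return an object of class `pressure_coupling` with field `ph` (length 2,
#'   resident and mutant).
#' @export
calibrate_homeostatic_pressure <- function(state, box, params,
                                           n_relax = 500L, dt = 0.01) {
  relaxed <- relax_tissue(state, box, params, n_steps = n_relax, dt = dt)
  tess <- build_tessellation(relaxed, box)
  P <- cell_pressure(tess, params, relaxed$types)
  ph <- c(resident = NaN, mutant = NaN)
  for (ty in type_codes)
    if (any(relaxed$types == ty)) ph[ty] <- mean(P[relaxed$types == ty])
  if (is.nan(ph["mutant"])) ph["mutant"] <- ph["resident"]
  if (is.nan(ph["resident"])) ph["resident"] <- ph["mutant"]
  structure(list(ph = unname(ph)), class = "pressure_coupling")
}

#' Divide a cell
#'
#' Topological division move: the parent center is removed and two children
#' are created at `parent +/- d * n`, where `n` is the unit normal to a
#' division segment of uniformly random angle through the cell center and
#' `d = offset_frac * sqrt(a_parent)`. Children inherit the parent's type and
#' draw fresh independent polarization angles; on retessellation their Voronoi
#' cells approximately bisect the parent along the segment.
#'
#' @param state a [tissue_state()].
#' @param box a [tissue_box()].
#' @param cell index of the dividing cell (position in the state, not id).
#' @param offset_frac child offset as a fraction of the parent linear size.
#' @return the new [tissue_state()] with N + 1 cells.
#' @export
divide_cell <- function(state, box, cell, offset_frac = 0.05) {
  n <- n_cells(state)
  stopifnot(cell >= 1, cell <= n)
  tess <- build_tessellation(state, box)
  d <- offset_frac * sqrt(tess$areas[cell])
  parent <- state$positions[cell, ]
  others <- state$positions[-cell, , drop = FALSE]
  for (try in 1:32) {
    phi <- stats::runif(1, 0, 2 * pi)
    nrm <- c(-sin(phi), cos(phi)) # normal to the division segment
    ch <- rbind(parent + d * nrm, parent - d * nrm)
    ch <- wrap_positions(ch, box)
    dmin <- min(apply(ch, 1, function(p) {
      dd <- minimum_image(others, matrix(p, nrow(others), 2, byrow = TRUE), box)
      sqrt(min(rowSums(dd^2)))
    }))
    if (dmin > 1e-9) {
      pos <- rbind(state$positions[-cell, , drop = FALSE], ch)
      ang <- c(state$angles[-cell], stats::runif(2, 0, 2 * pi))
      typ <- c(state$types[-cell], rep(state$types[cell], 2))
      ids <- c(state$ids[-cell], state$next_id, state$next_id + 1L)
      out <- tissue_state(pos, box, angles = ang, types = typ,
                          time = state$time, ids = ids)
      out$next_id <- state$next_id + 2L
      return(out)
    }
  }
  stop("could not place division children away from existing centers")
}

#' Extrude (remove) a cell
#'
#' Cell death/extrusion: the center is removed and, on retessellation, the
#' neighbors absorb exactly the removed cell's area.
#'
#' @inheritParams divide_cell
#' @return the new [tissue_state()] with N - 1 cells.
#' @export
extrude_cell <- function(state, box, cell) {
  n <- n_cells(state)
  stopifnot(cell >= 1, cell <= n)
  if (n <= 3) stop("refusing to extrude: a tissue needs at least 3 cells")
  out <- tissue_state(state$positions[-cell, , drop = FALSE], box,
                      angles = state$angles[-cell],
                      types = state$types[-cell],
                      time = state$time, ids = state$ids[-cell])
  out$next_id <- state$next_id
  out
}

#' One coupled mechanics + birth-death step
#'
#' Convenience wrapper for a single step of [simulate_tissue()] with a growth
#' coupling: one mechanical step, then birth/death events sampled at the
#' frozen rates.
#'
#' @inheritParams simulate_tissue
#' @return list with the advanced `state` and the `events` sampled this step.
#' @export
growth_step <- function(state, box, params, dt = 0.01, coupling = "area",
                        ph = NULL, div_offset = 0.05) {
  r <- simulate_tissue(state, box, params, n_steps = 1L, dt = dt,
                       record_every = 1L, coupling = coupling, ph = ph,
                       div_offset = div_offset, quiet = TRUE)
  list(state = r$state, events = r$events)
}

#' Grow a tissue under a mechanics-coupled birth-death process
#'
#' Runs the full coupled dynamics (default: area coupling / density
#' regulation). Under area coupling the cell number is attracted to the
#' carrying capacity \eqn{N_{SS} = N_0 / a_0}; without mechanical coupling
#' (`lam = 0`, `r0 > 0`) the cell number performs an unbiased random walk with
#' variance growing in time.
#'
#' @inheritParams simulate_tissue
#' @return an `spv_run` (see [simulate_tissue()]).
#' @export
grow_tissue <- function(state, box, params, n_steps, dt = 0.01,
                        record_every = 100L, coupling = "area", ph = NULL,
                        div_offset = 0.05, seed = NULL, quiet = FALSE) {
  simulate_tissue(state, box, params, n_steps = n_steps, dt = dt,
                  record_every = record_every, coupling = coupling, ph = ph,
                  div_offset = div_offset, seed = seed, quiet = quiet)
}

#' Replay an event log
#'
#' Reconstructs the cell count over time from a birth/death event log, for
#' consistency checks against recorded observables.
#'
#' @param events event data frame from an `spv_run`.
#' @param n0 cell count at the start of the log.
#' @return data frame with columns `time` and `n` after each event.
#' @export
replay_events <- function(events, n0) {
  if (nrow(events) == 0) return(data.frame(time = numeric(), n = integer()))
  delta <- ifelse(events$event == "birth", 1L, -1L)
  data.frame(time = events$time, n = n0 + cumsum(delta))
}

#' Write an event log CSV
#' @param events event data frame from an `spv_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an observables CSV
#' @param observables observables data frame from an `spv_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_observables <- function(observables, path) {
  utils::write.csv(observables, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
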