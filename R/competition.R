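#' Fitness estimate container
#'
#' A selection coefficient with its provenance.
#'
#' @param s selection coefficient (per time unit): growth-rate difference
#'   mutant minus resident.
#' @param stderr uncertainty of `s`.
#' @param method one of `"invasion_fit"`, `"mixture"`, `"meanfield_area"`,
#'   `"meanfield_perimeter"`.
#' @param window fitted time range (invasion fits), or `NULL`.
#' @param ... extra fields stored alongside (e.g. curvature diagnostics).
#' @return an object of class `fitness_estimate`.
#' @export
fitness_estimate <- function(s, stderr = NA_real_, method, window = NULL, ...) {
  structure(list(s = s, stderr = stderr, method = method, window = window, ...),
            class = "fitness_estimate")
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(sprintf("<fitness_estimate> s = %+.5g (se %.3g), method = %s\n",
              x$s, x$stderr, x$method))
  invisible(x)
}

#' Invasion experiment design
#'
#' Parameters of a mutant-invasion experiment: a droplet (or random sprinkle)
#' of mutants with initial fraction `initial_fraction` is introduced into an
#' equilibrated resident tissue and the coupled growth dynamics is run until
#' `horizon` time units, replicated `n_replicates` times.
#'
#' @param resident,mutant [type_params()] (or override lists, see
#'   [spv_params()]).
#' @param n0 initial cell count.
#' @param initial_fraction initial mutant fraction in (0, 1).
#' @param placement `"droplet"` (contiguous patch) or `"random"`.
#' @param n_replicates number of identical stochastic replicates.
#' @param horizon run length in time units.
#' @param dt,record_every integrator settings (1 time unit = `1/dt` steps).
#' @param relax_steps gradient-descent steps equilibrating the resident tissue
#'   before the droplet is introduced.
#' @param f_window logit fits exclude frames with `min(f, 1-f)` below this.
#' @param coupling growth coupling for the run (default `"area"`).
#' @param div_offset division offset fraction.
#' @return an object of class `invasion_design`.
#' @export
invasion_design <- function(resident = type_params(), mutant = resident,
                            n0 = 400, initial_fraction = 0.1,
                            placement = c("droplet", "random"),
                            n_replicates = 10, horizon = 25, dt = 0.01,
                            record_every = 50L, relax_steps = 300L,
                            f_window = 0.02, coupling = "area",
                            div_offset = 0.05) {
  placement <- match.arg(placement)
  if (!is.numeric(initial_fraction) || initial_fraction <= 0 ||
      initial_fraction >= 1)
    stop("initial_fraction must lie strictly between 0 and 1")
  if (ceiling(initial_fraction * n0) < 1)
    stop("initial_fraction * n0 must round up to at least one mutant")
  structure(list(params = spv_params(resident, mutant), n0 = n0,
                 initial_fraction = initial_fraction, placement = placement,
                 n_replicates = n_replicates, horizon = horizon, dt = dt,
                 record_every = as.integer(record_every),
                 relax_steps = as.integer(relax_steps), f_window = f_window,
                 coupling = coupling, div_offset = div_offset),
            class = "invasion_design")
}

#' Initial configuration of an invasion experiment
#'
#' Draws a uniformly random resident tissue, relaxes it to a nearby energy
#' minimum with the resident parameters, then labels the initial mutants:
#' `"droplet"` placement labels the `ceiling(f * N0)` cells nearest a random
#' point, `"random"` placement labels a uniform sample of that size.
#'
#' @param design an [invasion_design()].
#' @param box the periodic box (defaults to `tissue_box(design$n0)`).
#' @param seed optional seed (the droplet location is deterministic given it).
#' @return a labelled [tissue_state()].
#' @export
init_invasion <- function(design, box = tissue_box(design$n0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- make_fixture("random", design$n0, box)
  st <- relax_tissue(st, box, design$params$resident,
                     n_steps = design$relax_steps, dt = design$dt)
  if (design$placement == "droplet") {
    label_droplet(st, box, design$initial_fraction)
  } else {
    k <- ceiling(design$initial_fraction * design$n0)
    st$types[sample.int(design$n0, k)] <- "mutant"
    st
  }
}

#' Run an invasion experiment
#'
#' Evolves `n_replicates` independent invasions under the design's growth
#' coupling and fits the selection coefficient from the logistic fraction
#' dynamics: under frequency-independent selection
#' \eqn{\ln(f/(1-f)) = s t + const}, so `s` is the least-squares slope of the
#' replicate-averaged logit over the window where the mean fraction stays
#' inside `(f_window, 1 - f_window)`. A quadratic term fitted alongside serves
#' as a frequency-independence diagnostic (its estimate and standard error are
#' returned).
#'
#' @param design an [invasion_design()].
#' @param seed integer seed; replicate r uses a sub-seed derived from it.
#' @return list with `trajectory` (data frame: replicate, time, n, f, logit)
#'   and `fit` (a [fitness_estimate()] with fields `curvature`,
#'   `curvature_se`, `flag`).
#' @export
run_invasion <- function(design, seed = 1L) {
  box <- tissue_box(design$n0)
  steps <- round(design$horizon / design$dt)
  trajs <- vector("list", design$n_replicates)
  for (r in seq_len(design$n_replicates)) {
    set.seed(derive_seed(seed, "invasion", r))
    st <- init_invasion(design, box)
    run <- grow_tissue(st, box, design$params, n_steps = steps,
                       dt = design$dt, record_every = design$record_every,
                       coupling = design$coupling,
                       div_offset = design$div_offset, quiet = TRUE)
    o <- run$observables
    trajs[[r]] <- data.frame(replicate = r, time = o$time, n = o$n, f = o$f)
  }
  traj <- do.call(rbind, trajs)
  traj$logit <- ifelse(traj$f > 0 & traj$f < 1,
                       log(traj$f / (1 - traj$f)), NA_real_)
  fit <- fit_invasion_logit(traj, design$f_window)
  list(trajectory = traj, fit = fit)
}

# replicate-averaged logit fit with quadratic diagnostic
fit_invasion_logit <- function(traj, f_window) {
  ag <- stats::aggregate(cbind(logit, f) ~ time, data = traj,
                         FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  keep <- is.finite(ag$logit) & pmin(ag$f, 1 - ag$f) > f_window
  ag <- ag[keep, ]
  flag <- NULL
  if (nrow(ag) < 3) flag <- "fewer than 3 usable points (fixation/extinction?)"
  if (nrow(ag) < 2)
    return(fitness_estimate(NA_real_, NA_real_, "invasion_fit", window = NULL,
                            curvature = NA_real_, curvature_se = NA_real_,
                            flag = flag))
  lin <- stats::lm(logit ~ time, data = ag)
  s <- unname(stats::coef(lin)["time"])
  se <- tryCatch(unname(summary(lin)$coefficients["time", "Std. Error"]),
                 error = function(e) NA_real_)
  curv <- curv_se <- NA_real_
  if (nrow(ag) >= 4) {
    quad <- stats::lm(logit ~ time + I(time^2), data = ag)
    sm <- summary(quad)$coefficients
    if ("I(time^2)" %in% rownames(sm)) {
      curv <- sm["I(time^2)", "Estimate"]
      curv_se <- sm["I(time^2)", "Std. Error"]
    }
  }
  fitness_estimate(s, se, "invasion_fit",
                   window = range(ag$time), curvature = curv,
                   curvature_se = curv_se, flag = flag)
}

#' Non-growing mixture fitness predictor
#'
#' Simulates a 50-50 mutant/resident mixture with the labels fixed and no
#' birth or death, time-averages the realized areas of each type after a
#' burn-in, and predicts the selection coefficient under area coupling as
#' \deqn{s = \lambda [ (\bar a_m - a_{m0}) - (\bar a_r - a_{r0}) ].}
#' The sign of this predictor matches the invasion experiment; the magnitude
#' is generally somewhat different because a growing tissue also fluctuates in
#' cell number.
#'
#' @param resident,mutant [type_params()] (or override lists).
#' @param n0 number of cells in the mixture.
#' @param horizon run length in time units.
#' @param burn_in fraction of the run discarded before averaging.
#' @param dt,record_every integrator settings.
#' @param relax_steps descent steps before the active run.
#' @param seed integer seed.
#' @return a [fitness_estimate()] (method `"mixture"`) with fields `a_bar`
#'   (the two mean areas) and `run` (the recorded mixture run, including
#'   per-cell records for [estimate_c()]).
#' @export
mixture_predictor <- function(resident = type_params(), mutant = resident,
                              n0 = 100, horizon = 40, burn_in = 0.25,
                              dt = 0.01, record_every = 25L,
                              relax_steps = 300L, seed = 1L) {
  params <- spv_params(resident, mutant)
  if (params$resident$beta != 0 || params$mutant$beta != 0)
    stop("the mixture predictor assumes area coupling (beta = 0)")
  box <- tissue_box(n0)
  set.seed(derive_seed(seed, "mixture", 1L))
  st <- make_fixture("half_mixture", n0, box)
  st <- relax_tissue(st, box, params, n_steps = relax_steps, dt = dt)
  run <- simulate_tissue(st, box, params, n_steps = round(horizon / dt),
                         dt = dt, record_every = record_every,
                         coupling = "none", record_cells = TRUE, quiet = TRUE)
  o <- run$observables
  use <- o$time >= o$time[1] + burn_in * (o$time[nrow(o)] - o$time[1])
  am <- mean(o$mean_area_mutant[use]); ar <- mean(o$mean_area_resident[use])
  lam <- params$resident$lam
  if (params$mutant$lam != params$resident$lam)
    warning("types have different lambda; using the resident value in the predictor")
  dev <- (o$mean_area_mutant[use] - params$mutant$a0) -
         (o$mean_area_resident[use] - params$resident$a0)
  s <- lam * mean(dev)
  # stationarity diagnostic: compare the two halves of the averaging window
  half <- seq_along(dev) <= length(dev) / 2
  drift <- abs(mean(dev[half]) - mean(dev[!half]))
  if (drift > 3 * stats::sd(dev) / sqrt(sum(half)) + 1e-12 &&
      drift > 0.5 * (abs(mean(dev)) + 0.01))
    warning("mixture time-average is drifting; consider a longer burn-in or horizon")
  fitness_estimate(s, lam * stats::sd(dev) / sqrt(length(dev)), "mixture",
                   window = range(o$time[use]),
                   a_bar = c(resident = ar, mutant = am), run = run)
}

#' Regular-polygon shape coefficient
#'
#' For a regular n-gon, area and perimeter satisfy \eqn{a = p^2 / c_n} with
#' \eqn{c_n = 4 n \tan(\pi/n)}; for hexagons \eqn{c_6 \approx 13.86}.
#'
#' @param n number of polygon sides (>= 3).
#' @return the coefficient \eqn{c_n}.
#' @export
polygon_shape_coefficient <- function(n = 6) {
  stopifnot(n >= 3)
  4 * n * tan(pi / n)
}

#' Analytic hexagon area-perimeter slope
#'
#' Derivative \eqn{dp/da} at unit area along the regular-hexagon family
#' \eqn{p = \sqrt{c_6 a}}, i.e. \eqn{\sqrt{c_6}/2 \approx 1.861}. This is the
#' default proportionality coefficient `c` of the mean-field fitness formulas
#' in the solid-like phase, where cells are close to regular hexagons.
#'
#' @return the slope \eqn{\sqrt{c_6}/2}.
#' @export
hexagon_slope <- function() sqrt(polygon_shape_coefficient(6)) / 2

#' Estimate the area-perimeter coupling slope c
#'
#' Least-squares slope of the perimeter deviation against the area deviation
#' across cells and recorded frames of a non-growing mixture run (deviations
#' taken from each type's own time-pooled mean). In the solid-like phase the
#' fitted slope is close to the analytic hexagon value [hexagon_slope()]; in
#' the liquid-like phase it is smaller (weaker area-perimeter coupling).
#'
#' @param cell_records per-cell record data frame (`time`, `type`, `area`,
#'   `perimeter`) from a run with `record_cells = TRUE`, or a
#'   [mixture_predictor()] result.
#' @return the fitted slope (falls back to the analytic hexagon value, with a
#'   message, if the area variance is degenerate).
#' @export
estimate_c <- function(cell_records) {
  if (inherits(cell_records, "fitness_estimate"))
    cell_records <- cell_records$run$cell_records
  if (is.null(cell_records) || nrow(cell_records) == 0)
    stop("no per-cell records; run the mixture with record_cells = TRUE")
  a_dev <- p_dev <- numeric(0)
  for (ty in unique(cell_records$type)) {
    sel <- cell_records$type == ty
    a_dev <- c(a_dev, cell_records$area[sel] - mean(cell_records$area[sel]))
    p_dev <- c(p_dev, cell_records$perimeter[sel] - mean(cell_records$perimeter[sel]))
  }
  if (stats::var(a_dev) < 1e-12) {
    message("degenerate area variance; returning the analytic hexagon slope")
    return(hexagon_slope())
  }
  sum(a_dev * p_dev) / sum(a_dev^2)
}

#' Mean-field fitness of a preferred-area mutant
#'
#' Closed-form selection coefficient from energy minimization of a two-cell
#' mean-field mixture under the volume constraint, with the perimeter slaved
#' to the area through the slope `c`:
#' \deqn{s_{MFA} = -\lambda \Delta a_0 \frac{\Gamma c^2}{1 + \Gamma c^2},}
#' where \eqn{\Delta a_0 = a_{m0} - a_{r0}}. A smaller preferred area
#' (\eqn{\Delta a_0 < 0}) is advantageous; the magnitude grows with
#' \eqn{\Gamma} and saturates at \eqn{-\lambda \Delta a_0}.
#'
#' @param delta_a0 preferred-area difference mutant minus resident.
#' @param gamma perimeter elasticity \eqn{\bar\Gamma}.
#' @param lam growth-mechanics coupling \eqn{\lambda}.
#' @param c area-perimeter slope; defaults to the analytic hexagon value
#'   (appropriate in the solid-like phase), use [estimate_c()] otherwise.
#' @return a [fitness_estimate()] (method `"meanfield_area"`).
#' @export
meanfield_fitness_area <- function(delta_a0, gamma = 1, lam = 1,
                                   c = hexagon_slope()) {
  stopifnot(c > 0)
  s <- -lam * delta_a0 * gamma * c^2 / (1 + gamma * c^2)
  fitness_estimate(s, 0, "meanfield_area", c = c)
}

#' Mean-field fitness of a preferred-perimeter mutant
#'
#' Companion closed form to [meanfield_fitness_area()]:
#' \deqn{s_{MFP} = \lambda \Delta p_0 \frac{\Gamma c}{1 + \Gamma c^2},}
#' with \eqn{\Delta p_0 = p_{m0} - p_{r0}}. A larger preferred perimeter is
#' advantageous.
#'
#' @param delta_p0 preferred-perimeter difference mutant minus resident.
#' @inheritParams meanfield_fitness_area
#' @return a [fitness_estimate()] (method `"meanfield_perimeter"`).
#' @export
meanfield_fitness_perimeter <- function(delta_p0, gamma = 1, lam = 1,
                                        c = hexagon_slope()) {
  stopifnot(c > 0)
  s <- lam * delta_p0 * gamma * c / (1 + gamma * c^2)
  fitness_estimate(s, 0, "meanfield_perimeter", c = c)
}

#' Write a fitness summary JSON
#' @param fit a [fitness_estimate()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fitness_json <- function(fit, path) {
  x <- fit[c("s", "stderr", "method", "window")]
  for (nm in c("curvature", "curvature_se", "flag"))
    if (!is.null(fit[[nm]])) x[[nm]] <- fit[[nm]]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
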