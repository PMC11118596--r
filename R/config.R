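#' Default resident parameters
#'
#' Reference values of the resident population used throughout the competition
#' experiments: `a0 = 1`, `gamma = 1`, `k = 1`, `lam = 1`, `r0 = 0`,
#' `v0 = 0.05`, `d_r = 1`, `mu = 1`; the preferred perimeter `p0` selects the
#' phase (3.3 solid-like, 4.0 liquid-like) and is an explicit argument.
#'
#' @param p0 preferred perimeter / shape index.
#' @return a [type_params()] object.
#' @export
reference_resident <- function(p0 = 3.3) {
  type_params(a0 = 1, p0 = p0, gamma = 1, k = 1, lam = 1, r0 = 0,
              v0 = 0.05, d_r = 1, mobility = 1)
}

cfg_schema <- list(
  experiment = c("grow", "invade", "mixture", "meanfield"),
  box = c("n0"),
  integrator = c("dt", "horizon", "record_every", "seed"),
  resident = c("a0", "p0", "gamma", "k", "lam", "beta", "r0", "rb0", "rd0",
               "v0", "d_r", "mobility"),
  mutant = NULL, # same keys as resident
  growth = c("coupling", "division_offset"),
  design = c("initial_fraction", "placement", "n_replicates", "relax_steps",
             "burn_in", "f_window", "delta_a0", "delta_p0", "c")
)

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys (listing every
#' offending one), fills resident defaults from [reference_resident()] and
#' copies omitted mutant fields from the resident, so a single-parameter
#' mutant is declared by naming just the field that changes.
#'
#' @param path YAML file path.
#' @return a validated `run_config` list with elements `experiment`, `box`,
#'   `integrator`, `resident`, `mutant` (both [type_params()]), `growth` and
#'   `design`.
#' @export
load_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Validate a run configuration list
#' @param cfg a named list with the structure of [load_run_config()] output.
#' @return the validated, default-filled `run_config`.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("configuration must be a mapping")
  bad <- setdiff(names(cfg), names(cfg_schema))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$experiment))
    stop("missing required 'experiment' block (grow | invade | mixture | meanfield)")
  if (!cfg$experiment %in% cfg_schema$experiment)
    stop("experiment must be one of ", paste(cfg_schema$experiment, collapse = ", "))
  offenders <- character(0)
  for (blk in c("box", "integrator", "resident", "mutant", "growth", "design")) {
    allowed <- if (blk == "mutant") cfg_schema$resident else cfg_schema[[blk]]
    extra <- setdiff(names(cfg[[blk]]), allowed)
    if (length(extra)) offenders <- c(offenders, paste0(blk, ".", extra))
  }
  if (length(offenders))
    stop("unknown configuration key(s): ", paste(offenders, collapse = ", "))

  res_args <- utils::modifyList(unclass(reference_resident()),
                                cfg$resident %||% list())
  resident <- do.call(type_params, res_args)
  mut_args <- utils::modifyList(unclass(resident), cfg$mutant %||% list())
  mutant <- do.call(type_params, mut_args)

  out <- list(
    experiment = cfg$experiment,
    box = list(n0 = cfg$box$n0 %||% 100),
    integrator = list(dt = cfg$integrator$dt %||% 0.01,
                      horizon = cfg$integrator$horizon %||% 20,
                      record_every = as.integer(cfg$integrator$record_every %||% 100L),
                      seed = as.integer(cfg$integrator$seed %||% 1L)),
    resident = resident, mutant = mutant,
    growth = list(coupling = cfg$growth$coupling %||% "area",
                  division_offset = cfg$growth$division_offset %||% 0.05),
    design = utils::modifyList(
      list(initial_fraction = 0.1, placement = "droplet", n_replicates = 10,
           relax_steps = 300L, burn_in = 0.25, f_window = 0.02,
           delta_a0 = NULL, delta_p0 = NULL, c = NULL),
      cfg$design %||% list())
  )
  if (!out$growth$coupling %in% c("none", "area", "pressure", "general_beta"))
    stop("growth.coupling must be none, area, pressure or general_beta")
  class(out) <- "run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration
#' @param cfg a `run_config` (from [validate_run_config()]) or compatible list.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  plain <- list(experiment = cfg$experiment, box = cfg$box,
                integrator = cfg$integrator,
                resident = unclass(cfg$resident), mutant = unclass(cfg$mutant),
                growth = cfg$growth,
                design = Filter(Negate(is.null), cfg$design))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Run a configured experiment
#'
#' Dispatches a validated configuration to the matching experiment and, if
#' `out_dir` is given, writes its outputs (observables/trajectory CSV, fitness
#' JSON where applicable) together with a provenance header
#' (`provenance.yaml`: the full configuration, seed and a run id) from which
#' the run can be reproduced.
#'
#' @param cfg a `run_config` (see [load_run_config()]).
#' @param out_dir optional output directory (created if missing).
#' @return experiment-dependent: `grow` returns an `spv_run`; `invade` the
#'   [run_invasion()] result; `mixture` a [fitness_estimate()]; `meanfield`
#'   a list with both closed-form estimates.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  seed <- cfg$integrator$seed
  steps <- round(cfg$integrator$horizon / cfg$integrator$dt)
  params <- spv_params(cfg$resident, cfg$mutant)

  res <- switch(
    cfg$experiment,
    grow = {
      set.seed(derive_seed(seed, "grow", 1L))
      box <- tissue_box(cfg$box$n0)
      st <- make_fixture("random", cfg$box$n0, box)
      st <- relax_tissue(st, box, cfg$resident,
                         n_steps = cfg$design$relax_steps, dt = cfg$integrator$dt)
      ph <- NULL
      if (cfg$growth$coupling == "pressure")
        ph <- calibrate_homeostatic_pressure(st, box, params, dt = cfg$integrator$dt)
      grow_tissue(st, box, params, n_steps = steps, dt = cfg$integrator$dt,
                  record_every = cfg$integrator$record_every,
                  coupling = cfg$growth$coupling, ph = ph,
                  div_offset = cfg$growth$division_offset)
    },
    invade = {
      des <- invasion_design(cfg$resident, cfg$mutant, n0 = cfg$box$n0,
                             initial_fraction = cfg$design$initial_fraction,
                             placement = cfg$design$placement,
                             n_replicates = cfg$design$n_replicates,
                             horizon = cfg$integrator$horizon,
                             dt = cfg$integrator$dt,
                             record_every = cfg$integrator$record_every,
                             relax_steps = cfg$design$relax_steps,
                             f_window = cfg$design$f_window,
                             coupling = cfg$growth$coupling,
                             div_offset = cfg$growth$division_offset)
      run_invasion(des, seed = seed)
    },
    mixture = mixture_predictor(cfg$resident, cfg$mutant, n0 = cfg$box$n0,
                                horizon = cfg$integrator$horizon,
                                burn_in = cfg$design$burn_in,
                                dt = cfg$integrator$dt,
                                record_every = cfg$integrator$record_every,
                                relax_steps = cfg$design$relax_steps,
                                seed = seed),
    meanfield = {
      cc <- cfg$design$c %||% hexagon_slope()
      da <- cfg$design$delta_a0 %||% (cfg$mutant$a0 - cfg$resident$a0)
      dp <- cfg$design$delta_p0 %||% (cfg$mutant$p0 - cfg$resident$p0)
      list(area = meanfield_fitness_area(da, cfg$resident$gamma,
                                         cfg$resident$lam, cc),
           perimeter = meanfield_fitness_perimeter(dp, cfg$resident$gamma,
                                                   cfg$resident$lam, cc))
    })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    run_id <- sprintf("%s-%08x", cfg$experiment,
                      derive_seed(seed, paste0("runid-", cfg$experiment)))
    yaml::write_yaml(list(run_id = run_id, seed = seed,
                          config = list(experiment = cfg$experiment,
                                        box = cfg$box,
                                        integrator = cfg$integrator,
                                        resident = unclass(cfg$resident),
                                        mutant = unclass(cfg$mutant),
                                        growth = cfg$growth,
                                        design = Filter(Negate(is.null), cfg$design))),
                     file.path(out_dir, "provenance.yaml"))
    if (cfg$experiment == "grow") {
      write_observables(res$observables, file.path(out_dir, "observables.csv"))
      write_events(res$events, file.path(out_dir, "events.csv"))
    } else if (cfg$experiment == "invade") {
      utils::write.csv(res$trajectory, file.path(out_dir, "trajectory.csv"),
                       row.names = FALSE, quote = FALSE)
      write_fitness_json(res$fit, file.path(out_dir, "fitness.json"))
    } else if (cfg$experiment == "mixture") {
      write_fitness_json(res, file.path(out_dir, "fitness.json"))
    } else {
      jsonlite::write_json(list(area = res$area[c("s", "method")],
                                perimeter = res$perimeter[c("s", "method")]),
                           file.path(out_dir, "fitness.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  res
}
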