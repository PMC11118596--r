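#' Per-type cell parameters
#'
#' One population's mechanical, motility and growth parameters, in the
#' dimensionless units of the model (lengths in box units, energy normalized
#' by the resident area elasticity, rates per time unit).
#'
#' The basal birth/death rates of the stochastic growth process are exposed as
#' the pair (`rb0`, `rd0`). The convenience argument `r0` sets both equal,
#' which is the symmetric basal-noise case used for homogeneous growth; a
#' basal-rate *fitness* mutation raises `rb0` alone, since a symmetric
#' increase cancels exactly in the net growth rate and only adds demographic
#' noise.
#'
#' @param a0 preferred area (resident reference value 1).
#' @param p0 preferred perimeter; acts as the shape index that sets the
#'   solid-like (e.g. 3.3) vs liquid-like (e.g. 4.0) phase.
#' @param gamma perimeter elasticity \eqn{\bar\Gamma \ge 0}.
#' @param k area elasticity \eqn{\bar K > 0}; the resident value is the energy
#'   normalization and is fixed to 1.
#' @param lam coupling strength \eqn{\lambda \ge 0} between mechanics and the
#'   birth/death rates.
#' @param beta weight of the perimeter deviation relative to the area
#'   deviation in the growth stimulus. Must be finite and non-negative: the
#'   large-beta limit is unstable (cells elongate without bound) and is
#'   rejected at validation.
#' @param r0 basal rate; sets both `rb0` and `rd0` unless given explicitly.
#' @param rb0,rd0 basal birth and death rates (each >= 0).
#' @param v0 self-propulsion speed (resident reference value 0.05).
#' @param d_r rotational diffusion constant \eqn{D_r} (reference value 1).
#' @param mobility force mobility \eqn{\mu > 0} (default 1, homogeneous).
#' @return an object of class `type_params`.
#' @seealso [spv_params()] to pair resident and mutant parameter sets.
#' @export
type_params <- function(a0 = 1, p0 = 3.3, gamma = 1, k = 1, lam = 1,
                        beta = 0, r0 = 0, rb0 = r0, rd0 = r0,
                        v0 = 0.05, d_r = 1, mobility = 1) {
  p <- list(a0 = a0, p0 = p0, gamma = gamma, k = k, lam = lam, beta = beta,
            rb0 = rb0, rd0 = rd0, v0 = v0, d_r = d_r, mobility = mobility)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number")
  stopifnot(gamma >= 0, k > 0, lam >= 0, rb0 >= 0, rd0 >= 0,
            v0 >= 0, d_r >= 0, mobility > 0, beta >= 0)
  structure(p, class = "type_params")
}

#' Resident/mutant parameter pair
#'
#' Bundles the two populations' parameters. `mutant` defaults to a copy of
#' `resident`, so single-parameter mutants are written as e.g.
#' `spv_params(mutant = list(a0 = 0.9))`: fields not named in a list are
#' inherited from the resident, mirroring the reference-value convention of
#' the competition experiments.
#'
#' @param resident,mutant `type_params` objects, or named lists of overrides
#'   applied on top of the resident values.
#' @return an object of class `spv_params`.
#' @export
spv_params <- function(resident = type_params(), mutant = resident) {
  if (!inherits(resident, "type_params")) {
    stopifnot(is.list(resident))
    resident <- do.call(type_params, resident)
  }
  if (!inherits(mutant, "type_params")) {
    stopifnot(is.list(mutant))
    bad <- setdiff(names(mutant), names(resident))
    if (length(bad)) stop("unknown mutant parameter(s): ", paste(bad, collapse = ", "))
    merged <- unclass(resident)
    merged[names(mutant)] <- mutant
    mutant <- do.call(type_params, merged)
  }
  structure(list(resident = resident, mutant = mutant), class = "spv_params")
}

#' @export
print.type_params <- function(x, ...) {
  cat("<type_params>", paste(names(x), unlist(x), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
print.spv_params <- function(x, ...) {
  cat("resident: "); print(x$resident)
  cat("mutant:   "); print(x$mutant)
  invisible(x)
}

# 11 x 2 matrix handed to the C++ core; row order matches the ParRow enum.
par_matrix <- function(params) {
  if (inherits(params, "type_params")) params <- spv_params(params, params)
  stopifnot(inherits(params, "spv_params"))
  rows <- c("a0", "p0", "gamma", "k", "lam", "beta", "rb0", "rd0",
            "v0", "d_r", "mobility")
  m <- cbind(unlist(unclass(params$resident)[rows]),
             unlist(unclass(params$mutant)[rows]))
  dimnames(m) <- list(rows, c("resident", "mutant"))
  m
}

type_codes <- c("resident", "mutant")

as_type_int <- function(types) {
  i <- match(types, type_codes)
  if (anyNA(i)) stop("types must be 'resident' or 'mutant'")
  i - 1L
}
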