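#' Tissue configuration
#'
#' The evolving degrees of freedom of the model: cell-center positions,
#' polarization angles and type labels. Cell shapes are *derived* from the
#' positions by the periodic Voronoi tessellation ([build_tessellation()]).
#'
#' @param positions numeric matrix with N rows and 2 columns; wrapped into the
#'   primary box.
#' @param box a [tissue_box()].
#' @param angles polarization angles theta (radians), one per cell; drawn
#'   uniformly if missing. Angles are kept unwrapped since only cos/sin enter
#'   the dynamics.
#' @param types character vector of `"resident"` / `"mutant"` labels.
#' @param time dimensionless simulation time of the configuration.
#' @param ids persistent integer cell ids (assigned 1..N if missing); division
#'   retires the parent id and assigns fresh ids to both children.
#' @return an object of class `tissue_state`.
#' @export
tissue_state <- function(positions, box, angles = NULL, types = NULL,
                         time = 0, ids = NULL) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  if (ncol(positions) != 2) stop("positions must have two columns")
  n <- nrow(positions)
  if (n < 3) stop("a tissue needs at least 3 cells")
  if (is.null(angles)) angles <- stats::runif(n, 0, 2 * pi)
  if (is.null(types)) types <- rep("resident", n)
  if (is.null(ids)) ids <- seq_len(n)
  if (length(angles) != n || length(types) != n || length(ids) != n)
    stop("positions, angles, types and ids must have one entry per cell")
  as_type_int(types) # validates labels
  structure(list(positions = wrap_positions(positions, box),
                 angles = as.numeric(angles),
                 types = as.character(types),
                 time = as.numeric(time),
                 ids = as.integer(ids),
                 next_id = max(as.integer(ids)) + 1L),
            class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  nm <- sum(x$types == "mutant")
  cat(sprintf("<tissue_state> N = %d (%d mutant, f = %.3f), t = %.4g\n",
              nrow(x$positions), nm, nm / nrow(x$positions), x$time))
  invisible(x)
}

n_cells <- function(state) nrow(state$positions)

#' Mutant fraction of a state
#' @param state a [tissue_state()].
#' @return fraction of cells labelled `"mutant"`.
#' @export
mutant_fraction <- function(state) mean(state$types == "mutant")

#' Deterministic tissue fixtures
#'
#' Generates initial configurations used by the simulation experiments and the
#' test-suite: near-regular lattices, uniformly random tissues, and labelled
#' resident/mutant mixtures.
#'
#' Kinds:
#' * `"hexagonal"`: offset-row lattice. A square periodic box cannot hold
#'   exactly regular hexagons (the required row/column ratio \eqn{2/\sqrt 3}
#'   is irrational); the factorization of `n_cells` with an even number of
#'   rows closest to that ratio is used, and the residual strain enters cell
#'   perimeters only at second order. All cells have area exactly 1.
#' * `"square"`: square lattice, `n_cells` a perfect square.
#' * `"random"`: uniform positions.
#' * `"droplet_mixture"`: uniform positions; the `ceiling(fraction * n_cells)`
#'   cells nearest a random point are labelled mutant (a mutant droplet).
#' * `"half_mixture"`: uniform positions; exactly half the cells, chosen at
#'   random, are labelled mutant.
#'
#' @param kind one of the fixture kinds above.
#' @param n_cells number of cells (>= 3; lattice kinds constrain the count).
#' @param box the periodic box; defaults to `tissue_box(n_cells)` so the mean
#'   cell area is 1.
#' @param seed optional integer seed (fixtures are deterministic given it).
#' @param fraction mutant fraction for `"droplet_mixture"`.
#' @return a [tissue_state()].
#' @export
make_fixture <- function(kind = c("hexagonal", "square", "random",
                                  "droplet_mixture", "half_mixture"),
                         n_cells, box = tissue_box(n_cells), seed = NULL,
                         fraction = 0.1) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_cells)
  if (n < 3) stop("n_cells must be at least 3")
  L <- box$side

  if (kind == "square") {
    k <- round(sqrt(n))
    if (k * k != n)
      stop("square lattice needs a perfect square; nearest valid count is ", k * k)
    g <- (seq_len(k) - 0.5) * L / k
    pos <- as.matrix(expand.grid(x = g, y = g))
    return(tissue_state(pos, box, types = rep("resident", n)))
  }

  if (kind == "hexagonal") {
    fac <- hex_factorization(n)
    if (is.null(fac))
      stop("no even-row factorization of ", n,
           " cells; nearest valid count is ", nearest_hex_count(n))
    rows <- fac[1]; cols <- fac[2]
    dx <- L / cols; dy <- L / rows
    j <- rep(seq_len(rows) - 1L, each = cols)
    i <- rep(seq_len(cols) - 1L, times = rows)
    x <- (i + 0.25 + 0.5 * (j %% 2)) * dx
    y <- (j + 0.5) * dy
    return(tissue_state(cbind(x, y), box, types = rep("resident", n)))
  }

  pos <- cbind(stats::runif(n, 0, L), stats::runif(n, 0, L))
  types <- rep("resident", n)
  if (kind == "droplet_mixture") {
    st <- tissue_state(pos, box, types = types)
    return(label_droplet(st, box, fraction))
  }
  if (kind == "half_mixture")
    types[sample.int(n, n %/% 2)] <- "mutant"
  tissue_state(pos, box, types = types)
}

# even-row factorization of n with rows/cols closest to 2/sqrt(3)
hex_factorization <- function(n) {
  target <- 2 / sqrt(3)
  best <- NULL; best_err <- Inf
  for (rows in seq(2L, n %/% 3L, by = 2L)) {
    if (n %% rows != 0L) next
    cols <- n %/% rows
    if (cols < 3L) next
    err <- abs(log(rows / cols / target))
    if (err < best_err) { best_err <- err; best <- c(rows, cols) }
  }
  best
}

nearest_hex_count <- function(n) {
  for (d in 1:n) {
    for (cand in c(n - d, n + d))
      if (cand >= 6 && !is.null(hex_factorization(cand))) return(cand)
  }
  6L
}

#' Label a contiguous mutant droplet
#'
#' Labels the `ceiling(fraction * N)` cells nearest a point (random unless
#' given) as mutants, all others as residents.
#'
#' @param state a [tissue_state()].
#' @param box the periodic box.
#' @param fraction mutant fraction in (0, 1).
#' @param center optional 2-vector droplet center; drawn uniformly if `NULL`.
#' @return the relabelled state.
#' @export
label_droplet <- function(state, box, fraction, center = NULL) {
  n <- n_cells(state)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  k <- ceiling(fraction * n)
  if (k < 1 || k >= n) stop("droplet of ", k, " mutants among ", n, " cells is not a mixture")
  if (is.null(center)) center <- stats::runif(2, 0, box$side)
  d <- minimum_image(state$positions, matrix(center, n, 2, byrow = TRUE), box)
  ord <- order(d[, 1]^2 + d[, 2]^2)
  types <- rep("resident", n)
  types[ord[seq_len(k)]] <- "mutant"
  state$types <- types
  state
}
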