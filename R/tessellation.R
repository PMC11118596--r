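#' Periodic Voronoi tessellation of a tissue
#'
#' Computes the Voronoi partition of the square torus generated by the cell
#' centers, together with every per-cell geometric quantity the energy and
#' growth rules consume: areas, perimeters, neighbor lists and polygon
#' vertices (periodic-image-resolved).
#'
#' Each cell polygon is obtained by clipping against the perpendicular
#' bisectors of distance-sorted periodic-image candidates, which is exact for
#' cells smaller than the box and continuous across cocircular degeneracies
#' (a perfect square lattice tessellates without jittering). The areas
#' partition the box exactly: `sum(areas) == box$side^2` to numerical
#' round-off.
#'
#' @param state a [tissue_state()].
#' @param box a [tissue_box()].
#' @param edge_tol Voronoi edges shorter than this are dropped from the
#'   neighbor lists (they carry no force and arise only from near-degenerate
#'   vertices).
#' @return an object of class `tessellation`: list with `areas`, `perimeters`,
#'   `neighbors` (list of adjacent cell indices in polygon order, with
#'   multiplicity for periodic images), `vertices` (list of CCW polygon-vertex
#'   matrices, resolved to the image nearest the cell center) and `n`.
#' @export
build_tessellation <- function(state, box, edge_tol = 1e-9) {
  v <- .cpp_voronoi(state$positions[, 1], state$positions[, 2], box$side,
                    edge_tol)
  structure(list(areas = v$areas, perimeters = v$perimeters,
                 neighbors = v$neighbors, vertices = v$vertices,
                 n = n_cells(state)),
            class = "tessellation")
}

#' @export
print.tessellation <- function(x, ...) {
  cat(sprintf("<tessellation> %d cells; <a> = %.4f, <p> = %.4f\n",
              x$n, mean(x$areas), mean(x$perimeters)))
  invisible(x)
}

#' Write a snapshot CSV
#'
#' One row per cell: `cell_id, x, y, theta, type, area, perimeter`.
#'
#' @param state a [tissue_state()].
#' @param tess matching [build_tessellation()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, tess, path) {
  df <- data.frame(cell_id = state$ids,
                   x = state$positions[, 1], y = state$positions[, 2],
                   theta = state$angles, type = state$types,
                   area = tess$areas, perimeter = tess$perimeters)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a snapshot CSV
#' @param path file written by [write_snapshot()].
#' @param box the periodic box the snapshot belongs to.
#' @param time simulation time to stamp on the restored state.
#' @return a [tissue_state()].
#' @export
read_snapshot <- function(path, box, time = 0) {
  df <- utils::read.csv(path)
  tissue_state(cbind(df$x, df$y), box, angles = df$theta, types = df$type,
               time = time, ids = df$cell_id)
}

#' Dump cell polygons as JSON
#'
#' Writes a JSON object mapping cell id to its ordered vertex list, for
#' plotting and debugging.
#'
#' @param state,tess matching state and tessellation.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_polygons_json <- function(state, tess, path) {
  polys <- stats::setNames(lapply(tess$vertices, function(m) unname(m)),
                           as.character(state$ids))
  jsonlite::write_json(polys, path, digits = NA)
  invisible(path)
}
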