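#' Periodic simulation box
#'
#' The tissue lives on a square torus. All lengths are expressed in box units
#' in which the side is \eqn{\hat L = \sqrt{N_0}}, with \eqn{N_0} the initial
#' cell count, so the mean cell area at \eqn{t = 0} is exactly 1 and the mean
#' area at any later time equals \eqn{N_0 / N(t)}.
#'
#' @param n_ref initial cell count \eqn{N_0} used for normalization (>= 3).
#' @return an object of class `tissue_box` with fields `side` and `n_ref`.
#' @export
tissue_box <- function(n_ref) {
  if (!is.numeric(n_ref) || length(n_ref) != 1 || n_ref < 3)
    stop("n_ref must be a single number >= 3")
  structure(list(side = sqrt(n_ref), n_ref = as.numeric(n_ref)),
            class = "tissue_box")
}

#' @export
print.tissue_box <- function(x, ...) {
  cat(sprintf("<tissue_box> side %.6g (N0 = %g)\n", x$side, x$n_ref))
  invisible(x)
}

#' Minimum-image displacement on the torus
#'
#' Shortest vector from `q` to `p` across periodic images; each component lies
#' in \eqn{(-\hat L/2, \hat L/2]}.
#'
#' @param p,q numeric 2-vectors (or matrices with two columns) inside the box.
#' @param box a [tissue_box()].
#' @return displacement with the same shape as `p`.
#' @export
minimum_image <- function(p, q, box) {
  L <- box$side
  d <- p - q
  d - L * ceiling(d / L - 0.5)
}

wrap_positions <- function(pos, box) {
  w <- pos - box$side * floor(pos / box$side)
  w[w >= box$side] <- 0 # rounding guard
  w
}
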