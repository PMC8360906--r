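#' Mechanical energy of a single cell
#'
#' Dimensionless vertex-model energy
#' \eqn{U = (A-1)^2 + (g/2)\,(L + \Lambda/(2g))^2} with
#' \eqn{g = m\,\Gamma}, where `m` is the cell's contractility multiplier
#' (1 for wild type, `1 + cluster_increment` inside the cluster). The energy
#' is non-negative and vanishes exactly when \eqn{A = 1} and
#' \eqn{L = -\Lambda/(2g)}.
#'
#' @param area dimensionless cell area A (vectorised).
#' @param perimeter dimensionless cell perimeter L (vectorised).
#' @param params a [mechanical_params()].
#' @param gamma_multiplier per-cell factor on gamma.
#' @return numeric energy, same length as `area`.
#' @examples
#' p <- mechanical_params()
#' cell_energy(1, 0, p) # lambda^2 / (8 gamma)
#' @export
cell_energy <- function(area, perimeter, params, gamma_multiplier = 1) {
  stopifnot(inherits(params, "mechanical_params"),
            all(is.finite(area)), all(is.finite(perimeter)))
  g <- params$gamma * gamma_multiplier
  (area - 1)^2 + (g / 2) * (perimeter + params$lambda / (2 * g))^2
}

#' Isotropic cell-level stress Peff
#'
#' Isotropic component of the cell-level stress tensor,
#' \eqn{P_{eff} = A - 1 + g L^2/(2A) - \Lambda L/(4A)} with
#' \eqn{g = m\,\Gamma}. Positive values indicate net tension, negative values
#' net compression.
#'
#' @inheritParams cell_energy
#' @return numeric Peff, same length as `area`.
#' @examples
#' p <- mechanical_params()
#' peff(1, p$lambda / (2 * p$gamma), p) # exactly zero
#' @export
peff <- function(area, perimeter, params, gamma_multiplier = 1) {
  stopifnot(inherits(params, "mechanical_params"))
  if (any(area <= 0)) stop("`area` must be positive")
  g <- params$gamma * gamma_multiplier
  area - 1 + g * perimeter^2 / (2 * area) -
    params$lambda * perimeter / (4 * area)
}

#' Total mechanical energy of a tissue
#'
#' Sum of [cell_energy()] over all cells, with per-cell geometry computed
#' under periodic unwrapping. Invariant under rigid translation of all
#' vertices.
#'
#' @param tis a [tissue()].
#' @param params a [mechanical_params()].
#' @return single numeric energy.
#' @export
total_energy <- function(tis, params) {
  g <- cell_geometry(tis)
  sum(cell_energy(g$area, g$perimeter, params, tis$gamma_multiplier))
}

#' Energy gradient with respect to vertex positions
#'
#' Analytic derivative of [total_energy()] with respect to every vertex
#' coordinate; used by the relaxation and tested against central finite
#' differences.
#'
#' @inheritParams total_energy
#' @return numeric matrix (n_vertices x 2) of dU/dR.
#' @export
tissue_gradient <- function(tis, params) {
  csr <- tissue_csr(tis)
  gr <- .tissue_grad_cpp(tissue_par(tis), csr$cell_vert, csr$cell_ptr,
                         tis$box, params$lambda, params$gamma,
                         tis$gamma_multiplier)
  matrix(gr, ncol = 2, byrow = TRUE)
}

#' Per-cell stress of a tissue
#'
#' @inheritParams total_energy
#' @return numeric vector of [peff()] values, one per cell.
#' @export
tissue_peff <- function(tis, params) {
  g <- cell_geometry(tis)
  peff(g$area, g$perimeter, params, tis$gamma_multiplier)
}

#' Area-weighted mean tissue stress
#'
#' \eqn{\sum_c A_c P_{eff,c} / \sum_c A_c}; the quantity driven to zero by
#' [zero_net_stress()].
#'
#' @inheritParams total_energy
#' @return single numeric.
#' @export
mean_peff <- function(tis, params) {
  g <- cell_geometry(tis)
  p <- peff(g$area, g$perimeter, params, tis$gamma_multiplier)
  sum(g$area * p) / sum(g$area)
}
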