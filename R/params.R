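#' Mechanical parameters of the vertex model
#'
#' Bundle of the dimensionless mechanical parameters entering the per-cell
#' energy \eqn{U = (A-1)^2 + (\Gamma/2)(L + \Lambda/(2\Gamma))^2}, where
#' \eqn{A} and \eqn{L} are the dimensionless cell area and perimeter,
#' \eqn{\Gamma} is the cortical contractility/stiffness and \eqn{\Lambda} is a
#' line-tension-like parameter prescribing the preferred perimeter
#' \eqn{L_0 = -\Lambda/(2\Gamma)}. The defaults are the values previously
#' fitted to the Xenopus animal cap epithelium.
#'
#' A hyper-contractile cluster is modelled by multiplying \eqn{\Gamma} by
#' `1 + cluster_increment` inside flagged cells; \eqn{\Lambda} is unchanged.
#'
#' @param lambda line-tension-like parameter \eqn{\Lambda} (dimensionless).
#' @param gamma cortical contractility \eqn{\Gamma} (dimensionless, > 0).
#' @param cluster_increment fractional increase of \eqn{\Gamma} inside the
#'   cluster (0.09 = 9 percent); must be >= 0.
#' @return An object of class `mechanical_params` with fields `lambda`,
#'   `gamma`, `cluster_increment` and the derived `preferred_perimeter`.
#' @examples
#' p <- mechanical_params()
#' p$preferred_perimeter # -lambda / (2 gamma)
#' @export
mechanical_params <- function(lambda = 0.259, gamma = 0.172,
                              cluster_increment = 0) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("`gamma` must be a single positive number")
  if (!is.numeric(cluster_increment) || length(cluster_increment) != 1L ||
      is.na(cluster_increment) || cluster_increment < 0)
    stop("`cluster_increment` must be a single non-negative number")
  structure(
    list(lambda = lambda, gamma = gamma,
         cluster_increment = cluster_increment,
         preferred_perimeter = -lambda / (2 * gamma)),
    class = "mechanical_params")
}

#' @export
print.mechanical_params <- function(x, ...) {
  cat("Vertex-model mechanical parameters\n")
  cat(sprintf("  lambda (line tension)        : %.4g\n", x$lambda))
  cat(sprintf("  gamma (cortical contractility): %.4g\n", x$gamma))
  cat(sprintf("  preferred perimeter L0        : %.4g\n",
              x$preferred_perimeter))
  cat(sprintf("  cluster gamma increment       : %.4g (%.1f%%)\n",
              x$cluster_increment, 100 * x$cluster_increment))
  invisible(x)
}
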