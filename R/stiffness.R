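## Equipartition stiffness estimators.
##
## A tracked sequence embedded in a thermally fluctuating network behaves
## like a bead in an effective harmonic trap. Two routes to the effective
## network stiffness kappa:
##   - plateau route: g2(t -> infinity) = 2 kBT / kappa, so
##     kappa = 2 kBT / plateau;
##   - pair route: the pair distance fluctuates like points joined by an
##     effective spring, kappa = 2 kBT / sigma_d^2.
## kappa here is the effective network stiffness as defined by these
## identities (for a 2D trap of per-axis stiffness k the plateau is
## 4 kBT / k, so the estimator returns k/2 by construction).

.stiffness <- function(kappa, method, input, kT, temperature) {
  structure(list(kappa = kappa, method = method, input = input,
                 kBT = kT, temperature = temperature),
            class = "stiffness_estimate")
}

#' Effective stiffness from the g2 long-time plateau
#'
#' `kappa = 2 kBT / plateau`, with kBT in pN um, so kappa comes out in
#' pN/um when the plateau is in um^2.
#'
#' @param plateau Long-time g2 plateau in um^2.
#' @param temperature Kelvin (default 298).
#' @return A `stiffness_estimate` with `kappa` in pN/um.
#' @examples
#' stiffness_from_plateau(0.2)   # ~0.04 pN/um
#' @export
stiffness_from_plateau <- function(plateau, temperature = 298) {
  if (is.list(plateau)) plateau <- plateau$value
  if (!is.numeric(plateau) || plateau <= 0) stop("plateau must be > 0")
  kT <- kBT_pN_um(temperature)
  .stiffness(2 * kT / plateau, "plateau", plateau, kT, temperature)
}

#' Effective stiffness from pair-distance fluctuations
#'
#' `kappa = 2 kBT / sigma_d^2` where `sigma_d` is the standard deviation of
#' the distance between a pair of tracked sequences.
#'
#' @param sigma_d Standard deviation of the pair distance in um.
#' @param temperature Kelvin (default 298).
#' @return A `stiffness_estimate` with `kappa` in pN/um.
#' @examples
#' stiffness_from_pairs(0.17)    # ~0.28 pN/um
#' @export
stiffness_from_pairs <- function(sigma_d, temperature = 298) {
  if (!is.numeric(sigma_d) || sigma_d <= 0) stop("sigma_d must be > 0")
  kT <- kBT_pN_um(temperature)
  .stiffness(2 * kT / sigma_d^2, "pair_distance", sigma_d, kT, temperature)
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  inp <- if (x$method == "plateau")
    sprintf("plateau %.3g um^2", x$input) else sprintf("sigma_d %.3g um", x$input)
  cat(sprintf("kappa = %.3f pN/um (%s route, %s, T = %g K)\n",
              x$kappa, x$method, inp, x$temperature))
  invisible(x)
}
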