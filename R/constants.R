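#' Thermal energy in piconewton-micrometres
#'
#' Boltzmann constant times absolute temperature, expressed in pN um, the
#' natural unit for stiffnesses quoted in pN/um and fluctuations in um^2.
#' At the default laboratory temperature of 298 K this is about
#' 4.114e-3 pN um (4.11 pN nm).
#'
#' @param temperature Absolute temperature in kelvin.
#' @return Thermal energy kB*T in pN um.
#' @examples
#' kBT_pN_um()          # 298 K
#' kBT_pN_um(310)       # body temperature
#' @export
kBT_pN_um <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), temperature > 0)
  kB <- 1.380649e-23 # J/K, exact (SI)
  # 1 J = 1e12 pN * 1e6 um => 1e18 pN um
  kB * temperature * 1e18
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## consistent RNG scoping: run expr with a local seed, restore global state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
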