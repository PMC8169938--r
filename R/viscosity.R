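#' Dynamic viscosity of glycerol-water mixtures
#'
#' Exponential-mixing correlation for aqueous glycerol (Cheng 2008,
#' Ind. Eng. Chem. Res. 47:3285): the mixture viscosity is
#' `mu_w^a * mu_g^(1-a)` where the component viscosities carry the
#' temperature dependence
#' \deqn{\mu_w = 1.790\,\exp\frac{(-1230-T)T}{36100+360T},\qquad
#'       \mu_g = 12100\,\exp\frac{(-1233+T)T}{9900+70T}}
#' (both in cP, T in degrees C) and the mixing exponent `a` depends on the
#' glycerol mass fraction Cm:
#' \deqn{a = 1 - C_m + \frac{\alpha\beta C_m(1-C_m)}{\alpha C_m + \beta(1-C_m)}}
#' with `alpha = 0.705 - 0.0017 T` and `beta = (4.9 + 0.036 T) alpha^2.5`.
#' Valid for 0-100 degrees C over the full composition range (within ~5%
#' of measurement; much closer below 30% glycerol).
#'
#' Glycerol concentrations quoted by volume are converted to mass fraction
#' using densities 1.26 g/ml (glycerol) and 0.998 g/ml (water).
#'
#' @param fraction glycerol fraction in \[0, 1\]; vectorized.
#' @param temperature temperature (degrees C), in \[0, 100\].
#' @param basis whether `fraction` is a volume (default) or mass fraction.
#' @return dynamic viscosity (Pa s); use [viscosity_pas_to_cp()] for cP.
#' @examples
#' viscosity_pas_to_cp(glycerin_water_viscosity(0, 22))    # ~0.96 cP
#' viscosity_pas_to_cp(glycerin_water_viscosity(0.25, 22)) # ~2.28 cP
#' @export
glycerin_water_viscosity <- function(fraction, temperature = 22,
                                     basis = c("volume", "mass")) {
  basis <- match.arg(basis)
  .check_fraction(fraction, "fraction")
  if (!is.numeric(temperature) || anyNA(temperature) ||
      any(temperature < 0) || any(temperature > 100)) {
    stop("invalid input: `temperature` must lie in [0, 100] degrees C",
         call. = FALSE)
  }
  cm <- if (basis == "volume") {
    fraction * 1.26 / (fraction * 1.26 + (1 - fraction) * 0.998)
  } else {
    fraction
  }
  T <- temperature
  mu_w <- 1.790 * exp((-1230 - T) * T / (36100 + 360 * T))
  mu_g <- 12100 * exp((-1233 + T) * T / (9900 + 70 * T))
  alpha <- 0.705 - 0.0017 * T
  beta <- (4.9 + 0.036 * T) * alpha^2.5
  a <- 1 - cm + alpha * beta * cm * (1 - cm) / (alpha * cm + beta * (1 - cm))
  viscosity_cp_to_pas(mu_w^a * mu_g^(1 - a))
}
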