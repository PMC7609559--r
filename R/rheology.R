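#' Carreau-Yasuda shear-thinning blood rheology
#'
#' Parameter container for the Carreau-Yasuda viscosity law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'       \left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a}}
#' which interpolates between the zero-shear plateau `mu0` and the
#' infinite-shear plateau `mu_inf`. The defaults are a standard whole-blood
#' parameter set (`mu0` = 0.16 Pa s, `mu_inf` = 3.5 mPa s, `lambda` = 8.2 s,
#' `a` = 0.64, `n` = 0.2128); all are configurable.
#'
#' @param mu0 zero-shear viscosity, Pa s.
#' @param mu_inf infinite-shear viscosity, Pa s.
#' @param lambda relaxation time, s.
#' @param a transition exponent.
#' @param n power-law index in (0, 1).
#' @return An object of class `c("carreau_yasuda", "rheology")`.
#' @export
carreau_yasuda <- function(mu0 = 0.16, mu_inf = 3.5e-3, lambda = 8.2,
                           a = 0.64, n = 0.2128) {
  stopifnot(mu0 > mu_inf, mu_inf > 0, lambda > 0, a > 0, n > 0, n < 1)
  structure(list(mu0 = mu0, mu_inf = mu_inf, lambda = lambda, a = a, n = n),
            class = c("carreau_yasuda", "rheology"))
}

#' Newtonian rheology
#'
#' Constant-viscosity model, mainly for solver verification against
#' Hagen-Poiseuille theory.
#'
#' @param mu dynamic viscosity, Pa s (default 3.5 mPa s).
#' @return An object of class `c("newtonian", "rheology")`.
#' @export
newtonian <- function(mu = 3.5e-3) {
  stopifnot(mu > 0)
  structure(list(mu = mu), class = c("newtonian", "rheology"))
}

#' Carreau-Yasuda viscosity
#'
#' Evaluates the shear-thinning viscosity at given shear rates.
#'
#' @param shear_rate non-negative shear rates, 1/s.
#' @param params a [carreau_yasuda()] parameter set.
#' @return viscosities, Pa s.
#' @examples
#' carreau_yasuda_viscosity(0, carreau_yasuda())     # 0.16 (zero-shear limit)
#' carreau_yasuda_viscosity(100, carreau_yasuda())   # ~4.3e-3
#' @export
carreau_yasuda_viscosity <- function(shear_rate, params = carreau_yasuda()) {
  stopifnot(inherits(params, "carreau_yasuda"))
  if (any(shear_rate < 0)) stop("shear rate must be >= 0", call. = FALSE)
  params$mu_inf + (params$mu0 - params$mu_inf) *
    (1 + (params$lambda * shear_rate)^params$a)^((params$n - 1) / params$a)
}

#' Evaluate a rheology model
#'
#' Dispatches to the constant or Carreau-Yasuda law.
#'
#' @param rheology a `rheology` object.
#' @param shear_rate shear rates, 1/s.
#' @return viscosities, Pa s.
#' @export
viscosity_of <- function(rheology, shear_rate) {
  UseMethod("viscosity_of")
}

#' @export
viscosity_of.newtonian <- function(rheology, shear_rate) {
  rep_len(rheology$mu, length(shear_rate))
}

#' @export
viscosity_of.carreau_yasuda <- function(rheology, shear_rate) {
  carreau_yasuda_viscosity(shear_rate, rheology)
}
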