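#' Double-Debye dielectric parameters
#'
#' Container for the five parameters of the double-Debye relaxation model of
#' water-rich tissue at THz frequencies: a slow relaxation (static
#' permittivity `eps_static` relaxing to the intermediate value `eps_mid`
#' with time constant `tau1`) and a fast relaxation (`eps_mid` to the
#' high-frequency limit `eps_inf` with `tau2`).
#'
#' The defaults are a published healthy human skin parameterization
#' (in vivo, THz band). They are plausible for mammalian skin in general but
#' make no claim of matching any particular animal.
#'
#' @param eps_static Static (zero-frequency) relative permittivity.
#' @param eps_mid Intermediate permittivity between the two relaxations.
#' @param eps_inf High-frequency permittivity limit.
#' @param tau1 Slow relaxation time in seconds.
#' @param tau2 Fast relaxation time in seconds.
#' @return An object of class `debye_params`.
#' @examples
#' dp <- debye_params()
#' debye_permittivity(dp, 0.5)
#' @export
debye_params <- function(eps_static = 60.0, eps_mid = 3.6, eps_inf = 3.0,
                         tau1 = 10.6e-12, tau2 = 0.18e-12) {
  stopifnot(is.numeric(eps_static), is.numeric(eps_mid), is.numeric(eps_inf),
            is.numeric(tau1), is.numeric(tau2))
  if (!(eps_static >= eps_mid && eps_mid >= eps_inf && eps_inf > 0)) {
    stop("invalid Debye parameters: need eps_static >= eps_mid >= eps_inf > 0")
  }
  if (!(tau1 > tau2 && tau2 > 0)) {
    stop("invalid Debye parameters: need tau1 > tau2 > 0")
  }
  structure(list(eps_static = eps_static, eps_mid = eps_mid,
                 eps_inf = eps_inf, tau1 = tau1, tau2 = tau2),
            class = "debye_params")
}

#' Complex permittivity of the double-Debye model
#'
#' Evaluates
#' \deqn{\epsilon(\omega) = \epsilon_\infty +
#'   \frac{\epsilon_s - \epsilon_2}{1 - i\omega\tau_1} +
#'   \frac{\epsilon_2 - \epsilon_\infty}{1 - i\omega\tau_2}}
#' with \eqn{\omega = 2\pi f}. Sign convention: physics time dependence
#' \eqn{e^{-i\omega t}}, so the loss appears as a *non-negative imaginary
#' part* of the returned permittivity. (The forward model conjugates this
#' when applying responses on the FFT grid, whose synthesis kernel is
#' \eqn{e^{+i2\pi f t}}.)
#'
#' @param params A [debye_params()] object.
#' @param freq_thz Vector of non-negative frequencies in THz.
#' @return Complex vector, one permittivity per frequency.
#' @export
debye_permittivity <- function(params, freq_thz) {
  if (!inherits(params, "debye_params")) params <- do.call(debye_params, params)
  stopifnot(is.numeric(freq_thz), all(freq_thz >= 0))
  w <- 2 * pi * freq_thz * 1e12
  params$eps_inf +
    (params$eps_static - params$eps_mid) / (1 - 1i * w * params$tau1) +
    (params$eps_mid - params$eps_inf) / (1 - 1i * w * params$tau2)
}

#' Complex refractive index from permittivity
#'
#' Principal branch square root, `n = sqrt(eps)`. With the `e^{-i w t}`
#' convention used by [debye_permittivity()] (loss = positive imaginary
#' part) the principal root has `Re(n) > 0` and `Im(n) >= 0` for passive
#' media.
#'
#' @param eps Complex permittivity (vector allowed), must be nonzero.
#' @return Complex refractive index.
#' @export
refractive_index <- function(eps) {
  eps <- as.complex(eps)
  if (any(eps == 0)) stop("refractive_index: permittivity must be nonzero")
  n <- sqrt(eps)
  # principal branch: enforce Re(n) >= 0 (sqrt of complex in R already is)
  flip <- Re(n) < 0
  n[flip] <- -n[flip]
  n
}

#' Normal-incidence Fresnel reflection coefficient
#'
#' `r = (n1 - n2) / (n1 + n2)` for a wave travelling in medium 1 reflecting
#' off the interface with medium 2. For passive media `|r| <= 1`.
#'
#' @param n1,n2 Complex refractive indices (vectors recycled).
#' @return Complex reflection coefficient.
#' @export
fresnel_reflection <- function(n1, n2) {
  n1 <- as.complex(n1); n2 <- as.complex(n2)
  if (any(n1 + n2 == 0)) stop("fresnel_reflection: n1 + n2 must be nonzero")
  (n1 - n2) / (n1 + n2)
}
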