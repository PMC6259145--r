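## Effective cross-sections and flux-convention conversions.
##
## 1/v nuclides follow the Hogdahl convention: sigma_eff = sigma0 + f_H*I0(alpha).
## Non-1/v nuclides (e.g. Lu-176) use a Westcott k-factor so that the
## effective thermal cross-section is k*sigma0; the k-factor is an input
## constant that absorbs g(Tn), r and S0(alpha).

#' Cadmium cut-off correction xi(alpha)
#'
#' xi(alpha) = 0.429 / ((1 + 2 alpha) * E_Cd^alpha).  For an ideal 1/E
#' epithermal spectrum (alpha = 0) it reduces to 0.429.
#'
#' @param alpha epithermal spectrum shape parameter.
#' @param E_Cd cadmium cut-off energy, eV (> 0).
#' @return dimensionless correction.
#' @export
xi <- function(alpha, E_Cd = 0.55) {
  if (any(E_Cd <= 0)) stop("E_Cd must be positive (eV)")
  if (any(abs(1 + 2 * alpha) < 1e-12))
    stop("xi(alpha) is singular at alpha = -0.5")
  0.429 / ((1 + 2 * alpha) * E_Cd^alpha)
}

#' Westcott-to-Hogdahl conventional flux ratio
#'
#' phi_Westcott / phi_th,Hogdahl = 1 + f_H * xi(alpha).  For typical
#' research-reactor rigs (f_H ~ 0.02) the ratio stays within about 1 percent
#' of unity over the practical alpha range, which justifies using the
#' measured Hogdahl thermal flux in Westcott-formalism rate calculations.
#'
#' @param f_H epithermal-to-thermal flux ratio (>= 0).
#' @param alpha epithermal spectrum shape parameter.
#' @param E_Cd cadmium cut-off energy, eV.
#' @return dimensionless flux ratio (>= 1).
#' @export
westcott_hogdahl_flux_ratio <- function(f_H, alpha = 0, E_Cd = 0.55) {
  if (any(f_H < 0)) stop("f_H must be non-negative")
  1 + f_H * xi(alpha, E_Cd)
}

#' Hogdahl effective cross-section for a 1/v nuclide
#'
#' @param sigma0 thermal (2200 m/s) cross-section, barns.
#' @param I0_alpha resonance integral (alpha-corrected if available), barns.
#' @param f_H epithermal-to-thermal flux ratio.
#' @return effective cross-section, barns.
#' @export
sigma_eff_1v <- function(sigma0, I0_alpha, f_H) {
  if (any(sigma0 < 0) || any(I0_alpha < 0) || any(f_H < 0))
    stop("sigma0, I0 and f_H must be non-negative")
  sigma0 + f_H * I0_alpha
}

#' Westcott effective cross-section for a non-1/v nuclide
#'
#' k * sigma0.  Any fast-flux term is added separately by the caller.
#'
#' @param sigma0 thermal cross-section, barns.
#' @param k_factor Westcott k-factor (> 0).
#' @return effective cross-section, barns.
#' @export
sigma_eff_non1v <- function(sigma0, k_factor) {
  if (any(sigma0 < 0)) stop("sigma0 must be non-negative")
  if (any(k_factor <= 0)) stop("k_factor must be positive")
  k_factor * sigma0
}

#' Alpha-corrected resonance integral I0(alpha)
#'
#' The full Q0(alpha) correction needs the effective resonance energy Er of
#' the nuclide, which the bundled tables do not carry.  When `Er` is
#' supplied the standard k0-standardization form is used; otherwise the
#' uncorrected I0 is returned (exact for alpha = 0) and, for alpha != 0, a
#' warning notes the missing correction.
#'
#' @param sigma0,I0 barns.
#' @param alpha spectrum shape parameter.
#' @param E_Cd cadmium cut-off energy, eV.
#' @param Er effective resonance energy, eV, or NULL.
#' @return I0(alpha) in barns.
#' @export
I0_alpha <- function(sigma0, I0, alpha = 0, E_Cd = 0.55, Er = NULL) {
  if (alpha == 0) return(I0)
  if (is.null(Er)) {
    warning("alpha != 0 but no effective resonance energy supplied; ",
            "using uncorrected I0")
    return(I0)
  }
  Q0 <- I0 / sigma0
  Q0a <- (Q0 - 0.429) / Er^alpha +
    0.429 / ((1 + 2 * alpha) * E_Cd^alpha)
  Q0a * sigma0
}

#' Effective single-channel cross-section Omega
#'
#' Omega = sigma_eff + R_fast * sigma_fast, with sigma_eff chosen by nuclide
#' class: k*sigma0 for non-1/v channels, sigma0 + f_H*I0(alpha) for 1/v
#' channels.
#'
#' @param channel a [reaction_channel()].
#' @param field a [neutron_field()].
#' @param Er optional effective resonance energy for the alpha correction.
#' @return Omega in barns.
#' @export
omega <- function(channel, field, Er = NULL) {
  stopifnot(inherits(channel, "reaction_channel"),
            inherits(field, "neutron_field"))
  eff <- if (channel$non_1v) {
    sigma_eff_non1v(channel$sigma0, channel$k_factor)
  } else {
    i0a <- I0_alpha(channel$sigma0, channel$I0, field$alpha, field$E_Cd, Er)
    sigma_eff_1v(channel$sigma0, i0a, field$R_epi)
  }
  eff + field$R_fast * channel$sigma_fast
}

#' Spectrum corrections summary for one channel
#'
#' Bundles xi(alpha), Q0, the (possibly alpha-corrected) resonance
#' integral, the effective cross-section and the Westcott/Hogdahl flux
#' ratio into one record, mainly for logging and audit output.
#'
#' @inheritParams omega
#' @return object of class `spectrum_corrections`.
#' @export
spectrum_corrections <- function(channel, field, Er = NULL) {
  x <- xi(field$alpha, field$E_Cd)
  i0a <- if (channel$non_1v) NA_real_
         else I0_alpha(channel$sigma0, channel$I0, field$alpha, field$E_Cd, Er)
  structure(list(
    xi_alpha = x,
    Q0 = if (channel$sigma0 > 0) channel$I0 / channel$sigma0 else NA_real_,
    I0_alpha = i0a,
    sigma_eff = omega(channel, field, Er),
    flux_ratio_westcott_hogdahl =
      westcott_hogdahl_flux_ratio(field$R_epi, field$alpha, field$E_Cd)
  ), class = "spectrum_corrections")
}
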