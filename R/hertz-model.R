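#' Hertz contact model for a spherical indenter
#'
#' Forward and inverse evaluation of the Hertz contact model
#' \deqn{F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}}
#' for a rigid sphere of radius \eqn{R} indenting an elastic half-space of
#' Young's modulus \eqn{E} and Poisson ratio \eqn{\nu}. This is the contact
#' model used throughout the package for soft-cell indentation; the cell is
#' treated as incompressible by default (\eqn{\nu = 0.5}).
#'
#' @param delta_nm Indentation depth in nm (vectorised).
#' @param force_pN Loading force in pN (vectorised).
#' @param E_Pa Young's modulus in Pa.
#' @param R_m Indenter (tip) radius in m.
#' @param nu Poisson ratio of the sample; default 0.5 (incompressible).
#' @return `hertz_force()` returns force in pN; `hertz_indentation()` returns
#'   indentation in nm; `hertz_prefactor_pN_nm32()` returns the model
#'   prefactor in pN / nm^(3/2), i.e. `F_pN = prefactor * delta_nm^(3/2)`.
#' @examples
#' hertz_force(100, E_Pa = 10e3, R_m = 3e-6)        # ~974 pN at 100 nm
#' hertz_indentation(6000, E_Pa = 23.9e3, R_m = 3e-6)
#' @export
hertz_force <- function(delta_nm, E_Pa, R_m, nu = 0.5) {
  stopifnot(E_Pa > 0, R_m > 0, nu >= 0, nu < 0.5 + 1e-9)
  hertz_prefactor_pN_nm32(E_Pa, R_m, nu) * delta_nm^1.5
}

#' @rdname hertz_force
#' @export
hertz_indentation <- function(force_pN, E_Pa, R_m, nu = 0.5) {
  stopifnot(E_Pa > 0, R_m > 0)
  (force_pN / hertz_prefactor_pN_nm32(E_Pa, R_m, nu))^(2 / 3)
}

#' @rdname hertz_force
#' @export
hertz_prefactor_pN_nm32 <- function(E_Pa, R_m, nu = 0.5) {
  # SI prefactor is (4/3) E/(1-nu^2) sqrt(R) in N/m^(3/2);
  # converting F to pN (1e12) and delta to nm ((1e-9)^(3/2)) gives 10^(-1.5).
  (4 / 3) * E_Pa / (1 - nu^2) * sqrt(R_m) * 10^(-1.5)
}

# Young's modulus (Pa) from a through-origin slope in the (delta^{3/2}, F)
# plane expressed in pN / nm^(3/2).
hertz_E_from_slope <- function(slope_pN_nm32, R_m, nu = 0.5) {
  slope_pN_nm32 * 10^1.5 * (3 / 4) * (1 - nu^2) / sqrt(R_m)
}
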