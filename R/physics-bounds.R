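#' Diffusion coefficient implied by signal travel across the chamber
#'
#' If the quorum-sensing signal crosses the chamber (travel distance `L_a`
#' in micrometres) in time `t_D` hours, the implied diffusion coefficient
#' is `D_A = L_a^2 / t_D`, reported in um^2/min.
#'
#' @param L_um Travel distance, micrometres (> 0).
#' @param t_h Travel time, hours (> 0).
#' @return Diffusion coefficient, um^2/min.
#' @export
#' @examples
#' diffusion_coefficient(1800, 24) # 2250
diffusion_coefficient <- function(L_um, t_h) {
  if (any(L_um <= 0) || any(t_h <= 0))
    stop("distance and time must be positive")
  L_um^2 / (t_h * 60)
}

BOLTZMANN_J_PER_K <- 1.380649e-23

#' Stokes-Einstein bound on the signal molecule size
#'
#' Inverts the Stokes-Einstein relation `D = k_B T / (3 pi eta d)` to the
#' hydrodynamic size `d_A` of a molecule diffusing with coefficient `D_A`,
#' reported in nanometres. (The relation's `d` is a molecular diameter;
#' the literature on this bound uses "radius" and "diameter"
#' interchangeably for the same 13.05 nm figure — no factor of 2 is applied
#' here.) Defaults are water at 25 C.
#'
#' @param D_um2_min Diffusion coefficient, um^2/min (> 0).
#' @param T_K Absolute temperature, kelvin (default 298.15).
#' @param eta_Pa_s Solvent viscosity, Pa s (default 8.90e-4, water 25 C).
#' @return Hydrodynamic size `d_A`, nanometres.
#' @export
#' @examples
#' stokes_einstein_size(2250) # ~13.1 nm
stokes_einstein_size <- function(D_um2_min, T_K = 298.15,
                                 eta_Pa_s = 8.90e-4) {
  if (any(D_um2_min <= 0) || any(T_K <= 0) || any(eta_Pa_s <= 0))
    stop("all inputs must be positive")
  D_si <- um2_min_to_m2_s(D_um2_min)
  d_m <- BOLTZMANN_J_PER_K * T_K / (3 * pi * eta_Pa_s * D_si)
  d_m * 1e9
}

#' @rdname stokes_einstein_size
#' @param d_nm Hydrodynamic size in nanometres: the inverse map back to a
#'   diffusion coefficient in um^2/min.
#' @export
stokes_einstein_diffusion <- function(d_nm, T_K = 298.15,
                                      eta_Pa_s = 8.90e-4) {
  if (any(d_nm <= 0) || any(T_K <= 0) || any(eta_Pa_s <= 0))
    stop("all inputs must be positive")
  D_si <- BOLTZMANN_J_PER_K * T_K / (3 * pi * eta_Pa_s * (d_nm * 1e-9))
  m2_s_to_um2_min(D_si)
}

#' Unit conversions between um^2/min and m^2/s
#'
#' Exact factors: 1 um^2/min = 1e-12/60 m^2/s.
#'
#' @param x Value to convert.
#' @return Converted value.
#' @export
um2_min_to_m2_s <- function(x) x * 1e-12 / 60

#' @rdname um2_min_to_m2_s
#' @export
m2_s_to_um2_min <- function(x) x * 60 / 1e-12
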