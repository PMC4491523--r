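#' Pulse wave velocity of an elastic tube
#'
#' Wave speed of the 1D blood-flow system closed by the elastic tube law:
#' \deqn{c = \sqrt{\beta / (2 \rho A_d)}\, A^{1/4}.}
#' At `A = A_d` this is the diastolic PWV \eqn{c_d}.
#'
#' @param beta Wall stiffness (Pa m).
#' @param A_d Diastolic luminal area (m^2).
#' @param A Current luminal area (m^2).
#' @param rho Blood density (kg m^-3).
#' @return Wave speed (m/s); vectorised over its arguments.
#' @export
#' @examples
#' wave_speed(beta_from_pwv(5, 1e-4, 1050), 1e-4, 1e-4, 1050)  # 5 m/s
wave_speed <- function(beta, A_d, A, rho) {
  if (any(beta <= 0) || any(A_d <= 0) || any(A <= 0) || any(rho <= 0))
    stop("wave_speed: all inputs must be positive")
  sqrt(beta / (2 * rho * A_d)) * A^0.25
}

#' Elastic tube law
#'
#' Pressure-area relation for a thin, incompressible, linearly elastic
#' arterial wall:
#' \deqn{P = P_d + \frac{\beta}{A_d}\left(\sqrt{A} - \sqrt{A_d}\right).}
#'
#' @param A Luminal area (m^2).
#' @param A_d Diastolic area (m^2).
#' @param beta Wall stiffness (Pa m).
#' @param P_d Diastolic pressure (Pa). Default 0.
#' @return Pressure (Pa); vectorised.
#' @seealso [tube_law_area()] for the inverse relation.
#' @export
tube_law_pressure <- function(A, A_d, beta, P_d = 0) {
  if (any(A <= 0) || any(A_d <= 0))
    stop("tube_law_pressure: areas must be positive")
  P_d + beta / A_d * (sqrt(A) - sqrt(A_d))
}

#' Inverse tube law
#'
#' Area at a given pressure: \eqn{\sqrt{A} = \sqrt{A_d} + (P - P_d) A_d/\beta}.
#' Errors if the pressure is so low that the area would be non-positive
#' (the collapsed regime is outside the model's validity).
#'
#' @param P Pressure (Pa).
#' @inheritParams tube_law_pressure
#' @return Luminal area (m^2); vectorised.
#' @export
tube_law_area <- function(P, A_d, beta, P_d = 0) {
  if (any(A_d <= 0)) stop("tube_law_area: A_d must be positive")
  s <- sqrt(A_d) + (P - P_d) * A_d / beta
  if (any(s <= 0))
    stop("tube_law_area: pressure below the collapse limit of the tube law")
  s^2
}

#' Characteristic impedance of a segment
#'
#' Local impedance seen by a forward-travelling wave,
#' \eqn{Z_0(x) = \rho c_d(x) / A_d(x)}, evaluated on the diastolic state.
#'
#' @param segment An [arterial_segment()].
#' @param x Axial position (m) in `[0, length]`; vectorised. Defaults to the
#'   outlet, where terminal windkessels attach.
#' @param rho Blood density (kg m^-3).
#' @return Impedance (Pa s m^-3).
#' @export
characteristic_impedance <- function(segment, x = segment$length, rho) {
  if (any(x < 0) || any(x > segment$length))
    stop("characteristic_impedance: x outside [0, length] for segment '",
         segment$id, "'")
  rho * seg_wave_speed_d(segment, x, rho) / seg_area_d(segment, x)
}

#' Wall friction force per unit length
#'
#' \eqn{f = -2(\xi + 2)\pi\mu U} for a velocity profile of polynomial
#' order \eqn{\xi}; \eqn{\xi = 9} gives near-plug flow.
#'
#' @param U Cross-sectionally averaged axial velocity (m/s).
#' @param mu Blood viscosity (Pa s).
#' @param xi Velocity-profile order (dimensionless).
#' @return Friction force per unit length (N/m); vectorised, odd in `U`.
#' @export
friction_force <- function(U, mu, xi) {
  -2 * (xi + 2) * pi * mu * U
}
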