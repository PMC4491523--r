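#' Global haemodynamic parameters
#'
#' Container for the quantities shared by every vessel of an arterial
#' network: blood density and viscosity, the polynomial order of the axial
#' velocity profile (which sets the wall friction law), and the diastolic
#' reference pressure of the tube law.
#'
#' @param density Blood density \eqn{\rho} (kg m^-3). Default 1050.
#' @param viscosity Blood dynamic viscosity \eqn{\mu} (Pa s); zero selects
#'   the inviscid limit. Default 4e-3.
#' @param profile_order Polynomial order \eqn{\xi} of the velocity profile
#'   (dimensionless, >= 2). \eqn{\xi = 9} gives near-plug flow and a wall
#'   friction force per unit length \eqn{f = -2(\xi+2)\pi\mu U}. Default 9.
#' @param diastolic_pressure Diastolic pressure \eqn{P_d} (Pa) at which the
#'   luminal area equals the diastolic area \eqn{A_d}. Default 0 (pressures
#'   are then transmural perturbations about diastole).
#'
#' @return An object of class `global_params`.
#' @export
#' @examples
#' g <- global_params()
#' g$density
global_params <- function(density = 1050, viscosity = 4e-3,
                          profile_order = 9, diastolic_pressure = 0) {
  stopifnot(is.numeric(density), length(density) == 1L, is.finite(density),
            is.numeric(viscosity), length(viscosity) == 1L, is.finite(viscosity),
            is.numeric(profile_order), length(profile_order) == 1L,
            is.numeric(diastolic_pressure), length(diastolic_pressure) == 1L,
            is.finite(diastolic_pressure))
  if (density <= 0) stop("blood density must be positive")
  if (viscosity < 0) stop("blood viscosity must be non-negative")
  if (profile_order < 2) stop("velocity profile order must be >= 2")
  structure(list(density = density, viscosity = viscosity,
                 profile_order = profile_order,
                 diastolic_pressure = diastolic_pressure),
            class = "global_params")
}

#' @export
print.global_params <- function(x, ...) {
  cat("Global haemodynamic parameters\n")
  cat(sprintf("  density            : %g kg/m^3\n", x$density))
  cat(sprintf("  viscosity          : %g Pa s\n", x$viscosity))
  cat(sprintf("  profile order (xi) : %g\n", x$profile_order))
  cat(sprintf("  diastolic pressure : %g Pa\n", x$diastolic_pressure))
  invisible(x)
}

#' Conversion constant: 1 mmHg in Pa
#' @keywords internal
MMHG_PA <- 133.322
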