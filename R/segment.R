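#' A tapered elastic arterial segment
#'
#' One vessel of a 1D arterial network: a deformable, impermeable circular
#' tube whose diastolic radius and wall stiffness vary linearly along the
#' axial coordinate `x` in `[0, length]`. The diastolic area profile is
#' \eqn{A_d(x) = \pi r_d(x)^2} with \eqn{r_d} linear between `radius_in`
#' and `radius_out`; the stiffness profile \eqn{\beta(x)} (Pa m) is linear
#' between `beta_in` and `beta_out`. The diastolic pulse wave velocity
#' follows from \eqn{c_d(x) = \sqrt{\beta/(2\rho A_d)}\,A_d^{1/4}}.
#'
#' @param id Segment label (character scalar, unique within a network).
#' @param length Vessel length l (m), >= 0.
#' @param radius_in,radius_out Diastolic luminal radius (m) at the inlet
#'   (x = 0) and outlet (x = l). `radius_out` defaults to `radius_in`.
#' @param beta_in,beta_out Wall stiffness beta (Pa m) at inlet and outlet.
#'   `beta_out` defaults to `beta_in`. Alternatively supply `pwv_in` /
#'   `pwv_out` together with `rho`.
#' @param pwv_in,pwv_out Diastolic pulse wave velocity (m/s) at inlet and
#'   outlet; converted to beta via `beta_from_pwv()` (requires `rho`).
#' @param rho Blood density (kg m^-3); only needed when the stiffness is
#'   given as a PWV.
#' @param parent Id of the parent segment, or `NA` for the root.
#' @param generation Optional integer generation label (0 for the arterial
#'   trunk, +1 per generation of bifurcations). `NA` if unknown.
#'
#' @return An object of class `arterial_segment`.
#' @export
#' @examples
#' s <- arterial_segment("aorta", length = 0.1, radius_in = 0.01,
#'                       pwv_in = 5, rho = 1050)
#' seg_area_d(s, c(0, 0.05, 0.1))
arterial_segment <- function(id, length, radius_in, radius_out = radius_in,
                             beta_in = NULL, beta_out = NULL,
                             pwv_in = NULL, pwv_out = NULL, rho = NULL,
                             parent = NA_character_,
                             generation = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(length), length >= 0,
            is.numeric(radius_in), radius_in > 0,
            is.numeric(radius_out), radius_out > 0)
  if (is.null(beta_in)) {
    if (is.null(pwv_in) || is.null(rho))
      stop("supply either beta_in or (pwv_in and rho) for segment '", id, "'")
    beta_in <- beta_from_pwv(pwv_in, pi * radius_in^2, rho)
  }
  if (is.null(beta_out)) {
    beta_out <- if (!is.null(pwv_out)) {
      beta_from_pwv(pwv_out, pi * radius_out^2, rho)
    } else beta_in
  }
  if (beta_in <= 0 || beta_out <= 0)
    stop("wall stiffness must be positive for segment '", id, "'")
  structure(list(id = id, length = as.numeric(length),
                 radius_in = as.numeric(radius_in),
                 radius_out = as.numeric(radius_out),
                 beta_in = as.numeric(beta_in),
                 beta_out = as.numeric(beta_out),
                 parent = as.character(parent),
                 generation = as.integer(generation)),
            class = "arterial_segment")
}

#' @export
print.arterial_segment <- function(x, ...) {
  cat(sprintf("Arterial segment '%s': l = %.4g m, r = %.4g -> %.4g mm, beta = %.4g -> %.4g Pa m\n",
              x$id, x$length, 1e3 * x$radius_in, 1e3 * x$radius_out,
              x$beta_in, x$beta_out))
  invisible(x)
}

#' Stiffness from diastolic pulse wave velocity
#'
#' Inverts the wave-speed relation at diastole,
#' \eqn{c_d = \sqrt{\beta/(2\rho A_d)}\,A_d^{1/4}}, giving
#' \eqn{\beta = 2 \rho c_d^2 \sqrt{A_d}}.
#'
#' @param c_d Diastolic pulse wave velocity (m/s).
#' @param A_d Diastolic area (m^2).
#' @param rho Blood density (kg m^-3).
#' @return Stiffness beta (Pa m).
#' @export
beta_from_pwv <- function(c_d, A_d, rho) {
  if (any(c_d <= 0) || any(A_d <= 0) || any(rho <= 0))
    stop("c_d, A_d and rho must be positive")
  2 * rho * c_d^2 * sqrt(A_d)
}

## linear axial profiles; x may be a vector in [0, l]
seg_frac <- function(seg, x) {
  if (seg$length == 0) return(rep(0, length(x)))
  x / seg$length
}

#' Diastolic area, stiffness and wave-speed profiles of a segment
#'
#' @param seg An [arterial_segment()].
#' @param x Axial positions (m) in `[0, length]`; vectorised.
#' @param rho Blood density (kg m^-3), needed for the wave speed.
#' @return Numeric vector: diastolic area (m^2), stiffness (Pa m) or
#'   diastolic PWV (m/s) at `x`.
#' @export
seg_area_d <- function(seg, x) {
  s <- seg_frac(seg, x)
  r <- seg$radius_in + (seg$radius_out - seg$radius_in) * s
  pi * r^2
}

#' @rdname seg_area_d
#' @export
seg_beta <- function(seg, x) {
  s <- seg_frac(seg, x)
  seg$beta_in + (seg$beta_out - seg$beta_in) * s
}

#' @rdname seg_area_d
#' @export
seg_wave_speed_d <- function(seg, x, rho) {
  Ad <- seg_area_d(seg, x)
  wave_speed(seg_beta(seg, x), Ad, Ad, rho)
}
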