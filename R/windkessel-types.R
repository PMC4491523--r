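#' Three-element (RCR) windkessel outflow model
#'
#' Lumped model of the vasculature distal to a terminal vessel: a proximal
#' resistance `r1` (conventionally matched to the characteristic impedance
#' of the feeding vessel to minimise wave reflection), a compliance `c`
#' and a distal resistance `r2` draining to a constant outflow pressure
#' `p_out` (approximately the mean venous pressure).
#'
#' @param r1 Proximal resistance (Pa s m^-3), >= 0.
#' @param r2 Distal resistance (Pa s m^-3), > 0.
#' @param c Compliance (m^3 Pa^-1), > 0. (`c = 0` is tolerated by the 1D
#'   solver as a purely resistive outlet but not by the reduction algebra.)
#' @param p_out Outflow pressure (Pa). Default 0.
#' @return An object of class `windkessel3`.
#' @export
windkessel3 <- function(r1, r2, c, p_out = 0) {
  stopifnot(is.numeric(r1), is.numeric(r2), is.numeric(c), is.numeric(p_out))
  if (r1 < 0) stop("windkessel3: r1 must be >= 0")
  if (r2 <= 0) stop("windkessel3: r2 must be > 0")
  if (c < 0) stop("windkessel3: c must be >= 0")
  structure(list(r1 = as.numeric(r1), r2 = as.numeric(r2),
                 c = as.numeric(c), p_out = as.numeric(p_out)),
            class = "windkessel3")
}

#' Two-element (RC) windkessel model
#'
#' Frank's windkessel: a single resistance and compliance draining to a
#' constant outflow pressure. Produced by lumping a terminal 1D vessel
#' plus its RCR outlet ([lump_terminal()]) or a whole network
#' ([reduce_to_windkessel()]).
#'
#' @param r Resistance (Pa s m^-3), > 0.
#' @param c Compliance (m^3 Pa^-1), > 0.
#' @param p_out Outflow pressure (Pa). Default 0.
#' @return An object of class `windkessel2`.
#' @export
windkessel2 <- function(r, c, p_out = 0) {
  stopifnot(is.numeric(r), is.numeric(c), is.numeric(p_out))
  if (r <= 0) stop("windkessel2: r must be > 0")
  if (c <= 0) stop("windkessel2: c must be > 0")
  structure(list(r = as.numeric(r), c = as.numeric(c),
                 p_out = as.numeric(p_out)),
            class = "windkessel2")
}

#' @export
print.windkessel3 <- function(x, ...) {
  cat(sprintf("RCR windkessel: R1 = %.4g, R2 = %.4g Pa s/m^3, C = %.4g m^3/Pa, p_out = %.4g Pa\n",
              x$r1, x$r2, x$c, x$p_out))
  invisible(x)
}

#' @export
print.windkessel2 <- function(x, ...) {
  cat(sprintf("RC windkessel: R = %.4g Pa s/m^3, C = %.4g m^3/Pa, p_out = %.4g Pa\n",
              x$r, x$c, x$p_out))
  invisible(x)
}
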