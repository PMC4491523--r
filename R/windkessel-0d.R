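#' Two-element windkessel response to a prescribed inflow
#'
#' Integrates Frank's windkessel equation
#' \deqn{q_{in}(t) = \frac{p_{in} - \hat p_{out}}{R} + C \frac{dp_{in}}{dt}}
#' for the inlet pressure given a flow waveform, with an adaptive
#' solver (lsoda, relative tolerance 1e-10).
#'
#' @param q_in An [inflow_waveform()], or a function of time (m^3/s).
#' @param wk A [windkessel2()]; alternatively supply `r`, `c`, `p_out`.
#' @param r,c,p_out Resistance, compliance, outflow pressure (used when
#'   `wk` is missing).
#' @param p0 Initial inlet pressure (Pa). Default
#'   `p_out + mean(q_in) * r`, which starts close to the periodic state.
#' @param t_end Final time (s); default 5 periods of `q_in` (or 5 s).
#' @param n_out Number of output samples.
#' @return Object of class `lumped_response`: data frame with columns
#'   `time`, `p_in` (Pa) and `q_out` (m^3/s, the flow through the
#'   resistor).
#' @export
#' @examples
#' iw <- make_inflow(1, 70e-6, 0.3)
#' resp <- wk2_response(iw, windkessel2(1.3e8, 1e-8))
wk2_response <- function(q_in, wk = NULL, r = wk$r, c = wk$c,
                         p_out = wk$p_out, p0 = NULL, t_end = NULL,
                         n_out = 2048L) {
  qf <- if (inherits(q_in, "inflow_waveform")) q_in$q_fun else q_in
  if (is.null(t_end))
    t_end <- if (inherits(q_in, "inflow_waveform")) 5 * q_in$period else 5
  if (is.null(p0)) {
    qbar <- stats::integrate(function(t) vapply(t, qf, numeric(1)),
                             0, t_end, subdivisions = 500L,
                             rel.tol = 1e-8)$value / t_end
    p0 <- p_out + qbar * r
  }
  times <- seq(0, t_end, length.out = n_out)
  deriv <- function(t, y, parms)
    list((qf(t) - (y[1] - p_out) / r) / c)
  sol <- deSolve::lsoda(c(p = p0), times, deriv, NULL,
                        rtol = 1e-10, atol = 1e-10 * max(abs(p0), 1))
  p <- sol[, "p"]
  structure(data.frame(time = times, p_in = p, q_out = (p - p_out) / r),
            class = c("lumped_response", "data.frame"),
            params = list(r = r, c = c, p_out = p_out))
}

#' Three-element windkessel response to a prescribed flow
#'
#' Integrates the RCR windkessel equation driven by the flow entering the
#' model,
#' \deqn{\left(1 + \frac{R_1}{R_2}\right) q + C R_1 \frac{dq}{dt}
#'   = C \frac{dp}{dt} + \frac{p - \hat p_{out}}{R_2},}
#' where `p` is the pressure at the model inlet.
#'
#' @param q_in An [inflow_waveform()] or a function of time (m^3/s); its
#'   time derivative is obtained from a spline representation.
#' @param wk A [windkessel3()].
#' @param p0 Initial inlet pressure (Pa); default the steady value for
#'   the mean flow.
#' @param t_end,n_out As in [wk2_response()].
#' @return A `lumped_response` data frame (`time`, `p_in`, `q_out` with
#'   `q_out` the flow through `R2`).
#' @export
wk3_response <- function(q_in, wk, p0 = NULL, t_end = NULL, n_out = 2048L) {
  qf <- if (inherits(q_in, "inflow_waveform")) q_in$q_fun else q_in
  if (is.null(t_end))
    t_end <- if (inherits(q_in, "inflow_waveform")) 5 * q_in$period else 5
  ## spline the forcing for a smooth derivative
  tg <- seq(0, t_end, length.out = 4096L)
  sp <- stats::splinefun(tg, vapply(tg, qf, numeric(1)), method = "fmm")
  if (is.null(p0)) {
    qbar <- mean(sp(tg))
    p0 <- wk$p_out + (wk$r1 + wk$r2) * qbar
  }
  times <- seq(0, t_end, length.out = n_out)
  deriv <- function(t, y, parms) {
    q <- sp(t); dq <- sp(t, deriv = 1L)
    list(((1 + wk$r1 / wk$r2) * q + wk$c * wk$r1 * dq -
            (y[1] - wk$p_out) / wk$r2) / wk$c)
  }
  sol <- deSolve::lsoda(c(p = p0), times, deriv, NULL,
                        rtol = 1e-10, atol = 1e-10 * max(abs(p0), 1))
  p <- sol[, "p"]
  structure(data.frame(time = times, p_in = p,
                       q_out = (p - wk$r1 * sp(times) - wk$p_out) / wk$r2),
            class = c("lumped_response", "data.frame"),
            params = list(wk = wk))
}

#' Frank's windkessel model of a whole network
#'
#' Reduces the entire arterial network to a single two-element windkessel
#' whose resistance and compliance are the network's net peripheral
#' resistance and total effective compliance ([reduce_to_windkessel()])
#' and returns its pressure response to the inflow waveform. This is the
#' classical whole-system windkessel: it captures the diastolic pressure
#' decay (time constant `R C`) but not the wave-borne systolic features.
#'
#' @param net An [arterial_network()].
#' @param inflow An [inflow_waveform()].
#' @param ... Passed to [wk2_response()].
#' @return A `lumped_response` data frame; the reduced [windkessel2()] is
#'   attached as attribute `windkessel`.
#' @export
frank_whole_system <- function(net, inflow, ...) {
  wk <- reduce_to_windkessel(net)
  out <- wk2_response(inflow, wk, ...)
  attr(out, "windkessel") <- wk
  out
}
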