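#' A periodic inflow waveform
#'
#' Volumetric flow prescribed at the network root over one cardiac period,
#' extended periodically. Built either from time/flow samples (a periodic
#' interpolating spline is used between samples) or from an analytic
#' closure `q_fun(t)` defined on `[0, period)`.
#'
#' @param period Cardiac period T (s), > 0.
#' @param time,flow Sample times (s, strictly increasing, within one
#'   period) and flows (m^3/s). Ignored when `q_fun` is given, except as
#'   stored metadata.
#' @param q_fun Optional function of time on `[0, period)` returning the
#'   flow (m^3/s); evaluated modulo the period.
#' @param n_samples Number of stored samples when only `q_fun` is given.
#' @return An object of class `inflow_waveform` with elements `period`,
#'   `time`, `flow` and the periodic evaluator `q_fun`.
#' @export
#' @examples
#' iw <- make_inflow(period = 1, stroke_volume = 70e-6, systolic_fraction = 0.3)
#' iw$q_fun(c(0.1, 0.5))
inflow_waveform <- function(period, time = NULL, flow = NULL, q_fun = NULL,
                            n_samples = 256L) {
  stopifnot(is.numeric(period), length(period) == 1L, period > 0)
  if (is.null(q_fun)) {
    if (is.null(time) || is.null(flow))
      stop("supply either samples (time, flow) or q_fun")
    stopifnot(length(time) == length(flow), length(time) >= 2L)
    if (any(diff(time) <= 0)) stop("inflow sample times must be strictly increasing")
    if (min(time) < 0 || max(time) > period)
      stop("inflow sample times must lie within one period")
    ## periodic interpolation; close the cycle if the samples do not
    tt <- time; qq <- flow
    if (tt[1] > 0) { tt <- c(tt, period + tt[1]); qq <- c(qq, qq[1]) }
    else if (max(tt) < period) { tt <- c(tt, period); qq <- c(qq, qq[1]) }
    if (abs(qq[length(qq)] - qq[1]) > 0) qq[length(qq)] <- qq[1]
    sp <- stats::splinefun(tt, qq, method = "periodic")
    t0 <- tt[1]
    q_fun <- function(t) sp(t0 + (t - t0) %% period)
  } else {
    base_fun <- q_fun
    q_fun <- function(t) base_fun(t %% period)
    if (is.null(time)) {
      time <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
      flow <- q_fun(time)
    }
  }
  structure(list(period = period, time = time, flow = flow, q_fun = q_fun),
            class = "inflow_waveform")
}

#' @export
print.inflow_waveform <- function(x, ...) {
  sv <- stats::integrate(x$q_fun, 0, x$period, subdivisions = 500L,
                         rel.tol = 1e-8)$value
  cat(sprintf("Inflow waveform: T = %g s, peak %.4g mL/s, stroke volume %.4g mL\n",
              x$period, 1e6 * max(x$flow), 1e6 * sv))
  invisible(x)
}

#' Read / write an inflow waveform as CSV
#'
#' Two-column CSV with header `time_s, flow_m3s` spanning one period.
#'
#' @param path File path.
#' @param period Cardiac period (s); defaults to the last sample time.
#' @param inflow An [inflow_waveform()] (for writing).
#' @return `read_inflow()`: an [inflow_waveform()]. `write_inflow()`: the
#'   path, invisibly.
#' @export
read_inflow <- function(path, period = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "flow_m3s") %in% names(d)))
    stop("inflow CSV must have columns time_s and flow_m3s")
  if (is.null(period)) period <- max(d$time_s)
  keep <- d$time_s < period
  inflow_waveform(period, time = d$time_s[keep], flow = d$flow_m3s[keep])
}

#' @rdname read_inflow
#' @export
write_inflow <- function(inflow, path) {
  utils::write.csv(data.frame(time_s = inflow$time, flow_m3s = inflow$flow),
                   path, row.names = FALSE)
  invisible(path)
}
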