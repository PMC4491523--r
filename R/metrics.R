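#' Relative waveform-error metrics
#'
#' The six relative errors comparing a reduced model's pressure and flow
#' waveforms against the complete model's at one site, over a common
#' `N_t`-point time grid:
#' \deqn{\epsilon_{P,avg} = \frac{1}{N_t}\sum_i |P^R_i - P^C_i| / |P^C_i|,\quad
#'       \epsilon_{Q,avg} = \frac{1}{N_t}\sum_i |Q^R_i - Q^C_i| / \max_j Q^C_j,}
#' \deqn{\epsilon_{P,sys} = (\max P^R - \max P^C)/\max P^C,\quad
#'       \epsilon_{Q,sys} = (\max Q^R - \max Q^C)/\max Q^C,}
#' \deqn{\epsilon_{P,dias} = (\min P^R - \min P^C)/\min P^C,\quad
#'       \epsilon_{Q,dias} = (\min Q^R - \min Q^C)/\max_j Q^C_j.}
#' Flow errors are normalised by the maximum flow of the complete model to
#' avoid division by near-zero diastolic flow. Average errors are
#' absolute-valued; systolic and diastolic errors carry sign.
#'
#' @param complete,reduced [waveform_set()]s sampled on identical time
#'   grids, or two-column lists with elements `p` and `q`.
#' @param site Probe site name (when waveform sets are given).
#' @return Object of class `error_report`: list with fields `p_avg`,
#'   `q_avg`, `p_sys`, `q_sys`, `p_dias`, `q_dias` (dimensionless
#'   fractions; the print method shows percent).
#' @export
#' @examples
#' ep <- error_metrics(p_complete = c(100, 120, 110), p_reduced = c(101, 121, 111),
#'                     q_complete = c(0, 10, 5), q_reduced = c(1, 10, 4))
#' ep
error_report <- function(complete, reduced, site) {
  pc <- waveforms_at(complete, site)
  pr <- waveforms_at(reduced, site)
  if (length(pc$time) != length(pr$time) ||
      max(abs(pc$time - pr$time)) > 1e-9 * max(pc$time[length(pc$time)], 1))
    stop("error_report: waveform sets are not on the same time grid")
  error_metrics(pc$p, pr$p, pc$q, pr$q)
}

#' @rdname error_report
#' @param p_complete,p_reduced,q_complete,q_reduced Pressure (Pa) and flow
#'   (m^3/s) series on a common grid.
#' @export
error_metrics <- function(p_complete, p_reduced, q_complete, q_reduced) {
  nt <- length(p_complete)
  if (length(p_reduced) != nt || length(q_complete) != nt ||
      length(q_reduced) != nt)
    stop("error_metrics: series lengths differ")
  if (min(p_complete) <= 0)
    stop("error_metrics: complete-model pressure must be positive ",
         "(diastolic normaliser)")
  qmax <- max(q_complete)
  if (qmax <= 0)
    stop("error_metrics: complete-model flow maximum must be positive")
  structure(list(
    p_avg = mean(abs(p_reduced - p_complete) / abs(p_complete)),
    q_avg = mean(abs(q_reduced - q_complete)) / qmax,
    p_sys = (max(p_reduced) - max(p_complete)) / max(p_complete),
    q_sys = (max(q_reduced) - qmax) / qmax,
    p_dias = (min(p_reduced) - min(p_complete)) / min(p_complete),
    q_dias = (min(q_reduced) - min(q_complete)) / qmax),
    class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("Relative waveform errors (reduced vs complete)\n")
  cat(sprintf("  pressure: avg %7.3f%%  sys %+8.3f%%  dias %+8.3f%%\n",
              100 * x$p_avg, 100 * x$p_sys, 100 * x$p_dias))
  cat(sprintf("  flow    : avg %7.3f%%  sys %+8.3f%%  dias %+8.3f%%\n",
              100 * x$q_avg, 100 * x$q_sys, 100 * x$q_dias))
  invisible(x)
}

#' @export
as.data.frame.error_report <- function(x, ...) {
  data.frame(p_avg = x$p_avg, q_avg = x$q_avg, p_sys = x$p_sys,
             q_sys = x$q_sys, p_dias = x$p_dias, q_dias = x$q_dias)
}
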