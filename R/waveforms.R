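#' A set of probe waveforms
#'
#' Pressure, flow and area time series over one (converged) cardiac cycle
#' at a set of probe sites, all sharing one uniform time grid.
#'
#' @param time Time grid (s), uniform over one period, length `N_t`.
#' @param sites Named list; each element a list with numeric vectors `p`
#'   (Pa), `q` (m^3/s) and `a` (m^2) of length `N_t`.
#' @param period Cardiac period (s).
#' @param converged Logical: did the simulation reach cycle-to-cycle
#'   periodicity within the cycle budget?
#' @param cycles Number of cardiac cycles simulated.
#' @return Object of class `waveform_set`.
#' @export
waveform_set <- function(time, sites, period, converged = TRUE,
                         cycles = NA_integer_) {
  nt <- length(time)
  for (nm in names(sites)) {
    s <- sites[[nm]]
    if (length(s$p) != nt || length(s$q) != nt || length(s$a) != nt)
      stop("waveform_set: series at site '", nm, "' do not match the time grid")
    if (any(s$a <= 0)) stop("waveform_set: non-positive area at site '", nm, "'")
  }
  structure(list(time = time, sites = sites, period = period,
                 converged = converged, cycles = cycles),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("Waveform set: %d sites, N_t = %d, T = %g s, %s after %s cycles\n",
              length(x$sites), length(x$time), x$period,
              if (isTRUE(x$converged)) "periodic" else "NOT periodic",
              x$cycles))
  for (nm in names(x$sites)) {
    s <- x$sites[[nm]]
    cat(sprintf("  %-18s P [%7.1f, %7.1f] Pa, Q [%8.2f, %8.2f] mL/s\n",
                nm, min(s$p), max(s$p), 1e6 * min(s$q), 1e6 * max(s$q)))
  }
  invisible(x)
}

#' Extract one site's series from a waveform set
#'
#' @param ws A [waveform_set()] (or a bare list with `time`, `p`, `q`).
#' @param site Site name; may be omitted when only one site is present.
#' @return List with `time`, `p`, `q`, `a`.
#' @export
waveforms_at <- function(ws, site = NULL) {
  if (!inherits(ws, "waveform_set")) {
    stopifnot(!is.null(ws$p), !is.null(ws$q))
    return(ws)
  }
  if (is.null(site)) {
    if (length(ws$sites) != 1L)
      stop("site must be named when the waveform set has several sites")
    site <- names(ws$sites)[1]
  }
  if (!site %in% names(ws$sites))
    stop("no probe site '", site, "' in waveform set (have: ",
         paste(names(ws$sites), collapse = ", "), ")")
  c(list(time = ws$time), ws$sites[[site]])
}

#' Read / write probe waveforms as CSV
#'
#' Long-format CSV with columns `time`, `site`, `pressure`, `flow`,
#' `area`.
#'
#' @param ws A [waveform_set()].
#' @param path File path.
#' @param period,converged,cycles Metadata on read (period defaults to
#'   the last time sample).
#' @return `write_waveforms()`: the path, invisibly. `read_waveforms()`:
#'   a [waveform_set()].
#' @export
write_waveforms <- function(ws, path) {
  rows <- do.call(rbind, lapply(names(ws$sites), function(nm) {
    s <- ws$sites[[nm]]
    data.frame(time = ws$time, site = nm, pressure = s$p, flow = s$q,
               area = s$a)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path, period = NULL, converged = TRUE,
                           cycles = NA_integer_) {
  d <- utils::read.csv(path)
  need <- c("time", "site", "pressure", "flow", "area")
  if (!all(need %in% names(d)))
    stop("waveform CSV must have columns ", paste(need, collapse = ", "))
  sites <- lapply(split(d, d$site), function(g)
    list(p = g$pressure, q = g$flow, a = g$area))
  time <- d$time[d$site == d$site[1]]
  if (is.null(period)) period <- max(time)
  waveform_set(time, sites, period, converged, cycles)
}
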