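#' Run a model-reduction study
#'
#' Simulates the complete network, then applies a schedule of reduction
#' steps, re-simulates each progressively reduced model, and reports the
#' six relative waveform-error metrics at every probe that survives the
#' reduction. The final schedule entry may reduce the whole system to a
#' single two-element windkessel ([frank_whole_system()]), for which only
#' the root pressure is compared.
#'
#' Schedule entries are lists with a `type` field:
#' \describe{
#'   \item{`list(type = "trim_generation")`}{Lump the deepest generation
#'     of bifurcations ([trim_generation()]).}
#'   \item{`list(type = "to_generation", generation =, keep =)`}{Trim
#'     iteratively down to a generation ([trim_to_generation()]).}
#'   \item{`list(type = "pair", junction =)`}{Lump one peripheral
#'     junction ([trim_peripheral_pair()]).}
#'   \item{`list(type = "full")`}{Frank's whole-system windkessel.}
#' }
#' Steps are cumulative: each acts on the previous step's network.
#'
#' @param net An [arterial_network()] (the complete model).
#' @param inflow An [inflow_waveform()].
#' @param schedule List of reduction steps (see Details). Default: trim
#'   one generation at a time until only the root's generation remains,
#'   then the whole-system windkessel.
#' @param probes Probe data frame (`segment`, `position`, `name`) passed
#'   to the solver; defaults to the inlet of every segment of the
#'   complete model that survives to the last 1-D model, plus the root.
#' @param settings [solver_settings()] shared by all simulations.
#' @param out_dir Optional directory; if given, probe waveforms (CSV) and
#'   the error summary (CSV + JSON) are written there.
#' @return Object of class `reduction_study`: list with `complete` (the
#'   full-model solution), `models` (per step: `network` or `windkessel`,
#'   `solution`, `errors`), and `summary` (data frame of all error
#'   metrics in percent).
#' @export
run_reduction_study <- function(net, inflow, schedule = NULL, probes = NULL,
                                settings = solver_settings(),
                                out_dir = NULL) {
  if (is.null(schedule)) {
    gens <- net_generations(net)
    schedule <- c(lapply(seq_len(max(gens) - min(gens)),
                         function(i) list(type = "trim_generation")),
                  list(list(type = "full")))
  }
  ## build the chain of reduced networks first, so default probes can be
  ## restricted to sites present in every 1-D model
  nets <- list(net)
  for (st in schedule) {
    cur <- nets[[length(nets)]]
    nxt <- switch(st$type,
      trim_generation = trim_generation(cur),
      to_generation = trim_to_generation(cur, st$generation,
                                         keep = st$keep %||% character(0)),
      pair = trim_peripheral_pair(cur, st$junction),
      full = NULL,
      stop("unknown reduction step type: ", st$type))
    nets[length(nets) + 1L] <- list(nxt)   # keep NULL ("full") entries
  }
  oneD <- Filter(Negate(is.null), nets)
  common <- Reduce(intersect, lapply(oneD, net_ids))
  root <- net_root(net)
  if (is.null(probes))
    probes <- data.frame(segment = common, position = 0, name = common,
                         stringsAsFactors = FALSE)
  settings$probes <- probes
  message("simulating complete model (", length(net$segments), " segments)")
  complete <- simulate_network(net, inflow, settings)
  models <- vector("list", length(schedule))
  for (k in seq_along(schedule)) {
    st <- schedule[[k]]
    red <- nets[[k + 1L]]
    if (is.null(red)) {               # whole-system windkessel
      resp <- frank_whole_system(
        net, inflow, t_end = settings$cycles * inflow$period,
        n_out = settings$cycles * settings$n_t)
      keep <- resp$time >= (settings$cycles - 1L) * inflow$period
      t0 <- resp$time[keep] - (settings$cycles - 1L) * inflow$period
      p0 <- stats::approx(t0, resp$p_in[keep], xout = complete$waves$time,
                          rule = 2)$y
      qc <- waveforms_at(complete$waves, root)$q
      err <- list(error_metrics(waveforms_at(complete$waves, root)$p, p0,
                                qc, qc))
      names(err) <- root
      models[[k]] <- list(windkessel = attr(resp, "windkessel"),
                          solution = resp, errors = err,
                          label = "windkessel", segments = 0L)
    } else {
      sett <- settings
      sett$probes <- probes[probes$segment %in% net_ids(red), , drop = FALSE]
      message("simulating reduced model (", length(red$segments),
              " segments)")
      sol <- simulate_network(red, inflow, sett)
      err <- lapply(sett$probes$name, function(nm)
        error_report(complete$waves, sol$waves, nm))
      names(err) <- sett$probes$name
      models[[k]] <- list(network = red, solution = sol, errors = err,
                          label = paste0("seg", length(red$segments)),
                          segments = length(red$segments))
    }
  }
  summ <- do.call(rbind, lapply(models, function(m)
    do.call(rbind, lapply(names(m$errors), function(nm)
      cbind(data.frame(model = m$label, segments = m$segments, site = nm,
                       stringsAsFactors = FALSE),
            100 * as.data.frame(m$errors[[nm]]))))))
  rownames(summ) <- NULL
  out <- structure(list(complete = complete, models = models,
                        summary = summ),
                   class = "reduction_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summ, file.path(out_dir, "error_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summ, file.path(out_dir, "error_summary.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
    write_waveforms(complete$waves, file.path(out_dir, "complete.csv"))
    for (m in models)
      if (!is.null(m$network))
        write_waveforms(m$solution$waves,
                        file.path(out_dir, paste0(m$label, ".csv")))
  }
  out
}

#' @export
print.reduction_study <- function(x, ...) {
  cat("Reduction study:", length(x$complete$waves$sites), "probes,",
      length(x$models), "reduced models\n")
  cat("Mean |pressure| error by model (percent, across probes):\n")
  agg <- stats::aggregate(p_avg ~ model + segments, data = x$summary, FUN = mean)
  print(agg[order(-agg$segments), ], row.names = FALSE)
  invisible(x)
}
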