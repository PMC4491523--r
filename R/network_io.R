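#' Read and write arterial-network documents
#'
#' Networks are serialised as JSON (canonical) or YAML (accepted) documents
#' with top-level keys `globals`, `segments`, `terminals` and optionally
#' `inflow` and `units`. Each segment entry carries `id`, `parent` (absent
#' or null for the root), `length`, the inlet/outlet diastolic geometry as
#' `radius_in`/`radius_out` (m) or `area_in`/`area_out` (m^2), and the wall
#' stiffness as `beta_in`/`beta_out` (Pa m) or `pwv_in`/`pwv_out` (m/s,
#' converted using the document's blood density). Each terminal entry
#' carries `segment`, `r1` (a number, or the string `"Z0"` to match the
#' characteristic impedance of the leaf outlet), `r2`, `c` and `p_out`.
#'
#' With `units: "clinical"` the document expresses lengths in cm, radii in
#' mm, pressures in mmHg (1 mmHg = 133.322 Pa), flows in mL/s, resistances
#' in mmHg s/mL and compliances in mL/mmHg; `units: "SI"` (the default and
#' the only dialect written) uses m, Pa, m^3/s and SI-derived R and C.
#'
#' @param path File path; format inferred from the extension
#'   (`.json` vs `.yaml`/`.yml`) unless `format` is given.
#' @param format `"json"` or `"yaml"`.
#' @param net An [arterial_network()] (for writing).
#' @param inflow Optional [inflow_waveform()] embedded on write.
#' @return `read_network()`: an [arterial_network()]; if the document
#'   embeds an inflow it is attached as `attr(net, "inflow")`.
#'   `write_network()`: the path, invisibly.
#' @export
read_network <- function(path, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) "yaml" else "json"
  doc <- if (format == "yaml") yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  network_from_document(doc)
}

#' @rdname read_network
#' @export
write_network <- function(net, path, format = c("auto", "json", "yaml"),
                          inflow = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) "yaml" else "json"
  doc <- network_to_document(net, inflow = inflow)
  if (format == "yaml") yaml::write_yaml(doc, path, precision = 15L)
  else jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, null = "null")
  invisible(path)
}

## unit scale factors from document units to SI
io_scales <- function(units) {
  if (is.null(units) || identical(units, "SI")) {
    list(length = 1, radius = 1, area = 1, pressure = 1, flow = 1,
         resistance = 1, compliance = 1)
  } else if (identical(units, "clinical")) {
    list(length = 1e-2, radius = 1e-3, area = 1e-6, pressure = MMHG_PA,
         flow = 1e-6, resistance = MMHG_PA / 1e-6, compliance = 1e-6 / MMHG_PA)
  } else stop("unknown units dialect: ", units)
}

network_from_document <- function(doc) {
  if (is.null(doc$segments) || is.null(doc$terminals))
    stop("network document must contain 'segments' and 'terminals'")
  sc <- io_scales(doc$units)
  g <- doc$globals
  globals <- global_params(
    density = g$density %||% 1050,
    viscosity = g$viscosity %||% 4e-3,
    profile_order = g$profile_order %||% 9,
    diastolic_pressure = sc$pressure * (g$diastolic_pressure %||% 0))
  rho <- globals$density
  segments <- lapply(doc$segments, function(s) {
    if (is.null(s$id)) stop("segment without an id")
    if (!is.null(s$radius_in)) {
      r_in <- sc$radius * s$radius_in
      r_out <- sc$radius * (s$radius_out %||% s$radius_in)
    } else if (!is.null(s$area_in)) {
      r_in <- sqrt(sc$area * s$area_in / pi)
      r_out <- sqrt(sc$area * (s$area_out %||% s$area_in) / pi)
    } else stop("segment '", s$id, "': give radius_in or area_in")
    args <- list(id = s$id, length = sc$length * s$length,
                 radius_in = r_in, radius_out = r_out,
                 parent = {
                   p <- s$parent
                   if (is.null(p) || length(p) == 0L || is.na(p[[1]]) ||
                       identical(p[[1]], "")) NA_character_
                   else as.character(p[[1]])
                 },
                 generation = s$generation %||% NA_integer_)
    if (!is.null(s$beta_in)) {
      args$beta_in <- s$beta_in
      args$beta_out <- s$beta_out %||% s$beta_in
    } else if (!is.null(s$pwv_in)) {
      args$pwv_in <- s$pwv_in
      args$pwv_out <- s$pwv_out %||% s$pwv_in
      args$rho <- rho
    } else stop("segment '", s$id, "': give beta_in or pwv_in")
    do.call(arterial_segment, args)
  })
  names(segments) <- vapply(segments, `[[`, character(1), "id")
  terminals <- list()
  for (tm in doc$terminals) {
    if (is.null(tm$segment)) stop("terminal without a segment id")
    id <- tm$segment
    if (is.null(segments[[id]]))
      stop("terminal attached to unknown segment '", id, "'")
    r1 <- tm$r1 %||% "Z0"
    if (identical(r1, "Z0"))
      r1 <- characteristic_impedance(segments[[id]], rho = rho)
    else r1 <- sc$resistance * r1
    terminals[[id]] <- windkessel3(r1, sc$resistance * tm$r2,
                                   sc$compliance * tm$c,
                                   sc$pressure * (tm$p_out %||% 0))
  }
  net <- arterial_network(segments, terminals, globals)
  if (!is.null(doc$inflow)) {
    infl <- doc$inflow
    attr(net, "inflow") <- inflow_waveform(infl$period,
                                           time = as.numeric(infl$time),
                                           flow = sc$flow * as.numeric(infl$flow))
  }
  net
}

network_to_document <- function(net, inflow = NULL) {
  g <- net$globals
  doc <- list(
    units = "SI",
    globals = list(density = g$density, viscosity = g$viscosity,
                   profile_order = g$profile_order,
                   diastolic_pressure = g$diastolic_pressure),
    segments = lapply(unname(net$segments), function(s) {
      out <- list(id = s$id, parent = if (is.na(s$parent)) NULL else s$parent,
                  length = s$length, radius_in = s$radius_in,
                  radius_out = s$radius_out, beta_in = s$beta_in,
                  beta_out = s$beta_out)
      if (!is.na(s$generation)) out$generation <- s$generation
      out
    }),
    terminals = lapply(names(net$terminals), function(id) {
      wk <- net$terminals[[id]]
      list(segment = id, r1 = wk$r1, r2 = wk$r2, c = wk$c, p_out = wk$p_out)
    }))
  if (!is.null(inflow))
    doc$inflow <- list(period = inflow$period, time = inflow$time,
                       flow = inflow$flow)
  doc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
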