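#' An arterial network
#'
#' A rooted tree of [arterial_segment()]s. Each segment names its parent
#' (`NA` for the single root, whose inlet receives the inflow waveform);
#' every leaf segment carries exactly one [windkessel3()] outflow model.
#' Junctions may have any number of children (the packaged fixture trees are
#' binary, but n-furcations are permitted).
#'
#' @param segments List of [arterial_segment()]s (parent ids set on the
#'   segments themselves).
#' @param terminals Named list of [windkessel3()]s keyed by leaf segment id.
#' @param globals A [global_params()] object.
#' @param validate Check the tree structure (default `TRUE`).
#' @return An object of class `arterial_network`.
#' @export
#' @examples
#' g <- global_params()
#' s <- arterial_segment("v", 0.1, 0.003, pwv_in = 6, rho = g$density)
#' net <- arterial_network(list(s), list(v = windkessel3(0, 1e9, 1e-10)), g)
#' count_parameters(net)
arterial_network <- function(segments, terminals, globals = global_params(),
                             validate = TRUE) {
  if (inherits(segments, "arterial_segment")) segments <- list(segments)
  ids <- vapply(segments, function(s) s$id, character(1))
  names(segments) <- ids
  net <- structure(list(segments = segments, terminals = terminals,
                        globals = globals),
                   class = "arterial_network")
  if (validate) validate_network(net)
  net
}

#' Validate the structure of an arterial network
#'
#' Checks id uniqueness, existence of a single root, acyclicity,
#' one-windkessel-per-leaf, and positivity invariants. Errors (naming the
#' offending segment) on violation; returns the network invisibly.
#'
#' @param net An [arterial_network()].
#' @export
validate_network <- function(net) {
  segs <- net$segments
  ids <- names(segs)
  if (anyDuplicated(ids)) stop("duplicate segment ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  parents <- vapply(segs, function(s) s$parent, character(1))
  is_root <- is.na(parents)
  if (sum(is_root) != 1L)
    stop("network must have exactly one root segment (found ", sum(is_root), ")")
  bad <- !is_root & !(parents %in% ids)
  if (any(bad))
    stop("unknown parent for segment(s): ", paste(ids[bad], collapse = ", "))
  ## acyclicity / connectivity: walk up from every segment
  for (id in ids) {
    seen <- character(0)
    cur <- id
    while (!is.na(segs[[cur]]$parent)) {
      if (cur %in% seen) stop("cycle detected at segment '", id, "'")
      seen <- c(seen, cur)
      cur <- segs[[cur]]$parent
      if (length(seen) > length(ids)) stop("cycle detected at segment '", id, "'")
    }
  }
  leaves <- net_leaves(net)
  missing <- setdiff(leaves, names(net$terminals))
  if (length(missing))
    stop("leaf segment(s) lacking a terminal windkessel: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(net$terminals), leaves)
  if (length(extra))
    stop("terminal windkessel attached to non-leaf segment(s): ",
         paste(extra, collapse = ", "))
  for (wk in net$terminals)
    if (!inherits(wk, "windkessel3")) stop("terminals must be windkessel3 objects")
  invisible(net)
}

## ---- accessors -----------------------------------------------------------

#' Network accessors
#'
#' Small helpers over the tree structure of an [arterial_network()]:
#' segment ids, the root id, leaf ids, the children of each segment, and
#' segment generations.
#'
#' @param net An [arterial_network()].
#' @return `net_ids()`, `net_leaves()`: character vectors. `net_root()`:
#'   the root segment id. `net_children()`: named list of child-id vectors.
#'   `net_generations()`: named integer vector (see Details).
#' @details Generations count bifurcations from the root: stored
#'   `generation` labels are used when every segment has one (fixture trees
#'   label the aortic trunk generation 0); otherwise the generation is
#'   computed as the parent's generation plus one at junctions with more
#'   than one child (a single continuing child keeps its parent's
#'   generation).
#' @export
net_ids <- function(net) names(net$segments)

#' @rdname net_ids
#' @export
net_root <- function(net) {
  parents <- vapply(net$segments, function(s) s$parent, character(1))
  names(net$segments)[is.na(parents)]
}

#' @rdname net_ids
#' @export
net_children <- function(net) {
  ids <- net_ids(net)
  parents <- vapply(net$segments, function(s) s$parent, character(1))
  ch <- lapply(ids, function(id) ids[!is.na(parents) & parents == id])
  names(ch) <- ids
  ch
}

#' @rdname net_ids
#' @export
net_leaves <- function(net) {
  ch <- net_children(net)
  names(ch)[vapply(ch, length, integer(1)) == 0L]
}

#' @rdname net_ids
#' @export
net_generations <- function(net) {
  segs <- net$segments
  stored <- vapply(segs, function(s) s$generation, integer(1))
  if (!anyNA(stored)) return(stored)
  ch <- net_children(net)
  gen <- stats::setNames(rep(NA_integer_, length(segs)), names(segs))
  gen[net_root(net)] <- 0L
  queue <- net_root(net)
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    kids <- ch[[id]]
    if (length(kids)) {
      gen[kids] <- gen[id] + if (length(kids) > 1L) 1L else 0L
      queue <- c(queue, kids)
    }
  }
  gen
}

#' Topological order of the segment ids (root first)
#' @param net An [arterial_network()].
#' @return Character vector of segment ids; every parent precedes its
#'   children.
#' @export
net_topo_order <- function(net) {
  ch <- net_children(net)
  out <- character(0)
  queue <- net_root(net)
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    out <- c(out, id)
    queue <- c(queue, ch[[id]])
  }
  out
}

#' @export
print.arterial_network <- function(x, ...) {
  gen <- net_generations(x)
  cat(sprintf("Arterial network: %d segments, %d terminal windkessels, max generation %d\n",
              length(x$segments), length(x$terminals), max(gen)))
  cat(sprintf("  root: '%s'; parameters: %d\n", net_root(x), count_parameters(x)))
  invisible(x)
}

## ---- parameter accounting ------------------------------------------------

#' Count the independent parameters of a network
#'
#' Each arterial segment contributes three parameters (length, diastolic
#' area, diastolic PWV); each terminal windkessel contributes two
#' (peripheral resistance and compliance; the proximal resistance is tied
#' to the characteristic impedance of the feeding vessel). Six further
#' parameters are global: blood density, blood viscosity, the shape of the
#' velocity profile, the diastolic pressure, the inflow waveform and the
#' (shared) terminal outflow pressure.
#'
#' @param net An [arterial_network()].
#' @return Integer parameter count: `3 * segments + 2 * terminals + 6`.
#' @export
#' @examples
#' count_parameters(make_tree("tree-55-style"))  # 227
count_parameters <- function(net) {
  3L * length(net$segments) + 2L * length(net$terminals) + 6L
}

## ---- hypertensive transform ----------------------------------------------

#' Hypertensive transformation of a network
#'
#' Stiffens every vessel and raises every peripheral resistance by a
#' common factor: each segment's diastolic PWV is multiplied by `factor`
#' (implemented as `beta -> factor^2 * beta` at fixed diastolic area) and
#' each terminal's total resistance `R1 + R2` is multiplied by `factor`.
#' The proximal resistance is re-matched to the new characteristic
#' impedance of the feeding vessel's outlet and `R2` absorbs the
#' remainder; compliances and outflow pressures are unchanged.
#'
#' @param net An [arterial_network()].
#' @param factor Multiplier (> 0) applied to PWV and total peripheral
#'   resistance; 1.5 gives the canonical hypertensive variant.
#' @return The transformed [arterial_network()].
#' @export
apply_hypertension <- function(net, factor = 1.5) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("factor must be a positive scalar")
  if (factor == 1) return(net)
  rho <- net$globals$density
  net$segments <- lapply(net$segments, function(s) {
    s$beta_in <- factor^2 * s$beta_in
    s$beta_out <- factor^2 * s$beta_out
    s
  })
  net$terminals <- stats::setNames(lapply(names(net$terminals), function(id) {
    wk <- net$terminals[[id]]
    r_tot <- factor * (wk$r1 + wk$r2)
    z0 <- characteristic_impedance(net$segments[[id]], rho = rho)
    r2 <- r_tot - z0
    if (r2 <= 0)
      stop("apply_hypertension: outlet impedance of '", id,
           "' exceeds its scaled total resistance")
    windkessel3(z0, r2, wk$c, wk$p_out)
  }), names(net$terminals))
  net
}
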