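#' Axial integrals of a tapered vessel
#'
#' The three integrals that summarise a tapered 1D vessel for lumping:
#' \deqn{K_1 = \int_0^l \frac{A_d}{c_d^2}\,dx,\quad
#'       K_2 = \int_0^l \frac{dx}{A_d},\quad
#'       K_3 = \int_0^l \frac{dx}{A_d^2}.}
#' `K1 / rho` is the integrated compliance of the vessel, `K3` sets its
#' viscous resistance, and `K2` its (neglected) inertance. With the tube
#' law used here `A_d / c_d^2 = 2 \rho A_d^{3/2} / \beta`.
#'
#' Computed by adaptive Gauss--Kronrod quadrature (relative tolerance
#' 1e-10); `K3` is sharply weighted toward the narrow end of a tapered
#' vessel, which the adaptive rule resolves.
#'
#' @param segment An [arterial_segment()].
#' @param globals A [global_params()] (the density enters `K1` through
#'   the wave speed).
#' @return List with elements `k1`, `k2`, `k3` (all zero when `length == 0`).
#' @export
vessel_integrals <- function(segment, globals = global_params()) {
  l <- segment$length
  if (l == 0) return(list(k1 = 0, k2 = 0, k3 = 0))
  rho <- globals$density
  quad <- function(f)
    stats::integrate(f, 0, l, rel.tol = 1e-10, abs.tol = 0,
                     subdivisions = 500L)$value
  k1 <- quad(function(x) {
    ad <- seg_area_d(segment, x)
    ad / seg_wave_speed_d(segment, x, rho)^2
  })
  k2 <- quad(function(x) 1 / seg_area_d(segment, x))
  k3 <- quad(function(x) 1 / seg_area_d(segment, x)^2)
  list(k1 = k1, k2 = k2, k3 = k3)
}

#' Lumped resistance and compliance of a vessel
#'
#' Viscous resistance and integrated compliance of a 1D vessel:
#' \deqn{R_v = 2(\xi + 2)\pi\mu K_3, \qquad C_v = K_1 / \rho.}
#'
#' @inheritParams vessel_integrals
#' @return List with elements `r_v` (Pa s m^-3) and `c_v` (m^3 Pa^-1).
#' @export
vessel_rc <- function(segment, globals = global_params()) {
  k <- vessel_integrals(segment, globals)
  list(r_v = 2 * (globals$profile_order + 2) * pi * globals$viscosity * k$k3,
       c_v = k$k1 / globals$density)
}

#' Lump a terminal vessel and its RCR outlet into an RC windkessel
#'
#' Replaces a terminal 1D vessel (resistance `R_v`, compliance `C_v` from
#' [vessel_rc()]) plus its three-element windkessel (`R1`, `R2`, `C`) by
#' the equivalent two-element windkessel
#' \deqn{R_{new} = R_2 + R_1 + R_v,}
#' \deqn{C_{new} = \frac{C_v R_2 + C_v R_1 + C R_2 + R_v C_v}{R_2 + R_1 + R_v}.}
#' The equivalence holds when wave transit time across the vessel is small
#' compared with the cardiac period and fluid inertia is negligible
#' (see [reduction_validity()]).
#'
#' @param segment A leaf [arterial_segment()].
#' @param wk The [windkessel3()] attached to its outlet.
#' @param globals A [global_params()].
#' @return A [windkessel2()]; the outflow pressure is carried over.
#' @export
lump_terminal <- function(segment, wk, globals = global_params()) {
  rc <- vessel_rc(segment, globals)
  r_new <- wk$r2 + wk$r1 + rc$r_v
  c_new <- (rc$c_v * wk$r2 + rc$c_v * wk$r1 + wk$c * wk$r2 +
              rc$r_v * rc$c_v) / r_new
  windkessel2(r_new, c_new, wk$p_out)
}

#' Merge sibling RC lumps into an RCR windkessel on their parent
#'
#' Combines the two-element windkessels obtained by lumping all daughters
#' of a junction into a single three-element windkessel attached at the
#' parent's outlet. The total peripheral resistance is the parallel
#' combination \eqn{1/\sum_i 1/R_{T,i}}, the compliance is the sum
#' \eqn{\sum_i C_{T,i}}, and the proximal resistance `R_new,1` is matched
#' to the characteristic impedance of the parent outlet to minimise wave
#' reflection, `R_new,2` absorbing the remainder.
#'
#' @param parent The parent [arterial_segment()].
#' @param lumps List of [windkessel2()]s, one per daughter. All must share
#'   one outflow pressure.
#' @param globals A [global_params()].
#' @param r1 Proximal-resistance policy: `"z0"` (default; characteristic
#'   impedance of the parent outlet), `"zero"`, or a numeric value.
#' @return A [windkessel3()] to attach at the parent's outlet.
#' @details When the parent's characteristic impedance is not smaller than
#'   the combined peripheral resistance (a degenerate configuration the
#'   lumping formulas do not cover), `R_new,1` is clamped to 99% of the
#'   total with a warning so that `R_new,2` stays positive.
#' @export
merge_siblings <- function(parent, lumps, globals = global_params(),
                           r1 = "z0") {
  if (!length(lumps)) stop("merge_siblings: no lumps to merge")
  p_out <- vapply(lumps, `[[`, numeric(1), "p_out")
  if (diff(range(p_out)) > 1e-9 * (1 + max(abs(p_out))))
    stop("merge_siblings: mismatched outflow pressures at junction of '",
         parent$id, "'")
  r_total <- 1 / sum(1 / vapply(lumps, `[[`, numeric(1), "r"))
  c_new <- sum(vapply(lumps, `[[`, numeric(1), "c"))
  r1_val <- if (identical(r1, "z0")) {
    characteristic_impedance(parent, rho = globals$density)
  } else if (identical(r1, "zero")) 0 else as.numeric(r1)
  if (r1_val >= r_total) {
    warning("merge_siblings: parent impedance at '", parent$id,
            "' exceeds the combined peripheral resistance; clamping R1")
    r1_val <- 0.99 * r_total
  }
  windkessel3(r1_val, r_total - r1_val, c_new, p_out[1])
}

#' Lump all leaf children of one junction into a terminal windkessel
#'
#' Applies [lump_terminal()] to every child of `parent_id` (all of which
#' must be leaves) and [merge_siblings()] to the results; the children
#' are removed and the merged RCR is attached at the parent's outlet.
#'
#' @param net An [arterial_network()].
#' @param parent_id Id of the junction's parent segment.
#' @param r1 Proximal-resistance policy, as in [merge_siblings()].
#' @return The reduced [arterial_network()].
#' @export
lump_children_of <- function(net, parent_id, r1 = "z0") {
  ch <- net_children(net)[[parent_id]]
  if (!length(ch)) stop("segment '", parent_id, "' has no children to lump")
  not_leaf <- ch[!(ch %in% net_leaves(net))]
  if (length(not_leaf))
    stop("cannot lump non-leaf child(ren) of '", parent_id, "': ",
         paste(not_leaf, collapse = ", "))
  lumps <- lapply(ch, function(id)
    lump_terminal(net$segments[[id]], net$terminals[[id]], net$globals))
  wk <- merge_siblings(net$segments[[parent_id]], lumps, net$globals, r1 = r1)
  net$segments[ch] <- NULL
  net$terminals[ch] <- NULL
  net$terminals[[parent_id]] <- wk
  validate_network(net)
}

#' Trim the deepest generation of a network
#'
#' Lumps every segment of the deepest generation (together with its
#' terminal windkessel) into a two-element windkessel, merges sibling
#' lumps into a three-element windkessel on their parent, and removes the
#' generation. Every deepest-generation segment must be a leaf and all of
#' its junction siblings must belong to the same generation (this holds
#' for the packaged fixture trees down to the first generation; use
#' [trim_to_generation()] with a `keep` set for selective trimming).
#'
#' @param net An [arterial_network()].
#' @return The reduced [arterial_network()].
#' @export
#' @examples
#' net53 <- trim_generation(make_tree("tree-55-style"))
#' length(net53$segments)  # 53
trim_generation <- function(net) {
  gen <- net_generations(net)
  gmax <- max(gen)
  if (gmax < 1) stop("nothing to trim: network has no generations below the root")
  deepest <- names(gen)[gen == gmax]
  leaves <- net_leaves(net)
  if (!all(deepest %in% leaves))
    stop("deepest-generation segment(s) are not leaves: ",
         paste(setdiff(deepest, leaves), collapse = ", "))
  parents <- unique(vapply(net$segments[deepest], `[[`, character(1), "parent"))
  ch <- net_children(net)
  for (p in parents) {
    if (!all(ch[[p]] %in% deepest))
      stop("junction at '", p, "' mixes generations; use trim_to_generation()")
  }
  for (p in parents) net <- lump_children_of(net, p)
  net
}

#' Trim a network down to a target generation
#'
#' Repeatedly lumps junctions whose children are all leaves of generation
#' greater than `generation`, until none remain. Segments listed in
#' `keep` (and their ancestors) are never lumped, which reproduces
#' reductions that preserve a limb of interest.
#'
#' @param net An [arterial_network()].
#' @param generation Deepest generation to retain (>= 0; 0 keeps only
#'   the root's generation, e.g. an aortic trunk).
#' @param keep Character vector of segment ids to preserve.
#' @return The reduced [arterial_network()].
#' @export
trim_to_generation <- function(net, generation = 1L, keep = character(0)) {
  stopifnot(generation >= 0L)
  repeat {
    gen <- net_generations(net)
    leaves <- net_leaves(net)
    ch <- net_children(net)
    lumpable <- names(ch)[vapply(names(ch), function(p) {
      kids <- ch[[p]]
      length(kids) > 0 && all(kids %in% leaves) &&
        all(gen[kids] > generation) && !any(kids %in% keep)
    }, logical(1))]
    if (!length(lumpable)) break
    for (p in lumpable) net <- lump_children_of(net, p)
  }
  gen <- net_generations(net)
  over <- names(gen)[gen > generation & !(names(gen) %in% keep)]
  over <- setdiff(over, unlist(lapply(keep, function(k) ancestors_of(net, k))))
  if (length(over))
    stop("could not trim segment(s) to generation ", generation, ": ",
         paste(over, collapse = ", "))
  net
}

ancestors_of <- function(net, id) {
  out <- character(0)
  cur <- net$segments[[id]]$parent
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- net$segments[[cur]]$parent
  }
  out
}

#' Lump the most peripheral vessels at one junction
#'
#' Pairwise peripheral reduction: all children at the distal junction of
#' `junction` (each a leaf with a terminal windkessel) are lumped and
#' merged into a single three-element windkessel on `junction`.
#'
#' @param net An [arterial_network()].
#' @param junction Id of the parent segment whose children to lump.
#' @return The reduced [arterial_network()] (segment count decreases by
#'   the number of children).
#' @export
trim_peripheral_pair <- function(net, junction) {
  if (!junction %in% net_ids(net))
    stop("unknown segment '", junction, "'")
  lump_children_of(net, junction)
}

#' Reduce a whole network to a two-element windkessel
#'
#' Applies [lump_terminal()] / [merge_siblings()] leaf-to-root until a
#' single segment remains, then lumps it; the resulting RC windkessel
#' preserves the network's net resistance (series/parallel combination of
#' all vessel and peripheral resistances) exactly. Junctions are processed
#' deepest first, left-to-right by segment id, for deterministic output;
#' the result is order-invariant.
#'
#' @param net An [arterial_network()].
#' @param r1 Proximal-resistance policy for intermediate merges (see
#'   [merge_siblings()]).
#' @return A [windkessel2()] for the whole network.
#' @export
#' @examples
#' frank <- reduce_to_windkessel(make_tree("symmetric-tree", generations = 2))
reduce_to_windkessel <- function(net, r1 = "z0") {
  repeat {
    leaves <- net_leaves(net)
    if (length(net$segments) == 1L)
      return(lump_terminal(net$segments[[1]], net$terminals[[1]], net$globals))
    ch <- net_children(net)
    ready <- names(ch)[vapply(names(ch), function(p)
      length(ch[[p]]) > 0 && all(ch[[p]] %in% leaves), logical(1))]
    depth <- vapply(ready, function(id) length(ancestors_of(net, id)), integer(1))
    ready <- ready[order(-depth, ready)]
    net <- lump_children_of(net, ready[1], r1 = r1)
  }
}

#' Validity diagnostics for lumping a vessel
#'
#' The lumping formulas assume (i) the pulse transit time across the
#' vessel is much smaller than the cardiac period and (ii) fluid inertia
#' is negligible. This reports the transit-time ratio
#' \eqn{(\int_0^l dx/c_d)/T} (flagged above 0.1) and an inertia ratio
#' comparing the inertance impedance at the cardiac frequency,
#' \eqn{\rho K_2 (2\pi/T)}, with the resistive scale
#' \eqn{R_v + R_1 + R_2}.
#'
#' @param segment An [arterial_segment()].
#' @param wk The terminal [windkessel3()] (may be `NULL`; the resistive
#'   scale then uses `R_v` alone).
#' @param period Cardiac period T (s).
#' @param globals A [global_params()].
#' @return List with `transit_ratio`, `inertia_ratio`, and logical
#'   `flagged` (`TRUE` when `transit_ratio > 0.1`).
#' @export
reduction_validity <- function(segment, wk = NULL, period,
                               globals = global_params()) {
  stopifnot(period > 0)
  if (segment$length == 0)
    return(list(transit_ratio = 0, inertia_ratio = 0, flagged = FALSE))
  rho <- globals$density
  transit <- stats::integrate(function(x) 1 / seg_wave_speed_d(segment, x, rho),
                              0, segment$length, rel.tol = 1e-10,
                              abs.tol = 0, subdivisions = 500L)$value
  k <- vessel_integrals(segment, globals)
  rc <- vessel_rc(segment, globals)
  r_scale <- rc$r_v + if (!is.null(wk)) wk$r1 + wk$r2 else 0
  inertia <- if (r_scale > 0) rho * k$k2 * (2 * pi / period) / r_scale else Inf
  list(transit_ratio = transit / period, inertia_ratio = inertia,
       flagged = transit / period > 0.1)
}
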