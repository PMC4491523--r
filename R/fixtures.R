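#' Synthetic aortic inflow waveform
#'
#' Analytic surrogate for an aortic-root flow waveform: a half-sinusoid
#' ejection over the systolic fraction of the cycle and zero flow in
#' diastole. The peak flow is \eqn{\pi SV / (2 T_s)} so that the integral
#' over one period equals the stroke volume exactly.
#'
#' @param period Cardiac period T (s).
#' @param stroke_volume Ejected volume per beat (m^3); 70e-6 is a typical
#'   resting human stroke volume.
#' @param systolic_fraction Fraction of the period occupied by ejection.
#' @return An [inflow_waveform()].
#' @export
#' @examples
#' iw <- make_inflow(1, 70e-6, 0.3)
#' stats::integrate(iw$q_fun, 0, 1)$value  # 7e-05
make_inflow <- function(period = 0.8, stroke_volume = 70e-6,
                        systolic_fraction = 0.3) {
  stopifnot(period > 0, stroke_volume >= 0,
            systolic_fraction > 0, systolic_fraction < 1)
  ts <- systolic_fraction * period
  qpk <- pi * stroke_volume / (2 * ts)
  inflow_waveform(period, q_fun = function(t)
    ifelse(t < ts, qpk * sin(pi * t / ts), 0))
}

## ---- anatomy tables ------------------------------------------------------

## 55-segment systemic tree: aortic trunk (generation 0) plus five
## generations of bifurcations; radii (mm), lengths (cm) and diastolic
## PWVs (m/s) are representative values consistent with the declared
## physiological ranges.
anatomy_55 <- function() {
  tab <- c(
    "aorta_asc|NA|0|12.0|4.0|4.6",
    "arch_a|aorta_asc|0|11.2|2.5|4.6",
    "arch_b|arch_a|0|10.7|3.9|4.7",
    "thoracic_a|arch_b|0|10.0|5.2|4.8",
    "thoracic_b|thoracic_a|0|9.2|10.4|5.0",
    "abdominal_a|thoracic_b|0|8.0|5.3|5.2",
    "abdominal_b|abdominal_a|0|7.5|2.0|5.3",
    "abdominal_c|abdominal_b|0|7.0|2.0|5.4",
    "abdominal_d|abdominal_c|0|6.5|2.0|5.5",
    "abdominal_e|abdominal_d|0|6.0|5.3|5.6",
    "innominate|aorta_asc|1|6.2|3.4|5.0",
    "carotid_r|innominate|2|3.9|9.4|5.5",
    "carotid_int_r|carotid_r|3|2.6|13.9|6.5",
    "carotid_ext_r|carotid_r|3|2.3|13.9|6.5",
    "subclavian_r_a|innominate|2|4.2|6.8|5.5",
    "vertebral_r|subclavian_r_a|3|1.9|14.8|7.5",
    "subclavian_r_b|subclavian_r_a|3|3.5|22.5|6.0",
    "radial_r|subclavian_r_b|4|1.7|23.5|8.0",
    "ulnar_r_a|subclavian_r_b|4|2.2|6.7|8.0",
    "interosseous_r|ulnar_r_a|5|1.2|7.9|9.5",
    "ulnar_r_b|ulnar_r_a|5|1.9|17.1|8.5",
    "carotid_l|arch_a|1|3.9|13.9|5.5",
    "carotid_int_l|carotid_l|2|2.6|13.9|6.5",
    "carotid_ext_l|carotid_l|2|2.3|13.9|6.5",
    "subclavian_l_a|arch_b|1|4.2|3.4|5.5",
    "vertebral_l|subclavian_l_a|2|1.9|14.8|7.5",
    "subclavian_l_b|subclavian_l_a|2|3.5|22.5|6.0",
    "radial_l|subclavian_l_b|3|1.7|23.5|8.0",
    "ulnar_l_a|subclavian_l_b|3|2.2|6.7|8.0",
    "interosseous_l|ulnar_l_a|4|1.2|7.9|9.5",
    "ulnar_l_b|ulnar_l_a|4|1.9|17.1|8.5",
    "intercostals|thoracic_a|1|3.2|8.0|6.0",
    "celiac_a|thoracic_b|1|3.9|2.0|6.0",
    "celiac_b|celiac_a|2|2.6|2.0|6.5",
    "gastric|celiac_a|2|1.8|7.1|7.0",
    "hepatic|celiac_b|3|2.2|6.6|7.0",
    "splenic|celiac_b|3|1.8|6.3|7.0",
    "mesenteric_sup|abdominal_a|1|3.9|5.9|6.0",
    "renal_l|abdominal_b|1|2.6|3.2|6.5",
    "renal_r|abdominal_c|1|2.6|3.2|6.5",
    "mesenteric_inf|abdominal_d|1|1.6|5.0|7.0",
    "iliac_common_r|abdominal_e|1|3.7|5.8|6.0",
    "iliac_ext_r|iliac_common_r|2|2.9|14.4|6.5",
    "iliac_int_r|iliac_common_r|2|2.0|5.0|7.0",
    "femoral_r|iliac_ext_r|3|2.4|44.3|7.0",
    "femoral_deep_r|iliac_ext_r|3|2.0|12.6|7.5",
    "tibial_ant_r|femoral_r|4|1.3|32.1|9.0",
    "tibial_post_r|femoral_r|4|1.8|34.3|9.0",
    "iliac_common_l|abdominal_e|1|3.7|5.8|6.0",
    "iliac_ext_l|iliac_common_l|2|2.9|14.4|6.5",
    "iliac_int_l|iliac_common_l|2|2.0|5.0|7.0",
    "femoral_l|iliac_ext_l|3|2.4|44.3|7.0",
    "femoral_deep_l|iliac_ext_l|3|2.0|12.6|7.5",
    "tibial_ant_l|femoral_l|4|1.3|32.1|9.0",
    "tibial_post_l|femoral_l|4|1.8|34.3|9.0")
  d <- utils::read.table(text = paste(tab, collapse = "\n"), sep = "|",
                         col.names = c("id", "parent", "gen", "r_mm",
                                       "len_cm", "cd"),
                         stringsAsFactors = FALSE, na.strings = "NA")
  d
}

## hand extension: superficial palmar arch halves fed by the radial and
## (lower) ulnar arteries, each carrying two digital arteries
anatomy_hand <- function(side) {
  radial <- paste0("radial_", side)
  ulnarb <- paste0("ulnar_", side, "_b")
  g_rad <- if (side == "r") 4L else 3L   # continuation keeps the feeder's generation
  g_uln <- if (side == "r") 5L else 4L
  tab <- c(
    sprintf("palmar_arch_radial_%s|%s|%d|1.4|3.0|9.0", side, radial, g_rad),
    sprintf("digital_1_%s|palmar_arch_radial_%s|%d|1.1|6.0|10.0", side, side, g_rad + 1L),
    sprintf("digital_2_%s|palmar_arch_radial_%s|%d|1.1|6.0|10.0", side, side, g_rad + 1L),
    sprintf("palmar_arch_ulnar_%s|%s|%d|1.4|3.0|9.0", side, ulnarb, g_uln),
    sprintf("digital_3_%s|palmar_arch_ulnar_%s|%d|1.1|6.0|10.0", side, side, g_uln + 1L),
    sprintf("digital_4_%s|palmar_arch_ulnar_%s|%d|1.1|6.0|10.0", side, side, g_uln + 1L))
  utils::read.table(text = paste(tab, collapse = "\n"), sep = "|",
                    col.names = c("id", "parent", "gen", "r_mm", "len_cm", "cd"),
                    stringsAsFactors = FALSE, na.strings = "NA")
}

anatomy_67 <- function() rbind(anatomy_55(), anatomy_hand("r"), anatomy_hand("l"))

## symmetric binary tree of `generations` levels below the root
## An idealized impedance-matched binary tree: untapered segments whose
## daughter areas follow A_child = A_parent * c_parent-to-child ratio / 2,
## so every junction is reflection-free in the forward direction at the
## diastolic state (the standard idealization of healthy arterial
## branching). The r_mm column holds the nominal (unjittered) radii; the
## builder re-derives radii from the matching rule using the jittered
## wave speeds, so junctions stay matched for every seed.
anatomy_symmetric <- function(generations) {
  rows <- list(data.frame(id = "root", parent = NA_character_, gen = 0L,
                          r_mm = 12, len_cm = 6, cd = 5,
                          stringsAsFactors = FALSE))
  prev <- "root"
  r_nom <- 12
  for (g in seq_len(generations)) {
    r_nom <- r_nom * sqrt((5 + g) / (2 * (4 + g)))
    cur <- character(0)
    for (p in prev) for (k in 1:2) {
      id <- paste0(p, "_", k)
      rows[[length(rows) + 1L]] <-
        data.frame(id = id, parent = p, gen = g,
                   r_mm = r_nom, len_cm = 6 * 0.85^g, cd = 5 + g,
                   stringsAsFactors = FALSE)
      cur <- c(cur, id)
    }
    prev <- cur
  }
  tab <- do.call(rbind, rows)
  attr(tab, "matched") <- TRUE
  tab
}

## ---- network assembly ----------------------------------------------------

#' Deterministic synthetic arterial networks
#'
#' Generates schema-valid arterial trees for testing and demonstration:
#' \describe{
#'   \item{"single-vessel"}{One tapered vessel with an RCR outlet.}
#'   \item{"bifurcation"}{A parent and two daughters.}
#'   \item{"symmetric-tree"}{A full binary tree with `generations` levels
#'     of bifurcations below the root. Segments are untapered and every
#'     daughter's area follows from its parent's area and the two wave
#'     speeds so that junctions are forward reflection-free at the
#'     diastolic state (the usual idealization of healthy branching);
#'     jitter acts on wave speeds, lengths and the aortic root radius,
#'     never on the matching itself.}
#'   \item{"tree-55-style"}{A 55-segment systemic tree: a ten-segment
#'     aortic trunk and five generations of bifurcations with 28 terminal
#'     windkessels (227 independent parameters).}
#'   \item{"tree-67-style"}{The 55-segment tree extended with the
#'     superficial palmar arch and four digital arteries per hand
#'     (67 segments, 32 terminals, 271 parameters).}
#'   \item{"tree-21-style"}{The 55-style tree trimmed to the first
#'     generation of bifurcations (21 segments, 11 terminals).}
#'   \item{"tree-37-style"}{The 67-style tree trimmed to the first
#'     generation while preserving the innominate subtree (right carotid
#'     and right upper limb, including the hand): 37 segments.}
#' }
#' Topologies are fixed; radii, lengths and diastolic PWVs are
#' representative values jittered by up to +/-8% from `seed` and clamped
#' to the declared physiological ranges (radius 1--15 mm, length 2--50 cm,
#' PWV 4--12 m/s). Terminal windkessels take `R1` equal to the outlet
#' characteristic impedance; total peripheral resistances are distributed
#' inversely to outlet area and compliances proportionally to outlet
#' area, each scaled so that [reduce_to_windkessel()] of the full tree
#' returns exactly `net_resistance` and `net_compliance`.
#'
#' @param kind Fixture kind (see above).
#' @param generations Levels of bifurcations for `"symmetric-tree"`.
#' @param seed Integer seed; a fixed seed gives an identical network.
#' @param jitter Relative jitter amplitude applied to the representative
#'   parameter values (default 0.08; 0 gives the table values).
#' @param net_resistance Declared net (input) resistance of the tree
#'   (Pa s m^-3). Default 1.4e8, a resting mean arterial pressure of
#'   about 92 mmHg at 5.3 L/min.
#' @param net_compliance Declared total effective compliance (m^3 Pa^-1).
#'   Default 1.2e-8 (about 1.6 mL/mmHg).
#' @param p_out Terminal outflow pressure (Pa), shared by all terminals.
#' @param globals A [global_params()].
#' @return An [arterial_network()].
#' @export
#' @examples
#' net <- make_tree("tree-55-style", seed = 7)
#' count_parameters(net)  # 227
make_tree <- function(kind = c("single-vessel", "bifurcation",
                               "symmetric-tree", "tree-55-style",
                               "tree-67-style", "tree-21-style",
                               "tree-37-style"),
                      generations = 3L, seed = 1L, jitter = 0.08,
                      net_resistance = 1.4e8, net_compliance = 1.2e-8,
                      p_out = 0, globals = global_params()) {
  kind <- match.arg(kind)
  if (kind == "tree-21-style")
    return(trim_to_generation(
      make_tree("tree-55-style", seed = seed, jitter = jitter,
                net_resistance = net_resistance,
                net_compliance = net_compliance, p_out = p_out,
                globals = globals), 1L))
  if (kind == "tree-37-style")
    return(trim_to_generation(
      make_tree("tree-67-style", seed = seed, jitter = jitter,
                net_resistance = net_resistance,
                net_compliance = net_compliance, p_out = p_out,
                globals = globals), 1L,
      keep = innominate_subtree_ids()))
  tab <- switch(kind,
    "single-vessel" = data.frame(id = "vessel", parent = NA_character_,
                                 gen = 0L, r_mm = 10, len_cm = 24, cd = 5,
                                 stringsAsFactors = FALSE),
    "bifurcation" = data.frame(id = c("parent", "child_1", "child_2"),
                               parent = c(NA, "parent", "parent"),
                               gen = c(0L, 1L, 1L),
                               r_mm = c(10, 7, 7), len_cm = c(10, 15, 15),
                               cd = c(5, 6, 6), stringsAsFactors = FALSE),
    "symmetric-tree" = anatomy_symmetric(generations),
    "tree-55-style" = anatomy_55(),
    "tree-67-style" = anatomy_67())
  build_tree_from_table(tab, seed, jitter, net_resistance, net_compliance,
                        p_out, globals)
}

innominate_subtree_ids <- function() {
  c("innominate", "carotid_r", "carotid_int_r", "carotid_ext_r",
    "subclavian_r_a", "vertebral_r", "subclavian_r_b", "radial_r",
    "ulnar_r_a", "interosseous_r", "ulnar_r_b",
    "palmar_arch_radial_r", "digital_1_r", "digital_2_r",
    "palmar_arch_ulnar_r", "digital_3_r", "digital_4_r")
}

build_tree_from_table <- function(tab, seed, jitter, net_resistance,
                                  net_compliance, p_out, globals) {
  rho <- globals$density
  ## deterministic jitter without touching the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  jit <- function(v) v * (1 + jitter * stats::runif(length(v), -1, 1))
  r_in <- pmin(15, pmax(1, jit(tab$r_mm))) * 1e-3
  len <- pmin(50, pmax(2, jit(tab$len_cm))) * 1e-2
  cd <- pmin(12, pmax(4, jit(tab$cd)))
  if (isTRUE(attr(tab, "matched"))) {
    ## impedance-matched binary tree: untapered segments, each daughter
    ## inlet area derived from its parent's area and the jittered wave
    ## speeds so that junctions are forward reflection-free
    for (i in seq_len(nrow(tab))[-1L]) {
      p <- match(tab$parent[i], tab$id)
      r_in[i] <- r_in[p] * sqrt(cd[i] / (2 * cd[p]))
    }
    r_out <- r_in
  } else {
  ## the aortic trunk is contiguous: each trunk segment's outlet radius is
  ## the next trunk segment's inlet radius; other vessels taper by 0.9
  is_trunk <- tab$gen == 0L & grepl("^(aorta|arch|thoracic|abdominal)", tab$id)
  r_out <- 0.9 * r_in
  trunk_idx <- which(is_trunk)
  if (length(trunk_idx) > 1L) {
    for (i in seq_len(length(trunk_idx) - 1L))
      r_out[trunk_idx[i]] <- r_in[trunk_idx[i + 1L]]
    r_out[trunk_idx[length(trunk_idx)]] <-
      0.95 * r_in[trunk_idx[length(trunk_idx)]]
  }
  }
  segs <- lapply(seq_len(nrow(tab)), function(i)
    arterial_segment(tab$id[i], len[i], r_in[i], r_out[i],
                     pwv_in = cd[i], pwv_out = cd[i], rho = rho,
                     parent = if (is.na(tab$parent[i])) NA_character_
                              else tab$parent[i],
                     generation = tab$gen[i]))
  names(segs) <- tab$id
  net0 <- arterial_network(segs, terminals = list(), globals, validate = FALSE)
  leaves <- {
    ch <- net_children(net0)
    names(ch)[vapply(ch, length, integer(1)) == 0L]
  }
  cal <- calibrate_terminals(net0, leaves, net_resistance, net_compliance,
                             globals)
  terminals <- stats::setNames(lapply(leaves, function(id) {
    a_out <- seg_area_d(net0$segments[[id]], net0$segments[[id]]$length)
    z0 <- characteristic_impedance(net0$segments[[id]], rho = rho)
    r_tot <- cal$kr / a_out
    if (r_tot <= z0)
      stop("fixture calibration: terminal '", id,
           "' cannot absorb its characteristic impedance; ",
           "increase net_resistance")
    windkessel3(z0, r_tot - z0, cal$kc * a_out, p_out)
  }), leaves)
  arterial_network(segs, terminals, globals)
}

## Calibrate the terminal resistance/compliance scale factors so that the
## fully reduced tree matches the declared net resistance and compliance.
## Terminal i gets R_tot = kr / A_i and C = kc * A_i (A_i = outlet area).
calibrate_terminals <- function(net0, leaves, r_target, c_target, globals) {
  rho <- globals$density
  ids <- names(net0$segments)
  rcs <- lapply(net0$segments, vessel_rc, globals = globals)
  z0 <- vapply(net0$segments, characteristic_impedance, numeric(1), rho = rho)
  a_out <- vapply(net0$segments, function(s) seg_area_d(s, s$length), numeric(1))
  ch <- net_children(net0)
  root <- ids[vapply(net0$segments, function(s) is.na(s$parent), logical(1))]
  ## mirrors lump_terminal()/merge_siblings(): each call returns (R, C)
  ## of the lumped subtree rooted at `id` including its own vessel
  reduce_fast <- function(kr, kc) {
    rec <- function(id) {
      kids <- ch[[id]]
      if (!length(kids)) {            # leaf: RCR terminal is the load
        r_tot <- kr / a_out[id]
        r1 <- min(z0[id], 0.99 * r_tot)
        r2 <- r_tot - r1
        c_load <- kc * a_out[id]
      } else {                        # merged children are the load
        sub <- vapply(kids, rec, numeric(2))
        r_tot <- 1 / sum(1 / sub[1, ])
        r1 <- min(z0[id], 0.99 * r_tot)
        r2 <- r_tot - r1
        c_load <- sum(sub[2, ])
      }
      rv <- rcs[[id]]$r_v; cv <- rcs[[id]]$c_v
      r_new <- r_tot + rv
      c_new <- (cv * r_tot + c_load * r2 + rv * cv) / r_new
      c(r_new, c_new)
    }
    rec(root)
  }
  g <- function(kr) reduce_fast(kr, 0)[1] - r_target
  a_leaf_sum <- sum(a_out[leaves])
  k0 <- r_target * a_leaf_sum
  kr <- stats::uniroot(g, c(0.05 * k0, 50 * k0), extendInt = "upX",
                       tol = 1e-12 * k0)$root
  c0 <- reduce_fast(kr, 0)[2]
  c1 <- reduce_fast(kr, 1)[2]
  kc <- (c_target - c0) / (c1 - c0)
  if (!is.finite(kc) || kc <= 0)
    stop("fixture calibration: declared net_compliance (", c_target,
         ") does not exceed the vessels' own compliance (", signif(c0, 4),
         "); increase net_compliance")
  list(kr = kr, kc = kc)
}
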