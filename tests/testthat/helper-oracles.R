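## Independent oracles used by unit and acceptance tests.

## Brute-force input resistance of the linear DC circuit equivalent to an
## arterial tree: each segment is a series resistor R_v (viscous), each
## terminal a series R1 + R2 to the outflow node. Solved by nodal
## analysis on the full conductance matrix (no tree recursion), so it is
## independent of the package's reduction algebra.
circuit_input_resistance <- function(net) {
  g <- net$globals
  ids <- names(net$segments)
  ch <- net_children(net)
  root <- net_root(net)
  ## one electrical node per junction: a segment's outlet node is shared
  ## with all of its children's inlets; the root has its own inlet node;
  ## all terminals discharge into a common ground node
  inlet <- stats::setNames(integer(length(ids)), ids)
  n_nodes <- 1L
  inlet[root] <- 1L
  for (id in ids)
    if (length(ch[[id]])) {
      n_nodes <- n_nodes + 1L
      for (k in ch[[id]]) inlet[k] <- n_nodes
    }
  ground <- n_nodes + 1L
  G <- matrix(0, ground, ground)
  add <- function(i, j, cond) {
    G[i, i] <<- G[i, i] + cond
    G[j, j] <<- G[j, j] + cond
    G[i, j] <<- G[i, j] - cond
    G[j, i] <<- G[j, i] - cond
  }
  for (id in ids) {
    rv <- vessel_rc(net$segments[[id]], g)$r_v
    kids <- ch[[id]]
    if (length(kids)) {
      add(inlet[id], inlet[kids[1]], 1 / rv)
    } else {
      wk <- net$terminals[[id]]
      add(inlet[id], ground, 1 / (rv + wk$r1 + wk$r2))
    }
  }
  keep <- seq_len(ground - 1L)
  b <- numeric(ground - 1L); b[inlet[root]] <- 1
  v <- solve(G[keep, keep, drop = FALSE], b)
  v[inlet[root]]
}

## Random arterial tree for property tests: up to `max_gen` generations
## of bifurcations with random taper, length, stiffness and terminals.
random_tree <- function(max_gen = 4L, p_branch = 0.7, p_out = 0) {
  segs <- list()
  make <- function(id, parent, gen, r_in) {
    len <- stats::runif(1, 0.02, 0.3)
    r_out <- r_in * stats::runif(1, 0.8, 1)
    cd <- stats::runif(1, 4, 12)
    segs[[id]] <<- arterial_segment(id, len, r_in, r_out,
                                    pwv_in = cd, pwv_out = cd, rho = 1050,
                                    parent = parent, generation = gen)
    if (gen < max_gen && stats::runif(1) < p_branch) {
      make(paste0(id, "a"), id, gen + 1L, r_out * stats::runif(1, 0.6, 0.85))
      make(paste0(id, "b"), id, gen + 1L, r_out * stats::runif(1, 0.6, 0.85))
      FALSE
    } else TRUE
  }
  make("s", NA_character_, 0L, stats::runif(1, 0.004, 0.012))
  net0 <- arterial_network(segs, list(), global_params(), validate = FALSE)
  ch <- net_children(net0)
  leaves <- names(ch)[vapply(ch, length, integer(1)) == 0L]
  terms <- stats::setNames(lapply(leaves, function(id) {
    z0 <- characteristic_impedance(segs[[id]], rho = 1050)
    windkessel3(z0, z0 * stats::runif(1, 5, 50),
                stats::runif(1, 1e-11, 1e-9), p_out)
  }), leaves)
  arterial_network(segs, terms, global_params())
}

## 0-D compartment-chain oracle for a tapered vessel terminated by an RCR
## windkessel: an L-ladder of n linearized cells, each a series branch
## (inertance rho*dx/A, viscous resistance 2(xi+2) pi mu dx / A^2)
## followed by a shunt capacitor (wall compliance A dx / (rho c_d^2)),
## driven by a prescribed inflow through the first branch. Returns the
## inlet pressure on `times`. Independent of the package's 1-D solver
## and of its reduction algebra.
rc_chain_response <- function(seg, wk, q_fun, times, n = 200L,
                              globals = global_params()) {
  rho <- globals$density
  mu <- globals$viscosity
  xi <- globals$profile_order
  dx <- seg$length / n
  xm <- (seq_len(n) - 0.5) * dx
  a <- seg_area_d(seg, xm)
  b <- seg_beta(seg, xm)
  cd2 <- b * sqrt(a) / (2 * rho * a)          # diastolic wave speed^2
  Ccell <- a * dx / (rho * cd2)
  Rcell <- 2 * (xi + 2) * pi * mu * dx / a^2
  Lcell <- rho * dx / a
  ## states interleaved along the ladder so that the Jacobian is
  ## tridiagonal (lsoda band solver): y = (p_1, q_2, p_2, q_3, ...,
  ## q_n, p_n, p_c); p_i at 2i-1, q_i at 2i-2, p_c at 2n
  stopifnot(wk$r1 > 0)
  ip <- 2L * seq_len(n) - 1L
  iq <- if (n > 1) 2L * (2:n) - 2L else integer(0)
  deriv <- function(t, y, parms) {
    p <- y[ip]
    q <- y[iq]
    pcap <- y[2 * n]
    qin <- q_fun(t)
    q_wk <- (p[n] - pcap) / wk$r1
    dy <- numeric(2L * n)
    if (n > 1)
      dy[iq] <- (p[1:(n - 1)] - p[2:n] - Rcell[2:n] * q) / Lcell[2:n]
    dy[ip] <- (c(qin, q) - c(q, q_wk)) / Ccell
    dy[2 * n] <- (q_wk - (pcap - wk$p_out) / wk$r2) / wk$c
    list(dy)
  }
  y0 <- numeric(2L * n)
  y0[ip] <- wk$p_out; y0[2 * n] <- wk$p_out
  sol <- deSolve::lsoda(y0, times, deriv, NULL, rtol = 1e-8, atol = 1e-6,
                        jactype = "bandint", bandup = 1L, banddown = 1L)
  p1 <- sol[, 1L + ip[1]]
  ## inlet pressure includes the first branch's own series drop
  h <- 1e-5 * max(diff(range(times)), 1e-6)
  qdot <- (vapply(times + h, q_fun, numeric(1)) -
           vapply(times - h, q_fun, numeric(1))) / (2 * h)
  p1 + Rcell[1] * vapply(times, q_fun, numeric(1)) + Lcell[1] * qdot
}

## One uniform (or tapered) vessel with a resistive / RCR outlet, used by
## the solver oracle tests.
uniform_vessel_net <- function(l = 0.5, area = 2e-5, cd = 5, r_total = NULL,
                               c_term = 0, p_out = 0, viscosity = 4e-3,
                               taper = 1) {
  r_in <- sqrt(area / pi)
  g <- global_params(viscosity = viscosity)
  seg <- arterial_segment("v", l, r_in, taper * r_in, pwv_in = cd,
                          pwv_out = cd, rho = g$density)
  z0 <- characteristic_impedance(seg, rho = g$density)
  if (is.null(r_total)) r_total <- z0
  wk <- if (c_term > 0)
    windkessel3(z0, r_total - z0, c_term, p_out)
  else windkessel3(min(z0, r_total), max(r_total - min(z0, r_total), 1e-6),
                   0, p_out)
  arterial_network(list(v = seg), list(v = wk), g)
}

probes_at <- function(pos, names = paste0("x", seq_along(pos)))
  data.frame(segment = "v", position = pos, name = names,
             stringsAsFactors = FALSE)

## a narrow compact pulse on a quiescent matched vessel, reused by the
## transit-time and reflection tests
pulse_run <- function(r_total_factor = 1, l = 0.5, cd = 5) {
  net <- uniform_vessel_net(l = l, area = 2e-5, cd = cd,
                            r_total = NULL, viscosity = 0)
  if (r_total_factor != 1) {
    z0 <- characteristic_impedance(net$segments$v, rho = 1050)
    net$terminals$v <- if (r_total_factor > 1)
      windkessel3(z0, (r_total_factor - 1) * z0, 0, 0)
    else windkessel3(r_total_factor * z0, 1e-6, 0, 0)
  }
  tw <- 0.02
  iw <- inflow_waveform(0.4, q_fun = function(t) {
    tm <- t %% 0.4
    ifelse(tm < tw, 1e-6 * sin(pi * tm / tw)^2, 0)
  })
  simulate_network(net, iw, solver_settings(
    dx = 0.005, cycles = 1L,
    probes = probes_at(c(0.1, 0.5, 0.9))))
}

## the steady-Poiseuille oracle run shared by the solver and acceptance
## tests (probes at the first/last cell centres of a 0.4 m vessel)
poiseuille_run <- function() {
  net <- uniform_vessel_net(l = 0.4, area = 2e-5, cd = 5, r_total = 2e8)
  iw <- inflow_waveform(0.5, q_fun = function(t) 2e-7)
  simulate_network(net, iw, solver_settings(
    dx = 0.01, cycles = 20L, periodicity_tol = 1e-8,
    probes = probes_at(c(0, 1), c("in", "out"))))
}

## the periodic single-vessel fixture run shared by the solver and
## acceptance tests
single_vessel_periodic <- function() {
  iw <- make_inflow(0.8, 70e-6, 0.3)
  sv <- make_tree("single-vessel", seed = 1)
  simulate_network(sv, iw, solver_settings(dx = 0.02, cycles = 20L,
                                           init = 9.3e3))
}

## cache expensive simulations shared between unit and acceptance tests
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

## Max relative error between the lumped windkessel2 and the chain oracle
## for a set of vessel transit ratios, in the lumping's regime of validity
## (R1 << R1 + R2, slow single-harmonic forcing).
lump_chain_errors <- function(ratios) {
  period <- 0.8
  cd <- 5
  area <- 2e-5
  r <- sqrt(area / pi)
  rho <- 1050
  wk <- windkessel3(rho * cd / area, 1.3e10, 5e-11)
  q_fun <- function(t) 1e-5 + 5e-6 * sin(2 * pi * t / period)
  t_end <- 10 * period
  times <- seq(0, t_end, length.out = 1280L)
  last <- times > 9 * period
  vapply(ratios, function(ratio) {
    l <- ratio * period * cd
    seg <- arterial_segment("v", l, r, r, pwv_in = cd, pwv_out = cd,
                            rho = rho)
    lump <- lump_terminal(seg, wk)
    p_lump <- wk2_response(q_fun, lump, p0 = 0, t_end = t_end,
                           n_out = 1280L)$p_in
    p_chain <- rc_chain_response(seg, wk, q_fun, times, n = 200L)
    max(abs(p_lump[last] - p_chain[last])) / max(abs(p_chain[last]))
  }, numeric(1))
}

## Root-pressure error metrics of trimming the deepest generation of a
## 3-generation symmetric fixture tree, via full 1-D simulations.
trim_fidelity_root <- function(seed, generations = 3L) {
  iw <- make_inflow(0.8, 70e-6, 0.3)
  net <- make_tree("symmetric-tree", generations = generations, seed = seed)
  red <- trim_generation(net)
  st <- solver_settings(dx = 0.02, cycles = 10L, init = 9.3e3,
                        probes = data.frame(segment = "root", position = 0,
                                            name = "root",
                                            stringsAsFactors = FALSE))
  a <- suppressWarnings(simulate_network(net, iw, st))
  b <- suppressWarnings(simulate_network(red, iw, st))
  e <- error_report(a$waves, b$waves, "root")
  c(p_avg = e$p_avg, p_sys = e$p_sys,
    converged = as.numeric(isTRUE(a$converged) && isTRUE(b$converged)))
}
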