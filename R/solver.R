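#' Solver settings for the 1D network simulation
#'
#' @param dx Target cell size (m); each segment gets
#'   `max(min_cells, ceiling(length / dx))` finite-volume cells.
#' @param min_cells Minimum cells per segment.
#' @param cfl CFL number in (0, 1]; the fixed time step is
#'   `cfl * min(dx / c_d)` over all cells, estimated from the diastolic
#'   state and re-checked against `|U| + c` every step.
#' @param cycles Cardiac-cycle budget (>= 1).
#' @param periodicity_tol Relative max-norm tolerance on cycle-to-cycle
#'   change of probe pressures; once met, the run stops at the end of
#'   that cycle.
#' @param n_t Number of uniform sample points for the returned final-cycle
#'   waveforms (monotone cubic resampling).
#' @param probes Data frame with columns `segment`, `position` (fraction
#'   of length in `[0, 1]`) and `name`. Default: one probe at the root
#'   inlet named `"root"`.
#' @param init Initial condition: `"zero_pressure"` (area at zero
#'   transmural pressure, zero velocity; the default), `"equilibrium"`
#'   (uniform pressure equal to the mean terminal outflow pressure, zero
#'   velocity), or a numeric scalar giving a uniform starting pressure in
#'   Pa (zero velocity) to shorten the transient.
#' @return Object of class `solver_settings`.
#' @export
solver_settings <- function(dx = 5e-3, min_cells = 4L, cfl = 0.5,
                            cycles = 20L, periodicity_tol = 1e-3,
                            n_t = 1024L, probes = NULL,
                            init = c("zero_pressure", "equilibrium")) {
  if (is.numeric(init)) {
    stopifnot(length(init) == 1L, is.finite(init))
  } else {
    init <- match.arg(init)
  }
  stopifnot(dx > 0, min_cells >= 2L, cfl > 0, cfl <= 1, cycles >= 1L,
            periodicity_tol > 0, n_t >= 16L)
  structure(list(dx = dx, min_cells = as.integer(min_cells), cfl = cfl,
                 cycles = as.integer(cycles),
                 periodicity_tol = periodicity_tol, n_t = as.integer(n_t),
                 probes = probes, init = init),
            class = "solver_settings")
}

## ---- discretisation ------------------------------------------------------

discretise_segment <- function(seg, settings, rho) {
  n <- max(settings$min_cells, ceiling(seg$length / settings$dx))
  dxs <- seg$length / n
  xc <- (seq_len(n) - 0.5) * dxs
  xf <- (0:n) * dxs
  ad_c <- seg_area_d(seg, xc);  beta_c <- seg_beta(seg, xc)
  ad_f <- seg_area_d(seg, xf);  beta_f <- seg_beta(seg, xf)
  list(id = seg$id, n = n, dx = dxs,
       ad_c = ad_c, beta_c = beta_c, kc = beta_c / ad_c, sqad_c = sqrt(ad_c),
       ad_f = ad_f, beta_f = beta_f, kf = beta_f / ad_f, sqad_f = sqrt(ad_f),
       ccoef_f = sqrt(beta_f / (2 * rho * ad_f)),
       ccoef_c = sqrt(beta_c / (2 * rho * ad_c)),
       bcoef_f = beta_f / (3 * rho * ad_f),
       cd_c = sqrt(beta_c / (2 * rho * ad_c)) * ad_c^0.25)
}

## MC-limited slopes of a cell series (zero-curvature one-sided at the ends)
limited_slope <- function(v, dx) {
  n <- length(v)
  if (n < 2L) return(numeric(n))
  d <- diff(v) / dx
  s <- numeric(n)
  s[1] <- d[1]; s[n] <- d[n - 1L]
  if (n > 2L) {
    a <- d[-(n - 1L)]; b <- d[-1L]
    same <- (a * b) > 0
    m <- pmin(2 * abs(a), 2 * abs(b), 0.5 * abs(a + b))
    s[2:(n - 1L)] <- ifelse(same, sign(a) * m, 0)
  }
  s
}

## ---- boundary and junction characteristic solves -------------------------

#' Characteristic boundary states
#'
#' Low-level solvers for the starred (interface) states used by the 1D
#' scheme at domain boundaries and junctions. Each takes the adjacent cell
#' state `state = list(a, u)` (area m^2, velocity m/s) and the local face
#' geometry `face = list(ad, beta)` (diastolic area, stiffness), and
#' returns the interface state consistent with the characteristic leaving
#' the 1D domain and the boundary's algebraic/ODE constraint.
#'
#' `inflow_boundary_state()` enforces a prescribed volumetric inflow `q`
#' against the backward characteristic (a reflective, flow-source inlet).
#' `wk_outlet_state()` couples the forward characteristic to a
#' three-element windkessel whose capacitor pressure is currently `p_c`
#' (`c = 0` degenerates to a purely resistive outlet); it also returns
#' `dpc`, the capacitor-pressure time derivative. `junction_state()`
#' enforces conservation of mass and continuity of total pressure
#' \eqn{P + \rho U^2/2} between a parent outlet and any number of child
#' inlets via Newton iteration on the characteristic invariants
#' (tolerance 1e-10, at most 50 iterations).
#'
#' @param q Prescribed inflow (m^3/s).
#' @param state,parent_state Adjacent cell state `list(a, u)`.
#' @param face,parent_face Face geometry `list(ad, beta)`.
#' @param child_states,child_faces Lists of states/faces, one per child.
#' @param wk A [windkessel3()].
#' @param p_c Current capacitor pressure (Pa).
#' @param rho Blood density (kg m^-3).
#' @param p_d Diastolic pressure (Pa).
#' @return A list `list(a, u)` (plus `q`, `p`, `dpc` for the windkessel
#'   outlet); `junction_state()` returns `list(parent =, children = )`.
#' @keywords internal
#' @export
inflow_boundary_state <- function(q, state, face, rho) {
  ccoef <- sqrt(face$beta / (2 * rho * face$ad))
  w2 <- state$u - 4 * ccoef * state$a^0.25
  a <- state$a
  for (it in 1:60) {
    c4 <- 4 * ccoef * a^0.25
    g <- a * (w2 + c4) - q
    dg <- w2 + 1.25 * c4
    da <- -g / dg
    if (!is.finite(da)) break
    if (abs(da) > 0.5 * a) da <- sign(da) * 0.5 * a
    a <- a + da
    if (abs(da) <= 1e-14 * a) break
  }
  if (!is.finite(a) || a <= 0)
    stop("inflow boundary solve failed (non-physical area)")
  list(a = a, u = w2 + 4 * ccoef * a^0.25)
}

#' @rdname inflow_boundary_state
#' @export
wk_outlet_state <- function(state, face, wk, p_c, rho, p_d = 0) {
  ccoef <- sqrt(face$beta / (2 * rho * face$ad))
  kf <- face$beta / face$ad
  sqad <- sqrt(face$ad)
  w1 <- state$u + 4 * ccoef * state$a^0.25
  pres <- function(a) p_d + kf * (sqrt(a) - sqad)
  if (wk$c == 0) {            # purely resistive outlet
    rr <- wk$r1 + wk$r2; pref <- wk$p_out
  } else if (wk$r1 == 0) {    # area pinned by the capacitor pressure
    a <- tube_law_area(p_c, face$ad, face$beta, p_d)
    u <- w1 - 4 * ccoef * a^0.25
    q <- a * u
    return(list(a = a, u = u, q = q, p = p_c,
                dpc = (q - (p_c - wk$p_out) / wk$r2) / wk$c))
  } else { rr <- wk$r1; pref <- p_c }
  ## solve P(a) = pref + rr * q(a), q(a) = a * (w1 - 4 c(a))
  a <- state$a
  for (it in 1:60) {
    c4 <- 4 * ccoef * a^0.25
    qa <- a * (w1 - c4)
    g <- pres(a) - pref - rr * qa
    dg <- kf / (2 * sqrt(a)) - rr * (w1 - 1.25 * c4)
    da <- -g / dg
    if (!is.finite(da)) break
    if (abs(da) > 0.5 * a) da <- sign(da) * 0.5 * a
    a <- a + da
    if (abs(da) <= 1e-14 * a) break
  }
  if (!is.finite(a) || a <= 0)
    stop("windkessel outlet solve failed (non-physical area)")
  u <- w1 - 4 * ccoef * a^0.25
  q <- a * u
  p <- pres(a)
  dpc <- if (wk$c > 0) (q - (p_c - wk$p_out) / wk$r2) / wk$c else 0
  list(a = a, u = u, q = q, p = p, dpc = dpc)
}

#' @rdname inflow_boundary_state
#' @export
junction_state <- function(parent_state, parent_face, child_states,
                           child_faces, rho, p_d = 0) {
  k <- length(child_states)
  cc_p <- sqrt(parent_face$beta / (2 * rho * parent_face$ad))
  kf_p <- parent_face$beta / parent_face$ad
  cc_i <- vapply(child_faces, function(f) sqrt(f$beta / (2 * rho * f$ad)),
                 numeric(1))
  kf_i <- vapply(child_faces, function(f) f$beta / f$ad, numeric(1))
  sq_p <- sqrt(parent_face$ad)
  sq_i <- vapply(child_faces, function(f) sqrt(f$ad), numeric(1))
  w1 <- parent_state$u + 4 * cc_p * parent_state$a^0.25
  w2 <- vapply(seq_len(k), function(i)
    child_states[[i]]$u - 4 * cc_i[i] * child_states[[i]]$a^0.25, numeric(1))
  ## unknowns z = (A_p, U_p, A_1, U_1, ..., A_k, U_k)
  z <- c(parent_state$a, parent_state$u,
         unlist(lapply(child_states, function(s) c(s$a, s$u))))
  cd_p <- cc_p * parent_face$ad^0.25
  sc_u <- cd_p; sc_q <- parent_face$ad * cd_p; sc_p <- rho * cd_p^2
  for (it in 1:50) {
    ap <- z[1]; up <- z[2]
    ai <- z[seq(3, by = 2, length.out = k)]
    ui <- z[seq(4, by = 2, length.out = k)]
    if (any(!is.finite(z)) || ap <= 0 || any(ai <= 0))
      stop("junction solve produced a non-physical state")
    cp <- cc_p * ap^0.25; ci <- cc_i * ai^0.25
    pp <- p_d + kf_p * (sqrt(ap) - sq_p)
    pi_ <- p_d + kf_i * (sqrt(ai) - sq_i)
    r <- c((up + 4 * cp - w1) / sc_u,
           (ui - 4 * ci - w2) / sc_u,
           (ap * up - sum(ai * ui)) / sc_q,
           (pp + 0.5 * rho * up^2 - pi_ - 0.5 * rho * ui^2) / sc_p)
    if (max(abs(r)) < 1e-11) break
    if (it == 50L)
      stop("junction solve failed to converge in 50 Newton iterations")
    J <- matrix(0, 2 * k + 2, 2 * k + 2)
    J[1, 1] <- (cp / ap) / sc_u; J[1, 2] <- 1 / sc_u
    for (i in seq_len(k)) {
      J[1 + i, 2 * i + 1] <- (-ci[i] / ai[i]) / sc_u
      J[1 + i, 2 * i + 2] <- 1 / sc_u
    }
    J[k + 2, 1] <- up / sc_q; J[k + 2, 2] <- ap / sc_q
    for (i in seq_len(k)) {
      J[k + 2, 2 * i + 1] <- -ui[i] / sc_q
      J[k + 2, 2 * i + 2] <- -ai[i] / sc_q
    }
    for (i in seq_len(k)) {
      J[k + 2 + i, 1] <- (kf_p / (2 * sqrt(ap))) / sc_p
      J[k + 2 + i, 2] <- rho * up / sc_p
      J[k + 2 + i, 2 * i + 1] <- (-kf_i[i] / (2 * sqrt(ai[i]))) / sc_p
      J[k + 2 + i, 2 * i + 2] <- (-rho * ui[i]) / sc_p
    }
    dz <- tryCatch(solve(J, -r), error = function(e)
      stop("junction solve: singular Jacobian"))
    ## damp steps that would overshoot areas
    lim <- 1
    aidx <- c(1, seq(3, by = 2, length.out = k))
    for (j in aidx)
      if (dz[j] < 0) lim <- min(lim, -0.5 * z[j] / dz[j])
    z <- z + lim * dz
  }
  list(parent = list(a = z[1], u = z[2]),
       children = lapply(seq_len(k), function(i)
         list(a = z[2 * i + 1], u = z[2 * i + 2])))
}

## ---- spatial right-hand side ---------------------------------------------

## One segment's finite-volume residual. bst_in / bst_out are starred
## interface states list(a, u) at the inlet/outlet faces.
segment_rhs <- function(ds, A, Q, bst_in, bst_out, visc_coef, p_d) {
  n <- ds$n; dx <- ds$dx
  U <- Q / A
  P <- p_d + ds$kc * (sqrt(A) - ds$sqad_c)
  sP <- limited_slope(P, dx)
  sU <- limited_slope(U, dx)
  ## interior faces f = 2..n (face f sits between cells f-1 and f)
  if (n >= 2L) {
    fi <- 2:n
    hPL <- P[fi - 1L] + 0.5 * dx * sP[fi - 1L]
    hPR <- P[fi]      - 0.5 * dx * sP[fi]
    hUL <- U[fi - 1L] + 0.5 * dx * sU[fi - 1L]
    hUR <- U[fi]      - 0.5 * dx * sU[fi]
    adf <- ds$ad_f[fi]; bef <- ds$beta_f[fi]
    sAL <- ds$sqad_f[fi] + (hPL - p_d) * adf / bef
    sAR <- ds$sqad_f[fi] + (hPR - p_d) * adf / bef
    if (any(sAL <= 0) || any(sAR <= 0))
      stop("vessel collapse in segment '", ds$id, "' (tube law out of range)")
    AL <- sAL^2; AR <- sAR^2
    QL <- AL * hUL; QR <- AR * hUR
    ccf <- ds$ccoef_f[fi]; bcf <- ds$bcoef_f[fi]
    cL <- ccf * sqrt(sAL); cR <- ccf * sqrt(sAR)   # c = ccoef A^(1/4)
    sL <- pmin(hUL - cL, hUR - cR)
    sR <- pmax(hUL + cL, hUR + cR)
    F1L <- QL; F1R <- QR
    F2L <- QL * hUL + bcf * sAL^3
    F2R <- QR * hUR + bcf * sAR^3
    den <- sR - sL
    F1 <- (sR * F1L - sL * F1R + sL * sR * (AR - AL)) / den
    F2 <- (sR * F2L - sL * F2R + sL * sR * (QR - QL)) / den
    up <- sL >= 0; dn <- sR <= 0
    F1[up] <- F1L[up]; F2[up] <- F2L[up]
    F1[dn] <- F1R[dn]; F2[dn] <- F2R[dn]
  } else { F1 <- numeric(0); F2 <- numeric(0) }
  ## boundary faces: physical flux at the starred states
  a0 <- bst_in$a; u0 <- bst_in$u
  an <- bst_out$a; un <- bst_out$u
  F1 <- c(a0 * u0, F1, an * un)
  F2 <- c(a0 * u0^2 + ds$bcoef_f[1] * a0^1.5, F2,
          an * un^2 + ds$bcoef_f[n + 1L] * an^1.5)
  ## well-balanced geometric source: x-derivative of the pressure flux
  ## along the constant-pressure manifold of each cell
  iR <- 2:(n + 1L); iL <- 1:n
  sAeqR <- ds$sqad_f[iR] + (P - p_d) * ds$ad_f[iR] / ds$beta_f[iR]
  sAeqL <- ds$sqad_f[iL] + (P - p_d) * ds$ad_f[iL] / ds$beta_f[iL]
  Sg <- (ds$bcoef_f[iR] * sAeqR^3 - ds$bcoef_f[iL] * sAeqL^3) / dx
  dA <- -(F1[iR] - F1[iL]) / dx
  dQ <- -(F2[iR] - F2[iL]) / dx + Sg + visc_coef * U
  list(dA = dA, dQ = dQ)
}

## ---- main driver ---------------------------------------------------------

#' Simulate pulse waves on an arterial network
#'
#' Integrates the nonlinear 1D equations of blood flow in compliant
#' vessels (conservation of mass and momentum closed by the elastic tube
#' law) on a branched network, with a prescribed reflective inflow at the
#' root, conservation of mass and continuity of total pressure at
#' junctions, and three-element windkessel models at terminal outlets.
#' The scheme is a second-order MUSCL finite-volume method (primitive
#' pressure/velocity reconstruction with an MC limiter, HLL fluxes,
#' SSP-RK2 in time) with a well-balanced geometric source so that
#' uniform-pressure rest states on tapered vessels are exact. Cycles are
#' repeated until the probe pressure waveforms are periodic to
#' `settings$periodicity_tol` or the cycle budget is spent (the result is
#' then flagged `converged = FALSE` with a warning).
#'
#' @param net An [arterial_network()].
#' @param inflow An [inflow_waveform()].
#' @param settings A [solver_settings()].
#' @return Object of class `pulse_solution`: a list with
#'   \describe{
#'     \item{waves}{[waveform_set()] of the final cycle at the probes,
#'       resampled to `n_t` uniform points.}
#'     \item{inlet_flow}{Final-cycle inlet flow on the same grid (m^3/s).}
#'     \item{terminal_flow}{Named matrix of final-cycle terminal outflows.}
#'     \item{volume_balance}{Relative net-volume imbalance of the final
#'       cycle, `|V_in - V_out| / V_in` (`NA` for zero inflow).}
#'     \item{converged, cycles, dt}{Run diagnostics.}
#'   }
#' @export
#' @examples
#' \donttest{
#' net <- make_tree("single-vessel", seed = 1)
#' iw <- make_inflow(period = 0.8, stroke_volume = 1e-6, systolic_fraction = 0.35)
#' sol <- simulate_network(net, iw, solver_settings(cycles = 3))
#' }
simulate_network <- function(net, inflow, settings = solver_settings()) {
  validate_network(net)
  g <- net$globals
  rho <- g$density; p_d <- g$diastolic_pressure
  visc_coef <- -2 * (g$profile_order + 2) * pi * g$viscosity / rho
  Tp <- inflow$period
  ids <- net_topo_order(net)
  segs <- net$segments[ids]
  ds <- lapply(segs, discretise_segment, settings = settings, rho = rho)
  ch <- net_children(net)
  root <- net_root(net)
  leaves <- net_leaves(net)
  junction_parents <- ids[vapply(ids, function(i) length(ch[[i]]) > 0, logical(1))]

  probes <- settings$probes
  if (is.null(probes))
    probes <- data.frame(segment = root, position = 0, name = "root",
                         stringsAsFactors = FALSE)
  if (!all(probes$segment %in% ids))
    stop("probe(s) reference unknown segment(s): ",
         paste(setdiff(probes$segment, ids), collapse = ", "))
  probe_cell <- mapply(function(sid, pos) {
    n <- ds[[sid]]$n
    min(n, max(1L, as.integer(ceiling(pos * n))))
  }, probes$segment, probes$position)

  ## ---- initial state
  p_out_all <- vapply(net$terminals, `[[`, numeric(1), "p_out")
  state <- list()
  p0 <- if (is.numeric(settings$init)) {
    settings$init
  } else if (settings$init == "equilibrium") {
    if (length(p_out_all)) mean(p_out_all) else p_d
  } else {
    0
  }
  for (id in ids)
    state[[id]] <- list(A = tube_law_area(p0, ds[[id]]$ad_c,
                                          ds[[id]]$beta_c, p_d),
                        Q = numeric(ds[[id]]$n))
  pc <- vapply(leaves, function(id) p0, numeric(1))
  names(pc) <- leaves

  ## ---- fixed time step from the diastolic wave speed
  dt0 <- settings$cfl * min(vapply(ds, function(d) d$dx / max(d$cd_c),
                                   numeric(1)))
  steps_per_cycle <- as.integer(ceiling(Tp / dt0))
  dt <- Tp / steps_per_cycle
  max_steps <- settings$cycles * steps_per_cycle

  face_of <- function(d, i) list(ad = d$ad_f[i], beta = d$beta_f[i])
  ## present the edge cell to a face through its pressure, not its raw
  ## area: on a tapered vessel the cell-centre and face reference
  ## geometries differ, and mapping via the tube law keeps a uniform
  ## pressure state exactly invariant at the boundaries
  edge_state <- function(s, d, end) {
    i <- if (end == 1L) 1L else d$n
    j <- if (end == 1L) 1L else d$n + 1L
    p <- p_d + (d$beta_c[i] / d$ad_c[i]) * (sqrt(s$A[i]) - sqrt(d$ad_c[i]))
    list(a = tube_law_area(p, d$ad_f[j], d$beta_f[j], p_d),
         u = s$Q[i] / s$A[i])
  }

  ## starred interface states for every segment end at one stage
  boundary_states <- function(state, pc, t) {
    bin <- list(); bout <- list(); dpc <- pc * 0; qterm <- pc * 0
    ## inflow at the root
    d <- ds[[root]]
    bin[[root]] <- inflow_boundary_state(inflow$q_fun(t),
                                         edge_state(state[[root]], d, 1L),
                                         face_of(d, 1L), rho)
    ## junctions
    for (p in junction_parents) {
      kids <- ch[[p]]
      dp <- ds[[p]]
      js <- junction_state(edge_state(state[[p]], dp, 2L),
                           face_of(dp, dp$n + 1L),
                           lapply(kids, function(k)
                             edge_state(state[[k]], ds[[k]], 1L)),
                           lapply(kids, function(k) face_of(ds[[k]], 1L)),
                           rho, p_d)
      bout[[p]] <- js$parent
      for (i in seq_along(kids)) bin[[kids[i]]] <- js$children[[i]]
    }
    ## windkessel outlets
    for (id in leaves) {
      d <- ds[[id]]
      ws <- wk_outlet_state(edge_state(state[[id]], d, 2L),
                            face_of(d, d$n + 1L), net$terminals[[id]],
                            pc[[id]], rho, p_d)
      bout[[id]] <- ws
      dpc[[id]] <- ws$dpc
      qterm[[id]] <- ws$q
    }
    list(bin = bin, bout = bout, dpc = dpc, qterm = qterm,
         qin = bin[[root]]$a * bin[[root]]$u)
  }

  rhs_all <- function(state, bs) {
    lapply(ids, function(id)
      segment_rhs(ds[[id]], state[[id]]$A, state[[id]]$Q,
                  bs$bin[[id]], bs$bout[[id]], visc_coef, p_d))
  }

  np <- nrow(probes)
  rec_p <- matrix(NA_real_, max_steps + 1L, np)
  rec_q <- matrix(NA_real_, max_steps + 1L, np)
  rec_a <- matrix(NA_real_, max_steps + 1L, np)
  rec_qin <- numeric(max_steps + 1L)
  rec_qterm <- matrix(NA_real_, max_steps + 1L, length(leaves),
                      dimnames = list(NULL, leaves))

  ## recording needs only the inlet flow (enforced exactly by the
  ## reflective inflow) and the terminal outflows (scalar solves)
  record <- function(row, state, pc, t) {
    for (j in seq_len(np)) {
      id <- probes$segment[j]; i <- probe_cell[j]
      A <- state[[id]]$A[i]; Q <- state[[id]]$Q[i]
      rec_a[row, j] <<- A
      rec_q[row, j] <<- Q
      rec_p[row, j] <<- p_d + ds[[id]]$kc[i] * (sqrt(A) - ds[[id]]$sqad_c[i])
    }
    rec_qin[row] <<- inflow$q_fun(t)
    for (id in leaves) {
      d <- ds[[id]]
      rec_qterm[row, id] <<- wk_outlet_state(edge_state(state[[id]], d, 2L),
                                             face_of(d, d$n + 1L),
                                             net$terminals[[id]],
                                             pc[[id]], rho, p_d)$q
    }
  }

  record(1L, state, pc, 0)

  converged <- FALSE
  t <- 0; step <- 0L; cycle_done <- 0L
  while (step < max_steps) {
    step <- step + 1L
    ## stage 1
    bs1 <- boundary_states(state, pc, t)
    L1 <- rhs_all(state, bs1)
    s1 <- state
    for (i in seq_along(ids)) {
      id <- ids[i]
      s1[[id]]$A <- state[[id]]$A + dt * L1[[i]]$dA
      s1[[id]]$Q <- state[[id]]$Q + dt * L1[[i]]$dQ
    }
    pc1 <- pc + dt * bs1$dpc
    ## stage 2
    bs2 <- boundary_states(s1, pc1, t + dt)
    L2 <- rhs_all(s1, bs2)
    for (i in seq_along(ids)) {
      id <- ids[i]
      A <- 0.5 * (state[[id]]$A + s1[[id]]$A + dt * L2[[i]]$dA)
      Q <- 0.5 * (state[[id]]$Q + s1[[id]]$Q + dt * L2[[i]]$dQ)
      if (any(!is.finite(A)) || any(!is.finite(Q)) || any(A <= 0))
        stop("numerical failure in segment '", id, "' at t = ",
             signif(t + dt, 6), " s")
      state[[id]]$A <- A; state[[id]]$Q <- Q
    }
    pc <- 0.5 * (pc + pc1 + dt * bs2$dpc)
    t <- t + dt
    ## CFL re-check on the updated state
    smax_dt <- min(vapply(ids, function(id) {
      A <- state[[id]]$A
      ds[[id]]$dx / max(abs(state[[id]]$Q / A) + ds[[id]]$ccoef_c * A^0.25)
    }, numeric(1)))
    if (dt > smax_dt)
      stop("CFL violation at t = ", signif(t, 6),
           " s (wave speed grew beyond the diastolic estimate); ",
           "reduce solver_settings(cfl)")
    record(step + 1L, state, pc, t)
    ## end-of-cycle periodicity check
    if (step %% steps_per_cycle == 0L) {
      cycle_done <- cycle_done + 1L
      if (cycle_done >= 2L) {
        i2 <- (step - steps_per_cycle + 1L):(step + 1L)
        i1 <- i2 - steps_per_cycle
        rel <- max(vapply(seq_len(np), function(j) {
          sc <- max(abs(rec_p[i1, j]), 1e-12)
          max(abs(rec_p[i2, j] - rec_p[i1, j])) / sc
        }, numeric(1)))
        if (rel < settings$periodicity_tol) { converged <- TRUE; break }
      }
    }
  }
  if (!converged && settings$cycles > 1L)
    warning("periodicity not reached within ", settings$cycles, " cycles")
  if (settings$cycles == 1L) converged <- NA

  ## ---- final-cycle resampling to a uniform grid
  last <- cycle_done * steps_per_cycle + 1L
  idx <- (last - steps_per_cycle):last
  t_rec <- (idx - 1L) * dt
  t_out <- t_rec[1] + seq(0, Tp, length.out = settings$n_t + 1L)[-(settings$n_t + 1L)]
  resamp <- function(v) stats::splinefun(t_rec, v, method = "monoH.FC")(t_out)
  sites <- lapply(seq_len(np), function(j)
    list(p = resamp(rec_p[idx, j]), q = resamp(rec_q[idx, j]),
         a = resamp(rec_a[idx, j])))
  names(sites) <- probes$name
  waves <- waveform_set(t_out - t_rec[1], sites, Tp,
                        converged = isTRUE(converged), cycles = cycle_done)
  ## final-cycle volume balance (trapezoidal over the recorded steps)
  trapz <- function(v) dt * (sum(v) - 0.5 * (v[1] + v[length(v)]))
  v_in <- trapz(rec_qin[idx])
  v_out <- sum(apply(rec_qterm[idx, , drop = FALSE], 2, trapz))
  vb <- if (abs(v_in) > 0) abs(v_in - v_out) / abs(v_in) else NA_real_
  structure(list(waves = waves,
                 inlet_flow = resamp(rec_qin[idx]),
                 terminal_flow = rec_qterm[idx, , drop = FALSE],
                 volume_balance = vb, converged = converged,
                 cycles = cycle_done, dt = dt,
                 steps_per_cycle = steps_per_cycle, settings = settings),
            class = "pulse_solution")
}

#' @export
print.pulse_solution <- function(x, ...) {
  cat(sprintf("1D pulse solution: %s cycles (dt = %.3g ms), %s\n",
              x$cycles, 1e3 * x$dt,
              if (isTRUE(x$converged)) "periodic" else "not flagged periodic"))
  if (is.finite(x$volume_balance))
    cat(sprintf("  final-cycle volume imbalance: %.3g%%\n",
                100 * x$volume_balance))
  print(x$waves)
  invisible(x)
}
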