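test_that("constant-pressure rest state is preserved exactly (well-balanced)", {
  # strongly tapered vessel, zero inflow, outlet in equilibrium with the
  # initial pressure: the scheme must hold the rest state to round-off
  p0 <- 1e4
  g <- global_params()
  seg <- arterial_segment("v", 0.2, 0.006, 0.003, pwv_in = 5, pwv_out = 7,
                          rho = g$density)
  net <- arterial_network(list(v = seg),
                          list(v = windkessel3(1e7, 1e9, 1e-9, p_out = p0)),
                          g)
  iw <- inflow_waveform(0.1, q_fun = function(t) 0)
  sol <- simulate_network(net, iw, solver_settings(
    dx = 0.01, cycles = 1L, init = p0,
    probes = probes_at(c(0, 0.5, 1))))
  for (nm in c("x1", "x2", "x3")) {
    w <- waveforms_at(sol$waves, nm)
    expect_lt(max(abs(w$p - p0)) / p0, 1e-10)
    expect_lt(max(abs(w$q)), 1e-14)
  }
})

test_that("steady flow reproduces the Poiseuille-type pressure drop", {
  # small flow keeps the operating pressure well inside the linear regime
  # of the tube law, where the diastolic-geometry resistance integral is
  # the exact steady answer
  q0 <- 2e-7
  net <- uniform_vessel_net(l = 0.4, area = 2e-5, cd = 5, r_total = 2e8)
  rv <- vessel_rc(net$segments$v, net$globals)$r_v
  sol <- cached("poiseuille", poiseuille_run())
  p_in <- mean(waveforms_at(sol$waves, "in")$p)
  p_out <- mean(waveforms_at(sol$waves, "out")$p)
  # probes sit at the first/last cell centres, x = 0.005 and 0.395 of 0.4
  expect_equal(p_in - p_out, rv * q0 * (0.395 - 0.005) / 0.4,
               tolerance = 0.01)
  # the outlet probe sits R_total q0 plus the last half-cell's viscous
  # drop above the outflow pressure
  expect_equal(p_out, 2e8 * q0 + rv * q0 * 0.005 / 0.4, tolerance = 0.01)
})

test_that("pulse foot travels at the diastolic wave speed", {
  sol <- cached("pulse_matched", pulse_run())
  t <- sol$waves$time
  foot <- function(nm) {
    p <- waveforms_at(sol$waves, nm)$p
    t[which(p > 0.05 * max(p))[1]]
  }
  dt_num <- foot("x3") - foot("x1")
  dt_ref <- 0.8 * 0.5 / 5
  expect_equal(dt_num, dt_ref, tolerance = 0.03)
})

test_that("a matched resistive outlet is reflection-free", {
  sol <- cached("pulse_matched", pulse_run())
  t <- sol$waves$time
  p <- waveforms_at(sol$waves, "x2")$p
  incident <- max(p[t < 0.1])
  # any reflection passes the mid probe again within [0.1, 0.25] s
  residual <- max(abs(p[t > 0.12 & t < 0.25]))
  expect_lt(residual / incident, 0.03)
})

test_that("outlet reflection coefficient matches linear theory", {
  for (fac in c(3, 0.5)) {
    sol <- pulse_run(r_total_factor = fac)
    t <- sol$waves$time
    p <- waveforms_at(sol$waves, "x2")$p
    inc_window <- t < 0.1
    refl_window <- t > 0.12 & t < 0.25
    theory <- (fac - 1) / (fac + 1)
    # pulse areas are far less sensitive to numerical smearing than peaks
    measured <- sum(p[refl_window]) / sum(p[inc_window])
    expect_lt(abs(measured - theory), 0.05)
  }
})

test_that("periodic solutions satisfy the mean-pressure identity", {
  sv <- make_tree("single-vessel", seed = 1)
  sol <- cached("sv_periodic", single_vessel_periodic())
  expect_true(sol$converged)
  p_mean <- mean(waveforms_at(sol$waves, "root")$p)
  r_net <- reduce_to_windkessel(sv)$r
  expect_equal(p_mean, r_net * 70e-6 / 0.8, tolerance = 0.01)
})

test_that("per-cycle volume balance closes at periodicity", {
  sol <- cached("sv_periodic", NULL)
  expect_lt(sol$volume_balance, 1e-3)
})

test_that("the enforced inlet flow reproduces the prescribed inflow", {
  iw <- make_inflow(0.8, 70e-6, 0.3)
  sol <- cached("sv_periodic", NULL)
  q_root <- waveforms_at(sol$waves, "root")$q
  q_ref <- vapply(sol$waves$time, iw$q_fun, numeric(1))
  # the probe reads the first cell centre, half a cell inside the inlet,
  # so allow the O(dx) offset of the travelling wavefront
  expect_lt(max(abs(q_root - q_ref)) / max(q_ref), 0.05)
  # the cycle-averaged flow through that cell must carry the full stroke
  # volume once the solution is periodic
  expect_equal(mean(q_root) * 0.8, 70e-6, tolerance = 0.01)
})

test_that("junction solve: identical parent/child passes states through", {
  face <- list(ad = 2e-5, beta = 300)
  st <- list(a = 2.2e-5, u = 0.3)
  js <- junction_state(st, face, list(st), list(face), rho = 1050)
  expect_equal(js$parent$a, st$a, tolerance = 1e-10)
  expect_equal(js$parent$u, st$u, tolerance = 1e-10)
  expect_equal(js$children[[1]]$a, st$a, tolerance = 1e-10)
})

test_that("junction solve: symmetric bifurcation splits flow evenly", {
  fp <- list(ad = 4e-5, beta = 250)
  fc <- list(ad = 2.4e-5, beta = 300)
  sp <- list(a = 4.3e-5, u = 0.4)
  sc <- list(a = 2.4e-5, u = 0)
  js <- junction_state(sp, fp, list(sc, sc), list(fc, fc), rho = 1050)
  q_p <- js$parent$a * js$parent$u
  q_c <- vapply(js$children, function(s) s$a * s$u, numeric(1))
  expect_equal(q_c[1], q_c[2], tolerance = 1e-12)
  expect_equal(q_p, sum(q_c), tolerance = 1e-10 * abs(q_p))
  # total pressure continuity
  ptot <- function(s, f) (f$beta / f$ad) * (sqrt(s$a) - sqrt(f$ad)) +
    0.5 * 1050 * s$u^2
  expect_equal(ptot(js$parent, fp), ptot(js$children[[1]], fc),
               tolerance = 1e-8 * abs(ptot(js$parent, fp)))
})

test_that("a symmetric bifurcation simulation splits flow evenly", {
  net <- make_tree("bifurcation", seed = 2)
  # force exact symmetry (the fixture jitters the daughters independently)
  net$segments$child_2 <- net$segments$child_1
  net$segments$child_2$id <- "child_2"
  net$terminals$child_2 <- net$terminals$child_1
  net <- arterial_network(net$segments, net$terminals, net$globals)
  iw <- make_inflow(0.8, 70e-6, 0.3)
  sol <- suppressWarnings(simulate_network(net, iw, solver_settings(
    dx = 0.02, cycles = 6L, init = 9.3e3,
    probes = data.frame(segment = c("child_1", "child_2"),
                        position = c(0.5, 0.5), name = c("a", "b"),
                        stringsAsFactors = FALSE))))
  qa <- waveforms_at(sol$waves, "a")$q
  qb <- waveforms_at(sol$waves, "b")$q
  expect_lt(max(abs(qa - qb)) / max(abs(qa)), 1e-8)
})

test_that("solutions self-converge under grid refinement", {
  iw <- make_inflow(0.8, 70e-6, 0.3)
  sv <- make_tree("single-vessel", seed = 1)
  run <- function(dx) simulate_network(sv, iw, solver_settings(
    dx = dx, cycles = 12L, init = 9.3e3, periodicity_tol = 1e-4))
  p <- lapply(c(0.04, 0.02, 0.01), function(dx)
    waveforms_at(run(dx)$waves, "root")$p)
  e1 <- max(abs(p[[1]] - p[[2]]))
  e2 <- max(abs(p[[2]] - p[[3]]))
  expect_lt(e2, 0.7 * e1)
})

test_that("non-periodic runs are flagged", {
  iw <- make_inflow(0.8, 70e-6, 0.3)
  sv <- make_tree("single-vessel", seed = 1)
  expect_warning(
    sol <- simulate_network(sv, iw, solver_settings(dx = 0.02, cycles = 2L)),
    "periodicity")
  expect_false(isTRUE(sol$converged))
  expect_false(sol$waves$converged)
})

test_that("probe validation rejects unknown segments", {
  iw <- make_inflow(0.8, 70e-6, 0.3)
  sv <- make_tree("single-vessel", seed = 1)
  expect_error(simulate_network(sv, iw, solver_settings(
    probes = data.frame(segment = "nope", position = 0, name = "p"))),
    "unknown segment")
})
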