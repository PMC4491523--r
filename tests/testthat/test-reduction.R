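uniform_seg <- function(id = "v", l = 0.1, a = 1e-5, cd = 5, parent = NA,
                        generation = 0L) {
  r <- sqrt(a / pi)
  arterial_segment(id, l, r, r, pwv_in = cd, pwv_out = cd, rho = 1050,
                   parent = parent, generation = generation)
}

test_that("vessel integrals: closed forms for a uniform vessel", {
  k <- vessel_integrals(uniform_seg(l = 0.1, a = 1e-5, cd = 5))
  expect_equal(k$k1, 0.1 * 1e-5 / 25, tolerance = 1e-10)   # int A/c^2
  expect_equal(k$k2, 0.1 / 1e-5, tolerance = 1e-10)        # int 1/A
  expect_equal(k$k3, 0.1 / 1e-10, tolerance = 1e-10)       # int 1/A^2
  expect_equal(unlist(vessel_integrals(uniform_seg(l = 0))),
               c(k1 = 0, k2 = 0, k3 = 0))
})

test_that("vessel integrals: closed form for a linearly tapered radius", {
  r0 <- 0.002; r1 <- 0.001; l <- 0.1
  s <- arterial_segment("t", l, r0, r1, pwv_in = 5, pwv_out = 5, rho = 1050)
  k <- vessel_integrals(s)
  b <- (r1 - r0) / l
  # exact antiderivatives of 1/(pi r^2) and 1/(pi^2 r^4) for linear r(x)
  k2_exact <- (1 / r0 - 1 / r1) / (pi * b)
  k3_exact <- (1 / r0^3 - 1 / r1^3) / (3 * pi^2 * b)
  expect_equal(k$k2, k2_exact, tolerance = 1e-8)
  expect_equal(k$k3, k3_exact, tolerance = 1e-8)
})

test_that("viscous resistance and compliance of a uniform vessel", {
  rc <- vessel_rc(uniform_seg())
  expect_equal(rc$r_v, 2 * 11 * pi * 4e-3 * 1e9, tolerance = 1e-9)
  expect_equal(rc$c_v, 4e-8 / 1050, tolerance = 1e-9)
})

test_that("lump_terminal: numeric example", {
  wk <- windkessel3(1e8, 1e9, 1e-9)
  lt <- lump_terminal(uniform_seg(), wk)
  rv <- 2 * 11 * pi * 4e-3 * 1e9
  cv <- 4e-8 / 1050
  r_ref <- 1e9 + 1e8 + rv
  c_ref <- (cv * 1.1e9 + 1e-9 * 1e9 + rv * cv) / r_ref
  expect_equal(lt$r, r_ref, tolerance = 1e-10)
  expect_equal(lt$c, c_ref, tolerance = 1e-10)
  expect_equal(lt$r, 1.3765e9, tolerance = 1e-4)
  expect_equal(lt$c, 7.646e-10, tolerance = 1e-4)
})

test_that("lump_terminal closed-form limits", {
  # zero-length vessel: the windkessel passes through as R1+R2 and
  # C R2/(R1+R2)
  wk <- windkessel3(1e8, 1e9, 2e-9)
  lt0 <- lump_terminal(uniform_seg(l = 0), wk)
  expect_equal(lt0$r, 1.1e9, tolerance = 1e-12)
  expect_equal(lt0$c, 2e-9 * 1e9 / 1.1e9, tolerance = 1e-12)
  # R1 = R_v = 0 (inviscid vessel, no proximal resistance): compliances add
  g0 <- global_params(viscosity = 0)
  wk00 <- windkessel3(0, 1e9, 2e-9)
  lt00 <- lump_terminal(uniform_seg(), wk00, g0)
  cv <- 4e-8 / 1050
  expect_equal(lt00$r, 1e9, tolerance = 1e-12)
  expect_equal(lt00$c, cv + 2e-9, tolerance = 1e-12)
})

test_that("merge_siblings: identical lumps halve R and double C", {
  parent <- uniform_seg("p", a = 4e-5)
  lump <- windkessel2(1e9, 1e-9)
  m2 <- merge_siblings(parent, list(lump, lump))
  z0 <- characteristic_impedance(parent, rho = 1050)
  expect_equal(m2$r1, z0)
  expect_equal(m2$r1 + m2$r2, 0.5e9, tolerance = 1e-12)
  expect_equal(m2$c, 2e-9, tolerance = 1e-12)
  # single child: total R and C pass through
  m1 <- merge_siblings(parent, list(lump))
  expect_equal(m1$r1 + m1$r2, 1e9, tolerance = 1e-12)
  expect_equal(m1$c, 1e-9, tolerance = 1e-12)
})

test_that("merge_siblings: documented two-branch example", {
  parent <- uniform_seg("p", a = 1e-5)
  # choose wave speed so that Z0 = 5e7: c_d = Z0 A / rho
  cd <- 5e7 * 1e-5 / 1050
  r <- sqrt(1e-5 / pi)
  parent <- arterial_segment("p", 0.1, r, r, pwv_in = cd, pwv_out = cd,
                             rho = 1050)
  m <- merge_siblings(parent, list(windkessel2(1e9, 1e-9),
                                   windkessel2(2e9, 1e-9)))
  expect_equal(m$r1, 5e7)
  expect_equal(m$r1 + m$r2, 1 / (1 / 1e9 + 1 / 2e9), tolerance = 1e-12)
  expect_equal(m$r2, 1 / (1 / 1e9 + 1 / 2e9) - 5e7, tolerance = 1e-9)
  expect_equal(m$c, 2e-9, tolerance = 1e-12)
})

test_that("merge_siblings rejects mismatched outflow pressures", {
  parent <- uniform_seg("p")
  expect_error(merge_siblings(parent, list(windkessel2(1e9, 1e-9, p_out = 0),
                                           windkessel2(1e9, 1e-9, p_out = 100))),
               "outflow")
})

test_that("reduce_to_windkessel matches the brute-force circuit oracle", {
  set.seed(42)
  for (i in 1:25) {
    net <- random_tree(max_gen = 4L)
    r_pkg <- reduce_to_windkessel(net)$r
    r_circ <- circuit_input_resistance(net)
    expect_equal(r_pkg, r_circ, tolerance = 1e-10)
  }
})

test_that("net resistance is invariant to the stored segment order", {
  set.seed(7)
  net <- random_tree(max_gen = 3L)
  wk <- reduce_to_windkessel(net)
  perm <- sample(seq_along(net$segments))
  net2 <- arterial_network(net$segments[perm], net$terminals, net$globals)
  wk2 <- reduce_to_windkessel(net2)
  expect_equal(wk$r, wk2$r, tolerance = 1e-13)
  expect_equal(wk$c, wk2$c, tolerance = 1e-13)
})

test_that("zero-series-resistance limit: compliances simply add", {
  # inviscid vessels and r1 = 0 terminals, reduced with the r1 = "zero"
  # policy: total compliance is the sum of all vessel and terminal
  # compliances, exactly
  g0 <- global_params(viscosity = 0)
  rho <- 1050
  segs <- list(
    arterial_segment("p", 0.1, 0.005, 0.0045, pwv_in = 5, pwv_out = 5,
                     rho = rho, parent = NA),
    arterial_segment("c1", 0.08, 0.003, 0.0027, pwv_in = 6, pwv_out = 6,
                     rho = rho, parent = "p"),
    arterial_segment("c2", 0.07, 0.0028, 0.0025, pwv_in = 7, pwv_out = 7,
                     rho = rho, parent = "p"))
  names(segs) <- c("p", "c1", "c2")
  terms <- list(c1 = windkessel3(0, 1e9, 1.5e-9),
                c2 = windkessel3(0, 2e9, 0.5e-9))
  net <- arterial_network(segs, terms, g0)
  wk <- reduce_to_windkessel(net, r1 = "zero")
  c_sum <- sum(vapply(segs, function(s) vessel_rc(s, g0)$c_v, numeric(1))) +
    1.5e-9 + 0.5e-9
  expect_equal(wk$c, c_sum, tolerance = 1e-12)
  expect_equal(wk$r, 1 / (1 / 1e9 + 1 / 2e9), tolerance = 1e-12)
})

test_that("trim_generation lumps exactly the deepest generation", {
  net <- make_tree("symmetric-tree", generations = 3, seed = 9)
  red <- trim_generation(net)
  expect_identical(length(red$segments), 7L)
  expect_identical(max(net_generations(red)), 2L)
  # net resistance and compliance are preserved by construction
  expect_equal(reduce_to_windkessel(red)$r, reduce_to_windkessel(net)$r,
               tolerance = 1e-10)
  expect_equal(reduce_to_windkessel(red)$c, reduce_to_windkessel(net)$c,
               tolerance = 1e-10)
  expect_error(trim_generation(make_tree("single-vessel")))
})

test_that("55-style tree trims to 53 and then stepwise to 21 segments", {
  net <- make_tree("tree-55-style", seed = 11)
  red1 <- trim_generation(net)   # lumps the two generation-5 vessels
  expect_identical(length(red1$segments), 53L)
  red <- trim_to_generation(net, 1L)
  expect_identical(length(red$segments), 21L)
  expect_identical(length(red$terminals), 11L)
  expect_identical(count_parameters(red), 91L)
})

test_that("iliac junction pair-lumping gives the 19-segment variant", {
  net21 <- make_tree("tree-21-style", seed = 11)
  net19 <- trim_peripheral_pair(net21, "abdominal_e")
  expect_identical(length(net19$segments), 19L)
  expect_false("iliac_common_r" %in% net_ids(net19))
  expect_equal(reduce_to_windkessel(net19)$r, reduce_to_windkessel(net21)$r,
               tolerance = 1e-10)
  expect_error(trim_peripheral_pair(net21, "aorta_asc"))  # children not leaves
})

test_that("trim_to_generation keeps a protected subtree intact", {
  net <- make_tree("tree-67-style", seed = 11)
  keep <- c("innominate", "carotid_r", "carotid_int_r", "carotid_ext_r",
            "subclavian_r_a", "vertebral_r", "subclavian_r_b", "radial_r",
            "ulnar_r_a", "interosseous_r", "ulnar_r_b",
            "palmar_arch_radial_r", "digital_1_r", "digital_2_r",
            "palmar_arch_ulnar_r", "digital_3_r", "digital_4_r")
  red <- trim_to_generation(net, 1L, keep = keep)
  expect_identical(length(red$segments), 37L)
  expect_true(all(keep %in% net_ids(red)))
  expect_equal(reduce_to_windkessel(red)$r, reduce_to_windkessel(net)$r,
               tolerance = 1e-10)
})

test_that("every reduction step preserves net resistance and compliance", {
  net <- make_tree("tree-55-style", seed = 13)
  wk0 <- reduce_to_windkessel(net)
  for (g in (max(net_generations(net)) - 1L):1L) {
    red <- trim_to_generation(net, g)
    expect_lte(max(net_generations(red)), g)
    wk <- reduce_to_windkessel(red)
    expect_equal(wk$r, wk0$r, tolerance = 1e-9)
    expect_equal(wk$c, wk0$c, tolerance = 1e-9)
  }
  # below generation 1 the side branches off the trunk cannot be lumped
  # (a windkessel terminal can only replace the children of a leaf-only
  # junction), so the whole-network reduction is the windkessel itself
  expect_error(trim_to_generation(net, 0L), "could not trim")
})

test_that("reduction_validity flags long or slow-wave branches", {
  # transit ratio 0.02: l/c = 0.016 s over T = 0.8 s
  s_short <- uniform_seg(l = 0.08, cd = 5)
  v1 <- reduction_validity(s_short, windkessel3(1e8, 1e9, 1e-9), period = 0.8)
  expect_equal(v1$transit_ratio, 0.02, tolerance = 1e-6)
  expect_false(v1$flagged)
  # transit ratio 0.3125: l/c = 0.25 s
  s_long <- uniform_seg(l = 1.25, cd = 5)
  v2 <- reduction_validity(s_long, windkessel3(1e8, 1e9, 1e-9), period = 0.8)
  expect_equal(v2$transit_ratio, 0.3125, tolerance = 1e-6)
  expect_true(v2$flagged)
})
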