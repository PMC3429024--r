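test_that("saturation field solves the convective O2 balance", {
  net <- small_network()
  # zero consumption: saturation is uniform at the entrance value
  s0 <- compute_saturation(net, entrance_sO2 = 0.63, consumption = 0)
  expect_equal(range(s0$values), c(0.63, 0.63))

  # O2 lost by the blood equals tissue consumption (conservation oracle)
  s1 <- compute_saturation(net)
  bal <- saturation_balance(s1)
  expect_lt(bal$rel_residual, 5e-3)
  expect_true(all(s1$values >= 0 & s1$values <= 1))
  # non-increasing along flow in every segment
  expect_true(all(s1$seg_s_out <= s1$seg_s_in + 1e-12))

  # consumption beyond supply names the starved segment
  expect_error(compute_saturation(net, consumption = 1), "starves")
})

test_that("single capillary with uniform S gives a linear saturation drop", {
  net <- single_capillary_network()
  sat <- compute_saturation(net, entrance_sO2 = 0.63,
                            consumption = 1.5e-4)
  tab <- data.frame(z = sat$grid$s_um, S = sat$values)
  fit <- stats::lm(S ~ z, data = tab)
  expect_lt(max(abs(stats::residuals(fit))), 1e-12)
  expect_equal(tab$S[1], 0.63)
})

test_that("prescribed saturation profiles honor endpoints and functions", {
  net <- single_capillary_network()
  lin <- prescribed_saturation(net,
                               sO2_fun = function(z) 0.63 - 0.46 * z / 342)
  expect_equal(lin$values[1], 0.63)
  expect_equal(lin$values[length(lin$values)], 0.17)
  byends <- prescribed_saturation(net,
                                  endpoints = data.frame(id = "s001",
                                                         s_in = 0.63,
                                                         s_out = 0.17))
  expect_equal(lin$values, byends$values)
  expect_error(prescribed_saturation(net,
                                     sO2_fun = function(z) z / 100),
               "\\[0, 1\\]")
})

test_that("steady ATP profile matches the closed-form single-capillary oracle", {
  net <- single_capillary_network()
  sat <- prescribed_saturation(net, sO2_fun = function(z)
    rep(0.63, length(z)))
  f <- solve_atp_steady(net, sat, atp_in = 0)
  z <- f$grid$s_um
  oracle <- single_capillary_profile(z)
  expect_lt(max(abs(f$values_uM - oracle)) / max(oracle), 5e-3)

  # first-order convergence in the grid spacing
  errs <- vapply(c(8, 4, 2, 1), function(dz) {
    s <- prescribed_saturation(net, sO2_fun = function(z)
      rep(0.63, length(z)), dz_um = dz)
    ff <- solve_atp_steady(net, s, atp_in = 0)
    max(abs(ff$values_uM - single_capillary_profile(ff$grid$s_um)))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[1] / errs[4], 4)
})

test_that("trivial transport limits behave exactly", {
  net <- small_network()
  sat <- compute_saturation(net)
  # no release, no inflow: identically zero
  f0 <- solve_atp_steady(net, sat, transport_params(C0 = 0), atp_in = 0)
  expect_equal(max(abs(f0$values_uM)), 0)
  # no release, pure inflow: release scaling is irrelevant
  fa <- solve_atp_steady(net, sat, transport_params(C0 = 0), atp_in = 0.25)
  fb <- solve_atp_steady(net, sat,
                         transport_params(C0 = 0, release_scale = 0.5),
                         atp_in = 0.25)
  expect_equal(fa$values_uM, fb$values_uM)
  expect_true(all(fa$values_uM >= 0))
})

test_that("the steady field is linear in C0 and obeys superposition", {
  net <- small_network()
  sat <- compute_saturation(net)
  f1 <- solve_atp_steady(net, sat, atp_in = 0)
  fk <- solve_atp_steady(net, sat,
                         transport_params(release_scale = 0.37),
                         atp_in = 0)
  expect_equal(fk$values_uM, 0.37 * f1$values_uM,
               tolerance = 1e-5)

  fin <- solve_atp_steady(net, sat, transport_params(C0 = 0),
                          atp_in = 0.25)
  fboth <- solve_atp_steady(net, sat, atp_in = 0.25)
  expect_lt(max(abs(fboth$values_uM - (f1$values_uM + fin$values_uM))) /
              max(fboth$values_uM), 1e-4)
})

test_that("junction mixing is plasma-flow weighted", {
  pure <- transport_params(C0 = 0, k_d = 0)
  # equal flows carrying 0.1 and 0.3 uM mix to 0.2 uM
  f <- solve_atp_steady(y_network(), prescribed_saturation(
    y_network(), sO2_fun = function(z) rep(0.6, length(z))),
    pure, atp_in = c(inA = 0.1, inB = 0.3))
  out_vals <- f$values_uM[f$grid$seg_of == 3]
  expect_equal(out_vals, rep(0.2, length(out_vals)), tolerance = 1e-6)

  # 3:1 plasma flows: weighted mean (3*0.1 + 1*0.3)/4 = 0.15
  y31 <- y_network(velocity_a_mm_s = 0.6, velocity_b_mm_s = 0.2)
  f31 <- solve_atp_steady(y31, prescribed_saturation(
    y31, sO2_fun = function(z) rep(0.6, length(z))),
    pure, atp_in = c(inA = 0.1, inB = 0.3))
  out31 <- f31$values_uM[f31$grid$seg_of == 3]
  expect_equal(out31, rep(0.15, length(out31)), tolerance = 1e-6)
})

test_that("steady-state mass balance closes per segment and network-wide", {
  net <- small_network()
  sat <- compute_saturation(net)
  f <- solve_atp_steady(net, sat, atp_in = 0.25, steady_tol = 1e-8)
  mb <- atp_mass_balance(f)
  expect_lt(mb$network$rel_residual, 5e-3)
  expect_lt(max(mb$segment$rel_residual), 5e-3)
})

test_that("mean concentration weighting behaves as documented", {
  net <- small_network()
  fu <- inject_field(net, 0.42)
  expect_equal(mean_capillary_atp(fu, "volume"), 0.42)
  expect_equal(mean_capillary_atp(fu, "grid-point"), 0.42)

  # two identical-volume segments at 0.1 and 0.3 average to 0.2
  seg2 <- data.frame(id = c("a", "b"), node_from = c("n1", "n2"),
                     node_to = c("n2", "n3"), length_um = 100,
                     radius_um = 2.5, velocity_mm_s = 0.5,
                     h_t = 0.2, h_d = 0.25, z_mid_um = c(50, 150))
  chain <- capillary_network(seg2, inlets = "n1", outlets = "n3",
                             L_um = 200, tissue_dims_um = c(10, 10, 200))
  f2 <- inject_field(chain, rep(c(0.1, 0.3), each = 51))
  expect_equal(mean_capillary_atp(f2), 0.2)

  # volume-weighted mean of the closed-form profile matches its analytic
  # integral: mean = A_inf (1 - (ell/L)(1 - exp(-L/ell)))
  net1 <- single_capillary_network()
  sat1 <- prescribed_saturation(net1, sO2_fun = function(z)
    rep(0.63, length(z)), dz_um = 0.5)
  prof <- single_capillary_profile(sat1$grid$s_um)
  fprof <- inject_field(net1, prof, dz_um = 0.5)
  p <- transport_params()
  r_cm <- 2.5e-4; u_cm <- 0.05
  ell <- r_cm * u_cm * (1 - 0.25) / (2 * p$k_d)
  a_inf <- 1e9 * r_cm * 0.2 * p$C0 * (1 - p$C1 * 0.63) / (2 * p$k_d)
  l_cm <- 342e-4
  analytic_mean <- a_inf * (1 - ell / l_cm * (1 - exp(-l_cm / ell)))
  expect_equal(mean_capillary_atp(fprof), analytic_mean, tolerance = 1e-3)
})

test_that("dilation signal follows its exponential-sum definition", {
  # a single segment sitting at z = L contributes with weight 1
  seg <- data.frame(id = "s", node_from = "a", node_to = "b",
                    length_um = 100, radius_um = 2.5, velocity_mm_s = 0.5,
                    h_t = 0.2, h_d = 0.25, z_mid_um = 342)
  net <- capillary_network(seg, inlets = "a", outlets = "b", L_um = 342,
                           tissue_dims_um = c(10, 10, 342))
  f <- inject_field(net, 0.076)
  expect_equal(dilation_signal(f, 1)$sigma, 0.076e-9)

  # lambda -> infinity recovers the plain sum of segment concentrations
  edl <- generate_network(network_spec())
  fu <- inject_field(edl, 0.076)
  seg_sum <- sum(segment_mean_atp(fu)$atp_uM) * 1e-9
  expect_equal(dilation_signal(fu, 1e9)$sigma, seg_sum, tolerance = 1e-10)

  # 208 segments at 0.076 uM, lambda = 1 cm: direct-summation oracle
  z_cm <- edl$segments$z_mid_um * 1e-4
  oracle <- sum(0.076e-9 * exp(-(342e-4 - z_cm) / 1))
  sig <- dilation_signal(fu, 1)$sigma
  expect_equal(sig, oracle, tolerance = 1e-10)
  expect_gt(sig, 1.5e-8)
  expect_lt(sig, 1.65e-8)

  # short network, long attenuation length: sigma within 4% of the sum
  expect_lt(abs(sig - seg_sum) / seg_sum, 0.04)

  expect_error(dilation_signal(fu, -1), "positive")
})

test_that("counter-current segments are transported correctly", {
  # a capillary whose flow runs toward decreasing z gives the same profile
  # along its own flow direction as the co-current twin
  seg <- data.frame(id = "cc", node_from = "hi", node_to = "lo",
                    length_um = 342, radius_um = 2.5,
                    velocity_mm_s = -0.5, h_t = 0.2, h_d = 0.25,
                    z_mid_um = 171)
  nodes <- data.frame(id = c("hi", "lo"), x_um = 0, y_um = 0,
                      z_um = c(342, 0))
  cc <- capillary_network(seg, inlets = "hi", outlets = "lo", L_um = 342,
                          tissue_dims_um = c(10, 10, 342), nodes = nodes)
  sat_cc <- prescribed_saturation(cc, sO2_fun = function(z)
    rep(0.63, length(z)))
  f_cc <- solve_atp_steady(cc, sat_cc, atp_in = 0)

  co <- single_capillary_network()
  sat_co <- prescribed_saturation(co, sO2_fun = function(z)
    rep(0.63, length(z)))
  f_co <- solve_atp_steady(co, sat_co, atp_in = 0)
  expect_equal(f_cc$values_uM, f_co$values_uM, tolerance = 1e-12)

  # and the 208-segment fixture's counter-current track solves cleanly
  edl <- generate_network(network_spec())
  expect_gt(sum(edl$segments$velocity_mm_s < 0), 0)
  sat <- compute_saturation(edl)
  cc_idx <- which(edl$segments$velocity_mm_s < 0)
  expect_true(all(sat$seg_s_out[cc_idx] <= sat$seg_s_in[cc_idx]))
})

test_that("insulin network scenario halves the field exactly at zero inlet", {
  net <- small_network()
  sat <- compute_saturation(net)
  tab <- insulin_network_scenario(net, sat, atp_in_uM = c(0, 0.25))
  z <- tab[tab$atp_in_uM == 0, ]
  expect_equal(z$mean_decrease_pct, 50, tolerance = 1e-3)
  expect_equal(z$sigma_decrease_pct, 50, tolerance = 1e-3)
  nz <- tab[tab$atp_in_uM == 0.25, ]
  expect_gt(nz$mean_decrease_pct, 0)
  expect_lt(nz$mean_decrease_pct, 50)
  expect_gt(nz$sigma_decrease_pct, 0)
  expect_lt(nz$sigma_decrease_pct, 50)
})

test_that("solver guards its numerical preconditions", {
  net <- single_capillary_network()
  sat <- prescribed_saturation(net, sO2_fun = function(z)
    rep(0.63, length(z)))
  expect_error(solve_atp_steady(net, sat, cfl = 1.5), "cfl")
  expect_error(solve_atp_steady(net, sat, max_time_s = 1e-4),
               "steady state")
  expect_warning(solve_atp_steady(net, sat,
                                  transport_params(C1 = 2)),
                 "negative")
})
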