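test_that("pathway derivatives match direct evaluation of the kinetics", {
  zero <- c(gpa = 0, camp = 0, pkaa = 0, cftra = 0)

  # fully saturated hemoglobin, resting cell: nothing moves
  expect_equal(unname(pathway_rhs(zero, table1, thb = 0)), rep(0, 4))

  # desaturation drives only the G-protein term from rest
  d <- pathway_rhs(zero, table1, thb = 0.843)
  expect_equal(d[["gpa"]], 25.0 * 1 * 0.843^1.2)
  expect_equal(unname(d[c("camp", "pkaa", "cftra")]), rep(0, 3))

  # saturated G-protein pool relaxes at the reverse rate
  full <- c(gpa = 1, camp = 0, pkaa = 0, cftra = 0)
  expect_equal(pathway_rhs(full, table1, thb = 0.5)[["gpa"]], -3.36)

  # PKA feedback enters both cAMP terms
  st <- c(gpa = 0.4, camp = 0.3, pkaa = 0.2, cftra = 0.1)
  expect_equal(pathway_rhs(st, table1, thb = 0.6)[["camp"]],
               49.5 * 0.4 / (1 + 2.47 * 0.2) -
                 101 * 1 * 0.2 * 0.3 / (1 + 0.3))

  expect_error(pathway_rhs(zero, table1, thb = 1.2), "thb")
  expect_error(pathway_rhs(c(gpa = -0.1, camp = 0, pkaa = 0, cftra = 0),
                           table1, thb = 0.5), "non-negative")
})

test_that("constant desaturation reproduces the closed-form Gi kinetics", {
  # the Gi equation is linear and autonomous: for constant tHb,
  # GPa(t) = GPa_inf (1 - exp(-(k_on + k_off) t)) with
  # k_on = k_gp_f tHb^alpha
  thb <- 0.843
  k_on <- table1$k_gp_f * thb^table1$alpha
  k_off <- table1$k_gp_r
  gpa_inf <- k_on / (k_on + k_off)

  traj <- simulate_pathway(table1, stimulus_protocol(0, 5, 1 - thb),
                           t_end = 5)
  closed <- gpa_inf * (1 - exp(-(k_on + k_off) * traj$time_s))
  expect_lt(max(abs(traj$GPa - closed)), 1e-6)
  expect_equal(traj$GPa[nrow(traj)], gpa_inf, tolerance = 1e-7)
  expect_equal(gpa_inf, 0.858, tolerance = 1e-3)
})

test_that("a fully saturated protocol leaves the pathway silent", {
  traj <- simulate_pathway(table1, stimulus_protocol(0, 1, 1))
  expect_equal(max(abs(as.matrix(traj[, -1]))), 0)
  expect_equal(attr(traj, "total_release"), 0)
})

test_that("states respect pool bounds and conservation for random protocols", {
  set.seed(101)
  for (rep in 1:4) {
    edges <- sort(c(0, stats::runif(3, 0.02, 0.5), 0.6))
    proto <- stimulus_protocol(head(edges, -1), tail(edges, -1),
                               stats::runif(4, 0, 1))
    traj <- simulate_pathway(table1, proto)
    tol <- 1e-7
    expect_true(all(traj$GPa >= -tol & traj$GPa <= table1$gp_total + tol))
    expect_true(all(traj$PKAa >= -tol & traj$PKAa <= table1$pka_total + tol))
    expect_true(all(traj$CFTRa >= -tol &
                      traj$CFTRa <= table1$cftr_total + tol))
    expect_true(all(traj$cAMP >= -tol))
    expect_true(all(traj$F_ATP >= -tol))
  }
})

test_that("the reference pulse peaks where the kinetics say it should", {
  pk <- attr(reference_run(), "peaks")
  # cAMP leads, ATP flux lags by about 100 ms
  expect_gt(pk$F_ATP$time_s, pk$cAMP$time_s)
  expect_equal(1000 * pk$cAMP$time_s, 51, tolerance = 0.05)
  expect_equal(1000 * pk$F_ATP$time_s, 157, tolerance = 0.05)
})

test_that("total release integrates the flux curve exactly on simple shapes", {
  expect_equal(total_release(synthetic_trajectory(seq(0, 1, 0.01), 0)), 0)

  # rectangular flux of height h and duration d has area h*d
  tt <- seq(0, 0.5, by = 0.005)
  h <- 0.37; d <- 0.2
  traj <- synthetic_trajectory(tt, ifelse(tt <= d, h, 0))
  expect_equal(total_release(traj, window = c(0, d)), h * d)

  expect_error(total_release(traj, window = c(0.2, 0.1)), "increasing")
  expect_error(total_release(traj, window = c(0, 10)), "span")
})

test_that("total release is insensitive to halving the integrator tolerance", {
  r1 <- attr(reference_run(), "total_release")
  traj2 <- simulate_pathway(table1, desaturation_pulse(0.157),
                            rtol = 5e-9, atol = 5e-13)
  r2 <- attr(traj2, "total_release")
  expect_lt(abs(r1 - r2) / r1, 1e-3)
})

test_that("ATP flux decays below 1% of peak within 1 s of stimulus end", {
  traj <- reference_run()
  expect_lt(flux_decay_time(traj, frac = 0.01), 1)
  # and it really is a post-peak crossing, not the rising edge
  expect_gt(flux_decay_time(traj, frac = 0.01),
            attr(traj, "peaks")$F_ATP$time_s - 0.040)
})

test_that("protocol construction rejects malformed input", {
  expect_error(stimulus_protocol(c(0, 0.1), c(0.1, 0.3), c(1.2, 1)), "sO2")
  expect_error(stimulus_protocol(c(0, 0.2), c(0.1, 0.3), c(1, 1)),
               "contiguous")
  expect_error(stimulus_protocol(0, 0, 1), "t_end")
  expect_error(simulate_pathway(table1, desaturation_pulse(0.157),
                                t_end = 0.5), "t_end")
})

test_that("parameter files round-trip and defaults are validated", {
  f <- tempfile(fileext = ".csv")
  p <- pathway_params(pde3_rel = 1.87, gp_total = 0.6)
  write_pathway_params(p, f)
  q <- read_pathway_params(f)
  expect_equal(unclass(q), unclass(p))
  writeLines("nonsense,3", f)
  expect_error(read_pathway_params(f), "unknown")
  expect_error(pathway_params(k_gp_f = -1), "non-negative")
  expect_error(pathway_params(beta = 0), "> 0")
})
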