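test_that("generated networks pass the full invariant suite", {
  for (seed in c(1, 42, 99)) {
    net <- generate_network(network_spec(seed = seed))
    expect_silent(validate_network(net))
    expect_equal(nrow(net$segments), 208)
    expect_gt(sum(net$segments$velocity_mm_s < 0), 0)  # counter-current
  }
})

test_that("identical spec and seed reproduce the network byte-for-byte", {
  spec <- network_spec(seed = 42)
  d1 <- file.path(tempdir(), "netA")
  d2 <- file.path(tempdir(), "netB")
  write_network(generate_network(spec), d1)
  write_network(generate_network(spec), d2)
  expect_identical(readLines(paste0(d1, "_segments.csv")),
                   readLines(paste0(d2, "_segments.csv")))
  expect_identical(readLines(paste0(d1, "_network.json")),
                   readLines(paste0(d2, "_network.json")))

  # different seeds give different geometries, both invariant-clean
  other <- generate_network(network_spec(seed = 43))
  expect_false(identical(generate_network(spec)$segments, other$segments))
  expect_silent(validate_network(other))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_network(network_spec(n_segments = 30, n_tracks = 3)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("velocity and hematocrit marginals track the spec", {
  spec <- network_spec(seed = 42)
  s <- generate_network(spec)$segments
  expect_lt(abs(mean(abs(s$velocity_mm_s)) - spec$velocity_mean_mm_s) /
              spec$velocity_mean_mm_s, 0.1)
  expect_lt(abs(mean(s$h_d) - spec$h_d_mean) / spec$h_d_mean, 0.1)
  expect_equal(s$h_t / s$h_d, rep(spec$fahraeus_ratio, nrow(s)))
  expect_true(all(s$h_d > 0 & s$h_d < 1))
})

test_that("reference fixtures have their documented structure", {
  fx <- reference_fixtures()
  expect_equal(nrow(fx$single$segments), 1)
  expect_equal(nrow(fx$y$segments), 3)
  expect_equal(nrow(fx$edl208$segments), 208)
  expect_equal(fx$linear_sO2_fun(0), 0.63)
  expect_equal(fx$linear_sO2_fun(342), 0.17)
})

test_that("network invariants reject broken inputs", {
  net <- single_capillary_network()
  bad <- net$segments
  bad$velocity_mm_s <- 0
  expect_error(capillary_network(bad, "in", "out", 342, c(10, 10, 342)),
               "nonzero")
  bad <- net$segments
  bad$h_d <- 1.2
  expect_error(capillary_network(bad, "in", "out", 342, c(10, 10, 342)),
               "hematocrit")

  # plasma flow imbalance at an interior node
  seg2 <- data.frame(id = c("a", "b"), node_from = c("n1", "n2"),
                     node_to = c("n2", "n3"), length_um = 100,
                     radius_um = 2.5, velocity_mm_s = c(0.5, 0.9),
                     h_t = 0.2, h_d = 0.25, z_mid_um = c(50, 150))
  expect_error(capillary_network(seg2, "n1", "n3", 200, c(10, 10, 200)),
               "not conserved")

  # a flow cycle is rejected
  cyc <- data.frame(id = c("a", "b", "c"),
                    node_from = c("n1", "n2", "n3"),
                    node_to = c("n2", "n3", "n2"),
                    length_um = 100, radius_um = 2.5, velocity_mm_s = 0.5,
                    h_t = 0.2, h_d = 0.25, z_mid_um = 50)
  expect_error(capillary_network(cyc, "n1", character(0), 200,
                                 c(10, 10, 200)), "cycle|outflow|path")
})

test_that("the exchange format round-trips through disk", {
  net <- generate_network(network_spec(n_segments = 30, n_tracks = 3,
                                       seed = 5))
  stem <- file.path(tempdir(), "roundtrip")
  write_network(net, stem)
  back <- read_network(stem)
  expect_equal(back$segments$velocity_mm_s, net$segments$velocity_mm_s)
  expect_equal(back$inlets, net$inlets)
  expect_equal(back$L_um, net$L_um)
  expect_equal(back$nodes$z_um, net$nodes$z_um)
  expect_error(read_network(file.path(tempdir(), "missing")), "expected")
})
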