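# Shared fixtures and small helpers, built in code at test time.

table1 <- pathway_params()

# one cached reference run of the standard stimulus (40 ms pulse to 15.7%)
reference_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_pathway(table1,
                                                   desaturation_pulse(0.157))
    cache
  }
})

# wrap a hand-built flux curve as a minimal trajectory object
synthetic_trajectory <- function(time_s, f_atp,
                                 protocol = desaturation_pulse(0.157)) {
  structure(data.frame(time_s = time_s, GPa = 0, cAMP = 0, PKAa = 0,
                       CFTRa = f_atp / 2, F_ATP = f_atp),
            class = c("pathway_trajectory", "data.frame"),
            params = table1, protocol = protocol)
}

# small fast synthetic network for property tests
small_network <- function(seed = 7) {
  generate_network(network_spec(n_segments = 30, n_tracks = 3,
                                tissue_dims_um = c(60, 60, 342),
                                seed = seed))
}

# inject a concentration field (uM) into an atp_field shell so that
# summaries can be tested against hand-computed oracles
inject_field <- function(net, values_uM, dz_um = 2) {
  sat <- prescribed_saturation(net, sO2_fun = function(z) rep(0.63, length(z)),
                               dz_um = dz_um)
  vals <- if (length(values_uM) == 1) rep(values_uM, sat$grid$total)
          else values_uM
  structure(list(values_uM = vals, grid = sat$grid, network = net,
                 saturation = sat, params = transport_params(),
                 atp_in_uM = 0, dz_um = dz_um,
                 steady_time_s = 0, dt_s = 0),
            class = "atp_field")
}
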