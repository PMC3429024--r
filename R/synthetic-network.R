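#' Specification for a synthetic capillary network
#'
#' Describes the statistical structure of the synthetic networks produced
#' by [generate_network()]. The defaults emulate the reported structure of
#' a reconstructed rat extensor digitorum longus (EDL) capillary bed: 208
#' cylindrical segments in an 84 x 169 x 342 um tissue domain with 63%
#' mean entrance saturation, a tissue O2 consumption of 1.5e-4
#' ml O2/ml/s, rat-EDL-typical capillary velocities and hematocrits, and
#' one counter-current capillary. Length, radius, velocity and hematocrit
#' distributions are literature-typical placeholders for the unpublished
#' measured ones.
#'
#' @param n_segments target segment count.
#' @param tissue_dims_um tissue bounding box (um); the third dimension is
#'   the arterio-venous axis.
#' @param n_tracks number of capillary paths spanning the domain (one of
#'   which is counter-current when `counter_current = TRUE`).
#' @param radius_mean_um,radius_sd_um segment radius distribution.
#' @param crosslink_radius_mean_um mean radius of cross-connections
#'   (thinner than through-tracks, so they divert a minority of flow).
#' @param velocity_mean_mm_s,velocity_sd_mm_s inlet blood velocity
#'   distribution.
#' @param h_d_mean,h_d_sd inlet discharge hematocrit distribution.
#' @param fahraeus_ratio tube-to-discharge hematocrit ratio H_T/H_D
#'   (the Fahraeus effect: red cells travel faster than plasma, so the
#'   resident hematocrit is lower than the discharge hematocrit).
#' @param skim_exponent plasma-skimming exponent: at diverging junctions
#'   the red-cell flux fraction is the plasma fraction raised to this
#'   power (renormalized), biasing red cells into the faster branch.
#' @param counter_current include one counter-current track.
#' @param entrance_sO2,consumption companion O2 boundary conditions carried
#'   with the spec for convenience.
#' @param seed integer random seed; the same spec and seed reproduce the
#'   same network exactly.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(n_segments = 208,
                         tissue_dims_um = c(84, 169, 342),
                         n_tracks = 15,
                         radius_mean_um = 2.5, radius_sd_um = 0.2,
                         crosslink_radius_mean_um = 2.0,
                         velocity_mean_mm_s = 0.35,
                         velocity_sd_mm_s = 0.1,
                         h_d_mean = 0.2, h_d_sd = 0.05,
                         fahraeus_ratio = 0.8,
                         skim_exponent = 1.2,
                         counter_current = TRUE,
                         entrance_sO2 = 0.63,
                         consumption = 1.5e-4,
                         seed = 42) {
  stopifnot(n_segments >= 1, n_tracks >= 1,
            radius_mean_um > 0, velocity_mean_mm_s > 0,
            h_d_mean > 0, h_d_mean < 1,
            fahraeus_ratio > 0, fahraeus_ratio <= 1,
            length(tissue_dims_um) == 3, all(tissue_dims_um > 0))
  structure(as.list(environment()), class = "network_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a reproducible synthetic capillary network
#'
#' Builds a layered directed mesh from the arterial to the venular face of
#' the tissue domain: parallel capillary tracks subdivided into segments,
#' with occasional thinner cross-connections between neighboring tracks
#' and (by default) one counter-current track entering from the venular
#' face. Blood flow is routed from the inlets through the mesh — plasma
#' splits at diverging junctions in proportion to branch conductance
#' (radius^4) and red cells follow a plasma-skimming rule — so plasma and
#' red-cell volumetric flows are conserved exactly at every node, and
#' velocities and hematocrits are consistent with the routed flows rather
#' than drawn independently.
#'
#' @param spec a [network_spec()].
#' @return a `capillary_network` passing [validate_network()]; identical
#'   spec and seed give an identical network.
#' @examples
#' net <- generate_network(network_spec(n_segments = 30, n_tracks = 3))
#' net
#' @export
generate_network <- function(spec = network_spec()) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(spec$seed, build_synthetic_network(spec))
}

build_synthetic_network <- function(spec) {
  n_tracks <- spec$n_tracks
  zdim <- spec$tissue_dims_um[3]
  # segments per track chosen so tracks fill most of the target count,
  # the remainder becoming cross-connections
  m <- max(2L, floor(spec$n_segments / n_tracks))
  n_cross <- spec$n_segments - n_tracks * m
  if (n_cross < 0)
    stop("infeasible spec: n_segments < 2 * n_tracks", call. = FALSE)
  cc_track <- if (spec$counter_current) n_tracks else 0L

  # node layout: tracks on a grid over the cross-section, layers along z
  nx <- max(1L, round(sqrt(n_tracks * spec$tissue_dims_um[1] /
                             spec$tissue_dims_um[2])))
  ny <- ceiling(n_tracks / nx)
  xg <- seq(0.15, 0.85, length.out = nx) * spec$tissue_dims_um[1]
  yg <- seq(0.1, 0.9, length.out = ny) * spec$tissue_dims_um[2]
  zg <- seq(0, zdim, length.out = m + 1)

  nodes <- list()
  for (t in seq_len(n_tracks)) {
    ix <- (t - 1) %% nx + 1; iy <- (t - 1) %/% nx + 1
    zl <- zg
    if (m > 1)
      zl[2:m] <- zl[2:m] + stats::runif(m - 1, -0.08, 0.08) * zdim / m
    if (t == cc_track) zl <- rev(zl)   # counter-current: enters at high z
    for (l in 0:m) {
      nodes[[length(nodes) + 1]] <- data.frame(
        id = sprintf("t%02d_l%02d", t, l),
        x_um = xg[ix] + stats::runif(1, -3, 3),
        y_um = yg[iy] + stats::runif(1, -3, 3),
        z_um = zl[l + 1],
        track = t, layer = l)
    }
  }
  nodes <- do.call(rbind, nodes)
  nodes$z_um <- pmin(pmax(nodes$z_um, 0), zdim)

  node_id <- function(t, l) sprintf("t%02d_l%02d", t, l)
  edges <- list()
  for (t in seq_len(n_tracks)) {
    for (l in 0:(m - 1)) {
      edges[[length(edges) + 1]] <- data.frame(
        node_from = node_id(t, l), node_to = node_id(t, l + 1),
        radius_um = max(1, stats::rnorm(1, spec$radius_mean_um,
                                        spec$radius_sd_um)),
        cross = FALSE)
    }
  }
  # cross-connections between neighboring co-current tracks, from layer l
  # to layer l+1 (keeps the flow graph acyclic); never touch the
  # counter-current track
  if (n_cross > 0) {
    co <- setdiff(seq_len(n_tracks), cc_track)
    if (length(co) < 2)
      stop("infeasible spec: cross-links need at least two co-current tracks",
           call. = FALSE)
    slots <- expand.grid(t = co[-length(co)], l = 1:(m - 2))
    slots <- slots[sample(nrow(slots), min(n_cross, nrow(slots))), ]
    if (nrow(slots) < n_cross)
      stop("infeasible spec: not enough cross-link slots for n_segments",
           call. = FALSE)
    t2 <- co[match(slots$t, co) + 1]
    for (k in seq_len(nrow(slots))) {
      edges[[length(edges) + 1]] <- data.frame(
        node_from = node_id(slots$t[k], slots$l[k]),
        node_to = node_id(t2[k], slots$l[k] + 1),
        radius_um = max(1, stats::rnorm(1, spec$crosslink_radius_mean_um,
                                        spec$radius_sd_um)),
        cross = TRUE)
    }
  }
  edges <- do.call(rbind, edges)
  edges$id <- sprintf("s%03d", seq_len(nrow(edges)))

  coord <- function(ids, col) nodes[[col]][match(ids, nodes$id)]
  dx <- coord(edges$node_to, "x_um") - coord(edges$node_from, "x_um")
  dy <- coord(edges$node_to, "y_um") - coord(edges$node_from, "y_um")
  dz <- coord(edges$node_to, "z_um") - coord(edges$node_from, "z_um")
  edges$length_um <- sqrt(dx^2 + dy^2 + dz^2)
  edges$z_mid_um <- (coord(edges$node_from, "z_um") +
                       coord(edges$node_to, "z_um")) / 2

  inlets <- node_id(seq_len(n_tracks), 0)
  outlets <- node_id(seq_len(n_tracks), m)

  # ---- flow routing ----
  node_ids <- nodes$id
  qp_node <- qr_node <- stats::setNames(rep(0, length(node_ids)), node_ids)
  for (t in seq_len(n_tracks)) {
    u_in <- max(0.1, stats::rnorm(1, spec$velocity_mean_mm_s,
                                  spec$velocity_sd_mm_s))
    hd_in <- min(0.45, max(0.08, stats::rnorm(1, spec$h_d_mean,
                                              spec$h_d_sd)))
    r_first <- edges$radius_um[edges$node_from == node_id(t, 0)][1]
    q_tot <- pi * (r_first * 1e-4)^2 * u_in * 0.1     # cm^3/s
    qp_node[node_id(t, 0)] <- q_tot * (1 - hd_in)
    qr_node[node_id(t, 0)] <- q_tot * hd_in
  }

  edges$qp <- edges$qr <- NA_real_
  topo <- nodes$id[order(nodes$layer, nodes$track)]
  for (nd in topo) {
    out <- which(edges$node_from == nd)
    if (!length(out)) next
    w <- edges$radius_um[out]^4
    wp <- w / sum(w)
    wr <- wp^spec$skim_exponent
    wr <- wr / sum(wr)
    edges$qp[out] <- qp_node[nd] * wp
    edges$qr[out] <- qr_node[nd] * wr
    tgt <- edges$node_to[out]
    for (k in seq_along(out)) {
      qp_node[tgt[k]] <- qp_node[tgt[k]] + edges$qp[out[k]]
      qr_node[tgt[k]] <- qr_node[tgt[k]] + edges$qr[out[k]]
    }
  }

  q_tot <- edges$qp + edges$qr
  area_cm2 <- pi * (edges$radius_um * 1e-4)^2
  u_mm_s <- q_tot / area_cm2 * 10
  # uniform flow rescale so the velocity marginal mean matches the spec
  # exactly; preserves node conservation and hematocrits
  rescale <- spec$velocity_mean_mm_s / mean(u_mm_s)
  edges$qp <- edges$qp * rescale
  edges$qr <- edges$qr * rescale
  u_mm_s <- u_mm_s * rescale
  h_d <- edges$qr / q_tot
  h_t <- spec$fahraeus_ratio * h_d
  # orientation sign: negative when flow runs toward decreasing z
  sgn <- ifelse(dz < 0, -1, 1)

  segments <- data.frame(id = edges$id,
                         node_from = edges$node_from,
                         node_to = edges$node_to,
                         length_um = edges$length_um,
                         radius_um = edges$radius_um,
                         velocity_mm_s = sgn * u_mm_s,
                         h_t = h_t, h_d = h_d,
                         z_mid_um = edges$z_mid_um)
  capillary_network(segments, inlets = inlets, outlets = outlets,
                    L_um = zdim, tissue_dims_um = spec$tissue_dims_um,
                    nodes = nodes[, c("id", "x_um", "y_um", "z_um")])
}

#' Single straight capillary (the analytic test fixture)
#'
#' @param length_um,radius_um,velocity_mm_s,h_t,h_d segment properties.
#' @return a one-segment `capillary_network` spanning `[0, length_um]` on
#'   the arterio-venous axis.
#' @export
single_capillary_network <- function(length_um = 342, radius_um = 2.5,
                                     velocity_mm_s = 0.5, h_t = 0.2,
                                     h_d = 0.25) {
  segments <- data.frame(id = "s001", node_from = "in", node_to = "out",
                         length_um = length_um, radius_um = radius_um,
                         velocity_mm_s = velocity_mm_s,
                         h_t = h_t, h_d = h_d, z_mid_um = length_um / 2)
  nodes <- data.frame(id = c("in", "out"), x_um = 0, y_um = 0,
                      z_um = c(0, length_um))
  capillary_network(segments, inlets = "in", outlets = "out",
                    L_um = length_um,
                    tissue_dims_um = c(4 * radius_um, 4 * radius_um,
                                       length_um),
                    nodes = nodes)
}

#' Two-inlet converging-Y network (the junction-mixing fixture)
#'
#' Two inlet segments merge at a node feeding one outlet segment. With
#' equal radii and hematocrits, the plasma flows of the two branches are
#' in the ratio of their velocities, and the merged concentration is their
#' plasma-flow-weighted mean.
#'
#' @param velocity_a_mm_s,velocity_b_mm_s inlet branch velocities; the
#'   outlet velocity is their sum (equal radii), which conserves flow.
#' @param radius_um,h_t,h_d shared segment properties.
#' @param length_um length of each of the three segments.
#' @return a three-segment `capillary_network` with inlets `"inA"`,
#'   `"inB"`.
#' @export
y_network <- function(velocity_a_mm_s = 0.4, velocity_b_mm_s = 0.4,
                      radius_um = 2.5, h_t = 0.2, h_d = 0.25,
                      length_um = 100) {
  segments <- data.frame(
    id = c("sA", "sB", "sOut"),
    node_from = c("inA", "inB", "junction"),
    node_to = c("junction", "junction", "out"),
    length_um = length_um, radius_um = radius_um,
    velocity_mm_s = c(velocity_a_mm_s, velocity_b_mm_s,
                      velocity_a_mm_s + velocity_b_mm_s),
    h_t = h_t, h_d = h_d,
    z_mid_um = c(length_um / 2, length_um / 2, 1.5 * length_um))
  nodes <- data.frame(id = c("inA", "inB", "junction", "out"),
                      x_um = c(-10, 10, 0, 0), y_um = 0,
                      z_um = c(0, 0, length_um, 2 * length_um))
  capillary_network(segments, inlets = c("inA", "inB"), outlets = "out",
                    L_um = 2 * length_um,
                    tissue_dims_um = c(40, 40, 2 * length_um),
                    nodes = nodes)
}

#' Reference fixtures for testing and demonstration
#'
#' A named bundle: `single` (one straight capillary, the analytic
#' fixture), `y` (two-inlet converging junction), `edl208` (the default
#' 208-segment synthetic rat-EDL-like network, seed 42) and
#' `linear_sO2_fun` (a saturation profile decreasing linearly from 63% at
#' the arterial face to 17% at the venular face, for use with
#' [prescribed_saturation()]).
#'
#' @return a named list.
#' @export
reference_fixtures <- function() {
  list(single = single_capillary_network(),
       y = y_network(),
       edl208 = generate_network(network_spec(seed = 42)),
       linear_sO2_fun = function(z_um) 0.63 - (0.63 - 0.17) * z_um / 342)
}
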