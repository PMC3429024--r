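#' Steady-state capillary oxyhemoglobin saturation from a convective balance
#'
#' Computes per-segment saturation profiles S(z) from a one-dimensional
#' convective O2 balance: the O2 carried by the red-cell flux of each
#' segment decreases linearly along the segment by that segment's share of
#' the tissue consumption, apportioned by lateral surface area. Saturations
#' mix at converging nodes weighted by red-cell (hemoglobin) flux. With
#' zero consumption the field is uniform at the entrance saturation; with
#' realistic consumption the profiles decrease nearly linearly along the
#' flow, which is the regime this balance is designed for.
#'
#' @param net a `capillary_network`.
#' @param entrance_sO2 saturation at inlet nodes: a single fraction, or a
#'   named vector keyed by inlet node id.
#' @param consumption tissue O2 consumption rate (ml O2 / ml tissue / s).
#' @param hb_capacity O2-binding capacity of red cells at full saturation
#'   (ml O2 / ml RBC); 0.5 is the standard value.
#' @param dz_um axial grid spacing (um).
#' @return An object of class `saturation_field`: per-grid-point S in
#'   flow order, with the grid and network attached.
#' @export
compute_saturation <- function(net, entrance_sO2 = 0.63,
                               consumption = 1.5e-4, hb_capacity = 0.5,
                               dz_um = 2) {
  stopifnot(inherits(net, "capillary_network"))
  if (any(entrance_sO2 <= 0) || any(entrance_sO2 > 1))
    stop("entrance_sO2 must lie in (0, 1]", call. = FALSE)
  s <- net$segments
  grid <- build_grid(net, dz_um)
  q_rbc <- rbc_flow(net)                       # cm^3 RBC / s
  o2_cap <- q_rbc * hb_capacity                # ml O2 / s at S = 1

  v_tissue_ml <- prod(net$tissue_dims_um) * 1e-12
  area <- s$radius_um * s$length_um            # proportional lateral area
  q_seg <- consumption * v_tissue_ml * area / sum(area)  # ml O2/s removed

  inlet_s <- if (length(entrance_sO2) == 1) {
    stats::setNames(rep(entrance_sO2, length(net$inlets)), net$inlets)
  } else {
    if (!all(net$inlets %in% names(entrance_sO2)))
      stop("entrance_sO2 must name every inlet node", call. = FALSE)
    entrance_sO2[net$inlets]
  }

  order_nodes <- topological_nodes(net)
  node_s <- stats::setNames(rep(NA_real_, length(order_nodes)), order_nodes)
  node_s[names(inlet_s)] <- inlet_s
  seg_s_in <- seg_s_out <- rep(NA_real_, nrow(s))

  for (nd in order_nodes) {
    if (is.na(node_s[nd])) {
      inc <- which(s$node_to == nd)
      node_s[nd] <- sum(q_rbc[inc] * seg_s_out[inc]) / sum(q_rbc[inc])
    }
    out <- which(s$node_from == nd)
    for (e in out) {
      seg_s_in[e] <- node_s[nd]
      seg_s_out[e] <- seg_s_in[e] - q_seg[e] / o2_cap[e]
      if (seg_s_out[e] < 0)
        stop(sprintf(
          "O2 consumption exceeds supply: segment %s starves (S would reach %.3g)",
          s$id[e], seg_s_out[e]), call. = FALSE)
    }
  }

  frac <- grid$s_um / rep(s$length_um, grid$n_pts)
  values <- rep(seg_s_in, grid$n_pts) * (1 - frac) +
    rep(seg_s_out, grid$n_pts) * frac
  structure(list(values = values, grid = grid, dz_um = dz_um,
                 network = net,
                 seg_s_in = seg_s_in, seg_s_out = seg_s_out),
            class = "saturation_field")
}

#' Prescribe a saturation field instead of solving the O2 balance
#'
#' Builds a `saturation_field` from user-supplied data: either per-segment
#' endpoint saturations (linear within each segment, in flow order) or a
#' function of axial position z evaluated at every grid point (requires
#' node coordinates in the network).
#'
#' @param net a `capillary_network`.
#' @param endpoints data frame with columns `id`, `s_in`, `s_out` giving
#'   the flow-entrance and flow-exit saturation of each segment.
#' @param sO2_fun alternatively, a function `f(z_um)` returning S.
#' @param dz_um axial grid spacing (um).
#' @return a `saturation_field`.
#' @examples
#' net <- single_capillary_network()
#' f <- prescribed_saturation(net, sO2_fun = function(z) 0.63 - 0.46 * z / 342)
#' range(f$values)
#' @export
prescribed_saturation <- function(net, endpoints = NULL, sO2_fun = NULL,
                                  dz_um = 2) {
  stopifnot(inherits(net, "capillary_network"))
  grid <- build_grid(net, dz_um)
  s <- net$segments
  if (!is.null(sO2_fun)) {
    values <- sO2_fun(grid_z_um(net, grid))
  } else if (!is.null(endpoints)) {
    idx <- match(s$id, as.character(endpoints$id))
    if (anyNA(idx))
      stop("endpoints must cover every segment id", call. = FALSE)
    frac <- grid$s_um / rep(s$length_um, grid$n_pts)
    values <- rep(endpoints$s_in[idx], grid$n_pts) * (1 - frac) +
      rep(endpoints$s_out[idx], grid$n_pts) * frac
  } else {
    stop("supply either endpoints or sO2_fun", call. = FALSE)
  }
  if (any(values < 0 | values > 1))
    stop("prescribed saturation must lie in [0, 1]", call. = FALSE)
  structure(list(values = values, grid = grid, dz_um = dz_um,
                 network = net,
                 seg_s_in = values[grid$first],
                 seg_s_out = values[grid$last]),
            class = "saturation_field")
}

#' @export
print.saturation_field <- function(x, ...) {
  cat(sprintf("Saturation field on %d grid points (%d segments, dz = %g um)\n",
              x$grid$total, length(x$grid$n_pts), x$dz_um))
  cat(sprintf("  S range [%.3f, %.3f], inlet-weighted mean %.3f\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' Network O2 mass balance of a computed saturation field
#'
#' O2 flux carried into the network minus flux carried out, compared with
#' total tissue consumption; the relative residual is the conservation
#' check for [compute_saturation()].
#'
#' @param field a `saturation_field` from [compute_saturation()].
#' @param consumption,hb_capacity values used to compute the field.
#' @return list with `o2_in`, `o2_out`, `consumed` (ml O2/s) and
#'   `rel_residual`.
#' @export
saturation_balance <- function(field, consumption = 1.5e-4,
                               hb_capacity = 0.5) {
  net <- field$network
  s <- net$segments
  q_rbc <- rbc_flow(net)
  inlet_edges <- which(s$node_from %in% net$inlets)
  outlet_edges <- which(s$node_to %in% net$outlets)
  o2_in <- sum(q_rbc[inlet_edges] * hb_capacity *
                 field$seg_s_in[inlet_edges])
  o2_out <- sum(q_rbc[outlet_edges] * hb_capacity *
                  field$seg_s_out[outlet_edges])
  consumed <- consumption * prod(net$tissue_dims_um) * 1e-12
  list(o2_in = o2_in, o2_out = o2_out, consumed = consumed,
       rel_residual = abs((o2_in - o2_out) - consumed) / consumed)
}
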