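#' Parameters of the capillary ATP transport model
#'
#' The plasma ATP balance in each segment combines advection by plasma
#' flow, saturation-dependent ATP release from red cells, and degradation
#' by endothelial ecto-ATPases:
#' \deqn{(1-H_T)\,\partial_t [ATP] = -u(1-H_D)\,\partial_z [ATP]
#'   + H_T C_0 (1 - C_1 S) - (2/R)\, k_d [ATP]}
#' Release is a linear decreasing function of local saturation S (fully
#' saturated red cells release the least); degradation is a wall flux, so
#' its volumetric rate scales with 2/R.
#'
#' @param C0 red-cell ATP release coefficient, mol/(s cm^3) of red cells.
#' @param C1 dimensionless slope of the saturation dependence of release;
#'   the default keeps `1 - C1*S` positive for all physical S.
#' @param k_d endothelial ATP degradation rate constant (cm/s).
#' @param release_scale dimensionless multiplier on `C0` for scenarios
#'   (0.5 models the insulin-impaired release).
#' @return object of class `transport_params`.
#' @export
transport_params <- function(C0 = 1.4e-9, C1 = 0.891, k_d = 2.0e-4,
                             release_scale = 1) {
  stopifnot(C0 >= 0, C1 >= 0, k_d >= 0, release_scale >= 0)
  structure(list(C0 = C0, C1 = C1, k_d = k_d,
                 release_scale = release_scale),
            class = "transport_params")
}

#' Solve the plasma ATP transport equation to steady state
#'
#' Time-marches the segment-wise advection-reaction balance with a
#' first-order explicit upwind scheme from a zero initial concentration
#' until the field is stationary. Converging nodes mix concentrations
#' weighted by plasma volumetric flow (the conservative choice); inlet
#' nodes carry a fixed inflow concentration. The CFL-limited time step
#' guarantees positivity for non-negative inputs.
#'
#' Concentrations are handled internally in mol/cm^3 (matching the cgs
#' release and degradation parameters) and reported in uM
#' (1 uM = 1e-9 mol/cm^3).
#'
#' @param net a `capillary_network`.
#' @param saturation a `saturation_field` on the same network (from
#'   [compute_saturation()] or [prescribed_saturation()]).
#' @param params a [transport_params()] object.
#' @param atp_in inflow plasma ATP concentration (uM): a scalar applied to
#'   every inlet node, or a named vector keyed by inlet node id.
#' @param steady_tol stationarity tolerance: the march stops when the
#'   largest per-step concentration change falls below `steady_tol` times
#'   the current field maximum.
#' @param cfl Courant number (must be < 1; default 0.9).
#' @param max_time_s cap on simulated time before declaring
#'   non-convergence.
#' @return An object of class `atp_field`: per-grid-point `[ATP]` in uM
#'   (flow order), with the grid, network, saturation and parameters
#'   attached, plus `steady_time_s`, the simulated time marched.
#' @export
solve_atp_steady <- function(net, saturation, params = transport_params(),
                             atp_in = 0, steady_tol = 1e-6, cfl = 0.9,
                             max_time_s = 600) {
  stopifnot(inherits(net, "capillary_network"),
            inherits(saturation, "saturation_field"),
            inherits(params, "transport_params"))
  if (cfl <= 0 || cfl >= 1) stop("cfl must lie in (0, 1)", call. = FALSE)
  grid <- saturation$grid
  s <- net$segments
  n_seg <- nrow(s)

  # per-segment cgs quantities
  r_cm <- s$radius_um * 1e-4
  u_cm <- abs(s$velocity_mm_s) * 0.1
  dz_cm <- grid$dz_seg_um * 1e-4
  adv <- u_cm * (1 - s$h_d) / (1 - s$h_t)        # plasma advection speed
  lam_seg <- adv / dz_cm                          # 1/s per grid step
  deg_seg <- (2 * params$k_d / r_cm) / (1 - s$h_t)

  one_minus_c1s <- 1 - params$C1 * saturation$values
  if (any(one_minus_c1s < 0))
    warning("1 - C1*S is negative somewhere: the release term acts as a sink",
            call. = FALSE)
  src <- rep(s$h_t / (1 - s$h_t), grid$n_pts) *
    params$C0 * params$release_scale * one_minus_c1s   # mol/cm^3/s

  lam <- rep(lam_seg, grid$n_pts)
  deg <- rep(deg_seg, grid$n_pts)
  dt <- cfl / max(lam + deg)

  # node bookkeeping
  node_ids <- unique(c(s$node_from, s$node_to))
  up_node <- match(s$node_from, node_ids)
  qp <- plasma_flow(net)
  inc_seg <- seq_len(n_seg)                 # each segment feeds node_to
  inc_node <- match(s$node_to, node_ids)
  qp_sum <- as.vector(rowsum(qp, inc_node, reorder = FALSE))
  qp_sum_node <- rep(NA_real_, length(node_ids))
  qp_sum_node[unique(inc_node)] <- qp_sum

  atp_in_node <- rep(0, length(node_ids))
  if (length(atp_in) == 1) {
    atp_in_node[match(net$inlets, node_ids)] <- atp_in * 1e-9
  } else {
    if (!all(net$inlets %in% names(atp_in)))
      stop("atp_in must name every inlet node", call. = FALSE)
    atp_in_node[match(net$inlets, node_ids)] <- atp_in[net$inlets] * 1e-9
  }

  first <- grid$first
  rest <- setdiff(seq_len(grid$total), first)
  seg_first <- grid$seg_of[first]

  a <- numeric(grid$total)
  t_sim <- 0
  check_every <- 25L
  max_steps <- ceiling(max_time_s / dt)
  converged <- FALSE
  for (step in seq_len(max_steps)) {
    ends <- a[grid$last]
    mixed <- as.vector(rowsum(qp * ends, inc_node, reorder = FALSE))
    node_c <- atp_in_node
    node_c[unique(inc_node)] <- mixed / qp_sum
    a_new <- a
    a_new[first] <- node_c[up_node[seg_first]]
    a_new[rest] <- a[rest] +
      dt * (-lam[rest] * (a[rest] - a[rest - 1L]) +
              src[rest] - deg[rest] * a[rest])
    t_sim <- t_sim + dt
    if (step %% check_every == 0L || step == max_steps) {
      dmax <- max(abs(a_new - a))
      ref <- max(a_new, 1e-30)
      if (dmax <= steady_tol * ref) {
        a <- a_new
        converged <- TRUE
        break
      }
    }
    a <- a_new
  }
  if (!converged)
    stop(sprintf(
      "ATP solver did not reach steady state in %.3g simulated s (dt = %.3g s, max |dATP| = %.3g mol/cm^3)",
      t_sim, dt, max(abs(a_new - a))), call. = FALSE)
  if (min(src) >= 0 && min(atp_in_node) >= 0 && min(a) < 0)
    stop("internal error: upwind scheme produced a negative concentration",
         call. = FALSE)

  structure(list(values_uM = a * 1e9, grid = grid, network = net,
                 saturation = saturation, params = params,
                 atp_in_uM = atp_in, dz_um = saturation$dz_um,
                 steady_time_s = t_sim, dt_s = dt),
            class = "atp_field")
}

#' @export
print.atp_field <- function(x, ...) {
  cat(sprintf("Steady ATP field on %d grid points (%d segments)\n",
              x$grid$total, length(x$grid$n_pts)))
  cat(sprintf("  [ATP] range [%.4g, %.4g] uM, volume-weighted mean %.4g uM\n",
              min(x$values_uM), max(x$values_uM), mean_capillary_atp(x)))
  cat(sprintf("  marched %.3g simulated s at dt = %.3g s\n",
              x$steady_time_s, x$dt_s))
  invisible(x)
}

# trapezoidal volume weights per grid point (cm^3)
volume_weights <- function(field) {
  grid <- field$grid
  s <- field$network$segments
  w <- rep(grid$dz_seg_um * 1e-4 * pi * (s$radius_um * 1e-4)^2,
           grid$n_pts)
  w[grid$first] <- w[grid$first] / 2
  w[grid$last] <- w[grid$last] / 2
  w
}

#' Mean capillary ATP concentration
#'
#' @param field an `atp_field`.
#' @param weighting `"volume"` (default; grid points weighted by the vessel
#'   volume they represent) or `"grid-point"` (unweighted mean over grid
#'   points).
#' @return mean concentration in uM.
#' @export
mean_capillary_atp <- function(field, weighting = c("volume", "grid-point")) {
  stopifnot(inherits(field, "atp_field"))
  weighting <- match.arg(weighting)
  if (!length(field$values_uM)) stop("empty ATP field", call. = FALSE)
  if (weighting == "grid-point") return(mean(field$values_uM))
  w <- volume_weights(field)
  sum(w * field$values_uM) / sum(w)
}

#' Per-segment mean ATP concentrations
#' @param field an `atp_field`.
#' @return data frame with `id`, `z_mid_um`, `atp_uM` (within-segment
#'   volume-weighted mean), `atp_in_uM` and `atp_out_uM` (flow entrance and
#'   exit values).
#' @export
segment_mean_atp <- function(field) {
  stopifnot(inherits(field, "atp_field"))
  grid <- field$grid
  s <- field$network$segments
  w <- volume_weights(field)
  num <- rowsum(w * field$values_uM, grid$seg_of, reorder = FALSE)
  den <- rowsum(w, grid$seg_of, reorder = FALSE)
  data.frame(id = s$id, z_mid_um = s$z_mid_um,
             atp_uM = as.vector(num / den),
             atp_in_uM = field$values_uM[grid$first],
             atp_out_uM = field$values_uM[grid$last])
}

#' Steady-state ATP mass balance per segment and for the whole network
#'
#' At steady state each segment's plasma ATP outflow minus inflow must
#' equal its net interior production (release minus wall degradation),
#' and the network total must close as inflow + release = degradation +
#' outflow. Quadrature is taken consistently with the upwind scheme, so a
#' converged field closes to the solver tolerance.
#'
#' @param field an `atp_field`.
#' @return list with `segment` (data frame of per-segment relative
#'   residuals) and `network` (inflow, release, degradation, outflow in
#'   mol/s, and relative residual).
#' @export
atp_mass_balance <- function(field) {
  stopifnot(inherits(field, "atp_field"))
  grid <- field$grid
  net <- field$network
  s <- net$segments
  p <- field$params
  a <- field$values_uM * 1e-9
  qp <- plasma_flow(net)
  r_cm <- s$radius_um * 1e-4
  dz_cm <- grid$dz_seg_um * 1e-4
  area <- pi * r_cm^2

  # right-point rule matches the steady discrete upwind balance exactly
  rel_pt <- rep(s$h_t * area, grid$n_pts) * p$C0 * p$release_scale *
    (1 - p$C1 * field$saturation$values) * rep(dz_cm, grid$n_pts)
  deg_pt <- rep(2 * p$k_d / r_cm * area, grid$n_pts) * a *
    rep(dz_cm, grid$n_pts)
  rel_pt[grid$first] <- 0
  deg_pt[grid$first] <- 0
  release <- as.vector(rowsum(rel_pt, grid$seg_of, reorder = FALSE))
  degrade <- as.vector(rowsum(deg_pt, grid$seg_of, reorder = FALSE))

  conv <- qp * (a[grid$last] - a[grid$first])
  net_src <- release - degrade
  scale_seg <- pmax(abs(conv), release + degrade, 1e-30)
  seg_res <- abs(conv - net_src) / scale_seg

  inlet_edges <- which(s$node_from %in% net$inlets)
  outlet_edges <- which(s$node_to %in% net$outlets)
  inflow <- sum(qp[inlet_edges] * a[grid$first[inlet_edges]])
  outflow <- sum(qp[outlet_edges] * a[grid$last[outlet_edges]])
  tot_rel <- sum(release); tot_deg <- sum(degrade)
  net_res <- abs(inflow + tot_rel - tot_deg - outflow) /
    max(inflow + tot_rel, 1e-30)
  list(segment = data.frame(id = s$id, rel_residual = seg_res),
       network = list(inflow = inflow, release = tot_rel,
                      degradation = tot_deg, outflow = outflow,
                      rel_residual = net_res))
}

#' Closed-form steady profile for a single uniform capillary
#'
#' Independent analytic solution of the steady transport balance for one
#' segment with constant saturation and zero inflow concentration:
#' \deqn{[ATP](z) = \frac{R H_T C_0 (1 - C_1 S)}{2 k_d}
#'   \left(1 - e^{-2 k_d z / (R u (1-H_D))}\right)}
#' Used as the verification oracle for the numerical solver.
#'
#' @param z_um axial positions from the entrance (um).
#' @param radius_um,velocity_mm_s,h_t,h_d segment properties.
#' @param params a [transport_params()] object.
#' @param S constant saturation.
#' @return concentrations in uM at `z_um`.
#' @export
single_capillary_profile <- function(z_um, radius_um = 2.5,
                                     velocity_mm_s = 0.5, h_t = 0.2,
                                     h_d = 0.25,
                                     params = transport_params(),
                                     S = 0.63) {
  r_cm <- radius_um * 1e-4
  u_cm <- abs(velocity_mm_s) * 0.1
  z_cm <- z_um * 1e-4
  a_inf <- r_cm * h_t * params$C0 * params$release_scale *
    (1 - params$C1 * S) / (2 * params$k_d)
  1e9 * a_inf * (1 - exp(-2 * params$k_d * z_cm / (r_cm * u_cm * (1 - h_d))))
}

#' Export per-grid-point fields as a data frame
#' @param field an `atp_field`.
#' @return data frame with `segment_id`, `s_um` (distance along the
#'   segment in flow direction), `z_um` (arterio-venous position), `S` and
#'   `ATP_uM`.
#' @export
field_table <- function(field) {
  stopifnot(inherits(field, "atp_field"))
  grid <- field$grid
  s <- field$network$segments
  data.frame(segment_id = s$id[grid$seg_of],
             s_um = grid$s_um,
             z_um = grid_z_um(field$network, grid),
             S = field$saturation$values,
             ATP_uM = field$values_uM)
}
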