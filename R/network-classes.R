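#' Capillary network of cylindrical segments
#'
#' A directed graph of cylindrical capillary segments carrying blood from
#' inlet nodes to outlet nodes. By convention `node_from -> node_to` is the
#' flow direction of every segment; the sign of `velocity_mm_s` records the
#' segment's orientation along the arterio-venous (z) axis, negative for
#' counter-current segments whose flow runs toward decreasing z. Solvers use
#' the magnitude.
#'
#' @param segments data frame with one row per segment and columns `id`,
#'   `node_from`, `node_to`, `length_um`, `radius_um`, `velocity_mm_s`
#'   (nonzero, signed by axial orientation), `h_t` (tube hematocrit),
#'   `h_d` (discharge hematocrit), `z_mid_um` (axial position of the
#'   segment midpoint along the arterio-venous axis).
#' @param inlets,outlets character vectors of boundary node ids. Inlet
#'   nodes have no incoming segments, outlet nodes no outgoing segments.
#' @param L_um arterio-venous span of the network (um).
#' @param tissue_dims_um length-3 tissue bounding box (um).
#' @param nodes optional data frame of node coordinates (`id`, `x_um`,
#'   `y_um`, `z_um`); needed only for position-dependent prescribed
#'   saturation profiles.
#' @param validate run the full invariant suite (default `TRUE`).
#' @return An object of class `capillary_network`.
#' @seealso [generate_network()], [read_network()], [single_capillary_network()]
#' @export
capillary_network <- function(segments, inlets, outlets, L_um,
                              tissue_dims_um, nodes = NULL,
                              validate = TRUE) {
  req <- c("id", "node_from", "node_to", "length_um", "radius_um",
           "velocity_mm_s", "h_t", "h_d", "z_mid_um")
  missing_cols <- setdiff(req, names(segments))
  if (length(missing_cols))
    stop("segments is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  segments$id <- as.character(segments$id)
  segments$node_from <- as.character(segments$node_from)
  segments$node_to <- as.character(segments$node_to)
  net <- structure(list(segments = segments,
                        inlets = as.character(inlets),
                        outlets = as.character(outlets),
                        L_um = L_um,
                        tissue_dims_um = tissue_dims_um,
                        nodes = nodes),
                   class = "capillary_network")
  if (validate) validate_network(net)
  net
}

#' Validate the invariants of a capillary network
#'
#' Checks positive geometry, hematocrit bounds, nonzero velocities, graph
#' connectivity from inlets to outlets, acyclicity of the flow graph, and
#' conservation of plasma volumetric flow at every interior node.
#'
#' @param net a `capillary_network`.
#' @param flow_tol maximum relative plasma-flow residual allowed at an
#'   interior node.
#' @return `net`, invisibly; errors describe the first violated invariant.
#' @export
validate_network <- function(net, flow_tol = 1e-6) {
  s <- net$segments
  if (anyDuplicated(s$id))
    stop("duplicate segment ids", call. = FALSE)
  if (any(s$length_um <= 0) || any(s$radius_um <= 0))
    stop("segment lengths and radii must be positive", call. = FALSE)
  if (any(s$velocity_mm_s == 0))
    stop("segment velocities must be nonzero", call. = FALSE)
  if (any(s$h_t < 0 | s$h_t >= 1) || any(s$h_d < 0 | s$h_d >= 1))
    stop("hematocrits must lie in [0, 1)", call. = FALSE)
  node_ids <- unique(c(s$node_from, s$node_to))
  if (!all(net$inlets %in% node_ids) || !all(net$outlets %in% node_ids))
    stop("inlet/outlet ids not present among segment endpoints",
         call. = FALSE)
  n_in <- table(factor(s$node_to, levels = node_ids))
  n_out <- table(factor(s$node_from, levels = node_ids))
  interior <- setdiff(node_ids, c(net$inlets, net$outlets))
  bad <- interior[n_in[interior] < 1 | n_out[interior] < 1]
  if (length(bad))
    stop("interior node(s) without both inflow and outflow: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(n_in[net$inlets] > 0))
    stop("inlet node(s) have incoming segments", call. = FALSE)
  if (any(n_out[net$outlets] > 0))
    stop("outlet node(s) have outgoing segments", call. = FALSE)

  # acyclicity + reachability (flow graph must be a DAG spanning the nodes)
  if (is.null(topological_nodes(net)))
    stop("flow graph contains a cycle", call. = FALSE)
  reach_fwd <- reach_from(net, net$inlets, forward = TRUE)
  reach_bwd <- reach_from(net, net$outlets, forward = FALSE)
  stranded <- setdiff(node_ids, intersect(reach_fwd, reach_bwd))
  if (length(stranded))
    stop("node(s) not on an inlet-to-outlet path: ",
         paste(stranded, collapse = ", "), call. = FALSE)

  # plasma volumetric flow conservation at interior nodes
  qp <- plasma_flow(net)  # cm^3/s per segment
  for (nd in interior) {
    qin <- sum(qp[s$node_to == nd])
    qout <- sum(qp[s$node_from == nd])
    if (abs(qin - qout) > flow_tol * max(qin, qout))
      stop(sprintf(
        "plasma flow not conserved at node %s (in %.6g, out %.6g cm^3/s)",
        nd, qin, qout), call. = FALSE)
  }
  invisible(net)
}

# plasma volumetric flow per segment, cm^3/s
plasma_flow <- function(net) {
  s <- net$segments
  pi * (s$radius_um * 1e-4)^2 * abs(s$velocity_mm_s) * 0.1 * (1 - s$h_d)
}

# RBC volumetric flow per segment, cm^3/s
rbc_flow <- function(net) {
  s <- net$segments
  pi * (s$radius_um * 1e-4)^2 * abs(s$velocity_mm_s) * 0.1 * s$h_d
}

# Kahn topological sort of the node set; NULL if the flow graph has a cycle
topological_nodes <- function(net) {
  s <- net$segments
  node_ids <- unique(c(s$node_from, s$node_to))
  indeg <- table(factor(s$node_to, levels = node_ids))
  order <- character(0)
  avail <- node_ids[indeg == 0]
  indeg <- as.vector(indeg); names(indeg) <- node_ids
  remaining <- rep(TRUE, nrow(s))
  while (length(avail)) {
    nd <- avail[1]; avail <- avail[-1]
    order <- c(order, nd)
    out <- which(remaining & s$node_from == nd)
    for (e in out) {
      remaining[e] <- FALSE
      tgt <- s$node_to[e]
      indeg[tgt] <- indeg[tgt] - 1
      if (indeg[tgt] == 0) avail <- c(avail, tgt)
    }
  }
  if (length(order) != length(node_ids)) NULL else order
}

reach_from <- function(net, start, forward = TRUE) {
  s <- net$segments
  from <- if (forward) s$node_from else s$node_to
  to <- if (forward) s$node_to else s$node_from
  seen <- unique(start)
  frontier <- seen
  while (length(frontier)) {
    nxt <- unique(to[from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' @export
print.capillary_network <- function(x, ...) {
  s <- x$segments
  cat(sprintf("Capillary network: %d segments, %d nodes (%d inlets, %d outlets)\n",
              nrow(s), length(unique(c(s$node_from, s$node_to))),
              length(x$inlets), length(x$outlets)))
  cat(sprintf("  tissue domain %s um, arterio-venous span %g um\n",
              paste(x$tissue_dims_um, collapse = " x "), x$L_um))
  cat(sprintf("  |velocity| %.3g +/- %.3g mm/s, H_D %.3g +/- %.3g, radius %.3g +/- %.3g um\n",
              mean(abs(s$velocity_mm_s)), stats::sd(abs(s$velocity_mm_s)),
              mean(s$h_d), stats::sd(s$h_d),
              mean(s$radius_um), stats::sd(s$radius_um)))
  n_cc <- sum(s$velocity_mm_s < 0)
  if (n_cc) cat(sprintf("  %d counter-current segment(s)\n", n_cc))
  invisible(x)
}

#' Read and write the plain-text network exchange format
#'
#' A network is stored as two files sharing a stem: `<stem>_segments.csv`
#' (one row per segment with the columns of [capillary_network()]) and
#' `<stem>_network.json` (inlets, outlets, arterio-venous span, tissue
#' dimensions, and optionally node coordinates). The reader re-validates
#' all network invariants.
#'
#' @param stem file path stem (no extension).
#' @return `read_network()` returns a `capillary_network`;
#'   `write_network()` returns `stem` invisibly.
#' @export
read_network <- function(stem) {
  seg_path <- paste0(stem, "_segments.csv")
  hdr_path <- paste0(stem, "_network.json")
  if (!file.exists(seg_path) || !file.exists(hdr_path))
    stop("expected files ", seg_path, " and ", hdr_path, call. = FALSE)
  segments <- utils::read.csv(seg_path, stringsAsFactors = FALSE,
                              colClasses = c(id = "character",
                                             node_from = "character",
                                             node_to = "character"))
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  nodes <- if (!is.null(hdr$nodes)) as.data.frame(hdr$nodes) else NULL
  capillary_network(segments, inlets = hdr$inlets, outlets = hdr$outlets,
                    L_um = hdr$L_um, tissue_dims_um = hdr$tissue_dims_um,
                    nodes = nodes)
}

#' @rdname read_network
#' @param net a `capillary_network`.
#' @export
write_network <- function(net, stem) {
  stopifnot(inherits(net, "capillary_network"))
  utils::write.csv(net$segments, paste0(stem, "_segments.csv"),
                   row.names = FALSE, quote = FALSE)
  hdr <- list(inlets = net$inlets, outlets = net$outlets,
              L_um = net$L_um, tissue_dims_um = net$tissue_dims_um)
  if (!is.null(net$nodes)) hdr$nodes <- net$nodes
  jsonlite::write_json(hdr, paste0(stem, "_network.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(stem)
}

# Axial discretization shared by the saturation and ATP solvers.
# Points are stored segment-by-segment in FLOW order; the first point of a
# segment coincides with its flow-upstream node.
build_grid <- function(net, dz_um = 2) {
  if (dz_um <= 0) stop("dz_um must be positive", call. = FALSE)
  s <- net$segments
  n_pts <- pmax(2L, as.integer(ceiling(s$length_um / dz_um)) + 1L)
  dz_seg <- s$length_um / (n_pts - 1L)
  first <- cumsum(c(1L, n_pts[-length(n_pts)]))
  last <- first + n_pts - 1L
  seg_of <- rep(seq_len(nrow(s)), n_pts)
  s_um <- unlist(lapply(seq_len(nrow(s)),
                        function(i) seq(0, s$length_um[i],
                                        length.out = n_pts[i])))
  list(n_pts = n_pts, dz_seg_um = dz_seg, first = first, last = last,
       seg_of = seg_of, s_um = s_um, total = sum(n_pts))
}

# axial (arterio-venous) z of every grid point, um; uses node coordinates
# when available, otherwise the segment midpoint for all its points
grid_z_um <- function(net, grid) {
  s <- net$segments
  if (!is.null(net$nodes)) {
    zn <- stats::setNames(net$nodes$z_um, as.character(net$nodes$id))
    z_from <- unname(zn[s$node_from]); z_to <- unname(zn[s$node_to])
    frac <- grid$s_um / rep(s$length_um, grid$n_pts)
    rep(z_from, grid$n_pts) * (1 - frac) + rep(z_to, grid$n_pts) * frac
  } else {
    rep(s$z_mid_um, grid$n_pts)
  }
}
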