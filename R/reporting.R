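#' Reproduce a standard figure's numbers (and optionally the plot)
#'
#' Emits the CSV table underlying each of the four standard result
#' figures, plus a PNG plot as a convenience. Tables, not plots, are the
#' testable surface.
#'
#' \describe{
#'   \item{`"dynamics"`}{pathway time courses for the 40 ms pulse to
#'     15.7% sO2 (trajectory CSV with peak annotations).}
#'   \item{`"dose-response"`}{calibrated total release vs sO2 for baseline
#'     and insulin (PDE3_rel = 1.87) PDE3 activity.}
#'   \item{`"insulin-bars"`}{release and integrated cAMP at 15.7% sO2 vs
#'     PDE3 activity (1, 1.8, 4.1).}
#'   \item{`"network"`}{steady sO2 and [ATP] vs axial position on a
#'     network, for inlet ATP 0 and 0.25 uM, normal and impaired
#'     release.}
#' }
#'
#' @param tag one of `"dynamics"`, `"dose-response"`, `"insulin-bars"`,
#'   `"network"` (aliases `"fig3"` to `"fig6"` are accepted).
#' @param out_dir output directory (created if needed).
#' @param params a [pathway_params()] object.
#' @param network a `capillary_network` for `"network"`; defaults to the
#'   208-segment synthetic fixture.
#' @param sO2_grid saturation grid for the dose-response.
#' @param dz_um grid spacing for the network solve.
#' @param plot also write a PNG.
#' @return invisibly, a named list of the file paths written.
#' @export
reproduce_figure <- function(tag, out_dir = ".",
                             params = pathway_params(),
                             network = NULL,
                             sO2_grid = c(0.157, 0.216, 0.3, 0.413, 0.5,
                                          0.618, 0.75, 0.9, 1.0),
                             dz_um = 2, plot = TRUE) {
  tag <- switch(tag,
                fig3 = "dynamics", fig4 = "dose-response",
                fig5 = "insulin-bars", fig6 = "network", tag)
  tag <- match.arg(tag, c("dynamics", "dose-response", "insulin-bars",
                          "network"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  csv <- function(name) file.path(out_dir, paste0(name, ".csv"))
  png_path <- function(name) file.path(out_dir, paste0(name, ".png"))

  if (tag == "dynamics") {
    traj <- simulate_pathway(params, desaturation_pulse(0.157))
    utils::write.csv(as.data.frame(traj), csv("pathway_dynamics"),
                     row.names = FALSE)
    pk <- attr(traj, "peaks")
    utils::write.csv(
      data.frame(quantity = c("cAMP", "F_ATP"),
                 peak_time_ms = 1000 * c(pk$cAMP$time_s, pk$F_ATP$time_s),
                 peak_value = c(pk$cAMP$value, pk$F_ATP$value)),
      csv("pathway_peaks"), row.names = FALSE)
    paths <- list(table = csv("pathway_dynamics"),
                  peaks = csv("pathway_peaks"))
    if (plot) {
      grDevices::png(png_path("pathway_dynamics"), 900, 600)
      plot(traj, main = "Pathway response to a 40 ms pulse to 15.7% sO2")
      grDevices::dev.off()
      paths$plot <- png_path("pathway_dynamics")
    }
  } else if (tag == "dose-response") {
    cal <- calibrate_release(params)
    base <- dose_response(params, sO2_grid, calibration = cal)
    ins_params <- params; ins_params$pde3_rel <- 1.87
    ins <- dose_response(ins_params, sO2_grid, calibration = cal)
    tab <- rbind(cbind(condition = "baseline", base),
                 cbind(condition = "insulin_pde3_1.87", ins))
    utils::write.csv(tab, csv("dose_response"), row.names = FALSE)
    paths <- list(table = csv("dose_response"))
    if (plot) {
      grDevices::png(png_path("dose_response"), 800, 600)
      graphics::plot(base$sO2 * 100, base$release, type = "b", pch = 19,
                     col = "black", xlab = "sO2 (%)",
                     ylab = "total ATP release (nmol / 4e8 RBC)",
                     main = "Total ATP release vs hemoglobin saturation")
      graphics::lines(ins$sO2 * 100, ins$release, type = "b", pch = 17,
                      col = "red3")
      graphics::legend("topright", c("PDE3_rel = 1", "PDE3_rel = 1.87"),
                       col = c("black", "red3"), pch = c(19, 17), bty = "n")
      grDevices::dev.off()
      paths$plot <- png_path("dose_response")
    }
  } else if (tag == "insulin-bars") {
    tab <- insulin_scenario(params, c(1, 1.8, 4.1))
    utils::write.csv(tab, csv("insulin_bars"), row.names = FALSE)
    paths <- list(table = csv("insulin_bars"))
    if (plot) {
      grDevices::png(png_path("insulin_bars"), 800, 600)
      graphics::barplot(rbind(tab$release,
                              tab$camp_integral / max(tab$camp_integral) *
                                max(tab$release)),
                        beside = TRUE, names.arg = tab$pde3_rel,
                        col = c("cyan3", "purple"),
                        xlab = "relative PDE3 activity",
                        ylab = "release (nmol/4e8 RBC) / scaled cAMP integral",
                        main = "ATP release and cAMP exposure vs PDE3 activity")
      graphics::legend("topright", c("ATP release", "cAMP (scaled)"),
                       fill = c("cyan3", "purple"), bty = "n")
      grDevices::dev.off()
      paths$plot <- png_path("insulin_bars")
    }
  } else {
    if (is.null(network)) network <- generate_network(network_spec())
    sat <- compute_saturation(network, dz_um = dz_um)
    tabs <- list()
    for (ain in c(0, 0.25)) for (scl in c(1, 0.5)) {
      f <- solve_atp_steady(network, sat,
                            transport_params(release_scale = scl),
                            atp_in = ain)
      tabs[[length(tabs) + 1]] <-
        cbind(atp_in_uM = ain, release_scale = scl, field_table(f))
    }
    tab <- do.call(rbind, tabs)
    utils::write.csv(tab, csv("network_fields"), row.names = FALSE)
    paths <- list(table = csv("network_fields"))
    if (plot) {
      grDevices::png(png_path("network_fields"), 1000, 500)
      graphics::par(mfrow = c(1, 2))
      one <- tab[tab$atp_in_uM == 0 & tab$release_scale == 1, ]
      graphics::plot(one$z_um, one$S, pch = ".", col = "red3",
                     xlab = "z (um)", ylab = "sO2",
                     main = "Saturation vs axial position")
      graphics::plot(one$z_um, one$ATP_uM, pch = ".", col = "blue3",
                     xlab = "z (um)", ylab = "[ATP] (uM)",
                     main = "Steady [ATP] vs axial position")
      grDevices::dev.off()
      paths$plot <- png_path("network_fields")
    }
  }
  invisible(paths)
}

#' Run the standard perturbation scenarios and summarize as JSON
#'
#' Computes the package's headline scenario numbers: the percent decrease
#' in ATP release for a 40% Gi-protein deficit, the PDE3 activity that
#' rescues it, and the network-level consequences of insulin-halved
#' release for inlet ATP 0 and 0.25 uM.
#'
#' @param params a [pathway_params()] object.
#' @param network a `capillary_network`; defaults to the 208-segment
#'   synthetic fixture.
#' @param gp_fraction remaining Gi pool fraction for the deficit scenario.
#' @param out optional path to write the summary as JSON.
#' @param dz_um network grid spacing (um).
#' @return a named list of scenario results (also written to `out` when
#'   given).
#' @export
run_scenarios <- function(params = pathway_params(), network = NULL,
                          gp_fraction = 0.6, out = NULL, dz_um = 2) {
  if (is.null(network)) network <- generate_network(network_spec())
  sat <- compute_saturation(network, dz_um = dz_um)
  net_tab <- insulin_network_scenario(network, sat)
  res <- list(
    gi_deficit_pct = gi_deficit_scenario(params, gp_fraction),
    pde3_recovery = find_pde3_recovery(params, gp_fraction),
    network = net_tab)
  if (!is.null(out)) {
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  res
}
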