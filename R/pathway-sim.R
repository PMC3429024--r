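#' Right-hand side of the ATP release pathway ODE system
#'
#' Time derivatives of the four dynamic species: active G-protein (GPa),
#' cAMP, active PKA (PKAa) and active CFTR (CFTRa). Inactive forms follow
#' from pool conservation (GPi = GP_total - GPa, etc.). The driving input is
#' the desaturated hemoglobin fraction tHb = 1 - sO2.
#'
#' The kinetics are:
#' \deqn{dGPa/dt = k_{GPf} GPi \cdot tHb^{\alpha} - k_{GPr} GPa}
#' \deqn{dcAMP/dt = AC_{base} + k_{cAMPf} GPa / (1 + k_{cAMPi} PKAa)
#'   - v_0 PDE3_{rel} \, PKAa \cdot cAMP / (K_{PDE3} + cAMP)}
#' \deqn{dPKAa/dt = k_{PKAf} PKAi \cdot cAMP - k_{PKAr} PKAa}
#' \deqn{dCFTRa/dt = k_{CFTRf} CFTRi \cdot PKAa^{\beta} - k_{CFTRr} CFTRa}
#'
#' Active PKA feeds back on cAMP twice: it inhibits production (the
#' denominator of the synthesis term) and enhances PDE3-mediated
#' degradation (the Michaelis-Menten term).
#'
#' @param state named numeric vector with elements `gpa`, `camp`, `pkaa`,
#'   `cftra`, each within its pool bounds.
#' @param params a [pathway_params()] object.
#' @param thb desaturated hemoglobin fraction in `[0, 1]`.
#' @return named numeric vector of derivatives (1/s), names as `state`.
#' @examples
#' s <- c(gpa = 0, camp = 0, pkaa = 0, cftra = 0)
#' pathway_rhs(s, pathway_params(), thb = 0.843)
#' @export
pathway_rhs <- function(state, params, thb) {
  if (!is.numeric(thb) || length(thb) != 1 || is.na(thb) ||
      thb < 0 || thb > 1)
    stop("thb must be a single value in [0, 1]", call. = FALSE)
  gpa <- state[["gpa"]]; camp <- state[["camp"]]
  pkaa <- state[["pkaa"]]; cftra <- state[["cftra"]]
  if (min(gpa, camp, pkaa, cftra) < 0)
    stop("state components must be non-negative", call. = FALSE)
  p <- params
  gpi <- p$gp_total - gpa
  pkai <- p$pka_total - pkaa
  cftri <- p$cftr_total - cftra
  c(gpa = p$k_gp_f * gpi * thb^p$alpha - p$k_gp_r * gpa,
    camp = p$ac_base + p$k_camp_f * gpa / (1 + p$k_camp_i * pkaa) -
      p$v0 * p$pde3_rel * pkaa * camp / (p$K_pde3 + camp),
    pkaa = p$k_pka_f * pkai * camp - p$k_pka_r * pkaa,
    cftra = p$k_cftr_f * cftri * pkaa^p$beta - p$k_cftr_r * cftra)
}

# deSolve-facing wrapper (unchecked, called at every integrator step)
pathway_deriv <- function(t, y, parms) {
  p <- parms$p
  thb <- parms$thb
  camp <- max(y[2], 0)
  pkaa <- max(y[3], 0)
  list(c(p$k_gp_f * (p$gp_total - y[1]) * thb^p$alpha - p$k_gp_r * y[1],
         p$ac_base + p$k_camp_f * y[1] / (1 + p$k_camp_i * pkaa) -
           p$v0 * p$pde3_rel * pkaa * camp / (p$K_pde3 + camp),
         p$k_pka_f * (p$pka_total - y[3]) * camp - p$k_pka_r * y[3],
         p$k_cftr_f * (p$cftr_total - y[4]) * pkaa^p$beta -
           p$k_cftr_r * y[4]))
}

#' Simulate the ATP release pathway under a saturation protocol
#'
#' Integrates the four-variable pathway model from the all-zero initial
#' condition (fully saturated resting erythrocyte) with a stiff-capable
#' solver. Integration restarts at every protocol discontinuity so that
#' instantaneous saturation steps are not smoothed. The ATP release flux is
#' `F_ATP(t) = k_atp_flux * CFTRa(t)`; its time integral over the protocol
#' span is the total (relative) ATP release.
#'
#' @param params a [pathway_params()] object.
#' @param protocol a [stimulus_protocol()] (or a single saturation fraction,
#'   interpreted as a 40 ms desaturation pulse followed by resaturation).
#' @param t_end end of the simulation (s); defaults to the protocol end.
#' @param dt_out dense-output spacing (s); 0.5 ms resolves the peaks.
#' @param rtol,atol integrator tolerances passed to [deSolve::lsoda()].
#' @return An object of class `pathway_trajectory`: a data frame with
#'   columns `time_s`, `GPa`, `cAMP`, `PKAa`, `CFTRa`, `F_ATP`, with
#'   attributes `params`, `protocol`, `total_release` (area under F_ATP)
#'   and `peaks` (quadratically refined peak times and values for cAMP and
#'   F_ATP).
#' @examples
#' traj <- simulate_pathway(pathway_params(), desaturation_pulse(0.157))
#' attr(traj, "peaks")
#' @export
simulate_pathway <- function(params, protocol, t_end = NULL,
                             dt_out = 5e-4, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "pathway_params"))
  if (is.numeric(protocol) && length(protocol) == 1)
    protocol <- desaturation_pulse(protocol)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (is.null(t_end)) t_end <- max(protocol$t_end)
  if (t_end < max(protocol$t_end))
    stop("t_end must reach the end of the protocol", call. = FALSE)

  y <- c(GPa = 0, cAMP = 0, PKAa = 0, CFTRa = 0)
  pieces <- list()
  for (i in seq_len(nrow(protocol))) {
    t0 <- protocol$t_start[i]
    t1 <- if (i == nrow(protocol)) t_end else protocol$t_end[i]
    times <- unique(c(seq(t0, t1, by = dt_out), t1))
    sol <- deSolve::lsoda(y, times, pathway_deriv,
                          parms = list(p = params,
                                       thb = 1 - protocol$sO2[i]),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed on protocol interval ", i,
           " (lsoda istate = ", attr(sol, "istate")[1], ")", call. = FALSE)
    sol <- as.data.frame(sol)
    names(sol) <- c("time_s", "GPa", "cAMP", "PKAa", "CFTRa")
    y <- c(GPa = sol$GPa[nrow(sol)], cAMP = sol$cAMP[nrow(sol)],
           PKAa = sol$PKAa[nrow(sol)], CFTRa = sol$CFTRa[nrow(sol)])
    pieces[[i]] <- if (i > 1) sol[-1, , drop = FALSE] else sol
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$F_ATP <- params$k_atp_flux * out$CFTRa

  traj <- structure(out,
                    class = c("pathway_trajectory", "data.frame"),
                    params = params, protocol = protocol)
  attr(traj, "peaks") <- list(cAMP = refine_peak(out$time_s, out$cAMP),
                              F_ATP = refine_peak(out$time_s, out$F_ATP))
  attr(traj, "total_release") <- trapz(out$time_s, out$F_ATP)
  traj
}

# quadratic refinement of the discrete argmax (times in s)
refine_peak <- function(t, y) {
  i <- which.max(y)
  if (i == 1 || i == length(y) || max(y) <= 0)
    return(list(time_s = t[i], value = y[i]))
  t3 <- t[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
  # vertex of the parabola through the three bracketing points
  d1 <- (y3[2] - y3[1]) / (t3[2] - t3[1])
  d2 <- (y3[3] - y3[2]) / (t3[3] - t3[2])
  a <- (d2 - d1) / (t3[3] - t3[1])
  if (a >= 0) return(list(time_s = t3[2], value = y3[2]))
  tv <- (t3[1] + t3[2]) / 2 - d1 / (2 * a)
  yv <- y3[2] + a * (tv - t3[2])^2 +
    (d1 + a * (t3[2] - t3[1])) * (tv - t3[2])
  list(time_s = tv, value = yv)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' @export
print.pathway_trajectory <- function(x, ...) {
  pk <- attr(x, "peaks")
  cat(sprintf("Pathway trajectory: %d points over [%g, %g] s\n",
              nrow(x), min(x$time_s), max(x$time_s)))
  cat(sprintf("  cAMP peak  %.4g at %.1f ms\n",
              pk$cAMP$value, 1000 * pk$cAMP$time_s))
  cat(sprintf("  F_ATP peak %.4g at %.1f ms\n",
              pk$F_ATP$value, 1000 * pk$F_ATP$time_s))
  cat(sprintf("  total release (area under F_ATP): %.5g model units\n",
              attr(x, "total_release")))
  invisible(x)
}

#' @export
plot.pathway_trajectory <- function(x, ...) {
  graphics::matplot(x$time_s, cbind(x$GPa, x$cAMP, x$PKAa, x$F_ATP),
                    type = "l", lty = 1, lwd = 2,
                    col = c("grey40", "purple", "darkgreen", "cyan3"),
                    xlab = "time (s)", ylab = "activation / flux", ...)
  graphics::legend("topright", c("GPa", "cAMP", "PKAa", "F_ATP"),
                   col = c("grey40", "purple", "darkgreen", "cyan3"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Total ATP release: area under the release-flux curve
#'
#' Integrates `F_ATP(t)` over a window. The default window runs from 0
#' until the flux has decayed below 1e-6 of its peak after the stimulus (or
#' the trajectory end, whichever comes first), i.e. until release has
#' effectively stopped.
#'
#' @param traj a `pathway_trajectory`.
#' @param window length-2 numeric `[t0, t1]` in seconds, or `NULL` for the
#'   default decay-bounded window.
#' @return scalar total release in model units.
#' @export
total_release <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "pathway_trajectory"))
  t <- traj$time_s; f <- traj$F_ATP
  if (is.null(window)) {
    pk <- which.max(f)
    below <- which(t > t[pk] & f < 1e-6 * max(f))
    t1 <- if (length(below)) t[below[1]] else max(t)
    window <- c(min(t), t1)
  }
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be an increasing pair [t0, t1]", call. = FALSE)
  if (window[1] < min(t) - 1e-12 || window[2] > max(t) + 1e-12)
    stop("window must lie within the trajectory span", call. = FALSE)
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 2) stop("window contains no trajectory points", call. = FALSE)
  trapz(t[keep], f[keep])
}

#' Time for the ATP flux to return to (near) zero after the stimulus
#'
#' @param traj a `pathway_trajectory` for a pulse protocol.
#' @param frac decay threshold as a fraction of the flux peak (default 1%).
#' @return time in seconds measured from the end of the stimulus at which
#'   `F_ATP` first falls below `frac` times its peak value.
#' @export
flux_decay_time <- function(traj, frac = 0.01) {
  stopifnot(inherits(traj, "pathway_trajectory"))
  protocol <- attr(traj, "protocol")
  stim <- protocol$sO2 < max(protocol$sO2)
  if (!any(stim))
    stop("protocol contains no desaturation stimulus", call. = FALSE)
  stim_end <- max(protocol$t_end[stim])
  t <- traj$time_s; f <- traj$F_ATP
  pk <- which.max(f)
  if (f[pk] <= 0) return(0)
  below <- which(t > max(t[pk], stim_end) & f < frac * f[pk])
  if (!length(below))
    stop("flux did not decay below ", frac, " of its peak within the ",
         "trajectory span", call. = FALSE)
  t[below[1]] - stim_end
}

#' Calibrate model release units against an experimental anchor
#'
#' The pathway model computes relative release for an average pathway; to
#' compare with measured ATP release it is normalized so that a reference
#' desaturation pulse reproduces the experimentally measured release. The
#' default anchor is 11.8 nmol ATP per 4e8 erythrocytes for a 40 ms pulse
#' to 15.7% sO2.
#'
#' @param params a [pathway_params()] object (the calibration is performed
#'   with `pde3_rel = 1` regardless of the scenario value, so that
#'   perturbation scenarios share the baseline scale).
#' @param anchor_sO2 saturation of the anchor pulse (fraction).
#' @param anchor_experimental measured release at the anchor
#'   (nmol ATP / 4e8 erythrocytes).
#' @param pulse_duration_s pulse length (s).
#' @param ... passed to [simulate_pathway()].
#' @return An object of class `release_calibration` with elements
#'   `anchor_sO2`, `anchor_release_experimental`, `anchor_release_model`
#'   and `scale` (experimental / model units).
#' @examples
#' cal <- calibrate_release(pathway_params())
#' cal$scale
#' @export
calibrate_release <- function(params, anchor_sO2 = 0.157,
                              anchor_experimental = 11.8,
                              pulse_duration_s = 0.040, ...) {
  base <- params
  base$pde3_rel <- 1
  traj <- simulate_pathway(base,
                           desaturation_pulse(anchor_sO2,
                                              pulse_duration_s), ...)
  model <- total_release(traj)
  if (model <= 0)
    stop("calibration anchor produced zero model release; cannot ",
         "normalize", call. = FALSE)
  structure(list(anchor_sO2 = anchor_sO2,
                 anchor_release_experimental = anchor_experimental,
                 anchor_release_model = model,
                 scale = anchor_experimental / model),
            class = "release_calibration")
}

#' @export
print.release_calibration <- function(x, ...) {
  cat(sprintf(
    "Release calibration: %.3g model units at %.1f%% sO2 -> %.3g nmol/4e8 RBC (scale %.4g)\n",
    x$anchor_release_model, 100 * x$anchor_sO2,
    x$anchor_release_experimental, x$scale))
  invisible(x)
}
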