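#' Dose-response of total ATP release vs hemoglobin saturation
#'
#' Runs a fixed-duration desaturation pulse at each saturation value and
#' reports total release, calibrated to the experimental anchor. For fixed
#' parameters the release is non-increasing in sO2: less desaturation,
#' less Gi activation, less ATP.
#'
#' @param params a [pathway_params()] object (set `pde3_rel = 1.87` for the
#'   insulin condition).
#' @param sO2 vector of saturations in `[0, 1]`.
#' @param pulse_duration_s pulse length (s), default 40 ms.
#' @param calibration a [calibrate_release()] object, or `NULL` to
#'   calibrate from `params` at the default anchor.
#' @param ... passed to [simulate_pathway()].
#' @return data frame with columns `sO2`, `release_model` (model units) and
#'   `release` (nmol ATP / 4e8 erythrocytes).
#' @examples
#' \donttest{
#' dose_response(pathway_params(), c(0.216, 0.413, 0.618))
#' }
#' @export
dose_response <- function(params, sO2, pulse_duration_s = 0.040,
                          calibration = NULL, ...) {
  stopifnot(all(sO2 >= 0 & sO2 <= 1))
  if (is.null(calibration))
    calibration <- calibrate_release(params,
                                     pulse_duration_s = pulse_duration_s, ...)
  rel <- vapply(sO2, function(s) {
    total_release(simulate_pathway(params,
                                   desaturation_pulse(s, pulse_duration_s),
                                   ...))
  }, 0)
  data.frame(sO2 = sO2, release_model = rel,
             release = rel * calibration$scale)
}

#' Reduced Gi expression scenario
#'
#' In type 2 diabetes, erythrocyte membrane Gi expression is reduced by
#' roughly 40%. This scenario scales the conserved G-protein pool and
#' reports the resulting percent decrease in total ATP release for a
#' desaturation pulse, relative to the full-pool baseline.
#'
#' @param params a [pathway_params()] object.
#' @param gp_fraction remaining fraction of the G-protein pool in `[0, 1]`
#'   (0.6 models the diabetic deficit).
#' @param sO2 pulse saturation (default 15.7%).
#' @param pulse_duration_s pulse length (s).
#' @param ... passed to [simulate_pathway()].
#' @return percent decrease in total release,
#'   `100 * (1 - release(gp_fraction) / release(1))`.
#' @examples
#' \donttest{
#' gi_deficit_scenario(pathway_params(), 0.6)  # ~59-60%
#' }
#' @export
gi_deficit_scenario <- function(params, gp_fraction, sO2 = 0.157,
                                pulse_duration_s = 0.040, ...) {
  stopifnot(gp_fraction >= 0, gp_fraction <= 1)
  run <- function(frac) {
    p <- params
    p$gp_total <- params$gp_total * frac
    total_release(simulate_pathway(p,
                                   desaturation_pulse(sO2, pulse_duration_s),
                                   ...))
  }
  base <- run(1)
  if (base <= 0) stop("baseline release is zero", call. = FALSE)
  100 * (1 - run(gp_fraction) / base)
}

#' PDE3 activity required to rescue release after a Gi deficit
#'
#' Cilostazol-like PDE3 inhibition lowers cAMP hydrolysis and can restore
#' ATP release lost to reduced Gi expression. This finds, by root search,
#' the relative PDE3 activity at which a Gi-deficient model matches the
#' healthy baseline release (full pool, `pde3_rel = 1`) for the reference
#' pulse.
#'
#' @param params a [pathway_params()] object.
#' @param gp_fraction remaining G-protein pool fraction (must be > 0: with
#'   no Gi at all, no amount of PDE3 inhibition can restore release).
#' @param bracket search interval for `pde3_rel`.
#' @param tol relative tolerance on the matched release.
#' @param sO2,pulse_duration_s reference pulse (15.7% sO2 / 40 ms).
#' @param ... passed to [simulate_pathway()].
#' @return the rescuing `pde3_rel` value.
#' @examples
#' \donttest{
#' find_pde3_recovery(pathway_params(), 0.6)  # ~0.6
#' }
#' @export
find_pde3_recovery <- function(params, gp_fraction,
                               bracket = c(0.05, 1.0), tol = 5e-3,
                               sO2 = 0.157, pulse_duration_s = 0.040, ...) {
  stopifnot(gp_fraction >= 0, gp_fraction <= 1)
  protocol <- desaturation_pulse(sO2, pulse_duration_s)
  run <- function(frac, pde3) {
    p <- params
    p$gp_total <- params$gp_total * frac
    p$pde3_rel <- pde3
    total_release(simulate_pathway(p, protocol, ...))
  }
  target <- run(1, 1)
  if (gp_fraction == 0 || run(gp_fraction, bracket[1]) <= 0)
    stop("unrecoverable: release is zero for this G-protein deficit",
         call. = FALSE)
  f <- function(pde3) run(gp_fraction, pde3) / target - 1
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (flo * fhi > 0)
    stop("bracket [", bracket[1], ", ", bracket[2],
         "] does not straddle the baseline release", call. = FALSE)
  stats::uniroot(f, bracket, f.lower = flo, f.upper = fhi,
                 tol = tol * max(bracket))$root
}

#' Insulin scenario: release and cAMP production vs PDE3 activity
#'
#' Insulin at pre-diabetic plasma concentrations enhances erythrocyte PDE3
#' activity, accelerating cAMP hydrolysis and so reducing low-O2-induced
#' ATP release. This runs the reference desaturation pulse over a grid of
#' relative PDE3 activities and reports calibrated total ATP release and
#' integrated cAMP exposure (area under the cAMP curve).
#'
#' @param params a [pathway_params()] object.
#' @param pde3_rel relative PDE3 activities (> 0); 1 is baseline, 1.8-4.1
#'   span reported insulin effects.
#' @param sO2 pulse saturation (default 15.7%).
#' @param pulse_duration_s pulse length (s).
#' @param ... passed to [simulate_pathway()].
#' @return data frame with columns `pde3_rel`, `release`
#'   (nmol ATP / 4e8 erythrocytes, calibrated at the `pde3_rel = 1` anchor)
#'   and `camp_integral` (model units x s).
#' @examples
#' \donttest{
#' insulin_scenario(pathway_params(), c(1, 1.8, 4.1))
#' }
#' @export
insulin_scenario <- function(params, pde3_rel = c(1, 1.8, 4.1),
                             sO2 = 0.157, pulse_duration_s = 0.040, ...) {
  stopifnot(all(pde3_rel > 0))
  cal <- calibrate_release(params, pulse_duration_s = pulse_duration_s, ...)
  protocol <- desaturation_pulse(sO2, pulse_duration_s)
  rows <- lapply(pde3_rel, function(v) {
    p <- params
    p$pde3_rel <- v
    traj <- simulate_pathway(p, protocol, ...)
    data.frame(pde3_rel = v,
               release = cal$scale * total_release(traj),
               camp_integral = trapz(traj$time_s, traj$cAMP))
  })
  do.call(rbind, rows)
}
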