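#' Kinetic parameters of the erythrocyte ATP release pathway
#'
#' Constructs the parameter set for the five-step kinetic model of
#' low-oxygen-induced ATP release: G-protein (Gi) activation by desaturated
#' hemoglobin, cAMP production by adenylyl cyclase and hydrolysis by PDE3,
#' PKA activation, CFTR activation, and ATP efflux proportional to active
#' CFTR. Defaults are the published reference values for a human
#' erythrocyte; all rates are per second and concentrations/activations are
#' dimensionless, normalized to pool totals of 1.
#'
#' @param ac_base baseline cAMP production rate in the absence of G-protein
#'   stimulation (concentration/s). Zero by default: the oxygen-dependent
#'   pathway releases no ATP when hemoglobin is fully saturated.
#' @param k_camp_f cAMP production rate constant per unit active G-protein
#'   (1/s).
#' @param k_camp_i dimensionless gain of the PKA negative feedback that
#'   inhibits cAMP production.
#' @param v0 baseline cAMP degradation rate by PDE3 (1/s).
#' @param pde3_rel relative PDE3 activity (dimensionless, 1 = baseline).
#'   Insulin at pre-diabetic concentrations raises it (1.87 models 1 nM
#'   insulin).
#' @param K_pde3 half-maximal cAMP concentration of PDE3 hydrolysis
#'   (dimensionless concentration units).
#' @param k_pka_f forward rate constant for PKA activation by cAMP
#'   (1/(concentration s)).
#' @param k_pka_r PKA deactivation rate constant (1/s).
#' @param k_gp_f forward rate constant for G-protein activation by
#'   desaturated hemoglobin (1/s).
#' @param alpha exponent modulating the dependence of Gi activation on the
#'   desaturated-hemoglobin fraction tHb.
#' @param k_gp_r G-protein deactivation rate constant (1/s).
#' @param k_cftr_f forward rate constant for CFTR activation by active PKA
#'   (1/s).
#' @param beta exponent modulating the dependence of CFTR activation on
#'   active PKA; its large value (6.3) makes this step sharply switch-like.
#' @param k_cftr_r CFTR deactivation rate constant (1/s).
#' @param k_atp_flux ATP release rate per unit active CFTR (release-rate
#'   units).
#' @param gp_total,pka_total,cftr_total conserved pool sizes (dimensionless;
#'   active + inactive forms sum to these).
#'
#' @return An object of class `pathway_params` (a named list).
#' @seealso [simulate_pathway()], [read_pathway_params()]
#' @examples
#' p <- pathway_params()
#' p$k_gp_f
#' insulin <- pathway_params(pde3_rel = 1.87)
#' @export
pathway_params <- function(ac_base = 0,
                           k_camp_f = 49.5,
                           k_camp_i = 2.47,
                           v0 = 101,
                           pde3_rel = 1,
                           K_pde3 = 1,
                           k_pka_f = 60.5,
                           k_pka_r = 10.0,
                           k_gp_f = 25.0,
                           alpha = 1.2,
                           k_gp_r = 3.36,
                           k_cftr_f = 181,
                           beta = 6.3,
                           k_cftr_r = 11.3,
                           k_atp_flux = 2,
                           gp_total = 1,
                           pka_total = 1,
                           cftr_total = 1) {
  p <- list(ac_base = ac_base, k_camp_f = k_camp_f, k_camp_i = k_camp_i,
            v0 = v0, pde3_rel = pde3_rel, K_pde3 = K_pde3,
            k_pka_f = k_pka_f, k_pka_r = k_pka_r,
            k_gp_f = k_gp_f, alpha = alpha, k_gp_r = k_gp_r,
            k_cftr_f = k_cftr_f, beta = beta, k_cftr_r = k_cftr_r,
            k_atp_flux = k_atp_flux,
            gp_total = gp_total, pka_total = pka_total,
            cftr_total = cftr_total)
  validate_pathway_params(p)
  structure(p, class = "pathway_params")
}

validate_pathway_params <- function(p) {
  rates <- c("ac_base", "k_camp_f", "k_camp_i", "v0", "pde3_rel", "K_pde3",
             "k_pka_f", "k_pka_r", "k_gp_f", "k_gp_r", "k_cftr_f",
             "k_cftr_r", "k_atp_flux")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || is.na(p[[nm]]) ||
        p[[nm]] < 0) {
      stop("pathway parameter '", nm, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  for (nm in c("alpha", "beta")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      stop("exponent '", nm, "' must be > 0", call. = FALSE)
  }
  for (nm in c("gp_total", "pka_total", "cftr_total")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0)
      stop("pool size '", nm, "' must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.pathway_params <- function(x, ...) {
  cat("Erythrocyte ATP release pathway parameters\n")
  cat(sprintf("  Gi:   k_gp_f=%g 1/s, alpha=%g, k_gp_r=%g 1/s, GP_total=%g\n",
              x$k_gp_f, x$alpha, x$k_gp_r, x$gp_total))
  cat(sprintf("  cAMP: AC_base=%g, k_camp_f=%g, k_camp_i=%g, v0=%g 1/s, PDE3_rel=%g, K_pde3=%g\n",
              x$ac_base, x$k_camp_f, x$k_camp_i, x$v0, x$pde3_rel, x$K_pde3))
  cat(sprintf("  PKA:  k_pka_f=%g, k_pka_r=%g 1/s, PKA_total=%g\n",
              x$k_pka_f, x$k_pka_r, x$pka_total))
  cat(sprintf("  CFTR: k_cftr_f=%g, beta=%g, k_cftr_r=%g 1/s, CFTR_total=%g\n",
              x$k_cftr_f, x$beta, x$k_cftr_r, x$cftr_total))
  cat(sprintf("  ATP:  k_atp_flux=%g per CFTRa\n", x$k_atp_flux))
  invisible(x)
}

#' Read or write a pathway parameter file
#'
#' Flat key-value files (one `name = value` or `name: value` per line, or a
#' two-column CSV `name,value`) keyed by the parameter names of
#' [pathway_params()]. Unknown keys are an error; missing keys take default
#' values.
#'
#' @param path file path.
#' @return `read_pathway_params()` returns a `pathway_params` object;
#'   `write_pathway_params()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_pathway_params(pathway_params(pde3_rel = 1.87), f)
#' read_pathway_params(f)$pde3_rel
#' @export
read_pathway_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- setdiff(lines, "name,value")
  kv <- strsplit(lines, "[=:,]")
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) as.numeric(trimws(x[2])), 0)
  defaults <- pathway_params()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown))
    stop("unknown pathway parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- as.list(defaults)
  args[keys] <- vals
  do.call(pathway_params, args)
}

#' @rdname read_pathway_params
#' @param params a `pathway_params` object.
#' @export
write_pathway_params <- function(params, path) {
  stopifnot(inherits(params, "pathway_params"))
  writeLines(c("name,value",
               paste(names(params), vapply(params, format, ""), sep = ",")),
             path)
  invisible(path)
}

#' Stimulus protocol: hemoglobin saturation vs time
#'
#' A piecewise-constant oxyhemoglobin saturation protocol. The model is
#' driven by the desaturated ("tense"-state) hemoglobin fraction
#' tHb(t) = 1 - sO2(t).
#'
#' @param t_start,t_end interval endpoints (s); intervals must tile
#'   `[min(t_start), max(t_end)]` without gaps or overlap.
#' @param sO2 oxyhemoglobin saturation on each interval, in `[0, 1]`.
#' @return An object of class `stimulus_protocol` (a data frame with columns
#'   `t_start`, `t_end`, `sO2`).
#' @examples
#' # the reference stimulus: 40 ms desaturation step from 100% to 15.7% sO2
#' desaturation_pulse(0.157)
#' @export
stimulus_protocol <- function(t_start, t_end, sO2) {
  stopifnot(length(t_start) == length(t_end),
            length(t_start) == length(sO2))
  if (any(t_end <= t_start))
    stop("each interval must have t_end > t_start", call. = FALSE)
  o <- order(t_start)
  t_start <- t_start[o]; t_end <- t_end[o]; sO2 <- sO2[o]
  if (length(t_start) > 1 &&
      any(abs(t_start[-1] - t_end[-length(t_end)]) > 1e-12))
    stop("protocol intervals must be contiguous and non-overlapping",
         call. = FALSE)
  if (any(sO2 < 0 | sO2 > 1))
    stop("sO2 must lie in [0, 1]", call. = FALSE)
  structure(data.frame(t_start = t_start, t_end = t_end, sO2 = sO2),
            class = c("stimulus_protocol", "data.frame"))
}

#' @rdname stimulus_protocol
#' @param pulse_sO2 saturation during the desaturation pulse (fraction).
#' @param pulse_duration_s pulse length in seconds (default 40 ms).
#' @param baseline_sO2 saturation before and after the pulse (default 1,
#'   i.e. fully saturated hemoglobin).
#' @param t_end_s end of the protocol span (s).
#' @export
desaturation_pulse <- function(pulse_sO2, pulse_duration_s = 0.040,
                               baseline_sO2 = 1, t_end_s = 2) {
  if (t_end_s <= pulse_duration_s)
    stop("t_end_s must exceed the pulse duration", call. = FALSE)
  stimulus_protocol(t_start = c(0, pulse_duration_s),
                    t_end = c(pulse_duration_s, t_end_s),
                    sO2 = c(pulse_sO2, baseline_sO2))
}

#' Evaluate tHb(t) = 1 - sO2(t) for a protocol
#' @param protocol a `stimulus_protocol`.
#' @param t times (s) within the protocol span.
#' @return numeric vector of desaturated-hemoglobin fractions.
#' @keywords internal
protocol_thb <- function(protocol, t) {
  idx <- findInterval(t, protocol$t_start, rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  idx[idx > nrow(protocol)] <- nrow(protocol)
  1 - protocol$sO2[idx]
}
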