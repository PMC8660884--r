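#' Extract the post-permeabilization equilibrium from a time series
#'
#' After digitonin permeabilizes the membrane, the view-mean phasor relaxes
#' to the equilibrium of the buffer's calcium concentration; equilibrium is
#' taken as the mean of all samples at least `min_delay` seconds (default
#' 6 min) past the digitonin addition.
#'
#' @param series data frame with columns `time_s`, `G`, `S` and optionally
#'   `intensity` (one concentration, one replicate).
#' @param digitonin_time time of digitonin addition, s.
#' @param min_delay equilibration delay, s.
#' @return list with `g`, `s`, `intensity`, their within-window SDs
#'   (`sd_g`, `sd_s`, `sd_intensity`) and the window size `n`.
#' @export
extract_equilibrium <- function(series, digitonin_time, min_delay = 360) {
  sel <- series$time_s >= digitonin_time + min_delay
  if (!any(sel))
    stopf("no samples at least %g s past digitonin (series ends at %g s)",
          min_delay, max(series$time_s))
  w <- series[sel, ]
  inten <- if ("intensity" %in% names(w)) w$intensity else rep(NA_real_, nrow(w))
  list(g = mean(w$G), s = mean(w$S), intensity = mean(inten),
       sd_g = if (nrow(w) > 1) sd(w$G) else 0,
       sd_s = if (nrow(w) > 1) sd(w$S) else 0,
       sd_intensity = if (nrow(w) > 1) sd(inten) else 0,
       n = nrow(w))
}

# core of the polar-plot calibration, shared by the in situ (time series)
# and in vitro (well phasor) entry points: equilibrium-level table in,
# anchors + Hill fits + detection range out
calibrate_phasor_table <- function(eq, R, frequency_mhz,
                                   conf_level = 0.95) {
  concs <- sort(unique(eq$conc_nM))
  if (length(concs) < 2) stopf("fewer than 2 usable concentrations")
  c_lo <- min(concs); c_hi <- max(concs)
  anchors <- two_state_anchors(
    g_min = mean(eq$G[eq$conc_nM == c_lo]),
    s_min = mean(eq$S[eq$conc_nM == c_lo]),
    g_max = mean(eq$G[eq$conc_nM == c_hi]),
    s_max = mean(eq$S[eq$conc_nM == c_hi]),
    intensity_ratio_R = R, frequency_mhz = frequency_mhz)
  eq$a <- unclass_strip(line_fraction(eq$G, eq$S, anchors))
  eq$F <- fraction_bound(eq$a, R)
  hill_on_F <- fit_hill(eq$conc_nM, eq$F)
  hill_on_a <- fit_hill(eq$conc_nM, eq$a)
  range <- tryCatch(
    detection_range(eq$F[eq$conc_nM == c_lo], eq$F[eq$conc_nM == c_hi],
                    hill_on_F, conf_level = conf_level),
    error = function(e) list(ca_low = NA_real_, ca_high = NA_real_,
                             f_low = NA_real_, f_high = NA_real_,
                             degenerate = TRUE,
                             reason = conditionMessage(e)))
  structure(list(anchors = anchors, hill_on_F = hill_on_F,
                 hill_on_a = hill_on_a, detection_range = range,
                 equilibrium_table = eq, R = R,
                 frequency_mhz = frequency_mhz),
            class = "calibration_result")
}

#' In situ calibration from a permeabilization dataset
#'
#' For each concentration and replicate, extracts the post-digitonin
#' equilibrium phasor ([extract_equilibrium()]); the phasor anchors are the
#' mean equilibria of the lowest and highest concentration; each
#' equilibrium is projected onto the chord ([line_fraction()]) and
#' corrected to bound fraction with the supplied brightness ratio
#' ([fraction_bound()]); Hill models are fitted to both the corrected
#' fraction F and the raw line fraction a (the latter allows direct
#' conversion of experimental data without the intensity correction); the
#' detection range comes from replicate spread at the extremes
#' ([detection_range()]).
#'
#' @param dataset a `"calibration_dataset"` data frame (see
#'   [simulate_calibration_experiment()]) with columns `conc_nM`,
#'   `replicate`, `time_s`, `G`, `S`, `intensity`, `digitonin_time_s`.
#' @param R brightness ratio bound/unbound used for the intensity
#'   correction; defaults to the dataset's `intensity_ratio_R` attribute.
#' @param min_delay equilibration delay, s.
#' @param conf_level confidence level for the detection range.
#' @return an object of class `"calibration_result"` with fields
#'   `anchors`, `hill_on_F`, `hill_on_a`, `detection_range`,
#'   `equilibrium_table`, `R`, `frequency_mhz`.
#' @export
calibrate_in_situ <- function(dataset, R = attr(dataset, "intensity_ratio_R"),
                              min_delay = 360, conf_level = 0.95) {
  if (is.null(R)) stopf("supply the brightness ratio R")
  key <- interaction(dataset$conc_nM, dataset$replicate, drop = TRUE)
  eq <- do.call(rbind, lapply(split(dataset, key), function(d) {
    e <- extract_equilibrium(d, digitonin_time = d$digitonin_time_s[1],
                             min_delay = min_delay)
    data.frame(conc_nM = d$conc_nM[1], replicate = d$replicate[1],
               G = e$g, S = e$s, intensity = e$intensity)
  }))
  rownames(eq) <- NULL
  calibrate_phasor_table(eq, R = R,
                         frequency_mhz = attr(dataset, "frequency_mhz"),
                         conf_level = conf_level)
}

#' In vitro calibration from well-level phasors
#'
#' Same polar-plot analysis as [calibrate_in_situ()] but starting from one
#' equilibrium phasor per well (no time dimension), as recorded from
#' purified sensor in buffer plates.
#'
#' @param wells data frame with columns `conc_nM`, `replicate`, `G`, `S`
#'   and optionally `intensity` (see [simulate_well_phasors()]).
#' @inheritParams calibrate_in_situ
#' @param frequency_mhz modulation frequency; defaults to the table's
#'   attribute.
#' @return a `"calibration_result"`.
#' @export
calibrate_wells <- function(wells, R = attr(wells, "intensity_ratio_R"),
                            frequency_mhz = attr(wells, "frequency_mhz"),
                            conf_level = 0.95) {
  if (is.null(R)) stopf("supply the brightness ratio R")
  calibrate_phasor_table(wells, R = R, frequency_mhz = frequency_mhz,
                         conf_level = conf_level)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Two-state polar-plot calibration\n")
  print(x$anchors)
  cfF <- coef(x$hill_on_F); cfa <- coef(x$hill_on_a)
  cat(sprintf("  Hill on F: Kd = %.4g nM, n = %.4g\n", cfF["kd"], cfF["n"]))
  cat(sprintf("  Hill on a: Kd = %.4g nM, n = %.4g\n", cfa["kd"], cfa["n"]))
  dr <- x$detection_range
  if (isTRUE(dr$degenerate))
    cat("  detection range: degenerate (zero replicate spread at extremes)\n")
  else
    cat(sprintf("  detection range: %.3g nM - %.3g nM\n",
                dr$ca_low, dr$ca_high))
  invisible(x)
}

#' Detection range from replicate spread at the calibration extremes
#'
#' The lowest reliably measurable bound fraction is the mean F of the
#' zero-calcium replicates plus their 95% confidence half-width; the
#' highest is the mean at saturation minus its half-width. The half-width
#' is Student-t on the sample SD: `t(1 - alpha/2, n - 1) * sd`. Both
#' fractions are mapped through the Hill calibration inverse to
#' concentrations. Zero replicate variance collapses the range to the
#' clamping margins; the result is then flagged `degenerate`.
#'
#' @param F_zero bound-fraction replicates at zero calcium (>= 3).
#' @param F_sat bound-fraction replicates at saturation (>= 3).
#' @param hill_on_F the calibration `"hill_fit"` on F.
#' @param conf_level confidence level.
#' @return list with `ca_low`, `ca_high` (nM), `f_low`, `f_high` and a
#'   `degenerate` flag.
#' @export
detection_range <- function(F_zero, F_sat, hill_on_F, conf_level = 0.95) {
  if (length(F_zero) < 3 || length(F_sat) < 3)
    stopf("need >= 3 replicates per extreme")
  ci <- function(x) qt(1 - (1 - conf_level) / 2, length(x) - 1) * sd(x)
  f_low <- mean(F_zero) + ci(F_zero)
  f_high <- mean(F_sat) - ci(F_sat)
  degenerate <- sd(F_zero) == 0 && sd(F_sat) == 0
  if (!degenerate && f_low >= f_high)
    stopf("replicate spread too large: F_low >= F_high")
  lo <- concentration_from_fraction(f_low, hill_on_F)
  hi <- concentration_from_fraction(f_high, hill_on_F)
  list(ca_low = lo$ca_nM, ca_high = hi$ca_nM,
       f_low = f_low, f_high = f_high,
       degenerate = degenerate || !lo$in_range || !hi$in_range)
}
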