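#' Two-state phasor anchors
#'
#' The phasor endpoints of the calcium-free (`min`) and calcium-bound
#' (`max`) sensor states, plus the bound/unbound brightness ratio R. The
#' modulation frequency is stored so calibrations recorded at different
#' frequencies cannot be mixed.
#'
#' @param g_min,s_min phasor of the calcium-free state.
#' @param g_max,s_max phasor of the calcium-bound state.
#' @param intensity_ratio_R brightness ratio bound/unbound (> 0).
#' @param frequency_mhz modulation frequency, MHz.
#' @return an object of class `"two_state_anchors"`.
#' @export
two_state_anchors <- function(g_min, s_min, g_max, s_max,
                              intensity_ratio_R, frequency_mhz) {
  if ((g_max - g_min)^2 + (s_max - s_min)^2 <= 0)
    stopf("anchors coincide")
  if (intensity_ratio_R <= 0) stopf("intensity_ratio_R must be > 0")
  structure(list(g_min = g_min, s_min = s_min,
                 g_max = g_max, s_max = s_max,
                 intensity_ratio_R = intensity_ratio_R,
                 frequency_mhz = frequency_mhz),
            class = "two_state_anchors")
}

#' @export
print.two_state_anchors <- function(x, ...) {
  cat(sprintf(
    "Two-state anchors at %.4g MHz: apo (%.4f, %.4f) -> sat (%.4f, %.4f), R = %.3g\n",
    x$frequency_mhz, x$g_min, x$s_min, x$g_max, x$s_max,
    x$intensity_ratio_R))
  invisible(x)
}

#' Anchors of a sensor model at a given frequency
#'
#' Pure-state phasors from the model's phase/modulation lifetimes.
#'
#' @param model a [default_sensor_model()].
#' @param config an [instrument_config()].
#' @return a [two_state_anchors()] object.
#' @export
anchors_from_model <- function(model, config = instrument_config()) {
  f <- config$frequency_mhz
  apo <- lifetimes_to_phasor(model$tau_phi_apo, model$tau_mod_apo, f)
  sat <- lifetimes_to_phasor(model$tau_phi_sat, model$tau_mod_sat, f)
  two_state_anchors(apo$g, apo$s, sat$g, sat$s,
                    model$intensity_ratio_R, f)
}

#' Line fraction: projection onto the apo-saturated chord
#'
#' Orthogonal projection of phasor points onto the straight line between
#' the two anchors:
#' `a = (dG dG_max + dS dS_max) / (dG_max^2 + dS_max^2)` with
#' `dG = G - G_min`, `dS = S - S_min`. `a = 0` at the calcium-free anchor
#' and 1 at the calcium-bound anchor. Values outside `[0, 1]` are returned
#' as-is; the attribute `"in_range"` flags them.
#'
#' @param g,s phasor coordinates (vectors or matrices).
#' @param anchors a [two_state_anchors()] object.
#' @return numeric array of line fractions with logical attribute
#'   `"in_range"`.
#' @export
line_fraction <- function(g, s, anchors) {
  dg_max <- anchors$g_max - anchors$g_min
  ds_max <- anchors$s_max - anchors$s_min
  denom <- dg_max^2 + ds_max^2
  if (denom <= 0) stopf("anchors coincide")
  a <- ((g - anchors$g_min) * dg_max + (s - anchors$s_min) * ds_max) / denom
  attr(a, "in_range") <- a >= 0 & a <= 1
  a
}

#' Convert line fraction to molecular bound fraction and back
#'
#' The line fraction a weights the two states by intensity; because the
#' bound state is R times brighter, the molecular occupancy is
#' `F = a / (R (1 - a) + a)`, with inverse `a = R F / (1 + (R - 1) F)`.
#' Both maps are monotone increasing and fix 0 and 1 for any R > 0; at
#' R = 1 they are the identity.
#'
#' @param a line fraction(s).
#' @param F bound fraction(s).
#' @param R brightness ratio (> 0).
#' @return numeric of the same shape as the input.
#' @export
fraction_bound <- function(a, R) {
  if (R <= 0) stopf("R must be > 0")
  a <- unclass_strip(a)
  a / (R * (1 - a) + a)
}

#' @rdname fraction_bound
#' @export
line_fraction_from_F <- function(F, R) {
  if (R <= 0) stopf("R must be > 0")
  R * F / (1 + (R - 1) * F)
}

unclass_strip <- function(x) {
  attr(x, "in_range") <- NULL
  x
}

#' Session (daily-variance) correction
#'
#' Acquisition sessions drift in instrument phase and modulation relative
#' to the session in which the calibration was recorded. The correction is
#' estimated by forcing a measured saturated-state control (ionomycin or
#' Triton plus calcium) onto the calibration's saturated anchor:
#' `phase_offset = Phi_control - Phi_anchor` and
#' `modulation_factor = M_control / M_anchor`. Applying the correction
#' subtracts the offset from each pixel's phase and divides its modulation
#' by the factor.
#'
#' @param control either a `"phasor_image"` of the saturated control (the
#'   mean over valid pixels is used) or a numeric `c(g, s)` pair.
#' @param anchors a [two_state_anchors()] object.
#' @return an object of class `"session_correction"` with fields
#'   `phase_offset` (radians) and `modulation_factor`.
#' @export
estimate_session_correction <- function(control, anchors) {
  if (inherits(control, "phasor_image")) {
    ok <- control$valid_mask
    if (!any(ok)) stopf("control image has no valid pixels")
    gc <- mean(control$g[ok]); sc <- mean(control$s[ok])
  } else {
    gc <- control[1]; sc <- control[2]
  }
  m_ctl <- sqrt(gc^2 + sc^2)
  if (m_ctl <= 0) stopf("control modulation is <= 0")
  m_anchor <- sqrt(anchors$g_max^2 + anchors$s_max^2)
  structure(list(
    phase_offset = atan2(sc, gc) - atan2(anchors$s_max, anchors$g_max),
    modulation_factor = m_ctl / m_anchor
  ), class = "session_correction")
}

#' @rdname estimate_session_correction
#' @param ph a `"phasor_image"` (or list with `g`, `s`) to correct.
#' @param correction a `"session_correction"`.
#' @return `apply_session_correction()`: the corrected object.
#' @export
apply_session_correction <- function(ph, correction) {
  phi <- atan2(ph$s, ph$g) - correction$phase_offset
  m <- sqrt(ph$g^2 + ph$s^2) / correction$modulation_factor
  ph$g <- m * cos(phi)
  ph$s <- m * sin(phi)
  ph
}

#' @export
print.session_correction <- function(x, ...) {
  cat(sprintf("Session correction: phase offset %.5f rad, modulation factor %.5f\n",
              x$phase_offset, x$modulation_factor))
  invisible(x)
}

#' Convert a response to calcium concentration through a Hill calibration
#'
#' Inverts the calibration Hill model for per-pixel responses (bound
#' fraction F or line fraction a, depending on which calibration is
#' supplied). Responses are clamped to a small margin inside
#' `(fmin, fmax)`; clamped pixels are flagged out of range. With
#' `clamp = FALSE` such pixels become `NaN` instead (never an error on
#' images).
#'
#' @param x responses (vector or matrix).
#' @param calibration a `"hill_fit"` or a list with `fmin`, `fmax`, `kd`,
#'   `n`.
#' @param clamp clamp out-of-range responses to the margin (default) or
#'   return NaN.
#' @param margin relative clamping margin inside the (fmin, fmax) span.
#' @return list with `ca_nM` (same shape as `x`) and logical `in_range`.
#' @export
concentration_from_fraction <- function(x, calibration, clamp = TRUE,
                                        margin = 1e-4) {
  cf <- if (inherits(calibration, "hill_fit")) as.list(coef(calibration))
        else calibration
  if (cf$fmax == cf$fmin || cf$kd <= 0 || cf$n <= 0)
    stopf("invalid calibration: need fmax != fmin, kd > 0, n > 0")
  x <- unclass_strip(x)
  p <- (x - cf$fmin) / (cf$fmax - cf$fmin)
  in_range <- !is.na(p) & p > margin & p < 1 - margin
  pc <- pmin(pmax(p, margin), 1 - margin)
  ca <- cf$kd / ((1 / pc - 1)^(1 / cf$n))
  if (!clamp) ca[!in_range] <- NaN
  ca[is.na(p)] <- NaN
  if (!is.null(dim(x))) dim(ca) <- dim(in_range) <- dim(x)
  list(ca_nM = ca, in_range = in_range)
}

#' Quantify a phase stack into a calcium concentration map
#'
#' Composes the full analysis chain: [demodulate()] sample and reference
#' stacks, optional [background_correct()], [reference_calibrate()],
#' optional session correction from a saturated control, intensity
#' masking, chord projection ([line_fraction()]), brightness correction
#' ([fraction_bound()]) and Hill inversion
#' ([concentration_from_fraction()]).
#'
#' @param sample_stack,reference_stack [phase_stack()] objects with
#'   matching configs.
#' @param anchors a [two_state_anchors()]; its frequency must match the
#'   stacks'.
#' @param calibration a `"hill_fit"` on F (`mode = "F"`, the default) or on
#'   a (`mode = "a"`).
#' @param mode which response the calibration was fitted on.
#' @param session_control optional saturated-state control: a
#'   `"phasor_image"`, `c(g, s)` pair, or a precomputed
#'   `"session_correction"`.
#' @param background_mask optional logical matrix of pure-background
#'   pixels.
#' @param intensity_threshold strict intensity threshold for valid pixels.
#' @param tau_ref reference lifetime, ns.
#' @return an object of class `"concentration_map"`: matrices `ca_nM`,
#'   `fraction_bound`, `line_fraction`, `intensity`, logical `valid_mask`
#'   and `in_range_mask`.
#' @export
quantify_stack <- function(sample_stack, reference_stack, anchors,
                           calibration, mode = c("F", "a"),
                           session_control = NULL, background_mask = NULL,
                           intensity_threshold = 0,
                           tau_ref = sample_stack$config$reference_lifetime) {
  mode <- match.arg(mode)
  if (abs(anchors$frequency_mhz - sample_stack$config$frequency_mhz) > 1e-9)
    stopf("anchors recorded at %.4g MHz but stack at %.4g MHz",
          anchors$frequency_mhz, sample_stack$config$frequency_mhz)
  raw <- demodulate(sample_stack)
  if (!is.null(background_mask))
    raw <- background_correct(raw, background_mask)
  ph <- reference_calibrate(raw, demodulate(reference_stack),
                            tau_ref = tau_ref)
  if (!is.null(session_control)) {
    corr <- if (inherits(session_control, "session_correction"))
      session_control
    else estimate_session_correction(session_control, anchors)
    ph <- apply_session_correction(ph, corr)
  }
  valid <- ph$valid_mask & intensity_mask(ph$intensity, intensity_threshold)
  a <- unclass_strip(line_fraction(ph$g, ph$s, anchors))
  F <- fraction_bound(a, anchors$intensity_ratio_R)
  conv <- concentration_from_fraction(if (mode == "F") F else a, calibration)
  ca <- conv$ca_nM
  ca[!valid] <- NaN
  structure(list(ca_nM = ca, fraction_bound = F, line_fraction = a,
                 intensity = ph$intensity, valid_mask = valid,
                 in_range_mask = conv$in_range & valid),
            class = "concentration_map")
}

#' @export
print.concentration_map <- function(x, ...) {
  ok <- x$valid_mask
  cat(sprintf("Concentration map %d x %d px, %d valid (%d in range)\n",
              nrow(x$ca_nM), ncol(x$ca_nM), sum(ok), sum(x$in_range_mask)))
  if (any(ok))
    cat(sprintf("  median [Ca2+] over valid px: %.1f nM\n",
                median(x$ca_nM[ok], na.rm = TRUE)))
  invisible(x)
}

#' ROI time traces from a sequence of concentration maps
#'
#' Per ROI and timepoint: mean concentration and mean intensity over valid
#' pixels, plus the intensity fold-change F/F0 with F0 the ROI's mean
#' intensity over the first `f0_frames` timepoints.
#'
#' @param maps list of `"concentration_map"` objects (one per timepoint).
#' @param rois either a list of logical matrices or an integer label matrix
#'   (0 = background).
#' @param timestamps acquisition times, s; defaults to `0, 1, 2, ...`.
#' @param f0_frames number of initial frames defining F0.
#' @return data frame with columns `time_s`, `roi_id`, `ca_nM`,
#'   `intensity`, `fold_change`. If no ROI contains a valid pixel in any
#'   frame, a zero-row data frame with attribute `empty = TRUE` is
#'   returned.
#' @export
roi_trace <- function(maps, rois, timestamps = NULL, f0_frames = 3) {
  if (is.matrix(rois)) {
    ids <- sort(setdiff(unique(as.integer(rois)), 0L))
    rois <- lapply(ids, function(i) rois == i)
    names(rois) <- ids
  }
  if (length(rois) == 0 || !any(vapply(rois, any, logical(1))))
    stopf("empty ROI set")
  if (is.null(timestamps)) timestamps <- seq_along(maps) - 1
  if (is.null(names(rois))) names(rois) <- seq_along(rois)
  rows <- list()
  any_valid <- FALSE
  for (r in seq_along(rois)) {
    mask <- rois[[r]]
    ca <- inten <- rep(NA_real_, length(maps))
    for (t in seq_along(maps)) {
      m <- maps[[t]]
      sel <- mask & m$valid_mask
      if (any(sel)) {
        any_valid <- TRUE
        ca[t] <- mean(m$ca_nM[sel], na.rm = TRUE)
        inten[t] <- mean(m$intensity[sel])
      }
    }
    f0 <- mean(head(inten, f0_frames), na.rm = TRUE)
    rows[[r]] <- data.frame(time_s = timestamps, roi_id = names(rois)[r],
                            ca_nM = ca, intensity = inten,
                            fold_change = inten / f0)
  }
  out <- do.call(rbind, rows)
  if (!any_valid) {
    out <- out[0, ]
    attr(out, "empty") <- TRUE
  }
  rownames(out) <- NULL
  out
}
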