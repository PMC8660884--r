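#' Construct a phase stack
#'
#' A phase stack is the raw output of a homodyne FD-FLIM acquisition: one
#' image frame per detector phase step, frame axis first.
#'
#' @param frames 3-D numeric array `(phase_step, row, col)` of nonnegative
#'   counts.
#' @param config an [instrument_config()]; `config$n_phase_steps` must equal
#'   `dim(frames)[1]`.
#' @return an object of class `"phase_stack"`.
#' @export
phase_stack <- function(frames, config) {
  if (length(dim(frames)) != 3)
    stopf("frames must be a 3-D array (phase_step, row, col)")
  if (dim(frames)[1] != config$n_phase_steps)
    stopf("first axis (%d) != config$n_phase_steps (%d)",
          dim(frames)[1], config$n_phase_steps)
  if (any(frames < 0, na.rm = TRUE)) stopf("counts must be >= 0")
  structure(list(frames = frames, config = config), class = "phase_stack")
}

#' @export
print.phase_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Phase stack: %d frames of %d x %d px at %.4g MHz\n",
              d[1], d[2], d[3], x$config$frequency_mhz))
  invisible(x)
}

#' First-harmonic demodulation of a phase stack
#'
#' Per pixel computes the mean intensity (dc), the amplitude of the
#' fundamental (ac) and the raw phase of a phase stack by discrete Fourier
#' transform over the uniform detector phase steps:
#' `dc = mean_k I_k`, `c = (2/K) sum_k I_k exp(-i theta_k)`,
#' `ac = |c|`, `raw_phase = Arg(conj(c))`, so a frame set
#' `A [1 + m cos(theta_k - phi)]` returns `raw_phase = phi` and
#' `ac/dc = m` exactly. For a single-harmonic signal on uniform steps this
#' equals the linear least-squares fit of `a + b cos(theta) + c sin(theta)`.
#'
#' @param stack a [phase_stack()] with at least 3 phase steps.
#' @return an object of class `"raw_phasor_image"` with matrices `dc`, `ac`,
#'   `raw_phase`, a `valid` mask (FALSE where dc <= 0 or ac == 0, where the
#'   phase is undefined) and the acquisition `config`.
#' @export
demodulate <- function(stack) {
  stopifnot(inherits(stack, "phase_stack"))
  K <- stack$config$n_phase_steps
  if (K < 3) stopf("demodulation needs K >= 3 phase steps")
  theta <- phase_steps(stack$config)
  d <- dim(stack$frames)
  flat <- matrix(stack$frames, nrow = K)   # K x npix
  dc <- colMeans(flat)
  re <- (2 / K) * as.numeric(crossprod(flat, cos(theta)))
  im <- (2 / K) * as.numeric(crossprod(flat, sin(theta)))
  # c = re - i*im; raw_phase = Arg(conj(c)) = atan2(im, re)
  ac <- sqrt(re^2 + im^2)
  ph <- atan2(im, re)
  shape <- d[2:3]
  raw_phasor_image(
    dc = matrix(dc, shape[1], shape[2]),
    ac = matrix(ac, shape[1], shape[2]),
    raw_phase = matrix(ph, shape[1], shape[2]),
    config = stack$config
  )
}

raw_phasor_image <- function(dc, ac, raw_phase, config, valid = NULL) {
  # ac at floating-point noise level means no modulation: phase undefined
  if (is.null(valid)) valid <- dc > 0 & ac > dc * 1e-10
  structure(list(dc = dc, ac = ac, raw_phase = raw_phase,
                 valid = valid, config = config),
            class = "raw_phasor_image")
}

#' @export
print.raw_phasor_image <- function(x, ...) {
  cat(sprintf("Raw phasor image %d x %d px (%.4g MHz), %d valid px\n",
              nrow(x$dc), ncol(x$dc), x$config$frequency_mhz, sum(x$valid)))
  invisible(x)
}

#' Background correction of a raw phasor image
#'
#' Subtracts the background region's mean dc and mean complex fundamental
#' from every pixel, before any normalization by dc. Removing the complex
#' fundamental (not just intensity) removes the background's lifetime
#' contribution. Pixels whose dc becomes nonpositive are flagged invalid.
#'
#' @param sample a `"raw_phasor_image"`.
#' @param background_mask logical matrix selecting at least one pixel of
#'   pure background.
#' @return a corrected `"raw_phasor_image"`.
#' @export
background_correct <- function(sample, background_mask) {
  stopifnot(inherits(sample, "raw_phasor_image"))
  if (!any(background_mask)) stopf("background mask selects no pixels")
  z <- complex(modulus = sample$ac, argument = sample$raw_phase)
  bg_dc <- mean(sample$dc[background_mask])
  bg_z <- mean(z[background_mask])
  dc2 <- sample$dc - bg_dc
  z2 <- z - bg_z
  ac2 <- Mod(z2)
  ph2 <- Arg(z2)
  dim(ac2) <- dim(ph2) <- dim(sample$dc)
  raw_phasor_image(dc = dc2, ac = ac2, raw_phase = ph2,
                   config = sample$config,
                   valid = sample$valid & dc2 > 0)
}

#' Reference calibration of a raw phasor image
#'
#' Removes the instrument's phase offset and modulation attenuation using a
#' reference stack of a fluorophore with known mono-exponential lifetime.
#' The instrument phase is `mean(raw_phase_ref) - atan(omega tau_ref)` and
#' the instrument modulation `mean(ac_ref/dc_ref) / (1 + (omega tau_ref)^2)^-1/2`;
#' spatial means over the reference are 5%-trimmed to tolerate dead pixels.
#' Each sample pixel then gets `Phi = raw_phase - phase_inst`,
#' `M = (ac/dc)/mod_inst`, `G = M cos(Phi)`, `S = M sin(Phi)`.
#'
#' @param sample,reference `"raw_phasor_image"` objects sharing frequency
#'   and phase-step count.
#' @param tau_ref reference lifetime, ns; defaults to
#'   `sample$config$reference_lifetime`.
#' @param trim trimming fraction per tail for the reference spatial means.
#' @param max_modulation,min_phase validity thresholds: pixels with
#'   `M > max_modulation` or `Phi` outside `[min_phase, pi/2]` are flagged
#'   invalid (physically impossible for a decay).
#' @return an object of class `"phasor_image"` with matrices `g`, `s`,
#'   `intensity` (dc), logical `valid_mask`, and `config`.
#' @export
reference_calibrate <- function(sample, reference,
                                tau_ref = sample$config$reference_lifetime,
                                trim = 0.05,
                                max_modulation = 1.05, min_phase = -0.05) {
  stopifnot(inherits(sample, "raw_phasor_image"),
            inherits(reference, "raw_phasor_image"))
  if (sample$config$frequency_mhz != reference$config$frequency_mhz ||
      sample$config$n_phase_steps != reference$config$n_phase_steps)
    stopf("sample and reference configs do not match")
  w <- omega_rad_ns(sample$config$frequency_mhz)
  ok <- reference$valid
  if (!any(ok)) stopf("reference has no valid pixels")
  ref_mod <- mean((reference$ac / reference$dc)[ok], trim = trim)
  if (ref_mod <= 0) stopf("reference modulation is zero")
  inst_phase <- mean(reference$raw_phase[ok], trim = trim) - atan(w * tau_ref)
  inst_mod <- ref_mod * sqrt(1 + (w * tau_ref)^2)
  phi <- sample$raw_phase - inst_phase
  m <- (sample$ac / sample$dc) / inst_mod
  g <- m * cos(phi)
  s <- m * sin(phi)
  valid <- sample$valid & is.finite(m) &
    m <= max_modulation & phi >= min_phase & phi <= pi / 2
  phasor_image(g = g, s = s, intensity = sample$dc,
               valid_mask = valid, config = sample$config)
}

#' Construct a phasor image
#'
#' Calibrated per-pixel phasor coordinates `(G, S) = (M cos Phi, M sin Phi)`
#' plus steady-state intensity.
#'
#' @param g,s,intensity numeric matrices of equal dimension.
#' @param valid_mask logical matrix; defaults to all finite pixels.
#' @param config an [instrument_config()].
#' @return an object of class `"phasor_image"`.
#' @export
phasor_image <- function(g, s, intensity, valid_mask = NULL, config) {
  if (is.null(valid_mask)) valid_mask <- is.finite(g) & is.finite(s)
  structure(list(g = g, s = s, intensity = intensity,
                 valid_mask = valid_mask, config = config),
            class = "phasor_image")
}

#' @export
print.phasor_image <- function(x, ...) {
  cat(sprintf("Phasor image %d x %d px (%.4g MHz), %d valid px\n",
              nrow(x$g), ncol(x$g), x$config$frequency_mhz,
              sum(x$valid_mask)))
  if (any(x$valid_mask))
    cat(sprintf("  mean (G, S) over valid px: (%.4f, %.4f)\n",
                mean(x$g[x$valid_mask]), mean(x$s[x$valid_mask])))
  invisible(x)
}

#' Convert lifetimes to phasor coordinates
#'
#' `Phi = atan(omega tau_phi)`, `M = 1/sqrt(1 + (omega tau_mod)^2)`,
#' `G = M cos(Phi)`, `S = M sin(Phi)`. For a mono-exponential decay
#' (`tau_phi == tau_mod`) the point lies on the universal semicircle.
#'
#' @param tau_phi,tau_mod phase and modulation lifetimes, ns.
#' @param frequency_mhz modulation frequency, MHz.
#' @return list with numeric `g` and `s` (shaped like the inputs).
#' @export
lifetimes_to_phasor <- function(tau_phi, tau_mod, frequency_mhz) {
  if (frequency_mhz <= 0) stopf("frequency must be > 0")
  w <- omega_rad_ns(frequency_mhz)
  phi <- atan(w * tau_phi)
  m <- 1 / sqrt(1 + (w * tau_mod)^2)
  list(g = m * cos(phi), s = m * sin(phi))
}

#' Convert a phasor image to lifetime images
#'
#' Inverts the polar relations: `tau_phi = tan(Phi)/omega`,
#' `tau_mod = sqrt(1/M^2 - 1)/omega` with `Phi = atan2(S, G)` and
#' `M = sqrt(G^2 + S^2)`. Pixels that are invalid, or physically impossible
#' for a decay (`M > 1` beyond tolerance, `Phi < 0` beyond tolerance), are
#' returned as `NaN`; small excursions within tolerance are clipped to the
#' physical boundary (tau = 0, M = 1).
#'
#' @param ph a `"phasor_image"`.
#' @param max_modulation,min_phase tolerance thresholds, as in
#'   [reference_calibrate()].
#' @return an object of class `"lifetime_image"` with matrices `tau_phi`,
#'   `tau_mod` (ns), `intensity` and `valid_mask`.
#' @export
phasor_to_lifetimes <- function(ph, max_modulation = 1.05,
                                min_phase = -0.05) {
  stopifnot(inherits(ph, "phasor_image"))
  w <- omega_rad_ns(ph$config$frequency_mhz)
  phi <- atan2(ph$s, ph$g)
  m <- sqrt(ph$g^2 + ph$s^2)
  valid <- ph$valid_mask & is.finite(phi) & is.finite(m) &
    m > 0 & m <= max_modulation & phi >= min_phase & phi < pi / 2
  tau_phi <- tan(pmax(phi, 0)) / w
  tau_mod <- sqrt(pmax(1 / pmin(m, 1)^2 - 1, 0)) / w
  tau_phi[!valid] <- NaN
  tau_mod[!valid] <- NaN
  structure(list(tau_phi = tau_phi, tau_mod = tau_mod,
                 intensity = ph$intensity, valid_mask = valid,
                 config = ph$config),
            class = "lifetime_image")
}

#' @export
print.lifetime_image <- function(x, ...) {
  ok <- x$valid_mask
  cat(sprintf("Lifetime image %d x %d px, %d valid px\n",
              nrow(x$tau_phi), ncol(x$tau_phi), sum(ok)))
  if (any(ok))
    cat(sprintf("  mean tau_phi %.3f ns, mean tau_mod %.3f ns\n",
                mean(x$tau_phi[ok]), mean(x$tau_mod[ok])))
  invisible(x)
}

#' Intensity mask
#'
#' Strict threshold on mean intensity, used to exclude pixels dominated by
#' background fluorescence.
#'
#' @param intensity numeric matrix of mean counts.
#' @param threshold counts; pixels pass only if strictly greater.
#' @return logical matrix.
#' @export
intensity_mask <- function(intensity, threshold) {
  if (threshold < 0) stopf("threshold must be >= 0")
  intensity > threshold
}
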