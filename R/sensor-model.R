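#' Instrument configuration for homodyne FD-FLIM
#'
#' Describes the frequency-domain acquisition: a light source sinusoidally
#' modulated at `frequency_mhz`, a gain-modulated detector stepped through
#' `n_phase_steps` uniform phase offsets \eqn{\theta_k = 2\pi k/K}, and a
#' mono-exponential reference fluorophore used to calibrate instrument phase
#' and modulation. The angular frequency \eqn{\omega = 2\pi f} is always
#' derived from `frequency_mhz`, never stored.
#'
#' @param frequency_mhz modulation frequency, MHz (> 0).
#' @param n_phase_steps number of detector phase steps K (>= 3).
#' @param excitation_modulation_depth,detection_modulation_depth modulation
#'   depths in `[0, 1]`; only their product enters the forward model, and it
#'   is removed entirely by reference calibration.
#' @param reference_name,reference_lifetime reference fluorophore label and
#'   its mono-exponential lifetime in ns (defaults: Alexa488, 4.05 ns;
#'   Erythrosin B at 0.086 ns is the common short-lifetime alternative).
#' @return an object of class `"instrument_config"`.
#' @export
instrument_config <- function(frequency_mhz = 75.1,
                              n_phase_steps = 12L,
                              excitation_modulation_depth = 1.0,
                              detection_modulation_depth = 0.9,
                              reference_name = "Alexa488",
                              reference_lifetime = 4.05) {
  if (frequency_mhz <= 0) stopf("frequency_mhz must be > 0")
  if (n_phase_steps < 3) stopf("need at least 3 phase steps")
  if (reference_lifetime <= 0) stopf("reference_lifetime must be > 0")
  structure(list(
    frequency_mhz = frequency_mhz,
    n_phase_steps = as.integer(n_phase_steps),
    excitation_modulation_depth = excitation_modulation_depth,
    detection_modulation_depth = detection_modulation_depth,
    reference_name = reference_name,
    reference_lifetime = reference_lifetime
  ), class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat(sprintf(
    "FD-FLIM config: %.4g MHz, K = %d phase steps, m_ex*m_det = %.3g\n",
    x$frequency_mhz, x$n_phase_steps,
    x$excitation_modulation_depth * x$detection_modulation_depth))
  cat(sprintf("  reference: %s, tau = %.4g ns\n",
              x$reference_name, x$reference_lifetime))
  invisible(x)
}

# detector phase steps theta_k = 2*pi*k/K, k = 0..K-1
phase_steps <- function(config) 2 * pi * (seq_len(config$n_phase_steps) - 1) /
  config$n_phase_steps

#' Noise specification for the synthetic-data generators
#'
#' @param kind `"none"`, `"poisson"` (shot noise on counts) or `"gaussian"`.
#' @param gaussian_sd standard deviation in counts (gaussian kind only).
#' @param seed optional integer seed; with `kind = "none"` output is
#'   bit-reproducible regardless of seed.
#' @return an object of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("none", "poisson", "gaussian"),
                       gaussian_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, gaussian_sd = gaussian_sd, seed = seed),
            class = "noise_spec")
}

apply_noise <- function(x, noise) {
  if (is.null(noise) || noise$kind == "none") return(x)
  with_seed(noise$seed, {
    if (noise$kind == "poisson") {
      out <- x
      out[] <- rpois(length(x), pmax(x, 0))
    } else {
      out <- x + rnorm(length(x), sd = noise$gaussian_sd)
    }
    out
  })
}

#' Packaged ground-truth sensor models
#'
#' Returns the parameter set of the Tq-Ca-FLITS calcium biosensor used as
#' ground truth by every synthetic-data generator. Two presets reflect the
#' two calibration contexts of the sensor:
#' \describe{
#'   \item{`"in_situ"`}{brightness ratio R = 3.02 and occupancy Hill
#'     parameters Kd = 265 nM, n = 1.63 (polar-plot calibration in
#'     permeabilized cells).}
#'   \item{`"in_vitro"`}{R = 3.51; occupancy (lifetime-mode) Kd = 372 nM;
#'     intensity-mode apparent Hill parameters Kd = 360 nM, n = 1.51.}
#' }
#' Both presets share the photophysics: phase/modulation lifetimes
#' 1.40/1.80 ns (calcium-free) and 2.78/3.01 ns (calcium-bound), quantum
#' yields 0.25/0.75, extinction coefficients at 440 nm 30.6/33.7
#' mM^-1 cm^-1, a one-site pH model for the free state (pKa 4.36, Hill
#' coefficient 0.86) and a two-site model for the bound state (pKa 4.71
#' [0.70] and 5.91 [3.58]).
#'
#' The occupancy Hill (`binding`) always runs 0 to 1; the intensity-mode
#' titration (`intensity_binding`) carries its own apparent constants
#' because intensity and polar-plot analyses of the same titration yield
#' separately fitted apparent Kd values.
#'
#' @param preset `"in_situ"` or `"in_vitro"`.
#' @return an object of class `"sensor_model"`.
#' @examples
#' m <- default_sensor_model("in_situ")
#' m$binding$kd   # 265
#' @export
default_sensor_model <- function(preset = c("in_situ", "in_vitro")) {
  if (!is.character(preset) || !(preset[1] %in% c("in_situ", "in_vitro")))
    stopf("unknown sensor-model preset: %s", toString(preset[1]))
  preset <- preset[1]
  binding <- if (preset == "in_situ")
    list(fmin = 0, fmax = 1, kd = 265, n = 1.63)
  else
    list(fmin = 0, fmax = 1, kd = 372, n = 1.5)
  R <- if (preset == "in_situ") 3.02 else 3.51
  intensity_binding <- if (preset == "in_situ")
    list(fmin = 1000, fmax = 1000 * R, kd = 265, n = 1.63)
  else
    list(fmin = 1000, fmax = 1000 * R, kd = 360, n = 1.51)
  structure(list(
    preset = preset,
    tau_phi_apo = 1.40, tau_mod_apo = 1.80,
    tau_phi_sat = 2.78, tau_mod_sat = 3.01,
    intensity_ratio_R = R,
    binding = binding,
    intensity_binding = intensity_binding,
    ph_model_apo = list(model_kind = "one", fmin = 0, fmax = 1000,
                        pka1 = 4.36, n1 = 0.86),
    ph_model_sat = list(model_kind = "two", fmin = 0, fmed = 1000,
                        fmax = 3510, pka1 = 4.71, n1 = 0.70,
                        pka2 = 5.91, n2 = 3.58),
    qy_apo = 0.25, qy_sat = 0.75,
    lambda_abs_apo = 442, lambda_em_apo = 489,
    lambda_abs_sat = 439, lambda_em_sat = 481,
    eps440_apo = 30.6, eps440_sat = 33.7
  ), class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("Two-state calcium sensor model (preset \"%s\")\n", x$preset))
  cat(sprintf("  apo: tau_phi %.2f ns, tau_mod %.2f ns, QY %.2f\n",
              x$tau_phi_apo, x$tau_mod_apo, x$qy_apo))
  cat(sprintf("  sat: tau_phi %.2f ns, tau_mod %.2f ns, QY %.2f\n",
              x$tau_phi_sat, x$tau_mod_sat, x$qy_sat))
  cat(sprintf("  R = %.2f; occupancy Kd = %g nM, n = %g\n",
              x$intensity_ratio_R, x$binding$kd, x$binding$n))
  invisible(x)
}
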