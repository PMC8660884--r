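#' Phasor and relative intensity of the sensor at a given occupancy
#'
#' Forward model of the two-state mixture: the occupancy F (fraction of
#' sensors in the calcium-bound conformation) is converted to the bound
#' state's intensity weight `a = R F / (1 + (R - 1) F)`, and the observed
#' phasor is the intensity-weighted complex sum of the two pure-state
#' phasors. Total brightness scales as `(1 - F) + R F` relative to pure apo.
#'
#' @param model a [default_sensor_model()] (or compatible list).
#' @param config an [instrument_config()].
#' @param free_ca free calcium, nM; occupancy computed from
#'   `model$binding`. Exactly one of `free_ca`/`fraction_bound`.
#' @param fraction_bound occupancy F in `[0, 1]`.
#' @return list with `g`, `s`, `fraction_bound`, `line_fraction`,
#'   `rel_intensity` (brightness relative to pure apo).
#' @export
two_state_phasor <- function(model, config, free_ca = NULL,
                             fraction_bound = NULL) {
  if (is.null(free_ca) == is.null(fraction_bound))
    stopf("supply exactly one of free_ca or fraction_bound")
  F <- if (is.null(fraction_bound)) {
    b <- model$binding
    hill_response(free_ca, b$fmin, b$fmax, b$kd, b$n)
  } else fraction_bound
  if (any(F < 0 | F > 1)) stopf("fraction_bound outside [0, 1]")
  R <- model$intensity_ratio_R
  a <- line_fraction_from_F(F, R)
  f <- config$frequency_mhz
  apo <- lifetimes_to_phasor(model$tau_phi_apo, model$tau_mod_apo, f)
  sat <- lifetimes_to_phasor(model$tau_phi_sat, model$tau_mod_sat, f)
  list(g = a * sat$g + (1 - a) * apo$g,
       s = a * sat$s + (1 - a) * apo$s,
       fraction_bound = F, line_fraction = a,
       rel_intensity = (1 - F) + R * F)
}

# homodyne frame means for a signal of modulation m_sig and phase phi_sig
homodyne_frames <- function(amplitude, m_sig, phi_sig, offset, config,
                            dim, instrument_phase = 0) {
  K <- config$n_phase_steps
  theta <- phase_steps(config)
  m_inst <- config$excitation_modulation_depth *
    config$detection_modulation_depth
  per_frame <- amplitude *
    (1 + m_inst * m_sig * cos(theta - phi_sig - instrument_phase)) + offset
  array(rep(per_frame, times = prod(dim)), dim = c(K, dim))
}

#' Simulate a mono-exponential phase stack
#'
#' Homodyne single-harmonic forward model: frame k has pixel mean
#' `amplitude [1 + m_ex m_det M(tau) cos(theta_k - Phi(tau))] + offset`,
#' with `Phi = atan(omega tau)` and `M = 1/sqrt(1 + (omega tau)^2)` --
#' mono-exponential, so the same lifetime drives phase and modulation.
#'
#' @param tau lifetime, ns (>= 0).
#' @param config an [instrument_config()].
#' @param amplitude mean signal counts (> 0).
#' @param offset_background additive background counts per frame.
#' @param noise a [noise_spec()].
#' @param dim image size `c(rows, cols)`.
#' @param instrument_phase additional instrument phase offset, radians;
#'   removed later by [reference_calibrate()].
#' @return a [phase_stack()].
#' @export
simulate_mono_stack <- function(tau, config = instrument_config(),
                                amplitude = 1000, offset_background = 0,
                                noise = noise_spec("none"),
                                dim = c(32, 32), instrument_phase = 0) {
  if (tau < 0) stopf("tau must be >= 0")
  if (amplitude <= 0) stopf("amplitude must be > 0")
  w <- omega_rad_ns(config$frequency_mhz)
  frames <- homodyne_frames(amplitude,
                            m_sig = 1 / sqrt(1 + (w * tau)^2),
                            phi_sig = atan(w * tau),
                            offset = offset_background,
                            config = config, dim = dim,
                            instrument_phase = instrument_phase)
  phase_stack(apply_noise(frames, noise), config)
}

#' Simulate a two-state mixture phase stack
#'
#' Generates the phase stack a camera would record from sensor molecules at
#' a given calcium level: occupancy from the binding curve, phasor from the
#' intensity-weighted two-state mixture ([two_state_phasor()]), amplitude
#' scaled by the mixture brightness `(1 - F) + R F`.
#'
#' @inheritParams two_state_phasor
#' @inheritParams simulate_mono_stack
#' @param amplitude counts of a pure-apo pixel; mixtures scale up with
#'   occupancy.
#' @return a [phase_stack()].
#' @export
simulate_two_state_stack <- function(model, config = instrument_config(),
                                     free_ca = NULL, fraction_bound = NULL,
                                     amplitude = 1000, offset_background = 0,
                                     noise = noise_spec("none"),
                                     dim = c(32, 32), instrument_phase = 0) {
  mix <- two_state_phasor(model, config, free_ca = free_ca,
                          fraction_bound = fraction_bound)
  m_mix <- sqrt(mix$g^2 + mix$s^2)
  phi_mix <- atan2(mix$s, mix$g)
  frames <- homodyne_frames(amplitude * mix$rel_intensity,
                            m_sig = m_mix, phi_sig = phi_mix,
                            offset = offset_background,
                            config = config, dim = dim,
                            instrument_phase = instrument_phase)
  phase_stack(apply_noise(frames, noise), config)
}

#' Simulate an in situ calibration experiment
#'
#' Emulates the permeabilization calibration: cells in a series of calcium
#' buffers are imaged every 20 s; at `digitonin_time_s` the membrane is
#' permeabilized and the view-mean phasor relaxes exponentially from its
#' resting value to the two-state equilibrium phasor of the buffer
#' concentration.
#'
#' @param concentrations free calcium of the buffer series, nM; at least 2,
#'   spanning a near-zero and a saturating value. Default: 0 plus 10
#'   log-spaced values from 17 nM to 39 uM (an 11-step buffer ladder).
#' @param model,config ground truth, as in [simulate_two_state_stack()].
#' @param replicates replicate series per concentration.
#' @param n_frames frames per series (20 s interval).
#' @param digitonin_time_s time of permeabilization, s.
#' @param equilibration_rate exponential approach rate after digitonin,
#'   1/s; `Inf` gives instant equilibration.
#' @param resting_ca resting free calcium before permeabilization, nM.
#' @param amplitude view-mean counts of a pure-apo view.
#' @param noise a [noise_spec()]; gaussian sd applies to the phasor
#'   coordinates, and proportionally (sd/amplitude) to intensity.
#' @return a data frame of class `"calibration_dataset"` with columns
#'   `conc_nM`, `replicate`, `time_s`, `G`, `S`, `intensity`,
#'   `digitonin_time_s`; frequency and phase-step metadata in attributes.
#' @export
simulate_calibration_experiment <- function(
    concentrations = c(0, exp(seq(log(17), log(39000), length.out = 10))),
    model = default_sensor_model("in_situ"),
    config = instrument_config(),
    replicates = 3, n_frames = 48, digitonin_time_s = 60,
    equilibration_rate = 0.02, resting_ca = 100,
    amplitude = 2000, noise = noise_spec("none")) {
  if (length(concentrations) < 1) stopf("empty concentration list")
  if (length(concentrations) < 2)
    stopf("need at least 2 concentrations (a low and a saturating one)")
  times <- (seq_len(n_frames) - 1) * 20
  rest <- two_state_phasor(model, config, free_ca = resting_ca)
  rows <- vector("list", length(concentrations) * replicates)
  i <- 0
  for (conc in concentrations) {
    eq <- two_state_phasor(model, config, free_ca = conc)
    for (rep_id in seq_len(replicates)) {
      # exponential approach of the view-mean phasor to equilibrium
      lag <- ifelse(times < digitonin_time_s, 1,
                    exp(-equilibration_rate * (times - digitonin_time_s)))
      lag[times >= digitonin_time_s & is.infinite(equilibration_rate)] <- 0
      g <- eq$g + (rest$g - eq$g) * lag
      s <- eq$s + (rest$s - eq$s) * lag
      inten <- amplitude *
        (eq$rel_intensity + (rest$rel_intensity - eq$rel_intensity) * lag)
      if (noise$kind == "gaussian" && noise$gaussian_sd > 0) {
        seed_i <- if (is.null(noise$seed)) NULL else noise$seed + i
        gsn <- with_seed(seed_i, matrix(rnorm(3 * length(times),
                                              sd = noise$gaussian_sd), ncol = 3))
        g <- g + gsn[, 1]
        s <- s + gsn[, 2]
        inten <- inten * (1 + gsn[, 3] / amplitude)
      }
      i <- i + 1
      rows[[i]] <- data.frame(conc_nM = conc, replicate = rep_id,
                              time_s = times, G = g, S = s,
                              intensity = inten,
                              digitonin_time_s = digitonin_time_s)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "frequency_mhz") <- config$frequency_mhz
  attr(out, "intensity_ratio_R") <- model$intensity_ratio_R
  class(out) <- c("calibration_dataset", "data.frame")
  out
}

#' Simulate well-level equilibrium phasors for an in vitro titration
#'
#' One view-mean phasor per well (concentration x replicate), as read from
#' a plate of purified sensor in calibration buffers -- the lifetime-mode
#' companion of [simulate_titration_table()].
#'
#' @inheritParams simulate_calibration_experiment
#' @return data frame with columns `conc_nM`, `replicate`, `G`, `S`,
#'   `intensity`; frequency and R in attributes.
#' @export
simulate_well_phasors <- function(
    concentrations = c(0, exp(seq(log(17), log(39000), length.out = 10))),
    model = default_sensor_model("in_vitro"),
    config = instrument_config(),
    replicates = 3, amplitude = 2000, noise = noise_spec("none")) {
  if (length(concentrations) < 2) stopf("need at least 2 concentrations")
  grid <- expand.grid(replicate = seq_len(replicates),
                      conc_nM = concentrations)
  eq <- two_state_phasor(model, config, free_ca = grid$conc_nM)
  g <- eq$g; s <- eq$s
  inten <- amplitude * eq$rel_intensity
  if (noise$kind == "gaussian" && noise$gaussian_sd > 0) {
    gsn <- with_seed(noise$seed,
                     matrix(rnorm(3 * nrow(grid), sd = noise$gaussian_sd),
                            ncol = 3))
    g <- g + gsn[, 1]; s <- s + gsn[, 2]
    inten <- inten * (1 + gsn[, 3] / amplitude)
  }
  out <- data.frame(conc_nM = grid$conc_nM, replicate = grid$replicate,
                    G = g, S = s, intensity = inten)
  attr(out, "frequency_mhz") <- config$frequency_mhz
  attr(out, "intensity_ratio_R") <- model$intensity_ratio_R
  out
}

#' Simulate an intensity titration table
#'
#' Plate-reader intensities along the calcium ladder, generated from the
#' model's apparent intensity-mode Hill parameters
#' (`model$intensity_binding`); zero concentration maps to `fmin` exactly.
#'
#' @inheritParams simulate_calibration_experiment
#' @param noise a [noise_spec()]; gaussian sd in counts.
#' @return data frame with columns `concentration_nM`, `replicate`,
#'   `intensity`.
#' @export
simulate_titration_table <- function(
    model = default_sensor_model("in_vitro"),
    concentrations = c(0, exp(seq(log(17), log(39000), length.out = 10))),
    replicates = 3, noise = noise_spec("none")) {
  if (any(concentrations < 0)) stopf("concentrations must be >= 0")
  b <- model$intensity_binding
  grid <- expand.grid(replicate = seq_len(replicates),
                      concentration_nM = concentrations)
  y <- hill_response(grid$concentration_nM, b$fmin, b$fmax, b$kd, b$n)
  y <- as.numeric(apply_noise(y, noise))
  data.frame(concentration_nM = grid$concentration_nM,
             replicate = grid$replicate, intensity = y)
}

#' Evaluate a one- or two-site pH model
#'
#' One-site (Henderson-Hasselbalch with Hill coefficient):
#' `f = fmin + (fmax - fmin)/(1 + 10^(n1 (pKa1 - pH)))`.
#' Two-site adds a second transition:
#' `f = fmin + (fmed - fmin)/(1 + 10^(n1 (pKa1 - pH))) +
#'  (fmax - fmed)/(1 + 10^(n2 (pKa2 - pH)))`.
#'
#' @param ph pH value(s).
#' @param params list with `model_kind` (`"one"`/`"two"`), `fmin`, `fmax`,
#'   `pka1`, `n1` and for two-site also `fmed`, `pka2`, `n2`.
#' @return numeric vector.
#' @export
ph_response <- function(ph, params) {
  if (identical(params$model_kind, "two")) {
    params$fmin +
      (params$fmed - params$fmin) / (1 + 10^(params$n1 * (params$pka1 - ph))) +
      (params$fmax - params$fmed) / (1 + 10^(params$n2 * (params$pka2 - ph)))
  } else {
    params$fmin +
      (params$fmax - params$fmin) / (1 + 10^(params$n1 * (params$pka1 - ph)))
  }
}

#' Simulate a pH titration series
#'
#' Intensities along a pH ladder from the model's one-site (calcium-free)
#' or two-site (calcium-bound) pH model.
#'
#' @param state `"apo"` or `"sat"`.
#' @param model a [default_sensor_model()].
#' @param ph_values pH grid within 2-11.
#' @param replicates replicate wells per pH.
#' @param noise a [noise_spec()].
#' @return data frame with columns `pH`, `replicate`, `intensity`.
#' @export
simulate_ph_series <- function(state = c("apo", "sat"),
                               model = default_sensor_model("in_situ"),
                               ph_values = seq(2.8, 10.0, length.out = 20),
                               replicates = 3, noise = noise_spec("none")) {
  state <- match.arg(state)
  if (any(ph_values < 2 | ph_values > 11)) stopf("pH values must be in 2-11")
  params <- if (state == "apo") model$ph_model_apo else model$ph_model_sat
  grid <- expand.grid(replicate = seq_len(replicates), pH = ph_values)
  y <- ph_response(grid$pH, params)
  y <- as.numeric(apply_noise(y, noise))
  data.frame(pH = grid$pH, replicate = grid$replicate, intensity = y)
}

#' Simulate a dilution-series spectra set for quantum-yield estimation
#'
#' Builds absorbance/emission spectrum pairs for a dilution series with
#' absorbance at 440 nm inside the low-absorbance window (0.002-0.02) where
#' emission is linear in absorbance. Integrated emission is
#' `I_em = C QY A440` with a common instrument constant C, so the
#' through-origin slope of `I_em` on `A440` is proportional to the state's
#' quantum yield.
#'
#' @param state `"apo"`, `"sat"`, or `"reference"` (the mTurquoise2
#'   reference, QY 0.93).
#' @param model a [default_sensor_model()].
#' @param n_dilutions distinct A440 targets, spread over the window.
#' @param replicates spectra per dilution.
#' @param noise a [noise_spec()]; gaussian sd is applied as a relative
#'   perturbation of each dilution's absorbance and emission scale.
#' @return list of [spectral_record()] objects.
#' @export
simulate_spectra_set <- function(state = c("apo", "sat", "reference"),
                                 model = default_sensor_model("in_situ"),
                                 n_dilutions = 3, replicates = 3,
                                 noise = noise_spec("none")) {
  state <- match.arg(state)
  qy <- switch(state, apo = model$qy_apo, sat = model$qy_sat,
               reference = 0.93)
  lam_abs <- switch(state, apo = model$lambda_abs_apo,
                    sat = model$lambda_abs_sat, reference = 434)
  lam_em <- switch(state, apo = model$lambda_em_apo,
                   sat = model$lambda_em_sat, reference = 474)
  a440_targets <- seq(0.004, 0.016, length.out = n_dilutions)
  wl_abs <- 260:650
  wl_em <- seq(450, 650, by = 0.5)
  abs_shape <- exp(-((wl_abs - lam_abs) / 30)^2 / 2)
  abs_shape <- abs_shape / abs_shape[wl_abs == 440]
  em_shape <- exp(-((wl_em - lam_em) / 15)^2 / 2)
  em_area <- pracma::trapz(wl_em, em_shape)
  instrument_c <- 1e5   # emission counts per unit (QY x A440)
  recs <- list()
  k <- 0
  for (a440 in a440_targets) {
    for (r in seq_len(replicates)) {
      k <- k + 1
      scale <- 1
      if (noise$kind == "gaussian" && noise$gaussian_sd > 0) {
        seed_k <- if (is.null(noise$seed)) NULL else noise$seed + k
        scale <- 1 + with_seed(seed_k, rnorm(2, sd = noise$gaussian_sd))
      } else scale <- c(1, 1)
      a <- a440 * scale[1]
      recs[[k]] <- spectral_record(
        wavelength_nm = wl_abs,
        absorbance = abs_shape * a,
        em_wavelength_nm = wl_em,
        emission = em_shape * (instrument_c * qy * a * scale[2] / em_area))
    }
  }
  recs
}
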