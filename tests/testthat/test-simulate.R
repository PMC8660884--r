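test_that("packaged presets carry the sensor's tabulated properties", {
  m <- default_sensor_model("in_situ")
  expect_equal(m$binding$kd, 265)
  expect_equal(m$binding$n, 1.63)
  expect_equal(m$intensity_ratio_R, 3.02)
  v <- default_sensor_model("in_vitro")
  expect_equal(v$intensity_ratio_R, 3.51)
  expect_equal(c(v$tau_phi_apo, v$tau_mod_apo), c(1.40, 1.80))
  expect_equal(c(v$tau_phi_sat, v$tau_mod_sat), c(2.78, 3.01))
  expect_equal(v$intensity_binding$kd, 360)
  expect_equal(v$intensity_binding$n, 1.51)
  expect_equal(c(m$qy_apo, m$qy_sat), c(0.25, 0.75))
  expect_equal(c(m$eps440_apo, m$eps440_sat), c(30.6, 33.7))
  expect_equal(c(m$ph_model_apo$pka1, m$ph_model_apo$n1), c(4.36, 0.86))
  expect_equal(c(m$ph_model_sat$pka1, m$ph_model_sat$pka2), c(4.71, 5.91))
  expect_equal(c(m$ph_model_sat$n1, m$ph_model_sat$n2), c(0.70, 3.58))
  expect_equal(m$binding$fmin, 0)
  expect_equal(m$binding$fmax, 1)
  expect_error(default_sensor_model("nonsense"), "preset")
})

test_that("mono stack frame means follow the homodyne forward model", {
  cfg <- test_config()
  theta <- 2 * pi * (0:11) / 12
  m_inst <- cfg$excitation_modulation_depth * cfg$detection_modulation_depth
  # zero-lifetime limit: Phi = 0, M = 1
  s0 <- simulate_mono_stack(0, cfg, amplitude = 200, offset_background = 10,
                            dim = c(2, 2))
  expect_equal(s0$frames[, 1, 1], 200 * (1 + m_inst * cos(theta)) + 10,
               tolerance = 1e-12)
  # omega*tau = 1: phase pi/4, modulation m_inst/sqrt(2)
  w <- 2 * pi * 75.1e-3
  s1 <- demodulate(simulate_mono_stack(1 / w, cfg, dim = c(2, 2)))
  expect_equal(unname(s1$raw_phase[1, 1]), pi / 4, tolerance = 1e-12)
  expect_equal(unname((s1$ac / s1$dc)[1, 1]), m_inst / sqrt(2),
               tolerance = 1e-12)
})

test_that("DFT of the 4.05 ns reference sinusoid returns atan(1.9112)", {
  raw <- demodulate(simulate_mono_stack(4.05, test_config(), dim = c(2, 2)))
  expect_equal(unname(raw$raw_phase[1, 1]), atan(2 * pi * 75.1e-3 * 4.05),
               tolerance = 1e-12)
  expect_equal(unname(raw$raw_phase[1, 1]), 1.0886, tolerance = 1e-4)
})

test_that("noise-free simulators are bit-identical; seeded noise reproduces", {
  cfg <- test_config()
  a <- simulate_mono_stack(2, cfg, dim = px8)
  b <- simulate_mono_stack(2, cfg, dim = px8)
  expect_identical(a$frames, b$frames)
  n1 <- simulate_mono_stack(2, cfg, dim = px8,
                            noise = noise_spec("poisson", seed = 11))
  n2 <- simulate_mono_stack(2, cfg, dim = px8,
                            noise = noise_spec("poisson", seed = 11))
  expect_identical(n1$frames, n2$frames)
  n3 <- simulate_mono_stack(2, cfg, dim = px8,
                            noise = noise_spec("poisson", seed = 12))
  expect_false(identical(n1$frames, n3$frames))
})

test_that("noise-free mono stacks land on the universal semicircle", {
  cfg <- test_config()
  ref <- demodulate(simulate_mono_stack(4.05, cfg, dim = c(2, 2)))
  for (tau in c(0.086, 0.4, 1.4, 2.78, 4.05, 9)) {
    raw <- demodulate(simulate_mono_stack(tau, cfg, dim = c(2, 2)))
    ph <- reference_calibrate(raw, ref, 4.05)
    expect_lt(max(abs((ph$g - 0.5)^2 + ph$s^2 - 0.25)), 1e-12)
  }
})

test_that("two-state stacks demodulate onto the chord between the anchors", {
  cfg <- test_config()
  model <- default_sensor_model("in_situ")
  anchors <- anchors_from_model(model, cfg)
  ref <- demodulate(simulate_mono_stack(4.05, cfg, dim = c(2, 2)))
  chord <- c(anchors$g_max - anchors$g_min, anchors$s_max - anchors$s_min)
  for (F in c(0.1, 0.25, 0.5, 0.9)) {
    smp <- demodulate(simulate_two_state_stack(model, cfg,
                                               fraction_bound = F,
                                               dim = c(2, 2)))
    ph <- reference_calibrate(smp, ref, 4.05)
    # collinearity: cross product of (P - apo) with the chord vanishes
    cross <- (ph$g - anchors$g_min) * chord[2] -
      (ph$s - anchors$s_min) * chord[1]
    expect_lt(max(abs(cross)), 1e-10)
  }
  # pure bound state sits exactly on the saturated anchor
  sat <- demodulate(simulate_two_state_stack(model, cfg, fraction_bound = 1,
                                             dim = c(2, 2)))
  ph1 <- reference_calibrate(sat, ref, 4.05)
  expect_equal(unname(ph1$g[1, 1]), anchors$g_max, tolerance = 1e-12)
  expect_equal(unname(ph1$s[1, 1]), anchors$s_max, tolerance = 1e-12)
})

test_that("occupancy at the Kd is one half; weights follow the R ratio", {
  model <- default_sensor_model("in_vitro")
  mix <- two_state_phasor(model, test_config(), free_ca = model$binding$kd)
  expect_equal(mix$fraction_bound, 0.5, tolerance = 1e-12)
  expect_equal(mix$line_fraction, 0.7783, tolerance = 1e-4)
  expect_error(two_state_phasor(model, test_config(), fraction_bound = 1.2),
               "\\[0, 1\\]")
  expect_error(two_state_phasor(model, test_config()), "exactly one")
})

test_that("free-calcium -> line-fraction map is a Hill curve with Kd R^(-1/n)", {
  model <- default_sensor_model("in_situ")
  cfg <- test_config()
  L <- c(0, exp(seq(log(10), log(50000), length.out = 15)))
  a <- two_state_phasor(model, cfg, free_ca = L)$line_fraction
  fit <- fit_hill(L, a)
  b <- model$binding
  expect_equal(coef(fit)[["kd"]],
               b$kd * model$intensity_ratio_R^(-1 / b$n), tolerance = 1e-5)
  expect_equal(coef(fit)[["n"]], b$n, tolerance = 1e-5)
})

test_that("titration table follows the intensity-mode Hill curve exactly", {
  model <- default_sensor_model("in_vitro")
  tab <- simulate_titration_table(model, c(0, 360, 1e7), replicates = 1)
  b <- model$intensity_binding
  expect_equal(tab$intensity[tab$concentration_nM == 0], b$fmin)
  expect_equal(tab$intensity[tab$concentration_nM == 360],
               (b$fmin + b$fmax) / 2, tolerance = 1e-6)
})

test_that("calibration experiment relaxes to the equilibrium phasor", {
  model <- default_sensor_model("in_situ")
  cfg <- test_config()
  # instant equilibration: all post-digitonin frames equal equilibrium
  ds <- simulate_calibration_experiment(c(0, 39000), model, cfg,
                                        replicates = 1, n_frames = 24,
                                        equilibration_rate = Inf)
  apo <- anchors_from_model(model, cfg)
  zero <- ds[ds$conc_nM == 0 & ds$time_s >= ds$digitonin_time_s, ]
  expect_equal(zero$G, rep(apo$g_min, nrow(zero)), tolerance = 1e-12)
  expect_equal(zero$S, rep(apo$s_min, nrow(zero)), tolerance = 1e-12)
  expect_error(simulate_calibration_experiment(numeric(0)), "empty")
  expect_error(simulate_calibration_experiment(0), "2 concentrations")
})

test_that("pH series and spectra sets follow their generating models", {
  model <- default_sensor_model("in_situ")
  apo <- model$ph_model_apo
  s <- simulate_ph_series("apo", model, ph_values = c(apo$pka1, 10),
                          replicates = 1)
  expect_equal(s$intensity[1], (apo$fmin + apo$fmax) / 2, tolerance = 1e-12)
  # high-pH plateau
  expect_equal(s$intensity[2], apo$fmax, tolerance = 1e-3)
  # slope ratio equals the quantum-yield ratio
  sat <- simulate_spectra_set("sat", model)
  ref <- simulate_spectra_set("reference", model)
  slope <- function(recs) {
    a <- vapply(recs, function(r) r$a440, numeric(1))
    i <- vapply(recs, function(r) r$i_em, numeric(1))
    sum(a * i) / sum(a^2)
  }
  expect_equal(slope(sat) / slope(ref), 0.75 / 0.93, tolerance = 1e-6)
  expect_equal(slope(sat) / slope(ref), 0.8065, tolerance = 1e-4)
  expect_error(simulate_ph_series("apo", model, ph_values = c(1, 7)), "2-11")
})
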