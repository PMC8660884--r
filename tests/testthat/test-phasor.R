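test_that("demodulation inverts a known sinusoid exactly", {
  for (K in c(3L, 12L)) {
    cfg <- test_config(n_phase_steps = K)
    theta <- 2 * pi * (seq_len(K) - 1) / K
    frames <- array(rep(100 * (1 + 0.5 * cos(theta - 0.6)), 4),
                    dim = c(K, 2, 2))
    raw <- demodulate(phase_stack(frames, cfg))
    expect_equal(unname(raw$dc[1, 1]), 100, tolerance = 1e-12)
    expect_equal(unname(raw$ac[1, 1] / raw$dc[1, 1]), 0.5,
                 tolerance = 1e-12)
    expect_equal(unname(raw$raw_phase[1, 1]), 0.6, tolerance = 1e-12)
  }
})

test_that("constant frames demodulate to zero ac and are flagged invalid", {
  cfg <- test_config()
  frames <- array(42, dim = c(12, 2, 2))
  raw <- demodulate(phase_stack(frames, cfg))
  expect_equal(unname(raw$dc[1, 1]), 42)
  expect_equal(unname(raw$ac[1, 1]), 0, tolerance = 1e-10)
  expect_false(any(raw$valid))
})

test_that("demodulate equals the brute-force least-squares oracle", {
  cfg <- test_config()
  stack <- simulate_mono_stack(2.2, cfg, amplitude = 500,
                               noise = noise_spec("poisson", seed = 7),
                               dim = px8)
  raw <- demodulate(stack)
  oracle <- demod_oracle(stack)
  expect_equal(raw$dc, oracle$dc, tolerance = 1e-9)
  expect_equal(raw$ac, oracle$ac, tolerance = 1e-9)
  expect_equal(raw$raw_phase, oracle$raw_phase, tolerance = 1e-9)
})

test_that("reference self-calibration returns the reference lifetime", {
  cfg <- test_config()
  for (tau_ref in c(4.05, 0.086)) {
    ref <- demodulate(simulate_mono_stack(tau_ref, cfg, dim = px8))
    lt <- phasor_to_lifetimes(reference_calibrate(ref, ref, tau_ref))
    expect_equal(mean(lt$tau_phi), tau_ref, tolerance = 1e-9)
    expect_equal(mean(lt$tau_mod), tau_ref, tolerance = 1e-9)
  }
})

test_that("pure-state stacks recover the sensor's lifetimes", {
  cfg <- test_config()
  model <- default_sensor_model("in_vitro")
  ref <- demodulate(simulate_mono_stack(4.05, cfg, dim = px8))
  apo <- demodulate(simulate_two_state_stack(model, cfg,
                                             fraction_bound = 0, dim = px8))
  lt <- phasor_to_lifetimes(reference_calibrate(apo, ref, 4.05))
  expect_equal(mean(lt$tau_phi), 1.40, tolerance = 1e-9)
  expect_equal(mean(lt$tau_mod), 1.80, tolerance = 1e-9)
  sat <- demodulate(simulate_two_state_stack(model, cfg,
                                             fraction_bound = 1, dim = px8))
  lt2 <- phasor_to_lifetimes(reference_calibrate(sat, ref, 4.05))
  expect_equal(mean(lt2$tau_phi), 2.78, tolerance = 1e-9)
  expect_equal(mean(lt2$tau_mod), 3.01, tolerance = 1e-9)
})

test_that("reference calibration removes instrument phase and modulation", {
  cfg <- test_config(detection_modulation_depth = 0.73)
  model <- default_sensor_model("in_situ")
  clean_cfg <- test_config(detection_modulation_depth = 0.9)
  target <- local({
    ref <- demodulate(simulate_mono_stack(4.05, clean_cfg, dim = px8))
    smp <- demodulate(simulate_two_state_stack(model, clean_cfg,
                                               fraction_bound = 0.4,
                                               dim = px8))
    ph <- reference_calibrate(smp, ref, 4.05)
    c(mean(ph$g), mean(ph$s))
  })
  for (inst_phase in c(-0.4, 0.25)) {
    ref <- demodulate(simulate_mono_stack(4.05, cfg, dim = px8,
                                          instrument_phase = inst_phase))
    smp <- demodulate(simulate_two_state_stack(model, cfg,
                                               fraction_bound = 0.4,
                                               dim = px8,
                                               instrument_phase = inst_phase))
    ph <- reference_calibrate(smp, ref, 4.05)
    expect_equal(c(mean(ph$g), mean(ph$s)), target, tolerance = 1e-10)
  }
})

test_that("background correction is exact for an additive uniform background", {
  cfg <- test_config()
  model <- default_sensor_model("in_situ")
  signal <- simulate_two_state_stack(model, cfg, fraction_bound = 0.3,
                                     dim = px8)
  bg <- simulate_mono_stack(0.5, cfg, amplitude = 300, dim = px8)
  combined <- phase_stack(signal$frames + bg$frames, cfg)
  # mark the left half as pure background by zeroing the signal there
  mixed <- combined$frames
  mixed[, , 1:4] <- bg$frames[, , 1:4]
  mask <- matrix(FALSE, 8, 8); mask[, 1:4] <- TRUE
  corrected <- background_correct(demodulate(phase_stack(mixed, cfg)), mask)
  pure <- demodulate(signal)
  sel <- !mask & corrected$valid
  expect_true(any(sel))
  z_c <- complex(modulus = corrected$ac, argument = corrected$raw_phase)
  z_p <- complex(modulus = pure$ac, argument = pure$raw_phase)
  expect_lt(max(Mod(z_c - z_p)[sel]), 1e-10)
  expect_lt(max(abs(corrected$dc - pure$dc)[sel]), 1e-10)
})

test_that("background correction degenerate cases", {
  cfg <- test_config()
  raw <- demodulate(simulate_mono_stack(2, cfg, dim = px8))
  expect_error(background_correct(raw, matrix(FALSE, 8, 8)), "no pixels")
  # zero-count background region leaves the image unchanged
  frames <- simulate_mono_stack(2, cfg, dim = px8)$frames
  frames[, , 1] <- 0
  raw2 <- demodulate(phase_stack(frames, cfg))
  mask <- matrix(FALSE, 8, 8); mask[, 1] <- TRUE
  corr <- background_correct(raw2, mask)
  expect_equal(corr$dc[, -1], raw2$dc[, -1], tolerance = 1e-12)
  expect_equal(corr$ac[, -1], raw2$ac[, -1], tolerance = 1e-12)
  # over-subtraction flags pixels with nonpositive dc as invalid
  mask_sig <- matrix(FALSE, 8, 8); mask_sig[, 2:8] <- TRUE
  corr2 <- background_correct(raw2, mask_sig)
  expect_false(any(corr2$valid[, 1]))
})

test_that("lifetime/phasor conversions match hand-evaluated values", {
  expect_equal(lifetimes_to_phasor(0, 0, 75.1), list(g = 1, s = 0))
  w <- 2 * pi * 75.1e-3
  p <- lifetimes_to_phasor(1 / w, 1 / w, 75.1)
  expect_equal(p$g, 0.5, tolerance = 1e-12)
  expect_equal(p$s, 0.5, tolerance = 1e-12)
  apo <- lifetimes_to_phasor(1.40, 1.80, 75.1)
  expect_equal(c(apo$g, apo$s), c(0.636, 0.420), tolerance = 1e-3)
  sat <- lifetimes_to_phasor(2.78, 3.01, 75.1)
  expect_equal(c(sat$g, sat$s), c(0.349, 0.458), tolerance = 2e-3)
})

test_that("phasor -> lifetime round trip is the identity on (0, 20] ns", {
  cfg <- test_config()
  taus <- expand.grid(tp = c(0.086, 0.5, 1.4, 2.78, 4.05, 12, 20),
                      tm = c(0.086, 0.5, 1.8, 3.01, 4.05, 12, 20))
  taus <- taus[taus$tp <= taus$tm, ]   # physical mixtures have tau_phi <= tau_mod
  p <- lifetimes_to_phasor(taus$tp, taus$tm, 75.1)
  ph <- phasor_image(g = matrix(p$g), s = matrix(p$s),
                     intensity = matrix(1, length(p$g)), config = cfg)
  lt <- phasor_to_lifetimes(ph)
  expect_equal(as.numeric(lt$tau_phi), taus$tp, tolerance = 1e-10)
  expect_equal(as.numeric(lt$tau_mod), taus$tm, tolerance = 1e-10)
})

test_that("tau_phi <= tau_mod for noise-free two-state mixtures", {
  cfg <- test_config()
  model <- default_sensor_model("in_situ")
  ref <- demodulate(simulate_mono_stack(4.05, cfg, dim = c(2, 2)))
  for (F in seq(0, 1, by = 0.1)) {
    smp <- demodulate(simulate_two_state_stack(model, cfg,
                                               fraction_bound = F,
                                               dim = c(2, 2)))
    lt <- phasor_to_lifetimes(reference_calibrate(smp, ref, 4.05))
    expect_true(all(lt$tau_phi <= lt$tau_mod + 1e-12))
  }
})

test_that("intensity mask is a strict threshold", {
  img <- matrix(c(999, 1000, 1001, 5), 2, 2)
  expect_equal(intensity_mask(img, 1000),
               matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2))
  expect_true(all(intensity_mask(img, 0)))
  expect_false(any(intensity_mask(matrix(7, 3, 3), 7)))
  expect_error(intensity_mask(img, -1), ">= 0")
})

test_that("demodulation rejects underdetermined stacks", {
  expect_error(instrument_config(n_phase_steps = 2), "3")
})
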