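#' A corrected absorbance/emission spectrum pair
#'
#' Applies the standard spectro-assay corrections and summary quantities:
#' the absorbance spectrum is offset-corrected by subtracting its mean over
#' 631-650 nm, `a440` is the corrected absorbance at 440 nm, and `i_em` is
#' the trapezoidal integral of the (optionally detector-corrected) emission
#' spectrum over 450-650 nm.
#'
#' @param wavelength_nm absorbance wavelength grid, nm.
#' @param absorbance absorbance values on that grid.
#' @param em_wavelength_nm emission wavelength grid, nm.
#' @param emission emission counts on that grid.
#' @param detector_correction optional per-wavelength sensitivity curve
#'   (same length as `em_wavelength_nm`) multiplied into the emission
#'   before integration; identity by default.
#' @return an object of class `"spectral_record"` with the corrected
#'   spectra plus `a440` and `i_em`.
#' @export
spectral_record <- function(wavelength_nm, absorbance,
                            em_wavelength_nm, emission,
                            detector_correction = NULL) {
  off_sel <- wavelength_nm >= 631 & wavelength_nm <= 650
  offset <- if (any(off_sel)) mean(absorbance[off_sel]) else 0
  abs_corr <- absorbance - offset
  a440 <- approx(wavelength_nm, abs_corr, xout = 440)$y
  em <- if (is.null(detector_correction)) emission
        else emission * detector_correction
  int_sel <- em_wavelength_nm >= 450 & em_wavelength_nm <= 650
  i_em <- pracma::trapz(em_wavelength_nm[int_sel], em[int_sel])
  structure(list(wavelength_nm = wavelength_nm, absorbance = abs_corr,
                 em_wavelength_nm = em_wavelength_nm, emission = em,
                 a440 = a440, i_em = i_em),
            class = "spectral_record")
}

#' @export
print.spectral_record <- function(x, ...) {
  cat(sprintf("Spectral record: A440 = %.4g, I_em(450-650) = %.4g\n",
              x$a440, x$i_em))
  invisible(x)
}

# through-origin least-squares slope of I_em on A440
origin_slope <- function(records) {
  a <- vapply(records, function(r) r$a440, numeric(1))
  i <- vapply(records, function(r) r$i_em, numeric(1))
  if (sum(a^2) == 0 || length(unique(signif(a, 12))) < 2)
    stopf("rank-deficient dilution series: A440 values do not vary")
  sum(a * i) / sum(a^2)
}

#' Relative quantum yield from dilution-series spectra
#'
#' For each series the through-origin least-squares slope s of integrated
#' emission on A440 is computed; the sample's quantum yield is
#' `QY_s = QY_r * s_s / s_r` relative to a reference fluorophore of known
#' quantum yield (mTurquoise2, QY 0.93, by default). Valid only in the
#' low-absorbance window 0.002 < A440 < 0.02 where emission is linear in
#' absorbance; records outside the window trigger a warning.
#'
#' @param sample_records list of [spectral_record()]s of the sample (>= 3,
#'   spanning distinct A440).
#' @param reference_records matching reference series.
#' @param qy_reference quantum yield of the reference.
#' @return the sample quantum yield (scalar in (0, 1] for real
#'   fluorophores).
#' @export
quantum_yield <- function(sample_records, reference_records,
                          qy_reference = 0.93) {
  for (recs in list(sample_records, reference_records)) {
    if (length(recs) < 3) stopf("need >= 3 records per series")
    a <- vapply(recs, function(r) r$a440, numeric(1))
    if (any(a <= 0.002 | a >= 0.02))
      warning("A440 outside the linear window (0.002, 0.02)", call. = FALSE)
  }
  qy_reference * origin_slope(sample_records) /
    origin_slope(reference_records)
}

#' Extinction coefficient via alkali denaturation
#'
#' NaOH denaturation frees the chromophore, whose extinction coefficient
#' at its 462 nm alkaline peak is known (46 mM^-1 cm^-1 for the cyan
#' chromophore). Beer-Lambert gives the chromophore concentration from the
#' denatured absorbance, and the native extinction coefficient at 440 nm
#' follows: `eps440 = eps_denatured * A440_native / A462_denatured`.
#'
#' @param a440_native absorbance of the native protein at 440 nm.
#' @param a462_denatured absorbance of the denatured sample at 462 nm
#'   (> 0).
#' @param eps_denatured chromophore extinction coefficient, mM^-1 cm^-1.
#' @param path_cm cuvette path length, cm.
#' @return extinction coefficient at 440 nm, mM^-1 cm^-1.
#' @export
extinction_coefficient <- function(a440_native, a462_denatured,
                                   eps_denatured = 46, path_cm = 1) {
  if (any(a462_denatured <= 0)) stopf("denatured absorbance must be > 0")
  conc_mM <- a462_denatured / (eps_denatured * path_cm)
  a440_native / (conc_mM * path_cm)
}

#' Fit a one- or two-site pH model
#'
#' Bounded nonlinear least squares of the Henderson-Hasselbalch-type
#' models of [ph_response()] to a pH titration. Following the plate-assay
#' convention, `fmin` is restricted to `<= 0`. The two-site fit multistarts
#' over a grid of pKa pairs (ordering enforced by parameterizing the second
#' transition as `pka2 = pka1 + dpka`, `dpka > 0`) and keeps the best
#' converged fit.
#'
#' @param series data frame with columns `pH` and `intensity` (e.g. from
#'   [simulate_ph_series()]); >= 6 pH points spanning the transition(s).
#' @param model_kind `"one"` or `"two"`.
#' @param n_starts multistart attempts for the two-site model.
#' @return an object of class `"ph_fit"`: coefficients (`fmin`, `fmax`,
#'   `pka1`, `n1`, plus `fmed`, `pka2`, `n2` for two-site), diagnostics and
#'   the winning `nls` object.
#' @export
fit_ph <- function(series, model_kind = c("one", "two"), n_starts = 20) {
  model_kind <- match.arg(model_kind)
  dat <- data.frame(ph = series$pH, y = series$intensity)
  if (length(unique(dat$ph)) < 6) stopf("need >= 6 distinct pH points")
  if (diff(range(dat$y)) <= .Machine$double.eps^0.5 * max(1, abs(mean(dat$y))))
    stopf("degenerate response: intensity is constant")
  ymax <- max(dat$y)
  # port reports "false convergence" on exactly-fitting data; run with
  # warnOnly from several starts and keep the lowest-SSR fit
  best_of <- function(formula, starts, lower, upper) {
    best <- NULL; best_ssr <- Inf
    for (st in starts) {
      fit_j <- tryCatch(
        suppressWarnings(
          nls(formula, data = dat, start = st,
              lower = lower, upper = upper, algorithm = "port",
              control = list(maxiter = 500, warnOnly = TRUE))),
        error = function(e) NULL)
      if (!is.null(fit_j)) {
        ssr <- sum(residuals(fit_j)^2)
        if (ssr < best_ssr) { best <- fit_j; best_ssr <- ssr }
      }
    }
    best
  }
  if (model_kind == "one") {
    lower <- c(fmin = -Inf, fmax = -Inf, pka1 = 2, n1 = 0.1)
    upper <- c(fmin = 0, fmax = Inf, pka1 = 11, n1 = 10)
    # crude pKa guess: pH of half rise
    half <- min(dat$y) + diff(range(dat$y)) / 2
    pka0 <- dat$ph[which.min(abs(dat$y - half))]
    starts <- lapply(unique(c(pka0, 3, 5, 7, 9)), function(p)
      list(fmin = min(0, min(dat$y)), fmax = ymax, pka1 = p, n1 = 1))
    fit <- best_of(y ~ fmin + (fmax - fmin) / (1 + 10^(n1 * (pka1 - ph))),
                   starts, lower, upper)
    if (is.null(fit)) stopf("one-site pH fit did not converge from any start")
    cf <- coef(fit)[c("fmin", "fmax", "pka1", "n1")]
  } else {
    lower <- c(fmin = -Inf, fmed = -Inf, fmax = -Inf,
               pka1 = 2, n1 = 0.1, dpka = 0.05, n2 = 0.1)
    upper <- c(fmin = 0, fmed = Inf, fmax = Inf,
               pka1 = 11, n1 = 10, dpka = 9, n2 = 10)
    grid <- expand.grid(pka1 = seq(3, 7, length.out = 5),
                        dpka = c(0.5, 1, 2, 3))
    grid <- grid[seq_len(min(nrow(grid), n_starts)), ]
    starts <- lapply(seq_len(nrow(grid)), function(j)
      list(fmin = min(0, min(dat$y)), fmed = ymax / 3, fmax = ymax,
           pka1 = grid$pka1[j], n1 = 1, dpka = grid$dpka[j], n2 = 1))
    fit <- best_of(
      y ~ fmin + (fmed - fmin) / (1 + 10^(n1 * (pka1 - ph))) +
        (fmax - fmed) / (1 + 10^(n2 * (pka1 + dpka - ph))),
      starts, lower, upper)
    if (is.null(fit)) stopf("two-site pH fit did not converge from any start")
    cfr <- coef(fit)
    cf <- c(fmin = unname(cfr["fmin"]), fmed = unname(cfr["fmed"]),
            fmax = unname(cfr["fmax"]),
            pka1 = unname(cfr["pka1"]), n1 = unname(cfr["n1"]),
            pka2 = unname(cfr["pka1"] + cfr["dpka"]),
            n2 = unname(cfr["n2"]))
  }
  ssr <- sum(residuals(fit)^2)
  # an exact fit can trip port's "false convergence"; count it as converged
  structure(list(coefficients = cf, model_kind = model_kind,
                 residual_norm = sqrt(ssr),
                 converged = fit$convInfo$isConv ||
                   ssr <= 1e-12 * sum(dat$y^2),
                 data = dat, nls = fit),
            class = "ph_fit")
}

#' @export
coef.ph_fit <- function(object, ...) object$coefficients

#' @export
print.ph_fit <- function(x, digits = 4, ...) {
  cf <- coef(x)
  cat(sprintf("%s-site pH model fit\n",
              if (x$model_kind == "one") "One" else "Two"))
  cat(sprintf("  pKa1 = %s [n1 = %s]\n",
              signif(cf["pka1"], digits), signif(cf["n1"], digits)))
  if (x$model_kind == "two")
    cat(sprintf("  pKa2 = %s [n2 = %s]\n",
                signif(cf["pka2"], digits), signif(cf["n2"], digits)))
  cat(sprintf("  residual norm %.3g; converged: %s\n",
              x$residual_norm, x$converged))
  invisible(x)
}

#' @export
predict.ph_fit <- function(object, newdata = NULL, ...) {
  ph <- if (is.null(newdata)) object$data$ph
        else if (is.list(newdata)) newdata$ph else newdata
  cf <- as.list(coef(object))
  cf$model_kind <- object$model_kind
  ph_response(ph, cf)
}

#' @export
residuals.ph_fit <- function(object, ...) as.numeric(residuals(object$nls))

#' @export
plot.ph_fit <- function(x, ...) {
  plot(x$data$ph, x$data$y, xlab = "pH", ylab = "intensity", ...)
  grid <- seq(min(x$data$ph), max(x$data$ph), length.out = 200)
  lines(grid, predict(x, grid))
  invisible(x)
}

#' Dynamic-range curve from two pH models
#'
#' Ratio of the calcium-bound over the calcium-free pH model on a pH grid
#' -- the intensity contrast available at each pH.
#'
#' @param fit_sat,fit_apo `"ph_fit"` objects or parameter lists accepted by
#'   [ph_response()].
#' @param ph_grid pH values to evaluate.
#' @return data frame with columns `pH` and `dynamic_range`.
#' @export
dynamic_range_curve <- function(fit_sat, fit_apo,
                                ph_grid = seq(3, 10, by = 0.05)) {
  eval_model <- function(m, ph) {
    if (inherits(m, "ph_fit")) predict(m, ph) else ph_response(ph, m)
  }
  data.frame(pH = ph_grid,
             dynamic_range = eval_model(fit_sat, ph_grid) /
               eval_model(fit_apo, ph_grid))
}

#' Magnesium sensitivity as bound/free dynamic-range ratios
#'
#' Per magnesium level, mean intensity of the calcium-bound state divided
#' by the calcium-free state, with a delta-method standard deviation from
#' the replicate spread.
#'
#' @param table data frame with columns `mg_mM`, `state` (`"bound"` or
#'   `"free"`) and `intensity` (replicates per level and state).
#' @return data frame with columns `mg_mM`, `dynamic_range`, `sd`.
#' @export
magnesium_dynamic_range <- function(table) {
  stopifnot(all(c("mg_mM", "state", "intensity") %in% names(table)))
  levels_mg <- sort(unique(table$mg_mM))
  out <- lapply(levels_mg, function(mg) {
    b <- table$intensity[table$mg_mM == mg & table$state == "bound"]
    f <- table$intensity[table$mg_mM == mg & table$state == "free"]
    if (length(b) == 0 || length(f) == 0)
      stopf("unpaired measurements at Mg = %g mM", mg)
    mb <- mean(b); mf <- mean(f)
    if (mf == 0) stopf("zero free-state mean at Mg = %g mM", mg)
    se_b <- if (length(b) > 1) sd(b) / sqrt(length(b)) else 0
    se_f <- if (length(f) > 1) sd(f) / sqrt(length(f)) else 0
    data.frame(mg_mM = mg, dynamic_range = mb / mf,
               sd = abs(mb / mf) * sqrt((se_b / mb)^2 + (se_f / mf)^2))
  })
  do.call(rbind, out)
}

#' Plate-reader normalization and intensity fold-change
#'
#' Screening-plate convention: background (clear medium) is subtracted and
#' intensities are divided by an Erythrosin B reference well, then the
#' fold-change is the series maximum over the first read of the same well.
#' A well whose first normalized read is not positive (background-only)
#' gets `fold_change = NA` with a `defined` flag of `FALSE`.
#'
#' @param intensity raw intensity series of the well (first element = first
#'   read).
#' @param eb_intensity Erythrosin B reference-well intensity.
#' @param background background (clear medium) intensity.
#' @return list with `normalized` (series), `fold_change` and `defined`.
#' @export
plate_normalize_and_fold_change <- function(intensity, eb_intensity,
                                            background = 0) {
  if (eb_intensity <= background)
    stopf("EB reference intensity must exceed background")
  normalized <- (intensity - background) / eb_intensity
  defined <- is.finite(normalized[1]) && normalized[1] > 0
  fold <- if (defined) max(normalized) / normalized[1] else NA_real_
  list(normalized = normalized, fold_change = fold, defined = defined)
}
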