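#' Hill binding model
#'
#' Evaluate the four-parameter Hill model
#' \deqn{f(L) = f_{min} + \frac{f_{max} - f_{min}}{(K_d/L)^n + 1}}
#' The singular form at \eqn{L = 0} is replaced by its limit
#' \eqn{f(0) = f_{min}}.
#'
#' @param L ligand (free calcium) concentration, nM; vector, `L >= 0`.
#' @param fmin,fmax response at zero ligand and at saturation.
#' @param kd midpoint concentration, nM (> 0).
#' @param n Hill coefficient (> 0).
#' @return numeric vector of responses.
#' @seealso [fit_hill()], [hill_inverse()]
#' @export
hill_response <- function(L, fmin, fmax, kd, n) {
  out <- rep(fmin, length(L))
  pos <- !is.na(L) & L > 0
  out[pos] <- fmin + (fmax - fmin) / ((kd / L[pos])^n + 1)
  out[is.na(L)] <- NA_real_
  out
}

#' Invert the Hill model
#'
#' Solve \eqn{f(L) = y} for the ligand concentration:
#' \eqn{L = K_d / ((f_{max}-f_{min})/(y-f_{min}) - 1)^{1/n}}.
#' Responses at or outside the asymptotes return `NaN` (use the clamping in
#' [concentration_from_fraction()] for images).
#'
#' @param y response value(s).
#' @inheritParams hill_response
#' @return concentration(s), nM.
#' @export
hill_inverse <- function(y, fmin, fmax, kd, n) {
  p <- (y - fmin) / (fmax - fmin)
  out <- rep(NaN, length(y))
  ok <- !is.na(p) & p > 0 & p < 1
  out[ok] <- kd / ((1 / p[ok] - 1)^(1 / n))
  out[!is.na(p) & p <= 0] <- NaN
  out
}

#' Fit the Hill model to a titration
#'
#' Bounded nonlinear least squares (the `"port"` algorithm of [stats::nls()])
#' of the Hill model to responses versus ligand concentration. Used for every
#' titration-shaped fit in the package: well intensities, lifetimes, line
#' fractions and corrected bound fractions.
#'
#' Initialization: `kd` starts at the geometric mean of the positive
#' concentrations, `n` at 1, and `fmin`/`fmax` at the mean responses at the
#' lowest and highest concentration. Default bounds are
#' `kd` in `[min(x>0)/100, max(x)*100]` and `n` in `[0.1, 10]`. If the first
#' attempt does not converge, a small grid of `kd` starting values is tried.
#'
#' @param x concentrations, nM (>= 0); at least 4 distinct values.
#' @param y responses, same length as `x`.
#' @param bounds optional named list with `lower`/`upper` numeric vectors
#'   (names among `fmin`, `fmax`, `kd`, `n`) overriding the defaults.
#' @param init optional named numeric vector of starting values.
#' @return an object of class `"hill_fit"`: coefficients `fmin`, `fmax`,
#'   `kd`, `n`, plus fit diagnostics (`residual_norm`, `converged`) and the
#'   underlying `nls` object.
#' @examples
#' L <- c(0, 10^seq(1, 4, length.out = 10))
#' y <- hill_response(L, 0, 1, 265, 1.63)
#' fit <- fit_hill(L, y)
#' coef(fit)
#' @export
fit_hill <- function(x, y, bounds = NULL, init = NULL) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4L)
    stopf("need >= 4 distinct concentrations, got %d", length(unique(x)))
  if (diff(range(y)) <= .Machine$double.eps^0.5 * max(1, abs(mean(y))))
    stopf("degenerate response: y is constant")

  xp <- x[x > 0]
  kd0 <- exp(mean(log(xp)))
  start <- c(
    fmin = mean(y[x == min(x)]),
    fmax = mean(y[x == max(x)]),
    kd   = kd0,
    n    = 1
  )
  lower <- c(fmin = -Inf, fmax = -Inf, kd = min(xp) / 100, n = 0.1)
  upper <- c(fmin = Inf, fmax = Inf, kd = max(xp) * 100, n = 10)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  if (!is.null(init)) start[names(init)] <- init
  start <- pmin(pmax(start, lower), upper)

  dat <- data.frame(x = x, y = y)
  # port can stop with "false convergence" at a perfectly good optimum;
  # run with warnOnly over a few kd starts and keep the lowest SSR
  try_fit <- function(st) {
    tryCatch(
      suppressWarnings(
        nls(y ~ hill_response(x, fmin, fmax, kd, n),
            data = dat, start = as.list(st),
            lower = lower, upper = upper, algorithm = "port",
            control = list(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL
    )
  }
  kd_starts <- unique(c(start["kd"],
                        exp(seq(log(min(xp)), log(max(xp)),
                                length.out = 5))))
  fit <- NULL; best_ssr <- Inf
  for (kd_try in kd_starts) {
    st <- start; st["kd"] <- kd_try
    fit_j <- try_fit(st)
    if (!is.null(fit_j)) {
      ssr <- sum(residuals(fit_j)^2)
      if (ssr < best_ssr) { fit <- fit_j; best_ssr <- ssr }
      if (fit_j$convInfo$isConv && ssr <= best_ssr) break
    }
  }
  if (is.null(fit))
    stopf("Hill fit did not converge from any starting value")

  cf <- coef(fit)
  # stop codes 7/8 flag singular/false convergence, which at an interior
  # optimum of an exactly- or near-exactly-fitting model is still a
  # solution; record the solver message alongside
  structure(list(
    coefficients = cf[c("fmin", "fmax", "kd", "n")],
    residual_norm = sqrt(best_ssr),
    converged = fit$convInfo$isConv || fit$convInfo$stopCode %in% c(7L, 8L),
    convergence_message = fit$convInfo$stopMessage,
    fitted.values = fitted(fit),
    residuals = as.numeric(residuals(fit)),
    data = dat,
    nls = fit
  ), class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  cf <- coef(x)
  cat("Hill fit: f(L) = fmin + (fmax - fmin) / ((Kd/L)^n + 1)\n")
  cat(sprintf("  Kd = %s nM, n = %s, fmin = %s, fmax = %s\n",
              signif(cf["kd"], digits), signif(cf["n"], digits),
              signif(cf["fmin"], digits), signif(cf["fmax"], digits)))
  cat(sprintf("  residual norm %.3g on %d points; converged: %s\n",
              x$residual_norm, nrow(x$data), x$converged))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  s <- summary(object$nls)
  structure(list(coefficients = s$coefficients,
                 sigma = s$sigma,
                 residual_norm = object$residual_norm,
                 converged = object$converged),
            class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat("Hill model fit (bounded nonlinear least squares)\n")
  printCoefmat(x$coefficients)
  cat(sprintf("Residual standard error: %.4g\n", x$sigma))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  cf <- coef(object)
  L <- if (is.null(newdata)) object$data$x
       else if (is.list(newdata)) newdata$x else newdata
  hill_response(L, cf[["fmin"]], cf[["fmax"]], cf[["kd"]], cf[["n"]])
}

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
plot.hill_fit <- function(x, n_grid = 200, ...) {
  dat <- x$data
  xp <- dat$x[dat$x > 0]
  grid <- c(0, exp(seq(log(min(xp)), log(max(xp)), length.out = n_grid)))
  plot(pmax(dat$x, min(xp) / 3), dat$y, log = "x",
       xlab = "[Ca2+] (nM)", ylab = "response", ...)
  lines(pmax(grid, min(xp) / 3), predict(x, grid))
  invisible(x)
}
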