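#' Single-harmonic cosinor fit
#'
#' Least-squares fit of `y = M + a*cos(2*pi*t/T) + b*sin(2*pi*t/T)` at a
#' fixed trial period `T`. The mesor is the rhythm-adjusted mean `M`, the
#' amplitude is `sqrt(a^2 + b^2)` (half the fitted peak-to-trough), and the
#' acrophase is the time of the fitted maximum in `[0, T)`. Significance is
#' the F-test of the two harmonic terms against the intercept-only model.
#'
#' @param time sampling times in hours
#' @param y expression values (same length as `time`); replicated designs
#'   pass repeated time values
#' @param period trial period in hours (> 0)
#' @return an object of class `cosinor_fit` with elements `mesor`,
#'   `amplitude`, `amplitude_rel` (amplitude/mesor), `phase`, `period`, `p`,
#'   `coefficients`, `fitted`, `residuals`
#' @export
cosinor_fit <- function(time, y, period = 24) {
  stop_if_not(length(time) == length(y), "time and y lengths differ")
  stop_if_not(length(y) >= 4, "need at least 4 time points")
  stop_if_not(period > 0, "period must be positive")
  if (var(y) == 0) {
    return(structure(list(mesor = y[1], amplitude = 0, amplitude_rel = 0,
                          phase = 0, period = period, p = 1,
                          coefficients = c(mesor = y[1], a = 0, b = 0),
                          fitted = y, residuals = rep(0, length(y))),
                     class = "cosinor_fit"))
  }
  cw <- cos(2 * pi * time / period)
  sw <- sin(2 * pi * time / period)
  fit <- lm(y ~ cw + sw)
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  a <- cf[["cw"]]; b <- cf[["sw"]]
  amp <- sqrt(a^2 + b^2)
  # y = M + amp * cos(2*pi*(t - phase)/T) with phase from atan2(b, a)
  phase <- (atan2(b, a) * period / (2 * pi)) %% period
  rss1 <- sum(residuals(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  df2 <- length(y) - 3
  p <- if (df2 <= 0 || rss1 == 0) {
    if (rss1 < rss0) 0 else 1
  } else {
    f <- ((rss0 - rss1) / 2) / (rss1 / df2)
    pf(f, 2, df2, lower.tail = FALSE)
  }
  structure(list(mesor = unname(cf[1]), amplitude = unname(amp),
                 amplitude_rel = unname(if (cf[1] != 0) amp / abs(cf[1]) else NA_real_),
                 phase = unname(phase), period = period, p = unname(p),
                 coefficients = c(mesor = unname(cf[1]), a = a, b = b),
                 fitted = unname(fitted(fit)),
                 residuals = unname(residuals(fit))),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("cosinor fit (period %.1f h): mesor %.4g, amplitude %.4g, phase %.2f h, p = %.3g\n",
              x$period, x$mesor, x$amplitude, x$phase, x$p))
  invisible(x)
}

#' @export
coef.cosinor_fit <- function(object, ...) object$coefficients

#' @export
predict.cosinor_fit <- function(object, newtime = NULL, ...) {
  if (is.null(newtime)) return(object$fitted)
  object$mesor + object$amplitude *
    cos(2 * pi * (newtime - object$phase) / object$period)
}

#' @export
residuals.cosinor_fit <- function(object, ...) object$residuals
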