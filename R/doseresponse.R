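#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of
#' `v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`
#' with the IC50 estimated on the log10-dose axis. Initialization is
#' multi-start (a grid of Hill slopes and midpoint candidates refined by
#' Levenberg-Marquardt); the fit with the lowest residual sum of squares
#' wins. AUC is the mean fitted viability over the tested log-dose window
#' (the integral divided by the window width), which makes it invariant to
#' dose-unit rescaling and interpretable as a fraction between the
#' asymptotes. When no start converges the fit is flagged and the AUC falls
#' back to the trapezoid rule on the raw points.
#'
#' @param doses dose vector (> 0, at least 5 distinct levels spanning at
#'   least two decades)
#' @param viabilities viability fractions, same length as `doses`
#' @return an object of class `four_pl_fit`: top, bottom, ic50, hill, auc,
#'   rss, converged, extrapolated (IC50 outside 10x the dose range)
#' @export
fit_dose_response <- function(doses, viabilities) {
  stop_if_not(length(doses) == length(viabilities),
              "doses and viabilities lengths differ")
  stop_if_not(all(doses > 0), "doses must be positive")
  stop_if_not(length(unique(doses)) >= 5, "need at least 5 dose levels")
  stop_if_not(diff(range(log10(doses))) >= 2,
              "dose range must span at least 2 log10 units")
  x <- log10(doses); v <- viabilities
  xr <- range(x)

  fit4pl <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + 10^(hill * (x - m))),
        start = start,
        lower = c(top = -0.5, bottom = -0.5, m = xr[1] - 2, hill = 0.05),
        upper = c(top = 2, bottom = 2, m = xr[2] + 2, hill = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  t0 <- max(v); b0 <- min(v)
  mid <- (t0 + b0) / 2
  m0 <- x[which.min(abs(v - mid))]
  starts <- expand.grid(hill = c(0.5, 1, 2, 4),
                        m = unique(c(m0, mean(xr))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- fit4pl(list(top = t0, bottom = b0, m = starts$m[i],
                     hill = starts$hill[i]))
    if (!is.null(f)) {
      rss <- sum(residuals(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }

  if (is.null(best)) {
    ord <- order(x)
    auc <- sum(diff(x[ord]) * (v[ord][-1] + v[ord][-length(v)]) / 2) / diff(xr)
    return(structure(list(top = NA_real_, bottom = NA_real_,
                          ic50 = NA_real_, hill = NA_real_,
                          auc = auc, rss = NA_real_, converged = FALSE,
                          extrapolated = NA), class = "four_pl_fit"))
  }
  cf <- coef(best$fit)
  ic50 <- 10^cf[["m"]]
  f_curve <- function(z) cf[["bottom"]] +
    (cf[["top"]] - cf[["bottom"]]) / (1 + 10^(cf[["hill"]] * (z - cf[["m"]])))
  auc <- integrate(f_curve, xr[1], xr[2], rel.tol = 1e-9)$value / diff(xr)
  extrap <- ic50 < min(doses) / 10 || ic50 > max(doses) * 10
  structure(list(top = cf[["top"]], bottom = cf[["bottom"]], ic50 = ic50,
                 hill = cf[["hill"]], auc = auc, rss = best$rss,
                 converged = TRUE, extrapolated = extrap,
                 curve = f_curve, log10_window = xr),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("4PL fit: NOT converged; trapezoid AUC = %.4f\n", x$auc))
  } else {
    cat(sprintf("4PL fit: top %.3f, bottom %.3f, IC50 %.4g, hill %.3f, AUC %.4f%s\n",
                x$top, x$bottom, x$ic50, x$hill, x$auc,
                if (isTRUE(x$extrapolated)) " (IC50 extrapolated)" else ""))
  }
  invisible(x)
}

#' @export
coef.four_pl_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom,
    ic50 = object$ic50, hill = object$hill)
}

#' @export
predict.four_pl_fit <- function(object, doses, ...) {
  stop_if_not(object$converged, "fit did not converge")
  object$curve(log10(doses))
}

#' Temporal drug-efficacy statistics from a viability panel
#'
#' Fits a 4PL curve per (treatment time, replicate), collects the AUCs, and
#' tests for temporal variation in efficacy with a one-way ANOVA across
#' treatment times followed by Tukey's HSD. With a single replicate only
#' the AUC series is returned (ANOVA skipped with a warning).
#'
#' @param panel long data.frame with columns time_h, dose, viability,
#'   replicate (as produced by [generate_dose_response_panel()])
#' @param welch use Welch's ANOVA (unequal variances) instead of the
#'   classical one-way ANOVA
#' @return list with `auc` (data.frame time_h, replicate, auc, ic50,
#'   converged), `auc_mean` (named mean AUC per time), `anova` (`F`, `p`,
#'   df) or NULL, and `tukey` (pairwise table) or NULL
#' @export
temporal_efficacy <- function(panel, welch = FALSE) {
  need <- c("time_h", "dose", "viability", "replicate")
  stop_if_not(all(need %in% names(panel)),
              "panel must have columns %s", paste(need, collapse = ", "))
  stop_if_not(length(unique(panel$time_h)) >= 3, "need at least 3 time points")
  combos <- unique(panel[, c("time_h", "replicate")])
  fits <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- panel[panel$time_h == combos$time_h[i] &
                   panel$replicate == combos$replicate[i], ]
    f <- fit_dose_response(sub$dose, sub$viability)
    data.frame(time_h = combos$time_h[i], replicate = combos$replicate[i],
               auc = f$auc, ic50 = f$ic50, converged = f$converged)
  })
  auc <- do.call(rbind, fits)
  auc_mean <- tapply(auc$auc, auc$time_h, mean)
  n_rep <- max(panel$replicate)
  if (n_rep < 2) {
    warn_f("single replicate: ANOVA skipped, AUC series only")
    return(list(auc = auc, auc_mean = auc_mean, anova = NULL, tukey = NULL))
  }
  auc$time_f <- factor(auc$time_h)
  if (var(auc$auc) == 0) {
    # identical AUCs everywhere: no temporal signal at all
    an <- list(F = 0, p = 1, df = c(length(unique(auc$time_h)) - 1,
                                    nrow(auc) - length(unique(auc$time_h))))
    return(list(auc = auc, auc_mean = auc_mean, anova = an, tukey = NULL))
  }
  if (welch) {
    ow <- stats::oneway.test(auc ~ time_f, data = auc)
    an <- list(F = unname(ow$statistic), p = ow$p.value,
               df = unname(ow$parameter))
    tk <- NULL
  } else {
    fit <- aov(auc ~ time_f, data = auc)
    tab <- anova(fit)
    an <- list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
               df = tab$Df)
    tk <- as.data.frame(TukeyHSD(fit)$time_f)
    tk$pair <- rownames(tk)
    rownames(tk) <- NULL
  }
  list(auc = auc, auc_mean = auc_mean, anova = an, tukey = tk)
}

#' Amplitude of a temporal series
#'
#' Reports both the cosinor amplitude at a 24 h period (half the fitted
#' peak-to-trough) and the raw half peak-to-trough `(max - min) / 2`.
#'
#' @param time time points in hours (at least 4)
#' @param series values at those times
#' @return list with `amp_cosinor` and `amp_peak_trough`
#' @export
temporal_amplitude <- function(time, series) {
  stop_if_not(length(series) >= 4, "need at least 4 time points")
  fit <- cosinor_fit(time, series, period = 24)
  list(amp_cosinor = fit$amplitude,
       amp_peak_trough = (max(series) - min(series)) / 2)
}
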