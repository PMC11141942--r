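#' Generate a time-of-day dose-response viability panel
#'
#' For each treatment time a four-parameter-logistic viability curve is
#' sampled over the dose grid; the curve's IC50 oscillates with circadian
#' time as `ic50_mesor * (1 + ic50_rel_amp * cos(2*pi*(t - ic50_phase)/24))`,
#' emulating a drug whose potency is phase-locked to a rhythmic target. Noise
#' is additive Gaussian on the viability scale, truncated at 0.
#'
#' @param time_points treatment times in hours (default 7 points, 4 h apart)
#' @param doses dose grid (> 0, at least 5 levels; default 5-fold serial
#'   dilution over 9 levels around 1 uM)
#' @param ic50_mesor mean IC50 across the day (same unit as `doses`)
#' @param ic50_rel_amp relative IC50 amplitude, must be < 1 (an amplitude of
#'   1 or more would imply a non-positive IC50 at trough)
#' @param ic50_phase time of IC50 peak (hours); peak IC50 = least kill
#' @param hill Hill slope of the 4PL curve
#' @param top,bottom viability asymptotes
#' @param noise_sd additive Gaussian noise SD on viability
#' @param n_replicates replicates per (time, dose)
#' @param seed integer seed
#' @return a long data.frame with columns time_h, dose, viability, replicate,
#'   carrying the per-time true IC50 in attribute `"true_ic50"`
#' @export
generate_dose_response_panel <- function(time_points = seq(0, 24, by = 4),
                                         doses = 1e-3 * 5^(0:8),
                                         ic50_mesor = 1,
                                         ic50_rel_amp = 0.3,
                                         ic50_phase = 8,
                                         hill = 1,
                                         top = 1, bottom = 0,
                                         noise_sd = 0.02,
                                         n_replicates = 3,
                                         seed = 1L) {
  stop_if_not(all(doses > 0), "doses must be positive")
  stop_if_not(length(doses) >= 5, "need at least 5 dose levels")
  stop_if_not(abs(ic50_rel_amp) < 1,
              "ic50_rel_amp must be < 1 (IC50 would become non-positive)")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  true_ic50 <- ic50_mesor * (1 + ic50_rel_amp * cos(2 * pi * (time_points - ic50_phase) / 24))
  with_seed(substream_seed(seed, "doseresponse"), {
    rows <- do.call(rbind, lapply(seq_along(time_points), function(i) {
      v <- four_pl(doses, top = top, bottom = bottom,
                   ic50 = true_ic50[i], hill = hill)
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        data.frame(time_h = time_points[i], dose = doses,
                   viability = v, replicate = r)
      }))
    }))
    if (noise_sd > 0)
      rows$viability <- pmax(0, rows$viability + rnorm(nrow(rows), 0, noise_sd))
    attr(rows, "true_ic50") <- setNames(true_ic50, time_points)
    rows
  })
}

# 4PL viability: decreasing in dose for hill > 0.
four_pl <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}
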