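#' Synthetic temporal-expression configuration
#'
#' Defines the study design the generator emulates: a short circadian
#' time-course (default 7 points, 4 h apart, spanning 24 h) of TPM-scale
#' expression, a fraction of genes oscillating with ~24 h period, a
#' 15-gene core clock panel with fixed canonical phases, an optional set of
#' clock-coupled genes, and multiplicative lognormal measurement noise.
#'
#' @param n_genes number of background genes (clock panel is appended)
#' @param time_points sampling times in hours (strictly increasing)
#' @param n_replicates replicates per time point (share the true waveform)
#' @param frac_rhythmic fraction of background genes that oscillate
#' @param period_h true oscillation period in hours
#' @param amplitude_rel length-2 bounds of the relative-amplitude uniform
#'   distribution (amplitude as a fraction of the mesor); must be > 0
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise (0 = noiseless)
#' @param n_clock_genes size of the clock panel (default 15)
#' @param n_coupled_genes number of rhythmic background genes constructed as
#'   clock-coupled (sample correlation with their partner clock gene equals
#'   `coupling_strength` exactly when `noise_cv = 0`)
#' @param coupling_strength target |Pearson r| for coupled genes, in (0, 1]
#' @param seed integer seed; identical seeds give bit-identical output
#' @return a `synth_config` list
#' @export
synth_config <- function(n_genes = 1000,
                         time_points = seq(0, 24, by = 4),
                         n_replicates = 1,
                         frac_rhythmic = 0.2,
                         period_h = 24,
                         amplitude_rel = c(0.2, 0.8),
                         noise_cv = 0.1,
                         n_clock_genes = 15,
                         n_coupled_genes = 0,
                         coupling_strength = 0.8,
                         seed = 1L) {
  stop_if_not(is_count(n_genes), "n_genes must be a non-negative integer")
  stop_if_not(!is.unsorted(time_points, strictly = TRUE),
              "time_points must be strictly increasing")
  stop_if_not(frac_rhythmic >= 0 && frac_rhythmic <= 1,
              "frac_rhythmic must be in [0, 1]")
  stop_if_not(noise_cv >= 0, "noise_cv must be >= 0")
  stop_if_not(period_h > 0, "period_h must be positive")
  if (length(amplitude_rel) == 1) amplitude_rel <- rep(amplitude_rel, 2)
  stop_if_not(all(amplitude_rel > 0) && amplitude_rel[1] <= amplitude_rel[2],
              "amplitude_rel bounds must be positive and ordered (rhythmic genes need amplitude > 0)")
  stop_if_not(is_count(n_clock_genes) && n_clock_genes <= 15,
              "n_clock_genes must be an integer in [0, 15]")
  stop_if_not(abs(coupling_strength) <= 1 && coupling_strength != 0,
              "coupling_strength must be in [-1, 1], non-zero")
  n_rhythmic <- round(frac_rhythmic * n_genes)
  stop_if_not(n_coupled_genes <= n_rhythmic,
              "n_coupled_genes (%d) exceeds the rhythmic gene count (%d)",
              n_coupled_genes, n_rhythmic)
  if (n_coupled_genes > 0)
    stop_if_not(n_clock_genes > 0, "coupled genes require a clock panel")
  structure(list(n_genes = as.integer(n_genes),
                 time_points = as.numeric(time_points),
                 n_replicates = as.integer(n_replicates),
                 frac_rhythmic = frac_rhythmic,
                 period_h = period_h,
                 amplitude_rel = amplitude_rel,
                 noise_cv = noise_cv,
                 n_clock_genes = as.integer(n_clock_genes),
                 n_coupled_genes = as.integer(n_coupled_genes),
                 coupling_strength = coupling_strength,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Canonical clock panel: the 15 genes of the transcriptional/translational
# feedback loop, with peak phases (CT hours) fixed so that activators
# (BMAL1/CLOCK arm) sit roughly antiphase to the PER/CRY repressor arm.
clock_panel <- function(n = 15) {
  genes <- c(ARNTL = 22, CLOCK = 23, NPAS2 = 22, NR1D1 = 4, NR1D2 = 5,
             RORA = 18, RORB = 19, RORC = 17, PER1 = 9, PER2 = 10,
             PER3 = 11, CRY1 = 12, CRY2 = 10, DBP = 10, NFIL3 = 22)
  genes[seq_len(n)]
}

cosine_wave <- function(t, mesor, amp_rel, phase, period) {
  mesor * (1 + amp_rel * cos(2 * pi * (t - phase) / period))
}

# Exact cosinor projection of a deterministic harmonic series: returns the
# amplitude (relative to mesor) and peak phase implied by the sample values.
harmonic_truth <- function(t, y, period) {
  X <- cbind(1, cos(2 * pi * t / period), sin(2 * pi * t / period))
  cf <- qr.solve(X, y)
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  phase <- (atan2(cf[3], cf[2]) * period / (2 * pi)) %% period
  list(mesor = cf[1], amp_rel = amp / cf[1], phase = phase)
}

#' Generate a synthetic temporal expression matrix with ground truth
#'
#' Rhythmic genes follow `mesor * (1 + A * cos(2*pi*(t - phase)/period))`
#' with phases uniform on the clock face and amplitudes drawn from the
#' configured bounds; non-rhythmic genes are flat at their mesor. The clock
#' panel oscillates at fixed canonical phases. Clock-coupled genes are built
#' as affine combinations of their partner clock gene's noiseless waveform
#' and an orthogonal harmonic, so their sample Pearson correlation with the
#' partner equals `coupling_strength` exactly in the noiseless limit
#' (alternating sign). All genes receive multiplicative lognormal noise with
#' unit mean and coefficient of variation `noise_cv`; values are therefore
#' non-negative by construction.
#'
#' @param config a [synth_config()]
#' @return list with `matrix` (a [temporal_matrix()]) and `truth`, a
#'   data.frame with columns gene, is_rhythmic, true_phase, true_amplitude,
#'   coupled_clock_gene, true_coupling_sign
#' @export
generate_temporal_matrix <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  t_one <- cfg$time_points
  t_all <- rep(t_one, cfg$n_replicates)
  rep_idx <- rep(seq_len(cfg$n_replicates), each = length(t_one))

  with_seed(substream_seed(cfg$seed, "synthdata"), {
    n_bg <- cfg$n_genes
    n_r <- round(cfg$frac_rhythmic * n_bg)
    n_cp <- cfg$n_coupled_genes
    ids <- sprintf("G%05d", seq_len(n_bg))
    clock <- clock_panel(cfg$n_clock_genes)
    clock_amp <- mean(cfg$amplitude_rel)

    mesor <- rlnorm(n_bg + cfg$n_clock_genes, meanlog = log(50), sdlog = 0.8)
    phase <- runif(n_bg, 0, cfg$period_h)
    amp <- runif(n_bg, cfg$amplitude_rel[1], cfg$amplitude_rel[2])

    truth <- data.frame(gene = c(ids, names(clock)),
                        is_rhythmic = FALSE, true_phase = NA_real_,
                        true_amplitude = NA_real_,
                        coupled_clock_gene = NA_character_,
                        true_coupling_sign = "none",
                        stringsAsFactors = FALSE)

    base <- matrix(0, n_bg + cfg$n_clock_genes, length(t_one),
                   dimnames = list(truth$gene, NULL))
    # clock panel waveforms (noiseless reference used for coupling)
    clock_wave <- matrix(0, cfg$n_clock_genes, length(t_one),
                         dimnames = list(names(clock), NULL))
    for (j in seq_along(clock)) {
      mj <- mesor[n_bg + j]
      clock_wave[j, ] <- cosine_wave(t_one, mj, clock_amp, clock[j], cfg$period_h)
      base[n_bg + j, ] <- clock_wave[j, ]
      k <- n_bg + j
      truth$is_rhythmic[k] <- TRUE
      truth$true_phase[k] <- clock[j] %% cfg$period_h
      truth$true_amplitude[k] <- clock_amp
    }

    rhythmic_idx <- seq_len(n_r)
    coupled_idx <- seq_len(n_cp)
    for (i in seq_len(n_bg)) {
      if (i %in% coupled_idx) {
        j <- ((i - 1) %% cfg$n_clock_genes) + 1L
        sgn <- if (i %% 2 == 1) 1 else -1
        z <- clock_wave[j, ]
        w_raw <- cos(2 * pi * (t_one - (clock[j] + cfg$period_h / 4)) / cfg$period_h)
        z_c <- z - mean(z)
        w_c <- w_raw - mean(w_raw)
        w_o <- w_c - sum(w_c * z_c) / sum(z_c^2) * z_c   # orthogonal residual
        u <- sgn * abs(cfg$coupling_strength) * z_c / sqrt(sum(z_c^2)) +
          sqrt(1 - cfg$coupling_strength^2) * w_o / sqrt(sum(w_o^2))
        u <- u / max(abs(u))
        base[i, ] <- mesor[i] * (1 + amp[i] * u)
        ht <- harmonic_truth(t_one, base[i, ], cfg$period_h)
        truth$is_rhythmic[i] <- TRUE
        truth$true_phase[i] <- ht$phase
        truth$true_amplitude[i] <- ht$amp_rel
        truth$coupled_clock_gene[i] <- names(clock)[j]
        truth$true_coupling_sign[i] <- if (sgn > 0) "+" else "-"
      } else if (i %in% rhythmic_idx) {
        base[i, ] <- cosine_wave(t_one, mesor[i], amp[i], phase[i], cfg$period_h)
        truth$is_rhythmic[i] <- TRUE
        truth$true_phase[i] <- phase[i]
        truth$true_amplitude[i] <- amp[i]
      } else {
        base[i, ] <- mesor[i]
      }
    }

    signal <- base[, rep(seq_along(t_one), cfg$n_replicates), drop = FALSE]
    if (cfg$noise_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$noise_cv^2))
      noise <- matrix(rlnorm(length(signal), meanlog = -sdlog^2 / 2, sdlog = sdlog),
                      nrow = nrow(signal))
      signal <- signal * noise
    }
    rownames(signal) <- truth$gene
    list(matrix = temporal_matrix(signal, t_all, rep_idx), truth = truth)
  })
}

#' Write a ground-truth table as TSV
#' @param truth truth data.frame from [generate_temporal_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
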