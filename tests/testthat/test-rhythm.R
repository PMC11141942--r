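tm_from <- function(mat, time) {
  temporal_matrix(mat, time)
}

test_that("expression filter keeps the boundary and reports removals", {
  t <- seq(0, 24, 4)
  m <- rbind(low = rep(5, 7), boundary = rep(6, 7), high = rep(100, 7))
  x <- tm_from(m, t)
  f <- filter_expression(x, min_mean_count = 6, mode = "count")
  expect_setequal(rownames(f$values), c("boundary", "high"))
  expect_identical(attr(f, "removed"), "low")

  z <- tm_from(rbind(a = rep(0, 7), b = rep(0, 7)), t)
  expect_warning(fz <- filter_expression(z, mode = "count"), "no genes")
  expect_equal(nrow(fz$values), 0)
  expect_setequal(attr(fz, "removed"), c("a", "b"))
})

test_that("cosinor fit recovers closed-form parameters", {
  t <- seq(0, 24, 4)
  f <- cosinor_fit(t, 2 + cos(2 * pi * t / 24), period = 24)
  expect_equal(f$mesor, 2, tolerance = 1e-8)
  expect_equal(f$amplitude, 1, tolerance = 1e-8)
  expect_equal(f$phase, 0, tolerance = 1e-8)
  expect_lt(f$p, 1e-10)

  fc <- cosinor_fit(t, rep(3, 7), period = 24)
  expect_equal(fc$amplitude, 0)
  expect_equal(fc$p, 1)

  # cos(2*pi*(t - 6)/24) = sin(2*pi*t/24): phase must be 6 h
  fs <- cosinor_fit(t, 3 + 0.5 * sin(2 * pi * t / 24), period = 24)
  expect_equal(fs$phase, 6, tolerance = 1e-8)
  expect_equal(fs$amplitude, 0.5, tolerance = 1e-8)
  expect_equal(predict(fs, newtime = 6), 3.5, tolerance = 1e-8)
})

test_that("jtk matches exhaustive enumeration oracles at n = 6 and 7", {
  # bonferroni mode against independent per-reference enumeration
  for (n in c(6, 7)) {
    t <- seq(0, by = 4, length.out = n)
    set.seed(100 + n)
    for (rep in 1:2) {
      y <- rnorm(n)
      res <- jtk_cycle(t, y, grid_correction = "bonferroni")
      refs <- chronotarget:::jtk_reference_grid(t, c(20, 24, 28), 4)$refs
      tails <- vapply(seq_len(nrow(refs)), function(j) {
        oracle_kendall_tail(y, refs[j, ])
      }, numeric(1))
      expect_equal(res$p, min(1, min(tails) * nrow(refs)), tolerance = 1e-12)
    }
  }
  # exact joint mode against the brute-force grid oracle
  t <- seq(0, 24, 4)
  set.seed(42)
  for (rep in 1:2) {
    y <- rnorm(7)
    res <- jtk_cycle(t, y, grid_correction = "exact")
    grid <- chronotarget:::jtk_reference_grid(t, c(20, 24, 28), 4)
    expect_equal(res$p, oracle_jtk_grid_p(y, grid$refs), tolerance = 1e-12)
  }
})

test_that("jtk handles pure, reversed, and constant signals", {
  t <- seq(0, 24, 4)
  # round so the cosine's symmetric sampling positions tie exactly
  j <- jtk_cycle(t, round(cos(2 * pi * t / 24), 9))
  expect_equal(j$tau, 1)
  expect_equal(unname(j$best_period), 24)
  expect_equal(unname(j$best_lag), 0)

  jr <- jtk_cycle(t, round(-cos(2 * pi * t / 24), 9))
  expect_equal(unname(jr$best_period), 24)
  expect_equal(unname(jr$best_lag), 12)  # trough at lag 0 = peak half a period later
  expect_equal(jr$p, j$p)                # symmetry: same evidence strength

  expect_equal(jtk_cycle(t, rep(2, 7))$p, 1)
})

test_that("lomb-scargle finds the generative period and handles edge cases", {
  t <- seq(0, 24, 4)
  l <- lomb_scargle(t, cos(2 * pi * t / 24))
  res <- max(abs(diff(1 / l$freq)))
  expect_lt(abs(l$peak_period - 24), res + 1e-9)
  expect_lt(l$p, 0.01)
  expect_equal(lomb_scargle(t, rep(1, 7))$p, 1)
  # replicated time points are averaged
  t2 <- rep(t, 2)
  y2 <- c(cos(2 * pi * t / 24) + 2, cos(2 * pi * t / 24) + 2)
  l2 <- lomb_scargle(t2, y2)
  expect_equal(l2$power, l$power, tolerance = 1e-9)
})

test_that("lomb-scargle p-values are calibrated under the null", {
  t <- seq(0, 24, 4)
  set.seed(19)
  p <- replicate(600, lomb_scargle(t, rnorm(7))$p)
  frac <- mean(p <= 0.05)
  margin <- 2.576 * sqrt(0.05 * 0.95 / 600)
  expect_lt(frac, 0.05 + margin)
  expect_gt(frac, 0.05 - margin)
})

test_that("Fisher combination matches the chi-square oracle", {
  expect_equal(integrate_pvalues(c(1, 1, 1)), 1)
  # -2*3*log(0.05) = 17.9744, df 6
  expect_equal(integrate_pvalues(c(0.05, 0.05, 0.05)),
               pchisq(-6 * log(0.05), df = 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(integrate_pvalues(c(0.05, 0.05, 0.05)), 6.33e-3,
               tolerance = 1e-2)
  expect_equal(integrate_pvalues(0.2), 0.2)
  expect_warning(pz <- integrate_pvalues(c(0, 0.5)), "floored")
  expect_true(pz > 0 && pz < 1)
  expect_error(integrate_pvalues(c(0.5, 1.5)), "0, 1")
})

test_that("BH adjustment matches a brute-force oracle on short p-vectors", {
  set.seed(7)
  for (rep in 1:20) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("detect_rhythmic: all-constant matrix yields no rhythmic calls", {
  t <- seq(0, 24, 4)
  m <- matrix(5, 10, 7, dimnames = list(paste0("g", 1:10), NULL))
  rt <- detect_rhythmic(tm_from(m, t))
  expect_false(any(rt$rhythmic))
  expect_true(all(rt$p_integrated >= 0.99))
})

test_that("detect_rhythmic recovers planted rhythms (downscaled)", {
  cfg <- synth_config(n_genes = 250, frac_rhythmic = 0.2,
                      amplitude_rel = c(0.6, 0.6), noise_cv = 0.1, seed = 11)
  g <- generate_temporal_matrix(cfg)
  rt <- detect_rhythmic(filter_expression(g$matrix, mode = "tpm"))
  tr <- g$truth[match(rt$gene, g$truth$gene), ]
  sens <- mean(rt$rhythmic[tr$is_rhythmic])
  fdp <- if (any(rt$rhythmic)) mean(!tr$is_rhythmic[rt$rhythmic]) else 0
  expect_gt(sens, 0.7)
  expect_lt(fdp, 0.12)
  # table invariants
  expect_true(all(rt$fdr >= rt$p_integrated - 1e-12))
  expect_true(all(rt$phase_est >= 0 & rt$phase_est < rt$period_est))
  expect_identical(rt$rhythmic, rt$fdr <= 0.05)
})

test_that("recovered phase is within half a sampling interval when noiseless", {
  cfg <- synth_config(n_genes = 120, frac_rhythmic = 0.5,
                      amplitude_rel = c(0.6, 0.6), noise_cv = 0, seed = 3)
  g <- generate_temporal_matrix(cfg)
  rt <- detect_rhythmic(filter_expression(g$matrix, mode = "tpm"))
  tr <- g$truth[match(rt$gene, g$truth$gene), ]
  det <- rt$rhythmic & tr$is_rhythmic
  err <- abs(rt$phase_est[det] - tr$true_phase[det]) %% 24
  err <- pmin(err, 24 - err)
  expect_true(all(err <= 2))
})

test_that("detection power is monotone in amplitude at shared seeds", {
  sens <- vapply(c(0.2, 0.45, 0.8), function(a) {
    g <- generate_temporal_matrix(synth_config(
      n_genes = 120, frac_rhythmic = 0.5, amplitude_rel = c(a, a),
      noise_cv = 0.25, n_clock_genes = 0, seed = 77))
    rt <- detect_rhythmic(filter_expression(g$matrix, mode = "tpm"))
    tr <- g$truth[match(rt$gene, g$truth$gene), ]
    mean(rt$rhythmic[tr$is_rhythmic])
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("differential rhythmicity reports membership and Venn regions", {
  mk <- function(genes, rhythmic) {
    df <- data.frame(gene = genes, rhythmic = genes %in% rhythmic,
                     stringsAsFactors = FALSE)
    class(df) <- c("rhythmicity_table", "data.frame")
    df
  }
  genes <- paste0("g", 1:10)
  a <- mk(genes, paste0("g", 1:4))
  b <- mk(genes, paste0("g", 3:6))
  same <- differential_rhythmicity(list(x = a, y = a))
  expect_true(all(lengths(same$exclusive) == 0))

  d <- differential_rhythmicity(list(A = a, B = b))
  expect_setequal(d$exclusive$A, c("g1", "g2"))
  expect_setequal(d$exclusive$B, c("g5", "g6"))

  # three tables: every region against direct enumeration
  cst <- mk(genes, paste0("g", c(1, 3, 5, 7, 9)))
  d3 <- differential_rhythmicity(list(A = a, B = b, C = cst))
  regions <- d3$regions$regions
  sets <- list(A = paste0("g", 1:4), B = paste0("g", 3:6),
               C = paste0("g", c(1, 3, 5, 7, 9)))
  for (i in seq_len(nrow(regions))) {
    patt <- as.integer(strsplit(regions$pattern[i], "")[[1]])
    expected <- sum(vapply(genes, function(gn) {
      all((gn %in% sets$A) == patt[1], (gn %in% sets$B) == patt[2],
          (gn %in% sets$C) == patt[3])
    }, logical(1)))
    expect_equal(regions$count[i], expected)
  }
  # disjoint universes are an error
  z <- mk(paste0("h", 1:5), character(0))
  expect_error(differential_rhythmicity(list(a, z)), "disjoint")
})

test_that("rhythmicity table round-trips through TSV", {
  cfg <- synth_config(n_genes = 20, seed = 8)
  g <- generate_temporal_matrix(cfg)
  rt <- detect_rhythmic(g$matrix)
  path <- tempfile(fileext = ".tsv")
  write_rhythm_tsv(rt, path)
  back <- read.delim(path, comment.char = "#")
  expect_equal(nrow(back), nrow(rt))
  expect_equal(back$p_integrated, rt$p_integrated, tolerance = 1e-9)
})
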