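doses9 <- 1e-3 * 5^(0:8)

test_that("4PL fit recovers noiseless generative parameters", {
  v <- 0.05 + (1 - 0.05) / (1 + (doses9 / 0.5)^1.3)
  f <- fit_dose_response(doses9, v)
  expect_true(f$converged)
  expect_equal(f$top, 1, tolerance = 1e-6)
  expect_equal(f$bottom, 0.05, tolerance = 1e-6)
  expect_equal(f$ic50, 0.5, tolerance = 1e-6)
  expect_equal(f$hill, 1.3, tolerance = 1e-6)
  expect_false(f$extrapolated)
})

test_that("constant full viability gives AUC 1", {
  f <- fit_dose_response(doses9, rep(1, 9))
  expect_equal(f$auc, 1, tolerance = 1e-6)
})

test_that("fitted IC50 sits at the curve midpoint (bisection oracle)", {
  v <- 0 + 1 / (1 + (doses9 / 0.2)^2)
  f <- fit_dose_response(doses9, v)
  mid <- (f$top + f$bottom) / 2
  # bisection on the fitted curve for v = midpoint
  lo <- min(doses9); hi <- max(doses9)
  for (i in 1:60) {
    d <- sqrt(lo * hi)
    if (predict(f, d) > mid) lo <- d else hi <- d
  }
  expect_equal(sqrt(lo * hi), f$ic50, tolerance = 1e-4)
})

test_that("AUC is invariant to dose-unit rescaling", {
  v <- 1 / (1 + (doses9 / 0.3)^1.5)
  f1 <- fit_dose_response(doses9, v)
  f2 <- fit_dose_response(doses9 * 1000, v)
  expect_equal(f1$auc, f2$auc, tolerance = 1e-6)
  expect_equal(f2$ic50 / f1$ic50, 1000, tolerance = 1e-4)
})

test_that("IC50 estimate is nearly unbiased at realistic assay noise", {
  set.seed(8)
  est <- replicate(100, {
    v <- pmax(0, 1 / (1 + doses9 / 1) + rnorm(9, 0, 0.02))
    fit_dose_response(doses9, v)$ic50
  })
  expect_lt(abs(mean(est) - 1) / 1, 0.05)
})

test_that("temporal efficacy: degenerate and null panels", {
  # identical replicates everywhere: no temporal signal
  p0 <- generate_dose_response_panel(ic50_rel_amp = 0, noise_sd = 0,
                                     n_replicates = 3, seed = 1)
  eff0 <- temporal_efficacy(p0)
  expect_equal(eff0$anova$F, 0)
  expect_equal(eff0$anova$p, 1)
  expect_equal(diff(range(eff0$auc_mean)), 0, tolerance = 1e-9)

  # flat IC50 with noise: no significant time effect at a fixed seed
  pn <- generate_dose_response_panel(ic50_rel_amp = 0, noise_sd = 0.03,
                                     n_replicates = 3, seed = 15)
  effn <- temporal_efficacy(pn)
  expect_gt(effn$anova$p, 0.05)

  # single replicate: AUC series only, with a warning
  p1 <- generate_dose_response_panel(n_replicates = 1, seed = 2)
  expect_warning(eff1 <- temporal_efficacy(p1), "ANOVA skipped")
  expect_null(eff1$anova)
  expect_equal(length(eff1$auc_mean), 7)
})

test_that("one-way ANOVA on AUCs matches the textbook formula", {
  # modulated IC50 so replicate AUCs vary between times
  p <- generate_dose_response_panel(time_points = c(0, 8, 16),
                                    ic50_rel_amp = 0.4, noise_sd = 0.03,
                                    n_replicates = 3, seed = 7)
  eff <- temporal_efficacy(p)
  a <- eff$auc
  groups <- split(a$auc, a$time_h)
  k <- length(groups); N <- nrow(a)
  grand <- mean(a$auc)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  f_hand <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(eff$anova$F, f_hand, tolerance = 1e-9)
  expect_equal(eff$anova$p,
               pf(f_hand, k - 1, N - k, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(nrow(eff$tukey), choose(k, 2))
})

test_that("rhythmicity score normalizes, averages, and bounds", {
  t <- seq(0, 24, 4)
  m <- temporal_matrix(rbind(g1 = 2 * (1 + cos(2 * pi * t / 24)) + 0.5,
                             g2 = 5 * (1 - cos(2 * pi * t / 24)) + 0.5,
                             g3 = rep(7, 7)), t)
  s1 <- rhythmicity_score(m, "g1")
  expect_equal(unname(s1$score),
               unname(m$values[1, ] / max(m$values[1, ])),
               tolerance = 1e-12)
  # exact antiphase, equal relative shape 1 +- cos: score constant
  m2 <- temporal_matrix(rbind(a = 1 + cos(2 * pi * t / 24),
                              b = 1 - cos(2 * pi * t / 24)), t)
  s2 <- rhythmicity_score(m2, c("a", "b"))
  expect_equal(unname(s2$score), rep(0.5, 7), tolerance = 1e-12)
  # random sets match the two-line oracle and stay in (0, 1]
  set.seed(6)
  mr <- temporal_matrix(matrix(runif(35, 1, 9), 5, 7,
                               dimnames = list(paste0("r", 1:5), NULL)), t)
  sr <- rhythmicity_score(mr, paste0("r", 1:5))
  oracle <- colMeans(mr$values / apply(mr$values, 1, max))
  expect_equal(unname(sr$score), unname(oracle), tolerance = 1e-12)
  expect_true(all(sr$score > 0 & sr$score <= 1))
  # zero-max genes are dropped with a warning
  mz <- temporal_matrix(rbind(ok = 1 + cos(2 * pi * t / 24),
                              z = rep(0, 7)), t)
  expect_warning(sz <- rhythmicity_score(mz, c("ok", "z")), "zero maximum")
  expect_equal(sz$n_genes, 1)
})

test_that("efficacy-expression correlation: identities and oracle", {
  t <- seq(0, 24, 4)
  score <- 0.6 + 0.3 * cos(2 * pi * (t - 8) / 24)
  res <- efficacy_expression_correlation(t, score, t, 2 * score + 1)
  expect_equal(res$r2, 1, tolerance = 1e-12)
  set.seed(12)
  a <- rnorm(7); b <- rnorm(7)
  res2 <- efficacy_expression_correlation(t, a, t, b)
  expect_equal(res2$r, cor(a, b), tolerance = 1e-12)
  expect_equal(res2$p, cor.test(a, b)$p.value, tolerance = 1e-12)
  const <- efficacy_expression_correlation(t, rep(1, 7), t, a)
  expect_false(const$defined)
})

test_that("phase-locked IC50 ties drug response to target expression end to end", {
  t <- seq(0, 24, 4)
  phase <- 8
  target <- 10 * (1 + 0.5 * cos(2 * pi * (t - phase) / 24))
  panel <- generate_dose_response_panel(ic50_rel_amp = 0.4,
                                        ic50_phase = phase, noise_sd = 0,
                                        n_replicates = 1, seed = 3)
  eff <- suppressWarnings(temporal_efficacy(panel))
  res <- efficacy_expression_correlation(
    t, target, as.numeric(names(eff$auc_mean)), unname(eff$auc_mean))
  expect_gte(res$r2, 0.9)
  expect_gt(res$r, 0)   # higher target expression, higher IC50, more survival
})

test_that("temporal amplitude estimators agree on clean signals", {
  t <- seq(0, 24, 4)
  amp <- temporal_amplitude(t, 3 + 0.8 * cos(2 * pi * (t - 4) / 24))
  expect_equal(amp$amp_cosinor, 0.8, tolerance = 1e-9)
  expect_equal(amp$amp_peak_trough, 0.8, tolerance = 0.05)
  flat <- temporal_amplitude(t, rep(2, 7))
  expect_equal(flat$amp_cosinor, 0)
  expect_equal(flat$amp_peak_trough, 0)
  # noisy cosine: cosinor amplitude centered on the truth
  set.seed(23)
  est <- replicate(60, {
    y <- 3 + 0.8 * cos(2 * pi * (t - 4) / 24) + rnorm(7, 0, 0.1)
    temporal_amplitude(t, y)$amp_cosinor
  })
  expect_lt(abs(mean(est) - 0.8), 3 * sd(est) / sqrt(60))
})

test_that("target prioritization orders by coupling with deterministic ties", {
  rt <- data.frame(gene = c("A", "B", "C", "D"),
                   rhythmic = c(TRUE, TRUE, TRUE, FALSE),
                   stringsAsFactors = FALSE)
  class(rt) <- c("rhythmicity_table", "data.frame")
  ct <- make_cent_table(data.frame(node = c("A", "B", "C", "D"),
                                   mcc = c(10, 10, 50, 99),
                                   degree = c(3, 3, 5, 9)))
  r <- matrix(c(0.9, -0.5, 0.7, 0.2), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), "PER2"))
  cm <- structure(list(r = r, r2 = r^2,
                       n = matrix(7, 4, 1, dimnames = dimnames(r))),
                  class = "coupling_matrix")
  drugs <- data.frame(gene = c("A", "A"), drug = c("erlotinib", "gefitinib"))
  out <- prioritize_targets(rt, c("A", "B", "C", "D"), ct, cm, drugs)
  # D is not rhythmic: excluded despite the top MCC
  expect_false("D" %in% out$gene)
  expect_equal(out$gene, c("A", "C", "B"))  # by |r|: 0.9, 0.7, 0.5
  expect_equal(out$drugs[1], "erlotinib;gefitinib")
  expect_equal(out$rank, 1:3)
  # single candidate
  one <- prioritize_targets(rt, "A", ct, cm, drugs)
  expect_equal(one$gene, "A")
  expect_equal(one$rank, 1)
  # determinism under permuted candidate order
  out2 <- prioritize_targets(rt, c("C", "D", "B", "A"), ct, cm, drugs)
  expect_identical(out$gene, out2$gene)
  # empty r-CDG set
  none <- data.frame(gene = "Z", rhythmic = FALSE)
  class(none) <- c("rhythmicity_table", "data.frame")
  expect_warning(empty <- prioritize_targets(none, "Z", ct, cm, NULL),
                 "no rhythmic")
  expect_equal(nrow(empty), 0)
})
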