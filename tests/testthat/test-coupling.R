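mk_matrix <- function(rows, time = seq(0, 24, 4)) {
  temporal_matrix(do.call(rbind, rows), time)
}

test_that("pairwise correlation: exact cases and the textbook formula", {
  t <- seq(0, 24, 4)
  x <- cos(2 * pi * t / 24) + 2
  m <- mk_matrix(list(a = 2 * x + 3, b = -x + 5, clock = x))
  cm <- gene_gene_correlation(m, c("a", "b"), "clock")
  expect_equal(cm$r["a", "clock"], 1, tolerance = 1e-12)
  expect_equal(cm$r["b", "clock"], -1, tolerance = 1e-12)
  expect_equal(cm$r2["b", "clock"], 1, tolerance = 1e-12)

  set.seed(2)
  y1 <- runif(7, 1, 10); y2 <- runif(7, 1, 10)
  m2 <- mk_matrix(list(p = y1, q = y2))
  cm2 <- gene_gene_correlation(m2, "p", "q")
  r_hand <- sum((y1 - mean(y1)) * (y2 - mean(y2))) /
    sqrt(sum((y1 - mean(y1))^2) * sum((y2 - mean(y2))^2))
  expect_equal(unname(cm2$r["p", "q"]), r_hand, tolerance = 1e-12)

  # zero-variance series yields an undefined cell, excluded downstream
  m3 <- mk_matrix(list(flat = rep(4, 7), clock = x))
  cm3 <- gene_gene_correlation(m3, "flat", "clock")
  expect_true(is.na(cm3$r["flat", "clock"]))
  cs3 <- coupling_summary(cm3)
  expect_equal(cs3$per_candidate$tier, "none")
  expect_equal(cs3$global$n_sig, 0)
})

test_that("coupling summary applies inclusive and strict tiers", {
  # binary-exact values: 0.5^2 = 0.25, 0.75^2 = 0.5625, so the boundary
  # semantics are tested without floating-point fuzz
  r <- matrix(c(0.5, 0.75, -0.8, 0.1),
              nrow = 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  cm <- structure(list(r = r, r2 = r^2,
                       n = matrix(7, 2, 2, dimnames = dimnames(r))),
                  class = "coupling_matrix")
  cs <- coupling_summary(cm, r2_sig = 0.25, r2_strong = 0.5625)
  # R2 exactly at the significance boundary counts (inclusive)
  expect_equal(cs$per_candidate$n_clock_sig[1], 2)
  expect_equal(cs$per_candidate$tier[1], "strong-negative")  # best: -0.8
  expect_equal(cs$per_candidate$tier[2], "strong-positive")  # 0.5625 inclusive
  expect_equal(cs$global$n_strong_ge, 2)
  expect_equal(cs$global$n_strong_gt, 1)   # only 0.64 strictly above
  expect_equal(cs$global$n_strong_neg, 1)

  # random matrix: counts equal a brute-force threshold scan
  set.seed(11)
  rr <- matrix(runif(60, -1, 1), 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  cmr <- structure(list(r = rr, r2 = rr^2,
                        n = matrix(7, 10, 6, dimnames = dimnames(rr))),
                   class = "coupling_matrix")
  csr <- coupling_summary(cmr)
  expect_equal(csr$global$n_sig, sum(rr^2 >= 0.3))
  expect_equal(csr$per_clock$n_candidates_sig, unname(colSums(rr^2 >= 0.3)))
  expect_equal(csr$per_candidate$n_clock_sig, unname(rowSums(rr^2 >= 0.3)))
  expect_equal(csr$global$frac_candidates_sig,
               mean(rowSums(rr^2 >= 0.3) >= 1))
})

test_that("coupling recovery on synthetic data is exact in the noiseless limit", {
  g <- generate_temporal_matrix(synth_config(
    n_genes = 20, frac_rhythmic = 0.5, n_coupled_genes = 6,
    coupling_strength = 0.9, noise_cv = 0, seed = 21))
  cp <- g$truth[!is.na(g$truth$coupled_clock_gene), ]
  cm <- gene_gene_correlation(g$matrix, cp$gene,
                              unique(cp$coupled_clock_gene))
  for (i in seq_len(nrow(cp))) {
    r <- cm$r[cp$gene[i], cp$coupled_clock_gene[i]]
    expect_equal(abs(r), 0.9, tolerance = 1e-6)
    expect_equal(sign(r), if (cp$true_coupling_sign[i] == "+") 1 else -1)
  }
  # all planted pairs appear in the strong-coupling network (0.81 > 0.6)
  net <- build_coupling_network(cm, r2_min = 0.6)
  for (i in seq_len(nrow(cp))) {
    expect_true(any(net$candidate == cp$gene[i] &
                      net$clock_gene == cp$coupled_clock_gene[i]))
  }
})

test_that("strong-coupling network uses a strict boundary", {
  r <- matrix(c(0.75, 0.76), 1, 2,    # 0.5625 exactly at, 0.5776 above
              dimnames = list("g", c("c1", "c2")))
  cm <- structure(list(r = r, r2 = r^2,
                       n = matrix(7, 1, 2, dimnames = dimnames(r))),
                  class = "coupling_matrix")
  net <- build_coupling_network(cm, r2_min = 0.5625)
  expect_equal(nrow(net), 1)
  expect_equal(net$clock_gene, "c2")
  all_weak <- structure(list(r = r * 0.5, r2 = (r * 0.5)^2, n = cm$n),
                        class = "coupling_matrix")
  expect_equal(nrow(build_coupling_network(all_weak)), 0)
})

test_that("concordance trend: identity, negation, and noise attenuation", {
  set.seed(5)
  r <- matrix(runif(75, -1, 1), 5, 15,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:15)))
  cm <- structure(list(r = r, r2 = r^2,
                       n = matrix(7, 5, 15, dimnames = dimnames(r))),
                  class = "coupling_matrix")
  same <- concordance_trend(cm, cm)
  expect_equal(same$slope, rep(1, 5), tolerance = 1e-10)
  expect_equal(same$r, rep(1, 5), tolerance = 1e-10)

  neg <- structure(list(r = -r, r2 = r^2, n = cm$n),
                   class = "coupling_matrix")
  flip <- concordance_trend(cm, neg)
  expect_equal(flip$r, rep(-1, 5), tolerance = 1e-10)

  # additive noise attenuates r by sd_a / sqrt(sd_a^2 + sigma^2)
  set.seed(31)
  n_cand <- 150
  sigma <- 0.3
  a <- matrix(runif(n_cand * 15, -1, 1), n_cand, 15,
              dimnames = list(paste0("g", 1:n_cand), paste0("c", 1:15)))
  b <- a + matrix(rnorm(n_cand * 15, 0, sigma), n_cand, 15)
  cma <- structure(list(r = a, r2 = a^2,
                        n = matrix(7, n_cand, 15, dimnames = dimnames(a))),
                   class = "coupling_matrix")
  cmb <- structure(list(r = b, r2 = b^2, n = cma$n),
                   class = "coupling_matrix")
  tr <- concordance_trend(cma, cmb)
  sd_a <- sqrt(1 / 3)                      # sd of Uniform(-1, 1)
  expected <- sd_a / sqrt(sd_a^2 + sigma^2)
  expect_equal(mean(tr$r), expected, tolerance = 0.05)

  # slope symmetry: slope(A->B) * slope(B->A) = r^2 <= 1
  back <- concordance_trend(cmb, cma)
  prod <- tr$slope * back$slope
  expect_true(all(prod <= 1 + 1e-9))
  expect_equal(prod, tr$r^2, tolerance = 1e-9)
})

test_that("candidates missing in one cohort are skipped with a message", {
  r <- matrix(runif(30), 2, 15,
              dimnames = list(c("g1", "g2"), paste0("c", 1:15)))
  cm1 <- structure(list(r = r, r2 = r^2,
                        n = matrix(7, 2, 15, dimnames = dimnames(r))),
                   class = "coupling_matrix")
  cm2 <- structure(list(r = r[1, , drop = FALSE],
                        r2 = r[1, , drop = FALSE]^2,
                        n = cm1$n[1, , drop = FALSE]),
                   class = "coupling_matrix")
  expect_message(tr <- concordance_trend(cm1, cm2), "skipped")
  expect_equal(tr$gene, "g1")
})

test_that("coupling matrix writes a long-format TSV", {
  t <- seq(0, 24, 4)
  x <- cos(2 * pi * t / 24) + 2
  m <- mk_matrix(list(a = 2 * x + 3, clock = x))
  cm <- gene_gene_correlation(m, "a", "clock")
  path <- tempfile(fileext = ".tsv")
  write_coupling_tsv(cm, path)
  back <- read.delim(path, comment.char = "#")
  expect_equal(nrow(back), 1)
  expect_equal(back$r, 1, tolerance = 1e-9)
})
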