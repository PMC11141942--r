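# chronotarget

Circadian transcriptome analysis and chronotherapy target prioritization
for short temporal expression series.

## The problem

Solid tumors keep a working circadian clock: a sizeable fraction of their
transcriptome — including well-known cancer driver genes — oscillates over
the day. If a drug's target oscillates, the drug's efficacy can oscillate
too, which makes *when* to dose a clinically actionable question. Answering
it from data requires a chain of analyses: call rhythmic genes from a short
time course (typically 7 samples, 4 h apart, over 24 h), intersect them
with driver-gene catalogs, rank candidates by their position in the
protein-interaction network, quantify how tightly each candidate is coupled
to the 15-gene core clock (CLOCK, BMAL1, PERs, CRYs, NR1Ds, RORs, ...), and
finally relate the temporal expression of a chosen target to time-of-day
dose-response viability.

`chronotarget` implements that chain as a tested R package, together with a
seeded synthetic-data generator that produces temporal expression matrices,
planted-hub interaction networks and phase-modulated viability panels with
ground-truth tables, so every stage can be benchmarked against known truth.

## The statistics at the core

**Rhythm detection.** For each gene three periodicity statistics are
computed over a period window of 20–28 h:

- a **cosinor** harmonic regression
  `y = M + a·cos(2πt/T) + b·sin(2πt/T)` with amplitude `√(a²+b²)`,
  acrophase from `atan2(b, a)`, and an F-test against the flat model;
- a **JTK-style rank test**: Kendall's S between the series and reference
  cosines on a (period, lag) grid, with the *exact* null obtained by full
  enumeration of all n! orderings (distribution-free at these sample
  sizes), corrected over the grid by the exact joint null of the minimal
  tail;
- a floating-mean **Lomb–Scargle** periodogram with power
  `z = (n−1)R²/2`, calibrated against a tabulated Monte-Carlo null of the
  band-maximum power.

The three p-values are combined with Fisher's statistic `−2Σ ln pᵢ`;
because the statistics are computed on the same series, the combined
statistic is referred to its empirical null (simulated on the same sampling
design) rather than the χ²₆ reference, and Benjamini–Hochberg FDR control
at 0.05 flags rhythmic genes.

**Network centrality.** Twelve topology parameters per node (degree,
betweenness, stress, closeness, eccentricity, radiality, clustering
coefficient, MNC, DMNC, MCC, bottleneck, EPC). Hubs are called by the
consensus rule — top 5 % in at least 9 of the 12 parameters — and,
separately, by the degree > 30 rule; candidates are ranked by maximal
clique centrality, `MCC(v) = Σ (|C|−1)!` over maximal cliques containing
`v`.

**Clock coupling.** Pearson correlation of every candidate against the
15-gene clock panel, with the two R² tiers (≥ 0.3 significant, 0.6 strong)
and cross-cohort concordance trends.

**Chrono-efficacy.** Four-parameter logistic dose-response fits
`v(d) = bottom + (top−bottom)/(1 + (d/IC50)^hill)`, AUC as mean fitted
viability over the log-dose window, one-way ANOVA + Tukey HSD across
treatment times, a max-normalized rhythmicity score for gene sets, and the
correlation between the score and the per-time AUC series.

**Prioritization.** Rhythmic ∩ driver genes → shortlist by MCC (top 17) →
order by strongest clock coupling → annotate with drug–gene interactions.

## Worked example

```r
library(chronotarget)

cfg <- synth_config(n_genes = 300, frac_rhythmic = 0.2, n_coupled_genes = 3,
                    coupling_strength = 0.9, noise_cv = 0.1, seed = 42)
gen  <- generate_temporal_matrix(cfg)
gen$matrix
#> temporal_matrix: 315 genes x 7 samples (7 time points, 1 replicate)
#> time (h): 0, 4, 8, 12, 16, 20, 24

filt <- filter_expression(gen$matrix, mode = "tpm")
rt   <- detect_rhythmic(filt)
head(rt[order(rt$p_integrated), ], 3)
#>      gene p_cosinor  p_jtk  p_ls p_integrated    fdr phase_est amplitude_est rhythmic
#> 8  G00008  7.83e-05 0.0194 2e-04        5e-04 0.0197    26.761         0.714     TRUE
#> 6  G00006  2.09e-04 0.0194 2e-04        1e-03 0.0197    15.881         0.654     TRUE
#> 7  G00007  5.83e-05 0.0194 6e-04        1e-03 0.0197    17.755         0.698     TRUE
sum(rt$rhythmic)
#> [1] 54
```

Each row carries the three per-method p-values, the dependence-calibrated
integrated p, the BH FDR, and the cosinor period/phase/amplitude estimates
(phase in hours modulo the fitted period — `G00008`'s 26.8 h phase is at a
fitted 28 h period). Against the generator's truth table this run recovers
the planted rhythms at a realized false-discovery proportion of 0.056.

Clock coupling of the three planted coupled genes (target |r| = 0.9):

```r
cm <- gene_gene_correlation(filt, c("G00001", "G00002", "G00003"),
                            c("ARNTL", "PER2", "CRY1", "NR1D1"))
round(cm$r, 2)
#>        ARNTL  PER2  CRY1 NR1D1
#> G00001  0.84 -0.84 -0.98  0.49
#> G00002 -0.89  0.97  0.89  0.09
#> G00003  0.79 -0.82 -0.97  0.50
```

The full analysis graph — filtering, rhythm detection, overlap statistics,
enrichment, centrality + hub calling, coupling, target ranking, and a run
manifest — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), "out/")
res$targets   # ranked chronotherapy candidates with drug annotations
```

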