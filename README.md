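# strokeClock

Tools for analysing **hyperacute blood gene-expression time courses after
ischemic stroke**, and for asking the clinically loaded question hidden in
them: *can a blood sample tell how long ago the stroke started?*
Thrombolysis is only licensed within 4.5 h of onset, yet onset time is
often unknown — a transcriptional "stroke clock" would directly expand the
treatable population.

The package is aimed at researchers analysing dense early time courses of
blood expression after experimental stroke (e.g. rat middle cerebral
artery occlusion, 8 animals sampled at 0, 1, 2, 3, 6 and 24 h — 47
samples once one missing sample is accounted for), and at anyone who wants
a fully testable, self-contained reference implementation of this analysis
style.

## What it implements

**Time-course statistics.** Per-gene cell-means linear models over the
time factor, neighboring-timepoint contrasts (1−0, 2−1, 3−2, 6−3, 24−6),
and an empirical-Bayes **moderated F-statistic**: the residual variance of
gene *g* is shrunk toward a prior estimated across genes,

```
s̃²_g = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g),
F_g  = (Cβ̂_g)ᵀ [C(XᵀX)⁻¹Cᵀ]⁻¹ (Cβ̂_g) / (r·s̃²_g)  ~  F(r, d₀ + d_g),
```

with (d₀, s₀²) obtained by moment-matching log-variances through the
digamma/trigamma functions. Genes are ranked by p with the fixed cutoff
α = 5×10⁻⁷.

**Profile clustering.** Per-timepoint averaging, mean-centering, and
K-means under a **Spearman correlation distance** — realized exactly as
Euclidean K-means on rank z-scores, where ‖ũ−ṽ‖² = 2(m−1)(1−ρ) — with
k-means++ seeding, followed by rule-based classification of centroids into
eight named temporal **archetypes** (A: hyperacute transient up peaking at
2 h … F: monotone decline through 24 h … H: early dip then delayed peak).

**Biomarker cross-ranking.** Mapping literature candidate-biomarker lists
into the dataset's namespace via static homolog/alias tables, locating
them in a significance ranking, counting who survives the cutoff, and
two-condition Venn partitions of up/down gene lists. Transcriptions of the
published candidate tables ship as plain-text fixtures.

**The stroke clock.** A nearest-profile estimator of hours-since-onset: a
shape-diverse panel (top genes per archetype) is standardized by training
statistics, matched against centroid curves interpolated in log(1+t), and
scored; ties break to the earliest time. Evaluated by leave-one-animal-out
cross-validation (median absolute error in hours, 4.5 h window accuracy).

**Synthetic data with ground truth.** A generator reproducing the study
design (including the missing sample), planted archetypes, log2 baselines,
amplitudes and Gaussian noise — so every stage above is testable offline,
with truth tables for recovery experiments.

## Worked example

```r
library(strokeClock)

## simulate the study design with planted archetypes
ste <- simulateTimecourse(
  archetype_counts = c(A = 58, B = 231, C = 37, D = 120,
                       E = 71, F = 6, G = 83, H = 40),
  n_null = 1000, noise_sd = 0.25, seed = 1)
ste
#> StrokeTimecourseExperiment: 1646 genes x 47 samples
#>   samples per timepoint: 0h:8 1h:8 2h:8 3h:8 6h:7 24h:8
#>   ground truth: 646 signal genes, 1000 null genes

## moderated F over neighboring-timepoint contrasts
fits   <- fitGeneModels(ste)
prior  <- estimateVariancePrior(fits)
result <- moderatedFTest(fits, prior = prior, alpha = 5e-7)
result
#> ModeratedResult: 1646 genes; moderated F with 5 numerator df
#>   prior: d0 = Inf, s0^2 = 0.06267
#>   646 genes significant at alpha = 5e-07

## cluster the significant genes' temporal profiles
ranked <- rankAndThreshold(result, alpha = 5e-7)
sig    <- ranked$gene_id[ranked$significant]
std    <- standardizeProfiles(averageProfiles(ste)[sig, ])
cl     <- clusterProfiles(std, K = 8, seed = 1)
cl
#> ClusterResult: K = 8 clusters over 646 profiles (inertia 97.7318 )
#>   centroid archetypes: 1:D(118) 2:B(206) 3:E(82) 4:H(44) 5:A(58)
#>                        6:G(72) 7:C(60) 8:F(6)

## train a stroke clock and evaluate leave-one-animal-out
truth <- truthTable(ste)
panel <- selectPanel(ranked, setNames(truth$archetype, truth$gene_id), 3)
loao  <- evaluateLOAO(ste, panel)
round(c(median_abs_error_h = loao$median_abs_error,
        window_accuracy = loao$window_accuracy), 3)
#> median_abs_error_h    window_accuracy
#>                0.1                1.0
```

Reading the output: every one of the 646 planted time-responsive genes is
recovered at α = 5×10⁻⁷ (here the variance prior is degenerate, d₀ = ∞,
because all simulated genes share one true noise variance — complete
pooling is then the correct answer); the eight clusters carry one
archetype label each, with the hyperacute-transient-up cluster (A) at
exactly its planted size of 58; and a 24-gene panel dates held-out
samples to a median error of 0.1 h with every sample correctly placed
inside/outside the 4.5 h window.

The candidate-biomarker utilities work the same way on the shipped
transcriptions of the published tables, e.g.
`countSignificant(readRankingTable(system.file("extdata",
"candidate_ranking_literature.tsv", package = "strokeClock")), 5e-7)`
returns `29`.

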