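---
title: "Methods: co-abundance groups and phenotype markers in longitudinal microbiome interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-abundance groups and phenotype markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model of the data

`cagmark` analyses 16S amplicon studies that arrive as a finished OTU count
table (samples x OTUs), a taxonomy assignment per OTU, per-sample metadata,
and optionally a rooted phylogeny over the OTUs. Two study designs are
supported end to end:

* an **in vitro colon-model arm**: batch fermenters inoculated with a pooled
  fecal community, run under five supplementation regimes (polyphenol-rich
  berry fractions ANTH/FLAV, PACs, TPP, the sugar/acid fraction S/A, and a
  prebiotic fiber MIX) plus an unsupplemented control, three vessels per
  regime, sampled at 0, 16 and 24 h;
* a **longitudinal human feeding-study arm**: 17 subjects in two age groups
  (11 young, 6 old) sampled at a washout baseline (W0) and at weeks 2, 4
  and 6 of a daily berry-supplemented diet, with a fasting plasma panel
  (FRAP antioxidant capacity in umol/L, glucose in mg/dL, CRP in mg/L).

Counts are converted to per-sample relative abundances by dividing by the
sample's total reads; zero-total samples are flagged and excluded from
distance-based stages. No rarefaction is applied by default —
`rarefy_counts()` provides seeded even-depth subsampling for sensitivity
analyses only.

# Diversity

Alpha diversity per sample: observed species (count > 0; no minimum-count
threshold), Shannon entropy in nats, Gini–Simpson (`1 - sum p^2`),
bias-corrected Chao1 (`S_obs + F1(F1-1)/(2(F2+1))`, requiring raw integer
counts — the estimator is undefined on proportions, and the function
refuses them), and Faith's phylogenetic diversity (total branch length of
the minimal rooted subtree spanning the observed leaves, root path
included).

Beta diversity: unweighted UniFrac (branch length unique to one community
over total observed branch length), weighted UniFrac (raw
`sum_b l_b |pA_b - pB_b|` over branches, with descendant-proportion sums
`p`), and a Spearman correlation distance between sample profiles
(`1 - rho`, range [0, 2]; a constant profile has undefined rank
correlation and is assigned distance 1 with a warning). Weighted UniFrac
is reported **normalized** by default (divided by
`sum_b l_b (pA_b + pB_b)`, giving values in [0, 1]); the raw variant is a
flag away, since published analyses rarely state which one they used.

Ordination is classical PCoA: double-centering of `-d^2/2` followed by an
eigendecomposition. Negative eigenvalues (possible for non-Euclidean
dissimilarities) are retained in the report but excluded from the
coordinates and from the proportion-explained denominator.

# The testing toolbox

All group comparisons are rank-based. Kruskal–Wallis uses midranks with
tie correction (the fully tied case is returned as H = 0, p = 1). Dunn's
post-hoc z statistics use the shared midranks of the pooled data with the
pooled tie-corrected variance and two-sided normal p-values;
Benjamini–Hochberg adjustment is applied and results carry the compact
significance flags `*` (p_adj < 0.05) and `#` (0.05 <= p_adj < 0.1).

For the differential-taxa analysis the BH family is, by default, the full
set of (taxon x regime-pair) p-values of one analysis; a per-taxon family
is selectable. The source analyses do not state the family, and the two
choices genuinely differ, so the scope is an explicit argument rather than
a silent decision.

The paired Wilcoxon signed-rank test drops zero differences, and for up to
12 remaining pairs computes the two-sided p exactly by enumerating all
`2^n` sign assignments of the observed midranks — ties are thereby handled
exactly, which the textbook null distribution cannot do. Beyond 12 pairs a
normal approximation with tie-corrected variance takes over.

One-way PERMANOVA follows the pairwise form: `SS_total = sum_{i<j}
d_ij^2 / n`, within-group sums analogously per group, pseudo-F =
`(SS_between/(k-1)) / (SS_within/(n-k))`, and a seeded permutation p-value
`(1 + exceedances)/(1 + n_perm)` with 999 permutations by default.
Associations with *continuous* plasma covariates use the
McArdle–Anderson regression form (`permanova_continuous()`): the
Gower-centered inner-product matrix is projected on the covariate's hat
matrix, `R2 = tr(HG)/tr(G)`, and the covariate is permuted across samples.

# The in vitro workflow

Abundances at 16 h and 24 h are pooled per regime (the paired 16 h vs 24 h
signed-rank checks justify the pooling), aggregated to genus or family,
and screened by Kruskal–Wallis plus Dunn. The supplementation regimes form
two super-groups — G1 = {ANTH/FLAV, MIX, PACs} and G2 = {S/A, TPP} — and
for every sample the median weighted-UniFrac distance to the rest of its
own super-group and to the other super-group (self excluded) is computed;
the two collections of per-sample medians are compared by a Wilcoxon
rank-sum test.

A caveat worth knowing: the two median collections are *dependent* (every
sample contributes one median to each, and all medians are functions of
one distance matrix). With weighted UniFrac distances over simulated null
communities the test still attains its nominal type-I rate (4.5% at
alpha = 0.05 over 200 null replicates, inside the binomial band), and the
same holds for Euclidean distances; with Spearman rank-correlation sample
distances, however, the same construction rejects ~15% of null datasets
regardless of sample count. The within/across statistic should therefore
be read as calibrated *in its UniFrac setting* and treated as descriptive
if transplanted onto correlation distances; a label-permutation version
would be calibrated under any metric, but the classical Wilcoxon form is
what this package implements.

# Co-abundance groups (CAGs)

The mean relative abundance of every OTU is computed per time point over
all subjects, giving a 4-point mean temporal trend. Pairwise Kendall
tau-b over these trend vectors is converted to a distance and the OTUs
are clustered by Ward-D2; the tree is cut at `k` clusters (default 6).

The printed source formula for the distance, "1—(Kendall tau)/2", is
ambiguous between `(1 - tau)/2` and `1 - tau/2`. The default is
`(1 - tau)/2` — the conventional correlation distance mapping tau = 1 to
0 and tau = -1 to 1 — with the literal `1 - tau/2` selectable. The two
differ by an affine transformation, which can change Ward-D2 merge order,
hence the explicit switch. An OTU whose trend is exactly constant has
undefined tau; its distances are set to 0.5 and the OTU is flagged.

The cluster count is a parameter, not an inference: six is the default
because that is the structure the method is typically asked to reproduce,
and no formal cut criterion is imposed. Cluster labels C1..Ck are assigned
deterministically — by decreasing mean member trend at the earliest time
point where the cluster means differ — so repeated runs and permuted
inputs yield the same names.

Per-CAG cumulated abundances (sums of member relative abundances per
sample) are compared across time points with the same Kruskal–Wallis +
Dunn + BH machinery, and per-CAG species-frequency profiles count member
OTUs per defined species label.

# FRAP markers

The FRAP value itself is plain assay arithmetic:
`(sample - blank)/(standard - blank) * 1000 umol/L`, technical replicates
averaged before the ratio.

The marker discovery procedure has four stages, all seeded:

1. **Iterated importances** (`rf_importance_iterations`): 100 rounds of a
   random-forest regression of FRAP on all OTU abundances, each trained on
   a random 50% of samples and scored on the other 50%; per-feature
   importances (IncNodePurity) are averaged across rounds, and each
   sample's mean out-of-split prediction is correlated with its actual
   value. Forests use 500 trees, unlimited depth, and the engine's
   regression default `mtry = p/3` (the sqrt(p) convention belongs to
   classification and measurably degrades selection here); all three are
   arguments.
2. **Leave-one-out validation** (`rf_loo_validate`): each sample predicted
   by a forest trained on the remaining n-1, overall Spearman rho
   reported. This and the iterated procedure are deliberately two
   separate, explicit procedures rather than one coupled routine.
3. **Selection** (`select_markers`): features ranked by mean importance;
   the top 150 are filtered by Spearman association with FRAP at
   BH-FDR < 0.1 and split into positive/negative markers by the sign of
   rho. The BH family is, by default, *all* features jointly
   (`fdr_scope = "all"`). Restricting the family to the top set — the
   other reading of the source description — is selectable but
   anti-conservative: the importance ranking preferentially admits
   features whose chance association with the phenotype is large, so the
   selected family's null p-values are not uniform and the realized false
   discovery proportion can reach ~40% at these sample sizes. Alongside
   the fixed top-150, a knee estimate of the importance curve (maximal
   second difference of the sorted log mean importance) is reported.
4. **Validation of the set** (`compare_marker_models`): iterated
   50/50-split forests restricted to the markers versus all remaining
   features, on identical splits, compared by rank-sum on the two
   per-iteration rho distributions; plus Fisher-exact enrichment of
   markers in individual CAGs and per-subject delta-change associations
   (consecutive shared time points; e.g. delta-FRAP vs delta-glucose).

# The synthetic generators

`simulate_human_study()` emulates the longitudinal arm with exported
ground truth. Per subject and time point, an OTU's latent log abundance is
the sum of a lognormal baseline (sd 1.4 across OTUs), its archetype's
time-point multiplier, a subject-level effect (sd 0.6), sample noise
(sd 0.35), and — for marker OTUs — a signed loading (0.9) on a latent
per-sample antioxidant state; proportions are renormalized and counts
drawn multinomially at 20,000 reads per sample.

Design choices that matter and why:

* **Archetypes are rank codes.** A Kendall distance on a 4-point trend
  sees only the rank order of the four time points, so archetypes with the
  same rank order are mathematically indistinguishable to the clustering.
  The six planted archetypes are six rank orders at pairwise Kendall swap
  distance >= 2 (even permutations of the four points: rise-then-fall
  peaking at W4, monotone increase, monotone decrease, early peak, dip
  with rebound, late rise), with a geometric step of 1.75 between
  adjacent rank levels. Under these defaults Ward-D2 recovers the planted
  partition with adjusted Rand index 0.85–0.97 across seeds.
* **Markers ride a shared latent state.** FRAP = 900 + 150 u + N(0, 75)
  (cor(u, FRAP) about 0.9) and markers load on u with +-0.9, giving the
  planted per-marker |rho| of about 0.6 that the recovery analyses
  assume. Marker OTUs are drawn from the 25th–60th baseline-abundance
  percentile and the five negative markers are chosen to mass-balance the
  25 positive ones: if markers sat in the abundant tail, or their signed
  masses were unbalanced, the compositional denominator itself would track
  u and every null OTU would inherit a spurious (anti)correlation through
  closure.
* **Plasma at every time point.** The panel is generated at all four time
  points (a real study might assay fewer), so the default dataset carries
  68 phenotype-bearing samples. Glucose couples negatively to u
  (92 - 6u + N(0, 4) mg/dL), planting the negative delta-FRAP vs
  delta-glucose association.

`simulate_invitro()` emulates the fermenter arm: shared baseline
community; after 0 h the G2 regimes receive a 15-fold bloom of 20
designated OTUs collected under an Enterobacteriaceae-like genus (taking
it from a few percent of the community to roughly half, the scale seen
for sugar-responsive blooms in fermenter systems), and the G1 regimes a
3-fold rise of 30 fiber-responder OTUs; vessel effects are lognormal
(sd 0.3). `simulate_tree()` provides coalescent trees over the OTU set.

What the generators do **not** emulate: real 16S sparsity structure
(zero-inflation beyond the multinomial), phylogenetic correlation of
abundances (tree and abundances are independent), overdispersed library
sizes, subject-level covariates such as diet or medication, and any
feedback of the microbiota on the phenotype. Passing the recovery tests
therefore demonstrates that the pipeline's machinery is correct and
calibrated under its stated model — not that the biological effects in
any real dataset are of the planted sizes.

# Numerical and reproducibility choices

* Every stochastic stage takes one integer seed; internal stages derive
  per-step seeds through a fixed affine hash, so runs are bit-for-bit
  reproducible and independent stages are decoupled.
* Distance matrices are validated on construction (symmetry to 1e-12,
  zero diagonal, non-negativity); relative-abundance rows reconstruct to
  1 within 1e-9.
* PCoA discards eigenvalues below `1e-9 * max|eigenvalue|`.
* Permutation p-values use the add-one convention
  `(1 + exceedances)/(1 + n_perm)` and never return 0.
* The JSON run summaries contain no timestamps or environment details, so
  identical seeds give byte-identical summaries; timestamps live in the
  plain-text log.

The test suite exercises the documented defaults at the study's own sizes
(17 x 4 samples, 1000 OTUs) for the recovery checks, and scales the
replicate-based calibration checks to 100–200 replicates of smaller
instances (12–54 samples, 100–300 OTUs) — sizes chosen so each property is
measured with useful Monte-Carlo resolution while the whole suite stays
interactive.

# Known limitations

* The within/across Wilcoxon is calibrated with UniFrac or Euclidean
  distances but anti-conservative with Spearman sample distances (above).
* Marker selection with `fdr_scope = "top"` reproduces the
  winner's-curse behaviour discussed above; it exists for comparability,
  not as a recommendation.
* Chao1 needs genuine singleton/doubleton counts; any upstream denoising
  that removes singletons biases it downward.
* Kendall distances on 4 time points take at most 13 distinct values;
  with very few OTUs the Ward merge order can be tie-dominated. Input
  order breaks exact ties deterministically.
* The group PERMANOVA is one-way; designs with covariates beyond a single
  grouping or a single continuous variable are out of scope.
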