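---
title: "Methods: integrative microbiome–metabolome network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative microbiome-metabolome network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromet)
```

## The analytical problem

Case–control microbiome studies usually stop at per-feature contrasts:
which genera or metabolites differ between cohorts. This package targets
the next layer — the *relationships* between taxa and metabolites, and how
those relationships differ between health and disease states. The design
it serves is a three-cohort study (healthy controls, Crohn's disease,
ulcerative colitis) with matched stool 16S profiles, qPCR total bacterial
biomass, and metabolite concentration panels per participant.

Three properties of such data shape every downstream choice:

1. **Compositionality.** Sequencing yields proportions, not abundances.
   We restore an ecosystem scale by multiplying each sample's relative
   composition by its total 16S copy number (qPCR), and we use the
   centered log-ratio (CLR) transform and Aitchison geometry wherever a
   Euclidean view of community structure is needed.
2. **Non-normality.** Counts and concentrations are skewed and
   heavy-tailed, so group contrasts are rank-based (Kruskal–Wallis,
   Wilcoxon) and associations are Spearman correlations.
3. **Multiplicity.** Every stage tests many hypotheses; the
   Benjamini–Hochberg step-up rule is applied per clearly delimited test
   family, and exploratory significance is declared at q < 0.1.

## Pipeline and models

### Absolute abundance and CLR

`to_absolute()` computes `a(f,s) = count(f,s)/libsize(s) × copies(s)`;
column sums equal the measured biomass exactly, so relative structure is
untouched. `clr_transform()` uses `x'(f,s) = ln(v(f,s)+ε) − mean_f
ln(v(f,s)+ε)` with a default pseudocount ε = 0.5 — half the smallest
possible positive count, keeping zeros finite without dominating small
values. Each CLR sample sums to zero by construction; Aitchison distance
is the Euclidean distance between CLR columns.

### Diversity panel and permutation tests

Shannon entropy uses the natural log; inverse Simpson is `1/Σp²`. Chao1 is
the classic estimator `S_obs + F₁²/(2F₂)` with the bias form
`S_obs + F₁(F₁−1)/2` when no doubletons exist (and `S_obs` when no
singletons exist) — this is the form whose worked values the test suite
pins, and it differs from the bias-corrected variant some toolkits return.
Faith's PD sums the branch lengths spanning the observed leaves *including
the path to the root*, the common convention of the phylogenetic-diversity
toolchain this mirrors.

The one-factor PERMANOVA partitions squared distances:
`SS_total = Σ_{i<j} d²_ij/n`, `SS_within = Σ_g Σ_{i<j∈g} d²_ij/n_g`, and
`F = (SS_between/(a−1))/(SS_within/(n−a))`. P-values permute group labels
with the add-one convention `p = (1+#{F_perm ≥ F_obs})/(1+B)` so p is
never zero; when the number of distinct label assignments is at most 10×B
the complete enumeration is used and p is exact. The dispersion test
embeds samples by principal coordinates (all positive-eigenvalue axes),
measures each sample's distance to its group centroid, and permutes labels
around a one-way F on those distances, recomputing centroids per
permutation. The group-only tests reproduce the headline contrast of the
design; covariate-adjusted distance models are deliberately out of scope.

PCoA is the default ordination. NMDS (Kruskal stress minimisation) is
provided and initialised from the PCoA solution so it is deterministic,
but its optimiser rejects zero distances, so duplicated samples require
PCoA.

### Univariate contrasts

Per feature: Kruskal–Wallis omnibus (tie-corrected H, chi-square p), then
pairwise two-sided Wilcoxon rank-sum tests with the normal approximation
and tie correction. When all observations are identical the tie correction
degenerates and the result is defined as H = 0, p = 1 (no separation). BH
correction is applied across features within each contrast — matching how
per-feature q-values are reported beside an omnibus p in figure panels —
with a `within_feature` switch for the alternative family. Contrasts with
fewer than three samples on either side are reported missing and excluded
from the family.

### Association networks

For each cohort independently, every taxon × metabolite pair gets a
Spearman ρ (Pearson correlation of mid-ranks, tie-safe). The p-value uses
the t approximation `t = ρ√((n−2)/(1−ρ²))` for n ≥ 10 and exact
enumeration over all n! orderings for n < 10; pairs with a constant vector
are flagged degenerate (ρ = 0, p = 1) and excluded from the BH family. BH
runs across the cohort's full pair family (per-cohort families by default;
a global family is available), and edges are kept at `q ≤ 0.05` and
`|ρ| ≥ 0.5`, both signs retained. Cross-cohort artifacts — the Venn of
strong-positive genus edges, the per-genus association counts — use the
positive-sign subset (`ρ ≥ 0.5`).

Two genuinely open design points were settled as follows:

- **Correlation level.** Correlations are computed at ASV level and then
  collapsed to genus, because the median-per-genus-pair summary explicitly
  targets "genera with multiple associating strains", which only exists
  ASV-first. `correlation_level = "genus"` switches to genus-first.
- **Correlation scale.** Rank correlations run on the count scale by
  default. Per-sample qPCR rescaling multiplies each *sample* by a
  different factor, which is not a monotone transform of any taxon's
  cross-sample profile: empirically it attenuates a planted Spearman 0.7
  to roughly 0.5 under realistic biomass noise. The count scale is where
  rank-based effect sizes are exact; `correlation_scale = "absolute"` is
  available for sensitivity analysis.

### Differential-network analyses

`median_pair_correlations()` takes, for each (genus, metabolite, cohort),
the median ρ over *all tested* member ASVs — not only significant ones —
so a genus with one associating strain among several is summarised by its
typical behaviour. Sign-flip ("anticorrelation") pairs are those with
median ≥ 0.4 in HC and ≤ −0.4 in the disease cohort; pairs untested in a
cohort are excluded from that contrast rather than imputed as zero,
because the scatterplots of matching associations require a value in both
states. The same ±0.4 rule applies to both CD and UC, with `"either"`
taking the union.

Node rewiring follows a DyNet-style Dn score, reconstructed concretely
because the original application's normalisation is not fully specified:
for node v, build one weight vector per state over the union of v's
partners (entry = edge weight if present, else 0), take the elementwise
mean as centroid, and set `dn(v) = (1/S) Σ_s ‖w_s − centroid‖`. A
degree-corrected variant divides by the union degree; both are reported,
since degree normalisation is the main respect in which reimplementations
of such scores differ. `dn = 0` exactly when the neighbourhood is
identical in all states; dn scales linearly with the weights and is
invariant to state and partner order. Users comparing against other
rewiring tools should check the normalisation before comparing magnitudes.

For per-genus cross-state variability, "metabolites not shared by all
states in which the genus appears" is made precise as: shared = the
intersection over appearing states when the genus appears in at least two
states, else empty (sharing is vacuous with one state); variability =
|union| − |shared|. A genus seen in a single state therefore contributes
all of its metabolites.

### Over-representation analysis

For query set n drawn from background N with K pathway members in the
background and k observed hits: `p = P(X ≥ k)` for hypergeometric X,
expected hits `nK/N`, enrichment ratio k/(nK/N) (the conventional
observed/expected direction; an `invert_ratio` switch reports the
reciprocal for comparison with sources that quote it inverted). The
background is the *measured, library-mappable* metabolite universe — not
the whole library — conditioning on what the assay could have detected.
Pathways without background members are skipped and logged.

## The synthetic-cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not the raw instruments:

- **Copula.** Per cohort, a latent multivariate normal with identity
  correlation except for planted blocks: the driver ASV of a planted genus
  and the planted metabolite get latent Pearson `2 sin(πρ_s/6)`, the exact
  Gaussian-copula correspondence to a target Spearman ρ_s. Because
  Spearman correlation is invariant under the monotone quantile maps, the
  planted effect size is the expected empirical Spearman (up to ties among
  counts) — which is what makes recovery directly testable.
- **Margins.** ASV counts map through negative-binomial quantiles
  (dispersion 1.0; per-ASV means lognormal with median 100 and log-sd 1,
  the heterogeneity real panels show); metabolites through lognormal
  quantiles (per-metabolite location around log 50, log-sd 1). Biomass is
  lognormal with median 10⁹ copies/g and log-sd 0.5, the range qPCR
  typically reports for stool. Metabolite cells go missing completely at
  random at 2 %.
- **Group sizes** default to the study design: HC 20, CD 23, UC 37 — so
  power characteristics are measured at realistic n.
- **Panel dimensions.** Six genera holding 1–3 ASVs each (12 ASVs) and
  five metabolites. This is a deliberately compact, targeted-panel-sized
  problem: it keeps each cohort's BH family (60 pairs) in the regime where
  an n = 20 cohort retains non-trivial power to pass the
  `q ≤ 0.05, |ρ| ≥ 0.5` filter for a ρ = 0.7 effect, and it keeps the
  replicated studies (hundreds of full cohorts) fast on one CPU. Real 16S
  datasets have hundreds of ASVs; with family sizes in the thousands, an
  n = 20 cohort has little power for this filter — a property of the
  design, worth knowing before interpreting small-cohort networks.
- **One driver ASV per planted genus**, other members independent, so the
  genus-collapse and median logic face a known mixture of associated and
  null strains. The last genus carries the missing-genus placeholder to
  exercise the `<family>_unclassified` path. A random coalescent tree over
  the ASVs supports the phylogenetic diversity panel.

What the simulator does *not* emulate: sequencing-depth variation coupled
to biomass, compositional closure effects (taxa are latently independent
unless planted), covariate confounding, batch structure, and
metabolite–metabolite correlation. Passing the recovery and calibration
studies therefore demonstrates that the *statistical machinery* behaves as
specified under its own assumptions — not that real IBD data will yield
comparable recovery.

## Numerical choices

- Spearman p: t approximation at n ≥ 10, exact permutation enumeration
  below; the enumeration compares |ρ| with a 10⁻¹² slack so ties at the
  observed value count as extreme.
- Permutation p-values use the add-one convention except under complete
  enumeration, where the exact proportion is reported; seeds are recorded
  in every result, and all stage seeds derive from one master seed by
  stable hashing of stage names.
- PCoA keeps eigenvalues above 10⁻¹⁰ of the spectral radius; requesting
  more axes than the configuration's rank truncates with a warning.
- Missing metabolite cells are imputed as half the feature's minimum
  positive observed value (standard practice for left-censored assays);
  rank-based consumers use the unlogged imputed matrix since ranks are
  log-invariant; features with no observations are dropped with a warning.
- Degenerate (constant) vectors: correlations report ρ = 0, p = 1,
  flagged, outside the BH family; all-tied group comparisons report
  H = 0, p = 1.
- Ranking ties (genus tallies, rewiring tables) break lexicographically so
  outputs are deterministic; TSV outputs are written with fixed formatting
  so identical configurations reproduce byte-identical files.

## Validation studies and problem sizes

The test suite checks each statistic against an independent brute-force
oracle (exact Spearman enumeration at n ≤ 6, BH step-up, tie-corrected H,
hypergeometric enumeration at N ≤ 15, complete PERMANOVA enumeration at
n ≤ 8, naive rewiring recomputation), pins the closed-form spot values,
and cross-checks the distance-based tests against the vegan reference
implementations on Euclidean inputs. The replicated studies run at the
default panel and the design's group sizes: 100 replicates for
planted-edge recovery (ρ = 0.7) and sign-flip selection (±0.6), 200 for
the all-null calibration — sizes chosen so the full suite and the
acceptance script each complete in minutes on a single CPU.
`scripts/acceptance.R` recomputes all of these quantities from scratch
under a caller-supplied seed.

## Known limitations

- Spearman networks ignore compositional coupling between taxa; with small
  panels this is minor, but for full 16S tables a compositionally aware
  association method would be a natural extension. Partial or
  covariate-adjusted correlations are not provided.
- The sign-flip rule thresholds medians; it does not test the
  *difference* in correlations between cohorts, so borderline flips near
  ±0.4 are sensitive to sampling noise at n ≈ 20 — the replicated
  sign-flip study quantifies exactly this.
- The rewiring score is this package's fixed reconstruction of a Dn-style
  statistic; other implementations may normalise differently.
- NMDS requires strictly positive off-diagonal distances.
- Cohorts with fewer than four samples are excluded from network building;
  fewer than three samples make a pairwise contrast missing.
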