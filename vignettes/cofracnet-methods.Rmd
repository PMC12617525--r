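---
title: "Differential CF-MS interactome analysis with cofracnet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential CF-MS interactome analysis with cofracnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofracnet)
```

# The analysis problem

Co-fractionation mass spectrometry (CF-MS) infers protein–protein
interactions (PPIs) without antibodies or tags: a native lysate is separated
by size-exclusion chromatography (SEC) into many fractions (96 per extract
here), each fraction is quantified by LC-MS/MS, and proteins that belong to
the same complex co-elute — their abundance profiles across fractions share
a peak. `cofracnet` implements the full downstream analysis for a
*differential* design: several genotypes (e.g. wild-type, point-mutant
heterozygous/homozygous, knockout) each yield per-engine protein × fraction
matrices, and the goal is (i) a high-confidence PPI network per genotype,
(ii) overlapping complex predictions on each network, and (iii) the
cross-genotype differences: shared/exclusive interactions, interactions lost
in mutants attributed to hub proteins, and complex-level enrichment shifts.
A separate arm scores spot-level spatial expression (FCS/SNS, below).

Every stage is exercisable on synthetic data with planted ground truth, so
the package's claims are tested against known answers rather than against a
particular instrument run.

# Preprocessing

Per-engine matrices go through a fixed order: **impute** (explicitly missing
cells become zero counts), **filter** (proteins detected in at most one
fraction carry no co-elution signal and are removed), **combine** (engines
averaged cell-wise on the union of their proteins, a protein missed by one
engine contributing zero — union keeps identifications that only one search
engine made), and **normalize**. Row normalization rescales each profile to
unit total, removing abundance differences between proteins; column
normalization rescales each fraction to unit total, absorbing fraction bias
and injection variation; `mode = "both"` applies row then column (the order
is fixed and recorded in the report). All-zero rows and columns are left
untouched, so normalization preserves the zero pattern exactly and is
idempotent in row mode. Whether normalization should precede or follow
engine averaging is not determined by first principles; the package fixes
average-then-normalize and records the choice in the preprocessing report.

# Co-elution similarity features

For every candidate protein pair the package computes a feature vector of
profile similarities. The registry provides 13 metrics spanning four
families:

* correlation: `pearson`, `spearman`, `kendall` (midranks for ties),
  `cosine`, `cross_correlation_max` (best Pearson over elution shifts of up
  to 2 fractions, catching slightly offset peaks);
* co-detection: `jaccard_codetection`, `dice` on the binary detected
  pattern;
* abundance distance: `bray_curtis_similarity`, and `euclidean_similarity`
  / `manhattan_similarity` mapped to (0, 1] as 1/(1 + d);
* peak shape: `apex_match` (1/(1 + |Δapex|)), `mutual_information` (5
  equal-width bins per profile, scaled by log2(5) to [0, 1]),
  `co_peak_count` (shared fractions above each profile's 0.75 quantile,
  scaled by the smaller peak set).

The number 13 is not magic: classifiers accept any registered subset, and
the registry is the extension point for additional metrics. Degenerate
profiles (zero variance, e.g. all-zero after dropout) make correlation-type
metrics undefined; the registry maps those pairs to 0 — they carry no
co-elution evidence, and the rule keeps the feature table total. Candidate
pairs default to all-vs-all among retained proteins; an optional correlation
floor prefilter exists for very large matrices but is off by default.

# PPI classification and thresholds

Intra-complex pairs of a reference complex catalog (a CORUM-style gold
standard; in synthetic runs, the planted baseline catalog) are the
positives; negatives are drawn uniformly (default 1:1, seedable) from pairs
of annotated proteins that share no complex. Three classifiers — a 500-tree
random forest, a binomial logistic GLM, and an RBF-kernel SVM with Platt
probability calibration — are trained on the feature vectors and combined
as an **ensemble**: the unweighted mean of the three class probabilities,
the simplest order-independent combination rule. Performance is estimated
by stratified fivefold cross-validation at the pair level; a labeled pair's
reported score always comes from the fold where it was held out, so no
score is produced by a model that saw that pair. Unlabeled pairs are scored
by models refit on all labeled pairs.

The score threshold that turns scores into a network is chosen from the
pooled CV ROC. The default rule is Youden's J (maximize tpr − fpr, ties
broken toward the higher cutoff); `fixed:<v>` and `fpr_at:<v>` rules allow
reproducing externally chosen per-condition cutoffs. Finally, edges joining
topologically incompatible mitochondrial subcompartments (outer
membrane–matrix, intermembrane space–matrix) are vetoed; edges with an
unannotated endpoint pass but are counted, so the filter's reach is
auditable.

# Overlapping complex detection

Complexes are found by greedy cohesiveness clustering. The cohesiveness of
a node set V is

  w_in / (w_in + w_bound + p·|V|)

with w_in the total internal edge weight, w_bound the weight crossing the
boundary, and p a per-node penalty (default 2) modelling unobserved
connections. Seeds are taken in descending weighted-degree order among
still-unused nodes; from each seed the set grows or shrinks by the single
node move that most improves cohesiveness, stopping at a local optimum (so
every grown candidate is locally optimal under single-node moves — a
property the tests verify against a brute-force scorer). Candidates whose
overlap ω(A,B) = |A∩B|²/(|A||B|) exceeds the merge threshold `o` are merged
transitively; the merge pass is iterated to a fixpoint so re-running it
changes nothing. Merged unions are consolidations and need not themselves
be locally optimal. Last, groups below `min_size` (default 3) or with
internal weighted density below `d` are discarded — merge first, then
filter, a fixed order since it affects results.

Predictions are evaluated against a reference catalog with the standard
trio: clustering-wise sensitivity and PPV combine into Acc = √(Sn·PPV); MMR
is the maximum one-to-one ω-weighted bipartite matching divided by the
number of reference complexes; Overlap is the fraction of reference
complexes attaining ω ≥ 0.25. `optimize_params()` sweeps the conventional
(d ∈ 0.2–0.45) × (o ∈ 0.5–0.8) grid and returns the cell maximizing the
composite Acc + Overlap + MMR, ties toward higher d then higher o.

# Differential analyses

*Intersections.* The union of the genotypes' edge sets is partitioned by
exact presence pattern (the Venn decomposition); cell counts must and do sum
to the union size.

*Lost interactions.* An edge is lost when it is at/above threshold in the
reference genotype and below threshold in every comparison network. Each
lost edge is attributed to both endpoints, so per-hub percentages over
involved proteins sum to 200 — an arithmetic identity the report asserts.

*Complex-level enrichment.* Each predicted complex (consolidated across
genotypes) is treated as a gene set and scored against a per-protein
ranking statistic with the weighted Kolmogorov–Smirnov running sum: walking
down the ranked list the sum rises by the normalized |statistic|^α weight
at members (α = 1 by default; α = 0 gives the classic unweighted KS
statistic) and falls by 1/(N − k) at non-members; the enrichment score ES
is the extremum and the leading edge the members up to (or from) it. The
default ranking statistic is the summed-abundance log-ratio
log2((T_b + 1)/(T_a + 1)); a per-fraction mode (mean of per-fraction
log-ratios) weights profile shape instead of totals — both are exposed
because either reading of "comparing co-elution profiles" is defensible.
The null is gene-label permutation (random same-size sets), p = (1 +
#{|null same-sign ES| ≥ |ES|})/(1 + #same-sign nulls), the normalized ES
divides by the mean |same-sign null|, and BH adjusts across complexes. Sets
with fewer than 3 ranked members, or covering the whole universe (no
contrast), are skipped and logged.

# Spatial FCS/SNS scoring

Spots are first selected by three conjunctive rules: region label, an
externally supplied soma flag (the spot contains at least one complete
neuron soma), and every declared marker gene (e.g. the dopaminergic markers
Th, Slc6a3/DAT, Slc18a2/VMAT2) at or above a count floor. Counts are
normalized per spot to a fixed total of 10,000 and log2(x + 1) transformed.
The fixed target (rather than a data-dependent one such as the median spot
total) is deliberate: it makes the whole chain — means, SDs, t-test P,
scores, and DEG calls — exactly invariant to a global rescaling of the raw
counts, a property the tests enforce; with a data-dependent target the
scaling constant would survive into the log and shift every score.

Per gene, a two-sided two-sample t test compares groups (Welch by default
as the safer unequal-variance choice; Student's pooled variant is exposed).
Genes with zero variance in both groups get P = 1 by convention. The two
ranking scores are

  FCS = log2(μ_test / μ_ref) · (−log10 P)
  SNS = ((μ_test − μ_ref) / (σ_test + σ_ref)) · (−log10 P)

with a pseudocount of 1 entering the ratio when a mean is zero and the σ
sum when it is zero, keeping both scores finite. A gene is called a DEG
when P < 0.05 and it ranks in the top 20% by |FCS| **and** by |SNS| (dense
ranks, ties share a rank, cutoff ⌈0.2·N⌉; absolute scores capture both
directions, and a signed mode exists). Whether the t test should run on raw
or normalized counts is not an settled convention; the package defaults to
normalized and exposes `normalization = "none"`.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
study conditions used throughout the tests: 50 planted complexes of 3–8
subunits, 150 background proteins, 96 SEC fractions, 3 engine replicates.
Members of a complex share a Gaussian elution peak — the complex's apex and
width (width 5–12 fractions), a per-member apex jitter of at most 0.4
fractions, and member-specific lognormal amplitudes (median 5 counts).
Background proteins, and members of complexes deleted in a genotype, get
independent random apexes. Per engine, counts are drawn from a
gamma–Poisson (negative binomial) mixture at the profile mean
(overdispersion 1), and dropout independently zeroes 35% of cells;
`count_noise = 0` yields exactly the continuous mean profiles, the
noise-free case the tests lean on. The noise defaults were calibrated once
so that ensemble cross-validation on the default conditions lands in a
realistic 0.8–0.95 auROC band (it sits near the top of that band), and the
jitter bound keeps noise-free co-members above Pearson r = 0.99; neither
has been revisited since.

Genotype rewiring draws one action per complex from configured
probabilities: `kept`, `deleted` (members dissolve into background),
`split` (two disjoint subsets of ≥ 2 members with fresh apexes; size-3
complexes cannot split and fall back to `kept`, which the log records), or
`apex_shifted` (whole complex moved ≥ 10 fractions). The spatial generator
plants negative-binomial counts (dispersion 5) with a configurable DEG
fraction at ±`effect_size` log2 units, plus marker genes and a control
region so spot selection is exercisable.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: peptide-to-protein inference artifacts, correlated
dropout along the elution axis, shared subunits between complexes,
abundance-dependent detection, multi-peaked profiles from moonlighting
proteins, or batch structure between engines beyond independent noise.
Results on real matrices depend on upstream search-engine quality in ways
the simulation cannot certify.

# Numerical choices and degenerate inputs

* Correlation-type metrics return 0 for zero-variance profiles; MI bins
  collapse to one bin (MI 0) for constant profiles.
* Cohesiveness returns 0 when its denominator is 0 (isolated node, zero
  penalty); greedy growth accepts only strict improvements, so it cannot
  cycle.
* Grid ties break toward higher d then higher o; Youden ties toward the
  higher cutoff; ROC endpoint cutoffs (±Inf) are clamped into [0, 1].
* GSEA p-values use the +1-corrected permutation count, so p ∈ (0, 1] and
  the minimal attainable p is 1/(#same-sign nulls + 1).
* All stage outputs print floating-point numbers at 6 significant digits,
  and every stochastic stage consumes a named sub-seed derived from the
  master seed, which is what makes two runs of `run_pipeline()` with one
  seed byte-identical.

# Problem sizes used by the checks

The test-suite and the acceptance script run at sizes chosen as a
representative desk-scale version of the design: classifier checks at the
full default conditions (about 425 proteins, ~1,250 labeled pairs, fivefold
CV); clustering oracle checks on 100 random graphs of ≤ 10 nodes (where
brute force is exact); recovery checks on the 50-complex planted network;
GSEA calibration on 200 random sets of 15 genes at 1,000 permutations over
a 500-gene universe; spatial checks at 20 spots per group and 1,000 genes;
and the determinism check on an 8-complex, 48-fraction, two-genotype
configuration run twice end to end.

# Interfaces

The package is a function library: `run_pipeline()` with a
`pipeline_config()` (or a YAML file via `read_config()`) is the
orchestrated entry point, and each stage is equally usable on its own. All
artifacts are plain text — TSV for matrices, feature tables and edge lists
(canonical lexicographic pair order, kept/removed flags), GMT for complex
catalogs, JSON (with a schema field) for reports and the run manifest — so
runs are diffable and auditable.

# Known limitations

Cohesiveness growth is greedy, not exact; at scale there is no guarantee of
globally optimal clusters (brute force is a test oracle only). The ensemble
is a plain probability mean — no stacking or weighting. Negative training
pairs are drawn only among catalog-annotated proteins, which mirrors the
usual gold-standard construction but leaves un-annotated proteins scored
purely by extrapolation. The disease/ontology annotation of
genotype-exclusive assemblies is out of scope (database-dependent); the
assemblies themselves are exported.
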