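---
title: "Profiling bacterial environmental sensors across metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling bacterial environmental sensors across metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensorscape)
```

## The problem

Prokaryotes monitor their surroundings chiefly through two-component
systems, whose input side is the sensor histidine kinase (HK). An HK is
recognizable in domain-annotated data by the co-occurrence of its two
conserved domains — the HATPase catalytic domain (Pfam PF02518) and the
HisKA dimerization/phosphoacceptor domain (PF00512) — and it may carry
anywhere from zero to a few dozen *sensory* domains, the regions that
actually detect pH, oxygen, osmolarity, antimicrobial peptides and the
rest of the chemical and physical environment. A Pfam family such as PAS
is far too coarse to identify what a given sensor responds to: one
accession can cover thousands of functionally distinct sensors.

`sensorscape` implements the resulting analysis idea end to end: excise
the sensory domains of every HK in a collection of metagenomes, cluster
them at high sequence identity into putative *sensor families*, describe
each metagenome by the fraction of its gene copies assigned to each
family (the **sensor profile matrix**), and then ask what that profile
can tell you — which ecosystem the sample came from, what physical
parameters it experienced, which sensors discriminate disease states —
using gradient-boosted tree models with additive per-feature
attributions.

## Pipeline and model choices

### Extraction

A gene is an HK iff its hit set contains at least one hit for *each*
conserved accession. Coordinates are treated as 1-based and inclusive at
both ends (the Pfam/HMMER alignment-coordinate convention; annotation
exports rarely state theirs, so the convention is fixed and documented
here). Excision takes the exact substring of the protein at the recorded
coordinates for every hit whose accession is in the curated sensor set;
accessions in neither set are ignored. Overlapping sensor hits within
one gene are resolved by *dropping the shorter hit* (with a warning)
rather than truncating: excision must yield non-overlapping substrings,
and truncated fragments would contaminate downstream clustering with
artificial sequence boundaries. Repeated hits of the same accession each
yield their own sensor domain — repeat proteins genuinely carry many
similar sensing modules.

### Clustering

The clustering unit is the *unique* sensor sequence (exact duplicates
are collapsed first and re-expanded afterwards). The built-in clusterer
is greedy incremental centroid clustering in the CD-HIT tradition:
sequences are visited longest-first (ties broken lexicographically by
id, so the procedure is deterministic without any seed) and each joins
the first existing centroid meeting the identity and coverage
thresholds, else founds a new cluster. Identity comes from a global
Needleman–Wunsch alignment scored match +1 / mismatch 0 / gap −1 —
the scoring under which the optimal score directly counts matches minus
gaps — and is reported as matches over alignment columns; coverage is
aligned residue pairs over sequence length, with `bidirectional`
(minimum of the two), `target` and `query` modes. The alignment kernel
is compiled (quadratic DP with a fixed traceback preference:
diagonal, then gap-in-target, then gap-in-query), which keeps the
desk-scale corpora used here comfortably fast without any k-mer
prefilter.

Defaults are `min_identity = 0.5`, bidirectional coverage `0.8`. The
identity threshold intentionally sits *above* what Pfam-level grouping
implies but is left configurable: there is no single canonical value,
and the planted-family experiments below use 0.8. An adapter for an
MMseqs2-compatible external binary (`cluster_external()`) parses the
tool's native two-column cluster TSV into the same assignment structure;
a missing binary is a hard error, never a silent fallback to the
built-in path.

### The profile matrix

The value for metagenome $m$ and cluster $c$ is

$$x_{mc} = \frac{\sum_{g \in m,\, g \to c} \mathrm{copy}(g)}{\mathrm{total\ copy}(m)},$$

the copy-number-weighted fraction of $m$'s genes contributing at least
one sensor domain to $c$. A gene with domains in $k$ distinct clusters
contributes its full copy number to each of the $k$ clusters, but only
once per cluster however many of its domains land there; the
"count once total" alternative was rejected because it would make a
cluster's value depend on which *other* clusters a gene touches. A
consequence, documented rather than hidden, is that row sums can exceed
the per-gene sensor fraction when multi-cluster genes exist; the
conservation invariant is therefore stated per cluster-contribution, and
holds to 1e-9 relative tolerance in the test suite.

Two filters prepare the matrix for modeling, in this order: clusters
present in fewer than `min_prevalence` metagenomes are dropped (sparsity
control; prevalence means *presence*, value > 0, not a minimum
abundance), then label classes with `min_per_class` or fewer members are
dropped — strictly greater-than semantics, so the conventional value 30
keeps classes of 31 and up — along with any labels in `drop_labels`
(default `"Unclassified"`, matched against the full label and each
":"-separated level). Richness statistics are computed on the
*unfiltered* matrix: the prevalence filter exists for the models and
would bias diversity downward.

### Richness statistics

For ecosystem $E$ with cluster set $C_E$ (clusters present in at least
one sample of $E$) and global cluster set $C$:

* **RER** (Relative Ecosystem Richness) $= |C_E| / |C|$ — how much of
  the observed sensor landscape the ecosystem spans.
* **ETSR** (Ecosystem Typical Sample Richness) $=$ mean over samples of
  per-sample distinct-cluster count, divided by $|C_E|$ — how much of
  its own repertoire a typical sample carries. A single-sample ecosystem
  scores exactly 1; an ecosystem with no clusters is reported as `NA`,
  never 0/0.

Between-ecosystem Spearman correlations are computed on the per-class
*mean* abundance vectors. The plausible alternative — pooling samples
pairwise — is exposed by computing on any matrix you pass in, but mean
profiles are the default because they are well-defined for unbalanced
class sizes. Rarity counts (`rare_cluster_enrichment()`) default to
ecosystem-unique clusters (`rarity_max_ecosystems = 1`), configurable.

### Models

Classification (ecosystem, condition) and regression (physical
parameters) both run on gradient-boosted decision trees via xgboost,
driven single-threaded with a fixed seed so every fit is bit-for-bit
reproducible. The boosting backend is deliberately treated as an
abstract contract — fit, predict, per-class raw scores, tree-path
attributions — and nothing downstream depends on which library provides
it. Splits are 70/20/10 train/test/validation, stratified by class with
largest-remainder rounding (per-class counts within one sample of exact
proportionality). Grid search is an exhaustive Cartesian sweep over
learning rate, tree depth and L2 leaf regularization, selected on the
validation metric (accuracy or R²) with ties broken by grid order;
headline metrics are reported on the untouched test split. No class
reweighting and no feature selection are applied by default.

### Attributions

`attribute()` returns per-(sample, class, feature) additive
contributions computed by the tree ensemble's own TreeSHAP path
(`predcontrib`), whose defining *local accuracy* property — per sample
and class, contributions plus base value equal the raw margin — is the
module's hard gate on any backend and is asserted in the tests at 1e-6
relative tolerance. One numerical note: the backend accumulates scores
in single precision, so the additivity residual grows with the number of
boosting rounds and the margin magnitude; at the moderate model sizes
used throughout (tens to low hundreds of rounds) it stays one to two
orders of magnitude below the gate. Feature rankings sum absolute values
by default (signed sums are an option) because a feature that pushes
strongly in both directions is still informative; ties break by feature
id so rankings are invariant to sample order.

### Unsupervised views

Heatmap ordering uses average-linkage hierarchical clustering on
Euclidean distances of `log2(x + pseudocount)` values, the pseudocount
defaulting to half the smallest nonzero matrix entry (the smallest value
that cannot create spurious structure below the data's own resolution).
2-D embeddings use t-SNE with perplexity 30 clipped to $(n-1)/3$; up to
500 rows the exact gradient is used rather than the Barnes–Hut
approximation, which costs little at these sizes and makes duplicated
profiles embed essentially coincident — a property the tests rely on.
Embeddings are deterministic given their seed.

## The synthetic-data generator

Every stage is testable without external data because the generator
plants known structure and returns it as ground truth:

* A **family pool** of centroid sequences over the standard 20-letter
  alphabet (uniform composition — the simplest model that exercises
  identity-based clustering), rejection-sampled so all pairs are below
  50% identity: planted families are separable at any threshold ≥ 0.5.
  Family members substitute at most a `mutation_rate` fraction of
  positions, so within-family identity never falls below
  `1 − mutation_rate`. Since only substitutions are used, a variant and
  its centroid align trivially; families, not alignments, are what the
  generator is meant to stress.
* Each **ecosystem** gets abundance weights over the pool; per-sample
  mixtures are Dirichlet-distributed around them (concentration 50 by
  default — samples clearly resemble their ecosystem without being
  copies). The generating literature describes no per-sample noise
  model, so Dirichlet-multinomial is this module's choice, stated as
  such.
* Per-sample totals are Poisson around the background mean scaled so
  that HK sensor genes are Binomial at the ecosystem's
  `sensor_fraction_mean` — realized fractions calibrate to the mean
  within binomial noise, which the suite checks at three standard
  errors. Copy numbers are geometric with mean 2, exercising
  copy-number weighting without modeling read mapping. Default
  ecosystem sizes in the shipped configurations (tens of samples per
  class, ~100 genes per sample, 6–24 families) scale the corpus to
  seconds of runtime while leaving every statistic well away from
  small-number degeneracy.
* HK genes are laid out sensors-first, then HisKA, then HATPase, with
  5-residue linkers, and the full protein string is emitted with the
  sensor sequences spliced in at the annotated coordinates — so
  extraction can be verified as an exact substring recovery.
  `inject_multidomain_hk()` rebuilds a subset of genes with up to
  `max_domains` same-family sensor domains (non-overlapping, ordered by
  construction), which leaves planted per-family fractions untouched
  because profiling counts a gene once per family.

What the generator does *not* emulate: real Pfam domain models (hits
are planted, not found by HMM search), within-family
insertion/deletion variation, correlated family co-occurrence,
compositional biases of real proteomes, and annotation noise
(false/missed hits). Passing tests therefore demonstrate that the
machinery is correct and that planted structure of realistic magnitude
is recovered — not that any particular real ecosystem is classifiable
at a particular accuracy.

## Numerical and degenerate-input decisions

* Identity threshold 1.0 with all-distinct input yields singleton
  clusters; raising `min_identity` can only increase cluster counts
  (monotonicity, tested).
* `etsr()` on a clusterless ecosystem returns `NA`; `rer()` with no
  clusters anywhere is an error (there is no meaningful denominator).
* Spearman correlations involving a constant vector are `NA`, not an
  error, except for `correlated_feature_group()`'s anchor, where a
  constant anchor means the question itself is ill-posed.
* `split_profile()` refuses to stratify classes with fewer than 3
  samples, naming the class.
* A constant regression target is an error; predicting the held-out
  mean scores R² = 0 by construction.
* Grid-search metric ties resolve to the first grid point, making the
  search deterministic.
* Pipeline stage failures halt the run naming the stage; artifacts
  already written are retained for inspection.

## Problem sizes

The shipped test suite and the acceptance script run corpora of 80–200
metagenomes, 2–12 planted families and ~100 genes per sample: large
enough that classifier recovery, permutation nulls, calibration checks
and rank correlations are statistically meaningful, small enough that
the whole suite completes in a few minutes on one CPU. These sizes are
package choices for its own reproducible experiments; all stages accept
arbitrarily larger inputs, with the quadratic alignment step being the
first thing to watch as unique-sequence counts grow past tens of
thousands.

## Known limitations

* The greedy clusterer is exact but quadratic in comparisons; it has no
  k-mer prefilter, so very large unique-sequence sets belong with the
  external-tool adapter.
* Identity from a single optimal alignment is tie-broken by a fixed
  traceback preference; a different preference could report marginally
  different identities for equally-scoring alignments (partitions at
  the tested thresholds are unaffected).
* The Pfam-level comparison matrix assigns each cluster its majority
  accession; clusters with genuinely mixed annotation lose that nuance.
* Attribution values inherit the backend's single-precision arithmetic
  (see above); they are attributions of the *raw margin*, not of the
  softmax probability.
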