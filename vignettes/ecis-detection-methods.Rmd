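---
title: "Detecting and characterizing eCIS loci: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing eCIS loci: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecisfinder)
```

# The detection model

Extracellular contractile injection systems (eCIS) are operon-encoded,
phage-tail-derived particles. Detection works entirely at the annotation
level: it needs gene coordinates, pfam/COG assignments and HMM hits against
the Afp1–16 core profiles, never raw sequence. The procedure is a chain of
conservative filters; every one of them is a tunable in `core_config()` and
the defaults are the package's reference profile.

1. **Seeding.** Protein-coding genes whose pfam set intersects the eCIS
   pfam vocabulary are seeds. The shipped vocabulary covers the classic
   core domains (tail tube Phage_T4_gp19, sheath Phage_sheath_1, baseplate
   GPW_gp25 and Baseplate_J, spike PAAR_motif and Phage_GPD, AAA ATPase,
   and the DUF4255 cap domain, which maps to the eCIS-specific role
   afp16). It is deliberately small and user-extensible: any in-house
   pfam-to-role curation can be merged in, and all downstream behaviour
   follows the configured map, not a hard-coded list.
2. **Linkage chaining** (`linkage_gap_bp`, 12,000 bp). Seeds on one
   scaffold chain into a group while the nearest-boundary gap to the
   previous seed stays at or below the threshold. Distance is
   `max(0, start_downstream − end_upstream − 1)`, strand-ignored; "within
   12 kb" is read inclusively, and both conventions are fixed once, here,
   for every module.
3. **Seed filter** (`min_seed_genes` 4, `min_distinct_seed_pfams` 3).
   Requires a minimum of linked, domain-diverse evidence before anything
   else is spent on a group.
4. **Contamination screen** (`contamination_window_bp`, 10,000 bp).
   Because phage tails, T6SS and eCIS are homologous, any gene carrying a
   blocklisted phage pfam or T6SS COG within the window of any group
   member — including the members themselves — discards the group. The
   whole scaffold is scanned, not just the eventual locus window, since
   the window is anchored on the members.
5. **Expansion** (`expansion_genes`, 10). The group grows by up to ten
   protein-coding genes on each side to capture accessory genes; non-coding
   genes are skipped and do not consume the budget. Candidates whose
   expanded spans overlap on one scaffold are merged before finalization,
   so one physical locus split by a large internal gap is reported once,
   not as fragments.
6. **Core census and pyocin screen** (`min_core_genes` 10,
   `hmm_keep_fraction` 0.5). Core roles are the union of pfam-map roles
   and surviving HMM hits. A locus needs at least ten core genes —
   counted with gene multiplicity, because core genes frequently occur in
   paralogous copies; counting distinct roles instead would reject
   exactly the loci that motivated the rule (a `count_core_as` switch is
   provided) — and at least one eCIS-specific core (afp12/13/14/16),
   which separates eCIS from R-type pyocins that share everything except
   the inner-tube module.
7. **Boundaries** (`boundary_flank_genes`, 4). The reported locus runs
   four protein-coding genes beyond the extreme core genes, clipped at
   scaffold ends. The flank width is a reporting convention, not a claim
   about operon biology.

## The HMM percentile filter

HMM hits are rank-filtered by bitscore: the top `ceiling(f·n)` per profile
are kept, with two deliberate conventions. Ties with the last kept score
are retained — equal evidence is never discarded, and a lone hit always
survives — and the percentile is computed **per profile across the whole
batch**, not per genome, because profile score distributions differ by
orders of magnitude and per-genome percentiles would be unstable for rare
profiles (`percentile_scope = "global"` restores pooled ranking). E-values
are carried but not thresholded at this stage; only the fiber analysis
applies an E-value cutoff.

# Enrichment statistics

All 2×2 association tests use a two-sided Fisher exact test (sum of the
probabilities of all tables, at fixed margins, whose hypergeometric
probability is at most the observed one, with a 1 + 10⁻⁷ relative
tolerance — the same tolerance convention as `stats::fisher.test`, whose
p-values the implementation reproduces to 10⁻¹⁰ in tests). The reported
odds ratio is the **unconditional sample OR** `(a·d)/(b·c)` rather than the
conditional MLE, because complete depletion and complete fixation should
print as exactly 0 and ∞; `0/0` is reported as `NA`. Multiple testing uses
Benjamini–Hochberg; q-values that underflow to exactly zero are clamped to
10⁻²⁵⁰ so they survive `-log10` for volcano plots.

Pfam enrichment counts at **gene granularity**: a gene either carries a
domain or not, with repeat domains deduplicated within each gene, so a
50-repeat protein contributes once. The background is whatever gene
universe the caller supplies; the core/shell/cloud classes (>10, 4–10,
<4 phyla) need a genome-to-phylum mapping, and unmapped genomes pool into
one pseudo-phylum `"unclassified"` — with no mapping at all, every
in-locus domain is necessarily "cloud", which the output flags by
construction rather than hiding.

# The contrasting-pairs test

Genus-level Fisher tests inherit the taxonomic structure of sequence
databases: a trait fixed in one heavily sequenced clade looks enriched no
matter how often it evolved. The pairwise-comparison test conditions on
the phylogeny: it counts vertex-disjoint tip pairs with edge-disjoint
connecting paths (shared internal nodes allowed) whose members differ **in
both genotype and phenotype** — each such pair is one phylogenetically
independent instance, supporting the association when the genotype-1 tip
is the phenotype-1 tip, opposing otherwise. Under no association a pair
supports or opposes with equal probability, so the support count is
sign-tested against Binomial(max_pairs, ½); we report the upper tail.

Because several maximum pairings generally exist, the supporting count is
not unique; the dynamic program reports its attainable minimum and maximum
(`worst_support`, `best_support`) with the corresponding `p_worst` and
`p_best`, and the honest reading is the interval between them. The DP
works post-order: each subtree exports at most one unpaired tip (any pair
crossing the subtree boundary must use its root edge, and edges are
disjoint), so a node state is a census of exported tip classes; maximum
pairs and support bounds combine exactly, polytomies included. The
implementation is validated against brute-force enumeration on 500 random
trees in the test suite, and its null calibration is measured by
simulation: with 32-tip random trees and independent fair-coin traits the
fraction of replicates with `p_best < 0.05` sits at 0.05 within Monte
Carlo error (the best-case selection inflates it mildly; the worst-case
tail is correspondingly conservative — report both, trust neither alone).

Degenerate inputs are defined, not errors: tips with a missing state are
pruned per trait; no genotype variation means `max_pairs = 0` and `NA`
p-values; clade-confounded traits give `max_pairs = 1` regardless of tip
count, which is the entire point of the statistic.

# Tail-fiber classification

Afp13 fiber genes (top quartile of afp13 bitscores, ties kept — the same
rank rule as the core filter) are compared between two BLAST searches,
against tailed phages and against eukaryotic-targeting viruses. Hits with
E-value ≥ 10⁻³ are discarded — the cutoff is interpreted as a BLAST
E-value, the only significance measure tabular BLAST output carries. The
best surviving bitscore per database decides: a margin strictly greater
than 15 bits calls the database, a margin of at most 15 (inclusive) is
inconclusive, one-sided evidence is called for the database present (the
two-hit comparison degenerates naturally), and no surviving evidence is
`no_hit`. Raw bitscores are compared, not bitscore-per-length.

# What the synthetic generator does and does not emulate

`sim_genome()` plants, per scaffold, one feature with exact labels:
a valid operon (12 cores by default: four seed genes with distinct eCIS
pfams, the rest carrying HMM hits, always including an eCIS-specific
core), a pyocin-like decoy (same shape, no specific core), an undersized
operon (6 cores), phage/T6SS decoys (valid operon plus a blocklisted gene
at a configurable offset, 8 kb by default — inside the window; 11 kb
probes the clean side), or background only. Geometry defaults — gene
lengths 300–4,500 bp, intergenic gaps 5–500 bp — keep planted operons
comfortably inside the 12 kb linkage rule, as real eCIS operons are.
Planted HMM bitscores (60–100 bits) are strictly above noise scores
(10–25 bits), and one noise hit is emitted per planted hit of each
profile, so planted hits occupy the top half of every profile's ranking
and survive the percentile filter *by construction* — batch-wide, however
many plants share a profile. Background pfams are drawn from a vocabulary
disjoint from the eCIS and blocklist vocabularies, keeping truth labels
exact.

The generator is honest about what it is: annotation-level data with
clean margins. It does not emulate annotation noise (missing or wrong
pfam calls), HMM score overlap between true and spurious hits, operons
truncated by contig breaks, nested or tandem loci, or compositional
realism of any kind. Passing the planted benchmarks therefore
demonstrates that the *rules are implemented exactly*, not that the
thresholds are optimal on real annotations — on real data, sensitivity
is bounded by annotation quality, and the stringent defaults deliberately
trade recall for precision.

`sim_tree_traits()` provides the three association regimes (scattered
association, clade confounding, null); `sim_fiber_hits()` realizes each
intended fiber call under the margin rule, including single-database and
E-value-failing variants.

# Numerical conventions and problem sizes

* Coordinates are 1-based inclusive everywhere; half-open arithmetic never
  crosses an interface.
* All threshold comparisons are inclusive (`≤ 12,000`, `≤ 10,000`,
  `≥ 10 cores`); the fiber margin is the one strict comparison (`> 15`).
* Rank filters use `ceiling` and keep ties, so they are monotone in the
  kept fraction and permutation-invariant.
* Detection is deterministic; the only randomness in the package lives in
  the generators, which take explicit seeds and restore the RNG state.
* Output files are stamped with the package version, an md5 hash of the
  canonical YAML form of the configuration, and the seed; equal stamps
  imply byte-identical files.

The shipped test suite validates the Fisher implementation by exhaustive
enumeration over all 2×2 tables with margins ≤ 30 (about 164,000 tables),
the pairs DP on 500 random trees of up to 10 tips against brute force,
null calibration on 1,000 replicates of 32-tip trees, and detection on 240
planted scaffolds (40 genomes × 6 scenario kinds). These sizes were chosen
to exercise every boundary several times over while keeping a full run in
the low minutes on a single core; they scale linearly if heavier
validation is wanted.

# Known limitations

* Detection quality is bounded by the input annotation; genes without
  pfam/COG calls are invisible to seeding and the blocklists.
* The locus model is single-scaffold; operons split across contigs are
  reported as fragments or missed by the census.
* No subtype classification (subtype I/II) is attempted, and plasmid
  assignment is out of scope: an externally computed plasmid score column
  can be joined and thresholded (`plasmid_score_cut`, 0.7) but no score is
  computed here.
* The genus and pfam enrichment backgrounds are whatever universe is
  supplied; their q-values are only as meaningful as that universe is
  representative.
* `best_support`/`p_best` is a selection maximum; for confirmatory use,
  `p_worst` is the conservative bound.
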