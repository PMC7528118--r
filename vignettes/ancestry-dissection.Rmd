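---
title: "Dissecting hybrid cultivar ancestry: models, assumptions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting hybrid cultivar ancestry: models, assumptions, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybrisect)
```

`hybrisect` analyses a diploid SNP panel — two progenitor-species
accessions, optional outgroup species, and a set of hybrid cultivars —
called against the reference progenitor's transcriptome. This vignette is
the package's account of the models it implements, the parameters that
matter, what the simulator does and does not emulate, and the design
decisions taken where the problem left genuine choices.

## Genotype re-calling from allele depths

RNA-seq genotyping under-calls heterozygotes when allele expression is
uneven, so genotypes are re-defined from per-allele read fractions
(`recall_panel()`). With `f(a)` the fraction of the cell's reads carrying
allele `a`, and alt₁ the most-supported alternative allele:

* hom-ref when `f(ref) >= 0.80` (inclusive);
* hom-alt₁ when `f(alt1) > 0.80` (exclusive);
* het ref/alt₁ when `f(ref) > 0.30` and `f(alt1) > 0.30` and
  `f(ref) + f(alt1) >= 0.80`;
* otherwise missing. Cells with total depth `< 5` are missing before any
  rule applies.

The mixed strict/non-strict inequalities are preserved deliberately; a
vector such as 7 ref / 3 alt reads is missing (0.70 < 0.80 and 0.30 is
not > 0.30). All thresholds are configuration
(`recall_thresholds()`). Three consequences worth knowing:

* only ref/alt₁ heterozygotes can be produced — a het between two
  alternative alleles never comes out of re-calling (it can still enter a
  panel through GT fields when depths are absent);
* ties between alternative alleles break to VCF record order, but at the
  default thresholds a perfect tie can never satisfy the het sum rule, so
  the tie-break is only observable with relaxed thresholds;
* fractions are taken over reads of *all* observed alleles of the locus,
  the natural reading when multiallelic records are kept whole.

Two locus filters follow: `filter_informative()` keeps loci where at
least one cultivar differs from the reference progenitor's call (the
"entire dataset" all downstream stages use), and `subset_no_missing()`
keeps fully called loci. A locus whose reference-progenitor call is
missing is retained by the informative filter whenever a cultivar has a
call there: missingness cannot demonstrate monomorphism.

## The 12-way origin taxonomy

Given the progenitor calls at a locus (allele sets `A` and `B`) a
cultivar call maps to one of 12 categories (`genotype_categories()`).
Two constraints pin the numbering: category 7 is the heterozygote
carrying one allele shared by both progenitors and one novel allele, and
the out-carrying categories are exactly 6–10. `SHARED_HET` (5) covers
cultivars equal to a common heterozygous progenitor genotype.

Classification has two modes:

* **strict** (default, used for approach-1 proportions): progenitors are
  assumed homozygous, so a heterozygous progenitor call at a locus where
  `A != B` makes the locus `UNKNOWN`. Identically heterozygous
  progenitors (`A == B`) remain classifiable as shared.
* **containment**: each cultivar allele copy is classified by set
  membership — in `A` only, in `B` only, in both (shared), in neither
  (out) — and the copy pair decides the category.

The containment mode must be total over inputs the strict table never
produces. The resolution: out-carrying pairs first, then the mixed
ax/int heterozygote, then the both-copies-shared heterozygote, then
whole-pair containment (a het pair fully inside one progenitor's allele
set takes that progenitor's homozygous category, `A` checked before
`B`); a homozygote in `A ∩ B` is `SHARED_HOM` even when `A != B`. These
conventions only matter for heterozygous progenitor calls and are
irrelevant to the strict default.

## Three allele-proportion models

For a cultivar, `estimate_ancestry()` reports fractions of allele copies
`p_ax + p_int + p_shared + p_out + p_unknown = 1` under:

* **approach-1 allele counting** — category counts, each classified locus
  contributing 2 copies; heterozygous categories contribute 1 copy per
  side, so het progenitor-origin and out SNPs carry half the weight of
  their homozygous counterparts. `UNKNOWN`/`MISSING` loci are excluded
  from the denominator (reported as `n_unknown`); category *proportions*
  (`category_profile()`) by contrast keep them as categories, since a
  profile is a description of the dataset while allele proportions are
  meaningful only on classified loci. Two additional columns report the
  progenitor-polymorphic-denominator rates (`p_ax_poly`, `p_int_poly`):
  copies over twice the classified loci where the progenitors differ —
  the scale on which progenitor contributions are conventionally quoted.
* **pure parents** — a boundary model assuming hypothetical fully
  homozygous progenitors with no common allele: the reference allele is
  progenitor A's, the first alternative is progenitor B's, anything else
  is out. It never reads the progenitor calls, hence is invariant to
  them; `p_shared = 0` by construction and `p_unknown` counts only
  missing cultivar calls.
* **exact parents** — the opposite boundary: the sequenced progenitor
  samples are exactly the ancestral genotypes; copies are assigned by
  containment, loci with any missing call among progenitors and cultivar
  go to `p_unknown`.

Because pure-parents credits every reference copy (including shared
alleles) to progenitor A while exact-parents credits only A-exclusive
copies, the two bracket the progenitor-A contribution and the approach-1
estimate falls inside the bracket — a property the acceptance suite
verifies over randomized simulations. The margin is driven by the shared
allele mass and missingness; with no shared alleles and no missing data
all three coincide.

## Diversity statistics

Heterozygosity is het calls over non-missing calls by default; the
denominator is configurable to all loci. The non-missing convention
avoids deflating low-coverage samples at the cost of comparing rates
across slightly different locus sets. Pairwise SNP counts use
pairwise-complete loci and count any inequality of unordered allele
pairs (hom vs het sharing an allele counts); a lenient "disjoint allele
sets" mode is available.

## Map projection

Transcripts are placed on the linkage map wherever a mapped marker's
scaffold position falls inside a transcript anchor. Placements on one
linkage group are merged by single-linkage chaining at 1 cM (merged
position = unweighted mean of marker positions); farther-apart placements
are all retained — retention, not deletion, since distant double
placements are informative about paralogy or misassembly. Per-SNP
similarity rates (`similarity_rates()`) encode the fraction of the
category's allele copies identical to progenitor A: 1 for hom-A and
shared-hom, 0.5 for any het carrying one A or shared allele, 0
otherwise, with `UNKNOWN`/`MISSING` excluded. Track aggregation is
SNP-weighted, not transcript-weighted. Low-recombination regions — long
marker gaps, where few markers span a long genetic distance — are masked
from tracks; the default rule masks intervals between consecutive
markers more than 5 cM apart (`gap_cM` and `min_markers` are both
configurable, since no single threshold suits every map).

## Phenotype-group contrasts

Two between-group predicates are exposed because the informal notions
"polymorphic between groups" and "only polymorphic between groups"
differ: `between_group_polymorphic()` (any cross-group pair of
non-missing calls differs) and `fixed_difference_loci()` (each group
internally monomorphic and fully called, the shared calls differing).
Both are symmetric in the groups.

`category_enrichment()` reports, per cultivar, category proportions
inside a locus subset versus the whole panel and their ratio. That raw
ratio is biased above 1 under the null for het- and out-carrying
categories: conditioning on between-group polymorphism enriches
variable genotypes for *every* cultivar. The group-level statistic
therefore compares each group's mean subset proportion against the mean
over all contrast cultivars (`relative_ratio`), which is self-normalizing
(expectation 1 under exchangeable groups) — this is the statistic to read
for "is category 7 enriched in the trailing group". A label-permutation
p-value (`enrichment_permutation_test()`) is available as an extra
beyond the descriptive proportions; with 3 + 3 cultivars only 20 label
partitions exist, so its resolution is coarse.

`introgression_track()` counts out-category and category-7 SNPs per
placed map position, restricted to between-group polymorphic loci, per
cultivar and pooled (summed, not averaged) per group — pooling matches
reading the group ring of a map plot as total introgressed-allele
abundance.

## The simulator

`simulate_panel()` emulates the study conditions the analysis assumes:

* 7 linkage groups of 100 cM; transcripts (one synthetic scaffold each,
  ~1 kb, about 3 SNPs each) tiled uniformly; each transcript carries one
  mapped marker, so placement is exercised without a real genome.
* progenitor A nearly homozygous (`het_ax = 0.07`), progenitor B highly
  heterozygous (`het_int = 0.593`); at hom–hom loci the progenitors share
  the reference allele with probability `shared_allele_prob = 0.35`;
  heterozygous progenitor genotypes are ref/alt₁ (a shared ancestral
  polymorphism), which also produces shared and `SHARED_HET` loci.
* six cultivars (defaults): three trailing with
  `(p_ax, p_int, p_out) = (0.45–0.50, 0.45–0.50, 0.05)` and
  unconstrained heterozygosity (~45%), three upright with
  `(~0.70, ~0.27, 0.03)` and `het_target = 0.35`, which caps realized
  heterozygosity near 10% — upright cultivars are bred toward
  homozygosity, and `het_target` is the probability that the second
  allele copy is drawn independently rather than duplicated from the
  first (duplication preserves the origin marginals exactly).
* five 10-cM introgression hotspots on five linkage groups where
  `p_out` of trailing cultivars is multiplied by 10 (capped at 0.95,
  remaining mass renormalized to `p_ax:p_int`). With the trailing
  baseline `p_out = 0.05` the boosted rate is 0.5, and the genome-wide
  average out fraction of a trailing cultivar lands near 8–10%, the
  range observed for strongly introgressed cultivars, while uprights
  stay near 3%.
* `missing_rate = 0.02` applied cell-wise to all samples;
  read depths are negative binomial (`depth_mean = 20`,
  `depth_dispersion = 5`, matching overdispersed RNA-seq coverage) with
  a symmetric binomial split between the two true alleles and uniform
  miscalls at `error_rate = 0.005`.

Ground truth records every copy's *drawn* origin (ax/int/out, the
marginals the config specifies) and its *effective* origin by allele-set
membership (a drawn progenitor copy whose allele both progenitors carry
is effectively shared) — the first is what parameter-recovery tests
compare against, the second is what a perfect classifier could see.

What the simulator does **not** emulate: linkage disequilibrium and
recombination-breakpoint structure (loci are independent given the
hotspot layout), expression-level variation in coverage across
transcripts, allele-specific expression bias, reference-alignment bias,
and real map geometry (markers are uniform; real maps have marker
deserts). Passing recovery tests therefore demonstrates correctness of
the estimators under the declared generative model, not robustness to
alignment artifacts or LD structure in real panels.

## Numerical choices and problem sizes

All randomness flows from a single integer seed through a local
Mersenne-Twister stream that never touches the session RNG; identical
seeds give bit-identical panels, VCFs and pipeline outputs. Proportion
identities are checked to 1e-9. The validation suite uses problem sizes
chosen to make its tolerances comfortable: 50,000 loci for parameter
recovery (±0.01 for approach-1 and exact-parents, ±0.02 for
pure-parents; the observed error is ~0.002), ~10,000 loci for
heterozygosity recovery (99% binomial interval) and for the null
calibration of the enrichment ratio (100 replicates, ratio within
[0.8, 1.2]), 20 replicate panels at the default scale for hotspot
recovery (median ≥ 4 of 5 planted hotspots among the top-5 category-7
intervals), and 20 cultivars across randomized configurations for the
bracketing property. `scripts/acceptance.R` recomputes all of these from
scratch.

## Known limitations

* Approach-1 under strict mode discards loci where a progenitor is
  heterozygous; with a highly heterozygous progenitor B this can be a
  large fraction of loci. The exact-parents model uses them; comparing
  the two quantifies the information loss.
* Out-allele proportions conflate true third-species introgression with
  unsampled progenitor haplotypes; the package deliberately does not try
  to identify the donor species.
* cM positions do not translate to physical distance; tracks are
  comparable within a map, not across maps.
* The low-recombination mask is a heuristic on marker spacing, not an
  estimate of recombination rate.
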