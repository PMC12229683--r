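---
title: "Methods: harmonizing and analyzing Y-SNP haplogroup data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonizing and analyzing Y-SNP haplogroup data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ysnpdb)
```

## The problem

Y-chromosomal SNPs escape recombination and define a robust patrilineal
phylogeny, but published Y-SNP population data are heterogeneous in two
ways that make them hard to pool. First, nomenclature: the same physical
variant can carry several names (synonyms, e.g. M412 for L51), and several
distinct variants can define the same tree branch because no known
chromosome separates them (equivalent SNPs, e.g. L51 and Y410 both defining
R-L51). Second, resolution: one study may type tens of thousands of SNPs
from whole-genome sequencing while another typed ten SNPs with a
minisequencing assay. `ysnpdb` implements the computational core of a
repository that harmonizes such data against a single reference haplogroup
tree and answers frequency, interpolation and comparative-statistics
queries over it.

## The haplogroup tree and name resolution

The tree is a rooted phylogeny in which every non-root branch carries a
non-empty equivalence class of defining SNPs, each with optional synonyms.
Name resolution (`resolve_branch()`) is case-insensitive and
whitespace-trimmed but otherwise exact; we deliberately avoid fuzzy
matching so that resolution is deterministic and an unrecognized name is an
error rather than a guess. Every name — branch id, SNP primary name,
synonym — may occur only once tree-wide; collisions in an input file are a
load error, never silently merged, because a colliding name makes every
downstream count ambiguous.

Datasets are pinned to the tree version they were validated against, and
querying a dataset with a different tree version is an error. This mirrors
how a live repository must re-validate stored genotypes whenever the
reference phylogeny is updated.

## Membership and the frequency rule

A regional frequency is the number of samples carrying the derived state
for the queried haplogroup divided by the number of *informative* samples —
those in which at least one SNP defining the haplogroup was analyzed. Two
membership modes are provided because typed-allele counting and clade
membership subtly differ when panels are sparse:

* **direct** — only calls at the branch's own equivalence class count.
  Within the class, any derived call marks the sample derived unless
  ancestral calls are also present, in which case the majority wins and an
  exact tie is *conflicting* (excluded from numerator and denominator, and
  surfaced in a QC listing).
* **phylogenetic** (default) — additionally, a derived call at a strict
  descendant, or an assigned haplogroup inside the clade, implies the
  derived state. This realizes "proportion of samples belonging to the
  haplogroup" when a sample was typed only at higher resolution than the
  query.

We never infer the ancestral state from derived calls on disjoint branches:
that inference would assume the tree is complete and every lineage
exclusive, which older sparse panels cannot guarantee.

Paraphyletic queries (`E*(xV13)`: haplogroup E excluding the E-V13 clade)
remove a sample from numerator *and* denominator only on positive derived
evidence for an excluded clade. A sample uninformative for the exclusion
stays in: the alternative (requiring proof of non-membership) would shrink
the denominator toward the best-typed samples only. Exclusions must be
strict descendants of the main haplogroup; we reject disjoint exclusions
rather than silently ignoring them.

Frequencies are kept as exact fractions; the display percentage rounds half
away from zero to an integer, matching how such repositories print
percentages. Relative scaling divides each region's frequency by the
maximum observed regional frequency so that rare haplogroups remain
visible; the peak region then shows 1.

## Spatial interpolation

Regions without data can be estimated from neighboring regions holding at
least 50 informative individuals whose borders lie within 1000 km, when at
least three such neighbors exist. The estimate is the inverse-distance
weighted mean (power 1 — plain inverse distances, configurable) of the
neighbor frequencies, so it is always a convex combination of observed
values. Distances are shortest spherical (Haversine, R = 6371.0088 km)
distances between borders, computed as the minimum over boundary vertices
after densifying each ring to at most 50 km spacing; this approximates the
exact segment-to-segment distance with error below roughly half the
spacing, which is negligible against a 1000 km cutoff. Two numerical
guards: adjacent regions with near-zero border distance have their distance
floored at 1 km so no single neighbor receives unbounded weight, and
regions with *any* empirical data — however few samples — are never
overwritten by interpolation. The 50-individual eligibility threshold is
evaluated on samples informative *for the current query*, not on total
regional sample count, because informativeness is what controls the
reliability of the neighbor's frequency. Interpolation is deliberately
barrier-blind (no mountain ranges, seas or cultural boundaries); it is a
smoothing device, not a demographic model.

## Comparative statistics

Cross-population comparison of mixed-resolution data first restricts to a
reduced SNP panel: a SNP is kept when it was typed in at least 90% of the
pooled samples (a call at any equivalent SNP counts) and its derived
frequency among typed samples reaches 5% in at least one population. Both
criteria are evaluated at the equivalence-class level, so the class is kept
or dropped as a unit. Kept branches are re-linked to their nearest kept
ancestor, yielding a valid collapsed tree, and every sample is assigned the
deepest kept branch at which it is (phylogenetically) derived — samples
with no panel-relevant derived evidence collapse to the root.

On the resulting per-population haplogroup counts we compute:

* **Nei's gene diversity** `D = n/(n-1) * (1 - sum(p_k^2))` — 0 for a
  monomorphic population, exactly 1 when every lineage is a singleton.
* **Pairwise FST** by two-level analysis of molecular variance with 0/1
  haplotype distances (0 within a haplogroup, 1 between). The
  implementation uses the frequency-form closed expressions for the sums of
  squares; the test suite checks it against a literal O(N²)
  pairwise-distance AMOVA. Negative estimates (possible for near-identical
  populations, since this is a moment estimator) are reported as computed,
  with an optional clamp to zero. No permutation p-values are produced.
* **Classical metric MDS** of the FST matrix via double-centering and
  eigendecomposition (`stats::cmdscale`); each axis' explained fraction is
  its eigenvalue over the sum of positive eigenvalues.

## The synthetic-data generator

Because realistic multi-population Y-SNP repositories cannot be shipped,
the package generates its own study data with known ground truth
(`sim_tree()`, `sim_regions()`, `sim_dataset()`). The generator emulates
the three technology tiers such repositories mix: a whole-genome-scale
panel observing every SNP, a large targeted panel covering 60% of SNPs, and
a minisequencing-scale panel covering 5%, mixed at 17% / 78% / 5% within
each population — the approximate shares of WGS, large-panel and SNaPshot
data in mixed-technology Y-SNP studies. The default study uses a 40-branch
tree, 6 equatorial square regions with known inter-border gaps, and 6
populations of 200 samples; these sizes keep every property checkable by
brute force while leaving enough samples per region for binomial recovery
bounds to be meaningful.

Per-population leaf-haplogroup probabilities are drawn from a symmetric
Dirichlet over the tree's leaves, so the true membership probability of any
internal branch is the sum of its leaf probabilities — which is what makes
frequency-recovery tests possible. A sample's observed call is derived
exactly when the SNP's branch lies on its true root-to-leaf path: there is
no genotyping error, no back-mutation, and no recurrent mutation. Passing
recovery tests therefore demonstrates that the counting machinery is
unbiased under missingness and mixed resolution, *not* that the pipeline is
robust to call errors or tree misspecification. All generators draw from a
single explicitly seeded stream and restore the caller's RNG state, so
fixed seeds give byte-identical output files.

One estimator subtlety the simulation makes visible: in phylogenetic mode
the denominator of a sparsely-typed branch conditions on descendant-derived
evidence, which can only certify membership, never non-membership. For
branches observable only through descendants, informative samples are then
enriched for the derived state and the estimate is biased upward.
Recovery against ground truth is therefore stated for the direct
(typed-allele) estimator, which is an unbiased binomial sample whenever
panel assignment is independent of haplogroup — as it is in the generator
and, approximately, in real repositories where the genotyping technology
was chosen per study, not per lineage.

## Numerical and design choices

* Frequencies of regions with zero informative samples are undefined
  (`NA`), not zero; they are exactly the interpolation targets.
* Country-level aggregation of subregions sums counts and recomputes the
  fraction; averaging subregion fractions would weight subregions equally
  regardless of sample size.
* Exact derived/ancestral ties within one equivalence class are treated as
  conflicts and excluded; any majority, however slim, wins. With typical
  class sizes of 1–3 SNPs, ties essentially only arise from genuine
  data problems.
* `sample.int`-based tree growth attaches each branch to a uniform random
  predecessor, producing trees whose depth grows logarithmically — shallow
  compared to the real Y phylogeny, but deep enough to exercise nested
  queries, collapsing and re-parenting.
* The FST moment equations divide by `n' = (N - (n1^2+n2^2)/N)/(P-1)`;
  for equal sizes this is just n, and the estimator is undefined for
  populations of one sample (excluded with a warning).

## Limitations

The package stores call states, not nucleotides, so strand or allele
flips in source data are invisible to it. Border distances are
vertex-based approximations; overlapping polygons without shared vertices
report a small positive distance instead of 0. The reduced-panel typing
criterion pools all samples (as opposed to requiring 90% per population),
so one very large, well-typed population can carry a SNP into the panel.
The synthetic generator does not model coalescent structure, Y-STRs,
mutation, or migration; its Dirichlet frequencies are exchangeable across
regions, so it cannot produce the spatial autocorrelation that makes
real-world interpolation informative — interpolation correctness is
therefore tested through hand-computable configurations rather than through
the generator.
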