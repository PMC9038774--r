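---
title: "Mining soil viromes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining soil viromes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromine)
```

## What the pipeline does

`viromine` turns assembled soil metagenome contigs, their gene calls and
pre-tabulated annotation hits into the quantities used to compare viral
communities between clean and pesticide-contaminated soils:

1. **Viral screening** — a VirSorter category gate plus three
   annotation-fraction criteria decide which contigs are treated as viral.
2. **vOTU clustering** — greedy centroid clustering at 95% nucleotide
   identity over 80% coverage groups contigs into viral operational
   taxonomic units.
3. **Taxonomy** — a majority-rules protein vote assigns family labels, with
   optional propagation through externally supplied viral clusters (VCs).
4. **Host linkage** — exact shared tRNAs and CRISPR spacer/repeat logic link
   viruses to bacterial host taxa; link topology is classified as
   specialist, generalist or polyvalent.
5. **AMG profiling** — viral genes are partitioned into core functional
   genes versus auxiliary metabolic genes (AMGs), AMGs are validated
   positionally against viral hallmark genes and flagged DRAM-v-style, and
   per-sample AMG diversity and abundance are compared between groups.
6. **Community statistics** — TPM normalization, alpha diversity, Bray-Curtis
   dissimilarity, UPGMA trees and whole-graph network statistics.

A synthetic-community generator produces complete input datasets with
planted ground truth, so every stage can be validated end to end.

## Screening

A contig passes the category gate when its VirSorter category is in
{1, 2, 4, 5}. Contigs of 5 kb or less are retained on the gate alone. Longer
contigs are additionally evaluated against three criteria, phrased in
*genes covered* by at least one hit (multiple hits to one gene count once):

* **C1**: at least 5 genes with viral-protein-family (VPF) hits, KO-covered
  gene fraction strictly below 20%, and Pfam-covered gene fraction at most
  40%. The boundary semantics are implemented exactly as stated: strict `<`
  for KO, inclusive `<=` for Pfam.
* **C2**: at least as many VPF-covered genes as Pfam-covered genes.
* **C3**: VPF-covered genes reach 60% of all genes.

Fractions on a contig with zero genes are defined as 0, so degenerate
contigs are handled without special cases.

**Polarity.** The protocol this screen descends from *keeps* long contigs
that meet at least one criterion, and the small share of contigs such
screens typically remove is consistent only with that reading; a literal
reading of some method descriptions would instead discard them. We default
to `retain_if_any` and expose `screen_polarity = "discard_if_any"` so the
literal behavior remains one flag away rather than a silent choice.

## vOTU clustering

Pairs are compared with an end-gap-free (overlap) alignment — match +1,
mismatch −1, gap open −5, gap extend −1, all configurable — in both the
forward and reverse-complement orientation, keeping the better one.
`N` never counts as a match, not even against another `N`. Identity is
matched bases over aligned columns; coverage is aligned columns over the
*shorter* sequence's length, matching the behavior of the widely used
genome-clustering scripts this stage reimplements (the alternative —
requiring coverage of both sequences — is a stricter variant we did not
adopt; the choice only matters for nested or partially overlapping contigs).

Clustering is greedy first-match, longest-first: contigs are sorted by
length (descending; ties broken lexicographically by id so runs are
deterministic), and each contig joins the first existing representative it
matches at ≥ 95% identity and ≥ 80% coverage, else founds a new cluster.
Because candidates are always compared against representatives in founding
order after an internal sort, the partition is invariant to input order and
every representative is the longest member of its cluster. First-match
(rather than best-match) assignment is the standard centroid heuristic; it
can differ from best-match on borderline chains, which is why it is stated
here explicitly.

An optional prefilter skips alignment of pairs sharing no canonical 21-mer.
A pair at ≥ 95% identity over ≥ 80% of a ≥ 1 kb sequence shares a 21-mer
with overwhelming probability, and the package asserts in its test suite
that partitions with and without the prefilter are identical on synthetic
data; it is on by default.

vOTUs whose representative exceeds 10 kb (strict `>`) form the "long"
subset conventionally carried into protein-sharing analyses.

## Taxonomy

Each protein on a vOTU's member contigs casts at most one vote: its best
reference family by bitscore among hits with bitscore ≥ 50. A bitscore tie
between different families abstains (conservative: ambiguous proteins never
decide). The denominator is *all* proteins on the vOTU, including
unannotated ones — "more than half of the proteins", not "of the annotated
proteins" — configurable via `taxonomy_count_unannotated`. A family is
adopted only with strictly more than 50% of the votes.

Unassigned vOTUs inside an externally supplied VC adopt the family carried
by a strict majority of the VC's *directly* assigned members. Restricting
the majority to direct calls prevents propagation from feeding back on
itself, so direct calls never change and the assigned fraction can only
grow.

## Host linkage

* **tRNA evidence**: a link requires the full tRNA sequence to occur exactly
  (100% identity, 100% coverage, either strand) in a bacterial contig;
  self-hits and duplicate (virus, host contig) pairs are removed.
* **CRISPR evidence** is two-step: a spacer must match a viral protospacer
  over its full length with at most one mismatch (both strands), and the
  same array's repeat must occur exactly in a bacterial contig, which
  supplies the host taxon. Spacer matches whose repeat anchors nowhere are
  reported as orphans, never as links. The stated matching rule in the
  underlying protocols ("100% identity, mismatch ≤ 1") is internally
  contradictory; we implement ≤ 1 mismatch and provide
  `spacer_max_mismatch = 0` as the strict-exact mode.
* Rather than a BLAST E-value cutoff, a minimum spacer length (default
  20 nt) is the statistical control: a full-length exact or one-mismatch
  match of ≥ 20 nt against search spaces of ~10^5–10^6 bp has expectation
  far below 10^-5, so length bounds chance hits the way the E-value cutoff
  was meant to.

Topology classes come from the bipartite degree pattern of deduplicated
(virus, host-taxon) edges: specialist (1–1), generalist on the host side
(host with ≥ 2 viruses), polyvalent on the virus side (virus with ≥ 2 host
taxa); one edge can carry a class on each side.

## AMG profiling

Genes whose VOG functional category contains `Xr` (replication) or `Xs`
(structure) are core functional genes. Genes whose Pfam family appears in a
curated AMG family list are AMGs; the shipped list (`default_amg_families()`)
covers denitrification (*norD*, *norQ*), sulfate assimilation (*cysD*,
*cysH*), carbohydrate-active enzyme families (GH/GT/CBM), phosphorus
cycling, aldehyde dehydrogenase, and haloacid dehalogenase (L-DEX) families
implicated in organochlorine pesticide degradation. The list is data, not
code: published AMG catalogs are not distributed in reusable form, so the
shipped table is a documented reconstruction and category totals should not
be compared against any specific published count. When a gene matches both
a core category and an AMG family, core wins — structural genes must not
inflate AMG counts (the conflict is logged).

Positional validation: an AMG is `flanked_both_sides` when hallmark genes
occur at both a lower and a higher gene rank on its contig. Flags follow
the DRAM-v convention; two are recomputed from the layout because they are
purely positional: `F` for genes within 2 ranks (configurable) of either
contig end — the tool this mirrors does not publish its exact constant, so
the window is a parameter — and `B` for members of a run of ≥ 3 consecutive
metabolism-flagged (`M`) genes. Rank, not coordinate, drives both rules.

Per-sample AMG diversity (distinct categories with TPM > 0) and summed TPM
are compared clean versus contaminated with Wilcoxon rank-sum tests, and
category detection counts with Fisher's exact test. The co-occurrence
network joins gene pairs with Pearson |r| > 0.6 and two-sided p < 0.05
(t distribution, n − 2 df), both strict; constant profiles are excluded
because their correlation is undefined. P-values are deliberately *not*
multiple-testing corrected by default — display networks of this kind
conventionally are not — and `network_p_adjust = "BH"` turns correction on.

## Community statistics

TPM per sample is `1e6 * (c_i/L_i) / sum_j (c_j/L_j)`; every sample column
sums to one million. Alpha diversity reports observed richness,
bias-corrected Chao1 (`S + F1(F1−1)/(2(F2+1))`), ACE (rare cutoff 10,
squared coefficient of variation floored at 0; when a sample has no rare
species the estimator degenerates to observed richness), Shannon entropy
(natural log by default; the base is configurable because conventions
differ), the Gini–Simpson index `1 − Σp²` (the variant under which "higher
Simpson" means "more even"), and Pielou evenness `H / ln S` (absent when
S ≤ 1). Chao1, ACE, Shannon and Simpson are computed through vegan and
cross-checked against hand-coded formula oracles in the test suite.

Bray–Curtis dissimilarity feeds UPGMA (average linkage); samples are sorted
by id before agglomeration so tie-breaking is deterministic, and the
returned tree is ultrametric with node heights at half the merge
dissimilarity. Whole-graph statistics — density `2E/(N(N−1))`, average
neighbors `2E/N`, mean local clustering coefficient — follow the
NetworkAnalyzer convention of counting degree < 2 nodes as clustering 0
(a flag switches to averaging over degree ≥ 2 nodes only).

## The synthetic community generator

`synth_design()` describes a complete study: by default 3 clean samples
(C1–C3) and 6 contaminated (S1–S6; 3 light, 3 heavy), mirroring a
three-versus-six soil design.

* **Clustering truth.** Each viral lineage is an ancestor plus variants
  derived by *substitutions only* — no indels — confined to positions 26
  through L−25. Two consequences: pairwise identity is exactly
  `1 − m/L` (closed form, so alignment can be tested analytically), and an
  end-gap-free alignment can never trim a terminal mismatch and distort
  that identity. Ancestors are 10 bp longer than variants so the ancestor
  is always the longest member, hence always the greedy representative,
  making the planted partition exactly recoverable. Decoys at 90% identity
  sit safely below the 95% gate and must form singletons. Indel robustness
  is a property of the clusterer to be tested separately, not a generator
  feature.
* **Linkage truth.** tRNA plants copy a 75 nt sequence into both the
  ancestor and the host contig; CRISPR plants embed a repeat–spacer cassette
  in the host contig whose first spacer is a protospacer copy with 0, 1 or
  (as a planted negative) 2 substitutions. Plants are applied to ancestors
  *before* variants are derived so identity levels stay exact.
* **Screening truth.** Short viral contigs carry passing categories;
  category 3 decoys fail the gate; one 12 kb contig is annotated to pass
  the three criteria and one 6 kb contig to fail all of them.
* **Abundance.** Feature base abundances are lognormal (meanlog log 50,
  sdlog 0.6), converted to counts by Poisson draws per sample, so count
  tables are sparse and integer as diversity estimators require.
  Contamination effects are multiplicative and recorded in the ground
  truth: contaminated samples see `viral_richness_gain` times more viral
  lineages (clean samples see a subset), lose the rarest
  `bacterial_richness_drop` fraction of bacterial taxa, and multiply
  AMG-carrier abundance by `amg_tpm_multiplier` (light contamination gets
  the square root of the factor, heavy the full factor, so abundance rises
  with severity). Contamination-exclusive viral features enter at
  `gained_taxa_abundance` (default 0.3) of a typical base abundance:
  richness gained under disturbance comes from the rare tail, as in real
  rarefaction data, and relative-abundance (TPM) contrasts are
  scale-invariant, so without this the extra features could wash out the
  planted AMG share ordering in some draws.
* **Bacterial evenness.** Bacterial taxa follow a geometric rank-abundance
  series (ratio 0.75). Because contaminated samples drop the *rarest* taxa,
  their Pielou evenness rises without any separate evenness knob — the same
  mechanism that lowers richness raises evenness, which is the qualitative
  pattern disturbed communities show.
* Identical seeds give byte-identical datasets; the generator refuses
  infeasible designs (for example an identity level requiring more
  substitutions than the mutable region holds) before writing anything.

What the generator does **not** emulate: read-level sequencing error,
assembly artifacts, chimeras, indel variation within lineages, strain
mixtures within a sample, or compositional correlations between features.
Passing the planted-recovery tests therefore demonstrates that the
implementation computes what it claims on well-posed inputs — not that the
thresholds themselves are optimal for any particular real soil dataset.

## Problem sizes and numerical choices

The package's own validation uses instances chosen to exercise each claim
at meaningful scale: 1,000 random profiles against the screening oracle;
50 planted lineages (three variants at 97% identity) plus 50 decoys at 90%
for clustering, with order-shuffle invariance checked across 10
permutations of a 24-cluster instance; 500 random vote tables; 100 seeded
linkage datasets (including 1- and 2-mismatch plants and scrambled-spacer
negative controls); 1,000 random contig layouts for the F/B flag oracle;
and 100 seeded end-to-end replicates for the direction-of-effect claims,
with 100 null replicates (no planted effect) for type-I calibration of the
rank-sum comparison. Alpha-diversity values are required to match formula
oracles to 1e-10; TPM row sums to 1e-6 relative; graph and tree statistics
to 1e-12 against brute-force recomputation.

Ties and degenerate inputs are resolved deterministically throughout:
length ties in clustering break lexicographically; bitscore ties between
families abstain; UPGMA ties follow sample-id order; zero-gene contigs get
zero fractions; all-zero samples yield warnings and defined values (TPM 0,
Bray–Curtis 0, absent diversity indices) rather than NaNs.

## Known limitations

* The greedy clusterer is quadratic in the number of representatives;
  beyond a few thousand contigs the k-mer prefilter is essential, and very
  long sequences (above `align_max_len`) are rejected rather than aligned.
* VC construction (protein-sharing clustering) is out of scope; VC
  membership is an input table, so propagated taxonomy is only as good as
  the supplied VCs.
* The AMG family list is a curated reconstruction; users with a validated
  catalog should supply their own table.
* CRISPR arrays are consumed as tables; detecting them from reads or
  assemblies is upstream of this package.
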