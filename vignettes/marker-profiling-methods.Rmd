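---
title: "Marker-gene profiling with metamark: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene profiling with metamark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamark)
```

# Overview

`metamark` implements the computational core of marker-gene-based
meta-omic profiling: it builds species-specific marker databases from
annotated genomes, quantifies community composition from read-to-marker
alignments, genotypes strains from consensus marker sequences, types
strains by gene-family presence/absence, and profiles functional
potential through a tiered search. Every component can be exercised on
fully synthetic communities whose ground truth is known exactly, which
is how the package validates itself.

This vignette explains the underlying models, the tunable parameters
and their defaults, the numerical choices made where the design was
genuinely open, and what the synthetic validation does and does not
demonstrate about real data.

# Marker discovery from pangenomes

A species' *pangenome* is the union of gene families observed in any of
its genomes, at two clustering granularities: 90%-identity families
nested inside 50%-identity families. For every family we compute:

* **coreness** — the fraction of the species' genomes carrying the
  family (a core gene has coreness 1);
* **uniqueness** (per tier) — the number of *other* species whose
  pangenome contains the family; the `_sp` variants exclude species
  whose names mark them as low-quality taxa (provisional `Candidatus`
  names, `..._sp_...` binomials, unnamed `bacterium` entries and so
  on, matched by `flag_low_quality_species()`);
* **external genomes** (per tier) — the number of other-species
  *genomes* carrying it, which distinguishes a family shared with one
  widely sequenced species from one shared with many rare ones.

Good markers are near-core and near-unique. Candidates (restricted to
protein lengths of 150–1500 aa, the range where genes are long enough
to attract reads but short enough to be single-copy housekeeping-like
sequences) are binned into tiers of decreasing stringency:

| tier | coreness | u90 | u50 | eg90 | eg50 |
|------|------------|------|------|-------|-------|
| A | > 0.80 | ≤ 2 | ≤ 2 | ≤ 10 | ≤ 5 |
| B | (0.70, 0.80] | ≤ 5 | ≤ 5 | < 15 | < 10 |
| C | (0.50, 0.70] | < 10 | < 15 | < 25 | < 20 |
| U | single-genome species | 0 | 0 | — | — |

Boundary semantics ("higher than 80%" strict, "values of 5" inclusive,
"lower than 15" strict) are fixed in one table in the code
(`tier_satisfied()`). For a species with a single genome, coreness is
trivially 1 and tiers A–C are not evaluated; such species use tier U,
which requires zero sharing.

Selection is iterative: tier A candidates are gathered first; if a
round yields more than 50 candidates they are ranked by score and up to
150 markers are taken, ending the search; otherwise the round's
candidates are accumulated and the next tier is tried. A species
ending with fewer than 10 markers is dropped. The ranking score is

$$\mathrm{score} = S_\mathrm{coreness}\; S_{u50}\; S_{u90}, \qquad
S_u(u) = -\log\!\Big(1 - \tfrac{10^4 - \min(10^4, u)}{10^4}
+ 10^{-4}\Big)\times 15,$$

clamped at zero, with $S_\mathrm{coreness}$ the coreness fraction. The
$10^{-4}$ term regularizes the logarithm at $u = 0$ (where
$S_u \approx 138.155$); the factor decays to zero as $u \to 10^4$. We
use the coreness *fraction* rather than a percentage: a constant scale
factor cannot change the ranking, which is all the score is used for.

Markers shared with no other species are **unique markers**; markers
carrying a non-empty external-species list are **quasi-markers**,
usable when the sharing species are absent. After selection, external
lists can be refined by splitting each marker into non-overlapping
150 bp chunks and searching them, on both strands, against all
genomes (`refine_marker_externality()`). The built-in search is exact
substring matching, which is correct for the synthetic genomes the
package generates; per-chunk hit lists from a sensitive external
mapper can be supplied instead for real references, where near-exact
homology matters.

# Taxonomic profiling

Reads are aligned to the marker database (alignment is an input
contract: any mapper emitting read/marker/MAPQ/interval records will
do; `truth_alignments()` and `match_reads_exact()` are the built-in
producers for synthetic data). Records from reads shorter than 70 bp
or with MAPQ below 5 are discarded, and a multi-mapped read counts
toward exactly one marker (best MAPQ, most aligned bases, then
lexicographic marker id, so results are reproducible).

The depth of a marker is its aligned-base count divided by its length
(a read-count mode is available behind `depth_mode = "reads"`). A
clade's coverage is the **robust average** of its marker depths: the
depth vector — which deliberately includes zeros for unaligned markers,
down-weighting species supported by few markers — is sorted and
`floor(stat_q * n)` entries are dropped from each tail before
averaging. The default `stat_q = 0.2` trims the 20% highest and 20%
lowest marker depths, suppressing both spuriously recruiting markers
and markers missing from the sampled strain. Trimming uses integer
counts rather than quantile interpolation: with marker counts of a few
dozen, interpolation would mix the trimmed tail back in.

Two further rules govern species detection:

* a quasi-marker is excluded from a species' depth vector when any
  member of its external list has already been detected through unique
  markers — otherwise an abundant sharing species would inflate or
  create its neighbours;
* a species is reported only when more than a third of its retained
  markers have nonzero depth (`detect_frac = 1/3`, configurable).
  At the depths where profiling is meaningful (≥ 0.5×), a genuinely
  present species hits essentially all of its markers, so this mainly
  suppresses species seen only through a handful of stray alignments.

Species coverages are summed up the taxonomy and normalized per rank to
percentages. The **unknown fraction** — the share of reads from taxa
absent from the database — is estimated by converting each species'
coverage into an expected read count via its average genome length and
the sample's mean read length, and subtracting from the total:
$\mathrm{unknown} = 100 \cdot \max(0,\ N - \sum_t c_t L_t / \ell)/N$.
Known abundances are then rescaled to sum to $100 - \mathrm{unknown}$.
Profiles serialize to a tab-separated dialect with rank-prefixed clade
paths and taxid chains, or to the CAMI profiling format.

# Strain profiling

For each sample and marker, a consensus genotype is called per column
of the read pileup: the majority base is accepted when the column's
mean base quality is at least 30 and the major allele's frequency is at
least 0.8; otherwise the position is ambiguous (`N`). We aggregate
column quality as the mean of the per-observation base qualities — the
natural summary when qualities are per-base error estimates.
Consensus markers reconstructed from fewer than 8 reads or with breadth
of coverage (fraction of unambiguously called positions) below 0.8 are
rejected.

Sample/marker filtering then alternates two rules to a fixed point:
samples retaining fewer than 20 markers are dropped, then markers
present in fewer than 80% of the remaining samples, and so on. The
fixed point satisfies both thresholds simultaneously, which a single
pass does not guarantee.

Retained consensus sequences are trimmed by 50 bases at each end
(mapping depth decays at marker boundaries) and concatenated in
lexicographic marker order. Because all consensus sequences of one
marker are reconstructed against the same reference coordinates, the
concatenation *is* a valid multiple alignment; a marker missing from a
sample is N-padded (the sample already passed the 20-marker floor, so
padding stays a minority of columns). Indel-containing input — which
the built-in consensus caller never produces — raises an error
pointing at the external-aligner hook.

Pairwise strain distances use the Kimura two-parameter correction,
$d = -\tfrac12 \ln\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)$ with transition
fraction $P$ and transversion fraction $Q$ over sites where neither
sequence is `N`. Trees are built by neighbor joining (an external
maximum-likelihood builder can be substituted; NJ is the tested
default), and leaf-to-leaf path lengths are normalized by the total
branch length, giving distances in $[0, 1]$ that are invariant to a
global rescaling of the tree.

**Transmission inference.** With sample metadata (subject, collection
date) and a table of related pairs, a threshold for "identical
strains" is set at the first percentile of the *unrelated*-pair
distance distribution; related pairs below it are reported as potential
transmission events. Longitudinal subjects contribute only their
earliest sample (ties by sample id), and samples absent from the
metadata count as unrelated. The percentile is computed by linear
interpolation between order statistics; because an interpolated
percentile can leave marginally more than the nominal fraction of
unrelated distances strictly below it (up to $p + (1-p)/n$), the
threshold is capped at the $\lfloor np \rfloor + 1$-th unrelated order
statistic. The cap is inactive whenever the interpolated value already
satisfies the bound, and it makes the advertised 1% false-discovery
ceiling hold *by construction* for every $n$.

# Pangenome presence/absence typing

The coverage of a gene family is its depth-weighted base count divided
by the family's mean gene length,
$\mathrm{cov}(F) = \sum_{g \in F} d_g \ell_g \big/ \overline{\ell}_F$.
This base-count reading is invariant to splitting a read's alignments
into fragments and robust to how reads distribute among identical
family members across reference genomes.

Sorting a sample's family coverages descending gives its *coverage
curve*: a present strain produces a plateau at the strain's sequencing
depth, present families sit on it, and absent families fall off the
right edge. The plateau level is the median of the nonzero curve. A
sample is *detectable* when the plateau is at least `min_coverage = 2`
and the curve is flat around it: the value at the left edge must not
exceed `left_max = 1.25` times the plateau and the value at the right
edge must reach `right_min = 0.75` times it. Only the three multiplier
defaults are canonical; the edge *positions* are a design choice, and
we use the quartile convention (ranks $0.25k$ and $0.75k$ of the $k$
nonzero families), which brackets the plateau symmetrically. Within a
detectable sample a family is present when its coverage reaches half
the plateau, with an absolute floor of `min_coverage / 2`; the
half-plateau rule adapts to sequencing depth while the floor prevents
presence calls from pure noise in shallow samples.

For visualization and clustering, the binary matrix is pre-filtered in
two rounds (families present in fewer than 2 samples or absent from 5
or fewer samples; then families present in more than 95% or less than
5% of samples), distances are Jaccard on presence fingerprints, and
clustering is agglomerative with Ward's criterion. Co-occurring family
groups can be tested for genomic proximity: the statistic is the summed
gene length over the group's span along its contig (1 for adjacent
genes), and an empirical p-value is computed against random same-size
gene sets from the same contig with the add-one estimator
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_\mathrm{perm})$,
whose p-values are never exactly zero and remain valid at any
permutation count.

# Functional profiling

The tiered search assigns reads to gene families in two stages.
In the **nucleotide tier**, reads hit species pangenes; a database
sequence whose positions are covered below 50% by the union of its hit
intervals has *all* its hits discarded (the coverage filter — isolated
hits to an otherwise uncovered gene are far more often homology spill
than true presence). Each surviving read goes to its best-scoring
pangene (ties lexicographic), or, in the optional `multi_hit_k = 5`
mode, its weight is split equally over up to five best pangenes.
Reads left unmapped fall to the **translated tier**: protein-level
hits below 80% identity are dropped (inclusive floor — an 80.0% hit is
kept), only hits within 1% of the read's best surviving score are
retained, and the read's weight is split equally over the distinct
protein families of the survivors. The protein-level coverage filter
is applied before the identity filter, mirroring the per-target
semantics of the nucleotide tier.

Abundances are reads-per-kilobase (RPK) per family, stratified by the
contributing species (translated-tier weight is "unclassified"), and
can be regrouped to broader systems (e.g. EC numbers) by summing member
families — a family with several annotations contributes fully to each,
which keeps the stratum sums consistent under regrouping — and
renormalized to copies per million (CPM) with a single global factor.
Total read weight is conserved exactly at every tier:
assigned + translated + unclassified = input reads.

# The synthetic-data generator

The simulator is first-class, tested code; its defaults define the
validation conditions:

* **Pangenomes** — random-DNA gene families (uniform base composition,
  GC configurable, no repeats by default) of 450–1500 nt placed on one
  contig per genome with 100–300 nt spacers and random strands; core
  families in every genome, accessory families in random subsets.
  Family sequences are identical across a species' genomes.
* **Communities** — species abundances drawn log-normal(0, 1) and
  sum-normalized; reads sampled per species proportional to
  abundance × genome length (one genome per species acts as the
  sampled strain), with uniform start positions, random strand,
  independent substitution errors, and Phred qualities consistent with
  the error rate. Two gold-standard abundance scales are emitted,
  read-fraction and coverage/cell-fraction, because the two differ by
  the genome-length weighting and downstream consumers need each.
* **Strains** — a strain is a base genome with accessory families
  excised (coordinates rebuilt) and a fixed number of substitutions
  placed at distinct random positions inside retained gene bodies;
  transmission pairs share a byte-identical strain genome. Truth
  tables record every SNV and deletion.

All randomness flows from explicit seeds; identical seeds give
byte-identical output. The error model is substitutions only
(no indels) so that consensus and alignment fixtures remain exact;
this is a deliberate simplification.

# Validation scope and problem sizes

The package validates itself with property checks on synthetic data
(see `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`):
exact species recovery and ≥ 0.95 Bray–Curtis similarity on a
15-species, 50,000-read community; exhaustive agreement of the trimmed
mean with an iterative-removal oracle over all ≤ 12-element depth
multisets from a 5-value alphabet; brute-force re-verification of
marker tiers and scores over 20 random universes; perfect consensus
recovery at 10× from 30 strains; a first-percentile transmission
threshold that separates 10 seeded transmission pairs from 40 unrelated
subjects at a ≤ 1% empirical false-discovery fraction; ≥ 0.99 balanced
accuracy recovering a 10%-deleted gene repertoire at 4× (and correct
non-detectability at 1.2×); EC-level functional recovery at ≥ 0.95
Bray–Curtis on a 10-species community; and lossless format round trips.
These problem sizes were chosen as the smallest at which the asymptotic
behaviour of each estimator is visible.

Passing these checks demonstrates correctness of the *algorithms* under
the generator's assumptions. Real data differ in ways the generator
deliberately omits: within-species sequence divergence between sample
strains and database representatives, indels and structural variation,
non-uniform coverage (GC bias, origin-of-replication skew), chimeric
and low-quality reads, and databases that are incomplete or contaminated.
The mapper-facing interfaces (alignment records, per-chunk hit lists,
external MSA/tree hooks) exist precisely so that those effects are
handled by purpose-built tools upstream.

# Known limitations

* The built-in exact matcher requires equal-length, error-free reads;
  real samples must come with mapper output.
* Consensus calling assumes a colinear reference (no indels); divergent
  strains need the external-aligner hook.
* The unknown-fraction estimate inherits any bias in the per-species
  coverage estimator; it is clamped at zero and can saturate there when
  markers recruit reads from flanking sequence.
* NJ trees are a fast default, not a substitute for maximum-likelihood
  phylogenetics when branch-length accuracy matters.
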