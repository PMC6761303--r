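---
title: "Deconvolving host–endosymbiont assemblies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving host-endosymbiont assemblies: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Sequencing an endosymbiont usually means sequencing its host too: the
DNA cannot be separated beforehand, so the assembly interleaves contigs
from a eukaryotic genome, one or more bacterial genomes, and often
contaminants. Homology searches label only part of the assembly —
symbiont clades are poorly represented in reference databases and their
genomes are compositionally unusual (reduced, AT-rich). `endobin`
combines the partial homology labels with three signals that do not
depend on databases: oligonucleotide composition, read-pair linkage and
sequencing coverage, and turns them into a per-contig taxonomic
prediction plus an extracted target bin.

The package assumes: (i) the genomes in the pool differ enough in
composition (or coverage) for 3-mer statistics to carry signal; (ii)
read pairs rarely bridge unrelated genomes, so connected components of
the read-pair graph are mostly genome-pure; (iii) the target organism's
16S rRNA gene is present in the assembly and identifiable. When (iii)
fails the clustering stage cannot be anchored, and flow B (classifier
output only) is the supported alternative.

# Stages and their parameters

## Coverage (fragments per nucleotide)

Each sequenced *fragment* contributes one count: merged single-end
reads and same-contig pairs give 1 to their contig; a pair whose mates
map on different contigs gives 0.5 to each; a pair with one unmapped
mate gives 1 to the mapped contig (a fragment was certainly sequenced
from it). Coverage = count / contig length. This fragment-based unit —
rather than per-base depth — is what the 16S tie-break and the optional
`cov` clustering feature use. Half counts are kept as exact reals, never
rounded. No mapping-quality filter is applied by default; secondary and
supplementary alignments are always ignored.

## Canonical k-mer composition

Counting k-mers on both strands and summing the counts of each
reverse-complement pair is exactly proportional to counting the forward
strand and mapping every word to its canonical form (the
lexicographically smaller of word and reverse complement): each forward
window contributes its word once and its complement once, so every
canonical class — palindromes included — receives the same weight under
both schemes. The implementation counts forward-canonically; the test
suite checks the equivalence against an explicit both-strand counter.
Windows containing N are skipped rather than expanded; a contig with no
countable window yields an all-zero, flagged row. Defaults: k = 3
(32 canonical words) on contigs ≥ 1 kbp. The length threshold is read
inclusively (a 1000 nt contig passes); with longer k the minimum
sensible contig length grows roughly with the 4^k word space, which is
why k = 3 suits 1 kbp contigs.

## TaxonDensity labels

All thresholds are inclusive: HSPs with percent identity ≥ 70 (nt) /
≥ 80 (protein) and length ≥ 200 bp / ≥ 70 aa are kept, and the majority
label is retained when its density ≥ 0.75 — the threshold value itself
passes, consistent with reading "75% of the HSPs agree" as a passing
state. Nucleotide and protein hits are pooled *before* the density is
computed, with equal per-HSP weight; each HSP counts once even when the
same subject aligns repeatedly. The denominator excludes hits whose
lineage lacks the queried rank, so a rank-sparse lineage table cannot
silently dilute the density. Density ties leave the contig unlabeled.

## Read-pair graph transfer

Edges need ≥ 10 supporting pairs (`edges_min`); vertices keeping degree
> 5 after the edge filter are removed (`vertices_max_degree`). The
filter order is fixed — edges first, then a single vertex pass — and a
config switch can iterate the degree pass to a fixed point. Distances
in the graph are unweighted hop counts; weights only gate edge
existence.

Two transfer regimes exist, mirroring the either/or in how such label
propagation is controlled:

* `vertexdist = "all"` (default): within each connected component, the
  fraction f of labeled members disagreeing with the majority is
  computed; if f > `mixedcomp_max` (default 0.2) or the majority is
  tied, the component is skipped, otherwise the majority label spreads
  to every unlabeled member. In correction mode, skipped-mixed
  components additionally lose their predicted labels ("misclassified").
* integer `vertexdist`: the mixed-component veto is bypassed; the
  majority label (ties broken lexicographically, so the run stays
  deterministic) propagates up to the given hop distance, and stops two
  hops short of any conflicting labeled vertex. On a path
  L(A)–u1–u2–X(B) with distance 3 this labels u1 only. When several
  labeled sources could reach a vertex, only the majority label is
  ever transferred; conflicting labels act purely as blockers — the
  conservative resolution of an ambiguous rule.

Existing labels are never overwritten, and transfer is idempotent:
running extension twice equals running it once.

## Ensemble classification

100 replicates (`n_replicates`) of a stratified 66/33 split of the
labeled contigs train a random forest (500 trees) or radial-kernel SVM
on the canonical k-mer columns (GC and coverage appended only when
`feature_type` says so). Stratification is a deliberate choice over a
plain random split: it prevents a class from vanishing from a training
set. All replicates vote with equal weight — held-out accuracy is
reported as an error estimate but does not reweight models. The final
label is the vote-fraction argmax; exact ties are flagged ambiguous and
left unlabeled. Classes with fewer than 10 labeled contigs are dropped
before training; fewer than two surviving classes is a hard error, with
graph extension or looser thresholds as the suggested remedies. Nested
classification walks the configured rank sequence coarse-to-fine,
restricting the universe at each step to contigs matching the target
lineage at the previous rank, and applies graph correction after every
rank.

## Clustering and the 16S anchor

The predicted-target contigs' k-mer rows are embedded with UMAP
(`ncomp = 2`, n_neighbors = 15, min_dist = 0.1, Euclidean metric —
unstated in the method this package follows, so declared here as
package defaults) and clustered with DBSCAN (minPts = 5). DBSCAN is
implemented in the package (classic core/border/noise expansion over
the pairwise distance matrix). The radius eps, when not set, is taken
from the knee of the sorted minPts-nearest-neighbour distance curve
(maximum distance to the chord), because assemblies vary too widely in
scale for a fixed radius. GC/coverage channels, when enabled, are
z-score standardised and appended *after* the embedding, so clustering
operates on `[embedding ‖ extras]`. The cluster holding the target 16S
contig — the highest-coverage matching 16S when several exist, with a
deterministic lexicographic tie-break — becomes the target bin; a
noise-classed anchor is a hard error reporting the nearest cluster.
Noise points never join the bin through clustering but stay eligible
for graph-based rescue, which is how contigs below the 1 kbp
composition filter re-enter the result.

# What the synthetic generator emulates — and what it does not

`generate_mixture()` produces genomes as order-1 Markov chains whose
transition rows all place exactly the specified mass on G+C (so the
expected GC is exact) while the within-GC and within-AT splits are
jittered per genome, giving each genome a k-mer signature beyond GC.
Contig lengths are log-normal with a 200 nt floor; fragments are placed
proportionally to contig length at a rate of 0.02 fragments/nt per
coverage unit (20% merged single-end); consecutive contigs are bridged
by junction-spanning pairs (probability 0.3 per junction,
Poisson-distributed support with mean 15 × coverage multiplier), which
makes connected components short within-genome chains rather than one
giant component — leaving a realistic fraction of contigs unlabeled
after graph extension, so the classifier stage has real work to do.
The default study mixture is a GC-0.45 eukaryote-like host at 1× and a
GC-0.30 bacterial symbiont at 9× carrying the 16S anchor: the 9:1
coverage ratio is assigned to the *symbiont*, matching endosymbiont
biology (multiple bacterial cells and genome copies per host cell) and
making the highest-coverage-16S rule meaningful. The 16S-carrying
contig always receives homology hits, as its rRNA-database hit
guarantees in the real workflow. Hits are drawn above the HSP filters,
plus two below-threshold spike-ins per genome so the filter is
exercised end-to-end.

Real data differ in ways the generator does not model: sequencing
error, chimeric assembly, repeat-driven mis-joins, uneven within-genome
coverage, horizontally transferred regions whose composition resembles
the donor, and databases whose errors are correlated rather than
uniform. Passing the end-to-end checks therefore demonstrates that the
machinery is implemented correctly and behaves sensibly under the
stated generative model — not that any particular real assembly will
reach the same scores.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 input/output is
  converted at the boundary.
* All threshold comparisons (HSP length, identity, TaxonDensity,
  contig length, edge weight) are inclusive.
* Division-by-zero performance rates are reported as `NA`, never 0.
* An all-N or too-short sequence yields a flagged zero row (composition)
  or `NA` (GC), not an error; flagged rows are excluded from classifier
  and embedding inputs.
* One run seed fans out to stage-specific derived seeds (hash of stage
  name), so any stage can be rerun in isolation and reruns are
  byte-identical.
* The n−2 truncation rule with a conflict at distance ≤ 2 transfers
  nothing along that path beyond the source itself.

# Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at desk scale, chosen to keep a full run in minutes on one CPU
while leaving every stage statistically meaningful: 270–300 contigs per
mixture (~0.6 Mnt), 200 labeled / 100 unlabeled contigs for the
ensemble checks at the full 100 replicates, 1,000 random sequences for
the composition oracle, and 100 random multi-component graphs for the
transfer invariants.

# Known limitations

* Only one target bin is extracted per run; multiple symbionts require
  one run per target (with different 16S labels), as in the nested
  class-level configuration.
* The TaxonDensity consensus has no lowest-common-ancestor fallback: a
  contig split between two sibling classes stays unlabeled rather than
  being labeled at the parent rank.
* DBSCAN on a full distance matrix is quadratic in the number of
  predicted-target contigs; assemblies with tens of thousands of target
  contigs would need an indexed neighbour search.
* The coverage model ignores mapping quality and multi-mapping; for
  repeat-heavy hosts a stricter upstream mapping filter is advisable.
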