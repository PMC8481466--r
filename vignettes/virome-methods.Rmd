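---
title: "Methods: virome curation and longitudinal analysis in viromeflow"
author: "viromeflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virome curation and longitudinal analysis in viromeflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromeflow)
```

# Scope and model of the data

`viromeflow` implements the analysis chain used in shotgun faecal virome
studies with repeated sampling: assembled contigs plus per-contig protein
annotations and evidence flags come in; a curated nonredundant viral
database, presence-filtered count tables, diversity statistics and
differential-abundance calls come out. The package assumes the upstream
steps — read QC, assembly, homology search, gene calling against reference
HMM databases — were performed by the standard external tools; their
outputs are abstracted as an *evidence table* (per-contig booleans and
scores) and an *annotation table* (one row per protein annotation with a
category and score). This keeps every downstream decision rule explicit
and testable.

# Curation rules

A contig enters the viral database when **any** pooled line of evidence
holds: a viral RefSeq hit, circular topology in the viral-enriched
sequencing fraction, an external classifier call, dark matter (no
reference-database hit) in the viral-enriched fraction, or a length-tiered
count of viral orthologous-group (pVOG) protein hits — at least 3 hits
below 5 kb, 4 from 5–10 kb, 5 from 10–20 kb, 6 from 20–40 kb, 7 from
40–60 kb and 8 at 60 kb or more. Tier boundaries are half-open on the
lower edge: a 5,000 bp contig needs 4 hits. Pooling is a set union, so the
classification is monotone in evidence; this is asserted as a property
test.

Contigs shorter than 1,000 bp are discarded first. Contigs called viral
are then removed again if they encode ribosomal proteins (any hit) or a
plasmid replication protein with an HMM score of at least 15 — the score
boundary is inclusive, so 15.0 is removed and 14.9 retained.

**Circularity.** A contig is circular when a prefix of at least
`k_min = 20` bases exactly matches a suffix (a terminal direct repeat, the
signature an assembler leaves when a circular genome is linearized). The
detector computes the longest proper border of the sequence with the
Knuth–Morris–Pratt prefix function, so repeats that are internal rather
than terminal never qualify. The threshold of 20 bases is shared as a
single constant with the synthetic generator; at 20 bases the chance of a
spurious terminal match in a random genome is about $L/4^{20}$, i.e.
negligible at contig scale.

**Redundancy merging.** The database is made nonredundant by a greedy
longest-first sweep: a sequence is absorbed when it aligns to an
already-kept (longer) sequence at ≥ 90% identity over ≥ 90% of the
*shorter* sequence. Coverage relative to the shorter sequence
(containment) is chosen because the protocol retains the larger of two
homologous sequences; containment is exactly the condition under which
the smaller one is redundant. Both strands are checked. Equal-length ties
keep the lexicographically smaller contig id, which together with the
longest-first order makes the survivor set invariant to input order.
Candidate pairs are prefiltered by shared 15-mers (at least 8, counting
both strands) and then aligned locally with `Biostrings::pairwiseAlignment`;
homologous pairs at the 90%/90% thresholds share hundreds of 15-mers,
while unrelated contigs essentially never reach the cutoff, so the
prefilter changes cost, not outcome. The merge is idempotent, which is
tested directly.

# Annotation

The bundled ORF caller is deliberately minimal: maximal ATG-to-stop frames
of ≥ 30 codons on both strands, standard genetic code, with calls spanning
runs of more than 10 ambiguous bases suppressed. GTG/TTG starts are
omitted; the caller exists so the package is self-contained and strand
symmetry can be property-tested, not to compete with a production gene
caller. Lifestyle is a pure function of the annotation table: any
integrase or recombinase annotation makes a contig a lysogenic phage,
otherwise its replication strategy is unknown; no score threshold is
applied because the upstream HMM search is already thresholded. Family
assignment is a majority vote over protein-level family annotations, with
ties and missing data mapped to "unclassified"; votes are counted per
protein rather than score-weighted because weighting schemes of the
external classifiers are tool-specific.

# Clustering into viral clusters

Viral clusters (VCs, a pseudogenus-level rank) are derived from a
gene-sharing graph: contigs are connected when they share at least
`min_shared = 2` protein-family identifiers, with edge weight equal to the
shared count. Connected components of size ≥ 2 become clusters; isolated
contigs stay unclustered; articulation points — contigs whose removal
disconnects their component, i.e. contigs bridging otherwise separate
groups — are flagged ambiguous and treated as singletons downstream. This
replaces the MCL-based pipeline of the external gene-sharing tool with
the simplest mechanism that reproduces the three downstream statuses
(clustered / ambiguous / unclustered) the quantification stage consumes.
It is a stand-in, not an equivalence: graphs with dense overlapping
communities would be split differently by MCL.

# Abundance and the presence filter

Reads are assigned to at most one contig. The bundled mapper is an
exact-substring matcher for error-free (simulated) reads: ties go to the
lexicographically smallest contig, reverse complements are tried for
otherwise-unmapped reads, and circular contigs are matched against a
junction-extended copy (terminal repeat trimmed, first read-length − 1
bases appended) so reads wrapping the origin still map. Real alignments
are ingested from SAM via `sam_coverage()`, taking each alignment's
reference span from its CIGAR. Breadth of coverage is the fraction of
contig positions covered by ≥ 1 read, computed as an interval union.

A contig counts as present in a sample only when it attracted at least 3
reads **and** its breadth meets the length tier — 50% below 5 kb, 30%
from 5–20 kb, 10% at 20 kb and above; failing cells are recorded as
exactly zero. The two conditions are conjunctive: read count alone guards
against breadth computed from a handful of stacked reads, and breadth
alone guards against a single conserved element recruiting many reads.
Counts of contigs in one cluster are summed per sample; ambiguous and
unclustered contigs are retained as singleton rows, so aggregation
conserves per-sample totals (tested). Bacterial contamination of a virome
read set is estimated as the fraction of reads mapping to a marker-gene
database (a cpn60-like gene in the synthetic data).

# Diversity statistics

Shannon α-diversity uses the natural logarithm. Bray–Curtis dissimilarity
is computed on relative abundances: sequencing depth varies between
virome samples, and without the conversion depth differences would
masquerade as compositional change; rarefaction was rejected because it
discards counts that the NB model downstream uses. PCoA is classical
scaling of the double-centred squared dissimilarities; negative
eigenvalues (possible for non-Euclidean indices like Bray–Curtis) are
dropped from both the coordinates and the variance denominator — the
simplest defensible convention, and the count of dropped axes is
reported. PERMANOVA partitions the total sum of squared dissimilarities
(Gower formulation); the p value is the fraction of label permutations,
observed ordering included, with pseudo-F at least the observed, so with
999 permutations the smallest attainable p is 0.001. The permutation
stream is seeded and recorded. The implementation agrees with
`vegan::adonis2` to numerical precision on fixtures, and with a direct
hat-matrix trace decomposition used as an independent oracle in tests.

Per-animal longitudinal change is summarized by three Bray–Curtis values
(baseline vs. month 1, baseline vs. month 5, month 1 vs. month 5); an
animal's virome is classified as more dissimilar at T5 when the
base-anchored T5 value exceeds the T1 value. Averages are reported per
treatment and per cage, the latter because shared caging is an obvious
confounder in rodent microbiome designs. Rank-based group comparisons use
the Wilcoxon test for two groups and Kruskal–Wallis for more, with
Bonferroni correction `min(1, m·p)`.

# Differential abundance

Counts are normalized with median-of-ratios size factors (log-space
median over groups with no zero count; a positive-counts-only fallback
with a warning otherwise), identical to the reference implementation on
fixtures. The test is a deliberately simplified negative-binomial Wald
test rather than a reimplementation of the full DESeq2 machinery
(dispersion shrinkage, Cook's filtering, independent filtering): the
package's accuracy surface is error control and effect recovery on
synthetic data, not numerical identity with a specific release of an
external package. Per-group dispersions are method-of-moments estimates
pooled across the two conditions and *moderated from below*: the working
dispersion is the maximum of the per-group estimate and the median
estimate across groups. With the handful of replicates typical of animal
studies, raw moment estimates are noisy and occasionally near zero;
because the Wald denominator shrinks with the dispersion, such
underestimates would inflate the statistic far in the tail — precisely
where a Bonferroni threshold of $10^{-5}$ operates. Taking the maximum is
conservative by construction and leaves genuinely large dispersions
untouched. The log2 fold change is the ratio of normalized group means
with a pseudocount of 0.5, its standard error follows from the NB
variance $\mu + \alpha\mu^2$ by the delta method, and p values are
two-sided normal.

Contrasts are baseline vs. month 1 and baseline vs. month 5 within each
treatment arm, with Bonferroni correction over all groups × contrasts in
that arm; significance uses the adjusted p value against
$\alpha = 10^{-5}$ alone. The ±2 log2-fold-change lines in the exported
volcano table are reporting annotations, not filters. Concordance
classifies every group significant anywhere by the treatments and
timepoints in which it is altered (single-treatment vs. multi-treatment;
persistent when significant at both post-baseline timepoints within one
arm) and reports the component arithmetic — totals and the
single-treatment percentage rounded to one decimal.

# The synthetic community generator

The generator is first-class, tested code, and its defaults encode the
study design the package targets: 6 treatment arms (Sham, LPS, α-syn
monomer, monomer+LPS, PFF, PFF+LPS) × 3 timepoints (pre-treatment
baseline, 1 month, 5 months), animals split over two cages per arm with
cage–rat identifiers of the form `C<cage>-R<rat>`. Genome lengths default to
1.5–12 kb (faecal viromes are dominated by contigs of a few kb), 10% of
viral genomes are circular (most assemblies stay linear at realistic
depth), 20% carry an integrase/recombinase, and baseline abundances are
log-normal (meanlog 0, sdlog 1.5), the heavy-tailed shape typical of
virome profiles. Contaminants are bacterial chromosome fragments
(ribosomal-protein annotations plus an embedded cpn60-like marker gene)
and plasmids (replication-protein hits with scores ≥ 15, half of them
circular — which exercises the rule that circular contigs are first
called viral and then removed as contaminants). Planted clusters share a
core of 6 pVOG identifiers of which each member carries 4, so any two
members share at least the `min_shared = 2` families.

Per-sample counts follow a Gamma–Poisson (negative-binomial) abundance
model with a single dispersion (default 0.1, a typical overdispersion for
metagenomic counts), realized as Gamma weights followed by a multinomial
allocation of exactly `reads_per_sample` reads. The compound keeps
NB-like marginals while conserving the read budget exactly, which the
conservation test asserts; the fixed budget also means planted fold
changes are realized compositionally, so spiked genomes should be kept
rare when an absolute count ratio is being verified. Reads are error-free
uniform substrings (2×150-style length, single-end), and circular genomes
are read across the junction.

What the generator deliberately does **not** emulate: sequencing error
and quality scores, host (rat) genome contamination, RNA viruses and
reverse-transcription artefacts, paired-end insert geometry, and
between-sample depth variation (depth is a parameter, not a random
quantity, because the protocols underlying the design report per-pool
depth rather than a per-sample distribution). Consequently, passing
round-trip tests demonstrates that the decision rules and statistics are
implemented correctly — not that the pipeline is robust to alignment
noise or assembly artefacts in real data.

# Problem sizes and numerical choices

The bundled verification runs use community sizes chosen so the full
suite completes comfortably on a single core: round-trip recovery uses 50
viral genomes, 10 contaminants, 54 samples at 20,000 reads each;
PERMANOVA calibration uses 200 null datasets of 18 samples with 99
permutations; NB error control uses 100 spiked groups for sensitivity and
100 null datasets of 500 groups for dataset-wise false positives. Other
conventions: dispersion estimates floor at $10^{-8}$; PCoA eigenvalues
within $10^{-9}$ of zero (relative to the spectral radius) are treated as
null; Bray–Curtis on two all-zero profiles is an error rather than a
convention; all randomness flows from explicit seeds and seeded functions
restore the caller's RNG state.

# Known limitations

The exact-substring mapper is only meaningful for error-free reads; real
data should be aligned externally and ingested as SAM. The clustering
stand-in approximates, but does not reproduce, gene-sharing network tools
with their reference genomes and taxonomy propagation. The NB Wald test
is intentionally conservative in the extreme tail; users wanting
shrinkage estimators for visualization should treat the reported fold
changes as unshrunken. The concordance stage assumes the two
post-baseline timepoints named in the design; designs with more
timepoints would need the contrast list generalized.
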