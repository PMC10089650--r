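---
title: "Methods: TE landscapes, ERV-LINE interactions, and KZNF turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE landscapes, ERV-LINE interactions, and KZNF turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tescape)
```

# The problem

Mammalian genomes are usually dominated by LINE retrotransposons. When a
lineage instead accumulates endogenous retroviruses (ERVs) faster than
LINEs, several linked questions arise: is low LINE content due to loss or to
reduced gain; are the expanding ERV subfamilies autonomous or parasitic; do
ERVs physically interrupt LINE master copies; where do ERVs accumulate; and
does the host's KRAB zinc-finger (KZNF) repertoire expand in response?
`tescape` implements the computational procedures needed to answer these
questions from a repeat annotation, a gene annotation, and a genome layout —
and couples them to a synthetic-genome generator that plants every structure
the analyses are meant to find, so the whole pipeline is testable without
any external data.

# Data model and conventions

All coordinates are 0-based half-open internally; RepeatMasker `.out` and
GFF3, both 1-based inclusive, are converted at the boundary. On
minus-strand `.out` hits the three consensus-position columns arrive in
`(left) end begin` order and are normalized on read so `cons_start <=
cons_end` always holds; the consensus-conjoining logic depends on this.

Overlapping annotations are resolved in favour of the longer element; the
losing element is removed whole rather than truncated, since truncation
would fabricate coordinates no aligner produced. The annotation convention
leaves tie-breaking open, so we adopt lower divergence, then smaller start —
a deliberate package-level decision. The greedy longest-first sweep makes
the operation idempotent and the output overlap-free at the threshold.

# Divergence

Divergence from the subfamily consensus uses Kimura's two-parameter model,
K = -1/2 ln((1 - 2p - q) sqrt(1 - 2q)), with p and q the transition and
transversion proportions over comparable sites (gaps and ambiguous bases
excluded). Hypermutable CpG sites would otherwise inflate the age of old
elements, so the standard repeat-annotation adjustment is applied: at
positions inside a consensus CpG dinucleotide a transition counts 1/10, and
a CpG with both positions transitioned counts as a single 1/10 transition.
Transversions always count fully, and the site denominators are unchanged.
`cpg_correction = FALSE` recovers textbook K2P. Arguments that make either
logarithm operand non-positive mean the distance is undefined (saturation)
and raise an error rather than returning a number. The implementation is
pinned, site for site, to an independent brute-force classifier in the test
suite.

Landscape profiles assign each element's genomic length to the half-open
divergence bin containing its annotated divergence (width 1%, range 0-60%,
one overflow bin), so profile mass per class is exactly the class's
occupancy; occupancy itself is a union length, immune to double counting.

# DNA loss

The loss coefficient comes from E = A e^(-kt): k = ln(A/E)/t, with A = 2.8
Gb of ancestral assembly and t = 100 My in the rodent literature's
parameterization. The sentence defining E ("ancient TE DNA minus
lineage-specific TE DNA") conflicts with E's own meaning, so both readings
are implemented behind `mode`: the conventional reading (assembly size minus
lineage-specific TE bp) is the default because the literal one can be
negative; both values are always attached to the result. Retaining E = 1.75
of 2.8 Gb over 100 My gives k = 0.0047/My, the reference point used in the
tests.

# LTR dating and autonomy

ERV long terminal repeats are identical at insertion, so the percent
identity between an element's 5' and 3' LTRs estimates its age. The LTR
pair is taken as the best local alignment (match +1, mismatch -1, gap -2,
via Biostrings) between a prefix and a suffix window of
`min(2 kb, length/3)` bp, accepted at >= 100 aligned bp and >= 80%
identity; random sequence never reaches these thresholds in practice.

Autonomy classification mirrors the conservative rule used for short-read
assemblies, where many ERV copies contain assembly gaps: a subfamily is
nonautonomous only if at least five full-length, gap-free, ambiguity-free
copies exist and none carries a qualifying ORF; it is autonomous if any
full-length copy carries both gag and pro-pol evidence; everything else is
ambiguous. "Full length" is within 10% of the consensus length with at most
20 bp missing at either consensus edge (the convention leaves this
tolerance open; both knobs are arguments). When no domain labels are
supplied, any ORF of >= 200 codons is the machinery proxy — domain HMM
scanning is out of scope. Machinery screening is restricted to LINE
elements over 2,700 bp and LTR elements over 5,000 bp, the established
cutoffs for complete coding capacity.

# ERV-in-LINE interruption

A LINE interrupted by an ERV leaves a signature: two LINE fragments of the
same subfamily and strand whose consensus coordinates conjoin — the right
fragment resumes where the left one stopped — with ERV sequence filling the
genomic interval between them. Tolerances are needed because indels and
annotation fuzz shift both coordinate systems: the consensus gap at a
junction may be up to 100 bp (signed), and up to 50 bp per junction may be
unannotated. On the minus strand the fragment order along the genome
mirrors the consensus order, and the conjoining condition is reversed
accordingly. The interrupting ERV's own strand is unconstrained: insertion
in either orientation interrupts the host.

The strict census reproduces the conservative full-length count: exactly
two fragments, no non-ERV annotation between them, united consensus span
over 5,000 bp. Relaxed mode chains any number of conjoining fragments and
also reports sub-full-length (`fragmented`) reconstructions, so its count
dominates the strict count on every input.

For the per-subfamily enrichment test, the statistic is the number of the
subfamily's elements whose nearest annotated neighbours on both sides are
LINE fragments of one same subfamily and strand. We deliberately do not
require consensus conjoining or a base-pair gap cap here (both are exposed
as options): the flanking formulation matches the census question ("is this
ERV sitting inside a LINE?") without conditioning on the fragments still
being alignable, and it keeps the permutation null informative rather than
degenerate at zero. The null re-places the subfamily's elements uniformly
per chromosome, preserving lengths, counts, and chromosome assignment, with
all other annotations fixed; shuffled elements may overlap others, as the
annotation-randomization description implies. p = (r + 1)/(n + 1) over
n permutations — never exactly zero at finite n — and Q is Bonferroni over
tested subfamilies.

# Genomic distribution

Feature coverage is intersected union length over feature length, per
feature class (CDS, lncRNA, gene bodies, each chromosome) and TE class,
with an optional re-placement null yielding one-sided depletion and
enrichment p-values. Nearest-gene distances are bp gaps (0 on overlap);
stranded mode restricts candidate genes to the element's strand and records
a missing value when no candidate exists.

Upstream enrichment counts the elements of a subfamily that overlap, on the
gene's own strand, the 5-kb region upstream of its transcription start
(clipped at chromosome edges). Regions of different genes are intentionally
not merged — the count is per gene, matching the per-gene phrasing of the
procedure — though an element is counted once however many regions it
touches. The expected count is the mean over per-chromosome
re-placements; the reported Fisher p compares observed vs the rounded
expectation (in/out of regions), and because that rounding is a known
artifact source, the permutation p is always reported alongside. An
apparent upstream bias can also be manufactured by segmental duplications
that copied a gene together with its upstream element, so for each enriched
subfamily the SD coverage of the upstream regions of element-bearing genes
is compared to an SD re-placement null, and significant subfamilies are
flagged for exclusion.

Hotspots are the 100-kb tiling windows whose ERV density (covered bp over
window length; the trailing partial window keeps its true length) reaches
the 95th percentile of all window densities, computed as the type-7
linearly interpolated quantile; the tie rule is `>=`, and all-zero windows
are never hotspots. Window densities are a partition statistic: density
times length sums to covered bp per chromosome, exactly. Two formation
modes are distinguishable by the divergence of neighbouring ERVs:
independent insertions accumulate unrelated ages (large neighbour deltas),
while segmental duplication copies existing insertions (near-zero deltas);
consecutive same-chromosome ERV pairs are compared inside vs outside
hotspots by two-sided Mann-Whitney U. The gene-density association is an
ordinary least-squares fit of gene density on ERV density by default — the
contract is the coefficient sign and p — with a quasibinomial logit variant
behind `family`.

# KZNF duplicate ages

KZNF families evolve by birth-death duplication, so each gene's most recent
duplicate is its minimal-divergence partner in a pairwise divergence matrix
(an input; alignment construction is out of scope). Ties break to the
lexicographically smaller id; by default every gene contributes a record
(each mutual pair thus counted twice), with `dedupe_pairs` collapsing
pairs. A gene is "in hotspot" on >= 1 bp overlap with a hotspot window.
Ages between hotspot and non-hotspot genes are compared by two-sided
Mann-Whitney U. KDE peaks use a Gaussian kernel with Scott's bandwidth
(sd x n^(-1/5)) on a 0.1%-step grid over [0, max + 3 bw]; the argmax is the
peak, ties taking the lower value, and a zero-variance sample returns its
common value directly.

# Statistics

The two-sided Fisher test sums hypergeometric probabilities of all tables
(fixed margins) no more probable than the observed one, with 1e-12 relative
slack for ties — implemented directly over `dhyper` so the tie tolerance is
under our control, and verified against full enumeration for every table
with margins up to 12. Mann-Whitney U uses the exact distribution of U for
n <= 20 without ties, full enumeration of group assignments on midranks
with ties at that size, and the tie-corrected normal approximation with
continuity correction above; the two-sided p is P(|U - mu| >= |u - mu|),
valid because the permutation distribution of U is symmetric. Bonferroni is
the only multiplicity correction used. Every stochastic routine takes an
explicit seed, and subfamily-level analyses derive a child seed by hashing
(seed, subfamily name), so results are independent of annotation-file
order and bit-reproducible.

# The synthetic generator

The generator emulates the statistical structure the analyses assume, not
sequence evolution. Its default configuration is the study condition used
throughout the tests: a 10-Mb genome over five 2-Mb chromosomes carrying
about 5,000 annotations from a cricetid-like community (a recently active
lineage-specific L1 and an ancient shared L1, a lineage-specific SINE, six
lineage-specific ERVK subfamilies, ancestral ERVL/MaLR copies, a relic DNA
transposon), 50 planted interruption triples whose fragments conjoin
exactly (consensus gap 0, genomic junction gaps 0) with united spans over
5,000 bp, five grid-aligned 100-kb hotspot windows filled to 2.5x the
background ERV density, four KZNF clusters of 24 genes (half colocated with
hotspots) with duplicate divergences at means 17.2% (hotspot) vs 22.2%
(other), and 400 background genes. Divergences are drawn once per copy and
written into the annotation; copy lengths are uniform fractions of the
consensus; placement is uniform per chromosome with rejection sampling
keeping annotations overlap-free (a retry cap turns capacity exhaustion
into an error). Background genes avoid hotspot windows — ERV-dense regions
are gene-poor in real genomes — which is what plants the negative gene-ERV
density dependence. Segmental-duplication hotspot mode instead copies one
block repeatedly with near-equal divergences and emits a covering SD
interval. The KZNF divergence matrix designates within-cluster duplicate
pairs (truncated normal draws) against a uniform 40-60% background, so each
gene's nearest duplicate is its designated partner. An upstream-bias plant
places `factor x` the analytically expected uniform count of a subfamily
inside same-strand upstream regions; with the default community the
expected fraction is large enough that a 10x request saturates near the
subfamily's copy number, so recovered ratios sit in the 5-10 range rather
than exactly at 10 — the planted excess, not the nominal factor, is the
ground truth recorded in the manifest.

`null_config()` strips every plant (interruptions, hotspots, upstream bias,
KZNF shift, SDs) while preserving seeds; under it, every enrichment stage
must produce calibrated p-values. The dedicated `calibration_config()`
builds one null genome per calibration replicate: a dominant LINE
subfamily (12,000 copies), a single tested ERV subfamily, and a dense gene
complement. Two design points matter. First, one tested subfamily per
genome: when several subfamilies are tested in one genome, each
subfamily's elements are part of the others' permutation contexts, the
resulting p-values are correlated, and a goodness-of-fit test across them
misreads the correlation as miscalibration — the per-subfamily p-values of
the analysis itself remain valid either way (each is marginally uniform
under its null); only their joint use in a uniformity check demands
independence. Second, high copy numbers (1,000-3,000, log-spread across
replicates): permutation p-values of a count statistic are discrete, and
ties between observed and null counts make the (r + 1)/(n + 1) p-value
conservative by roughly the mass at the count's mode, which shrinks with
the square root of the expected count. Placement allows overlap there,
since only annotation order and region membership enter the calibrated
statistics. Calibration runs use 200 such genomes (200 independent
subfamily-replicates per statistic) at 199 permutations each; the
segmental-duplication power check uses 100 seeds of a reduced two-chromosome
genome — problem sizes chosen to make the checks sharp while the whole
suite stays comfortably runnable on a laptop.

What passing these tests shows — and what it does not: recovery and
calibration on generator output demonstrate that the implementations
compute what they claim under the stated models (uniform placement,
annotation-level divergences, exact conjoining up to tolerances). Real
repeat annotations add fragmentation beyond two fragments, insertion-site
preference, divergence-dependent detectability, and reference errors; none
of these are emulated, and conclusions about real genomes inherit those
caveats.

# Known limitations

Defragmentation of scattered hits into joined elements is consumed, not
performed; `.align` files are not parsed; subfamily discovery, consensus
building, phylogenetics, and domain HMM scanning are out of scope. The
interruption census assumes the annotation's subfamily assignments are
correct — misassigned fragments cannot conjoin. The Fisher variant of the
upstream test inherits its rounding artifact by construction; use the
permutation p when the two disagree. KDE peaks on small samples (tens of
observations) are noisy and should be read qualitatively.
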