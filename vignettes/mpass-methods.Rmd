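---
title: "Methods: proteome-wide average similarity distances for metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide average similarity distances for metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Shotgun metagenomic sequencing yields, after assembly and gene calling, one
predicted proteome per sample. Methods that compare such samples through
taxonomic or functional assignment discard the sequences themselves and
depend on reference databases; k-mer methods use raw composition that is only
indirectly related to gene function. The approach implemented here compares
the proteomes directly: two microbial communities are similar when the
proteins of one find close homologs in the other, weighted by how abundant
the encoding organisms are. The result is a single dissimilarity per sample
pair, a distance matrix, and a neighbor-joining "metagenomic tree" whose
topology can then be compared against environmental gradients.

## The distance

For an ordered sample pair (A, B), every retained protein *g* of A is
searched against all proteins of B; with best-hit bit score
$b_g$ and self-score $s_g$ (the score of *g* against itself under the same
scoring scheme), the per-gene similarity is $b_g / s_g \in [0, 1]$ and the
per-gene dissimilarity is $d_g = 1 - b_g / s_g$. A query with no reported hit
(e-value above the threshold) gets $d_g = 1$: genes present in only one of
the two metagenomes carry signal and are not discarded. The one-way
aggregate is the coverage-weighted mean

$$T_{A \to B} = \frac{\sum_g w_g\, d_g}{\sum_g w_g}, \qquad
  w_g = \text{k-tuple coverage of } g,$$

and the pair's **normalized average dissimilarity** is the arithmetic mean
$T = (T_{A \to B} + T_{B \to A})/2$, which makes T symmetric. The weights
are normalized within each sample, so multiplying one sample's coverages by
any positive constant leaves T unchanged. Coverage weighting is the step
that distinguishes metagenome comparison from genome comparison: in a
metagenome the same gene family appears at a depth proportional to the
abundance of its organism, and that abundance should count.

A note on direction: the quantity is often described as an average
*similarity*, but the distance grows with it; this package fixes the
convention as a **dissimilarity** (T = 0 for identical proteomes) so that
the transform below is increasing in divergence. The raw weighted
similarity is available as an attribute of the returned value.

T is then mapped onto an interpretable evolutionary scale by the calibrated
exponential transform

$$S = c_1\, e^{c_2 T}, \qquad c_1 = 4.142,\; c_2 = 2.824,$$

whose constants were fitted by regressing percent Poisson-corrected 16S
rRNA substitution rates, $S_2' = -\ln(1 - S_1') \times 100$ with
$S_1' = 1 - \text{matched}/(\text{alignment length} - \text{gapped})$,
against whole-proteome T values across a balanced panel of prokaryote,
eukaryote, and archaeal genomes. S is therefore expressed in percent
substitution-rate equivalents, the unit shown on tree branch lengths.
`estimate_constants()` re-fits $(c_1, c_2)$ from any set of calibration
points by log-linear least squares (`lm(log(S2') ~ T)`), optionally refined
by `nls()` on the original scale; which variable is treated as the response
is genuinely ambiguous in the method's lineage, and this package fixes
$S_2'$-on-T as its convention (the reverse fit is a matter of exchanging
the arguments).

Two consequences of the transform are deliberate properties, not bugs:
S(T = 0) equals $c_1$, not 0 (two identical proteomes map to the
calibration intercept), and the distance matrix therefore stores 0 on its
diagonal by convention — tree methods require zero self-distance — while
the per-pair log keeps the raw T and S values.

## Alignment engines and scoring

Per-gene similarity needs a *local* protein alignment score. Two engines
produce it behind one interface:

* **exact** — Smith–Waterman via `Biostrings::pairwiseAlignment()`,
  exhaustive over all query–target pairs. Used for small problems and as
  the reference in tests.
* **blast** — the NCBI `blastp` binary when present on the PATH, the same
  search tool the method was designed around. Used automatically for large
  problems (`engine = "auto"`).

Scoring defaults are the standard BLASTP configuration: BLOSUM62, gap open
11, gap extend 1. Raw Smith–Waterman scores are converted to bit scores
with the gapped Karlin–Altschul parameters for that scheme
($\lambda = 0.267$, $K = 0.041$). E-values are recomputed uniformly from
bit scores as $E = m \cdot n \cdot 2^{-\text{bits}}$ with *m* the query
length and *n* the total residue count of the target sample, so the
reporting threshold (default $E \le 10$) means the same thing under either
engine; each engine supplies its own self-scores so that the score ratio is
internally consistent, and the ratio is clamped to $[0, 1]$.

Identical sequences across samples are dereplicated before alignment: the
all-against-all search runs once over the unique sequence set and every
pair comparison is a lookup. This changes nothing in the results and makes
the cost scale with unique proteins rather than records, which matters for
simulation studies where many samples share sequences.

## Preprocessing

Three standard steps precede the comparison, mirroring common practice for
assembled shotgun data:

* reads can be trimmed to a fixed length (5' prefix kept) and down-sampled
  without replacement to the smallest library among the samples, so that
  sequencing effort is equalized — down-sampling is seeded and
  reproducible. Trimming is opt-in: it is chemistry-specific, so no default
  trimming is applied;
* predicted proteins lacking a start or a stop codon in their encoding
  sequence (partial genes at contig edges) are removed;
* proteins shorter than 100 residues are removed — very short predictions
  are enriched for assembly artifacts. The boundary is strict: a 100-residue
  protein is kept.

Completeness is read from metadata written by the gene caller or assembler
(three header dialects are parsed, plus a permissive fallback that assumes
coverage 1 and complete flags), rather than re-predicted: gene calling is
external to this package.

## Trees and topology comparison

The distance matrix feeds standard Saitou–Nei neighbor joining
(`ape::nj()`); negative branch lengths, which NJ can produce on
non-additive input, are clamped to 0, and the tree is handled unrooted.
Tie-breaking among equal Q-criterion pairs follows the NJ implementation's
deterministic internal order. Any rooting for display is cosmetic and never
affects topology comparisons.

Topologies are compared by the unweighted Robinson–Foulds symmetric
difference: the number of non-trivial bipartitions (splits induced by
internal edges) present in exactly one tree. The package extracts
bipartitions itself in a canonical encoding and counts the symmetric
difference directly; tests cross-check the count against an independent
implementation. Multifurcating trees are compared on their bipartition
sets as-is, without forced binary resolution.

Environmental dendrograms are the package's own convention where the
method's description leaves a gap: each single parameter is clustered
agglomeratively (`hclust`) on absolute pairwise value differences, with
average linkage by default (single and complete as options). Exact ties in
merge heights are collapsed into multifurcations so that arbitrary binary
resolutions do not inflate the symmetric difference, and the topology is
invariant under positive affine transforms of the parameter. Parameters are
then ranked by their dendrogram's symmetric difference to the metagenomic
tree, ascending — the lowest values mark candidate environmental drivers.

## Per-gene conservation tracing

To ask *which* genes follow the community phylogeny, the same machinery is
applied gene by gene: for each of the focal sample's top-coverage genes
(default top 1,000), the per-gene distance
$S_g = c_1 e^{c_2 d_g}$ to every other sample is computed **without
averaging over genes**, and correlated (Pearson) with the patristic
distance from the focal leaf to each other leaf. "Branch length in the
tree" is interpreted as patristic distance — the only per-sample scalar
consistent with correlating a per-sample vector — and genes with
$r > 0.7$ are flagged tree-concordant. Genes with constant distance
profiles are excluded (their correlation is undefined); note that in
simulations without cross-sample sequence evolution most high-coverage
genes are identical everywhere and legitimately fall in this class. An
alternative mode maps best-hit e-values monotonically onto $[0, 1]$
(clipped $-\log_{10} E$, rescaled by the self-hit); the e-value transform
is not specified in the method's lineage, so this mode is provided for
fidelity experiments and is explicitly non-normative — the score-ratio
mode is the default.

## The simulators

Two abundance-vector schemes generate 30 samples in three groups of 10 from
the three base compositions
(0.297, 0.507, 0.116, 0.058, 0.022), (0.345, 0.244, 0.281, 0.088, 0.042),
(0.526, 0.320, 0.042, 0.066, 0.046):

* **convergent** — at step *k*, components above the base vector's mean are
  multiplied by $(1 - 0.05)^k$ and components below by $(1 + 0.05)^k$, then
  renormalized; each group's composition converges toward uniform, so
  high-step samples have lost most of their group signature. The scheme's
  verbal description admits a one-shot ±5% reading; the convergent,
  cumulative reading is implemented as normative because the expected tree
  shape (most-changed samples branching deepest) depends on it, and a
  non-cumulative variant is available behind `cumulative = FALSE`.
* **gaussian** — each component *c* becomes $c + |N(0, c)|/5$, renormalized,
  ten times per base vector. "One-fifth Gaussian noise with standard
  deviation equal to the component" is read as $|N(0, c)|/5$ rather than
  $|N(0, c/5)|$; the choice is recorded here because the phrasing admits
  both.

Synthetic genomes replace real bacterial genomes so the whole pipeline is
self-contained: five (by default) 50 kb genomes built from a common
ancestral set of 100 protein-coding genes (100–160 residues), each species
carrying every gene as an ORF (ATG … stop, no internal stops) mutated at
30% per residue — enough divergence to keep cross-species best hits rare —
with shuffled gene order and random intergenic sequence. A seeded read
sampler draws reads multinomially in proportion to abundance × genome
length, with uniform start positions, random strand, and optional uniform
substitution errors.

`community_proteome()` is the assembly-free shortcut from a community to a
proteome. Literally translating every gene of every member would make all
samples' protein *sequences* identical, with only coverages differing — and
since identical sequences align perfectly, every pairwise T would be 0
regardless of weights. The mechanism by which abundance differences reach
the proteome in the real pipeline is assembly: low-coverage genes fail to
assemble. The shortcut therefore emulates that detection step with the
Poisson coverage-gap model — a species at per-gene coverage *c* contributes
the fraction $1 - e^{-c}$ of its genes (the probability a locus is covered
at all), deterministically the first *k* genes in the species' fixed order,
with $c = n_{\text{species}} \times \text{mean\_coverage} \times
\text{abundance}$ and `mean_coverage = 2` by default. Recovery is
deterministic so that equal compositions always yield equal proteomes;
`detect = FALSE` disables the dropout and recovers the literal translation.

What the simulators do **not** emulate is worth stating plainly: there is
no sequence evolution *across samples* (all samples draw from the same five
genomes), no assembly chimerism or fragmentation, no strain-level variation,
and the read sampler's error model is uniform rather than
platform-calibrated. Passing simulation tests therefore demonstrates that
the pipeline orders and groups samples correctly when gene *content* and
*abundance* carry the signal; they do not certify behaviour under
real-world assembly noise.

## Numerical choices and degenerate inputs

* Score ratios are clamped to $[0, 1]$ before $d_g$ is formed (engine bit
  scores can differ marginally from the self-score convention).
* T outside $[0, 1]$ is rejected by `distance_from_T()`; $c_2 = 0$ is
  permitted as a degenerate diagnostic transform.
* Zero total coverage weight is an error (the weighted mean is undefined).
* `poisson_corrected_rate()` rejects alignments with no unambiguous loci
  and rejects $S_1' = 1$ (infinite rate).
* Non-positive $S_2'$ calibration points are excluded from the constant
  fit with a warning; fewer than 3 usable points, or all-equal T, is an
  error.
* All-equal environmental parameters yield a star dendrogram with a
  warning rather than an error, so a screening run over many parameters
  does not abort; samples with missing values are dropped with a warning
  and fewer than 4 remaining is an error.
* Down-sampling more reads than exist is an error that reports the
  available count.

## Problem sizes used by the test suite

The package's own checks run the full 30-sample convergent simulation at
5 species × 100 genes × 50 kb (the tree-recovery check, about half a
minute with the blast engine), 200-replicate oracle sweeps for NJ recovery
and Robinson–Foulds counting at 4–12 leaves, and smaller exact-engine
fixtures (5–25 proteins, 40–150 residues) everywhere the brute-force
alignment oracle is involved. These sizes were chosen so the whole suite
exercises every stage, including both engines, in a few minutes on one
core.

## Known limitations

* The coverage-weighting convention (per-gene weights normalized within
  each sample, directions averaged arithmetically) is one reasonable
  reading of a procedure whose full specification lives in supplementary
  material of the method's lineage; it is fixed and documented here as the
  package's convention.
* Bit-score normalization assumes fixed Karlin–Altschul parameters rather
  than per-alignment estimates; for the score *ratio* this cancels to
  first order.
* The blast engine requires the `blastp` binary; without it, the exact
  engine is used and large problems are slow.
* `rank_env_parameters()` compares one parameter at a time; multivariate
  dendrograms are out of scope.
* Re-deriving the default transform constants requires whole-genome and
  16S data for a reference panel; the package ships the published
  constants and the fitting routine, not the panel.
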