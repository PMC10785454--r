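---
title: "Simulating and evaluating metagenome-assembled genomes with magsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating metagenome-assembled genomes with magsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`magsim` simulates a genome-resolved metagenomic study end to end — from a
user-defined community of source sequences, through read simulation,
assembly and binning, to the evaluation of the resulting bins against the
known sources. Because every stage is deterministic given its seed and all
provenance is retained, completeness, contamination, ANI and downstream
prediction errors can be *computed* exactly rather than estimated. This
vignette documents the models, the parameters that matter, the numerical
choices, and the limits of what the synthetic setting can show.

```{r setup}
library(magsim)
```

## Community model and read budgets

A community is a table of source sequences (chromosomes or plasmids) with
a relative genome-copy abundance $a_g$ per sample. Read pairs for a sample
are shared out proportionally to $a_g \cdot L_g$ (abundance × length), so
two genomes at equal abundance receive equal *depth*, not equal read
counts — the convention of genome-copy-based community simulators.
Integerisation uses the largest-remainder method with ties broken by table
order, so the allocation always sums exactly to the requested total.
Abundance 0 is legal and means "absent from this sample". The per-sample
sequencing budget is a user parameter (default 250,000 pairs); with the
default 150 bp reads, the expected depth of genome $g$ is
$2 \cdot 150 \cdot n_g / L_g$.

Community abundances for the bundled fixtures are drawn from
uniform(1, 3.5) and then *spread* so that abundance-adjacent genomes differ
by at least a configurable ratio (`min_depth_ratio`, default 1.8). The
spreading step plays the role of the manual curation a community designer
would apply: organisms with near-identical depth are the classic cause of
hybrid bins, and a community intended as a clean baseline avoids them. The
ratio is exposed as a recipe parameter rather than hard-coded because no
canonical value exists.

## Read simulation

Reads are simulated internally rather than by an external simulator so the
package is dependency-free and fully reproducible. Fragments start
uniformly over valid positions; insert lengths are
normal(`insert_mean` = 400, `insert_sd` = 40) truncated to
[`min_insert` = 200, genome length]; each fragment is sequenced from a
random strand, mate 2 being the reverse complement of the far end.
Substitution errors are applied per read position at the rate given by the
error profile (default flat 0.002); the matching Phred track is
$Q = \mathrm{round}(-10\log_{10}\max(r, 10^{-4.1}))$ clamped to [2, 41].
Error profiles are plain 2-column TSVs (position, substitution rate), so
profiles measured from any instrument can be supplied.

Deliberate simplifications: no indels or PCR duplicates (substitutions
dominate Illumina error and keep alignment on a single diagonal, which the
evaluator exploits), no adapter contamination, no origin-spanning
fragments on circular replicons, and no long-read mode. Each simplification
makes ground truth exact at the cost of some realism; none changes the
qualitative behaviour of binning, which is driven by depth and composition.

Trimming implements the standard 3′ Phred rule (cut at the position
maximising $\sum (Q_t - q_i)$ over the trailing segment; pairs dropped
whole below `min_length`). Under the default profile every base is Q27,
which is provably untouched by the default Q20 threshold, so the pipeline
short-circuits the trim pass in that case; the rule itself is exercised
directly by the unit tests on mixed-quality records.

## Pseudo-assembly and binning

Assembly is *simulated*, not re-implemented: each source is split at
maximal runs of zero mate coverage, pieces shorter than
`min_scaffold_len` (default 1500 bp, the conventional binning minimum) are
discarded, and — optionally — two pieces from different sources sharing an
exact substring of at least `chimera_anchor_len` (default 2000 bp) are
merged into a chimeric scaffold whose shared region takes the first
source's sequence. This reproduces, controllably, the two failure modes
that matter downstream: fragmentation and consensus chimeras between close
relatives. Read placement uses the simulator's provenance directly
(mate 1 covers the fragment start, mate 2 the end), replacing a mapper;
dropped pairs are removed and surviving pairs keep their untrimmed
coordinates, which is exact under the default no-op trim.

The depth table follows the `jgi_summarize_bam_contig_depths` dialect
(average depth and population variance of per-base coverage, per scaffold
and sample). Binning uses the two signals real binners use:

$$d_{ij} = w\,\lVert \mathrm{TNF}_i - \mathrm{TNF}_j \rVert_2
  + (1-w)\,\overline{\left|\log(1{+}\mathrm{depth}_i) -
  \log(1{+}\mathrm{depth}_j)\right|}$$

with TNF the 136-class reverse-complement-canonical tetranucleotide
frequency vector and the depth term averaged over samples (each sample is
assembled and binned separately in the pipeline, so in practice one term).
Scaffolds are clustered by average linkage and the dendrogram cut at
`distance_threshold` (default 0.15); clusters below `min_bin_size_bp`
(default 200,000; 10,000 in plasmid mode) dissolve into the unbinned pool.
With $w = 0.7$ the cut corresponds to a raw log-depth difference of 0.5,
i.e. roughly a 1.6-fold depth ratio at 20×; the fixture default
`min_depth_ratio` = 1.8 sits deliberately above that. The binning seed only
permutes the order in which scaffolds enter the clustering (tie-breaking);
results are a pure function of inputs and seed. No claim of equivalence
with any particular production binner is made — the stand-in exists so that
binning *behaviour* (including its sensitivity to 1 % depth changes) can be
studied against ground truth.

## Alignment, ANI and matching

The evaluator uses an internal anchor-chain aligner: maximal exact matches
of length ≥ `anchor_k` (default 20) found by k-mer hashing, chained along a
diagonal when separated by ≤ `max_gap` (default 500 bp), identity computed
column-wise over the chained span. Because divergence is planted as
substitutions, chains stay on one diagonal and the identity is exact; the
aligner is forward-strand only, which suffices because pseudo-assembly
preserves orientation. Planted insertions (resistance genes) simply start
new diagonals and appear as separate hits.

Hits are filtered inclusively at ≥ 2000 bp and ≥ 70 % identity; a
100 %-identity secondary subset is available for the stricter
contamination view. ANI between a source and a bin is the length-weighted
mean identity of the longest mutually consistent (non-overlapping on both
sides) hit subset, selected greedily by length. A bin is matched to a
source only when it is the source's highest-ANI bin, the source is the
bin's highest-ANI source, and the bin is not the unbinned pool; ties break
by aligned fraction, then lexicographic id. Completeness is the covered
fraction of the source by hits to its matched bin; contamination is the
fraction of the bin covered by hits from *other* sources; interval unions
merge overlaps. The high-quality call is strict: completeness > 90 **and**
contamination < 5.

## The subsampling experiment

Starting from a completed run, read pairs are retained independently with
probability 0.99 (one Bernoulli per pair, mates inseparable), depth is
recomputed over the unchanged scaffolds, binning is repeated with the same
seed and settings, and matching is re-run. The report lists, per source
and subsampling replicate, whether it was matched before and after. At
rate 1.0 the experiment reproduces the original bins exactly, which the
tests assert; at 0.99 it demonstrates that the machinery can change bin
membership under depth fluctuations of about 1 %.

## Resistance-gene concordance

Sources and matched bins are screened against a gene catalogue; a gene is
reported at ≥ 90 % identity and ≥ 60 % gene coverage (inclusive), the
usual resistance-screening defaults, with a denser anchor (k = 15) because
catalogue genes are about a kilobase. Detected genes map to predicted
resistance as the union of their phenotypes over the panel (84 generic
slots by default; real panels load from a TSV). Confusion counts per
antimicrobial (TP, FN, FP, TN) yield sensitivity, specificity, accuracy,
precision and F-score, with 0/0 reported as `NA`; community-level metrics
pool counts across matched chromosome pairs (micro-averaging). Point
mutations conferring resistance are out of scope — only gene
presence/absence is modelled.

## Problem sizes and defaults used in the shipped checks

The end-to-end checks use a four-genome baseline community (lengths
300/280/250/220 kb, GC 0.35–0.65, 250,000 pairs, every genome ≥ 20×
expected depth, depth ratios ≥ 1.8) — large enough that every bin clears
the 200 kb minimum bin size and small enough that the whole suite runs on
one CPU in minutes. Genome lengths are two orders of magnitude below real
bacterial chromosomes; this scales the analysis down without changing any
of the decision rules, and all thresholds retain their real-data values.

## What passing tests do and do not show

The fixtures emulate the statistical structure binning relies on (GC-driven
composition, depth separation, planted divergence, plasmid copy number)
but not rRNA operons, repeat families, real taxa, inter-genome horizontal
transfer, or assembler-specific artefacts. A clean pass on the baseline
community therefore demonstrates the *machinery* — conservation,
determinism, exact ground-truth arithmetic, threshold fidelity — and a
best-case recovery scenario; it does not certify recovery rates on real
communities, where fragmentation and chimerism are richer. The
`community_1a/1b/2` presets exist precisely to re-introduce those failure
modes in controlled doses.

## Known limitations

* Substitution-only divergence and error; no indels anywhere in the stack.
* Forward-strand alignment; inversions or reverse-complemented assemblies
  would be missed (they cannot arise from the internal pseudo-assembler).
* The binner is a transparent stand-in, not a reimplementation of any
  published tool; absolute bin boundaries differ from production binners
  even where qualitative behaviour matches.
* Circular replicons are treated as linear.
* Dereplication-style clustering of genomes is not reproduced; only the
  pairwise ANI and the mutual-best matching that the evaluation consumes.
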