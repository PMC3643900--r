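---
title: "Methods: profiling microbial DNA and deamination damage in ancient bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling microbial DNA and deamination damage in ancient bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bonemeta` analyses the microbial fraction of ancient-bone shotgun
metagenomes sequenced on 454-style platforms. This vignette documents the
models and procedures, the parameters that matter, the design decisions
taken where the design was genuinely open, and what the synthetic-data
tests do and do not demonstrate about real data.

## The analysis at a glance

Reads pass through: mean-quality filter → duplicate-read clustering →
adaptor trimming → rRNA similarity search → majority-LCA taxonomic
assignment → composition profiles → taxon/gene binning → reference-guided
consensus → read-versus-consensus substitution spectrum. Two side analyses
support experimental design and validation: in silico restriction
digestion with the CpG-targeting enzyme mixes, and a precision/recall
benchmark of rRNA read detection.

## Preprocessing

**Quality.** Reads with mean Phred quality strictly below 20 are removed;
a read at exactly 20 is kept. High-quality 454 bone libraries (mean ~27)
typically lose nothing here; the filter matters for older datasets.

**Duplicates.** Emulsion PCR multiplies single library molecules onto
several beads, producing artifactual duplicate reads that must be removed
before any abundance or diversity statement. Two modes are provided.
*Linkage* mode computes pairwise Levenshtein distances normalized by the
longer read, runs single-linkage clustering, and cuts at a normalized
distance (default 0.03 — about one difference per 33 bases, comfortably
above the platform error rate but below inter-taxon rRNA divergence), for
each emulsion set separately: duplicates cannot arise across emulsions, so
the partition never crosses sets. *Greedy* mode reproduces cd-hit-454
semantics: reads are processed longest-first and each joins the first
representative reaching 97% identity over at least 80% of the longer
sequence (identity is matches over aligned columns of an ends-free
alignment). Linkage mode is the stricter, slower choice used for
substitution analyses; greedy mode is for cross-dataset comparability.
The per-emulsion linkage cutoffs used in the original large-scale analyses
are not published; the 0.03 default here is this package's own choice and
is validated only on synthetic duplicates.

**Adaptors.** Raw reads begin with a fixed 4-bp key (removed when present
as an exact prefix) and may end in a complete 44-bp end adaptor, a partial
prefix of it, or none, depending on template length. The trimmer removes
the longest read suffix matching an adaptor prefix with mismatch fraction
≤ 0.1 and length ≥ 6, recording the state (full/partial/none). Only the
forward orientation is searched — the end adaptor is a known sequence on
the read strand. With a 6-base minimum overlap at 10% mismatches, the
chance of clipping a random read suffix is small but not zero
(≈ 4⁻⁶ per read per offset); partial-adaptor states on real data are
therefore an upper bound.

## rRNA taxonomy

**Reference curation.** SILVA-style tables carry alignment-quality and
pintail (chimera) scores and taxonomies from several sources. Entries are
dropped when align_quality < 75, pintail < 100, when the annotated domain
differs between taxonomy sources (mostly organellar sequences), when
taxonomically uninformative (unlabelled metagenome reads), on a
tRNA-contamination blacklist, or when metadata is missing. Curation is
idempotent and logs each rejection with its reason.

**Search.** The built-in search locally aligns each read against every
reference on both strands (match +1, mismatch −2, gap open 3, extend 1)
and converts scores to e-values with the Karlin–Altschul form
`E = K·m·n·exp(−λS)` using fixed constants λ = 1.33, K = 0.621 for this
scoring scheme and the summed reference length as the database size. Hits
above the cutoff (default 1e-10) are suppressed. The contract is threshold
behaviour at the cutoff, not e-value agreement with external engines; at
desk scale this keeps the whole pipeline dependency-free, and tabular hit
files from an external search can be imported instead wherever hits are
consumed.

**Majority LCA.** A strict lowest common ancestor is fragile: one
misannotated reference among the tied best hits drags the assignment to
the root. The classifier therefore descends from domain towards genus and
at each rank keeps the child taxon supported by at least a `majority`
(default 0.5, read as "≥ 50%") of the hits tied at the best e-value,
stopping at the last rank with a unique qualifying winner; an exact 50/50
split has no unique winner and stops at the parent. Independently, a read
whose tied hits span more than one phylum is truncated to the domain
(`strict_phylum = TRUE` by default). The two rules can conflict — a
9-to-1 cross-phylum hit set has a clear majority but still spans two
phyla — and the truncation rule is applied unconditionally by default
because cross-phylum tied hits at equal e-value are strong evidence of a
conserved region carrying no sub-domain signal. E-value ties are detected
after rounding to 3 significant figures, the precision of tabular hit
files; genus is the deepest rank attempted. Raising `majority` can only
shorten the assigned path (this monotonicity is property-tested).

**Profiles.** Composition tables at a chosen rank count assigned reads;
reads classified above the requested rank roll up into a bucket labelled
with their deepest achieved taxon, so counts always partition the
assigned reads.

## Consensus and the substitution spectrum

**Binning.** Reads enter an assembly bin per taxon and per gene (SSU and
LSU separately), requiring assignment at or below the bin taxon and a
best bit score strictly greater than 75 among hits to references of that
gene — the score filter keeps diverged or partial matches from
contaminating the consensus.

**Consensus.** Reads are locally aligned in both orientations to a layout
(a provided reference, else the longest read). The consensus base per
column is the quality-weighted majority; ties go to the alphabetically
first base. Column quality is the summed Phred of agreeing bases minus
disagreeing bases, floored at zero; coverage counts spanning reads.
The seed defines coordinates only — it never votes, so an error-free read
tiling reproduces the reference exactly, and a systematic difference from
the seed is called as long as reads support it. A single alignment pass
against the layout is used (no iterative realignment); with the low
divergence inside a bin this is sufficient, and it keeps the procedure
deterministic and cheap.

**Spectrum.** Each member read is compared with the consensus in its own
5′→3′ orientation. Counting starts only after the first `skip_run = 5`
contiguous consensus-matching bases — leftover partial adaptor at a read
start would otherwise masquerade as a burst of substitutions — and a read
with more than `max_changes = 5` counted changes is discarded entirely,
contributing to neither numerator nor denominator. The discard rule is
evaluated on the post-skip changes, i.e. on the same quantity the
statistic counts. Changes are collapsed into the six complementary class
pairs, so the tally is invariant under reverse-complementing the reads.
Indel columns are excluded from both numerator and denominator and
reported as a separate diagnostic count, because homopolymer indels are a
platform artifact, not a damage signal. The denominator is the number of
read bases aligned to consensus columns after the skip point over retained
reads; an "all aligned bases" denominator would mix pre- and post-skip
conventions between numerator and denominator, so the post-skip choice is
used for internal consistency. The skip rule is applied from the 5′ end
only, where the adaptor remnant motivates it. Frequencies are compared to
an instrument error floor of 4×10⁻⁴ per site, the standard estimate for
this platform; `plot_spectrum()` draws it as a reference line.

## The synthetic-data generator

The generator emulates the features of 454 bone libraries that the
pipeline must survive: bimodal read lengths (normal mixture with modes 44
and 255 bp, 80% short, truncated at 20 bp), per-group emulsion duplicates
(geometric group sizes), the 4-bp key and 44-bp end adaptor with
full/partial/absent states, a 4×10⁻⁴/site substitution error floor,
homopolymer-run indels, per-base qualities with mean ≈ 27, and a
deamination model. Damage is applied to the template before duplication
and sequencing error, since deamination precedes amplification chemically;
duplicates therefore share damaged sites but differ at sequencing errors,
exactly the structure duplicate clustering must tolerate.

**Damage parametrization.** `ct_interior` is defined as the expected
per-sequenced-base rate of damage-induced C→T-class changes away from read
ends, converted internally to a per-template-C probability
(`ct_interior · L / n_C`). This makes the generator's dial and the
spectrum's read-out commensurable: simulating `ct_interior = 5e-3` yields
a C→T/G→A class frequency of 5×10⁻³ directly, which is what the
parameter-recovery tests assert. The alternative convention (a per-C
probability) differs by the factor 1/f_C ≈ 4 and would decouple the dial
from the statistic. The 5′-terminal enhancement multiplies the rate by
`terminal_factor` (default 55, within the 50–60-fold range reported for
ancient DNA) decaying geometrically with length `decay_length = 3`
positions — the literature's end-enhancement is well established but its
exact functional form is not prescribed, and a one-parameter geometric
decay is the simplest faithful shape. Qualities are decorative (drawn
independently of error positions); tests that need error truth use the
truth table, not qualities.

The generator does **not** model flowgram signal processing, paired ends,
chimeras, contamination between samples, or non-uniform fragmentation.
Passing tests therefore demonstrate correctness of the statistics under
known truth, not robustness to every real-data pathology.

## Digestion and benchmark

Restriction sites are found by scanning the forward strand for IUPAC
motifs (overlaps counted, coinciding positions collapsed, `N` matches
nothing); all seven motifs in the two mixes are reverse-complement
palindromes, so forward scanning is complete — asserted as a test. Cuts
are placed at motif starts; for mean fragment length (sequence length /
(cuts + 1)) any consistent within-site offset is equivalent. The analytic
expectation multiplies allowed-base probabilities per motif position and
sums over motifs, ignoring motif overlap — a first-order approximation
accurate to a few percent at these motif densities, and the Monte-Carlo
tests compare against it at 10% tolerance.

The detection benchmark classifies searched reads by their true genomic
interval: a hit overlapping an rRNA gene by ≥ 50 bp is a true positive; a
hit entirely outside every gene ± 1 kb is a false positive; hits near gene
borders or in the flank are ignored as ambiguous; true rRNA reads without
hits are false negatives. Precision = TP/(TP+FP), recall = TP/(TP+FN).

## Problem sizes and determinism

Every stochastic step takes an explicit seed and is byte-deterministic
given it, including the full pipeline run (the resolved-config copy, which
records the output path, is the only run-specific artifact). The test
suite and the acceptance script use desk-scale problem sizes chosen to
give comfortable statistical margins: 2,000 reads (≈ 3.4×10⁵ counted
bases) for damage-parameter recovery, 200 reads for duplicate-recovery
scoring, 1,000 random taxonomies for the LCA oracle comparison, 1 Mb for
digestion Monte Carlo. At these sizes the binomial sampling error of the
recovered C→T/G→A frequency is ~4% relative, well inside the 25% assertion
band.

## Known limitations

* The built-in search is O(queries × references) full dynamic programming;
  it is a desk-scale tool, not a BLAST replacement. Import tabular hits
  for large databases.
* Consensus building is single-pass and reference-guided; it does not
  discover structural variants or assemble de novo across bins.
* The damage model treats sites independently; real deamination shows
  fragment-end and single-strand-overhang structure beyond the geometric
  5′ decay modelled here, and the package reports raw positional rates
  only as a diagnostic (`read_position_rates()`), deliberately avoiding
  positional model fitting.
* Duplicate clustering assumes duplicates are sequence-near; a duplicate
  pair split across emulsion-set labels (mislabelled libraries) will not
  be merged in linkage mode.
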