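# bonemeta

Microbial metagenome profiling and ancient-DNA damage analysis for bone
samples.

Ancient bones are dominated by microbial DNA: in deep-sequenced Neanderthal
and mammoth libraries the endogenous fraction is a few percent, and the rest
is a taphonomic community — largely high-GC Actinobacteria such as
*Streptomyces* — whose age and identity matter both for understanding bone
diagenesis and for strategies (like restriction digestion of GC-rich DNA)
that enrich the endogenous fraction. `bonemeta` implements the computational
pipeline for this problem as a tested, reusable R package:

* **454-style preprocessing** — mean-quality filtering, emulsion-PCR
  duplicate removal (strict per-emulsion single-linkage clustering of
  globally aligned reads, or greedy cd-hit-style clustering at 97%
  identity / 80% coverage), and detection/trimming of the 4-bp key adaptor
  and the 44-bp end adaptor (full, partial or absent).
* **rRNA taxonomic profiling** — curation rules for a SILVA-style reference
  table (alignment quality ≥ 75, pintail = 100, cross-source domain
  agreement, informative entries only), a built-in desk-scale similarity
  search (Karlin–Altschul e-values, E ≤ 1e-10, both strands) or import of
  standard 12-column tabular hits, and a *majority* lowest-common-ancestor
  classifier: among the hits tied at the best e-value, descend the ranked
  taxonomy and keep the child taxon carried by ≥ 50% of the tied hits;
  reads whose tied hits span more than one phylum are classified only to
  the domain.
* **Consensus + damage spectrum** — taxon/gene-binned reference-guided
  consensus building (quality-weighted majority per column), and the
  substitution-spectrum statistic that separates ancient from modern DNA.
* **In silico restriction digestion** — IUPAC-motif scanning for the two
  CpG-targeting enzyme cocktails (Mix1: BstUI `CGCG`, BsiEI `CGRYCG`,
  Hpy99I `CGWCG`; Mix2 adds TaqI `TCGA`, MspI `CCGG`, TauI `GCSGC`,
  HinP1I `GCGC`), with first-order analytic expectations for i.i.d.
  sequence.
* **Detection benchmark** — precision/recall of rRNA read detection with
  the ≥ 50 bp overlap rule and a ±1 kb ignore zone around operons.
* **Synthetic data with truth** — a simulator of mock communities and
  454-style reads (bimodal 44/255 bp lengths, duplicates, adaptors,
  homopolymer indels, a 4e-4/site error floor, and a deamination model
  with 50–60-fold 5′-terminal enhancement) so that every stage is testable
  without downloads.

## The damage statistic

Post-mortem hydrolytic deamination converts cytosine to uracil, read as
C→T (and G→A on the complementary strand). For each consensus contig,
every member read is compared to the consensus and changes are tallied
into the six complementary substitution classes

> C→T/G→A, T→C/A→G, C→A/G→T, A→C/T→G, C→G/G→C, A→T/T→A

with frequency = changes / total aligned bases. Two guards remove
alignment artifacts from leftover adaptor sequence: counting starts only
after the first 5 contiguous bases of a read that agree with the consensus,
and reads with more than 5 counted changes are discarded entirely. Ancient
DNA shows C→T/G→A far above the 4×10⁻⁴/site instrument error floor;
modern DNA shows all six classes in the range of that floor.

## Worked example

The `analysis/` directory is a numbered workflow over the package: simulate
a four-phylum bone community in which only the dominant actinobacterial
taxon is ancient, preprocess, classify, assemble, and profile damage:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_classify.R
Rscript analysis/04_consensus_damage.R
Rscript analysis/05_digest_benchmark.R
```

Stage 3 prints the recovered community profile:

```
phylum-level composition:
  Actinobacteria        175 reads   37.72%
  Proteobacteria        142 reads   30.60%
  Firmicutes             98 reads   21.12%
  Bacteroidetes          43 reads    9.27%
  Bacteria                6 reads    1.29%
true phylum recovered for 98.7% of classified reads
```

(the `Bacteria` row collects reads classifiable only to the domain), and
stage 4 the per-bin substitution spectra:

```
Actinobacteria_SSU      56 reads  consensus 1314 bp  cov   4.7x  C>T/G>A 6.17e-03  others <= 1.03e-03
Proteobacteria_SSU      64 reads  consensus 1405 bp  cov   4.2x  C>T/G>A 0.00e+00  others <= 1.79e-04
...
ancient bin Actinobacteria_SSU: C>T/G>A = 6.17e-03 (15x the error floor)
```

— the simulated-ancient taxon stands out in the C→T/G→A class only, while
the modern bins sit at the error floor, which is exactly the read-out used
to decide whether bone bacteria are old colonisers or modern contaminants.
Stage 5 shows why restriction digestion enriches host DNA: at GC 0.72 the
Mix2 cocktail cuts i.i.d. sequence into ~14 bp expected fragments versus
~1 kb for Mix1 at GC 0.30.

All tables land under `results/analysis/`.

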