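---
title: "Combined hybrid-capture and complement amplicon analysis: methods"
author: "exocomp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined hybrid-capture and complement amplicon analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the workflow

Hybrid-capture whole-exome sequencing (WES) systematically fails to
sequence a slice of the protein-coding space: some CDS bases are outside
the capture probe design entirely, and others sit in GC-rich or
repetitive tracts where capture efficiency collapses, leaving read depth
below the 10x callability floor (RD10). When a recessive disorder is
caused by a compound heterozygote and one of the two hits lies in such a
pocket, a WES-only analysis sees a single heterozygous variant in the
gene and reports nothing.

`exocomp` implements, at desk scale, the remedy of pairing WES with a
complementary custom CDS panel (CCCS) built by selective circularization:

1. **Coverage accounting** (`computeDepth`, `coverageAtThreshold`,
   `unionCoverage`): per-base depth over on-target space (capture probes
   padded by 100 bp), RD10/RD15 fractions per chromosome and for the
   WES ∪ CCCS union.
2. **Complement extraction and panel design** (`extractComplement`,
   `designProbeSet`): CDS bases with design-sample depth < 15 or outside
   padded probe space become the panel target; candidate amplicons are
   runs of restriction fragments validated by remapping their simulated
   100 bp end-read pair, in three stringency tiers.
3. **Platform-aware read processing** (`trimAdapter`, `markDuplicates`,
   `filterPairs`, `maskEnds`): the two platforms differ in exactly three
   steps — PCR-duplicate removal (WES only), 3' adapter trimming and
   5 bp terminal masking (CCCS only), and rescue (CCCS only).
4. **Rescue** (`rescuePairs`): rejected pairs are realigned with a
   complete enumerator; a pair survives only with a *single* proper
   placement at its minimum total mismatch count (ties discard).
5. **Calling** (`buildPileup`, `callVariants`, `classifyZygosity`,
   `mergeCallsets`): threshold caller with quality >= 20, depth in
   [10, 10000), alt-frequency bands (het = [0.25, 0.75], hom > 0.75,
   otherwise missing), score gates >= 20, left-normalized indels, and
   per-site WES/CCCS merging.
6. **Interpretation** (`annotateVariants`, `filterKnown`,
   `filterConsequence`, `inheritanceFilter`, `variantCascade`,
   `concordance`): consequence annotation against one transcript per
   gene, database exclusion with pathogenic-MAF rescue (< 0.01),
   nonsynonymous restriction, Mendelian models and array concordance.

`runCombined()` orchestrates the whole flow; the CCCS branch triggers
only when the WES branch produces no candidates under the configured
inheritance models (or when forced).

# The synthetic cohort

Everything is testable without external data because the generator
(`simulateReference`, `plantPedigree`, `simulateWesReads`,
`simulateCccsReads`) produces the full input universe. Its defaults
describe one fixed study condition, not a tuning surface.

## Genome and gene models

Two 500 kb chromosomes carry 200 genes of five exons each (exon lengths
90–240 bp, rounded to codon multiples; introns 150–600 bp; both strands).
Each CDS is a sense-codon sequence opened by ATG and closed by a stop, so
stop-gain detection is meaningful. Two kinds of capture-resistant
structure are embedded:

* **GC pockets** (`lowcovFraction = 0.08`): middle exons regenerated from
  GC-heavy sense codons (GC fraction ≈ 0.8 vs ≈ 0.5 genome-wide),
  emulating the empirical observation that roughly 7–10 % of CDS stays
  under-sequenced on capture platforms.
* **Off-probe exons** (`offProbeFraction = 0.04`): exons simply left out
  of the capture design, the "not covered by probes" category.

Capture probes are 120-mers tiled at 90 bp steps over all remaining
exons (± 10 bp), giving > 90 % designed CDS coverage.

## Capture bias and read models

Capture efficiency is a single monotone penalty
$w = \exp(-s\,\max(0,\,GC - 0.55))$ with `gcBiasStrength` $s = 20$, which
drives pocket exons (GC ≈ 0.8) to about 2 % of nominal efficiency —
mean pocket depth ≈ 1–2x against a genome-wide target of
`wesMeanDepth = 70` (the scale of published capture experiments).
Fragments are Normal(180, 30) inserts sequenced as 100 bp pairs;
substitution errors at `errorRate = 0.001` carry qualities U(10, 30)
against Q35 elsewhere, so the Q20 pileup filter is exercised; PCR
duplicates are injected at `dupRate = 0.1`.

Amplicon (CCCS) reads derive only from accepted panel amplicons, start
exactly at the amplicon's restriction-site ends, and read through into
the configured Illumina adapter prefixes when the amplicon is shorter
than 100 bp; target mean on-amplicon depth is `cccsMeanDepth = 170`,
matching the scale reported for selective-circularization panels.
Post-filter called depth runs some 10–15 % below the nominal targets
(duplicate removal, ± 2 SD insert window, quality filtering); the
configuration values describe sequencing effort, not called depth.

## Pedigree genetics

Each member carries two haplotypes. Founders receive common
database-known variants (site frequencies U(0.05, 0.45); these sites are
also the array content), rare background variants of mixed classes
(missense, synonymous, intronic, splice-site, nonsense,
frameshift deletions — one gene at most each, so no accidental
compound hets), and the focal variants: a compound-het nonsense pair
(partner A in an ordinary exon on the paternal haplotype, partner B
inside a GC pocket on the maternal haplotype), an AR-homozygous nonsense
in an off-probe exon, and a de novo nonsense added only to the affected
child. Children inherit one whole haplotype per parent; the affected
child receives the carrier haplotypes, unaffected siblings the others.
This forced transmission realizes the designated inheritance labels
exactly and is intentional — the generator defines a truth scenario, not
a population model.

One rare missense is flagged known-pathogenic at MAF 0.005 so the
database filter's rescue path is exercised.

## What the generator does *not* emulate

No recombination, no de novo indels beyond 10 bp, no
sequencing-machine-specific error profiles or quality decay along the
read, no sex-chromosome/PAR structure, no mappability structure beyond
the planted repeats in test fixtures, and haplotype-uniform sampling
(no allele-specific capture bias). Passing tests therefore demonstrate
the pipeline's logic — coverage arithmetic, the rescue rule, threshold
calling, Mendelian filtering — under controlled conditions; they do not
certify caller performance on real instrument data.

# Numerical and design choices

* **Coordinates.** All in-memory intervals are 1-based closed
  GRanges/IRanges, the Bioconductor convention; BED I/O converts to the
  0-based half-open disk form via `rtracklayer`, VCF output is 1-based.
* **First pass vs rescue.** The built-in mapper anchors exact seeds
  (pigeonhole: `maxMm + 1` disjoint segments guarantee a hit) and fully
  verifies candidates; the first pass allows 2 substitutions per mate
  (strict, like a default short-read mapper), rescue re-enumerates
  completely at 5. A single gap up to 10 bp is fitted for mates with no
  ungapped placement, standing in for local indel realignment; gap bases
  count 1 each toward the mismatch total.
* **Scores.** The variant score is the capped sum of alt base qualities
  (Phred-scaled probability that all alt evidence is error); the
  consensus score is the Phred-scaled posterior of the called genotype
  under a symmetric-error binomial with uniform genotype prior. Both are
  deterministic, monotone in evidence, and gated at 20. These are the
  package's own definitions; the historical tools' internals are
  version-bound and unspecified.
* **Zygosity boundaries** are closed: alt frequency exactly 0.25 or 0.75
  is heterozygous; 0.76 is homozygous; below 0.25 or depth below 10 is
  missing.
* **Ties and degeneracy.** Multi-allelic columns emit the highest-count
  alt; duplicate classes keep the highest summed base quality; gapped
  fits take the leftmost minimal split; indels are left-normalized
  (idempotent), and the generator plants indels already normalized.
* **Panel design.** Candidate amplicons are concatenations of adjacent
  restriction fragments; the default motif panel is eight 4-cutters
  (AluI, DpnII, HaeIII, RsaI, NlaIII, MseI, TaqI, TaiI), emulating a
  two-reaction digest — with only four motifs the ~64 bp site spacing
  left structural holes no amplicon could cover once the 5 bp terminal
  mask is honoured. Amplicons are capped at 190 bp
  (2 x readLen − 2 x mask) so a single pair covers every callable base,
  and the greedy cover counts only the edge-trimmed footprint, forcing
  overlapping neighbours at amplicon boundaries. Tier semantics: tiers
  1–2 demand the simulated read pair's placement be unique outright
  (tier 2 merely admits 50–149 bp amplicons); tier 3 accepts a placement
  that beats the runner-up by at least one mismatch. Bases no validated
  candidate can cover are reported as residual — on the default scenario
  a few such holes remain, which is faithful to practice (published
  complement panels covered only about two-thirds of their requested
  target).
* **Design sample.** The panel is designed from the first founder's
  depth profile only; its adequacy for the other members is a measured
  outcome (the depth profiles of low-coverage regions are strongly
  shared across samples), not an assumption.
* **Conditional branch.** The candidate models for the affected child
  default to the recessive set {AR-homozygous, compound-het}; the
  de novo model is implemented and tested but not in the default set, so
  a planted de novo does not short-circuit the complement branch of the
  default scenario.
* **Concordance.** Comparable sites are array sites inside callable
  (RD10) space; the default conservative mode additionally excludes
  sites whose sequencing evidence is sub-threshold ("missing": at least
  two quality-passing alt reads but no call), rather than scoring them
  as reference — the raw mode is available.

# Problem sizes used by the test-suite

The full recovery scenario runs on the default configuration (1 Mb over
two chromosomes, 200 genes, trio, capture depth 70x, panel depth 170x)
— about 160 k read pairs in total. Unit and property tests use toy
instances: ≤ 10 kb references for per-base brute-force oracles, a ≤ 5 kb
repeat-bearing genome with 500 random pairs for the placement-enumeration
oracle, and 60–150 kb genomes for pipeline-level checks. These sizes are
the package's chosen trade-off between statistical resolution and a test
suite that runs in minutes on a laptop core.

# Known limitations

* One transcript per gene; no UTR annotation (gene models are pure CDS),
  no multi-transcript consequence ranking.
* The caller is a per-sample threshold caller; no joint genotyping, no
  base-quality recalibration, no haplotype assembly. Indel support is
  limited to one gap of at most 10 bp per read.
* Mate-overlap double counting is retained in depth and allele counts
  (naive pileup semantics) — documented, and consistent between depth
  and call statistics.
* The placement enumerator is complete only for substitutions within the
  per-mate bound; gapped placements are best-effort.
* `enumeratePlacements` completeness requires reads of at least
  8 x (maxMm + 1) bases (seed pigeonholing); the trimming minimum of
  50 bp guarantees this for the default bounds.
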