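---
title: "mirforge: methods for two-library small RNA miRNA discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirforge: methods for two-library small RNA miRNA discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirforge)
```

## Overview

mirforge implements the classical two-library small RNA sequencing
workflow for miRNA discovery and profiling in a species with an
incomplete miRNA catalog: read filtering and collapsing, three-tier
annotation (known in the species, conserved in other mammals, novel
candidates supported by a predicted hairpin), isomiR collapsing with
representative selection, unreplicated differential expression by
Fisher's exact test, and microarray-style validation utilities. A
simulator plants hairpin precursors with known abundances in a synthetic
genome so that every stage can be validated against ground truth.

This vignette documents the methods and the reasoning behind the
defaults. The worked end-to-end example is in the README.

## Read processing

Reads are optionally 3' adapter trimmed (longest read suffix matching an
adapter prefix, minimum overlap 8 nt, leftmost occurrence when the full
adapter occurs internally), collapsed to unique tags with per-library
counts, and passed through a filter cascade:

1. size selection, 10--40 nt inclusive;
2. removal of tags containing `N`;
3. removal of low-complexity tags (one base at or above 90% of the
   sequence);
4. removal of tags whose *total* count across both libraries is below 2
   (singleton removal).

Every step reports `reads_in = reads_out + reads_removed`, and the
output of one step is the input of the next, so read counts are
conserved through the cascade. The surviving ("mappable") totals per
library are the denominators used for counts-per-million normalization
and the Fisher test. Tags matching a catalog of other non-coding RNA
classes (rRNA, tRNA, snRNA, snoRNA, mRNA fragments, repeats) are removed
before annotation, with per-class read fractions reported.

## Hairpin folding

Candidate precursors are folded with a weighted Nussinov dynamic
program: maximum-weight non-crossing base pairing with pair weights
GC = 3, AU = 2, GU = 1 and a minimum hairpin loop of 3 nt. This
replaces a thermodynamic folder deliberately: the optimization is
self-contained and exactly checkable against exhaustive enumeration
(`fold_exhaustive()`), which is one of the package's acceptance
criteria. An external folder can be substituted through the annotation
API if nearest-neighbor energies are wanted.

Two details matter in practice:

* **Tie-breaking.** The maximum-weight pairing is rarely unique. Among
  equal-weight optima the traceback realizes the structure with the
  maximum number of stacked pair adjacencies, computed exactly by a
  lexicographic dynamic program. Without this, a planted near-perfect
  stem can be returned as an arbitrarily fragmented rearrangement of
  the same score. Zero-weight pair types (e.g. GU when its weight is
  set to 0) are treated as unpairable so they never enter a structure
  merely to improve stacking.
* **GU asymmetry.** Because GU pairs do not survive reverse
  complementation, fold scores are strand-symmetric only when the GU
  weight is zero; tests exploit this as an invariant.

### Hairpin acceptance

`hairpin_features()` reduces a folded window to: the longest *stem*, the
loop it encloses, the fraction of mature bases paired, and the arm
carrying the mature sequence. A stem is the longest chain of nested
pairs in which consecutive pairs are stacked or separated by at most
2 nt on either side, with at most 2 such interruptions overall. The
restriction is the point: maximum-weight structures of random sequences
contain long cascades of pairs scattered over many short helices, which
an unrestricted chain length would count as one stem. A mature/star
duplex with up to two interior mismatches remains a single stem under
this definition, while random cascades fragment.

`is_valid_hairpin()` accepts a window when the stem carries at least 14
pairs, at least 60% of mature bases are paired, the mature lies on one
arm (not spanning the loop), and the loop is at least 3 nt. The stem
threshold was calibrated on planted hairpins versus dinucleotide-shuffled
versions of the same precursors (Altschul--Erikson shuffle, preserving
dinucleotide composition): at 14 pairs the planted acceptance is 100%
while shuffled acceptance is about 1% (the defect-limited stem
definition is what separates the two populations; without it, shuffled
sequences pass at over 40%).

## Three-tier annotation

Tier assignment is sequential and exclusive:

1. **known_species** -- tags mapping (up to 1 substitution) to the
   same-species precursor catalog;
2. **conserved_mammal** -- remaining tags mapping to other-mammal
   precursors;
3. **candidate** -- remaining tags *longer than 18 nt* with genomic
   hits whose locus, extended by 60 nt flanks on both sides, folds into
   a window passing `is_valid_hairpin()`.

Mapping uses a seed-and-verify scheme (pigeonhole split of each pattern
into `max_mismatch + 1` exact pieces, dictionary scan, Hamming
verification) over both strands for genomic search. Tags are clustered
into mature loci with a 3 nt start/end slop; within a precursor the most
abundant cluster is the mature, and other clusters are tested as the
miRNA* partner.

A star call requires the mature/star duplex geometry left by
Drosha/Dicer processing: both strands' 3' overhangs within 0--4 nt. The
duplex is assessed from sequence complementarity between the two spans
(best antiparallel register subject to the overhang bounds, at least 60%
complementary positions, Watson--Crick or GU), not from the realized
pairs of the folded structure: the weighted optimum is not unique, and a
score tie can realize a structure in which a genuine duplex is absent
even though the arms are near-perfect reverse complements.

For candidate loci, a tag and its star each map to *both* strands of the
locus (a tag and its near reverse complement mirror each other), so
candidate star grouping compares all same-strand window pairs between
cluster loci rather than only each cluster's best window.

## isomiR collapsing

Sequence variants within 3 nt terminal offsets at either end and at most
1 substitution of a reference mature sequence form one family. Each
family is represented by its most abundant member (ties: longer
sequence, then lexicographic), and the family's reported count is the
representative's count. The package measures how faithfully the
representative tracks the family total as the per-library Pearson
correlation of `log10(count + 1)` across families; on simulated data
this exceeds 0.99.

## Differential expression

With one library per condition there is no replication, so testing uses
Fisher's exact test on the 2x2 table of each miRNA's counts against the
remaining mappable reads in the two libraries. The two-sided p-value
follows the point-probability rule: the sum of hypergeometric
probabilities of all tables (at fixed margins) no more likely than the
observed one, with a relative tolerance of 1e-7 in the likelihood
comparison. The implementation is validated against direct enumeration
from log binomial coefficients and against `stats::fisher.test`, and its
empirical type-I error at p < 0.001 is measured under a simulated null
(the discrete test is conservative, so the observed fraction is below
the nominal level).

A miRNA is called differentially expressed when it is detected in both
libraries (co-expressed) and p < 0.001 (strict); fold changes are
reported as CPM ratios with a 1.5-fold band for direction calls.
Detection in only one library is reported as library specificity, not
differential expression. No multiple-testing correction is applied by
default, matching the unreplicated two-library design; a
Benjamini--Hochberg option exists.

## Validation utilities

The microarray-style module provides median probe-to-miRNA collapse,
quantile normalization (each column forced to the cross-column mean
distribution, via limma's implementation with mean-of-ties handling),
upper-quartile scaling as an alternative, Pearson correlation with
t-based p-values for replicate agreement, and cross-platform concordance
of log2 fold changes over the identifier intersection. A probe-level
simulator emulates the validation experiment (probe affinity offsets,
replicate noise, measurement noise) for closed-loop testing.

## Simulator

`generate_genome()` plants hairpin precursors at non-overlapping loci
(random strand) in a random background genome. Each precursor is built
from a random mature arm, a loop, and a star arm that is the reverse
complement of the mature with 0--2 interior mismatches, padded by 2 nt
at the 5' end and 4 nt at the 3' end; the annotated mature/star spans
are shifted 2 nt so the duplex has the canonical 2 nt 3' overhangs, and
the extra 3' padding keeps templated 3'-extension isomiRs inside the
precursor. Construction is verified: each draw is folded and must pass
`is_valid_hairpin()`, otherwise it is redrawn (about 1% of draws realize
an unrelated higher-scoring pairing through the loop or pads; the
guarantee is a postcondition of the generator, verification of a
construction rather than rejection sampling of random sequence).

Known-tier precursors enter the same-species catalog, conserved-tier
precursors the other-mammal catalog, candidates neither; decoy entries
are added to both catalogs. Reads are drawn multinomially per library
across mature variants (isomiR profile), star arms, contaminant
fragments, and an oversize tail, then subjected to per-base substitution
errors. All randomness derives from the configuration seed; the same
configuration reproduces the same dataset byte for byte.

## Benchmarks

`run_benchmark()` executes the validation scenarios end to end --
Fisher versus enumeration, type-I error, planted differential-expression
recovery, planted versus shuffled hairpin acceptance, folding optimality
versus exhaustive search, isomiR representative correlation, and
noiseless tier recovery -- and reports observed versus required values.
`scripts/acceptance.R` writes the same quantities as JSON for a given
seed.

## Limitations

* The folding objective is weighted pair maximization, not free energy;
  loop-type-specific energies, dangles, and coaxial stacking are out of
  scope, and the hairpin thresholds are calibrated to this objective.
* Mapping allows substitutions only (no indels), consistent with the
  isomiR model used.
* The differential-expression model is the unreplicated two-library
  Fisher test; with replicates, count-model tools are preferable.
* The simulator plants one contig and independent loci; clustered miRNA
  families and cross-mapping paralogs are not modeled.
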