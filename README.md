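# mirforge

Small RNA-seq miRNA discovery, isomiR collapsing, and two-library
differential expression — with a planted-truth simulator so every stage
is testable against ground truth.

## What it does

mirforge implements the classical discovery workflow for profiling
microRNAs in a species with an incomplete catalog, from two unreplicated
small RNA libraries (e.g. one per condition or developmental stage):

* **Read processing** — adapter trimming, collapsing to unique tags,
  size selection (10–40 nt), N / low-complexity / minimum-count filters,
  with read-count conservation verified at every step, and removal of
  other RNA classes (rRNA, tRNA, snRNA, snoRNA, mRNA, repeats).
* **Three-tier annotation** — tags are assigned sequentially to
  *known_species* (same-species precursor catalog), *conserved_mammal*
  (other-mammal catalogs), or *candidate*: unannotated tags longer than
  18 nt whose genomic locus, extended by 60 nt flanks, folds into an
  acceptable hairpin. miRNA* partners are recognized by the mature/star
  duplex geometry (0–4 nt 3' overhangs).
* **Hairpin folding** — a weighted Nussinov base-pair maximization
  (GC = 3, AU = 2, GU = 1, minimum loop 3) with a stacking-maximal
  tie-break, exactly checkable against exhaustive enumeration; hairpin
  acceptance uses a defect-limited stem definition calibrated on planted
  versus dinucleotide-shuffled precursors.
* **isomiR collapsing** — families of variants within ±3 nt terminal
  offsets and ≤1 substitution of a reference, quantified by their most
  abundant member.
* **Differential expression** — Fisher's exact test per miRNA against
  mappable library totals (point-probability two-sided rule), CPM fold
  changes, library-specificity classes, DE at p < 0.001 with a 1.5-fold
  direction band.
* **Validation utilities** — microarray-style probe median collapse,
  quantile normalization, replicate correlation, and cross-platform
  fold-change concordance.
* **Simulator & benchmarks** — plants verified hairpins with known
  abundances, fold changes, isomiR profiles, contaminants and sequencing
  error in a synthetic genome; `run_benchmark()` measures every claim
  end to end.

See `vignettes/mirforge-methods.Rmd` for the methods and the reasoning
behind the defaults.

## Worked example

Simulate two 20,000-read libraries over 50 planted miRNAs (20 known-tier,
15 conserved-tier, 15 candidate-tier), with the first three planted at a
true 4-fold up-regulation in library B, then run the full pipeline:

```r
library(mirforge)

cfg <- sim_config(seed = 42, library_depths = c(A = 20000, B = 20000),
                  true_fold_changes = c(rep(4, 3), rep(1, 47)),
                  mirna_weights = rep(1, 50))
ds  <- generate_genome(cfg)
sim <- simulate_libraries(ds)

pc  <- pipeline_config(reads = sim$reads, genome = ds$genome,
                       known_precursors  = ds$known_precursors,
                       mammal_precursors = ds$mammal_precursors,
                       other_rna = ds$other_rna, seed = 42)
res <- run_pipeline(pc)
print(res)
```

```
mirforge pipeline result
  mappable reads: A=17014, B=18502
              tier n_mirna n_precursor n_star count_A count_B
1    known_species      20          20     20    5894    8472
2 conserved_mammal      15          15     15    4108    4283
3        candidate      15          28     13    4188    4006
  co-expressed: 50 of 50 (100.00%)
  DE miRNAs (p < 0.001): 4
```

All 50 planted miRNAs are recovered in their correct tiers, every
planted star arm is flagged, and the differential-expression table ranks
the three planted changes first:

```r
de <- res$de_table
head(de[order(de$p_value),
        c("id", "tier", "cpm_A", "cpm_B", "fold_change", "p_value",
          "is_DE", "direction")], 5)
```

```
                                               id          tier cpm_A cpm_B fold_change  p_value is_DE direction
ssc-mir-K003-3p                   ssc-mir-K003-3p known_species 10638 40428       3.800 2.48e-74  TRUE        up
ssc-mir-K001-5p                   ssc-mir-K001-5p known_species  8993 36699       4.081 4.12e-72  TRUE        up
ssc-mir-K002-3p                   ssc-mir-K002-3p known_species  9580 37077       3.870 2.35e-69  TRUE        up
cand-chr1:4765-4789(+)     cand-chr1:4765-4789(+)     candidate 11285  7783       0.690 7.94e-04  TRUE      down
cand-chr1:27971-27995(+) cand-chr1:27971-27995(+)     candidate 12225  8756       0.716 1.40e-03 FALSE      none
```

The fourth call is sampling noise squeaking under the threshold — the
expected behavior of an unreplicated exact test at p < 0.001 without
multiple-testing correction (a `call_de(..., adjust = TRUE)` option
applies Benjamini–Hochberg).

The filter report shows read conservation through the cascade
(`reads_in = reads_out + reads_removed`, chained between steps):

```r
res$filter_report
```

```
          filter library reads_in reads_out reads_removed
1    size_filter       A    20000     19771           229
2    size_filter       B    20000     19808           192
3       n_filter       A    19771     19771             0
4       n_filter       B    19808     19808             0
5 low_complexity       A    19771     19771             0
6 low_complexity       B    19808     19808             0
7      min_count       A    19771     17014          2757
8      min_count       B    19808     18502          1306
```

### Command line

The same workflow is scriptable through `exec/mirforge`:

```sh
mirforge simulate --seed 3 --outdir sim --depth 20000
mirforge run --fastq-a sim/library_A.fastq --fastq-b sim/library_B.fastq \
    --genome sim/genome.fa --known sim/known.fa --mammal sim/mammal.fa \
    --other-rna sim/other_rna.fa --outdir out --seed 3
mirforge benchmark --seed 1
```

## Testing and reproduction

The test suite validates each module against independent oracles
(exhaustive fold enumeration, naive quadratic alignment, direct Fisher
enumeration, hand-worked arithmetic) plus end-to-end planted-truth
recovery:

```r
testthat::test_dir("tests/testthat", package = "mirforge",
                   load_package = "installed")
```

The benchmark quantities — Fisher-vs-enumeration error, type-I error at
p < 0.001, planted DE sensitivity/FDR, planted vs shuffled hairpin
acceptance, folding optimality, isomiR representative correlation, and
noiseless tier recovery — can be reproduced for any seed with:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

which writes one JSON object per quantity
(`{"<name>": {"value": ..., "n": ...}}`). Typical values at seed 1:
maximum Fisher error 1.6e-13 over 1000 tables, type-I fraction 3.5e-4 at
nominal 1e-3, DE sensitivity 1.0 with FDR 0 on 40 planted 4-fold changes
at 10^6-read depth, 100/100 planted hairpins accepted versus 2/100
dinucleotide shuffles, 0/500 folding mismatches against exhaustive
search, and isomiR representative–total correlations above 0.999.
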