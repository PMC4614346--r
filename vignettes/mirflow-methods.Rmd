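---
title: "mirflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mirflow` re-implements, as a tested and reusable pipeline, the classic
small RNA-seq workflow used to compare miRNA expression between two
insect strains — in the motivating use case, a *Bacillus thuringiensis*
Cry1Ab-resistant and a susceptible strain of the Asian corn borer, each
sequenced as two replicate libraries.  This vignette records the models
the package implements, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the workflow description left the design open.

## 1. Read cleaning and accounting

Raw reads are classified into exactly one category, tested in a fixed
priority order: low-quality (excluded from the high-quality total),
5' adapter contaminant, 3' adapter-null, insert-null, polyA,
shorter-than-18-nt, and clean.  Because the categories are mutually
exclusive by construction, the accounting identity

```
high_quality = adapter3_null + insert_null + adapter5_contaminant
             + shorter_than_18 + polyA + clean_reads
```

holds for every library, and `library_summary()` refuses inputs that
violate it.  Pipelines of this family report their accounting in
exactly this layout, and the published per-library columns satisfy the
identity exactly (e.g. 5,964,851 high-quality reads minus the five
filter categories leaves 5,763,509 clean reads).

Workflow descriptions rarely pin down the operational details, so the
following are explicit, configurable choices (`clean_params()`):

* **low quality**: any base below Phred 5 (`min_quality`), or more than
  10% N.  The threshold is conventional; the source workflow never
  defines "low quality".
* **3' adapter match**: leftmost position with at least 6 nt
  (`adapter_min_overlap`) of adapter prefix and at most 1 mismatch
  (`adapter_max_mismatch`).
* **polyA**: insert with ≥ 80% A (`polyA_fraction`); the source rule
  says only "poly (A)".
* **length window**: inserts shorter than 18 nt are removed; inserts
  longer than 30 nt are *kept* as clean but excluded from the 18–30 nt
  length histogram (the published clean totals include them).
* **category order**: the filters are named but not ordered in the
  source; the order above makes the categories a partition so the
  accounting identity is testable.

## 2. Annotation priority

Each unique tag gets exactly one annotation, by the priority rule
rRNA-class references (GenBank-derived before Rfam-derived) > known
miRNA > repeat > exon > intron > unannotated.  Non-coding classes match
by exact substring containment in the reference sequences.  Known
miRNAs match by near-exact alignment to the mature region of a
precursor: both tag ends within ±2 nt of the mature ends, at most 2
mismatches, no indels (`mirna_tolerance()`).  These tolerances are not
stated in the source workflow; they mirror common miRBase-pipeline
practice.  Variants (isomiRs) of one reference pool under one name, the
representative sequence being the variant with the most reads, and
names take the species prefix (`Ofu-`).  Ties between references are
broken by mismatch count, then end shift, then lexicographic reference
id, for determinism.  The repeat/exon/intron categories are optional
inputs and are skipped when absent (the motivating study had no
assembled genome either).

## 3. Novel miRNA discovery

Unannotated tags with at least `min_support` (default 3) reads and
length 20–24 nt are mapped to the genome by perfect matching on both
strands.  Around each placement two candidate precursors are excised:
tag on the 5' arm (15 nt upstream + 85 nt downstream) and the mirrored
3'-arm window, clipped at contig edges.  The windows are sized to
reproduce the 75–95 nt precursor range typical of insect miRNA
hairpins.

### Energy model

`fold_mfe()` is a dynamic program over all nested structures with
minimum hairpin loop 3, under a deliberately minimal nearest-neighbor
model: Watson–Crick and G·U pairs, Turner-style helix stacking free
energies, no dangles and no loop/multiloop penalties.  The energy of a
structure is the sum of stacking terms over directly adjacent pairs.
Because some G·U-on-G·U stacks in the table are *positive*, the
recursion separates "(i,j) stacked on (i+1,j-1)" from "(i,j) closing
anything else" so that unfavourable stacks are always charged; a naive
Nussinov-with-stacks recursion silently drops them.  Ties are broken
deterministically (fewer pairs, then a fixed enumeration order), so the
traceback is reproducible.  The DP is verified against exhaustive
structure enumeration for sequences up to 18 nt.

The original analysis used Mireap with an external folding engine;
published precursor energies are therefore treated as *descriptive*
(the package reproduces the ≤ −18 kcal/mol acceptance behaviour, not
the printed decimals).

### Acceptance criteria

A candidate is accepted iff (`hairpin_criteria()`):

1. MFE ≤ −18 kcal/mol;
2. exactly one terminal loop (single stem-loop);
3. ≥ 75% of mature bases paired;
4. the mature does not span the terminal loop;
5. a star region exists: both mature ends anchored in the duplex
   (within 2 nt) and the partner region, shifted by the 2-nt 3'
   overhang characteristic of Dicer processing, lies inside the
   precursor without overlapping the mature;
6. mature length 20–24 nt.

**Stem-trim refinement.** A fixed excision window drags in random
flanking genome sequence, which frequently folds into small side
hairpins; the single-stem-loop test would then reject a perfectly good
locus.  When a window is rejected for a structural reason, the
candidate is trimmed to the maximal run of pairs that encloses exactly
the tag's terminal loop (plus a 3 nt margin for the star overhang),
refolded, and re-evaluated against the unchanged criteria.  This is
what Mireap-class finders effectively do when they excise the
stem-loop.

Because a hairpin is also its reverse complement's hairpin, one locus
can yield mirrored candidates on both strands; overlapping
same-mature, same-contig candidates keep the better-scoring strand.
Identical mature+precursor pairs at *different* loci are kept as
separate records (multi-locus miRNA families), and accepted candidates
are numbered `Ofu-m0001_5p`, `Ofu-m0002_3p`, ... in locus order.

## 4. Differential expression

Counts are normalized to tags-per-million of library clean reads:
`norm = count / total_clean_reads × 1e6`, with exact zeros replaced by
0.01 so fold-changes stay defined; miRNAs whose normalized expression
is below 1 in *all* libraries are dropped.  Replicates are pooled per
strain — counts summed, clean-read totals summed — before
normalization and testing; this is the arithmetic that reproduces the
published normalized values to four decimals from the printed counts
and per-library clean totals (e.g. 31,180 / (5,804,468 + 5,834,651) ×
10^6 = 2678.8969).  Fold-change is `log2(resistant / susceptible)` of
pooled normalized values, computed from unrounded normalization (the
published table's own rounding shows this: its −7.8309 row is
reproducible from the raw counts but not from the printed 4-decimal
pair).

Significance uses the Audic–Claverie two-library statistic.  With
library sizes `N1`, `N2` and `r = N2/N1`, conditional on `x` counts in
library 1 the count `y` in library 2 under equal abundance follows

```
p(y | x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1))
```

and the reported p-value is the doubled smaller tail, capped at 1.
Both tails are summed directly in log space (the upper tail by
truncated summation), so tiny p-values keep full relative precision;
the implementation is checked against a direct-summation oracle to 10
significant digits and against a type-I-error bound (≤ 0.07 at α =
0.05) under null Poisson sampling.  The published p-values themselves
are *not* reproducible from the printed pooled counts — identical
p-values appear for different count pairs — so they are not used as
golden values; the fold-changes and normalized expressions are.
Replicate quality control is the Pearson correlation of per-miRNA
normalized expression between replicates, with 0.85 as the customary
adequacy bar.  No multiple-testing correction is applied to the DE
table, matching the source workflow.

## 5. Target prediction

Plant-style complementarity scoring after Allen/Schwab: with the site
aligned antiparallel to the miRNA, each mismatch or gap scores 1, each
G·U wobble 0.5, doubled at miRNA positions 2–13, and sites with
penalty ≤ 4.0 pass.  These constants come from the cited rule set (the
source paper does not restate them) and are configurable
(`target_thresholds()`).  Passing sites must also reach a duplex
hybridization energy ≤ −20 kcal/mol, computed as the minimum stacking
energy over ungapped antiparallel alignments with no intramolecular
pairs — the same energy table as the hairpin module, verified against
subset enumeration.  The full transcript is scanned (the reference
transcriptome carries no UTR annotation), every window is scored, and
overlapping passing sites of one miRNA on one transcript merge to the
best-scoring one.  Output is sorted and independent of input order.

## 6. Enrichment

For a candidate target-gene set of size `n` drawn from an annotated
universe of `N` genes, a term annotating `M` genes with `m` of them in
the candidate set is scored with the upper-tail hypergeometric
probability `P(X ≥ m)`, accumulated in log space.  Only terms with
`m ≥ 1` are tested, and the multiple-testing denominator counts
exactly those (the source does not specify this; it is documented
here).  GO uses Bonferroni, KEGG uses Benjamini–Hochberg FDR, both at
0.05, matching the source's two correction choices; the upper tail
(enrichment only) is tested, since "significantly enriched" is the
stated goal.  Term maps are flat gene→term tables; ontology-graph
propagation is out of scope.

## 7. qPCR validation

Relative expression versus the U6 snRNA internal reference is
`2^−(CT_miRNA − CT_U6)`; strain differences use the classic
equal-variance two-sample t-test (the SAS-era default — Welch is
available via `var_equal = FALSE`).

## 8. The synthetic-data generator

`simulate_reference()` + `simulate_libraries()` generate everything the
pipeline consumes, with ground truth: genome contigs with planted
hairpin loci, a known-miRNA database, non-coding RNA references,
transcripts with planted complementary target sites, gene→GO/KEGG
maps, and four FASTQ libraries.  The stated world mirrors the
motivating study:

* **libraries**: 2 conditions × 2 replicates, default 2×10^4 reads
  each (tests scale to 5×10^4 per library = 10^5 per condition for the
  recovery criterion, and down for fuzzing);
* **reads**: 18–30 nt inserts followed by the 3' adapter and random
  padding to 49 nt (the source trimmed reads under 50 nt), constant
  high quality;
* **contamination**: the five filter categories drawn multinomially at
  the published first-column rates (≈0.07% 3'-adapter-null, 0.02%
  insert-null, 0.19% 5'-contaminant, 3.1% short, ~5×10^-6 polyA);
* **composition of clean reads**: ≈6% known miRNA, 1% novel, 45%
  non-coding background (rRNA-heavy), 48% unannotated — matching the
  published ~5.8% maximal miRNA share and rRNA-dominated background;
* **counts**: per-miRNA negative-binomial with condition-dependent
  means (dispersion 0 degenerates to Poisson; default 0.05, mild
  overdispersion).  Base abundances are log-normal (sdlog 1); planted
  DE miRNAs get twice the median base abundance so they are detectable
  at moderate depth.  The resistant means are `weight × 2^lfc`
  *without* renormalization, so planted count ratios are exactly
  `2^lfc` in expectation;
* **novel loci**: perfect inverted-repeat stems (arm 28–35 nt, loop
  8–12 nt, short flanks) sized so the precursor fits the 15/85
  excision window; every planted precursor is validated against the
  package's own folding and acceptance criteria before planting, so
  recovery failures indicate pipeline defects, not unlucky draws;
* **contaminants and inserts** are constructed and then validated with
  the cleanse module's own detectors (resampled on failure), so the
  expected accounting is exact a priori, not approximate.

What the generator does **not** emulate: sequencing error models and
quality-score decay, isomiR edit variants beyond ±1 shifts, repetitive
genomes (multi-mapping beyond planted duplicates), expression-dependent
ligation bias, and real miRBase/Rfam sequence composition.  A green
recovery test therefore establishes that the pipeline's logic is
correct on data satisfying its own assumptions — not that the defaults
are optimal for real libraries.

## 9. Numerical choices and degenerate inputs

* All tail sums (count test, hypergeometric) run in log space with a
  log-sum-exp reduction; the count test's upper tail extends its
  summation window until terms fall 45 nats below the maximum.
* Folding ties: fewer pairs first, then a fixed enumeration order;
  energy comparisons use a 10^-9 tolerance.
* Zero substitution (0.01) applies to normalized values only, never to
  the raw counts entering the p-value.
* The two-sided count test includes the observed count in both tails;
  as a consequence, swapping the two libraries changes the p-value by
  at most twice the observed point's probability mass (an unavoidable
  discreteness effect — the property tests assert symmetry up to that
  bound, not exact symmetry).
* Degenerate inputs error early with the offending field named:
  zero-depth libraries, contamination fractions summing ≥ 1, empty
  adapters, constant vectors in `replicate_pearson()`, impossible
  hypergeometric configurations, non-finite CTs.
* Internal coordinates are 0-based half-open; GFF3 emission converts
  to 1-based closed.  Tags are uppercased and U→T on input.

## 10. Known limitations

* The energy model omits loop penalties, dangles and multiloop terms;
  absolute MFE values are more negative than Turner-complete engines,
  which is why published precursor energies are treated as descriptive
  only.
* The Audic–Claverie test assumes Poisson sampling; with biological
  overdispersion it is anticonservative, which is visible as extra
  (honest) false positives on overdispersed synthetic corpora.  The
  source workflow has the same property.
* Known-miRNA matching is substring/near-match based, not a full
  aligner; it is adequate for the ±2 nt / ≤2 mismatch contract but not
  for indel isomiRs.
* Target scanning is ungapped; the Allen/Schwab gap penalty is applied
  only to pre-gapped alignments passed to `penalty_score()` directly.
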