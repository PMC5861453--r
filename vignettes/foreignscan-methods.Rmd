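---
title: "Methods: TU-map refinement and compositional foreignness analysis"
author: "foreignscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TU-map refinement and compositional foreignness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foreignscan)
```

## The scientific question

When a basal transcription factor is deleted in an archaeon such as
*Haloferax volcanii*, the transcriptome response can be asymmetric with
respect to gene ancestry: genes acquired by lateral transfer (residing on
megaplasmids, in prophage regions, or simply compositionally atypical) may
respond differently from native genes. foreignscan implements the downstream
analysis that makes this question testable from standard RNA-seq outputs:

1. **Transcription-unit (TU) map refinement.** Operon maps inherited from
   older annotations carry stale 5′ ends. Given a table of mapped primary
   transcription start sites (TSSs), each TU's 5′ coordinate is moved to its
   primary TSS, TUs with an *internal* primary TSS are shortened to that
   position, and genes with an assigned TSS but no TU become new single-gene
   units. Promoter windows (−50..+10 around each TSS, 61 nt) are extracted
   for downstream motif discovery.
2. **Compositional foreignness metrics.** Genome-wide synonymous codon
   usage defines the *rare-codon set* (codons with strictly less than 10%
   of their synonymous family's genome-wide usage); each gene is scored by
   its rare-codon frequency and its AT content. Laterally acquired genes in
   a GC-rich halophile tend to score high on both.
3. **Association with differential-expression (DE) direction.** Genes are
   classified up / down / ns at adjusted *p* < 0.01 and tested for
   association between direction and (a) replicon of residence, (b)
   composition quartile (Q1 vs Q4), (c) functional category, and (d)
   per-TU transcript abundance (Wilcoxon rank-sum on the first cistron's
   direction), using two-sided Fisher exact tests with Bonferroni
   correction where families of tests arise.

Every stage is exercised end to end on synthetic data with known ground
truth; the generator is first-class, tested code.

## Coordinate and counting conventions

* Internally all intervals are **0-based half-open**; conversions to GFF3 /
  TSS-table convention (1-based inclusive) and BED (0-based half-open)
  happen only in the readers and writers.
* A TU's 5′ end is its `start` on the plus strand and `end − 1` on the
  minus strand; refinement never touches the 3′ coordinate, strand or
  replicon.
* Codon metrics use the CDS in frame 0; stop codons and codons containing
  ambiguous bases are excluded from all counts. CDS whose length is not a
  multiple of 3 are skipped with a warning; an internal stop truncates
  counting at the stop, with a warning. AT content is computed on the
  annotated gene span on the reference strand (it is strand-invariant), with
  ambiguous bases excluded from numerator and denominator.
* The rare-codon threshold is a **strict** inequality (a codon at exactly
  0.100 synonymous usage is not rare). Single-codon families (Met, Trp)
  can never be rare; families never observed are excluded from the rare set
  rather than being declared all-rare. Start codons are counted as ordinary
  sense codons.
* The two-sided Fisher *p* is the point-probability sum — all tables with
  the observed margins whose probability is at most that of the observed
  table, with the `1 + 1e-7` relative inclusion tolerance used by mainstream
  exact-test implementations. The reported odds ratio is the sample odds
  ratio, flagged as such.

## TSS-to-TU matching and refinement policies

The matching rule is deliberately explicit because annotation pipelines
rarely publish one:

* A TSS that carries a gene id is routed through that gene's TU; this
  mirrors upstream TSS-calling pipelines that already assign genes, and it
  prevents an orphan gene's TSS from capturing a neighbouring TU. A
  gene-less TSS falls back to positional matching: the nearest same-strand
  TU whose 5′ end lies within `max_distance_bp` (default 500, generously
  covering the >100 bp adjustment tail) downstream of the TSS, or that
  contains it.
* A TSS strictly downstream of the first cistron's translation start is
  *internal*. When several non-internal TSSs match one TU, the one nearest
  the annotated 5′ end wins; ties go to the more upstream TSS (minimal
  perturbation, deterministic output).
* Internal-TSS shortening replaces the TU with the interval from the
  internal TSS to the old 3′ end. What happens to the upstream cistrons is
  genuinely ambiguous in practice; the default discards them (each loss is
  logged in the adjustment ledger), and `keep_upstream_remainder = TRUE`
  retains them as a residual unit with id suffix `_up`. Note the two modes
  trade different invariants: the keep mode conserves every gene in exactly
  one unit and makes refinement idempotent even with internal TSSs; the
  discard mode reproduces the stricter reading of "shortened to the primary
  TSS position" but a second refinement pass will re-house the discarded
  first cistron as an orphan unit.
* A refinement that would create an empty interval is refused, not clamped,
  and noted in the ledger.

The adjustment report tallies: TUs 5′-adjusted (with the signed adjustment,
positive = extension), the median absolute adjustment over adjusted TUs
only, adjustments >100 bp, internal shortenings, and orphan units added.

## Promoter windows

Windows span the genomic interval from 50 bp before to 10 bp after the TSS
(61 nt); minus-strand windows are reverse-complemented so the TSS-proximal
end is 3′-most, which is what motif finders expect when searching the given
strand only. Windows that would run past a replicon end are dropped and
counted, never clamped — motif discovery tools assume equal-length input.

## The synthetic study

`synthetic_config()` encodes the study conditions the generator emulates.
Defaults were chosen once, to scale the real study's structure down to a
size where the full battery runs in seconds, and are not tuned per run:

* **Genome**: a 370 kb native main replicon (270 genes) plus a 48 kb
  foreign replicon (30 genes, 10% of genes — laterally acquired genes are a
  minority, which is essential: with a large foreign share its preferred
  codons would no longer be rare *genome-wide*). Native codon usage prefers
  G/C-ending codons (weight $e^{2.2\,\mathrm{GC}}$ per codon, normalised
  within each synonymous family), the foreign regime prefers A/T-rich
  codons ($e^{2.0\,\mathrm{AT}}$), concentrating well over half its mass on
  codons rare under the native regime. Intergenic AT is 0.35 (native) and
  0.48 (foreign). Every CDS is in frame with an ATG start, no internal
  stop, and one stop codon; genes never overlap.
* **TU map and TSS table**: consecutive same-strand genes form operons
  (boundary probability 1/3 between same-strand neighbours, giving ~200
  TUs for 300 genes); the true primary TSS sits 10–60 bp upstream of the
  first cistron. Annotated 5′ ends are displaced by a two-regime offset:
  zero with probability 0.30, otherwise 1 + Geometric(mean 6) bp, with a 9%
  atom of >100 bp offsets (101 + Geometric(mean 50)); 80% of displacements
  put the annotation downstream of the true TSS so refinement extends the
  unit. These choices reproduce the real map's two-regime shape (median
  adjustment 5 bp with a substantial >100 bp tail, mostly extensions); the
  true per-unit offset distribution is not published, so beyond those
  anchors the defaults are modelling choices, not claims. Two multi-gene
  TUs receive an internal primary TSS at a downstream cistron start; five
  single-gene TUs are dropped from the map (orphan genes) but keep their
  TSS.
* **DE model**: the true log2 fold change is
  $N(0, 1.2) + \beta_\mathrm{rare}\,f_\mathrm{rare} + \beta_\mathrm{AT}(\mathrm{AT}-\overline{\mathrm{AT}}) + \mathrm{replicon} + \mathrm{category}$
  with $\beta_\mathrm{rare} = \beta_\mathrm{AT} = -10$, a −1 shift for the
  foreign replicon and a −2.5 shift for the prophage-like category (a
  contiguous 15-gene block on the main replicon). Genes with |true lfc| >
  1.2 are significant; 1% of null genes receive a false-positive adjusted
  *p* (the `alpha` injection rate). This yields ~42% misregulated genes,
  near the 38% of the real study. Per-TU abundance is log-normal (log2
  mean 8, sd 1.5) with a +2 log2 shift for TUs whose first cistron is truly
  down; two replicate TPM columns each sum to $10^6$.
* **Effect sizes are amplified relative to the real data.** At 300 genes a
  subtle real-scale effect is statistically invisible; the defaults were
  calibrated (once, by oracle power runs at three candidate levels) so the
  planted signals are recovered in ≥95% of seeds while the null
  configuration (all planted effects zero) fires in ≤5%. Passing tests
  therefore demonstrate correct recovery of planted structure at this
  scale, not sensitivity to effects as weak as the real ones.

Determinism: each generator stage derives its stream from the configured
seed (`seed`, `seed+1`, `seed+2` for genome, TU/TSS, DE), so a stage is
reproducible regardless of call order, and the caller's RNG state is left
untouched. Identical configuration and seed give byte-identical output
files.

What the generator does **not** emulate: read-level noise and mapping
artefacts, library-prep strand biases, dispersion estimation (adjusted
p-values are assigned from the truth model, since only direction and
significance feed the downstream statistics), operonic correlation of DE,
and real *H. volcanii* sequence content.

## Statistical constructions

* **Replicon contrasts.** For each non-reference replicon and each
  direction, the default 2×2 table is (direction, not-direction) ×
  (replicon, reference) among detected genes — the most direct reading of a
  test "compared to the main chromosome". The alternative construction
  (direction vs opposite direction) is also provided; note it produces one
  table per replicon, shared by both directions, so per-direction
  exclusivity of significance calls is only meaningful under the default
  construction. The chromosomally integrated plasmid is excluded from the
  reference by treating it as its own replicon in the input table.
* **Quartile contrasts.** Genes are ordered by the metric with ties broken
  by gene id (deterministic); Q1 and Q4 are the bottom and top
  $\lfloor n/4\rfloor$ genes. The table is (Q4, Q1) × (direction,
  not-direction).
* **Category enrichment.** Per category and direction, (in-category,
  out-of-category) × (direction, not-direction); uncategorised genes count
  in the out-of-category margin. Bonferroni multiplicity is the number of
  categories times the number of directions actually tested, and `m` is
  always reported with the results rather than assumed.
* **Missing adjusted p-values** classify as `ns` and stay in every
  denominator, keeping "detected" totals honest.
* **Abundance contrast.** Per-TU abundance is the geometric mean of the
  replicate TPM columns; each TU is labelled by the DE direction of its
  first cistron; up vs down log-abundances are compared by two-sided
  Wilcoxon rank-sum (normal approximation; abundances are continuous).

## Numerical and degenerate-input choices

* Fisher tables with a zero margin return *p* = 1 with a warning rather
  than erroring — degenerate margins are expected when a category swallows
  every gene.
* Zero sense codons give a missing rare-codon frequency, never 0.
* Empty intervals error in AT content; empty groups error in the abundance
  contrast; a region summary of an empty gene set returns zeros.
* The Fisher implementation is checked against exhaustive enumeration of
  all 2×2 tables with total ≤ 40 to 10⁻¹² in the test suite, and against an
  independent library implementation on random tables.

## Problem sizes used by the test suite

Property suites run the generator at 115 genes (fast loops) or the default
300 genes (power and recovery checks): TU 5′-recovery over 50 seeds,
planted-effect and null quartile contrasts over 100 seeds each, and
monotonicity of the recovered odds ratio over three effect levels × 50
seeds. These sizes were chosen so the entire suite completes in about two
minutes on a laptop while keeping binomial counting bounds meaningful.

## Known limitations

* The refinement assumes primary TSSs; secondary/antisense TSS
  classification is upstream of this package.
* Gene–TU membership for loaded (file-based) maps is recomputed by
  same-strand overlap, largest overlap winning; pathological overlapping
  annotations may re-house a gene differently from the source annotation.
* The DE generator plants independent per-gene effects; it cannot be used
  to study operon-level correlation of differential expression.
* The category labels are plain strings supplied with the annotation;
  there is no ontology handling.
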