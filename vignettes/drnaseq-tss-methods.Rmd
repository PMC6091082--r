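---
title: "Methods: TSS calling, classification and differential expression from dRNA-Seq 5'-end data"
author: "drnatss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS calling, classification and differential expression from dRNA-Seq 5'-end data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drnatss)
```

## The measurement and the model

Differential RNA-Seq (dRNA-Seq) distinguishes true transcription initiation
events from RNA processing and degradation products by sequencing two
libraries per sample. The *primary* library is treated with terminator
5'-phosphate-dependent exonuclease (TEX), which degrades processed
5'-monophosphate RNAs and thereby enriches primary transcripts that carry a
5'-triphosphate. The *minus* library is left untreated and serves as a
negative control reporting all 5' ends. A genomic position where the primary
libraries consistently accumulate many more read 5' ends than the minus
libraries is a transcription start site (TSS).

`drnatss` implements this analysis for bacterial (here, cyanobacterial)
genomes across four growth conditions — control (CT), dark (DK), high light
(HL) and high temperature (HT) — with two replicates per condition and
library type, which is the design the package's defaults assume.

## TSS calling

The caller works position by position on strand-specific 5'-end count
tracks. With per-replicate primary counts $p_1,\dots,p_r$ and minus counts
$m_1,\dots,m_r$, the enrichment at a position is the pseudocounted ratio

$$E = \frac{\sum_i p_i + c}{\sum_i m_i + c}, \qquad c = 1,$$

and a position is called in a condition when (a) every replicate has a
primary count of at least `min_primary_count_per_replicate` (default 10) and
(b) $E \ge$ `min_enrichment` (default 2). Requiring each replicate
separately, rather than the sum, is what makes the criterion replicate-aware:
a single aberrant library cannot create a TSS. Runs of called positions
closer than `cluster_window` (default 3 bp) collapse to the position with the
largest summed primary count; exact ties go to the most upstream position
relative to the strand, because a TSS is the 5' boundary of a transcript and
determinism is required. The published analysis this package re-implements
delegates its calling step to an external replicate-assisted
background-subtraction tool; the interface here deliberately isolates the
enrichment rule so an alternative caller could drop in behind
`call_condition_tss()`.

The per-condition candidate sets are merged by position into a master table,
and a TSS counts as *active* in a condition when its raw primary counts
summed over that condition's replicates reach `min_raw_reads_activity`
(default 300 reads). The threshold is applied to raw, un-normalized counts;
we read the activity rule's "at one of the libraries" as the per-condition
replicate sum, which is the more conservative of the two readings (a single
library would need the full 300 on its own otherwise). TSSs active in no
condition are dropped from all downstream statistics.

## Positional classification

Each master TSS gets exactly one class, evaluated against the annotation in
the fixed precedence order gTSS > iTSS > aTSS > nTSS:

* **gTSS** — same strand, at or within 200 nt upstream (`upstream_window`)
  of a protein-coding gene start. Upstream distance is measured strand-aware
  from the annotated start coordinate (gene `start` on +, `end` on −);
  distance 0 counts. A TSS inside gene A that is also within the window
  upstream of gene B is the gTSS of B — reads initiating there run into B.
* **iTSS** — inside a protein-coding gene on the same strand.
* **aTSS** — inside, or within 50 nt (`antisense_flank`) of either end of,
  any annotated gene on the opposite strand.
* **nTSS** — everything else: intergenic TSSs and TSSs in front of
  non-coding features (ncRNA, rRNA, tRNA). For bookkeeping the nearest such
  downstream feature within the upstream window is recorded as the
  associated gene, which is what later drives the rRNA/tRNA exclusion.

The precedence order is a design choice: the published counts show that each
TSS carries exactly one label and that the intergenic class is the explicit
fallback, but the resolution order among overlapping rules is not stated.
Putting gTSS first reflects the biological priority of mRNA starts; both
window parameters are configurable for sensitivity analysis. The test suite
checks the vectorized classifier against an independent brute-force
enumerator (every gene × every rule, scalar logic) on thousands of
positions.

## 5'-UTRs, leaderless transcripts and start-codon re-annotation

For gTSSs the 5'-UTR length is the strand-aware distance from the TSS to the
first base of the start codon; 0 marks a leaderless-transcript candidate.
The summary reports the median — for an even count, the lower of the two
central values, so the reported median is always an observed length — and a
histogram in fixed 10-nt bins.

gTSSs closer than 10 nt to the start codon (strict inequality) are evaluated
against protein-homology evidence, consumed as a precomputed table because
the underlying homolog search runs against external databases: strictly more
than 45% of homologs sharing the annotated start supports a *leaderless*
transcript; strictly more than 45% supporting a shorter protein proposes
*re-annotation* of the start codon. When both fractions exceed the cutoff
the call is reported as *ambiguous* with both fractions rather than silently
resolved, and when neither does, as *no evidence*.

## Differential TSS expression

Counts from the primary libraries only (the minus libraries are controls,
not expression measurements) are filtered — TSSs initiating rRNAs or tRNAs
are removed, and a TSS must reach 300 raw reads in at least one library —
then normalized with median-of-ratios size factors. For each contrast
against control (DK/CT, HL/CT, HT/CT) the package fits a simplified
negative-binomial Wald test of its own rather than wrapping an existing DE
package: per-TSS dispersions are estimated by the method of moments within
each condition, a dispersion trend $\alpha(\mu) = c_0 + c_1/\mu$ is fitted
across all TSSs, and each TSS's dispersion is shrunk toward the trend with
weight `trend_weight` (default 0.9). With two replicates per condition the
genewise moment estimate has roughly one degree of freedom, so nearly all
weight belongs on the trend; simulation during development showed that this
choice keeps the type-I error at the nominal level while lighter shrinkage
is visibly anticonservative. The installed DESeq2 serves as an independent
cross-check of the fold-change estimates in the test suite, never as the
implementation.

The Wald statistic tests
$\log_2\mathrm{FC} = \log_2\!\big((\bar\mu_T + 0.5)/(\bar\mu_C + 0.5)\big)$
with the delta-method variance
$\mathrm{Var}(\log \bar\mu_g) \approx (1/\bar\mu_g + \alpha)/n_g$ per group
(adjusted for size factors); the 0.5 pseudocount keeps fold changes finite at
zero counts. p values are Benjamini–Hochberg adjusted within each contrast,
and a TSS is differentially expressed (DET) when $|\log_2\mathrm{FC}| \ge 1$
and adjusted $p \le 0.01$ — both thresholds sharp, the fold-change bound
inclusive.

## The synthetic fixture generator

`sim_config()` + `simulate_drnaseq()` generate a complete test bed with
planted ground truth. The generator emulates exactly the structure the
analysis assumes:

* a random replicon (default 50 kb) with non-overlapping stranded genes
  (default 40, lengths 400–1200 bp) including one rRNA, one tRNA and one
  ncRNA so the exclusion rules have work to do;
* planted TSSs per class (default 30/10/15/5 for gTSS/iTSS/aTSS/nTSS),
  placed so that re-classifying the planted coordinates reproduces the
  planted class for every record — gTSSs anchored to CDS starts with 5'-UTR
  lengths drawn from a rounded log-normal with median 52 nt, the others
  sampled from an exhaustive class map of every genomic position;
* negative-binomial 5'-end counts at planted TSSs (default mean 500,
  dispersion 0.05) with condition-dependent means following planted log2
  fold changes relative to CT (default: 30% of TSSs get a ±2 effect in one
  random non-control condition), attenuated 10-fold (`tex_enrichment`) in
  the minus libraries;
* a position-wise Poisson background (default rate 0.05 per position) in
  both library types, modelling processed/degraded 5' ends. The pooled,
  rRNA-depleted reference library of the original experimental design is
  not simulated; no stage implemented here consumes it.

The planted initiation nucleotide is written into the genome sequence at
each TSS (52.3% A, 35.6% G by default, matching the purine preference of
cyanobacterial promoters). Seeds are mandatory and drive independent
sub-streams per stage, so identical configurations produce byte-identical
fixture bundles.

What the generator does **not** emulate: mapping artifacts, positional
count autocorrelation (reads smearing around a TSS), rRNA contamination
profiles, operon structure, or library-size imbalance beyond what the NB
noise produces. Passing recovery tests therefore demonstrates the
correctness of the pipeline's logic under its own model assumptions — not
performance on real libraries, where the enrichment and activity thresholds
would interact with much messier backgrounds.

## Numerical choices and degenerate inputs

* Internal coordinates are 1-based inclusive everywhere; bedGraph's 0-based
  half-open intervals are converted at the I/O boundary, GFF3 passes through
  unchanged.
* Median-of-ratios size factors need at least one zero-free row; the error
  message points to the pseudocount fallback rather than guessing one.
* The dispersion floor is 1e-8; fold changes use a 0.5 pseudocount on
  normalized means.
* Clustering ties break to the most upstream position relative to the
  strand; ranking ties order stably by TSS id; all writers sort by
  (replicon, position, strand), so every output is deterministic.
* Degenerate inputs fail loudly: genes that cannot be placed without
  overlap, classes with no eligible genomic space, unstranded annotation
  features, overlapping bedGraph intervals, negative counts, single-replicate
  contrasts.

## Problem sizes used in the checks

The bundled tests run the full pipeline on the default 50 kb / 60-TSS
fixture (seconds per run) and the statistical checks on 500-TSS count
matrices; the reporting script uses an additional 300 kb fixture with 520
planted TSSs so that sample medians and base-composition percentages are
stable. These sizes were chosen so the whole suite exercises every stage,
including end-to-end determinism, while remaining quick enough to run on
every change.

## Known limitations

* The enrichment caller is a transparent stand-in for the original
  replicate-assisted background-subtraction algorithm, which is not restated
  in the source publication; parameters are documented and the module
  boundary allows a faithful re-implementation to replace it.
* The NB test trades DESeq2's empirical-Bayes machinery for a simpler
  trend-shrunk moments estimator; p values agree in calibration, not
  numerically.
* Whether the 45% homolog rule counts all hits or the best hit per species
  is unspecified upstream; the package consumes whatever fractions the
  evidence table provides.
* Condition labels are fixed to the four-condition design; other designs
  work for calling/classification but the DE contrasts expect a CT
  reference.
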