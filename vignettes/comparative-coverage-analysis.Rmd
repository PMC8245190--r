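---
title: "Comparative coverage analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative coverage analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Songbird germ cells carry a germline-restricted chromosome (GRC) that is
eliminated from somatic tissue early in development. A germline (testis)
assembly therefore mixes two kinds of sequence: the diploid A-chromosome
complement shared by all cells, and GRC-derived contigs present only in
the germline. Because the GRC is largely patched together from copies of
A-chromosome sequence, reads from one compartment routinely mismap onto
paralogs in the other, which defeats naive subtractive approaches. The
same structure appears wherever cells with and without a chromosome can
be sequenced separately — B chromosomes, or Y/W discovery from
male/female sibling sequencing.

`grcoverage` detects lineage-restricted contigs by *comparative coverage
analysis*: replicated germline and somatic DNA read sets are mapped to
the same germline assembly, each contig is treated as a single
intronless transcript, per-contig coverage is expressed as FPKM
(fragments per kilobase of sequence per million mapped fragments), and
the germline-to-soma FPKM ratio is tested for each contig across
replicates.

## The model

For contig $c$ in sample $j$ with fragment count $k_{cj}$, length $L_c$
(bp) and library size $N_j$ (mapped fragments),

$$\mathrm{FPKM}_{cj} = \frac{k_{cj} \cdot 10^9}{L_c \, N_j}.$$

Dividing by $N_j$ removes library-depth differences between replicates
— duplicating every read of a library leaves its FPKM column
bit-identical, an invariant the test suite asserts literally. The
per-contig effect size is the linear ratio of group means with a small
pseudocount $\varepsilon$ (default 0.01 FPKM) guarding empty
denominators:

$$\mathrm{FC}_c = \frac{\overline{\mathrm{FPKM}}^{\,\mathrm{germ}}_c +
\varepsilon}{\overline{\mathrm{FPKM}}^{\,\mathrm{soma}}_c + \varepsilon}.$$

Taking a ratio of germline to somatic coverage normalises
simultaneously for read mismapping between paralogs (both tissues
mismap onto the same targets) and for copy-number variation shared by
both tissues.

Significance is assessed per contig by an ordinary-least-squares F-test
of the two-group model against the intercept-only model on
$\log_2(\mathrm{FPKM}+1)$ values (df 1 and $n-2$); this equals the
squared pooled-variance t statistic, and the suite verifies
$F = t^2$ to $10^{-9}$ relative tolerance. p-values are adjusted by
Benjamini–Hochberg across all tested contigs of a run as a single
family (`stats::p.adjust`; a hand-rolled step-up serves as the test
oracle). The log transform matches the default behaviour of the
transcriptomic tooling this method descends from, while the *reported*
fold change stays on the linear scale, where the diploid-plus-one-allele
expectation is exactly $3{:}2 = 1.5$; both are emitted.

High-confidence calls require all three of

* fold change $\ge$ 2 (inclusive — the volcano plot's vertical line),
* q-value $<$ 0.05 (strict),
* contig length $>$ 2,000 bp (strict).

Contigs with zero counts in every sample are excluded from the test
family and flagged untested (fold change $\varepsilon/\varepsilon = 1$).
If either group has fewer than two replicates the test path refuses to
run; with two replicates it runs but warns, since at least three
replicate animals are needed for stable q-values.

## Three categories of restricted sequence, and copy number

Called and near-called contigs are interpreted in three classes:

1. **high-copy** — multicopy GRC sequence collapsed into one assembly
   contig; the germline numerator drives the fold change.
2. **low-copy divergent** — single or low copy, diverged from every
   A-chromosome paralog; somatic reads barely map, so the near-zero
   denominator drives the fold change (somatic mean FPKM below 1 by
   default).
3. **low-copy similar** — one germline allele nearly identical to its
   A paralog. The contig attracts two somatic allele's reads and three
   germline allele's reads, so the expected ratio is only 3:2 and the
   2-fold threshold is *not* met. These are reported when the fold
   change falls in a configurable band (default $[1.2, 2.0)$, bracketing
   1.5 below the calling cutoff) at significant q.

Copy number is estimated from germline depth alone. The baseline is the
length-weighted median of per-contig mean germline depth, averaged over
replicates, divided by the background ploidy (default 2). The median is
dominated by the diploid A-chromosome mass, so after the ploidy division
the baseline estimates the sequencing depth of one haploid copy, and
`depth / baseline` reads directly in haploid copies: a diploid A contig
sits near 2, a collapsed 8-copy contig near 8. (Reporting in
diploid-equivalents instead would halve every estimate and make a
collapsed 8-copy contig read as 4; the haploid convention is what makes
the copy-number threshold between classes 1 and 2 — two copies — and
the size estimate below interpretable.) Called contigs then contribute
$L_c \cdot \max(1, \widehat{cn}_c)$ to the total restricted-sequence
length: the floor encodes that a detected contig exists at least once,
and the multiplier compensates for assembly collapse of multicopy
sequence. This estimator is a documented, configurable reconstruction
of the published size-estimation idea; it is not claimed to reproduce
any particular published total.

## The synthetic data generator

Real germline/soma read sets are multi-gigabyte downloads, so the
package ships a generator that reproduces the *statistical structure*
the method relies on, end to end:

* a diploid A-chromosome background of i.i.d. uniform ACGT contigs,
  present as two copies in both tissues;
* class-1 contigs: one assembly contig, 3–10 germline copies (drawn
  uniformly), absent from soma — modelling collapsed multicopy GRC;
* class-2 contigs: one germline copy, 5% substitution divergence from a
  randomly chosen A paralog, absent from soma;
* class-3 alleles: one extra germline copy at 0.2% divergence from its
  A paralog, **not** added to the assembly — their reads collapse onto
  the paralog contig, producing the 3:2 signal;
* single-end reads of fixed length (default 100 bp), Poisson read
  counts per copy with mean `depth * L / read_length`, uniform start
  positions, either strand with probability 1/2, substitution errors at
  0.2% per base, fixed quality.

Read counts are Poisson rather than deterministic so that replicates
carry genuine sampling variance; with deterministic counts the
within-group variance would be an artifact of mapping noise only and
the F-test would be vacuous.

Divergence defaults (5% for class 2, 0.2% for class 3) are
placeholders chosen to separate the two regimes — real paralog
divergence on the GRC is not quantified — and are exposed in
`simulation_config()`.

A deterministic best-hit mapper is included so the pipeline needs no
external aligner: exact 31-mer seeding (non-overlapping seeds plus the
final window, both strands), full-read Hamming extension, and a single
primary alignment per read with ties broken by lowest contig index,
then leftmost position, then forward strand. Substitution-only
divergence is what makes Hamming scoring sufficient; indel realism
would require full alignment machinery without changing what the
pipeline is being tested for. For error-free reads every seed is exact,
so the seeded search provably reproduces an exhaustive all-positions
Hamming scan (asserted in the suite); with sequencing errors a read
whose every seed covers an error can be missed or mapped suboptimally,
exactly as with any seeded aligner.

What the generator does *not* model: indels and structural variation,
GC and coverage bias, base-quality profiles, paired ends, adapter
artifacts, and assembly errors. Passing tests therefore demonstrate
correctness of the statistics and the detection logic under the
method's own assumptions, not robustness to every artifact of real
sequencing data.

## Numerical and design choices

* Coordinates are 1-based inclusive externally (GFF3, SAM); internal
  arithmetic is 0-based half-open in the C++ mapper.
* All contigs are annotated on the `+` strand; DNA coverage is
  strand-agnostic. `gene_id = transcript_id = contig_id`, so downstream
  tables key on contig id alone.
* `N` bases count toward contig length (coverage denominators use the
  full length); no masking rule is applied.
* Counting is primary-alignment-only (neither secondary nor
  supplementary), emulating a best-hit aligner's single reported
  alignment; no duplicate marking; MAPQ filter defaults to 0 (off).
  Aligned length sums reference-consuming `M`/`=`/`X` operations;
  deletions can be included via a flag.
* Fragments equal reads: the pipeline is single-end by contract and
  refuses paired flags.
* A contig with total sum of squares below $10^{-12}$ across samples
  (all values equal) gets $F = 0$, $p = 1$ rather than 0/0.
* The library-size normalisation inherent in FPKM means that extra
  germline-only read mass deflates every germline FPKM slightly; with
  the default simulation the restricted fraction is a few percent and
  the background fold change sits just below 1. The generator warns
  when restricted contigs exceed 10% of assembly length, where this
  distortion stops being negligible.

## Problem sizes used in the checks

The shipped checks run, per seed, 120 A contigs of 1.5–3.5 kb with 3+2+2
restricted contigs, 4+4 replicates at 20× per haploid copy (roughly a
million 100 bp reads per dataset), repeated over 20 seeds for the
recovery and replicate-power studies; the 3:2 ratio check uses 240
diploid contigs with 8 collapsed alleles at 20×. These sizes keep each
study in the minutes range on a single core while leaving the Poisson
sampling error on the quantities being checked well inside the
tolerances asserted.

## Known limitations

* Single-copy restricted sequence nearly identical to its paralog
  (class 3) is reported from a fold-change band, not called with high
  confidence; SNP-level methods are the appropriate complement.
* The copy-number baseline assumes the assembly is dominated by
  single-copy diploid sequence; a genome where collapsed repeats carry
  most of the length would need a different baseline.
* The internal mapper is for simulation-scale data; for real read sets,
  map with a production best-hit aligner and feed the SAM/BAM files to
  `count_sample()` / `run_pipeline()`.
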